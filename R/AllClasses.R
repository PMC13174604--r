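## Central S4 containers. Sequence payloads live in Biostrings objects,
## count data in a SummarizedExperiment subclass, per-construct results in
## DataFrame subclasses, mirroring standard Bioconductor layering.

#' ConstructLibrary: a reporter 5' UTR library
#'
#' Holds the candidate 5' UTR sequences of a pooled reporter library as a
#' named [Biostrings::DNAStringSet], one record per construct, together with
#' per-construct roles (`family`: `positive_control`, `negative_control`,
#' `spike_in`, or `candidate:<group>`) in the element metadata, and the three
#' fixed library constants: the A-cap class barcode, the G-cap class barcode,
#' and the common adapter separating the UTR from the reporter ORF.
#'
#' RNA input (U) is accepted by the constructors and stored as DNA (T);
#' coordinates throughout the package are 1-based closed intervals.
#'
#' @slot sequences [Biostrings::DNAStringSet] named by `construct_id`; mcols
#'   carry at least `family` and `is_spike_in`, and design columns (`rule`,
#'   `interval`, `wildtype_id`) for designed variant libraries.
#' @slot acapBarcode,gcapBarcode single DNA strings of equal length that
#'   distinguish A-cap from G-cap reads.
#' @slot commonAdapter single DNA string; 3' boundary of the UTR insert.
#'
#' @seealso [loadConstructs()], [designScanningMutants()]
#' @export
setClass("ConstructLibrary",
  slots = c(
    sequences     = "DNAStringSet",
    acapBarcode   = "character",
    gcapBarcode   = "character",
    commonAdapter = "character"
  )
)

setValidity("ConstructLibrary", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    msg <- c(msg, "every construct needs a non-empty construct_id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    msg <- c(msg, paste0("duplicate construct_id: ",
                         paste(unique(dup), collapse = ", ")))
  if (length(object@sequences) && any(Biostrings::width(object@sequences) == 0))
    msg <- c(msg, "empty utr_sequence not allowed")
  af <- Biostrings::alphabetFrequency(object@sequences, baseOnly = TRUE)
  if (length(object@sequences) && any(af[, "other"] > 0))
    msg <- c(msg, "sequences must be over {A,C,G,T} (IUPAC ambiguity codes rejected)")
  md <- S4Vectors::mcols(object@sequences)
  if (is.null(md) || !all(c("family", "is_spike_in") %in% colnames(md))) {
    msg <- c(msg, "mcols must carry 'family' and 'is_spike_in'")
  } else if (!identical(unname(md$is_spike_in), unname(md$family == "spike_in"))) {
    msg <- c(msg, "is_spike_in must hold exactly when family == 'spike_in'")
  }
  for (s in c("acapBarcode", "gcapBarcode", "commonAdapter"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, paste0(s, " must be a single string"))
  if (length(object@acapBarcode) == 1L && length(object@gcapBarcode) == 1L) {
    if (identical(object@acapBarcode, object@gcapBarcode))
      msg <- c(msg, "acapBarcode and gcapBarcode must differ")
    if (nchar(object@acapBarcode) != nchar(object@gcapBarcode))
      msg <- c(msg, "acapBarcode and gcapBarcode must have equal length")
  }
  if (length(msg)) msg else TRUE
})

#' PairedRegion: one base-paired helix or pseudoknot stem
#'
#' A named pair of equal-length, non-overlapping 1-based closed intervals on
#' a wildtype sequence; the left interval lies strictly upstream of the
#' right. Used to design helix disruption (L, R) and compensatory (C)
#' mutants and to anchor rescue analyses.
#'
#' @slot name helix label, e.g. `"PKI"`.
#' @slot left,right integer vectors `c(start, end)`.
#' @export
setClass("PairedRegion",
  slots = c(name = "character", left = "integer", right = "integer")
)

setValidity("PairedRegion", function(object) {
  msg <- character()
  if (length(object@left) != 2L || length(object@right) != 2L)
    msg <- c(msg, "left and right must each be c(start, end)")
  else {
    if (object@left[1] < 1L || object@left[1] > object@left[2])
      msg <- c(msg, "left interval invalid (need 1 <= start <= end)")
    if (object@right[1] < 1L || object@right[1] > object@right[2])
      msg <- c(msg, "right interval invalid (need 1 <= start <= end)")
    if (object@left[2] >= object@right[1])
      msg <- c(msg, "left interval must end strictly before right begins")
    if (diff(object@left) != diff(object@right))
      msg <- c(msg, "left and right intervals must have equal length")
  }
  if (length(msg)) msg else TRUE
})

#' SimulationTruth: ground truth for a simulated reporter experiment
#'
#' Per (construct, cap class) input abundances and true translation
#' efficiencies, plus the global simulation parameters (substitution error
#' rate, UMI length weights, stagger range, spike-in fractions, read depth,
#' PCR duplication mean). Produced by [buildTruth()], consumed by
#' [simulateReads()]; deterministic given its seed.
#'
#' @slot truth `DataFrame` with columns `construct_id`, `cap_class`,
#'   `input_abundance`, `true_te`.
#' @slot params list of global simulator parameters.
#' @slot seed integer seed the truth was drawn with.
#' @export
setClass("SimulationTruth",
  slots = c(truth = "DFrame", params = "list", seed = "integer")
)

setValidity("SimulationTruth", function(object) {
  msg <- character()
  need <- c("construct_id", "cap_class", "input_abundance", "true_te")
  if (!all(need %in% colnames(object@truth)))
    return(paste("truth must have columns:", paste(need, collapse = ", ")))
  if (any(object@truth$input_abundance < 0))
    msg <- c(msg, "input_abundance must be nonnegative")
  if (sum(object@truth$input_abundance) <= 0)
    msg <- c(msg, "input_abundance must sum to a positive value")
  if (any(object@truth$true_te <= 0))
    msg <- c(msg, "true_te must be positive")
  if (!all(object@truth$cap_class %in% c("a_cap", "g_cap")))
    msg <- c(msg, "cap_class must be a_cap or g_cap")
  eps <- object@params$epsilon
  if (!is.null(eps) && (eps < 0 || eps > 0.1))
    msg <- c(msg, "epsilon must lie in [0, 0.1]")
  sf <- object@params$spikeFractions
  if (length(sf) == 3L && any(diff(sf) <= 0))
    msg <- c(msg, "spikeFractions must be strictly increasing (serial dilution)")
  if (length(msg)) msg else TRUE
})

#' CapCounts: unique-UMI counts per construct, cap class and sample
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one row per
#' (construct, cap class) and one column per sequencing sample. The single
#' `counts` assay holds unique-UMI molecule counts (never raw reads).
#' `rowData` carries `construct_id` and `cap_class`; `colData` carries
#' `sample_id`, `role` (`input`/`IP`), `condition` (`control`/`stress`),
#' `bio_rep` and `tech_rep`.
#'
#' @export
setClass("CapCounts", contains = "SummarizedExperiment")

setValidity("CapCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("CapCounts needs a 'counts' assay")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msg <- c(msg, "counts must be nonnegative integers (unique-UMI molecules)")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("construct_id", "cap_class") %in% colnames(rd)))
    msg <- c(msg, "rowData needs construct_id and cap_class")
  else if (!all(rd$cap_class %in% c("a_cap", "g_cap")))
    msg <- c(msg, "cap_class must be a_cap or g_cap")
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "role", "condition", "bio_rep", "tech_rep")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData needs:", paste(need, collapse = ", ")))
  else {
    if (!all(cd$role %in% c("input", "IP")))
      msg <- c(msg, "role must be 'input' or 'IP'")
    if (anyDuplicated(cd$sample_id))
      msg <- c(msg, "sample_id must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' TETable: per-construct translation efficiencies
#'
#' A `DataFrame` subclass with one row per retained or filtered
#' (construct, cap class): raw combined counts, RPM under whole-sample
#' normalization, linear and log2 TE, and the two bookkeeping flags
#' `filtered_low_input` (construct dropped for sparse input; TE columns NA)
#' and `ip_pseudocounted` (zero IP count replaced by the pseudocount).
#' `metadata()` records `condition`, `pseudocount` and `min_input`.
#'
#' @export
setClass("TETable", contains = "DFrame")

setValidity("TETable", function(object) {
  need <- c("construct_id", "cap_class", "input_count", "ip_count",
            "input_rpm", "ip_rpm", "te_linear", "log2_te",
            "filtered_low_input", "ip_pseudocounted")
  if (!all(need %in% colnames(object)))
    return(paste("TETable needs columns:", paste(need, collapse = ", ")))
  keep <- !object$filtered_low_input
  msg <- character()
  if (any(keep) && any(!is.finite(object$te_linear[keep]) |
                       object$te_linear[keep] <= 0))
    msg <- c(msg, "retained rows must have te_linear > 0")
  if (any(keep)) {
    d <- abs(object$log2_te[keep] - log2(object$te_linear[keep]))
    if (any(d > 1e-8)) msg <- c(msg, "log2_te must equal log2(te_linear)")
  }
  if (any(!keep) && any(!is.na(object$te_linear[!keep])))
    msg <- c(msg, "filtered rows must carry no TE values")
  if (length(msg)) msg else TRUE
})

#' SpikeInSet: spike-in design and fitted normalization factors
#'
#' The three serially diluted G-cap spike-in constructs (designed relative
#' abundances 0.01 : 0.1 : 1 up to scale), and, after
#' [fitSpikeInFactors()], one multiplicative TE normalization factor per
#' condition (reference condition fixed at 1) with a per-condition linearity
#' R^2 of observed vs designed log input abundance.
#'
#' @slot spikeIds three construct ids, in increasing designed abundance.
#' @slot designedRelAbundance numeric(3), strictly increasing.
#' @slot factors named numeric, one per condition (empty before fitting).
#' @slot linearityR2 named numeric, one per condition.
#' @slot reference reference condition name (factor fixed at 1).
#' @export
setClass("SpikeInSet",
  slots = c(
    spikeIds             = "character",
    designedRelAbundance = "numeric",
    factors              = "numeric",
    linearityR2          = "numeric",
    reference            = "character"
  )
)

setValidity("SpikeInSet", function(object) {
  msg <- character()
  if (length(object@spikeIds) != 3L)
    msg <- c(msg, "exactly three spike-in constructs expected")
  if (length(object@designedRelAbundance) != 3L ||
      any(diff(object@designedRelAbundance) <= 0) ||
      any(object@designedRelAbundance <= 0))
    msg <- c(msg, "designedRelAbundance must be three strictly increasing positive values")
  if (length(object@factors)) {
    if (any(object@factors <= 0)) msg <- c(msg, "factors must be positive")
    if (length(object@reference) == 1L &&
        object@reference %in% names(object@factors) &&
        abs(object@factors[[object@reference]] - 1) > 1e-12)
      msg <- c(msg, "reference condition factor must equal 1")
  }
  if (length(msg)) msg else TRUE
})

#' SecondaryStructure: a dot-bracket RNA secondary structure
#'
#' A sequence with its dot-bracket structure string; round `()` brackets
#' hold the nested secondary structure and square/curly bracket classes
#' (`[]`, `{}`) annotate pseudoknotted stems. The derived base-pair list is
#' computed at construction and available via [basePairs()].
#'
#' @slot sequence nucleotide string (DNA alphabet; U mapped to T on input).
#' @slot dotbracket structure string of equal length over `.(){}[]`.
#' @slot pairs integer matrix, columns `i` < `j`, one row per base pair.
#' @export
setClass("SecondaryStructure",
  slots = c(sequence = "character", dotbracket = "character", pairs = "matrix")
)

setValidity("SecondaryStructure", function(object) {
  if (nchar(object@sequence) != nchar(object@dotbracket))
    return("sequence and dotbracket must have equal length")
  chars <- unique(strsplit(object@dotbracket, "")[[1]])
  if (length(setdiff(chars, c(".", "(", ")", "[", "]", "{", "}"))))
    return("dotbracket may only contain . ( ) [ ] { }")
  if (nrow(object@pairs) &&
      (any(object@pairs < 1) || any(object@pairs > nchar(object@sequence))))
    return("pair positions out of sequence bounds")
  TRUE
})
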