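## Synthetic paired-end read simulator. Every downstream stage of the
## pipeline is testable against the ground truth this module emits.
##
## Simulated library molecule (mate-1 orientation):
##
##   [stagger 0-6 N] [5' anchor] [cap adapter] [UTR] [common adapter]
##                                          [rc(RT anchor)] [rc(UMI 9-11)]
##
## Mate 1 is the first `readLength` bases of this fragment; mate 2 the first
## `readLength` bases of its reverse complement, so mate 2 begins with the
## UMI followed by the fixed 15-nt reporter-side RT anchor. The stagger is a
## PCR-primer artifact, so PCR duplicates of one molecule share the UMI but
## not the stagger.

#' Default read architecture
#'
#' The fixed constants of the assay's read structure: common adapter,
#' A-cap and G-cap class adapters, the mate-1 5' anchor (reverse complement
#' of the common adapter), the reporter-side RT anchor flanking the UMI,
#' and the read length.
#'
#' @param readLength sequencing read length (nt).
#' @return a named list of architecture constants.
#' @export
readArchitecture <- function(readLength = 150L) {
  list(
    common = .ADAPTERS$common, acap = .ADAPTERS$acap, gcap = .ADAPTERS$gcap,
    pair5 = .ADAPTERS$pair5, rtAnchor = .ADAPTERS$rtAnchor,
    readLength = as.integer(readLength),
    staggerRange = 0:6, umiLengths = 9:11
  )
}

#' Draw the ground truth for a simulated reporter experiment
#'
#' Assigns every (construct, cap class) an input abundance (log-normal
#' unless fixed) and a true translation efficiency (2^Uniform over
#' `teRange` unless fixed). Spike-in constructs are G-cap only; their
#' abundances follow the designed 1:10:100 serial dilution and together
#' make up `spikeFraction` of the pool, emulating spike-in lysate added to
#' 1% of each sample.
#'
#' @param library a [ConstructLibrary-class]; spike-ins are the records with
#'   family `spike_in` (in increasing designed abundance order).
#' @param config named list overriding defaults: `epsilon` (substitution
#'   error rate, default 0.001), `teRange` (log2 TE range, default
#'   `c(-5, 5)`), `fixedTE` (scalar or named linear TE vector), `fixedAbundance`
#'   (scalar or named vector), `abundanceSdlog` (default 1), `spikeRatio`
#'   (default `c(0.01, 0.1, 1)`), `spikeFraction` (default 0.01),
#'   `umiLengths`/`umiWeights` (default 9:11, uniform), `staggerRange`
#'   (default 0:6), `readsPerSample` (default 1e5), `duplicationMean`
#'   (default 1.5), `readLength` (default 150).
#' @param seed integer; the truth is deterministic given the seed.
#' @return a [SimulationTruth-class]
#' @export
buildTruth <- function(library, config = list(), seed = 1L) {
  if (!length(library)) stop("library has zero constructs")
  defaults <- list(
    epsilon = 0.001, teRange = c(-5, 5), fixedTE = NULL,
    fixedAbundance = NULL, abundanceSdlog = 1,
    spikeRatio = c(0.01, 0.1, 1), spikeFraction = 0.01,
    umiLengths = 9:11, umiWeights = c(1, 1, 1) / 3, staggerRange = 0:6,
    readsPerSample = 1e5L, duplicationMean = 1.5, readLength = 150L
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown simulator config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  set.seed(as.integer(seed))

  ids <- constructIds(library)
  spike <- isSpikeIn(library)
  spikeIds <- ids[spike]
  if (length(spikeIds) && length(spikeIds) != 3L)
    stop("expected 0 or 3 spike-in constructs, found ", length(spikeIds))

  ## one abundance per construct (A-cap and G-cap pools are co-transfected
  ## at equal composition)
  ab <- rlnorm(length(ids), meanlog = 0, sdlog = cfg$abundanceSdlog)
  names(ab) <- ids
  if (!is.null(cfg$fixedAbundance)) {
    fx <- cfg$fixedAbundance
    if (is.null(names(fx))) ab[] <- fx else ab[names(fx)] <- fx
  }
  if (length(spikeIds)) {
    ratio <- cfg$spikeRatio / sum(cfg$spikeRatio)
    rest <- sum(ab[!spike])
    ## spike-only library (the reference spike-in lysate itself): designed
    ## ratio directly; otherwise spikes make up spikeFraction of the pool
    ab[spikeIds] <- if (rest > 0)
      ratio * rest * cfg$spikeFraction / (1 - cfg$spikeFraction)
    else ratio
  }

  rows <- rbind(
    data.frame(construct_id = ids, cap_class = "a_cap",
               stringsAsFactors = FALSE)[!spike, ],
    data.frame(construct_id = ids, cap_class = "g_cap",
               stringsAsFactors = FALSE)
  )
  te <- 2 ^ runif(nrow(rows), cfg$teRange[1], cfg$teRange[2])
  names(te) <- NULL
  if (!is.null(cfg$fixedTE)) {
    fx <- cfg$fixedTE
    if (is.null(names(fx))) te[] <- fx
    else {
      hit <- rows$construct_id %in% names(fx)
      te[hit] <- fx[rows$construct_id[hit]]
    }
  }
  te[rows$construct_id %in% spikeIds] <- 1

  truth <- S4Vectors::DataFrame(
    construct_id = rows$construct_id, cap_class = rows$cap_class,
    input_abundance = unname(ab[rows$construct_id]), true_te = te
  )
  spikeFracs <- if (length(spikeIds))
    sort(unname(ab[spikeIds]) / sum(ab)) else numeric()
  params <- list(
    epsilon = cfg$epsilon, umiLengths = as.integer(cfg$umiLengths),
    umiWeights = cfg$umiWeights, staggerRange = as.integer(cfg$staggerRange),
    spikeFractions = spikeFracs, spikeIds = spikeIds,
    readsPerSample = as.integer(cfg$readsPerSample),
    duplicationMean = cfg$duplicationMean,
    readLength = as.integer(cfg$readLength)
  )
  new("SimulationTruth", truth = truth, params = params,
      seed = as.integer(seed))
}

#' @rdname SimulationTruth-class
#' @param x a `SimulationTruth`
#' @export
setMethod("truthTable", "SimulationTruth",
          function(x) as.data.frame(x@truth))

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", nrow(object@truth), "construct x cap-class rows\n")
  cat(sprintf("  epsilon = %g, duplication mean = %g, reads/sample = %d\n",
              object@params$epsilon, object@params$duplicationMean,
              object@params$readsPerSample))
  if (length(object@params$spikeFractions))
    cat("  spike fractions:",
        paste(signif(object@params$spikeFractions, 3), collapse = " : "), "\n")
})

#' Rescale true translation efficiencies
#'
#' Multiplies `true_te` by `factor` for the selected rows; used to impose
#' known global or class-specific effects (e.g. a uniform IP-efficiency drop
#' or a cap-class-specific stress response) on a simulated condition.
#'
#' @param truth a [SimulationTruth-class]
#' @param factor positive multiplier.
#' @param capClass restrict to `"a_cap"`/`"g_cap"` (default: both).
#' @param constructs restrict to these construct ids (default: all).
#' @param includeSpikeIns also scale spike-in rows (default TRUE: a global
#'   IP-efficiency change affects spikes too).
#' @return a modified [SimulationTruth-class]
#' @export
scaleTrueTE <- function(truth, factor, capClass = NULL, constructs = NULL,
                        includeSpikeIns = TRUE) {
  stopifnot(factor > 0)
  tt <- truth@truth
  sel <- rep(TRUE, nrow(tt))
  if (!is.null(capClass)) sel <- sel & tt$cap_class %in% capClass
  if (!is.null(constructs)) sel <- sel & tt$construct_id %in% constructs
  if (!includeSpikeIns) sel <- sel & !(tt$construct_id %in% truth@params$spikeIds)
  tt$true_te[sel] <- tt$true_te[sel] * factor
  initialize(truth, truth = tt)
}

## vectorized random UMIs of lengths 9-11
.randomUmis <- function(n, lengths, weights) {
  lens <- sample(lengths, n, replace = TRUE, prob = weights)
  maxlen <- max(lengths)
  mat <- matrix(sample(c("A", "C", "G", "T"), n * maxlen, replace = TRUE),
                nrow = n)
  full <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
  substr(full, 1L, lens)
}

.writeFastq <- function(seqs, ids, path) {
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(dss)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
}

#' Simulate a paired-end FASTQ sample with ground-truth sidecar
#'
#' Emits read pairs under the assay's read architecture. cDNA molecule
#' counts per (construct, cap class) are multinomial with weights
#' `input_abundance` (input samples) or `input_abundance * true_te` (IP
#' samples); each molecule receives a random 9-11 nt UMI and a geometric
#' number of PCR duplicate read pairs (mean `duplicationMean`), each with
#' its own 0-6 nt stagger; substitution errors are applied i.i.d. at rate
#' `epsilon`. Output is bit-identical for identical (truth, seed).
#'
#' @param truth a [SimulationTruth-class]
#' @param library the matching [ConstructLibrary-class]
#' @param sampleRole `"input"` or `"IP"`.
#' @param outR1,outR2 output FASTQ paths (`.gz` for compressed).
#' @param sidecar optional path for the per-read truth TSV (`read_id`,
#'   `construct_id`, `cap_class`, `umi`, `molecule_id`).
#' @param nReads approximate number of read pairs (default
#'   `readsPerSample` from the truth).
#' @param seed integer seed for this sample.
#' @return invisibly, the sidecar data.frame.
#' @export
simulateReads <- function(truth, library, sampleRole = c("input", "IP"),
                          outR1, outR2, sidecar = NULL, nReads = NULL,
                          seed = 1L) {
  sampleRole <- match.arg(sampleRole)
  tt <- truth@truth
  if (!all(tt$construct_id %in% constructIds(library)))
    stop("truth names constructs absent from the library")
  p <- truth@params
  if (is.null(nReads)) nReads <- p$readsPerSample
  set.seed(as.integer(seed))

  w <- tt$input_abundance
  if (sampleRole == "IP") w <- w * tt$true_te
  nMol <- max(1L, as.integer(round(nReads / p$duplicationMean)))
  molPerRow <- as.integer(rmultinom(1, nMol, prob = w))

  rowIdx <- rep.int(seq_len(nrow(tt)), molPerRow)
  nmol <- length(rowIdx)
  umis <- .randomUmis(nmol, p$umiLengths, p$umiWeights)
  copies <- 1L + rgeom(nmol, prob = 1 / p$duplicationMean)
  molIdx <- rep.int(seq_len(nmol), copies)
  nrd <- length(molIdx)
  stag <- sample(p$staggerRange, nrd, replace = TRUE)

  utrs <- as.character(utrSequences(library))
  capAd <- ifelse(tt$cap_class == "a_cap", acapBarcode(library),
                  gcapBarcode(library))
  core <- paste0(.ADAPTERS$pair5, capAd, utrs[tt$construct_id],
                 commonAdapter(library), .revcomp(.ADAPTERS$rtAnchor))
  fragMol <- paste0(core[rowIdx], .revcomp(umis))

  frag <- paste0(strrep("N", stag), fragMol[molIdx])
  m1 <- substr(frag, 1L, p$readLength)
  m2 <- substr(.revcomp(frag), 1L, p$readLength)
  if (p$epsilon > 0) {
    m1 <- cpp_inject_errors(m1, p$epsilon)
    m2 <- cpp_inject_errors(m2, p$epsilon)
  }
  ids <- sprintf("rd%07d", seq_len(nrd))
  .writeFastq(m1, ids, outR1)
  .writeFastq(m2, ids, outR2)

  sc <- data.frame(
    read_id = ids,
    construct_id = tt$construct_id[rowIdx][molIdx],
    cap_class = tt$cap_class[rowIdx][molIdx],
    umi = umis[molIdx],
    molecule_id = molIdx,
    stringsAsFactors = FALSE
  )
  if (!is.null(sidecar)) .writeTsv(sc, sidecar)
  invisible(sc)
}

#' Simulate unique-UMI counts directly (count-level marginal)
#'
#' Draws the molecule-count marginal of the read-level generative model:
#' unique-molecule counts per (construct, cap class) are multinomial with
#' weights `input_abundance` (input) or `input_abundance * true_te` (IP).
#' Unique-UMI counts equal molecule counts up to UMI collisions, which are
#' negligible in a >= 4^9 UMI space. Use this for deep-coverage designs
#' where per-read FASTQ realism adds nothing (e.g. spike-in factor
#' recovery); use [simulateReads()] to exercise the read processing itself.
#'
#' @inheritParams simulateReads
#' @param nMolecules number of cDNA molecules to draw (default
#'   `readsPerSample / duplicationMean` from the truth).
#' @return data.frame `construct_id`, `cap_class`, `umi_count`.
#' @export
simulateCounts <- function(truth, sampleRole = c("input", "IP"),
                           nMolecules = NULL, seed = 1L) {
  sampleRole <- match.arg(sampleRole)
  tt <- truth@truth
  p <- truth@params
  if (is.null(nMolecules))
    nMolecules <- max(1L, round(p$readsPerSample / p$duplicationMean))
  set.seed(as.integer(seed))
  w <- tt$input_abundance
  if (sampleRole == "IP") w <- w * tt$true_te
  data.frame(construct_id = tt$construct_id, cap_class = tt$cap_class,
             umi_count = as.integer(rmultinom(1, nMolecules, prob = w)),
             stringsAsFactors = FALSE)
}

#' Simulate a count matrix for a sample sheet
#'
#' [simulateCounts()] per sample sheet row, assembled into a
#' [CapCounts-class].
#'
#' @inheritParams simulateExperiment
#' @param library the [ConstructLibrary-class] (fixes the row universe).
#' @param nMolecules per-sample molecule count.
#' @return a [CapCounts-class]
#' @export
simulateCountMatrix <- function(truths, library, samples, nMolecules = NULL,
                                seed = 1L) {
  if (is(truths, "SimulationTruth"))
    truths <- setNames(rep(list(truths), length(unique(samples$condition))),
                       unique(samples$condition))
  long <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    tr <- truths[[samples$condition[i]]]
    cnt <- simulateCounts(tr, samples$role[i], nMolecules,
                          seed = .childSeed(seed, i))
    cnt$sample_id <- samples$sample_id[i]
    cnt
  }))
  CapCounts(long, samples, library)
}

#' Simulate a whole multi-sample experiment
#'
#' Runs [simulateReads()] once per row of a sample sheet, writing FASTQ
#' pairs (and sidecars) into `dir`. Conditions may use different truths
#' (e.g. a stress condition built with [scaleTrueTE()]).
#'
#' @param truths a [SimulationTruth-class], or a named list of them keyed by
#'   condition.
#' @param library the [ConstructLibrary-class]
#' @param samples data.frame with columns `sample_id`, `role`, `condition`,
#'   `bio_rep`, `tech_rep`.
#' @param dir output directory (created if needed).
#' @param seed base seed; each sample uses a derived child seed.
#' @param nReads optional per-sample read count override.
#' @return the sample sheet with `fastq_r1`, `fastq_r2`, `sidecar` columns
#'   added; also written to `dir/samples.tsv`.
#' @export
simulateExperiment <- function(truths, library, samples, dir, seed = 1L,
                               nReads = NULL) {
  if (is(truths, "SimulationTruth"))
    truths <- setNames(rep(list(truths), length(unique(samples$condition))),
                       unique(samples$condition))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  need <- c("sample_id", "role", "condition", "bio_rep", "tech_rep")
  stopifnot(all(need %in% names(samples)))
  samples$fastq_r1 <- file.path(dir, paste0(samples$sample_id, "_R1.fastq"))
  samples$fastq_r2 <- file.path(dir, paste0(samples$sample_id, "_R2.fastq"))
  samples$sidecar <- file.path(dir, paste0(samples$sample_id, "_truth.tsv"))
  for (i in seq_len(nrow(samples))) {
    tr <- truths[[samples$condition[i]]]
    if (is.null(tr)) stop("no truth for condition ", samples$condition[i])
    simulateReads(tr, library, samples$role[i],
                  samples$fastq_r1[i], samples$fastq_r2[i],
                  sidecar = samples$sidecar[i], nReads = nReads,
                  seed = .childSeed(seed, i))
  }
  .writeTsv(samples, file.path(dir, "samples.tsv"))
  samples
}
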