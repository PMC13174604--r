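## Library constants: the fixed adapter set of the assay. The common adapter
## separates the UTR insert from the reporter ORF; its reverse complement is
## the mate-1 5' anchor. The two 17-nt cap-class adapters sit at the UTR 5'
## end and identify A-cap vs G-cap molecules. The RT anchor is the fixed
## reporter-side primer landing site next to the UMI (FLAG-tag coding start).
.ADAPTERS <- list(
  common   = "AGATCTGTGATTAAG",
  acap     = "AGTCCGCATCCAAGCTT",
  gcap     = "TCCAAGCGATCAAGCTT",
  pair5    = "CTTAATCACAGATCT",
  rtAnchor = "GACTACAAGGACGAC"
)

.CAP_CLASSES <- c("a_cap", "g_cap")

## uppercase, RNA->DNA; rejects anything outside {A,C,G,T}
.normalizeSeq <- function(x, what = "sequence") {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(what, " contains non-ACGT characters: ",
         paste(head(unique(unlist(strsplit(gsub("[ACGT]", "", x[bad]), ""))), 5),
               collapse = ", "), call. = FALSE)
  x
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build a construct library
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet] of
#'   5' UTR sequences; names are construct ids. RNA (U) input is converted
#'   to DNA.
#' @param family per-construct role labels (`positive_control`,
#'   `negative_control`, `spike_in`, `candidate:<group>`); recycled default
#'   `"candidate:unlabeled"`.
#' @param acapBarcode,gcapBarcode,commonAdapter library constants;
#'   defaults are the assay's fixed adapters.
#' @param manifest optional `DataFrame`/data.frame of design columns
#'   (`rule`, `interval`, `wildtype_id`), one row per construct.
#' @return a [ConstructLibrary-class]
#' @export
ConstructLibrary <- function(sequences, family = NULL,
                             acapBarcode = .ADAPTERS$acap,
                             gcapBarcode = .ADAPTERS$gcap,
                             commonAdapter = .ADAPTERS$common,
                             manifest = NULL) {
  if (is(sequences, "XStringSet")) {
    seqs <- setNames(as.character(sequences), names(sequences))
  } else {
    seqs <- sequences
  }
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("sequences must be named by construct_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate construct_id: ", paste(dup, collapse = ", "))
  if (any(nchar(seqs) == 0))
    stop("empty sequence for construct: ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  seqs <- .normalizeSeq(seqs)
  if (is.null(family)) family <- rep("candidate:unlabeled", length(seqs))
  family <- rep_len(family, length(seqs))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  md <- S4Vectors::DataFrame(family = family,
                             is_spike_in = family == "spike_in")
  if (!is.null(manifest)) {
    manifest <- as(manifest, "DataFrame")
    stopifnot(nrow(manifest) == length(dss))
    md <- cbind(md, manifest)
  }
  S4Vectors::mcols(dss) <- md
  new("ConstructLibrary", sequences = dss,
      acapBarcode = as.character(acapBarcode),
      gcapBarcode = as.character(gcapBarcode),
      commonAdapter = .normalizeSeq(as.character(commonAdapter), "commonAdapter"))
}

#' Read a construct library from FASTA
#'
#' Record ids may carry a family tag as `id|family=<tag>` or
#' `id family=<tag>`; untagged records default to `candidate:unlabeled`.
#' Sequences are uppercased and RNA (U) is converted to DNA (T). Duplicate
#' ids, empty sequences and non-ACGT characters are hard errors.
#'
#' @param path FASTA file of construct 5' UTRs.
#' @inheritParams ConstructLibrary
#' @return a [ConstructLibrary-class]
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">HCV family=positive_control", "ACGTACGT",
#'              ">scr1 family=negative_control", "TTTTCCCC"), fa)
#' lib <- loadConstructs(fa)
#' constructIds(lib)
#' @export
loadConstructs <- function(path,
                           acapBarcode = .ADAPTERS$acap,
                           gcapBarcode = .ADAPTERS$gcap,
                           commonAdapter = .ADAPTERS$common) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  ## read as raw strings so RNA (U) and invalid characters reach the
  ## normalizer instead of being silently dropped by the DNA parser
  dss <- Biostrings::readBStringSet(path)
  if (!length(dss)) stop("no records in ", path)
  hdr <- names(dss)
  m <- regmatches(hdr, regexec("^(\\S+?)(?:[| ]family=(\\S+))?\\s*$", hdr))
  ids <- vapply(m, `[`, "", 2L)
  fam <- vapply(m, `[`, "", 3L)
  fam[!nzchar(fam)] <- "candidate:unlabeled"
  seqs <- setNames(as.character(dss), ids)
  ConstructLibrary(seqs, family = fam, acapBarcode = acapBarcode,
                   gcapBarcode = gcapBarcode, commonAdapter = commonAdapter)
}

#' Write a construct library to FASTA
#'
#' Headers are `><construct_id> family=<tag>`; sequence lines wrap at 80
#' columns.
#'
#' @param x a [ConstructLibrary-class]
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeConstructs <- function(x, path) {
  dss <- x@sequences
  names(dss) <- paste0(names(dss), " family=", constructFamily(x))
  Biostrings::writeXStringSet(dss, path, width = 80L)
  invisible(path)
}

#' @rdname ConstructLibrary-class
#' @export
setMethod("constructIds", "ConstructLibrary", function(x) names(x@sequences))

#' @rdname ConstructLibrary-class
#' @export
setMethod("utrSequences", "ConstructLibrary", function(x) x@sequences)

#' @rdname ConstructLibrary-class
#' @export
setMethod("constructFamily", "ConstructLibrary",
          function(x) setNames(S4Vectors::mcols(x@sequences)$family,
                               names(x@sequences)))

#' @rdname ConstructLibrary-class
#' @export
setMethod("isSpikeIn", "ConstructLibrary",
          function(x) setNames(S4Vectors::mcols(x@sequences)$is_spike_in,
                               names(x@sequences)))

#' @rdname ConstructLibrary-class
#' @export
setMethod("acapBarcode", "ConstructLibrary", function(x) x@acapBarcode)

#' @rdname ConstructLibrary-class
#' @export
setMethod("gcapBarcode", "ConstructLibrary", function(x) x@gcapBarcode)

#' @rdname ConstructLibrary-class
#' @export
setMethod("commonAdapter", "ConstructLibrary", function(x) x@commonAdapter)

#' @rdname ConstructLibrary-class
#' @export
setMethod("length", "ConstructLibrary", function(x) length(x@sequences))

#' @rdname ConstructLibrary-class
#' @param i index: construct ids, positions or logical.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ConstructLibrary", function(x, i, j, ..., drop = TRUE) {
  initialize(x, sequences = x@sequences[i])
})

setMethod("show", "ConstructLibrary", function(object) {
  fam <- table(constructFamily(object))
  cat("ConstructLibrary with", length(object), "constructs\n")
  cat("  families:",
      paste(sprintf("%s (%d)", names(fam), fam), collapse = ", "), "\n")
  cat("  UTR widths:",
      paste(range(Biostrings::width(object@sequences)), collapse = "-"),
      "nt\n")
  cat("  A-cap/G-cap barcodes:", object@acapBarcode, "/",
      object@gcapBarcode, "\n")
})

#' Insert the A-cap class barcode into a UTR
#'
#' A-cap reporter mRNAs carry a short barcode in the 5' UTR so that A-cap
#' and G-cap molecules can be told apart by sequencing. Inserts `barcode`
#' at 0-based `offset` (0 = prefix, `nchar(utr)` = suffix).
#'
#' @param utr UTR sequence(s).
#' @param barcode barcode string (may be empty).
#' @param offset 0-based insertion offset, in `[0, nchar(utr)]`.
#' @return the barcoded sequence(s), length `nchar(utr) + nchar(barcode)`.
#' @examples
#' attachAcapBarcode("AAAA", "GG", 0)  # "GGAAAA"
#' @export
attachAcapBarcode <- function(utr, barcode, offset = 0L) {
  if (any(offset < 0L) || any(offset > nchar(utr)))
    stop("offset must lie in [0, nchar(utr)]")
  paste0(substr(utr, 1L, offset), barcode,
         substr(utr, offset + 1L, nchar(utr)))
}

#' @rdname PairedRegion-class
#' @param name helix label.
#' @param left,right `c(start, end)` 1-based closed intervals; left strictly
#'   upstream of right, equal lengths.
#' @export
PairedRegion <- function(name, left, right) {
  new("PairedRegion", name = as.character(name),
      left = as.integer(left), right = as.integer(right))
}

setMethod("show", "PairedRegion", function(object) {
  cat(sprintf("PairedRegion '%s': left %d-%d / right %d-%d\n", object@name,
              object@left[1], object@left[2], object@right[1], object@right[2]))
})
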