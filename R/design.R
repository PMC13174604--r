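## Variant library design: scanning mutagenesis, helix disruption/rescue
## mutants, and rRNA-complement tiles. All designs record their provenance
## (rule, mutated interval, wildtype id) in the library's design manifest so
## downstream fold-change profiling can map variants back to positions.

#' Transversion swap of a DNA string
#'
#' Maps A<->C and G<->T per position, removing base-pairing potential while
#' preserving purine/pyrimidine content asymmetrically. An involution:
#' applying it twice restores the input.
#'
#' @param x DNA string(s).
#' @return swapped string(s).
#' @examples
#' transversionSwap("ACGT")  # "CATG"
#' @export
transversionSwap <- function(x) chartr("ACGT", "CATG", x)

## per-position complement, no reversal
.complementBases <- function(x) chartr("ACGT", "TGCA", x)

.mutateWindow <- function(seq, s, e, rule) {
  win <- substr(seq, s, e)
  new <- switch(rule,
    replace_AAA      = strrep("A", e - s + 1L),
    transversion_swap = transversionSwap(win),
    complement       = .complementBases(win),
    stop("unknown mutation rule: ", rule)
  )
  paste0(substr(seq, 1L, s - 1L), new, substr(seq, e + 1L, nchar(seq)))
}

#' Design a scanning mutagenesis library
#'
#' Tiles mutation windows across a wildtype sequence: one variant per window
#' start `s` in `1, 1+step, 1+2*step, ...` with `s+window-1 <= length`.
#' `replace_AAA` sets the window to all adenosines (3-nt windows in 1-nt
#' steps in the original design); `transversion_swap` applies A<->C, G<->T
#' within the window (4-nt windows in 3-nt steps), ablating base-pairing
#' potential. Variant ids encode the 1-based closed window interval and the
#' wildtype itself is appended as a labelled reference record.
#'
#' @param wildtype wildtype UTR sequence (DNA or RNA; U converted).
#' @param window window width (nt), `>= 1`.
#' @param step window start step (nt), `>= 1`.
#' @param rule `"replace_AAA"` or `"transversion_swap"`.
#' @param wildtypeId id of the wildtype record; variant ids are
#'   `<wildtypeId>_<rule>_<start>-<end>`.
#' @param family family label for the variants.
#' @return a [ConstructLibrary-class] of `floor((L-window)/step)+1` variants
#'   plus the wildtype; its design manifest maps ids to intervals.
#' @seealso [mutagenesisProfile()] which consumes the manifest.
#' @export
designScanningMutants <- function(wildtype, window, step = 1L,
                                  rule = c("replace_AAA", "transversion_swap"),
                                  wildtypeId = "WT",
                                  family = "candidate:scanning") {
  rule <- match.arg(rule)
  wildtype <- .normalizeSeq(wildtype, "wildtype")
  window <- as.integer(window); step <- as.integer(step)
  L <- nchar(wildtype)
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  if (window > L) stop("window (", window, ") exceeds sequence length (", L, ")")
  starts <- seq.int(1L, L - window + 1L, by = step)
  ends <- starts + window - 1L
  seqs <- vapply(seq_along(starts),
                 function(k) .mutateWindow(wildtype, starts[k], ends[k], rule),
                 "")
  ids <- sprintf("%s_%s_%d-%d", wildtypeId, rule, starts, ends)
  seqs <- c(setNames(seqs, ids), setNames(wildtype, wildtypeId))
  manifest <- S4Vectors::DataFrame(
    rule = c(rep(rule, length(starts)), "wildtype"),
    interval = c(sprintf("%d-%d", starts, ends), NA_character_),
    wildtype_id = wildtypeId
  )
  ConstructLibrary(seqs, family = c(rep(family, length(starts)),
                                    "candidate:wildtype"),
                   manifest = manifest)
}

#' Design helix disruption and compensatory mutants
#'
#' For one base-paired region, builds the L variant (every nucleotide of the
#' left strand complemented in place, no reversal), the R variant (right
#' strand likewise) and the compensatory C variant (both strands
#' complemented, restoring pairing potential). Positions outside the two
#' intervals are untouched; C equals applying R to the L variant.
#'
#' @param wildtype wildtype sequence.
#' @param region a [PairedRegion-class] giving the helix strands.
#' @param wildtypeId id prefix for variant ids
#'   (`<wildtypeId>_<region>_L` / `_R` / `_C`).
#' @return a [ConstructLibrary-class] with the three variants (manifest
#'   records rule `helix_L`/`helix_R`/`helix_C` and both intervals).
#' @export
designHelixMutants <- function(wildtype, region, wildtypeId = "WT") {
  stopifnot(is(region, "PairedRegion"))
  validObject(region)
  wildtype <- .normalizeSeq(wildtype, "wildtype")
  L <- nchar(wildtype)
  if (region@right[2] > L)
    stop("region extends beyond sequence (length ", L, ")")
  mutL <- .mutateWindow(wildtype, region@left[1], region@left[2], "complement")
  mutR <- .mutateWindow(wildtype, region@right[1], region@right[2], "complement")
  mutC <- .mutateWindow(mutL, region@right[1], region@right[2], "complement")
  ids <- sprintf("%s_%s_%s", wildtypeId, region@name, c("L", "R", "C"))
  iv <- sprintf("%d-%d,%d-%d", region@left[1], region@left[2],
                region@right[1], region@right[2])
  manifest <- S4Vectors::DataFrame(
    rule = c("helix_L", "helix_R", "helix_C"),
    interval = iv, wildtype_id = wildtypeId
  )
  ConstructLibrary(setNames(c(mutL, mutR, mutC), ids),
                   family = "candidate:helix", manifest = manifest)
}

#' Design tiles complementary to an rRNA
#'
#' Each tile is the reverse complement of a window of the rRNA, emitted
#' 5' to 3' along the rRNA; ids encode the rRNA window coordinates. The
#' defaults (50-nt tiles, 60-nt step) give ~31 tiles over a full-length 18S
#' rRNA.
#'
#' @param rrna rRNA sequence (RNA accepted).
#' @param tileLen tile length, `<= nchar(rrna)`.
#' @param step window step, `>= 1`.
#' @param prefix id prefix (`<prefix>_tile_<start>-<end>`).
#' @return a [ConstructLibrary-class] of `floor((L-tileLen)/step)+1` tiles.
#' @export
designRrnaTiles <- function(rrna, tileLen = 50L, step = 60L, prefix = "18S") {
  rrna <- .normalizeSeq(rrna, "rrna")
  tileLen <- as.integer(tileLen); step <- as.integer(step)
  L <- nchar(rrna)
  if (tileLen > L) stop("tileLen (", tileLen, ") exceeds rRNA length (", L, ")")
  if (step < 1L) stop("step must be >= 1")
  starts <- seq.int(1L, L - tileLen + 1L, by = step)
  ends <- starts + tileLen - 1L
  tiles <- .revcomp(substring(rrna, starts, ends))
  ids <- sprintf("%s_tile_%d-%d", prefix, starts, ends)
  manifest <- S4Vectors::DataFrame(rule = "rrna_tile",
                                   interval = sprintf("%d-%d", starts, ends),
                                   wildtype_id = NA_character_)
  ConstructLibrary(setNames(tiles, ids), family = "candidate:rrna_tile",
                   manifest = manifest)
}

#' @rdname designScanningMutants
#' @param x a designed [ConstructLibrary-class]
#' @return `designManifest()`: a `DataFrame` with `construct_id`, `rule`,
#'   `interval`, `wildtype_id`.
#' @export
setMethod("designManifest", "ConstructLibrary", function(x) {
  md <- S4Vectors::mcols(x@sequences)
  if (!"rule" %in% colnames(md))
    stop("library carries no design manifest")
  S4Vectors::DataFrame(construct_id = names(x@sequences),
                       md[, c("rule", "interval", "wildtype_id")])
})

#' Write a design manifest TSV
#'
#' @param x a designed [ConstructLibrary-class]
#' @param path output TSV (construct_id, rule, interval, wildtype_id).
#' @return `path`, invisibly.
#' @export
writeDesignManifest <- function(x, path) {
  .writeTsv(as.data.frame(designManifest(x)), path)
  invisible(path)
}

## merge several libraries (shared adapters taken from the first)
#' Concatenate construct libraries
#'
#' @param ... [ConstructLibrary-class] objects; adapters are taken from the
#'   first. Ids must be globally unique.
#' @return a combined [ConstructLibrary-class]
#' @export
combineLibraries <- function(...) {
  libs <- list(...)
  stopifnot(length(libs) >= 1L)
  seqs <- unlist(lapply(libs, function(l) setNames(as.character(l@sequences),
                                                   names(l@sequences))))
  fams <- unlist(lapply(libs, function(l) unname(constructFamily(l))))
  mans <- lapply(libs, function(l) {
    md <- S4Vectors::mcols(l@sequences)
    if ("rule" %in% colnames(md)) md[, c("rule", "interval", "wildtype_id")]
    else S4Vectors::DataFrame(rule = rep(NA_character_, length(l)),
                              interval = NA_character_,
                              wildtype_id = NA_character_)
  })
  ConstructLibrary(seqs, family = fams,
                   acapBarcode = libs[[1]]@acapBarcode,
                   gcapBarcode = libs[[1]]@gcapBarcode,
                   commonAdapter = libs[[1]]@commonAdapter,
                   manifest = do.call(rbind, mans))
}
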