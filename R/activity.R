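## Activity classification, IRES-vs-CDI statistics, scanning-mutagenesis
## fold-change profiles, helix rescue, and strong-pair group comparison.

#' Classify constructs as active or inactive IRESes
#'
#' A construct is `active` when its A-cap (IRES) linear TE is at least the
#' A-cap TE of the threshold construct from the same experiment - by
#' default the CrPV IRES, the canonical positive control whose activity
#' defines the lower boundary of "drove at least as much translation".
#' The comparison is inclusive, so the threshold construct itself is
#' active.
#'
#' @param te a [TETable-class]
#' @param thresholdConstruct id of the threshold construct (default
#'   `"CrPV"`).
#' @return `DataFrame` with `construct_id`, `ires_te`, `cdi_te`,
#'   `pct_cdi` (`100 * ires_te / cdi_te`), `label`
#'   (`active`/`inactive`), `threshold_te`; `metadata()` records the
#'   threshold construct and value.
#' @export
classifyActive <- function(te, thresholdConstruct = "CrPV") {
  a <- te[te$cap_class == "a_cap" & !te$filtered_low_input, ]
  g <- te[te$cap_class == "g_cap" & !te$filtered_low_input, ]
  thr <- a$te_linear[a$construct_id == thresholdConstruct]
  if (!length(thr))
    stop("threshold construct '", thresholdConstruct,
         "' absent or filtered from the A-cap TE table")
  cdi <- g$te_linear[match(a$construct_id, g$construct_id)]
  out <- S4Vectors::DataFrame(
    construct_id = a$construct_id,
    ires_te = a$te_linear,
    cdi_te = cdi,
    pct_cdi = 100 * a$te_linear / cdi,
    label = ifelse(a$te_linear >= thr, "active", "inactive"),
    threshold_te = thr
  )
  S4Vectors::metadata(out) <- list(threshold_construct = thresholdConstruct,
                                   threshold_te = thr)
  out
}

#' IRES TE as a percentage of CDI TE
#'
#' `100 * te_linear(a_cap) / te_linear(g_cap)` per construct. Candidates
#' whose IRES activity is a small percentage of their own cap-dependent
#' translation are unlikely to be biologically meaningful IRESes.
#' Constructs whose G-cap row is filtered are omitted with a warning.
#'
#' @param te a [TETable-class]
#' @return named numeric vector of percentages.
#' @export
iresPctCdi <- function(te) {
  a <- te[te$cap_class == "a_cap" & !te$filtered_low_input, ]
  g <- te[te$cap_class == "g_cap" & !te$filtered_low_input, ]
  m <- match(a$construct_id, g$construct_id)
  if (anyNA(m))
    warning(sum(is.na(m)), " construct(s) without a retained G-cap row ",
            "omitted from %CDI")
  ok <- !is.na(m)
  setNames(100 * a$te_linear[ok] / g$te_linear[m[ok]], a$construct_id[ok])
}

#' Scanning-mutagenesis fold-change profile
#'
#' For each scanning-mutant window, `fold_change` is the variant's A-cap
#' (IRES) TE over the wildtype's; values below 1 are decreases. The
#' per-position track assigns each window's fold change to the window's
#' center nucleotide, `floor((start + end) / 2)` (nt 2 for window 1-3).
#'
#' @param te a [TETable-class]
#' @param manifest design manifest (`DataFrame`/data.frame from
#'   [designManifest()], or a TSV path) with `construct_id`, `rule`,
#'   `interval`, `wildtype_id`.
#' @param wildtypeId wildtype id (default: from the manifest).
#' @return `DataFrame` with `construct_id`, `start`, `end`, `position`
#'   (the center), `fold_change`, ordered by window start; `metadata()`
#'   holds the wildtype TE and the min/max fold change. Variants absent
#'   from the TE table leave `NA` gaps with a warning.
#' @export
mutagenesisProfile <- function(te, manifest, wildtypeId = NULL) {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- .readTsv(manifest)
  manifest <- as.data.frame(manifest)
  win <- manifest[!is.na(manifest$interval) &
                  grepl("^\\d+-\\d+$", manifest$interval), , drop = FALSE]
  if (is.null(wildtypeId)) {
    wildtypeId <- unique(win$wildtype_id)
    wildtypeId <- wildtypeId[!is.na(wildtypeId)]
    if (length(wildtypeId) != 1L)
      stop("cannot infer a unique wildtype id from the manifest")
  }
  a <- te[te$cap_class == "a_cap" & !te$filtered_low_input, ]
  wt <- a$te_linear[a$construct_id == wildtypeId]
  if (!length(wt))
    stop("wildtype '", wildtypeId, "' absent or filtered from the TE table")
  iv <- do.call(rbind, strsplit(win$interval, "-"))
  s <- as.integer(iv[, 1]); e <- as.integer(iv[, 2])
  fc <- a$te_linear[match(win$construct_id, a$construct_id)] / wt
  if (anyNA(fc))
    warning(sum(is.na(fc)), " variant(s) missing from the TE table; ",
            "profile has gaps")
  o <- order(s)
  out <- S4Vectors::DataFrame(
    construct_id = win$construct_id[o], start = s[o], end = e[o],
    position = (s[o] + e[o]) %/% 2L, fold_change = fc[o]
  )
  S4Vectors::metadata(out) <- list(
    wildtype_id = wildtypeId, wildtype_te = wt,
    fold_change_range = range(out$fold_change, na.rm = TRUE))
  out
}

#' Helix disruption / rescue analysis
#'
#' Compares the wildtype with the left (L), right (R) and compensatory (C)
#' helix mutants of one base-paired region (A-cap TEs).
#' `rescue_index = te_C / sqrt(te_L * te_R)` (1 = no rescue beyond the
#' disrupted baseline); `restoration_fraction` places `log2(te_C)` on the
#' scale from the mean disrupted level (0) to the wildtype level (1),
#' clipped to `[0, 1.5]` for reporting. Compensatory restoration validates
#' that the helix's base pairing, not its sequence, carries the activity.
#'
#' @param te a [TETable-class]
#' @param idL,idR,idC,wildtypeId construct ids of the three mutants and the
#'   wildtype.
#' @param region optional [PairedRegion-class], echoed in the output.
#' @return one-row data.frame with the four TEs, `rescue_index` and
#'   `restoration_fraction`.
#' @export
helixRescue <- function(te, idL, idR, idC, wildtypeId, region = NULL) {
  a <- te[te$cap_class == "a_cap" & !te$filtered_low_input, ]
  grab <- function(id) {
    v <- a$te_linear[a$construct_id == id]
    if (!length(v)) stop("construct '", id, "' absent or filtered")
    v
  }
  teL <- grab(idL); teR <- grab(idR); teC <- grab(idC)
  teW <- grab(wildtypeId)
  base <- mean(c(log2(teL), log2(teR)))
  rf <- (log2(teC) - base) / (log2(teW) - base)
  data.frame(
    region = if (is.null(region)) NA_character_ else region@name,
    te_wt = teW, te_L = teL, te_R = teR, te_C = teC,
    rescue_index = teC / sqrt(teL * teR),
    restoration_fraction = min(max(rf, 0), 1.5),
    stringsAsFactors = FALSE
  )
}

#' Compare strong-pair fractions between activity groups
#'
#' One-sided rank-sum (Mann-Whitney) test of the hypothesis that active
#' IRESes have higher G-C pair fractions than inactive ones, with the
#' exact null distribution at small group sizes (ties fall back to the
#' normal approximation).
#'
#' @param fractions named numeric vector of G-C pair percentages per
#'   construct (see [gcPairFraction()]).
#' @param labels activity labels: a `DataFrame` from [classifyActive()] or
#'   a character vector (`active`/`inactive`) named by construct.
#' @return one-row data.frame: `U`, `p_value`, `median_active`,
#'   `median_inactive`, `n_active`, `n_inactive`, `test`.
#' @export
compareGcGroups <- function(fractions, labels) {
  if (is(labels, "DataFrame"))
    labels <- setNames(labels$label, labels$construct_id)
  labels <- labels[names(fractions)]
  act <- fractions[!is.na(labels) & labels == "active"]
  ina <- fractions[!is.na(labels) & labels == "inactive"]
  if (length(act) < 2L || length(ina) < 2L)
    stop("need at least two constructs per activity group")
  wt <- wilcox.test(act, ina, alternative = "greater",
                    exact = length(act) + length(ina) < 50)
  data.frame(
    U = unname(wt$statistic), p_value = wt$p.value,
    median_active = median(act), median_inactive = median(ina),
    n_active = length(act), n_inactive = length(ina),
    test = "one-sided exact rank-sum (active > inactive)",
    stringsAsFactors = FALSE
  )
}
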