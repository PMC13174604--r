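## Spike-in anchored normalization across conditions. The three G-cap
## spike-in reporters come from one unstressed lysate added identically (1%
## of volume) to every sample, so any apparent TE difference of the spikes
## between conditions measures a global technical/IP shift, not biology.
## The per-condition factor is the geometric mean of the three spike TE
## ratios (reference / condition) - robust on a three-point log scale - and
## is applied multiplicatively to the condition's TEs.

#' Construct a SpikeInSet
#'
#' @param spikeIds the three spike-in construct ids, in increasing designed
#'   abundance order.
#' @param designedRelAbundance designed relative abundances (default the
#'   1 : 10 : 100 serial dilution, i.e. `c(0.01, 0.1, 1)` up to scale).
#' @return a [SpikeInSet-class]
#' @export
SpikeInSet <- function(spikeIds, designedRelAbundance = c(0.01, 0.1, 1)) {
  new("SpikeInSet", spikeIds = as.character(spikeIds),
      designedRelAbundance = as.numeric(designedRelAbundance),
      factors = numeric(), linearityR2 = numeric(),
      reference = NA_character_)
}

#' @rdname SpikeInSet-class
#' @param lib a [ConstructLibrary-class] with three `spike_in` records (in
#'   increasing designed abundance order).
#' @export
spikeInSetFromLibrary <- function(lib) {
  ids <- constructIds(lib)[isSpikeIn(lib)]
  if (length(ids) != 3L) stop("library must contain exactly 3 spike-ins")
  SpikeInSet(ids)
}

setMethod("show", "SpikeInSet", function(object) {
  cat("SpikeInSet:", paste(object@spikeIds, collapse = ", "), "\n")
  cat("  designed abundances:",
      paste(object@designedRelAbundance, collapse = " : "), "\n")
  if (length(object@factors)) {
    cat("  reference:", object@reference, "\n")
    for (cond in names(object@factors))
      cat(sprintf("  factor[%s] = %.4g (linearity R2 = %.3f)\n", cond,
                  object@factors[[cond]], object@linearityR2[[cond]]))
  } else cat("  factors: not fitted\n")
})

#' @rdname fitSpikeInFactors
#' @param x a fitted [SpikeInSet-class]
#' @export
setMethod("normFactors", "SpikeInSet", function(x) x@factors)

.spikeTe <- function(te, ids) {
  m <- match(paste(ids, "g_cap"), paste(te$construct_id, te$cap_class))
  if (anyNA(m))
    stop("spike-in absent from TE table: ",
         paste(ids[is.na(m)], collapse = ", "))
  bad <- te$filtered_low_input[m] | te$input_count[m] == 0
  if (any(bad))
    stop("spike-in filtered or without input counts: ",
         paste(ids[bad], collapse = ", "))
  list(te = te$te_linear[m], input_rpm = te$input_rpm[m])
}

#' Fit per-condition spike-in normalization factors
#'
#' `factor(condition)` is the geometric mean over the three G-cap spike-ins
#' of `te_spike(reference) / te_spike(condition)`; the reference condition
#' is fixed at 1. A per-condition linearity R^2 (observed log spike input
#' RPM regressed on designed log abundance) reports how well the serial
#' dilution was recovered.
#'
#' @param teTables named list of [TETable-class] objects, one per condition.
#' @param spikes a [SpikeInSet-class]
#' @param reference name of the reference condition (factor 1).
#' @return the [SpikeInSet-class] with `factors` and `linearityR2` filled.
#' @export
fitSpikeInFactors <- function(teTables, spikes, reference = "control") {
  if (!reference %in% names(teTables))
    stop("reference condition '", reference, "' not among TE tables")
  ref <- .spikeTe(teTables[[reference]], spikes@spikeIds)
  factors <- vapply(teTables, function(te) {
    s <- .spikeTe(te, spikes@spikeIds)
    .geomean(ref$te / s$te)
  }, 0)
  r2 <- vapply(teTables, function(te) {
    s <- .spikeTe(te, spikes@spikeIds)
    summary(lm(log(s$input_rpm) ~ log(spikes@designedRelAbundance)))$r.squared
  }, 0)
  initialize(spikes, factors = factors, linearityR2 = r2,
             reference = reference)
}

#' Apply a spike-in factor to a TE table
#'
#' Multiplies `te_linear` (and shifts `log2_te`) by the condition's fitted
#' factor; the reference condition is unchanged by construction
#' (factor 1).
#'
#' @param te a [TETable-class]
#' @param spikes a fitted [SpikeInSet-class]
#' @param condition condition of `te` (default: from the table's metadata).
#' @return the adjusted [TETable-class]
#' @export
adjustTE <- function(te, spikes, condition = NULL) {
  if (is.null(condition)) condition <- S4Vectors::metadata(te)$condition
  if (!condition %in% names(spikes@factors))
    stop("no fitted factor for condition '", condition, "'")
  f <- spikes@factors[[condition]]
  md <- S4Vectors::metadata(te)
  df <- as.data.frame(te)
  df$te_linear <- df$te_linear * f
  df$log2_te <- df$log2_te + log2(f)
  out <- .TETable(df, condition, md$pseudocount, md$min_input)
  S4Vectors::metadata(out)$spike_factor <- f
  out
}

#' Differential TE between stress and control
#'
#' Per (construct, cap class): `log2_fc = log2(te_stress / te_control)` on
#' spike-adjusted TEs, plus the construct's IRES activity as a percentage
#' of its CDI activity in each condition. Constructs missing (filtered) in
#' either condition are omitted with a warning.
#'
#' @param control,stress spike-adjusted [TETable-class] objects on the same
#'   reference.
#' @return `DataFrame` with `construct_id`, `cap_class`, `te_control`,
#'   `te_stress`, `log2_fc`, `pct_cdi_control`, `pct_cdi_stress`.
#' @export
differentialTE <- function(control, stress) {
  key <- paste(control$construct_id, control$cap_class)
  m <- match(key, paste(stress$construct_id, stress$cap_class))
  ok <- !is.na(m) & !control$filtered_low_input &
    !stress$filtered_low_input[pmax(m, 1L)]
  ## warn only where a construct is retained in one condition but not the
  ## other; rows filtered everywhere drop silently
  oneSided <- !ok & (is.na(m) |
                       xor(control$filtered_low_input,
                           stress$filtered_low_input[pmax(m, 1L)]))
  dropped <- unique(control$construct_id[oneSided])
  if (length(dropped))
    warning(length(dropped), " construct(s) missing in one condition, ",
            "omitted: ", paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  ctl <- control[ok, ]; str <- stress[m[ok], ]
  pct <- function(te) {
    a <- te$te_linear[te$cap_class == "a_cap"]
    g <- te$te_linear[te$cap_class == "g_cap"]
    ids <- te$construct_id[te$cap_class == "a_cap"]
    setNames(100 * a / g[match(ids, te$construct_id[te$cap_class == "g_cap"])],
             ids)
  }
  pc <- pct(ctl); ps <- pct(str)
  out <- S4Vectors::DataFrame(
    construct_id = ctl$construct_id, cap_class = ctl$cap_class,
    te_control = ctl$te_linear, te_stress = str$te_linear,
    log2_fc = log2(str$te_linear / ctl$te_linear),
    pct_cdi_control = unname(pc[ctl$construct_id]),
    pct_cdi_stress = unname(ps[ctl$construct_id])
  )
  S4Vectors::metadata(out) <- list(
    reference = S4Vectors::metadata(control)$condition,
    spike_factor_stress = S4Vectors::metadata(stress)$spike_factor)
  out
}
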