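## Unique-UMI counts -> translation efficiencies. Replicates are summed
## (technical before biological, after correlation QC), constructs with
## sparse input are removed, counts are normalized to reads per million
## within the whole sequencing sample (both cap classes together: A-cap and
## G-cap reads derive from one co-transfected pool split in silico, and
## per-class normalization would erase the global IRES-vs-CDI difference),
## and TE = IP RPM / input RPM with a small pseudocount for zero IP counts.

#' Sum counts across replicates
#'
#' `"technical"` sums technical replicates within (role, condition,
#' biological replicate); `"biological"` sums everything within (role,
#' condition). Sum technical replicates first, then biological, with
#' replicate correlation QC in between.
#'
#' @param cc a [CapCounts-class]
#' @param level `"technical"` or `"biological"`.
#' @return a collapsed [CapCounts-class]
#' @export
combineReplicates <- function(cc, level = c("technical", "biological")) {
  level <- match.arg(level)
  cd <- SummarizedExperiment::colData(cc)
  grp <- if (level == "technical")
    paste(cd$role, cd$condition, cd$bio_rep, sep = ".")
  else paste(cd$role, cd$condition, sep = ".")
  if (anyNA(cd$role)) stop("missing role in sample metadata")
  mat <- SummarizedExperiment::assay(cc, "counts")
  groups <- unique(grp)
  newMat <- vapply(groups, function(g)
    rowSums(mat[, grp == g, drop = FALSE]), numeric(nrow(mat)))
  first <- match(groups, grp)
  newCd <- S4Vectors::DataFrame(
    sample_id = groups,
    role = cd$role[first],
    condition = cd$condition[first],
    bio_rep = if (level == "technical") cd$bio_rep[first] else "combined",
    tech_rep = "combined"
  )
  rownames(newCd) <- groups
  storage.mode(newMat) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = newMat),
    rowData = SummarizedExperiment::rowData(cc), colData = newCd)
  out <- new("CapCounts", se)
  S4Vectors::metadata(out) <- S4Vectors::metadata(cc)
  out
}

#' Flag constructs with sparse input
#'
#' A (construct, cap class) is flagged `filtered_low_input` when its count
#' is below `minInput` in any input library (any condition); flagged rows
#' are excluded from RPM/TE computation. Exactly `minInput` is retained
#' (the filter removes "fewer than" `minInput`).
#'
#' @param cc a [CapCounts-class], combined at the intended replicate level.
#' @param minInput minimum input count (default 10).
#' @return `cc` with a `filtered_low_input` column added to `rowData`.
#' @export
filterLowInput <- function(cc, minInput = 10L) {
  cd <- SummarizedExperiment::colData(cc)
  inputCols <- which(cd$role == "input")
  if (!length(inputCols)) stop("no input samples present")
  mat <- SummarizedExperiment::assay(cc, "counts")[, inputCols, drop = FALSE]
  flag <- apply(mat < minInput, 1L, any)
  SummarizedExperiment::rowData(cc)$filtered_low_input <- unname(flag)
  S4Vectors::metadata(cc)$min_input <- minInput
  cc
}

#' Reads-per-million normalization with IP pseudocounting
#'
#' Within each sequencing sample, `RPM = count * 1e6 / total`, where the
#' total runs over all retained rows of that sample across both cap
#' classes. For IP samples, zero counts are first replaced by `pseudocount`
#' (default 0.000001) and flagged. Filtered rows get `NA` RPM and do not
#' enter the totals.
#'
#' @param cc a [CapCounts-class] carrying the `filtered_low_input` flag
#'   (see [filterLowInput()]).
#' @param pseudocount replacement for zero IP counts.
#' @return `cc` with `rpm` (numeric) and `pseudocounted` (logical) assays.
#' @export
computeRPM <- function(cc, pseudocount = 1e-6) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  rd <- SummarizedExperiment::rowData(cc)
  if (is.null(rd$filtered_low_input))
    stop("run filterLowInput() before computeRPM()")
  keep <- !rd$filtered_low_input
  cd <- SummarizedExperiment::colData(cc)
  num <- SummarizedExperiment::assay(cc, "counts") * 1.0
  pseudo <- matrix(FALSE, nrow(num), ncol(num), dimnames = dimnames(num))
  ipCols <- cd$role == "IP"
  z <- num[keep, ipCols, drop = FALSE] == 0
  num[keep, ipCols][z] <- pseudocount
  pseudo[keep, ipCols][z] <- TRUE
  totals <- colSums(num[keep, , drop = FALSE])
  if (any(totals <= 0))
    stop("sample(s) with zero total retained counts: ",
         paste(colnames(num)[totals <= 0], collapse = ", "))
  rpm <- sweep(num, 2L, totals / 1e6, "/")
  rpm[!keep, ] <- NA_real_
  SummarizedExperiment::assay(cc, "rpm") <- rpm
  SummarizedExperiment::assay(cc, "pseudocounted") <- pseudo
  S4Vectors::metadata(cc)$pseudocount <- pseudocount
  cc
}

.TETable <- function(df, condition, pseudocount, minInput) {
  out <- new("TETable", as(df, "DFrame"))
  S4Vectors::metadata(out) <- list(condition = condition,
                                   pseudocount = pseudocount,
                                   min_input = minInput)
  out
}

#' Compute translation efficiencies
#'
#' For each condition, pairs its input and IP sample (combine replicates
#' first) and computes per (construct, cap class):
#' `te_linear = ip_rpm / input_rpm` and `log2_te = log2(te_linear)`. The
#' A-cap rows give the IRES TE and the G-cap rows the CDI TE of each
#' construct. Filtered rows carry `NA` TE.
#'
#' @param cc a [CapCounts-class] after [filterLowInput()] and
#'   [computeRPM()].
#' @param condition condition(s) to compute; default: all present.
#' @return a [TETable-class], or a named list of them when several
#'   conditions are requested.
#' @export
computeTE <- function(cc, condition = NULL) {
  if (!"rpm" %in% SummarizedExperiment::assayNames(cc))
    stop("run computeRPM() before computeTE()")
  cd <- SummarizedExperiment::colData(cc)
  if (is.null(condition)) condition <- unique(cd$condition)
  res <- lapply(condition, function(cond) {
    inCol <- which(cd$condition == cond & cd$role == "input")
    ipCol <- which(cd$condition == cond & cd$role == "IP")
    if (length(inCol) != 1L || length(ipCol) != 1L)
      stop("condition '", cond, "' needs exactly one input and one IP ",
           "sample; combine replicates first")
    rd <- SummarizedExperiment::rowData(cc)
    rpm <- SummarizedExperiment::assay(cc, "rpm")
    cnt <- SummarizedExperiment::assay(cc, "counts")
    pse <- SummarizedExperiment::assay(cc, "pseudocounted")
    keep <- !rd$filtered_low_input
    inputRpm <- rpm[, inCol]
    if (any(keep & (is.na(inputRpm) | inputRpm == 0)))
      stop("retained row with zero input RPM (should be precluded by the ",
           "input filter)")
    te <- ifelse(keep, rpm[, ipCol] / inputRpm, NA_real_)
    df <- S4Vectors::DataFrame(
      construct_id = rd$construct_id, cap_class = rd$cap_class,
      input_count = cnt[, inCol], ip_count = cnt[, ipCol],
      input_rpm = ifelse(keep, inputRpm, NA_real_),
      ip_rpm = ifelse(keep, rpm[, ipCol], NA_real_),
      te_linear = te, log2_te = log2(te),
      filtered_low_input = rd$filtered_low_input,
      ip_pseudocounted = pse[, ipCol]
    )
    if (!is.null(rd$family)) df$family <- rd$family
    rownames(df) <- rownames(rd)
    .TETable(df, cond, S4Vectors::metadata(cc)$pseudocount,
             S4Vectors::metadata(cc)$min_input)
  })
  names(res) <- condition
  if (length(res) == 1L) res[[1]] else res
}

#' Counts to TE in one call
#'
#' Convenience wrapper chaining [combineReplicates()] (technical then
#' biological), [filterLowInput()], [computeRPM()] and [computeTE()].
#'
#' @inheritParams computeTE
#' @inheritParams filterLowInput
#' @inheritParams computeRPM
#' @param combine combine replicates before quantification.
#' @return as [computeTE()].
#' @export
teFromCounts <- function(cc, minInput = 10L, pseudocount = 1e-6,
                         condition = NULL, combine = TRUE) {
  if (combine) {
    cc <- combineReplicates(cc, "technical")
    cc <- combineReplicates(cc, "biological")
  }
  cc <- filterLowInput(cc, minInput)
  cc <- computeRPM(cc, pseudocount)
  computeTE(cc, condition)
}

#' Pairwise replicate correlation of log2 TE
#'
#' Pearson correlation of `log2_te` between replicate TE tables over the
#' constructs retained in both members of a pair, excluding any construct
#' with zero IP counts in either replicate of that pair.
#'
#' @param teTables list of per-replicate [TETable-class] objects.
#' @return list with `r` (correlation matrix) and `n` (matrix of construct
#'   counts used per pair).
#' @export
replicateCorrelation <- function(teTables) {
  k <- length(teTables)
  if (k < 2L) stop("need at least two replicates")
  nm <- names(teTables)
  if (is.null(nm)) nm <- paste0("rep", seq_len(k))
  r <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  n <- matrix(0L, k, k, dimnames = list(nm, nm))
  diag(r) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- teTables[[i]]; b <- teTables[[j]]
    key <- paste(a$construct_id, a$cap_class)
    m <- match(key, paste(b$construct_id, b$cap_class))
    ok <- !is.na(m) & !a$filtered_low_input & !b$filtered_low_input[m] &
      a$ip_count > 0 & b$ip_count[m] > 0
    if (sum(ok) < 2L) stop("fewer than 2 shared constructs for pair ",
                           nm[i], " vs ", nm[j])
    r[i, j] <- r[j, i] <- cor(a$log2_te[ok], b$log2_te[m][ok])
    n[i, j] <- n[j, i] <- sum(ok)
  }
  diag(n) <- vapply(teTables, function(t)
    sum(!t$filtered_low_input & t$ip_count > 0), 0L)
  list(r = r, n = n)
}

#' Background-corrected luciferase ratio
#'
#' `(nluc - nlucBg) / (fluc - flucBg)`, with backgrounds from untransfected
#' wells. Used to validate reporter TEs by individual co-transfections.
#'
#' @param nluc,fluc luminescence of the test (N-luc) and control (F-luc)
#'   reporters.
#' @param nlucBg,flucBg matched untransfected-well backgrounds.
#' @return the normalized ratio(s).
#' @export
normalizeLuciferase <- function(nluc, fluc, nlucBg, flucBg) {
  den <- fluc - flucBg
  if (any(den <= 0)) stop("non-positive F-luc signal after background subtraction")
  (nluc - nlucBg) / den
}

#' Write a TE table to TSV
#'
#' @param te a [TETable-class]
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeTETable <- function(te, path) {
  df <- as.data.frame(te)
  df$condition <- S4Vectors::metadata(te)$condition
  .writeTsv(df, path)
  invisible(path)
}
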