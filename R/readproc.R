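## Raw read pairs -> unique-UMI counts per (construct, cap class, sample).
## Stages: overlap merging, UMI/stagger extraction, cap-class splitting,
## stage-one duplicate collapse, ungapped assignment to the known construct
## set, unique-UMI counting. The external aligner of a conventional pipeline
## is replaced by exact/near-exact Hamming matching with an explicit
## ambiguity class: references are short and fully known, and mis-mapped
## reads inflate apparent weak IRES activity, so ties are discarded rather
## than broken.

.asCharReads <- function(x) {
  if (is(x, "XStringSet")) setNames(as.character(x), names(x)) else x
}

#' Read a FASTQ file as a character vector
#'
#' Qualities are not used anywhere in the pipeline and are dropped.
#'
#' @param path FASTQ path (gzip ok).
#' @return named character vector of read sequences (names = read ids).
#' @export
readFastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(dss), sub("\\s.*$", "", names(dss)))
}

#' Merge read pairs by ungapped overlap
#'
#' Aligns mate 1 against the reverse complement of mate 2 at every ungapped
#' offset; if the best overlap has length `>= minOverlap` and mismatch
#' fraction `<= maxMismatchRate`, the merged consensus is emitted
#' (disagreements resolved toward mate 1, which covers the UTR 5' end where
#' the cap-class adapter lives). Short inserts merge into single reads;
#' longer inserts stay as pairs.
#'
#' @param r1,r2 character vectors (or `DNAStringSet`) of mate sequences; if
#'   both are named the names must agree.
#' @param minOverlap minimum acceptable overlap length (nt).
#' @param maxMismatchRate maximum mismatch fraction within the overlap.
#' @return character vector: merged sequence, or `NA` where the pair stays
#'   unmerged.
#' @export
mergePairs <- function(r1, r2, minOverlap = 20L, maxMismatchRate = 0.1) {
  r1 <- .asCharReads(r1); r2 <- .asCharReads(r2)
  if (length(r1) != length(r2)) stop("mate vectors differ in length")
  if (!is.null(names(r1)) && !is.null(names(r2)) &&
      !identical(names(r1), names(r2)))
    stop("mate read ids do not match")
  r2rc <- .revcomp(r2)
  out <- cpp_merge_pairs(unname(r1), r2rc, as.integer(minOverlap),
                         maxMismatchRate)
  names(out) <- names(r1)
  out
}

#' Extract UMI and stagger from reads
#'
#' In `"merged"` mode the whole fragment is one read: the stagger is the
#' 0-6 nt prefix before the 5' anchor (located exactly, mirroring the
#' zero-error single-read dialect), and the UMI is the reverse complement of
#' the 9-11 bases past the reverse-complemented RT anchor at the fragment 3'
#' end. In `"paired"` mode the stagger comes from mate 1 (anchor located
#' with up to `floor(0.07 * 15) = 1` mismatch) and the UMI is the 9-11 nt
#' prefix of mate 2 before the RT anchor, whose offset disambiguates the UMI
#' length. Reads whose anchors cannot be located within budget get `NA`
#' UMIs and are excluded from counting downstream.
#'
#' @param reads merged reads (merged mode) or mate-1 reads (paired mode).
#' @param mate2 mate-2 reads (paired mode only).
#' @param mode `"merged"` or `"paired"`.
#' @param arch read architecture constants, see [readArchitecture()].
#' @return data.frame with `umi`, `stagger_len`, and `core` (the read
#'   portion between the 5' anchor and the RT anchor, still carrying the
#'   cap adapter and common adapter).
#' @export
extractUmiStagger <- function(reads, mate2 = NULL,
                              mode = c("merged", "paired"),
                              arch = readArchitecture()) {
  mode <- match.arg(mode)
  reads <- unname(.asCharReads(reads))
  la <- nchar(arch$pair5)
  budget <- if (mode == "merged") 0L else floor(0.07 * la)
  apos <- cpp_find_pattern(reads, arch$pair5, budget, 0L,
                           max(arch$staggerRange))
  stagger <- apos - 1L
  coreStart <- apos + la

  if (mode == "merged") {
    rcAnchor <- .revcomp(arch$rtAnchor)
    rpos <- cpp_find_pattern(reads, rcAnchor, 0L, 0L, -1L)
    umiRc <- substr(reads, rpos + nchar(rcAnchor), nchar(reads))
    umi <- ifelse(is.na(rpos), NA_character_, .revcomp(ifelse(is.na(rpos), "A", umiRc)))
    core <- substr(reads, coreStart, ifelse(is.na(rpos), 0L, rpos - 1L))
    core[is.na(apos) | is.na(rpos)] <- NA_character_
  } else {
    stopifnot(!is.null(mate2))
    mate2 <- unname(.asCharReads(mate2))
    ub <- floor(0.07 * nchar(arch$rtAnchor))
    rpos <- cpp_find_pattern(mate2, arch$rtAnchor, ub,
                             min(arch$umiLengths), max(arch$umiLengths))
    umi <- ifelse(is.na(rpos), NA_character_, substr(mate2, 1L, rpos - 1L))
    core <- substr(reads, coreStart, nchar(reads))
    core[is.na(apos)] <- NA_character_
  }
  badLen <- !is.na(umi) & !(nchar(umi) %in% arch$umiLengths)
  umi[badLen] <- NA_character_
  data.frame(umi = umi, stagger_len = stagger, core = core,
             stringsAsFactors = FALSE)
}

#' Split reads into cap classes and trim to the UTR insert
#'
#' Single (merged) mode mirrors an exact-match adapter dialect (`-e 0`):
#' the common adapter is located exactly and removed with everything
#' downstream; the remaining sequence is then searched for the A-cap and
#' G-cap adapters with zero mismatches. Paired mode allows
#' `floor(0.07 * nchar(adapter))` mismatches (`-e 0.07`) and expects the cap
#' adapter directly after the 5' anchor on the trimmed mate-1 core; the
#' common adapter, if reached, is also trimmed with up to the same budget.
#' Reads matching neither or both cap adapters are `unassigned` - a value,
#' not an error - and excluded from counting.
#'
#' @param cores character vector of reads after 5'-anchor/stagger removal
#'   (the `core` column of [extractUmiStagger()]).
#' @param mode `"single"` for merged reads, `"paired"` for mate-1 cores of
#'   unmerged pairs.
#' @param arch read architecture constants.
#' @return data.frame with `cap_class` (`a_cap`/`g_cap`/`unassigned`) and
#'   `insert` (the trimmed UTR-facing sequence; `NA` when unassigned).
#' @export
splitCapClasses <- function(cores, mode = c("single", "paired"),
                            arch = readArchitecture()) {
  mode <- match.arg(mode)
  cores <- unname(.asCharReads(cores))
  n <- length(cores)
  capClass <- rep("unassigned", n)
  insert <- rep(NA_character_, n)
  ok <- !is.na(cores)

  if (mode == "single") {
    cpos <- regexpr(arch$common, cores, fixed = TRUE)
    has <- ok & cpos > 0L
    left <- substr(cores, 1L, ifelse(has, cpos - 1L, 0L))
    apos <- regexpr(arch$acap, left, fixed = TRUE)
    gpos <- regexpr(arch$gcap, left, fixed = TRUE)
    isA <- has & apos > 0L & gpos < 0L
    isG <- has & gpos > 0L & apos < 0L
    capClass[isA] <- "a_cap"
    capClass[isG] <- "g_cap"
    st <- ifelse(isA, apos + nchar(arch$acap), gpos + nchar(arch$gcap))
    assigned <- isA | isG
    insert[assigned] <- substr(cores[assigned], st[assigned],
                               cpos[assigned] - 1L)
  } else {
    budget <- floor(0.07 * nchar(arch$acap))
    pa <- cpp_find_pattern(cores, arch$acap, budget, 0L, 0L)
    pg <- cpp_find_pattern(cores, arch$gcap, budget, 0L, 0L)
    isA <- ok & !is.na(pa) & is.na(pg)
    isG <- ok & !is.na(pg) & is.na(pa)
    capClass[isA] <- "a_cap"
    capClass[isG] <- "g_cap"
    assigned <- isA | isG
    body <- substr(cores, nchar(arch$acap) + 1L, nchar(cores))
    cb <- floor(0.07 * nchar(arch$common))
    cpos <- cpp_find_pattern(body, arch$common, cb, 0L, -1L)
    end <- ifelse(is.na(cpos), nchar(body), cpos - 1L)
    insert[assigned] <- substr(body[assigned], 1L, end[assigned])
  }
  data.frame(cap_class = capClass, insert = insert, stringsAsFactors = FALSE)
}

#' Stage-one duplicate collapse
#'
#' Collapses reads identical in (insert, UMI, stagger length) to one
#' representative. This mirrors the first collapse stage of the assay's
#' processing, which is deliberately partial: duplicates that differ only in
#' library stagger survive and are resolved later by unique-UMI counting.
#'
#' The collapse key includes the cap class when present: the original
#' collapse runs on untrimmed sequences, where the cap-class adapter still
#' separates A-cap from G-cap reads that share a trimmed insert.
#'
#' @param reads data.frame with at least `insert`, `umi`, `stagger_len`
#'   (and optionally `cap_class`).
#' @return the data.frame with duplicate rows removed.
#' @export
precollapseDuplicates <- function(reads) {
  if (!nrow(reads)) return(reads)
  key <- paste(reads$insert, reads$umi, reads$stagger_len, sep = "\r")
  if (!is.null(reads$cap_class))
    key <- paste(key, reads$cap_class, sep = "\r")
  reads[!duplicated(key), , drop = FALSE]
}

## admissible reference sequences: plain UTRs for both classes, plus the
## A-cap-barcoded form of each UTR for a_cap reads (the barcode may or may
## not have been consumed by adapter trimming upstream)
.referenceSet <- function(library, capClass) {
  utr <- as.character(utrSequences(library))
  ids <- constructIds(library)
  if (identical(capClass, "a_cap")) {
    refs <- c(utr, attachAcapBarcode(utr, acapBarcode(library), 0L))
    data.frame(ref = refs, construct_id = c(ids, ids),
               stringsAsFactors = FALSE)
  } else {
    data.frame(ref = utr, construct_id = ids, stringsAsFactors = FALSE)
  }
}

.assignAgainst <- function(inserts, refs, refIds, maxMismatches, prefix) {
  out <- rep("unassigned", length(inserts))
  ok <- which(!is.na(inserts) & nzchar(inserts))
  if (!length(ok)) return(out)
  uq <- unique(inserts[ok])
  res <- rep("unassigned", length(uq))
  if (prefix) {
    ## compare each insert against the same-length prefix of every
    ## sufficiently long reference, per insert-length group
    byLen <- split(seq_along(uq), nchar(uq))
    for (L in names(byLen)) {
      len <- as.integer(L)
      keep <- nchar(refs) >= len
      if (!any(keep)) next
      sub <- substr(refs[keep], 1L, len)
      hit <- cpp_hamming_assign(uq[byLen[[L]]], sub, as.integer(maxMismatches))
      ids <- refIds[keep]
      r <- ifelse(hit[, 1] == 0L, "unassigned",
                  ifelse(hit[, 3] > 1L, "ambiguous", ids[pmax(hit[, 1], 1L)]))
      res[byLen[[L]]] <- r
    }
  } else {
    ## exact fast path for inserts equal to a reference whose sequence is
    ## unique in the set; everything else takes the Hamming kernel
    uniqueRef <- !(duplicated(refs) | duplicated(refs, fromLast = TRUE))
    em <- match(uq, refs)
    fast <- !is.na(em) & uniqueRef[pmax(em, 1L)]
    res[fast] <- refIds[em[fast]]
    slow <- which(!fast)
    if (length(slow)) {
      hit <- cpp_hamming_assign(uq[slow], refs, as.integer(maxMismatches))
      res[slow] <- ifelse(hit[, 1] == 0L, "unassigned",
                          ifelse(hit[, 3] > 1L, "ambiguous",
                                 refIds[pmax(hit[, 1], 1L)]))
    }
  }
  out[ok] <- res[match(inserts[ok], uq)]
  out
}

#' Assign inserts to constructs by near-exact matching
#'
#' Ungapped full-insert comparison against the known construct set: the
#' unique construct whose UTR (with or without the A-cap barcode, consistent
#' with the read's cap class) matches within `maxMismatches` substitutions
#' wins. Two or more equally good best hits give `"ambiguous"`, no hit
#' within budget gives `"unassigned"`; both are excluded from counting.
#' With `prefix = TRUE` (unmerged pairs, which only observe the UTR 5'
#' end) the comparison runs against same-length reference prefixes.
#'
#' @param inserts character vector of trimmed inserts.
#' @param library a [ConstructLibrary-class]
#' @param maxMismatches substitution budget (default 2).
#' @param capClass `"a_cap"`, `"g_cap"`, or a per-insert vector; governs
#'   whether barcoded reference forms are admissible.
#' @param prefix compare against reference prefixes (unmerged-pair mode).
#' @return character vector of construct ids, `"ambiguous"`, or
#'   `"unassigned"`.
#' @export
assignToConstruct <- function(inserts, library, maxMismatches = 2L,
                              capClass = "g_cap", prefix = FALSE) {
  inserts <- unname(.asCharReads(inserts))
  if (length(capClass) == 1L) capClass <- rep(capClass, length(inserts))
  out <- rep("unassigned", length(inserts))
  for (cls in intersect(c("a_cap", "g_cap"), unique(capClass))) {
    sel <- which(capClass == cls)
    rs <- .referenceSet(library, cls)
    out[sel] <- .assignAgainst(inserts[sel], rs$ref, rs$construct_id,
                               maxMismatches, prefix)
  }
  out
}

#' Count unique UMIs per construct and cap class
#'
#' The count for a (construct, cap class, sample) key is the number of
#' distinct UMI strings observed for it; the same UMI seen on two different
#' constructs counts once for each. UMI matching is exact - no
#' near-duplicate clustering.
#'
#' @param assigned data.frame with `construct_id`, `cap_class`, `umi`
#'   (rows with `NA` UMI or non-construct assignment already excluded).
#' @param sampleId sample identifier for the output slice.
#' @return data.frame `construct_id`, `cap_class`, `sample_id`, `umi_count`.
#' @export
countUniqueUmis <- function(assigned, sampleId) {
  if (!nrow(assigned)) {
    return(data.frame(construct_id = character(), cap_class = character(),
                      sample_id = character(), umi_count = integer(),
                      stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(assigned[, c("construct_id", "cap_class", "umi")])
  cnt <- dt[, list(umi_count = data.table::uniqueN(umi)),
            by = c("construct_id", "cap_class")]
  cnt <- as.data.frame(cnt)
  cnt$sample_id <- sampleId
  cnt[order(cnt$construct_id, cnt$cap_class),
      c("construct_id", "cap_class", "sample_id", "umi_count")]
}

#' Process one sequencing sample to unique-UMI counts
#'
#' Chains the full per-sample read processing: FASTQ input, pair merging,
#' UMI/stagger extraction, cap-class splitting (single mode for merged
#' reads, paired mode for the rest), stage-one duplicate collapse,
#' construct assignment, unique-UMI counting.
#'
#' @param fastqR1,fastqR2 FASTQ paths for the mate files.
#' @param library a [ConstructLibrary-class]
#' @param sampleId sample identifier.
#' @param minOverlap,maxMismatchRate merge parameters, see [mergePairs()].
#' @param maxMismatches assignment budget, see [assignToConstruct()].
#' @param arch read architecture constants.
#' @param keepReads also return the per-read table (read id, merge status,
#'   cap class, UMI, assignment) for diagnostics.
#' @return list with `counts` (long data.frame as [countUniqueUmis()]),
#'   `report` (one-row data.frame: total, merged, a_cap, g_cap, unassigned,
#'   ambiguous), and optionally `reads`.
#' @export
processSample <- function(fastqR1, fastqR2, library, sampleId = "sample",
                          minOverlap = 20L, maxMismatchRate = 0.1,
                          maxMismatches = 2L, arch = readArchitecture(),
                          keepReads = FALSE) {
  r1 <- readFastq(fastqR1)
  r2 <- readFastq(fastqR2)
  if (!identical(names(r1), names(r2)))
    stop("mate read ids differ between ", fastqR1, " and ", fastqR2)
  ids <- names(r1)
  merged <- mergePairs(r1, r2, minOverlap, maxMismatchRate)
  isM <- !is.na(merged)

  n <- length(r1)
  umi <- rep(NA_character_, n)
  stag <- rep(NA_integer_, n)
  capClass <- rep("unassigned", n)
  insert <- rep(NA_character_, n)

  if (any(isM)) {
    ex <- extractUmiStagger(merged[isM], mode = "merged", arch = arch)
    sp <- splitCapClasses(ex$core, mode = "single", arch = arch)
    umi[isM] <- ex$umi; stag[isM] <- ex$stagger_len
    capClass[isM] <- sp$cap_class; insert[isM] <- sp$insert
  }
  if (any(!isM)) {
    ex <- extractUmiStagger(r1[!isM], mate2 = r2[!isM], mode = "paired",
                            arch = arch)
    sp <- splitCapClasses(ex$core, mode = "paired", arch = arch)
    umi[!isM] <- ex$umi; stag[!isM] <- ex$stagger_len
    capClass[!isM] <- sp$cap_class; insert[!isM] <- sp$insert
  }

  reads <- data.frame(read_id = ids, merged = isM, umi = umi,
                      stagger_len = stag, cap_class = capClass,
                      insert = insert, stringsAsFactors = FALSE)
  usable <- reads$cap_class != "unassigned" & !is.na(reads$umi)
  work <- precollapseDuplicates(reads[usable, , drop = FALSE])

  work$construct_id <- rep("unassigned", nrow(work))
  for (mrg in c(TRUE, FALSE)) {
    sel <- work$merged == mrg
    if (!any(sel)) next
    work$construct_id[sel] <- assignToConstruct(
      work$insert[sel], library, maxMismatches,
      capClass = work$cap_class[sel], prefix = !mrg)
  }

  good <- !(work$construct_id %in% c("ambiguous", "unassigned"))
  counts <- countUniqueUmis(work[good, , drop = FALSE], sampleId)
  report <- data.frame(
    sample_id = sampleId, total = n, merged = sum(isM),
    a_cap = sum(reads$cap_class == "a_cap"),
    g_cap = sum(reads$cap_class == "g_cap"),
    unassigned = sum(reads$cap_class == "unassigned"),
    ambiguous = sum(work$construct_id == "ambiguous"),
    stringsAsFactors = FALSE
  )
  out <- list(counts = counts, report = report)
  if (keepReads) {
    reads$construct_id <- NA_character_
    reads$construct_id[match(work$read_id, reads$read_id)] <- work$construct_id
    out$reads <- reads
  }
  out
}

#' Build a CapCounts object from a sample sheet
#'
#' Runs [processSample()] for every row of a sample sheet and assembles the
#' unique-UMI counts into a [CapCounts-class] over the full
#' (construct x cap class) grid (zeros where a key was never observed;
#' A-cap rows are kept for spike-ins too so the grid stays rectangular).
#'
#' @param samples data.frame (or TSV path) with columns `sample_id`,
#'   `fastq_r1`, `fastq_r2`, `role`, `condition`, `bio_rep`, `tech_rep`.
#' @param library a [ConstructLibrary-class]
#' @param ... passed to [processSample()].
#' @return a [CapCounts-class]; per-sample processing reports are stored in
#'   `metadata()$reports`.
#' @export
buildCapCounts <- function(samples, library, ...) {
  if (is.character(samples)) samples <- .readTsv(samples)
  need <- c("sample_id", "fastq_r1", "fastq_r2", "role", "condition",
            "bio_rep", "tech_rep")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
  res <- lapply(seq_len(nrow(samples)), function(i)
    processSample(samples$fastq_r1[i], samples$fastq_r2[i], library,
                  sampleId = samples$sample_id[i], ...))
  counts <- do.call(rbind, lapply(res, `[[`, "counts"))
  reports <- do.call(rbind, lapply(res, `[[`, "report"))
  cc <- CapCounts(counts, samples[need[-(2:3)]], library)
  S4Vectors::metadata(cc)$reports <- reports
  cc
}

#' Construct a CapCounts from long counts
#'
#' @param counts long data.frame with `construct_id`, `cap_class`,
#'   `sample_id`, `umi_count`.
#' @param samples data.frame with `sample_id`, `role`, `condition`,
#'   `bio_rep`, `tech_rep`.
#' @param library optional [ConstructLibrary-class]; fixes the row universe
#'   to every (construct, cap class) and annotates families.
#' @return a [CapCounts-class]
#' @export
CapCounts <- function(counts, samples, library = NULL) {
  if (is.null(library)) {
    ids <- unique(counts$construct_id)
    fam <- NULL
  } else {
    ids <- constructIds(library)
    fam <- constructFamily(library)
  }
  rd <- S4Vectors::DataFrame(
    construct_id = rep(ids, each = 2L),
    cap_class = rep(c("a_cap", "g_cap"), length(ids))
  )
  if (!is.null(fam)) rd$family <- fam[rd$construct_id]
  rownames(rd) <- paste(rd$construct_id, rd$cap_class, sep = ".")
  cd <- S4Vectors::DataFrame(samples)
  rownames(cd) <- cd$sample_id
  mat <- matrix(0L, nrow = nrow(rd), ncol = nrow(cd),
                dimnames = list(rownames(rd), rownames(cd)))
  key <- paste(counts$construct_id, counts$cap_class, sep = ".")
  bad <- !key %in% rownames(rd)
  if (any(bad))
    stop("counts name unknown constructs: ",
         paste(head(unique(counts$construct_id[bad])), collapse = ", "))
  mat[cbind(match(key, rownames(rd)),
            match(counts$sample_id, rownames(cd)))] <- as.integer(counts$umi_count)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat), rowData = rd, colData = cd)
  new("CapCounts", se)
}

setMethod("show", "CapCounts", function(object) {
  callNextMethod()
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("  roles: %s | conditions: %s\n",
              paste(names(table(cd$role)), table(cd$role), collapse = ", "),
              paste(unique(cd$condition), collapse = ", ")))
})
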