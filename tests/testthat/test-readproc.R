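arch <- readArchitecture()
rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

test_that("pair merging recovers exact overlaps with the right length", {
  frag <- unname(randomSeqs(1, 225, seed = 31))
  r1 <- substr(frag, 1, 150)
  r2 <- rc(substr(frag, 76, 225))
  m <- mergePairs(r1, r2)
  expect_equal(unname(m), frag)
  expect_equal(nchar(m), nchar(r1) + nchar(r2) - 75)
  # disagreements resolve toward mate 1
  r2bad <- r2
  substr(r2bad, 100, 100) <- ifelse(substr(r2bad, 100, 100) == "A", "C", "A")
  expect_equal(unname(mergePairs(r1, r2bad)), frag)
})

test_that("pairs without an acceptable overlap pass through unmerged", {
  a <- unname(randomSeqs(1, 150, seed = 32))
  b <- unname(randomSeqs(1, 150, seed = 33))
  expect_true(is.na(mergePairs(a, b, minOverlap = 20)))
  expect_error(mergePairs(setNames("ACGT", "x"), setNames("ACGT", "y")),
               "ids do not match")
})

test_that("merge decision respects the mismatch-rate budget at the boundary", {
  set.seed(34)
  frag <- unname(randomSeqs(1, 200, seed = 34))
  r1 <- substr(frag, 1, 120)
  tail20 <- substr(frag, 101, 200)  # r2 covers 101-200, overlap = 20
  flip <- function(s, k) {
    substr(s, k, k) <- chartr("ACGT", "GTAC", substr(s, k, k)); s
  }
  # floor(0.1 * 20) = 2 mismatches allowed within the 20-nt overlap
  ov2 <- tail20; for (k in c(3, 9)) ov2 <- flip(ov2, k)
  ov3 <- tail20; for (k in c(3, 9, 15)) ov3 <- flip(ov3, k)
  expect_false(is.na(mergePairs(r1, rc(ov2), minOverlap = 20,
                                maxMismatchRate = 0.1)))
  expect_true(is.na(mergePairs(r1, rc(ov3), minOverlap = 20,
                               maxMismatchRate = 0.1)))
})

test_that("cap-class splitting is exact in single mode, 7% tolerant in paired", {
  utr <- unname(randomSeqs(1, 80, seed = 35))
  mkCore <- function(ad) paste0(ad, utr, arch$common, "GACTACAAGG")
  single <- splitCapClasses(c(mkCore(arch$gcap), mkCore(arch$acap),
                              mkCore("AAAAAAAAAAAAAAAAA")), mode = "single")
  expect_equal(single$cap_class, c("g_cap", "a_cap", "unassigned"))
  expect_equal(single$insert[1:2], c(utr, utr))
  expect_true(is.na(single$insert[3]))

  # one substitution in the cap adapter: rejected in single mode (e = 0),
  # accepted in paired mode (floor(0.07 * 17) = 1)
  gcapMut <- paste0("A", substr(arch$gcap, 2, 17))
  expect_equal(splitCapClasses(mkCore(gcapMut), mode = "single")$cap_class,
               "unassigned")
  paired <- splitCapClasses(paste0(gcapMut, utr), mode = "paired")
  expect_equal(paired$cap_class, "g_cap")
  expect_equal(paired$insert, utr)
  # two substitutions exceed the paired budget
  gcapMut2 <- paste0("AA", substr(arch$gcap, 3, 17))
  expect_equal(splitCapClasses(paste0(gcapMut2, utr), mode = "paired")$cap_class,
               "unassigned")
})

test_that("UMI and stagger extraction locates the anchors", {
  utr <- unname(randomSeqs(1, 60, seed = 36))
  umi <- "ACGTACGTA"  # 9 nt
  core <- paste0(arch$gcap, utr, arch$common)
  merged <- paste0("NNN", arch$pair5, core, rc(arch$rtAnchor), rc(umi))
  ex <- extractUmiStagger(merged, mode = "merged")
  expect_equal(ex$stagger_len, 3L)
  expect_equal(ex$umi, umi)
  expect_equal(ex$core, core)
  # anchor absent: read excluded (NA umi), nothing invented
  noAnchor <- paste0("NNN", arch$pair5, core)
  ex2 <- extractUmiStagger(noAnchor, mode = "merged")
  expect_true(is.na(ex2$umi))
  # paired mode: umi from mate 2, stagger from mate 1
  m1 <- paste0("NN", arch$pair5, arch$acap, utr)
  m2 <- paste0("GATTACAGATT", arch$rtAnchor, rc(arch$common), rc(utr))
  ex3 <- extractUmiStagger(m1, mate2 = m2, mode = "paired")
  expect_equal(ex3$stagger_len, 2L)
  expect_equal(ex3$umi, "GATTACAGATT")  # 11 nt, disambiguated by offset
  # UMI lengths outside 9-11 are rejected
  m2short <- paste0("ACGTACGT", arch$rtAnchor, rc(arch$common))
  expect_true(is.na(extractUmiStagger(m1, mate2 = m2short, mode = "paired")$umi))
})

test_that("stage-one collapse keeps distinct stagger lengths apart", {
  df <- data.frame(insert = "AAA", umi = "CCCCCCCCC",
                   stagger_len = c(2, 2, 5, 5))
  expect_equal(nrow(precollapseDuplicates(df)), 2L)
  uniq <- data.frame(insert = c("A", "C"), umi = "G", stagger_len = 1)
  expect_equal(precollapseDuplicates(uniq), uniq)
  expect_equal(nrow(precollapseDuplicates(df[0, ])), 0L)
})

test_that("construct assignment matches a brute-force Hamming oracle", {
  set.seed(37)
  lib <- ConstructLibrary(randomSeqs(30, 60))
  refs <- as.character(utrSequences(lib))
  mutate <- function(s, k) {
    pos <- sample(nchar(s), k)
    for (p in pos) substr(s, p, p) <- chartr("ACGT", "CAGT"[c(2, 1, 4, 3)][1],
                                             substr(s, p, p))
    s
  }
  oracle <- function(ins, maxMM = 2) {
    d <- vapply(refs, function(r) hammingDist(ins, r), 0)
    best <- min(d)
    if (best > maxMM) return("unassigned")
    hits <- names(d)[d == best]
    if (length(hits) > 1) "ambiguous" else hits
  }
  queries <- c(refs[1:5],
               vapply(refs[sample(30, 20, TRUE)], function(s) {
                 k <- sample(0:4, 1)
                 if (k == 0) s else {
                   pos <- sample(nchar(s), k)
                   sp <- strsplit(s, "")[[1]]
                   sp[pos] <- vapply(sp[pos], function(b)
                     sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
                   paste(sp, collapse = "")
                 }
               }, ""))
  got <- assignToConstruct(queries, lib, maxMismatches = 2)
  expect_equal(unname(got), unname(vapply(queries, oracle, "")))
})

test_that("equidistant scanning siblings are ambiguous, never guessed", {
  wt <- strrep("GCGT", 5)  # A-free, so AAA windows differ predictably
  lib <- designScanningMutants(wt, 3, 1, "replace_AAA", wildtypeId = "W")
  seqs <- as.character(utrSequences(lib))
  # siblings from windows 1-3 and 2-4 differ at positions 1 and 4
  v1 <- seqs[["W_replace_AAA_1-3"]]; v2 <- seqs[["W_replace_AAA_2-4"]]
  expect_equal(hammingDist(v1, v2), 2)
  half <- v1
  substr(half, 1, 1) <- substr(v2, 1, 1)  # now equidistant (1 vs 1)
  expect_equal(hammingDist(half, v1), hammingDist(half, v2))
  expect_equal(unname(assignToConstruct(half, lib, maxMismatches = 4)),
               "ambiguous")
  # the wildtype itself (distance <= window from several variants) stays exact
  expect_equal(unname(assignToConstruct(wt, lib, maxMismatches = 0)), "W")
})

test_that("unique-UMI counting is a set cardinality per construct", {
  df <- data.frame(
    construct_id = c("X", "X", "X", "Y"),
    cap_class = "a_cap",
    umi = c("AAAAAAAAA", "AAAAAAAAA", "CCCCCCCCC", "AAAAAAAAA"))
  cnt <- countUniqueUmis(df, "s1")
  expect_equal(cnt$umi_count[cnt$construct_id == "X"], 2L)
  # the same UMI on two constructs counts once for each
  expect_equal(cnt$umi_count[cnt$construct_id == "Y"], 1L)
  # invariant to read order and to duplication
  perm <- df[sample(nrow(df)), ]
  expect_equal(countUniqueUmis(perm, "s1"), cnt)
  expect_equal(countUniqueUmis(rbind(df, df), "s1"), cnt)
})

test_that("every read lands in exactly one cap class (partition)", {
  lib <- testLibrary(nCand = 4)
  tr <- buildTruth(lib, config = list(readsPerSample = 2000L), seed = 41)
  d <- tempfile(); dir.create(d)
  simulateReads(tr, lib, "input", file.path(d, "r1.fq"), file.path(d, "r2.fq"),
                seed = 42)
  ps <- processSample(file.path(d, "r1.fq"), file.path(d, "r2.fq"), lib)
  rep <- ps$report
  expect_equal(rep$a_cap + rep$g_cap + rep$unassigned, rep$total)
})
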