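mkCC <- function(counts, samples) CapCounts(counts, samples)

test_that("replicate combination sums counts within groups", {
  counts <- data.frame(
    construct_id = "X", cap_class = "a_cap",
    sample_id = c("t1", "t2", "b2"),
    umi_count = c(3L, 7L, 5L))
  samples <- data.frame(
    sample_id = c("t1", "t2", "b2"), role = "input", condition = "control",
    bio_rep = c(1L, 1L, 2L), tech_rep = c(1L, 2L, 1L))
  cc <- mkCC(counts, samples)
  tech <- combineReplicates(cc, "technical")
  m <- SummarizedExperiment::assay(tech, "counts")
  expect_equal(unname(m["X.a_cap", ]), c(10L, 5L))
  bio <- combineReplicates(tech, "biological")
  expect_equal(unname(SummarizedExperiment::assay(bio, "counts")["X.a_cap", 1]),
               15L)
  # single replicate is the identity on counts
  one <- mkCC(counts[1, ], samples[1, ])
  expect_equal(unname(SummarizedExperiment::assay(
    combineReplicates(one, "technical"), "counts")["X.a_cap", 1]), 3L)
})

test_that("the input filter removes below 10 in any library, keeps exactly 10", {
  counts <- rbind(
    data.frame(construct_id = "weak", cap_class = "a_cap",
               sample_id = c("inA", "inB", "ip"), umi_count = c(9L, 1000L, 50L)),
    data.frame(construct_id = "edge", cap_class = "a_cap",
               sample_id = c("inA", "inB", "ip"), umi_count = c(10L, 10L, 50L)),
    data.frame(construct_id = "zero", cap_class = "a_cap",
               sample_id = c("inA", "inB", "ip"), umi_count = c(0L, 500L, 50L)))
  samples <- data.frame(sample_id = c("inA", "inB", "ip"),
                        role = c("input", "input", "IP"),
                        condition = c("control", "stress", "control"),
                        bio_rep = 1L, tech_rep = 1L)
  cc <- filterLowInput(mkCC(counts, samples), minInput = 10L)
  rd <- SummarizedExperiment::rowData(cc)
  flag <- setNames(rd$filtered_low_input, rownames(rd))
  expect_true(flag[["weak.a_cap"]])   # 9 in one input library is enough to drop
  expect_false(flag[["edge.a_cap"]])  # 10 is not "fewer than 10"
  expect_true(flag[["zero.a_cap"]])
  # monotone: raising the threshold never rescues a construct
  f20 <- SummarizedExperiment::rowData(filterLowInput(cc, 20L))$filtered_low_input
  expect_true(all(rd$filtered_low_input <= f20))
})

quantFixture <- function() {
  spec <- list(
    hi   = list(a_cap = c(400L, 200L), g_cap = c(300L, 300L)),
    lo   = list(a_cap = c(100L, 0L),   g_cap = c(100L, 400L)),
    gone = list(a_cap = c(5L, 60L),    g_cap = c(95L, 40L)))
  countsFromSpec(spec)
}

test_that("RPM normalization: whole-sample denominator, IP pseudocount, 1e6 total", {
  cc <- computeRPM(filterLowInput(quantFixture(), 10L), pseudocount = 1e-6)
  rpm <- SummarizedExperiment::assay(cc, "rpm")
  pse <- SummarizedExperiment::assay(cc, "pseudocounted")
  # input sample: retained total = 400+300+100+100+95 = 995? no - gone.a_cap
  # filtered, gone.g_cap retained: 400+300+100+100+95 = 995
  expect_equal(unname(rpm["hi.a_cap", "in1"]), 400 * 1e6 / 995)
  # zero IP count gets the pseudocount and the flag
  expect_true(pse["lo.a_cap", "ip1"])
  expect_gt(rpm["lo.a_cap", "ip1"], 0)
  # filtered rows carry NA and stay out of totals
  expect_true(is.na(rpm["gone.a_cap", "in1"]))
  tot <- colSums(rpm, na.rm = TRUE)
  expect_true(all(abs(tot - 1e6) < 1))
  expect_error(computeRPM(quantFixture()), "filterLowInput")
  expect_error(computeRPM(filterLowInput(quantFixture()), pseudocount = 0),
               "positive")
})

test_that("TE is the RPM ratio, log2'd, per cap class", {
  te <- teFromCounts(quantFixture(), combine = FALSE)
  expect_s4_class(te, "TETable")
  # equal input and IP RPM share -> TE 1... compute explicit expectations
  inTot <- 400 + 300 + 100 + 100 + 95
  ipTot <- 200 + 300 + 1e-6 + 400 + 40
  expect_equal(te$te_linear[rownames(te) == "hi.g_cap"],
               (300 / ipTot) / (300 / inTot))
  expect_equal(te$log2_te, log2(te$te_linear))
  expect_true(all(is.na(te$te_linear[te$filtered_low_input])))
  expect_true(te$ip_pseudocounted[rownames(te) == "lo.a_cap"])
  expect_true(is.finite(te$log2_te[rownames(te) == "lo.a_cap"]))
  expect_true(validObject(te))
})

test_that("TE is invariant to uniform sequencing depth changes", {
  # no construct near the input-filter boundary, so x7 leaves the retained
  # set unchanged and the invariance is exact
  cc1 <- countsFromSpec(list(
    hi = list(a_cap = c(400L, 200L), g_cap = c(300L, 300L)),
    lo = list(a_cap = c(100L, 50L), g_cap = c(100L, 400L)),
    zz = list(a_cap = c(0L, 60L), g_cap = c(95L, 40L))))
  counts7 <- data.frame(SummarizedExperiment::rowData(cc1)[
    rep(seq_len(nrow(cc1)), ncol(cc1)), c("construct_id", "cap_class")],
    sample_id = rep(colnames(cc1), each = nrow(cc1)),
    umi_count = as.vector(SummarizedExperiment::assay(cc1, "counts")) * 7L)
  cc7 <- CapCounts(counts7, as.data.frame(SummarizedExperiment::colData(cc1)))
  te1 <- teFromCounts(cc1, combine = FALSE)
  te7 <- teFromCounts(cc7, combine = FALSE)
  keep <- !te1$filtered_low_input & !te1$ip_pseudocounted
  expect_equal(te7$te_linear[keep], te1$te_linear[keep], tolerance = 1e-12)
})

test_that("replicate correlation excludes zero-IP constructs pairwise", {
  spec <- list(a = list(a_cap = c(100L, 50L)), b = list(a_cap = c(100L, 80L)),
               c = list(a_cap = c(100L, 0L)), d = list(a_cap = c(100L, 20L)))
  r1 <- teFromCounts(countsFromSpec(spec), combine = FALSE)
  spec2 <- spec; spec2$c$a_cap <- c(100L, 33L)
  r2 <- teFromCounts(countsFromSpec(spec2), combine = FALSE)
  qc <- replicateCorrelation(list(rep1 = r1, rep2 = r2))
  expect_equal(qc$r["rep1", "rep1"], 1)
  # construct c has zero IP in rep1: excluded from the pair
  # (a_cap and g_cap rows of a, b, d remain; g_cap rows are all-zero input
  # so filtered, leaving the three a_cap rows)
  expect_equal(qc$n["rep1", "rep2"], 3L)
  expect_true(abs(qc$r["rep1", "rep2"]) <= 1)
  expect_error(replicateCorrelation(list(r1)), "at least two")
})

test_that("luciferase normalization subtracts backgrounds and guards the ratio", {
  expect_equal(normalizeLuciferase(1100, 600, 100, 100), 2.0)
  expect_equal(normalizeLuciferase(100, 600, 100, 100), 0)
  expect_error(normalizeLuciferase(1100, 100, 100, 100), "non-positive")
})
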