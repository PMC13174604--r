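## a hand-built TE table: CrPV threshold at 1.0 (a_cap)
activityFixture <- function() {
  spec <- list(
    CrPV   = list(a_cap = c(1000L, 100L), g_cap = c(1000L, 400L)),
    strong = list(a_cap = c(1000L, 400L), g_cap = c(1000L, 400L)),
    equal  = list(a_cap = c(1000L, 100L), g_cap = c(1000L, 400L)),
    weak   = list(a_cap = c(1000L, 10L),  g_cap = c(1000L, 400L)),
    dead   = list(a_cap = c(1000L, 0L),   g_cap = c(1000L, 400L)))
  teFromCounts(countsFromSpec(spec), combine = FALSE)
}

test_that("activity threshold is the CrPV TE, inclusive", {
  calls <- classifyActive(activityFixture(), "CrPV")
  lab <- setNames(calls$label, calls$construct_id)
  expect_equal(lab[["CrPV"]], "active")     # reflexivity
  expect_equal(lab[["equal"]], "active")    # exactly at threshold
  expect_equal(lab[["strong"]], "active")
  expect_equal(lab[["weak"]], "inactive")
  expect_equal(lab[["dead"]], "inactive")   # pseudocounted zero-IP
  expect_true(all(calls$threshold_te ==
                    calls$ires_te[calls$construct_id == "CrPV"]))
  expect_error(classifyActive(activityFixture(), "absent"), "absent")
})

test_that("IRES as %CDI is the linear TE ratio times 100", {
  te <- activityFixture()
  pct <- iresPctCdi(te)
  # strong: a_cap TE == g_cap TE -> 100%
  expect_equal(unname(pct["strong"]), 100)
  # equal: IP 100 vs 400 at equal input -> 25%
  expect_equal(unname(pct["equal"]), 25)
  # ires_te 0.46, cdi_te 1.0 -> 46%
  spec <- list(x = list(a_cap = c(1000L, 46L), g_cap = c(1000L, 100L)))
  te2 <- teFromCounts(countsFromSpec(spec), combine = FALSE)
  expect_equal(unname(iresPctCdi(te2)["x"]), 46)
})

test_that("mutagenesis profiles map fold changes to window centers", {
  wt <- unname(randomSeqs(1, 20, seed = 61))
  lib <- designScanningMutants(wt, 3, 1, "replace_AAA", wildtypeId = "IAPV")
  man <- designManifest(lib)
  ids <- man$construct_id[man$rule != "wildtype"]
  # wildtype TE 1.0; variant k gets TE k/10
  spec <- c(setNames(lapply(seq_along(ids), function(k)
    list(a_cap = c(1000L, k * 10L), g_cap = c(1000L, 100L))), ids),
    list(IAPV = list(a_cap = c(1000L, 100L), g_cap = c(1000L, 100L))))
  te <- teFromCounts(countsFromSpec(spec), combine = FALSE)
  prof <- mutagenesisProfile(te, man)
  expect_equal(prof$position, (prof$start + prof$end) %/% 2L)
  expect_equal(prof$position[prof$start == 1], 2L)  # window 1-3 -> nt 2
  m <- match(ids, prof$construct_id)
  expect_equal(prof$fold_change[m], seq_along(ids) / 10, tolerance = 1e-9)
  # wildtype against itself is exactly 1 everywhere
  specWT <- c(setNames(lapply(ids, function(k)
    list(a_cap = c(1000L, 100L), g_cap = c(1000L, 100L))), ids),
    list(IAPV = list(a_cap = c(1000L, 100L), g_cap = c(1000L, 100L))))
  teWT <- teFromCounts(countsFromSpec(specWT), combine = FALSE)
  expect_true(all(mutagenesisProfile(teWT, man)$fold_change == 1))
  expect_error(mutagenesisProfile(te, man, wildtypeId = "nope"), "nope")
})

test_that("helix rescue quantifies compensatory restoration", {
  mk <- function(teL, teR, teC, teW) {
    spec <- list(L = list(a_cap = c(1000L, as.integer(teL * 100))),
                 R = list(a_cap = c(1000L, as.integer(teR * 100))),
                 C = list(a_cap = c(1000L, as.integer(teC * 100))),
                 W = list(a_cap = c(1000L, as.integer(teW * 100))))
    teFromCounts(countsFromSpec(spec), combine = FALSE)
  }
  # L = R = WT/16, C = WT/2 -> restoration 3/4
  r <- helixRescue(mk(1, 1, 8, 16), "L", "R", "C", "W")
  expect_equal(r$restoration_fraction, 0.75)
  # full rescue: C == WT
  r2 <- helixRescue(mk(1, 1, 16, 16), "L", "R", "C", "W")
  expect_equal(r2$restoration_fraction, 1)
  # no rescue: C at the geometric mean of L and R
  r3 <- helixRescue(mk(1, 4, 2, 16), "L", "R", "C", "W")
  expect_equal(r3$rescue_index, 1)
  expect_equal(r3$restoration_fraction, 0)
  expect_error(helixRescue(mk(1, 1, 8, 16), "L", "R", "C", "missing"),
               "missing")
})

test_that("rank-sum comparison matches the enumerated exact null", {
  # complete separation at n = 2 vs 2: one of C(4,2) = 6 orderings
  res <- compareGcGroups(c(a = 80, b = 90, c = 10, d = 20),
                         setNames(c("active", "active", "inactive", "inactive"),
                                  c("a", "b", "c", "d")))
  expect_equal(res$p_value, 1 / 6)
  expect_equal(res$U, 4)
  expect_equal(res$n_active, 2L)
  # label permutations under the null give a uniform-ish p (sanity: the
  # separation p is the minimum achievable)
  set.seed(62)
  ps <- replicate(20, {
    lab <- sample(c("active", "active", "inactive", "inactive"))
    compareGcGroups(c(a = 80, b = 90, c = 10, d = 20),
                    setNames(lab, c("a", "b", "c", "d")))$p_value
  })
  expect_true(all(ps >= 1 / 6))
  expect_error(compareGcGroups(c(a = 1, b = 2),
                               setNames(c("active", "inactive"), c("a", "b"))),
               "at least two")
})
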