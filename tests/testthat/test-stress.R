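## deep count-level coverage so the tiny spike-in 1 (~1e-4 of the pool)
## carries enough molecules for stable factor estimates. A global
## IP-efficiency drop hits the treated lysate's reporters but not the
## spike-ins, whose ribosome loading was fixed in the unstressed donor
## lysate; `unaffected` exempts further constructs from the drop.
stressFixture <- function(globalIpFactor = 1, nMol = 3e6, seed = 7,
                          unaffected = character(),
                          fixedAbundance = NULL) {
  lib <- testLibrary(nCand = 6, seed = 19)
  truth <- buildTruth(lib, config = list(fixedTE = 1,
                                         fixedAbundance = fixedAbundance),
                      seed = seed)
  hit <- setdiff(constructIds(lib), unaffected)
  truths <- list(control = truth,
                 stress = scaleTrueTE(truth, globalIpFactor,
                                      constructs = hit,
                                      includeSpikeIns = FALSE))
  samples <- rbind(singleSampleSheet("control"), singleSampleSheet("stress"))
  cc <- simulateCountMatrix(truths, lib, samples, nMolecules = nMol,
                            seed = seed + 1)
  tes <- teFromCounts(cc)
  list(lib = lib, tes = tes, spikes = spikeInSetFromLibrary(lib))
}

test_that("identical conditions give unit factors", {
  fx <- stressFixture(globalIpFactor = 1)
  fit <- fitSpikeInFactors(fx$tes, fx$spikes, reference = "control")
  expect_equal(unname(normFactors(fit)["control"]), 1)
  expect_equal(unname(normFactors(fit)["stress"]), 1, tolerance = 0.1)
  expect_true(all(fit@linearityR2 > 0.99))
})

test_that("a global 2x IP-efficiency drop is absorbed by the spike factor", {
  # the exempt constructs are a small slice of the pool (as positive
  # controls are in a real library), so the drop is effectively global
  fx <- stressFixture(globalIpFactor = 0.5, nMol = 1e7,
                      unaffected = c("c001", "CrPV"),
                      fixedAbundance = c(c001 = 0.01, c002 = 1, c003 = 1,
                                         c004 = 1, c005 = 1, c006 = 1,
                                         CrPV = 0.01))
  fit <- fitSpikeInFactors(fx$tes, fx$spikes, reference = "control")
  # factor = geomean(te_ref / te_stress) over spikes; its reciprocal is the
  # measured global IP-efficiency shift
  expect_equal(1 / unname(normFactors(fit)["stress"]), 2, tolerance = 0.05)
  d <- differentialTE(adjustTE(fx$tes$control, fit),
                      adjustTE(fx$tes$stress, fit))
  un <- d$construct_id %in% c("c001", "CrPV")
  sp <- grepl("^spike", d$construct_id)
  # unaffected constructs: no differential TE after adjustment
  expect_true(all(abs(d$log2_fc[un]) < 0.1))
  # affected constructs recover the imposed 2x drop
  expect_equal(mean(d$log2_fc[!un & !sp]), -1, tolerance = 0.05)
})

test_that("adjustTE is the multiplicative factor, identity at factor 1", {
  fx <- stressFixture()
  fit <- fitSpikeInFactors(fx$tes, fx$spikes, reference = "control")
  adj <- adjustTE(fx$tes$control, fit)
  expect_equal(adj$te_linear, fx$tes$control$te_linear)  # reference: factor 1
  fit@factors[["stress"]] <- 2
  adj2 <- adjustTE(fx$tes$stress, fit, condition = "stress")
  expect_equal(adj2$te_linear, fx$tes$stress$te_linear * 2)
  expect_equal(adj2$log2_te, fx$tes$stress$log2_te + 1)
  expect_error(adjustTE(fx$tes$control, fit, condition = "unknown"),
               "no fitted factor")
})

test_that("spike TEs agree across conditions after their own adjustment", {
  fx <- stressFixture(globalIpFactor = 0.5, nMol = 1e6)
  fit <- fitSpikeInFactors(fx$tes, fx$spikes, reference = "control")
  a <- adjustTE(fx$tes$control, fit)
  b <- adjustTE(fx$tes$stress, fit)
  key <- paste(a$construct_id, a$cap_class)
  for (sp in fit@spikeIds) {
    i <- match(paste(sp, "g_cap"), key)
    expect_equal(log2(b$te_linear[i] / a$te_linear[i]), 0, tolerance = 0.2)
  }
})

test_that("factors compose across reference choices", {
  fx <- stressFixture(globalIpFactor = 0.5, nMol = 3e5)
  fitA <- fitSpikeInFactors(fx$tes, fx$spikes, reference = "control")
  fitB <- fitSpikeInFactors(fx$tes, fx$spikes, reference = "stress")
  fA <- normFactors(fitA); fB <- normFactors(fitB)
  # re-expressing control-referenced factors against stress equals fitB
  expect_equal(unname(fA["stress"] / fA["control"]),
               unname(fB["control"] ^ -1), tolerance = 1e-9)
  expect_equal(unname(fB["stress"]), 1)
})

test_that("differentialTE: zero for identical inputs, direction for mixtures", {
  fx <- stressFixture()
  te <- fx$tes$control
  d0 <- differentialTE(te, te)
  expect_true(all(d0$log2_fc == 0))
  # IRES up 2x, CDI down 40%: %CDI must rise
  lib <- fx$lib
  truth <- buildTruth(lib, config = list(fixedTE = 2), seed = 3)
  stressT <- scaleTrueTE(scaleTrueTE(truth, 2, capClass = "a_cap",
                                     includeSpikeIns = FALSE),
                         0.6, capClass = "g_cap", includeSpikeIns = FALSE)
  samples <- rbind(singleSampleSheet("control"), singleSampleSheet("stress"))
  cc <- simulateCountMatrix(list(control = truth, stress = stressT), lib,
                            samples, nMolecules = 2e5, seed = 8)
  tes <- teFromCounts(cc)
  fit <- fitSpikeInFactors(tes, fx$spikes, reference = "control")
  d <- differentialTE(adjustTE(tes$control, fit), adjustTE(tes$stress, fit))
  cand <- grepl("^c0", d$construct_id)
  expect_true(all(d$pct_cdi_stress[cand] > d$pct_cdi_control[cand]))
})

test_that("missing spikes are reported by name", {
  fx <- stressFixture()
  spikes <- SpikeInSet(c("spike1", "spike2", "nope"))
  expect_error(fitSpikeInFactors(fx$tes, spikes, reference = "control"),
               "nope")
})
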