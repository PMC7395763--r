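# Saltelli design and Sobol index estimation.

test_that("the Saltelli design has the documented shape and bounds", {
  sp <- makeParameterSpace(c(u_glu = 16.7e-12, u_o2 = 2.93e-15, u_ym = 1050,
                             s = 0.5))
  d <- saltelliDesign(sp, 128, seed = 1)
  expect_equal(nrow(d), 128 * (4 + 2))
  expect_equal(colnames(d), sp@parameters)
  for (j in 1:4) {
    expect_true(all(d[, j] >= sp@lower[j] & d[, j] <= sp@upper[j]))
    expect_equal(sp@lower[j], sp@reference[j] * 0.6, tolerance = 1e-12)
    expect_equal(sp@upper[j], sp@reference[j] * 1.4, tolerance = 1e-12)
  }
  expect_identical(d, saltelliDesign(sp, 128, seed = 1))
  expect_error(saltelliDesign(sp, 4), "at least 8")
  expect_error(makeParameterSpace(c(a = 1), lower = 1, upper = 1),
               "positive width")
})

test_that("an additive two-parameter model splits the variance evenly", {
  sp <- makeParameterSpace(c(x1 = 0.5, x2 = 0.5), lower = c(0, 0),
                           upper = c(1, 1))
  d <- saltelliDesign(sp, 512, seed = 4)
  out <- sobolIndices(function(p) p[["x1"]] + p[["x2"]], d, nBoot = 50)
  # 3 sigma Monte-Carlo bounds at this base sample size
  expect_lt(max(abs(out$S1 - 0.5)), 0.12)
  expect_lt(max(abs(out$ST - 0.5)), 0.12)
  expect_true(all(abs(out$ST - out$S1) < 0.12))   # additive: total = first order
  expect_false(any(out$outOfRange))
  expect_true(all(out$S1_lo <= out$S1 & out$S1 <= out$S1_hi))
})

test_that("a constant model yields undefined indices", {
  sp <- makeParameterSpace(c(a = 1, b = 2))
  d <- saltelliDesign(sp, 16, seed = 2)
  expect_message(out <- sobolIndices(function(p) 3.14, d), "zero variance")
  expect_true(all(is.na(out$S1)))
})

test_that("the Ishigami indices are recovered within Monte-Carlo error", {
  sp <- makeParameterSpace(c(x1 = 0, x2 = 0, x3 = 0), lower = rep(-pi, 3),
                           upper = rep(pi, 3))
  d <- saltelliDesign(sp, 512, seed = 10)
  out <- sobolIndices(function(p) ishigami(p), d, nBoot = 50)
  truth <- ishigamiIndices()
  # 3 sigma Monte-Carlo bounds at this base sample size
  expect_lt(max(abs(out$S1 - c(truth$S1, truth$S2, truth$S3))), 0.15)
  expect_lt(max(abs(out$ST - c(truth$ST1, truth$ST2, truth$ST3))), 0.2)
})

test_that("index estimates do not depend on parameter ordering", {
  f <- function(p) 2 * p[["x1"]] + p[["x2"]]
  spA <- makeParameterSpace(c(x1 = 0.5, x2 = 0.5), lower = c(0, 0),
                            upper = c(1, 1))
  spB <- makeParameterSpace(c(x2 = 0.5, x1 = 0.5), lower = c(0, 0),
                            upper = c(1, 1))
  outA <- sobolIndices(f, saltelliDesign(spA, 512, seed = 3), nBoot = 20)
  outB <- sobolIndices(f, saltelliDesign(spB, 512, seed = 3), nBoot = 20)
  sA <- stats::setNames(outA$S1, outA$parameter)
  sB <- stats::setNames(outB$S1, outB$parameter)
  expect_lt(max(abs(sA[c("x1", "x2")] - sB[c("x1", "x2")])), 0.12)
})

test_that("the output-SD time course starts at zero density spread", {
  cfg <- tinyConfig(nLayers = 4L, hours = 4)
  sp <- makeParameterSpace(cfg@parameters[c("a", "c")], relVariation = 0.4)
  tc <- outputStdTimecourse(sp, cfg, nSamples = 3, seed = 2,
                            nReplicateSeeds = 1)
  expect_equal(nrow(tc), 5)
  expect_equal(tc$sdDensity[1], 0)   # density is pinned to 1 at the start
  expect_true(all(is.finite(tc$sdYoungModulus)))
})

test_that("the simulator wrapper produces a scalar, parameter-sensitive output", {
  cfg <- tinyConfig(nLayers = 4L, hours = 4)
  model <- makeSimulatorModel(cfg, "meanYoungModulus", nReplicateSeeds = 1)
  row <- cfg@parameters[c("a", "lox")]
  y1 <- model(row)
  expect_true(is.finite(y1) && length(y1) == 1)
  y0 <- model(replace(row, "lox", 0))
  expect_equal(y0, 47)
  expect_gt(y1, 47)
})
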