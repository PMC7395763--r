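# Analysis layer: density, MAPE, radial profiles, stiffness, comparisons.

test_that("cell density is living cells normalised to the initial population", {
  res <- runSimulation(tinyConfig(hours = 12), seed = 2)
  d <- densitySeries(res)
  expect_equal(d$density[1], 1)
  expect_equal(nrow(d), 13)
  living <- res@counts[, "P"] + res@counts[, "Q"]
  expect_equal(d$density, unname(living / living[1]))

  # deterministic rules, counted by hand: all proliferant cells die at the
  # first iteration and degrade at the second
  cfg <- tinyConfig(nLayers = 3L, hours = 3,
                    rules = c("die: P -> D, 1", "deg: D -> empty, 1"))
  dd <- densitySeries(runSimulation(cfg, seed = 1))
  expect_equal(dd$density, c(1, 0, 0, 0))
})

test_that("MAPE is the elementwise absolute relative error", {
  expect_equal(mape(c(1, 1.25, 0.5, 1.5), c(1, 1, 1, 1)), c(0, 0.25, 0.5, 0.5))
  expect_error(mape(1, 0), "non-positive")
  expect_error(mape(c(1, 2), 1), "matched")
})

test_that("radial profiles are flat at the initial instant", {
  rs <- runReplicates(tinyConfig(hours = 6), 2, baseSeed = 3)
  for (q in c("Glc", "O2", "YM")) {
    prof <- radialProfile(rs, q)
    expect_equal(unname(prof@values[, 1]), rep(1, length(prof@bins)), info = q)
  }
  prof <- radialProfile(rs, "density")
  first <- prof@values[, 1]
  expect_true(all(is.na(first) | abs(first - 1) < 1e-12))
  expect_equal(sum(prof@binVoxelCounts), 125)
})

test_that("stiffness summaries report both dispersion views", {
  rs <- runReplicates(defaultConfig("mdamb231", hours = 24), 3, baseSeed = 9)
  pooled <- stiffnessSummary(rs, "pooled")
  per <- stiffnessSummary(rs, "per_scaffold")
  expect_equal(pooled$mean, per$mean, tolerance = 1e-9)
  expect_gt(pooled$mean, 47)
  expect_equal(pooled$dispersionRatio, per$dispersionRatio)
  expect_gt(pooled$dispersion, per$dispersion)
  expect_error(stiffnessSummary(rs[1], "per_scaffold"), "at least 2")

  # identical replicates: per-scaffold dispersion and CI width collapse to 0
  rs2 <- list(rs[[1]], rs[[1]])
  per2 <- stiffnessSummary(rs2, "per_scaffold")
  expect_equal(per2$dispersion, 0)
  expect_equal(diff(per2$ci), 0)

  # untouched scaffold: mean 47 in both modes
  rs0 <- runReplicates(applyParameters(defaultConfig("mdamb231", hours = 12),
                                       c(lox = 0)), 2, baseSeed = 1)
  expect_equal(stiffnessSummary(rs0, "pooled")$mean, 47)
  expect_equal(stiffnessSummary(rs0, "per_scaffold")$mean, 47)
})

test_that("the dispersion ratio matches a constructed variance decomposition", {
  base <- runSimulation(tinyConfig(hours = 1), seed = 1)
  n <- 125
  w <- scale(stats::rnorm(n), center = TRUE, scale = FALSE)[, 1]  # mean 0
  b <- c(0, 2, 4, 6)
  rs <- lapply(b, function(bk) {
    r <- base
    r@snapshots[["1"]]$youngModulus <- array(50 + bk + w, dim = c(5, 5, 5))
    r
  })
  got <- stiffnessSummary(rs, "pooled")
  K <- length(b)
  pooledVar <- (K * sum((w - mean(w))^2) + n * sum((b - mean(b))^2)) /
    (K * n - 1)
  expect_equal(got$dispersion, sqrt(pooledVar), tolerance = 1e-12)
  expect_equal(got$dispersionRatio, sqrt(pooledVar) / stats::sd(b),
               tolerance = 1e-12)
})

test_that("group comparison reproduces the rank-sum oracle", {
  out <- compareGroups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out$statistic, 0)
  expect_false(out$degenerate)

  tied <- compareGroups(c(47, 47), c(47, 47))
  expect_true(tied$degenerate)
  expect_equal(tied$statistic, 0)

  sep <- compareGroups(rep(47, 20), rep(58, 20))
  expect_lt(sep$p.value, 1e-6)

  # tie-free hand-ranked example: H from the rank-sum formula
  a <- c(1, 5, 7); bb <- c(2, 3, 9)
  ranks <- rank(c(a, bb))
  N <- 6
  H <- 12 / (N * (N + 1)) *
    (sum(ranks[1:3])^2 / 3 + sum(ranks[4:6])^2 / 3) - 3 * (N + 1)
  expect_equal(compareGroups(a, bb)$statistic, H, tolerance = 1e-12)
})

test_that("shell spread summarises intrascaffold stiffness variability", {
  rs <- runReplicates(applyParameters(defaultConfig("mdamb231", hours = 12),
                                      c(lox = 0)), 2, baseSeed = 2)
  expect_equal(shellRelativeSpread(rs), 0)   # untouched scaffold: no spread
})
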