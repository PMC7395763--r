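# Fick's-law transport: FTCS solver, boundary modes, media changes.

test_that("a uniform field in equilibrium with its boundary is a fixed point", {
  f <- array(4.5, c(5, 5, 5))
  for (mode in c("reservoir", "dirichlet", "zero-flux")) {
    out <- diffusionStep(f, 2.412, 1, 2, mode, boundaryValue = 4.5,
                         mediumVolume = 1)
    expect_equal(out$field, f, info = mode)
  }
  expect_equal(diffusionStep(f, 2.412, 1, 2, "reservoir", 4.5, 1)$reservoir, 4.5)
})

test_that("zero-flux transport conserves mass to 1e-10 relative", {
  set.seed(3)
  f <- array(runif(343, 0, 5), c(7, 7, 7))
  m0 <- sum(f)
  for (i in 1:5) f <- diffusionStep(f, 3.1, 1, 1.5, "zero-flux")$field
  expect_lt(abs(sum(f) - m0) / m0, 1e-10)
  expect_true(all(f >= 0))
})

test_that("a single-voxel pulse matches the heat kernel within 1%", {
  n <- 21
  g <- array(0, c(n, n, n))
  g[11, 11, 11] <- 1
  for (t in c(8, 12)) {
    out <- diffusionStep(g, 2.412, t, 1, "zero-flux")$field
    expect_lt(abs(out[11, 11, 11] / heatKernelCenter(2.412, t, 1, n) - 1),
              0.01, label = sprintf("relative center error at t=%g", t))
  }
})

test_that("solutions converge under sub-step refinement (first order)", {
  set.seed(4)
  f0 <- array(4.5, c(6, 6, 6))
  f0[3, 3, 3] <- 1
  f0[5, 2, 4] <- 2.5
  run <- function(pieces) {
    f <- f0
    for (i in seq_len(pieces))
      f <- diffusionStep(f, 2.412, 1 / pieces, 1, "zero-flux")$field
    f
  }
  coarse <- run(1)
  fine <- run(4)      # quarters dt_sub
  finest <- run(16)
  e1 <- max(abs(coarse - finest))
  e2 <- max(abs(fine - finest))
  expect_lt(e2, e1)                       # refinement reduces the error
  expect_lt(e1 / max(finest), 5e-3)       # already small at the default step
})

test_that("mirror-symmetric initial conditions stay symmetric", {
  n <- 8
  f <- array(0, c(n, n, n))
  f[2, 4, 4] <- 3
  f[n - 1, 4, 4] <- 3   # symmetric under x -> n+1-x
  for (mode in c("zero-flux", "dirichlet")) {
    out <- diffusionStep(f, 2.0, 2, 1, mode, boundaryValue = 1,
                         mediumVolume = 1)$field
    expect_equal(out, out[n:1, , ], info = mode)
  }
})

test_that("reservoir mode exchanges mass with a finite medium", {
  f <- array(0, c(5, 5, 5))   # empty scaffold, full reservoir
  out <- diffusionStep(f, 2.412, 1, 2, "reservoir", boundaryValue = 4.5,
                       mediumVolume = 1)
  voxL <- 8e-6
  gained <- sum(out$field) * voxL
  lost <- (4.5 - out$reservoir) * 1e-3
  expect_gt(gained, 0)
  expect_equal(gained, lost, tolerance = 1e-9)
})

test_that("media change resets glucose everywhere and only glucose", {
  cfg <- tinyConfig()
  res <- runSimulation(cfg, seed = 2)
  st <- createState(cfg)
  st@glucose[] <- runif(125, 0, 2)
  st@mediumGlucose <- 0.3
  o2Before <- oxygenField(st)
  st2 <- applyMediaChange(st)
  expect_true(all(glucoseField(st2) == cfg@diffusion@mediaGlucose))
  expect_equal(st2@mediumGlucose, cfg@diffusion@mediaGlucose)
  expect_identical(oxygenField(st2), o2Before)
  expect_identical(applyMediaChange(st2), st2)   # idempotent
})

test_that("invalid transport inputs are rejected", {
  f <- array(1, c(4, 4, 4))
  expect_error(diffusionStep(f, 1, 0, 1, "zero-flux"), "dt must be positive")
  f[1] <- NaN
  expect_error(diffusionStep(f, 1, 1, 1, "zero-flux"), "non-finite")
})
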