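# Engine: environmental rules, behavioural selection, full runs, replicates.

test_that("environmental uptake matches the arithmetic oracle", {
  cfg <- defaultConfig("mdamb231")
  scale <- scaffoldsim:::.defaultScale(cfg)
  expect_equal(scale@aggregationRatio, 5e6 / 21)
  st <- createState(cfg)
  st <- seedUniform(st, 1, c(P = 1), seed = 1)
  pos <- cellRecords(st)[1, c("x", "y", "z")]
  st2 <- applyEnvironmentalRules(st, cfg, scale)
  drop <- glucoseField(st)[pos$x + 1, pos$y + 1, pos$z + 1] -
    glucoseField(st2)[pos$x + 1, pos$y + 1, pos$z + 1]
  # aggregation x 16.7e-12 g/cell/h over a 1 mm^3 voxel
  expect_equal(drop, 5e6 / 21 * 16.7e-12 / 1e-6, tolerance = 1e-12)
  expect_equal(drop, 3.976, tolerance = 1e-3)
  # uptake floors at zero, never negative
  st3 <- applyEnvironmentalRules(st2, cfg, scale)
  expect_true(all(glucoseField(st3) >= 0))
})

test_that("quiescent cells consume the fraction s of proliferant amounts", {
  cfg <- tinyConfig(parameters = replace(scaffoldsim:::.DEFAULT_PARAMS, "s", 0.5))
  scale <- scaffoldsim:::.defaultScale(cfg)
  st <- createState(cfg)
  st <- seedUniform(st, 2, c(P = 0.5, Q = 0.5), seed = 8)
  cells <- cellRecords(st)
  # force one of each type
  st@cells$type <- c("P", "Q")
  st2 <- applyEnvironmentalRules(st, cfg, scale)
  at <- function(s, r) glucoseField(s)[r$x + 1, r$y + 1, r$z + 1]
  dP <- at(st, cells[1, ]) - at(st2, cells[1, ])
  dQ <- at(st, cells[2, ]) - at(st2, cells[2, ])
  expect_equal(dQ, dP / 2, tolerance = 1e-12)
})

test_that("stiffening requires lox > 0 and only ever increases", {
  cfg0 <- applyParameters(defaultConfig("mdamb231", hours = 24), c(lox = 0))
  res0 <- runSimulation(cfg0, seed = 5)
  expect_true(all(res0@snapshots[["24"]]$youngModulus == 47))

  cfg <- defaultConfig("mdamb231", hours = 48)
  res <- runSimulation(cfg, seed = 5)
  expect_true(all(res@snapshots[["48"]]$youngModulus >= 47))
  ymMeans <- res@meanFields[, "youngModulus"]
  expect_true(all(diff(ymMeans) >= -1e-12))
})

test_that("stiffening reaches the whole neighbourhood with a conserved total", {
  cfg <- tinyConfig(hours = 1, rules = c("stiff: P -> U, environment (YM)"),
                    mediaChangeHours = 0)
  scale <- scaffoldsim:::.defaultScale(cfg)
  st <- createState(cfg)
  st <- seedUniform(st, 1, c(P = 1), seed = 3)
  st2 <- applyEnvironmentalRules(st, cfg, scale)
  gain <- youngModulusField(st2) - 47
  expect_equal(sum(gain > 0), length(neighbourhood(
    unlist(cellRecords(st)[1, c("x", "y", "z")]), st)) + 1)
  p <- cfg@parameters
  expect_equal(sum(gain), 7 * p[["lox"]] * p[["u_ym"]] * 1, tolerance = 1e-9)
})

test_that("behavioural selection honours degenerate probabilities", {
  # all probabilities zero: the state is untouched
  cfg <- tinyConfig(rules = c("dup: P -> P + P, 0"))
  st <- seedUniform(createState(cfg), 4, c(P = 1), seed = 2)
  set.seed(1)
  st2 <- selectAndExecuteBehaviour(1L, st, cfg, 1, 24)
  expect_identical(cellGrid(st2), cellGrid(st))
  expect_identical(cellRecords(st2), cellRecords(st))

  # duplication with every neighbour occupied is a silent no-op
  cfg3 <- tinyConfig(nLayers = 3L, rules = c("dup: P -> P + P, 1"))
  full <- seedUniform(createState(cfg3), 27, c(P = 1), seed = 2)
  center <- which(cellRecords(full)$x == 1 & cellRecords(full)$y == 1 &
                    cellRecords(full)$z == 1)
  set.seed(1)
  out <- selectAndExecuteBehaviour(cellRecords(full)$id[center], full, cfg3, 1, 24)
  expect_identical(cellGrid(out), cellGrid(full))
  expect_equal(cellRecords(out)$last_division, cellRecords(full)$last_division)

  # forced degradation empties the site within one iteration
  cfgD <- tinyConfig(rules = c("die: P -> D, 1", "deg: D -> empty, 1"),
                     hours = 2)
  res <- runSimulation(cfgD, seed = 1)
  expect_equal(sum(res@counts[2, ]), res@initialCount)  # all dead, still occupying
  expect_equal(unname(res@counts[2, "D"]), res@initialCount)
  expect_equal(sum(res@counts[3, ]), 0)                 # degraded
})

test_that("probabilities summing above one are renormalized with a warning", {
  cfg <- tinyConfig(rules = c("q1: P -> Q, 0.8", "q2: P -> D, 0.8"), hours = 1)
  expect_warning(runSimulation(cfg, seed = 1), "renormalizing")
})

test_that("an empty scaffold in equilibrium is a fixed point of an iteration", {
  cfg <- defaultConfig("mdamb231")
  st <- createState(cfg)
  st2 <- runIteration(st, cfg, 1, 240)
  expect_equal(glucoseField(st2), glucoseField(st))
  expect_equal(oxygenField(st2), oxygenField(st))
  expect_equal(youngModulusField(st2), youngModulusField(st))
  expect_equal(nrow(cellRecords(st2)), 0)
})

test_that("a media-change iteration restores the interior glucose", {
  cfg <- defaultConfig("mdamb231")   # media change every 24 h
  st <- createState(cfg)
  st@glucose[] <- 0.2                # heavily depleted
  st2 <- runIteration(st, cfg, 24, 240)
  expect_true(all(glucoseField(st2) == 4.5))
  st3 <- runIteration(st, cfg, 23, 240)   # not due yet
  expect_true(all(glucoseField(st3) < 4.5))
})

test_that("runs are bitwise reproducible and correctly bookkept", {
  cfg <- tinyConfig(hours = 18)
  r1 <- runSimulation(cfg, seed = 7)
  r2 <- runSimulation(cfg, seed = 7)
  expect_identical(r1@counts, r2@counts)
  expect_identical(r1@events, r2@events)
  expect_identical(r1@snapshots, r2@snapshots)
  expect_equal(nrow(r1@counts), 19)
  expect_equal(densitySeries(r1)$density[1], 1)
  expect_equal(r1@configHash, configHash(cfg))

  r3 <- runSimulation(tinyConfig(hours = 0), seed = 7)
  expect_equal(nrow(r3@counts), 1)   # only the initial state
})

test_that("the event log replays to the recorded counts", {
  for (s in 1:3) {
    res <- runSimulation(tinyConfig(nLayers = 4L, hours = 12), seed = s)
    expect_identical(unname(replayCounts(res)), unname(res@counts) * 1L,
                     info = sprintf("seed %d", s))
  }
})

test_that("every cell has a consistent life history", {
  res <- runSimulation(tinyConfig(hours = 48, nVitro = 4e7), seed = 11)
  ev <- res@events
  for (id in unique(ev$cell_id)) {
    e <- ev[ev$cell_id == id, ]
    expect_equal(sum(e$event == "birth"), 1)
    expect_lte(sum(e$event == "death"), 1)
    expect_lte(sum(e$event == "degrade"), 1)
    if (any(e$event == "degrade")) {
      expect_true(any(e$event == "death"))
      expect_gte(e$iteration[e$event == "degrade"],
                 e$iteration[e$event == "death"])
    }
    expect_equal(e$iteration[e$event == "birth"], min(e$iteration))
  }
})

test_that("with a closed glucose boundary, mass loss equals cell uptake", {
  cfg <- tinyConfig(hours = 10, mediaChangeHours = 0, mediaGlucose = 1e9,
                    glucoseBoundary = "zero-flux")
  res <- runSimulation(cfg, seed = 6)
  scale <- res@scale
  p <- cfg@parameters
  voxL <- cfg@voxelSize^3 * 1e-6
  nsites <- cfg@nLayers^3
  massStart <- res@meanFields[1, "glucose"] * nsites * voxL
  massEnd <- res@meanFields[nrow(res@meanFields), "glucose"] * nsites * voxL
  # uptake during iteration t is driven by the populations after t-1
  upt <- scale@aggregationRatio * p[["u_glu"]] *
    sum(res@counts[-nrow(res@counts), "P"] +
          p[["s"]] * res@counts[-nrow(res@counts), "Q"])
  expect_equal(massStart - massEnd, upt, tolerance = 1e-6)
})

test_that("replicate batches are deterministic and independent", {
  cfg <- tinyConfig(hours = 6)
  b1 <- runReplicates(cfg, 3, baseSeed = 5)
  b2 <- runReplicates(cfg, 3, baseSeed = 5)
  expect_identical(lapply(b1, function(r) r@counts),
                   lapply(b2, function(r) r@counts))
  seeds <- vapply(b1, function(r) r@seed, integer(1))
  expect_equal(anyDuplicated(seeds), 0)
  d0 <- vapply(b1, function(r) densitySeries(r)$density[1], numeric(1))
  expect_equal(stats::sd(d0), 0)   # deterministic output: zero variance
})
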