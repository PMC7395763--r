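# Shared fixtures and independent oracles, built in code.

# Small, fast configuration for engine-level tests.
tinyConfig <- function(nLayers = 5L, hours = 24, nVitro = 2e7, seed = 1L, ...) {
  simulationConfig(nLayers = nLayers, hours = hours, nVitro = nVitro,
                   seed = seed, ...)
}

# Independent event-log replay oracle: reconstructs the per-iteration type
# counts from the event log alone and compares nothing against the engine's
# internal bookkeeping.
replayCounts <- function(result) {
  types <- names(result@config@cellTypes)
  nIter <- nrow(result@counts) - 1L
  ev <- result@events
  cellType <- character(0)   # named by cell id
  present <- logical(0)
  counts <- matrix(0L, nIter + 1L, length(types),
                   dimnames = list(rownames(result@counts), types))
  for (t in 0:nIter) {
    rows <- which(ev$iteration == t)
    for (r in rows) {
      id <- as.character(ev$cell_id[r])
      switch(ev$event[r],
        birth = { cellType[id] <- ev$to_type[r]; present[id] <- TRUE },
        divide = ,
        transition = ,
        move = ,
        death = { cellType[id] <- ev$to_type[r] },
        degrade = { present[id] <- FALSE })
    }
    tab <- table(factor(cellType[names(present)[present]], levels = types))
    counts[t + 1L, ] <- as.integer(tab)
  }
  counts
}

# Voxel-integrated separable heat-kernel solution: concentration at the
# central voxel after time t for a unit-concentration single-voxel pulse at
# the center of an n^3 zero-flux box (continuum solution; Neumann walls
# handled by the method of images, axis-separable).
heatKernelCenter <- function(D, t, h, n) {
  L <- n * h
  axisMass <- function(off) stats::integrate(function(u)
    (stats::pnorm((h / 2 - u - off) / sqrt(2 * D * t)) -
       stats::pnorm((-h / 2 - u - off) / sqrt(2 * D * t))) / h,
    -h / 2, h / 2, rel.tol = 1e-12)$value
  sum(vapply(-3:3, function(m) axisMass(L * m), numeric(1)))^3
}

# Closed-form Sobol indices of the Ishigami function on [-pi, pi]^3,
# recomputed from the variance decomposition integrals:
#   f = sin(x1) + A sin(x2)^2 + B x3^4 sin(x1)
#   V1 = (1 + B pi^4 / 5)^2 / 2,  V2 = A^2 / 8,  V13 = 8 B^2 pi^8 / 225
#   V  = V1 + V2 + V13
ishigami <- function(x, A = 7, B = 0.1)
  sin(x[1]) + A * sin(x[2])^2 + B * x[3]^4 * sin(x[1])

ishigamiIndices <- function(A = 7, B = 0.1) {
  V1 <- (1 + B * pi^4 / 5)^2 / 2
  V2 <- A^2 / 8
  V13 <- 8 * B^2 * pi^8 / 225
  V <- V1 + V2 + V13
  list(S1 = V1 / V, S2 = V2 / V, S3 = 0,
       ST1 = (V1 + V13) / V, ST2 = V2 / V, ST3 = V13 / V)
}
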