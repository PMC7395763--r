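# Simulation engine. One iteration = (1) diffusion of glucose and oxygen,
# (2) media change when due, (3) all environmental rules for every cell,
# (4) exactly one behavioural rule (or "stay") per cell, in a freshly
# shuffled random order. Internally the engine works on a mutable
# environment (plain vectors/arrays) for speed; the exported phase
# operations wrap it so a ScaffoldState can be advanced step by step.

.ROLE_UPTAKE <- function(roles, s) ifelse(roles == "quiescent", s,
                                          ifelse(roles == "dead", 0, 1))

# Classify a behavioural rule's execution semantics.
.ruleKind <- function(rule) {
  hasExtra <- !is.na(rule@extraProduct)
  bEmpty <- rule@productType == .EMPTY_TYPE
  if (hasExtra) {
    cEmpty <- rule@extraProduct == .EMPTY_TYPE
    if (bEmpty && !cEmpty) return("migration")
    if (!bEmpty && !cEmpty) return("duplication")
    stop(sprintf("rule '%s': 'empty' is not a valid extra product", rule@ruleId),
         call. = FALSE)
  }
  if (bEmpty) return("degradation")
  "transition"
}

# Compile all behavioural rules of one source type into a single function
# returning the vector of (unclamped) probabilities.
.compileTypeRules <- function(rules, argNames) {
  body <- as.call(c(list(quote(c)), lapply(rules, function(r) r@expr)))
  f <- function() NULL
  formals(f) <- stats::setNames(rep(list(quote(expr = )), length(argNames)),
                                argNames)
  body(f) <- body
  environment(f) <- baseenv()
  f
}

.linToXYZ <- function(lin, n) {
  lin0 <- lin - 1L
  c(lin0 %% n, (lin0 %/% n) %% n, lin0 %/% (n * n))
}

# Build the mutable simulation environment from a config and a (seeded or
# empty) scaffold state.
.simInit <- function(config, scale, state, recordEvents = TRUE) {
  sim <- new.env(parent = emptyenv())
  n <- config@nLayers
  sim$config <- config
  sim$n <- n
  sim$nsites <- n^3
  sim$dt <- config@dtHours
  sim$voxL <- config@voxelSize^3 * 1e-6
  sim$typeNames <- names(config@cellTypes)
  sim$roles <- unname(config@cellTypes)
  sim$nTypes <- length(sim$typeNames)
  sim$capacity <- as.numeric(sim$nsites) * config@capacityPerSite
  sim$params <- config@parameters
  sim$agg <- scale@aggregationRatio
  sim$scale <- scale
  sim$recordEvents <- recordEvents
  sim$events <- .newEventBuffer()
  sim$renormWarned <- FALSE

  # geometry services; stiffening deposits are boundary-normalized so a
  # cell's total remodeling effect (7 voxel-shares) is conserved when its
  # neighbourhood is clipped at the scaffold surface
  nb <- .neighbourIndexList(n)
  sim$nbSelf <- nb
  sim$nbOnly <- lapply(nb, function(v) v[-1])
  sim$nbWeight <- 7 / lengths(nb)

  # probability evaluators per source type
  argNames <- c(.CONTEXT_VARS, paste0(".count_", sim$typeNames))
  sim$argNames <- argNames
  sim$rulesByType <- vector("list", sim$nTypes)
  for (k in seq_len(sim$nTypes)) {
    rl <- Filter(function(r) r@sourceType == sim$typeNames[k], config@rules)
    if (!length(rl)) next
    kinds <- vapply(rl, .ruleKind, character(1))
    sim$rulesByType[[k]] <- list(
      rules = rl,
      ids = vapply(rl, function(r) r@ruleId, character(1)),
      fn = .compileTypeRules(rl, argNames),
      kinds = kinds,
      prodIdx = match(vapply(rl, function(r) r@productType, character(1)),
                      sim$typeNames),
      extraIdx = match(vapply(rl, function(r) r@extraProduct, character(1)),
                       sim$typeNames))
  }

  # environmental amounts per (tag, type); NA = no rule
  refAmt <- c(Glc = unname(sim$params["u_glu"]), O2 = unname(sim$params["u_o2"]),
              YM = unname(sim$params["u_ym"]))
  sim$envAmounts <- sapply(c("Glc", "O2", "YM"), function(tag) {
    amt <- rep(NA_real_, sim$nTypes)
    for (r in config@envRules) {
      if (r@tag != tag) next
      k <- match(r@sourceType, sim$typeNames)
      amt[k] <- if (r@amountIsReference) refAmt[[tag]] else r@amount
    }
    amt
  })

  # fields and occupancy
  sim$grid <- as.integer(state@cellGrid)
  sim$glc <- state@glucose
  sim$o2 <- state@oxygen
  sim$ym <- state@youngModulus
  sim$resGlc <- state@mediumGlucose

  # registry (structure of arrays; grows by doubling)
  cells <- state@cells
  cap <- max(64L, 2L * nrow(cells))
  sim$nCells <- nrow(cells)
  sim$typeIdx <- c(match(cells$type, sim$typeNames), integer(cap - nrow(cells)))
  sim$posLin <- c(cells$z * n * n + cells$y * n + cells$x + 1L,
                  integer(cap - nrow(cells)))
  sim$birth <- c(cells$birth, integer(cap - nrow(cells)))
  sim$lastDiv <- c(cells$last_division, integer(cap - nrow(cells)))
  sim$death <- c(cells$death, rep(NA_integer_, cap - nrow(cells)))
  sim$present <- c(cells$present, logical(cap - nrow(cells)))
  sim
}

.simGrow <- function(sim) {
  sim$typeIdx <- c(sim$typeIdx, integer(length(sim$typeIdx)))
  sim$posLin <- c(sim$posLin, integer(length(sim$posLin)))
  sim$birth <- c(sim$birth, integer(length(sim$birth)))
  sim$lastDiv <- c(sim$lastDiv, integer(length(sim$lastDiv)))
  sim$death <- c(sim$death, rep(NA_integer_, length(sim$death)))
  sim$present <- c(sim$present, logical(length(sim$present)))
  invisible(sim)
}

.simAddCell <- function(sim, typeIdx, posLin, t) {
  id <- sim$nCells + 1L
  if (id > length(sim$typeIdx)) .simGrow(sim)
  sim$nCells <- id
  sim$typeIdx[id] <- typeIdx
  sim$posLin[id] <- posLin
  sim$birth[id] <- t
  sim$lastDiv[id] <- t
  sim$death[id] <- NA_integer_
  sim$present[id] <- TRUE
  sim$grid[posLin] <- id
  id
}

.simEvent <- function(sim, t, id, event, fromIdx, toIdx, posLin) {
  if (!sim$recordEvents) return(invisible(NULL))
  ty <- function(k) if (is.na(k)) .EMPTY_TYPE else sim$typeNames[k]
  xyz <- .linToXYZ(posLin, sim$n)
  .pushEvent(sim$events, t, id, event, ty(fromIdx), ty(toIdx),
             xyz[1], xyz[2], xyz[3])
}

# Phase 1-2: transport and media change.
.simTransport <- function(sim, t) {
  spec <- sim$config@diffusion
  st <- list(glucose = sim$glc, oxygen = sim$o2)
  g <- diffusionStep(sim$glc, spec@dGlucose, sim$dt, sim$config@voxelSize,
                     mode = spec@glucoseBoundary, boundaryValue = sim$resGlc,
                     mediumVolume = spec@mediumVolume)
  sim$glc <- g$field
  if (spec@glucoseBoundary == "reservoir") sim$resGlc <- g$reservoir
  o <- diffusionStep(sim$o2, spec@dOxygen, sim$dt, sim$config@voxelSize,
                     mode = spec@oxygenBoundary,
                     boundaryValue = spec@incubatorOxygen,
                     mediumVolume = spec@mediumVolume)
  sim$o2 <- o$field
  hour <- t * sim$dt
  p <- sim$config@mediaChangeHours
  if (p > 0 && abs(hour / p - round(hour / p)) < 1e-9) {
    sim$glc[] <- sim$config@diffusion@mediaGlucose
    sim$resGlc <- sim$config@diffusion@mediaGlucose
  }
  invisible(sim)
}

# Phase 3: environmental rules (uptake and stiffening), vectorised by type.
.simEnvironment <- function(sim, t) {
  s <- sim$params[["s"]]
  lox <- sim$params[["lox"]]
  uptakeMult <- .ROLE_UPTAKE(sim$roles, s)
  for (k in seq_len(sim$nTypes)) {
    ids <- which(sim$present[seq_len(sim$nCells)] &
                   sim$typeIdx[seq_len(sim$nCells)] == k)
    if (!length(ids)) next
    pos <- sim$posLin[ids]
    aGlc <- sim$envAmounts[k, "Glc"]
    if (!is.na(aGlc)) {
      delta <- sim$agg * aGlc * uptakeMult[k] * sim$dt / sim$voxL
      sim$glc[pos] <- pmax(0, sim$glc[pos] - delta)
    }
    aO2 <- sim$envAmounts[k, "O2"]
    if (!is.na(aO2)) {
      delta <- sim$agg * aO2 * uptakeMult[k] * sim$dt / sim$voxL
      sim$o2[pos] <- pmax(0, sim$o2[pos] - delta)
    }
    aYM <- sim$envAmounts[k, "YM"]
    if (!is.na(aYM) && lox * aYM > 0) {
      idx <- unlist(sim$nbSelf[pos])
      wts <- rep(sim$nbWeight[pos], lengths(sim$nbSelf[pos]))
      acc <- rowsum(wts, idx)
      hits <- numeric(sim$nsites)
      hits[as.integer(rownames(acc))] <- acc
      sim$ym <- sim$ym + lox * aYM * sim$dt * hits
    }
  }
  invisible(sim)
}

# Phase 4 helper: behavioural selection and execution for one cell.
.simBehaveCell <- function(sim, id, t, nIter, countArgs) {
  k <- sim$typeIdx[id]
  tr <- sim$rulesByType[[k]]
  if (is.null(tr)) return(invisible(NULL))
  pos <- sim$posLin[id]
  dead <- !is.na(sim$death[id])
  args <- c(list(
    if (nIter > 0) t / nIter else 0,                              # TIME
    if (dead && nIter > 0) sim$death[id] / nIter else 0,          # TD
    sim$glc[pos] / sim$config@diffusion@mediaGlucose,             # Glc
    sim$o2[pos] / sim$config@diffusion@incubatorOxygen,           # O2
    if (t > 0) (t - sim$birth[id]) / t else 0,                    # AGE
    if (t > 0) (t - sim$lastDiv[id]) / t else 0,                  # TLD
    sim$ym[pos] / sim$config@initialStiffness),                   # YM
    countArgs)
  p <- do.call(tr$fn, args)
  if (any(!is.finite(p)))
    stop(sprintf("rule '%s': probability evaluated to a non-finite value",
                 tr$ids[which(!is.finite(p))[1]]), call. = FALSE)
  p <- .clamp(p)
  tot <- sum(p)
  if (tot > 1) {
    p <- p / tot
    tot <- 1
    if (!sim$renormWarned) {
      sim$renormWarned <- TRUE
      warning("behavioural rule probabilities sum above 1; renormalizing ",
              "(the rule set is likely mis-calibrated)", call. = FALSE)
    }
  }
  u <- stats::runif(1)
  if (u >= tot) return(invisible(NULL))    # residual "stay"
  sel <- which(u < cumsum(p))[1]
  kind <- tr$kinds[sel]
  if (kind == "transition") {
    newK <- tr$prodIdx[sel]
    if (newK == k) return(invisible(NULL))
    sim$typeIdx[id] <- newK
    isDeath <- sim$roles[newK] == "dead"
    if (isDeath) sim$death[id] <- t
    .simEvent(sim, t, id, if (isDeath) "death" else "transition", k, newK, pos)
  } else if (kind == "degradation") {
    sim$grid[pos] <- 0L
    sim$present[id] <- FALSE
    .simEvent(sim, t, id, "degrade", k, NA_integer_, pos)
  } else {
    nb <- sim$nbOnly[[pos]]
    emptyNb <- nb[sim$grid[nb] == 0L]
    if (!length(emptyNb)) return(invisible(NULL))    # blocked: no-op
    target <- emptyNb[sample.int(length(emptyNb), 1L)]
    if (kind == "duplication") {
      newK <- tr$prodIdx[sel]
      childK <- tr$extraIdx[sel]
      sim$typeIdx[id] <- newK
      sim$lastDiv[id] <- t
      child <- .simAddCell(sim, childK, target, t)
      .simEvent(sim, t, id, "divide", k, newK, pos)
      .simEvent(sim, t, child, "birth", NA_integer_, childK, target)
    } else {    # migration
      sim$grid[pos] <- 0L
      sim$grid[target] <- id
      sim$posLin[id] <- target
      sim$typeIdx[id] <- tr$extraIdx[sel]
      .simEvent(sim, t, id, "move", k, tr$extraIdx[sel], target)
    }
  }
  invisible(NULL)
}

# Phase 4: one behavioural rule per cell, random processing order. The
# population-count context variables are snapshot at phase entry.
.simBehaviour <- function(sim, t, nIter) {
  act <- which(sim$present[seq_len(sim$nCells)])
  if (!length(act)) return(invisible(sim))
  counts <- tabulate(sim$typeIdx[act], nbins = sim$nTypes)
  countArgs <- as.list(counts / sim$capacity)
  order <- act[sample.int(length(act))]
  for (id in order) {
    if (!sim$present[id]) next
    .simBehaveCell(sim, id, t, nIter, countArgs)
  }
  invisible(sim)
}

.simIterate <- function(sim, t, nIter) {
  .simTransport(sim, t)
  .simEnvironment(sim, t)
  .simBehaviour(sim, t, nIter)
  invisible(sim)
}

# Extract a ScaffoldState from the simulation environment.
.simState <- function(sim) {
  n <- sim$n
  idx <- seq_len(sim$nCells)
  lin0 <- sim$posLin[idx] - 1L
  cells <- data.frame(
    id = idx, type = sim$typeNames[sim$typeIdx[idx]],
    x = as.integer(lin0 %% n), y = as.integer((lin0 %/% n) %% n),
    z = as.integer(lin0 %/% (n * n)),
    birth = sim$birth[idx], last_division = sim$lastDiv[idx],
    death = sim$death[idx], present = sim$present[idx],
    stringsAsFactors = FALSE)
  new("ScaffoldState",
      nLayers = sim$config@nLayers, voxelSize = sim$config@voxelSize,
      cellGrid = array(sim$grid, dim = c(n, n, n)),
      glucose = sim$glc, oxygen = sim$o2, youngModulus = sim$ym,
      mediumGlucose = sim$resGlc, mediumVolume = sim$config@diffusion@mediumVolume,
      referenceGlucose = sim$config@diffusion@mediaGlucose,
      referenceOxygen = sim$config@diffusion@incubatorOxygen,
      initialStiffness = sim$config@initialStiffness,
      capacityPerSite = sim$config@capacityPerSite, cells = cells)
}

.defaultScale <- function(config) {
  computeScaleFactor(config@nVitro, config@cellVolume,
                     (config@nLayers * config@voxelSize)^3,
                     as.numeric(config@nLayers)^3 * config@capacityPerSite)
}

#' Apply all environmental rules once
#'
#' For every cell with an environmental rule: local glucose and oxygen drop
#' by aggregation ratio x amount x dt / voxel volume (quiescent cells consume
#' the fraction \code{s} of the proliferant amounts; concentrations floor at
#' zero), and cells with a stiffening rule add lox x amount x dt to the
#' Young's modulus of their own voxel and its entire 6-neighbourhood.
#'
#' @param state a \linkS4class{ScaffoldState}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param scale a \linkS4class{ScaleFactor} (default: derived from config).
#' @return the updated state.
#' @export
applyEnvironmentalRules <- function(state, config, scale = .defaultScale(config)) {
  sim <- .simInit(config, scale, state, recordEvents = FALSE)
  .simEnvironment(sim, 0L)
  .simState(sim)
}

#' Select and execute one behavioural rule for one cell
#'
#' Evaluates all behavioural rules whose source type matches the cell's type,
#' clamps each probability into [0, 1], renormalizes when their sum exceeds 1
#' (with a warning: this signals a mis-calibrated rule set) and draws one
#' rule, or "stay" with the residual probability. Duplication and migration
#' target a uniformly drawn empty face-neighbour and are silent no-ops when
#' every neighbour is occupied; transition to a type with the dead role sets
#' the death iteration; degradation frees the lattice site.
#'
#' @param cellId id of the cell to update.
#' @param state a \linkS4class{ScaffoldState}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param iteration current iteration.
#' @param totalIterations protocol length in iterations.
#' @param scale a \linkS4class{ScaleFactor}.
#' @return the updated state. Uses (and advances) the current RNG stream.
#' @export
selectAndExecuteBehaviour <- function(cellId, state, config, iteration,
                                      totalIterations,
                                      scale = .defaultScale(config)) {
  sim <- .simInit(config, scale, state, recordEvents = FALSE)
  if (cellId > sim$nCells || !sim$present[cellId])
    stop(sprintf("cell %d is not present", cellId), call. = FALSE)
  act <- which(sim$present[seq_len(sim$nCells)])
  counts <- tabulate(sim$typeIdx[act], nbins = sim$nTypes)
  .simBehaveCell(sim, cellId, iteration, totalIterations,
                 as.list(counts / sim$capacity))
  .simState(sim)
}

#' Run one full iteration
#'
#' Executes the four phases in their fixed order: field diffusion over dt,
#' media change when due, environmental rules for all cells, then one
#' behavioural rule per cell in a freshly shuffled random order.
#'
#' @inheritParams selectAndExecuteBehaviour
#' @return the updated \linkS4class{ScaffoldState}.
#' @export
runIteration <- function(state, config, iteration, totalIterations,
                         scale = .defaultScale(config)) {
  if (iteration < 1 || iteration > totalIterations)
    stop("iteration must lie in [1, totalIterations]", call. = FALSE)
  sim <- .simInit(config, scale, state, recordEvents = FALSE)
  .simIterate(sim, iteration, totalIterations)
  .simState(sim)
}

#' Run a complete simulation
#'
#' Seeds the scaffold (occupancy scale factor, uniform random placement) and
#' executes the full protocol. The run is bitwise reproducible given the
#' configuration and seed. Per-iteration population counts, spatial field
#' means and Manhattan-shell means are always recorded; full field snapshots
#' are stored at the configured snapshot hours and every event (birth,
#' division, move, transition, death, degradation) is logged.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed RNG seed (default: the seed stored in the config).
#' @return a \linkS4class{SimulationResult}.
#' @examples
#' cfg <- defaultConfig("mdamb231", nLayers = 5L, hours = 12)
#' res <- runSimulation(cfg, seed = 1)
#' head(densitySeries(res))
#' @export
runSimulation <- function(config, seed = config@seed) {
  validObject(config)
  seed <- as.integer(seed)
  set.seed(seed)
  nIter <- as.integer(round(config@hours / config@dtHours))
  scale <- .defaultScale(config)
  state <- createState(config)
  state <- seedUniform(state, scale@nVirtual, config@composition, seed = NULL)
  sim <- .simInit(config, scale, state, recordEvents = TRUE)
  for (id in seq_len(sim$nCells))
    .simEvent(sim, 0L, id, "birth", NA_integer_, sim$typeIdx[id], sim$posLin[id])

  typeNames <- sim$typeNames
  livingIdx <- which(sim$roles %in% c("proliferant", "quiescent"))
  shells <- .shellBins(config@nLayers, config@voxelSize)
  nBins <- length(shells$edges)
  binIdx <- split(seq_len(sim$nsites), shells$bin)
  binVox <- lengths(binIdx)
  hours <- seq(0, config@hours, by = config@dtHours)

  counts <- matrix(0L, nrow = nIter + 1L, ncol = sim$nTypes,
                   dimnames = list(hours, typeNames))
  meanFields <- matrix(NA_real_, nrow = nIter + 1L, ncol = 3,
                       dimnames = list(hours, c("glucose", "oxygen", "youngModulus")))
  shellMeans <- list(
    livingCells = matrix(0, nIter + 1L, nBins, dimnames = list(hours, shells$edges)),
    glucose = matrix(NA_real_, nIter + 1L, nBins, dimnames = list(hours, shells$edges)),
    oxygen = matrix(NA_real_, nIter + 1L, nBins, dimnames = list(hours, shells$edges)),
    youngModulus = matrix(NA_real_, nIter + 1L, nBins,
                          dimnames = list(hours, shells$edges)))
  snapshots <- list()

  record <- function(row) {
    act <- which(sim$present[seq_len(sim$nCells)])
    counts[row, ] <<- tabulate(sim$typeIdx[act], nbins = sim$nTypes)
    meanFields[row, ] <<- c(mean(sim$glc), mean(sim$o2), mean(sim$ym))
    living <- act[sim$typeIdx[act] %in% livingIdx]
    shellMeans$livingCells[row, ] <<-
      tabulate(shells$bin[sim$posLin[living]], nbins = nBins)
    for (f in c("glucose", "oxygen", "youngModulus")) {
      fld <- switch(f, glucose = sim$glc, oxygen = sim$o2, youngModulus = sim$ym)
      shellMeans[[f]][row, ] <<-
        vapply(binIdx, function(ix) mean(fld[ix]), numeric(1))
    }
  }
  snap <- function(hour) {
    if (any(abs(config@snapshotHours - hour) < 1e-9))
      snapshots[[as.character(hour)]] <<- list(
        glucose = sim$glc, oxygen = sim$o2, youngModulus = sim$ym,
        cellGrid = array(sim$grid, dim = rep(sim$n, 3)))
  }

  record(1L)
  snap(0)
  for (t in seq_len(nIter)) {
    .simIterate(sim, t, nIter)
    record(t + 1L)
    snap(t * config@dtHours)
  }

  new("SimulationResult",
      counts = counts, meanFields = meanFields, shellMeans = shellMeans,
      shellBins = shells$edges, shellVoxelCounts = as.integer(binVox),
      snapshots = snapshots, events = .eventsAsDataFrame(sim$events),
      initialCount = scale@nVirtual, scale = scale, seed = seed,
      configHash = configHash(config), config = config)
}

#' Run a batch of replicate simulations
#'
#' Replicate k runs with the deterministic seed
#' (baseSeed + 99991 k) mod (2^31 - 1), so batches are reproducible and
#' replicates are order-insensitive.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param nReplicates number of replicates (>= 1).
#' @param baseSeed base seed for the splitting scheme.
#' @return a list of \linkS4class{SimulationResult} objects.
#' @export
runReplicates <- function(config, nReplicates, baseSeed = config@seed) {
  stopifnot(nReplicates >= 1)
  lapply(seq_len(nReplicates), function(k)
    runSimulation(config, seed = .replicateSeed(baseSeed, k)))
}

setMethod("show", "SimulationResult", function(object) {
  nIter <- nrow(object@counts) - 1L
  final <- object@counts[nrow(object@counts), ]
  cat(sprintf("SimulationResult: %d iterations, seed %d\n", nIter, object@seed))
  cat(sprintf("  initial cells: %d | final: %s\n", object@initialCount,
              paste(sprintf("%s=%d", names(final), final), collapse = ", ")))
  cat(sprintf("  final mean stiffness: %.3f kPa | events: %d\n",
              object@meanFields[nrow(object@meanFields), "youngModulus"],
              nrow(object@events)))
})
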