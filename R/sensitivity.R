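# Variance-based global sensitivity analysis: uniform +/- 40 percent
# parameter ranges, Saltelli sample design, Monte-Carlo estimators of the
# first-order and total Sobol indices, and the time course of output
# standard deviation under parameter uncertainty.

#' Define a parameter space for sensitivity analysis
#'
#' Independent uniform ranges centered on the reference values, by default
#' reference +/- 40 percent. Explicit bounds override the relative rule
#' (used e.g. for analytic test functions).
#'
#' @param reference named numeric vector of reference parameter values.
#' @param relVariation half-width of the range relative to the reference.
#' @param lower,upper optional explicit bounds (same length as reference).
#' @return a \linkS4class{ParameterSpace}.
#' @examples
#' makeParameterSpace(c(a = 0.44, e = 0.01))
#' @export
makeParameterSpace <- function(reference, relVariation = 0.4,
                               lower = NULL, upper = NULL) {
  nm <- names(reference)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("reference values must be named", call. = FALSE)
  if (is.null(lower)) lower <- reference - relVariation * abs(reference)
  if (is.null(upper)) upper <- reference + relVariation * abs(reference)
  new("ParameterSpace", parameters = nm, reference = unname(reference),
      lower = unname(lower), upper = unname(upper))
}

setMethod("show", "ParameterSpace", function(object) {
  cat(sprintf("ParameterSpace: %d parameters\n", length(object@parameters)))
  for (i in seq_along(object@parameters))
    cat(sprintf("  %-8s ref %.4g in [%.4g, %.4g]\n", object@parameters[i],
                object@reference[i], object@lower[i], object@upper[i]))
})

#' Saltelli sample design
#'
#' Builds the radial Saltelli design for first-order and total Sobol index
#' estimation: two independent uniform base matrices A and B of nBase rows,
#' followed by the k cross matrices AB_i (A with column i taken from B), for
#' a total of nBase (k + 2) model evaluations.
#'
#' @param space a \linkS4class{ParameterSpace}.
#' @param nBase base sample size (>= 8; powers of two recommended).
#' @param seed RNG seed making the design deterministic.
#' @return a numeric matrix with named columns and attributes \code{nBase}
#'   and \code{blocks} (row ranges of A, B and each AB_i).
#' @export
saltelliDesign <- function(space, nBase, seed = 1) {
  validObject(space)
  if (nBase < 8) stop("nBase must be at least 8", call. = FALSE)
  k <- length(space@parameters)
  set.seed(seed)
  sampleBlock <- function()
    vapply(seq_len(k), function(j)
      stats::runif(nBase, space@lower[j], space@upper[j]), numeric(nBase))
  A <- sampleBlock()
  B <- sampleBlock()
  ABs <- lapply(seq_len(k), function(i) { M <- A; M[, i] <- B[, i]; M })
  design <- do.call(rbind, c(list(A, B), ABs))
  colnames(design) <- space@parameters
  attr(design, "nBase") <- nBase
  attr(design, "k") <- k
  design
}

#' First-order and total Sobol indices (Monte-Carlo Saltelli estimators)
#'
#' Evaluates the model on every design row and applies the standard
#' estimators: S_i = mean(yB (yAB_i - yA)) / V (first order) and
#' ST_i = mean((yA - yAB_i)^2) / (2 V) (total, Jansen form), with V the
#' variance of the pooled A and B evaluations. Percentile bootstrap
#' confidence intervals are computed over the base-sample index. Estimates
#' are clipped into [-0.05, 1.05]; values outside that band before clipping
#' are flagged. A zero-variance model yields NA indices.
#'
#' @param model a function mapping one named parameter row to a scalar
#'   output (or a precomputed numeric vector of outputs, one per design row).
#' @param design a matrix from \code{\link{saltelliDesign}}.
#' @param nBoot bootstrap resamples for the confidence intervals.
#' @return a data.frame with one row per parameter: \code{S1}, \code{S1_lo},
#'   \code{S1_hi}, \code{ST}, \code{ST_lo}, \code{ST_hi}, \code{outOfRange}.
#' @examples
#' sp <- makeParameterSpace(c(x1 = 0.5, x2 = 0.5), lower = c(0, 0), upper = c(1, 1))
#' d <- saltelliDesign(sp, 128, seed = 1)
#' sobolIndices(function(p) p["x1"] + p["x2"], d)
#' @export
sobolIndices <- function(model, design, nBoot = 200) {
  nBase <- attr(design, "nBase")
  k <- attr(design, "k")
  if (is.null(nBase) || is.null(k))
    stop("design must come from saltelliDesign()", call. = FALSE)
  y <- if (is.function(model))
    vapply(seq_len(nrow(design)), function(i) model(design[i, ]), numeric(1))
  else as.numeric(model)
  if (length(y) != nrow(design))
    stop("model output length does not match the design", call. = FALSE)
  yA <- y[seq_len(nBase)]
  yB <- y[nBase + seq_len(nBase)]
  yAB <- lapply(seq_len(k), function(i) y[(1 + i) * nBase + seq_len(nBase)])
  est <- function(idx) {
    mu <- mean(c(yA[idx], yB[idx]))   # centering reduces estimator variance
    a <- yA[idx] - mu
    b <- yB[idx] - mu
    V <- stats::var(c(a, b))
    if (!is.finite(V) || V == 0) return(NULL)
    t(vapply(seq_len(k), function(i) {
      ab <- yAB[[i]][idx] - mu
      c(S1 = mean(b * (ab - a)) / V,
        ST = mean((a - ab)^2) / (2 * V))
    }, numeric(2)))
  }
  full <- est(seq_len(nBase))
  if (is.null(full)) {
    message("model output has zero variance; Sobol indices are undefined")
    return(data.frame(parameter = colnames(design),
                      S1 = NA_real_, S1_lo = NA_real_, S1_hi = NA_real_,
                      ST = NA_real_, ST_lo = NA_real_, ST_hi = NA_real_,
                      outOfRange = FALSE))
  }
  boots <- array(NA_real_, dim = c(k, 2, nBoot))
  for (b in seq_len(nBoot)) {
    e <- est(sample.int(nBase, nBase, replace = TRUE))
    if (!is.null(e)) boots[, , b] <- e
  }
  qs <- apply(boots, c(1, 2), stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  outOfRange <- full[, "S1"] < -0.05 | full[, "S1"] > 1.05 |
    full[, "ST"] < -0.05 | full[, "ST"] > 1.05
  clip <- function(x) .clamp(x, -0.05, 1.05)
  data.frame(parameter = colnames(design),
             S1 = clip(full[, "S1"]), S1_lo = clip(qs[1, , 1]),
             S1_hi = clip(qs[2, , 1]),
             ST = clip(full[, "ST"]), ST_lo = clip(qs[1, , 2]),
             ST_hi = clip(qs[2, , 2]),
             outOfRange = outOfRange, row.names = NULL)
}

#' Build a scalar simulator output for sensitivity analysis
#'
#' Wraps a configuration into a model function mapping a named parameter row
#' to a scalar output, averaging a small fixed number of replicate seeds to
#' tame run-to-run stochasticity. Replicate seeds are derived
#' deterministically from the row values so the analysis is reproducible.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param output \code{"finalDensity"} (living cells at the last iteration /
#'   initial population) or \code{"meanYoungModulus"} (final spatial mean).
#' @param nReplicateSeeds replicate runs averaged per parameter row.
#' @param baseSeed seed offset for the replicate derivation.
#' @return a function suitable for \code{\link{sobolIndices}}.
#' @export
makeSimulatorModel <- function(config,
                               output = c("finalDensity", "meanYoungModulus"),
                               nReplicateSeeds = 3, baseSeed = 1) {
  output <- match.arg(output)
  rowCounter <- new.env(parent = emptyenv())
  rowCounter$i <- 0L
  function(row) {
    rowCounter$i <- rowCounter$i + 1L
    cfg <- applyParameters(config, row)
    vals <- vapply(seq_len(nReplicateSeeds), function(j) {
      res <- runSimulation(cfg, seed = .replicateSeed(baseSeed,
                                                      1000L * rowCounter$i + j))
      if (output == "finalDensity") {
        d <- densitySeries(res)
        d$density[nrow(d)]
      } else res@meanFields[nrow(res@meanFields), "youngModulus"]
    }, numeric(1))
    mean(vals)
  }
}

#' Time course of output standard deviation under parameter uncertainty
#'
#' Samples parameter rows uniformly from the space, runs the simulator for
#' each (averaging a few replicate seeds per row) and reports, per
#' iteration, the standard deviation across rows of the two outputs (cell
#' density and spatial mean Young's modulus) - i.e. how stochasticity and
#' parameter uncertainty propagate through the simulation.
#'
#' @param space a \linkS4class{ParameterSpace} over simulation parameters.
#' @param config a \linkS4class{SimulationConfig}.
#' @param nSamples number of parameter rows (>= 2).
#' @param seed RNG seed for the row sampling.
#' @param nReplicateSeeds replicate runs averaged per row.
#' @return a data.frame with columns \code{hour}, \code{sdDensity},
#'   \code{sdYoungModulus}.
#' @export
outputStdTimecourse <- function(space, config, nSamples, seed = 1,
                                nReplicateSeeds = 3) {
  stopifnot(nSamples >= 2)
  validObject(space)
  set.seed(seed)
  k <- length(space@parameters)
  rows <- vapply(seq_len(k), function(j)
    stats::runif(nSamples, space@lower[j], space@upper[j]), numeric(nSamples))
  colnames(rows) <- space@parameters
  dens <- NULL
  ymm <- NULL
  for (i in seq_len(nSamples)) {
    cfg <- applyParameters(config, rows[i, ])
    di <- NULL
    yi <- NULL
    for (j in seq_len(nReplicateSeeds)) {
      res <- runSimulation(cfg, seed = .replicateSeed(seed, 1000L * i + j))
      d <- densitySeries(res)$density
      y <- res@meanFields[, "youngModulus"]
      di <- if (is.null(di)) d else di + d
      yi <- if (is.null(yi)) y else yi + y
    }
    dens <- cbind(dens, di / nReplicateSeeds)
    ymm <- cbind(ymm, yi / nReplicateSeeds)
  }
  hours <- seq(0, config@hours, by = config@dtHours)
  data.frame(hour = hours,
             sdDensity = apply(dens, 1, stats::sd),
             sdYoungModulus = apply(ymm, 1, stats::sd))
}
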