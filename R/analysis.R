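# Analysis layer: density time courses, validation error, radial profiles,
# stiffness dispersion statistics and group comparisons.

.livingTypes <- function(config) {
  names(config@cellTypes)[config@cellTypes %in% c("proliferant", "quiescent")]
}

#' Cell-density time course
#'
#' Cell density is the number of living cells (proliferant + quiescent)
#' normalised to the cardinality of the initial population, so density(0) = 1
#' by construction.
#'
#' @param result a \linkS4class{SimulationResult}.
#' @return a data.frame with columns \code{hour} and \code{density}.
#' @export
densitySeries <- function(result) {
  living <- .livingTypes(result@config)
  tot <- rowSums(result@counts[, living, drop = FALSE])
  if (tot[1] == 0) stop("initial population is empty", call. = FALSE)
  data.frame(hour = as.numeric(rownames(result@counts)),
             density = unname(tot / tot[1]))
}

#' Mean absolute percentage error between simulation and experiment
#'
#' Elementwise |silico - vitro| / vitro at matched time points (the
#' validation protocol samples days 1, 3, 7 and 10).
#'
#' @param silico simulated values.
#' @param vitro experimental values at the same time points (all > 0).
#' @return per-point error vector.
#' @examples
#' mape(c(1.25, 0.5), c(1, 1))
#' @export
mape <- function(silico, vitro) {
  if (length(silico) != length(vitro))
    stop("silico and vitro must have matched time points", call. = FALSE)
  if (any(vitro <= 0))
    stop("MAPE is undefined for non-positive in-vitro values", call. = FALSE)
  abs(silico - vitro) / vitro
}

#' Radial profile by Manhattan distance from the scaffold center
#'
#' Bins the per-iteration shell means recorded by the engine into the 1 mm
#' left-closed Manhattan-distance bins and averages across replicates.
#' Cell density is normalised as (summed living cells in a bin at time t)
#' over (summed living cells in that bin at time 0) across replicates; bins
#' that start empty are reported as missing (NA), not zero. Fields are
#' normalised to their initial spatial average.
#'
#' @param results a list of \linkS4class{SimulationResult} (or a single one).
#' @param quantity one of \code{"density"}, \code{"Glc"}, \code{"O2"},
#'   \code{"YM"}.
#' @return a \linkS4class{RadialProfile}.
#' @export
radialProfile <- function(results, quantity = c("density", "Glc", "O2", "YM")) {
  quantity <- match.arg(quantity)
  if (is(results, "SimulationResult")) results <- list(results)
  stopifnot(length(results) >= 1)
  bins <- results[[1]]@shellBins
  hours <- as.numeric(rownames(results[[1]]@counts))
  binVox <- results[[1]]@shellVoxelCounts
  field <- switch(quantity, density = "livingCells", Glc = "glucose",
                  O2 = "oxygen", YM = "youngModulus")
  stack <- lapply(results, function(r) r@shellMeans[[field]])
  summed <- Reduce(`+`, stack)
  if (quantity == "density") {
    init <- summed[1, ]
    values <- sweep(summed, 2, ifelse(init > 0, init, NA_real_), "/")
    raw <- sweep(summed / length(results), 2, binVox, "/")
  } else {
    raw <- summed / length(results)
    init0 <- mean(vapply(results, function(r) r@meanFields[1, field], numeric(1)))
    values <- raw / init0
  }
  new("RadialProfile", quantity = quantity, hours = hours, bins = bins,
      values = t(values), raw = t(raw), binVoxelCounts = binVox)
}

setMethod("show", "RadialProfile", function(object) {
  cat(sprintf("RadialProfile (%s): %d bins x %d hours\n", object@quantity,
              length(object@bins), length(object@hours)))
  last <- object@values[, ncol(object@values)]
  cat("  final column (normalised):",
      paste(sprintf("%.3g", last), collapse = " "), "\n")
})

# Final-hour raw shell means of a quantity, averaged across replicates.
.finalShellMeans <- function(results, quantity = "YM") {
  prof <- radialProfile(results, quantity)
  prof@raw[, ncol(prof@raw)]
}

#' Relative shell-to-shell spread of the final stiffness field
#'
#' Intrascaffold variability summary: 100 x (max bin mean - min bin mean) /
#' mean of bin means, over the Manhattan-distance shells at the final
#' iteration, replicate-averaged.
#'
#' @param results a list of \linkS4class{SimulationResult}.
#' @param quantity quantity to profile (default stiffness).
#' @return percentage spread.
#' @export
shellRelativeSpread <- function(results, quantity = "YM") {
  m <- .finalShellMeans(results, quantity)
  100 * (max(m) - min(m)) / mean(m)
}

#' Stiffness summary statistics
#'
#' Pooled mode treats every voxel of every replicate's final
#' Young's-modulus snapshot as one observation (the dispersion of the full
#' stiffness distribution); per-scaffold mode treats each replicate's mean
#' stiffness as one observation (the between-scaffold view used for
#' experimental error bars). Both modes report the pooled / per-scaffold
#' dispersion ratio, the factor by which the population-level spread exceeds
#' the spread of scaffold averages. The 95 percent confidence interval is
#' the normal approximation mean +/- 1.96 SE (percentile bootstrap on
#' request); a Shapiro-Wilk p-value is attached as a normality diagnostic.
#'
#' @param results a list of \linkS4class{SimulationResult} with a final-hour
#'   snapshot (>= 2 results for confidence intervals).
#' @param mode \code{"pooled"} or \code{"per_scaffold"}.
#' @param bootstrap use a percentile bootstrap for the CI.
#' @param nBoot bootstrap resamples.
#' @return a list with elements \code{mode}, \code{mean}, \code{ci},
#'   \code{dispersion}, \code{dispersionRatio}, \code{shapiroP}, \code{n}.
#' @export
stiffnessSummary <- function(results, mode = c("pooled", "per_scaffold"),
                             bootstrap = FALSE, nBoot = 1000) {
  mode <- match.arg(mode)
  if (is(results, "SimulationResult")) results <- list(results)
  hour <- max(as.numeric(names(results[[1]]@snapshots)))
  voxels <- lapply(results, function(r) {
    sn <- r@snapshots[[as.character(hour)]]
    if (is.null(sn)) stop("results lack a final-hour field snapshot", call. = FALSE)
    as.numeric(sn$youngModulus)
  })
  repMeans <- vapply(voxels, mean, numeric(1))
  pooledSd <- stats::sd(unlist(voxels))
  if (mode == "per_scaffold" && length(results) < 2)
    stop("per_scaffold mode needs at least 2 replicates", call. = FALSE)
  perSd <- if (length(results) >= 2) stats::sd(repMeans) else NA_real_
  values <- if (mode == "pooled") unlist(voxels) else repMeans
  n <- length(values)
  m <- mean(values)
  sdv <- stats::sd(values)
  ci <- if (bootstrap) {
    bm <- vapply(seq_len(nBoot), function(i)
      mean(values[sample.int(n, n, replace = TRUE)]), numeric(1))
    unname(stats::quantile(bm, c(0.025, 0.975)))
  } else m + c(-1.96, 1.96) * sdv / sqrt(n)
  swSample <- if (n > 5000) values[round(seq(1, n, length.out = 5000))] else values
  shapiroP <- if (length(unique(swSample)) > 1 && length(swSample) >= 3)
    tryCatch(stats::shapiro.test(swSample)$p.value, error = function(e) NA_real_)
  else NA_real_
  list(mode = mode, hour = hour, mean = m, ci = ci, dispersion = sdv,
       dispersionRatio = if (is.na(perSd) || perSd == 0) NA_real_
                         else pooledSd / perSd,
       shapiroP = shapiroP, n = n)
}

#' Compare two samples (Kruskal-Wallis)
#'
#' Library-backed Kruskal-Wallis rank-sum test between two groups, with an
#' explicit flag for the degenerate all-tied input on which the test
#' statistic is undefined.
#'
#' @param sampleA,sampleB non-empty numeric vectors.
#' @return a list with \code{statistic} (H), \code{p.value} and
#'   \code{degenerate}.
#' @export
compareGroups <- function(sampleA, sampleB) {
  stopifnot(length(sampleA) > 0, length(sampleB) > 0)
  if (length(unique(c(sampleA, sampleB))) == 1)
    return(list(statistic = 0, p.value = 1, degenerate = TRUE))
  kw <- stats::kruskal.test(list(sampleA, sampleB))
  list(statistic = unname(kw$statistic), p.value = kw$p.value,
       degenerate = FALSE)
}
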