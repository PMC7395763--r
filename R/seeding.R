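# Seeding: in-vitro to in-silico population scaling and random placement.

#' Compute the in-vitro / in-silico occupancy scale factor
#'
#' The fraction of the scaffold volume initially occupied by the biological
#' population (cell count times the average eukaryotic cell volume, 4.2e-6
#' mm^3, over the scaffold volume) is preserved on the lattice: the virtual
#' population is that fraction of the lattice capacity, rounded half away
#' from zero with a minimum of one cell. The aggregation ratio (biological
#' cells per virtual cell) scales the per-cell uptakes in the environmental
#' rules so total consumption matches the wet-lab experiment.
#'
#' @param nVitro in-vitro population cardinality (> 0).
#' @param cellVolume biological cell volume, mm^3.
#' @param scaffoldVolume scaffold volume, mm^3.
#' @param capacity lattice capacity (sites times capacity per site).
#' @return a \linkS4class{ScaleFactor}.
#' @examples
#' computeScaleFactor(5e6, 4.2e-6, 1000, 1000)   # 21 virtual cells
#' @export
computeScaleFactor <- function(nVitro, cellVolume, scaffoldVolume, capacity) {
  if (nVitro <= 0)
    stop("nVitro must be positive (request an empty seeding explicitly instead)",
         call. = FALSE)
  if (cellVolume <= 0 || scaffoldVolume <= 0 || capacity <= 0)
    stop("cellVolume, scaffoldVolume and capacity must be positive", call. = FALSE)
  frac <- nVitro * cellVolume / scaffoldVolume
  nVirtual <- max(1L, as.integer(.roundHalfAway(frac * capacity)))
  new("ScaleFactor", occupiedFraction = frac, nVirtual = nVirtual,
      aggregationRatio = nVitro / nVirtual)
}

setMethod("show", "ScaleFactor", function(object) {
  cat(sprintf(
    "ScaleFactor: occupancy %.4g, %d virtual cells, %.4g biological cells each\n",
    object@occupiedFraction, object@nVirtual, object@aggregationRatio))
})

#' Seed cells uniformly at random
#'
#' Places \code{nVirtual} cells on distinct empty lattice sites drawn
#' uniformly at random (a seeded shuffle of the empty-site list, taking the
#' first \code{nVirtual} entries), with types assigned per the composition
#' fractions (independent draws, i.e. multinomial counts).
#'
#' @param state a \linkS4class{ScaffoldState}.
#' @param nVirtual number of virtual cells to place.
#' @param composition named numeric vector of type fractions summing to 1.
#' @param seed optional RNG seed; \code{NULL} continues the current RNG
#'   stream (used inside \code{\link{runSimulation}}).
#' @return the updated \linkS4class{ScaffoldState}.
#' @export
seedUniform <- function(state, nVirtual, composition, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(composition) - 1) > 1e-6)
    stop("composition fractions must sum to 1", call. = FALSE)
  if (any(composition < 0)) stop("composition fractions must be non-negative",
                                 call. = FALSE)
  empty <- which(state@cellGrid == 0L)
  if (nVirtual > length(empty))
    stop(sprintf("cannot seed %d cells: only %d empty sites", nVirtual,
                 length(empty)), call. = FALSE)
  if (nVirtual == 0) return(state)
  sites <- sample(empty)[seq_len(nVirtual)]
  types <- sample(names(composition), nVirtual, replace = TRUE,
                  prob = composition)
  n <- state@nLayers
  lin <- sites - 1L
  x <- lin %% n
  y <- (lin %/% n) %% n
  z <- lin %/% (n * n)
  ids <- seq_len(nVirtual)
  state@cellGrid[sites] <- ids
  state@cells <- data.frame(
    id = ids, type = types, x = as.integer(x), y = as.integer(y),
    z = as.integer(z), birth = 0L, last_division = 0L, death = NA_integer_,
    present = TRUE, stringsAsFactors = FALSE)
  state
}
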