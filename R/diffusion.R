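# Nutrient and oxygen transport: Fick's second law on the voxel lattice,
# explicit central differences (FTCS) with automatic stability sub-stepping,
# boundary exchange with the external medium, periodic media changes.

# Precomputed gather indices for the six face-neighbours of every voxel.
# Out-of-bounds neighbours point either back to the voxel itself (mirror /
# zero-flux) or to an extra ghost slot nsites + 1 (dirichlet / reservoir).
# ghostCount is the number of external exposures per voxel (face voxels 1,
# edges 2, corners 3). Cached per (dims, mirror).
.diffCache <- new.env(parent = emptyenv())

.diffIndices <- function(d, mirror) {
  key <- paste(c(d, mirror), collapse = "x")
  hit <- .diffCache[[key]]
  if (!is.null(hit)) return(hit)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  nsites <- nx * ny * nz
  lin <- seq_len(nsites) - 1L
  x <- lin %% nx
  y <- (lin %/% nx) %% ny
  z <- lin %/% (nx * ny)
  ghost <- nsites + 1L
  mk <- function(ok, nbr) {
    out <- ifelse(ok, nbr, if (mirror) lin + 1L else ghost)
    as.integer(out)
  }
  idx <- list(mk(x > 0, lin), mk(x < nx - 1, lin + 2L),
              mk(y > 0, lin + 1L - nx), mk(y < ny - 1, lin + 1L + nx),
              mk(z > 0, lin + 1L - nx * ny), mk(z < nz - 1, lin + 1L + nx * ny))
  ghostCount <- (x == 0) + (x == nx - 1) + (y == 0) + (y == ny - 1) +
    (z == 0) + (z == nz - 1)
  res <- list(idx = idx, ghostCount = as.numeric(ghostCount))
  .diffCache[[key]] <- res
  res
}

#' Advance a concentration field by one protocol time step
#'
#' Integrates dC/dt = D Laplacian(C) with the explicit FTCS scheme,
#' internally sub-stepped so every sub-step satisfies the stability bound
#' dt_sub <= h^2 / (6 D). Three boundary modes are supported:
#' \code{"zero-flux"} (mirrored ghost voxels, closed system),
#' \code{"dirichlet"} (face voxels see a fixed external concentration) and
#' \code{"reservoir"} (face voxels exchange mass with a finite well-mixed
#' external medium whose concentration is updated accordingly).
#'
#' @param field 3D non-negative concentration array, g/L.
#' @param D diffusivity, mm^2/h.
#' @param dt time step, h.
#' @param voxelSize voxel edge, mm.
#' @param mode boundary mode.
#' @param boundaryValue external concentration for dirichlet/reservoir, g/L.
#' @param mediumVolume reservoir volume, mL (reservoir mode).
#' @return \code{list(field, reservoir)} with the updated field and (in
#'   reservoir mode) the updated external concentration.
#' @export
diffusionStep <- function(field, D, dt, voxelSize,
                          mode = c("reservoir", "dirichlet", "zero-flux"),
                          boundaryValue = NA_real_, mediumVolume = NA_real_) {
  mode <- match.arg(mode)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (any(!is.finite(field))) stop("field contains non-finite values", call. = FALSE)
  h <- voxelSize
  # lambda = D dt_sub / h^2 <= 1/12: twice as strict as the 1/6 stability
  # bound, keeping the self-weight of the update >= 1/2 so single-voxel
  # pulses do not excite the parity (checkerboard) mode of the stencil
  nSub <- max(1L, as.integer(ceiling(12 * D * dt / h^2)))
  dtSub <- dt / nSub
  lam <- D * dtSub / h^2
  voxL <- h^3 * 1e-6    # mm^3 -> L
  medL <- mediumVolume * 1e-3  # mL -> L
  res <- boundaryValue
  if (mode != "zero-flux" && !is.finite(res))
    stop("boundaryValue required for dirichlet/reservoir modes", call. = FALSE)
  if (mode == "reservoir" && !is.finite(medL))
    stop("mediumVolume required for reservoir mode", call. = FALSE)
  d <- dim(field)
  mirror <- mode == "zero-flux"
  g <- .diffIndices(d, mirror)
  i1 <- g$idx[[1]]; i2 <- g$idx[[2]]; i3 <- g$idx[[3]]
  i4 <- g$idx[[4]]; i5 <- g$idx[[5]]; i6 <- g$idx[[6]]
  f <- as.numeric(field)
  for (i in seq_len(nSub)) {
    fx <- c(f, if (mirror) 0 else res)
    s <- fx[i1] + fx[i2] + fx[i3] + fx[i4] + fx[i5] + fx[i6]
    newF <- f + lam * (s - 6 * f)
    if (mode == "reservoir") {
      influx <- lam * sum(g$ghostCount * (res - f)) * voxL
      res <- max(0, res - influx / medL)
    }
    f <- newF
  }
  list(field = array(f, dim = d),
       reservoir = if (mode == "reservoir") res else boundaryValue)
}

# Advance both fields of a scaffold state by dt, per the diffusion spec.
.diffuseState <- function(state, spec, dt) {
  g <- diffusionStep(state@glucose, spec@dGlucose, dt, state@voxelSize,
                     mode = spec@glucoseBoundary,
                     boundaryValue = state@mediumGlucose,
                     mediumVolume = state@mediumVolume)
  state@glucose <- g$field
  if (spec@glucoseBoundary == "reservoir") state@mediumGlucose <- g$reservoir
  o <- diffusionStep(state@oxygen, spec@dOxygen, dt, state@voxelSize,
                     mode = spec@oxygenBoundary,
                     boundaryValue = spec@incubatorOxygen,
                     mediumVolume = state@mediumVolume)
  state@oxygen <- o$field
  state
}

#' Apply a culture-medium change
#'
#' Models medium substitution by resetting the glucose concentration to the
#' fresh-medium value at every point of the scaffold and refilling the
#' external reservoir; the oxygen field is untouched (gas exchange keeps the
#' medium saturated independently of medium changes).
#'
#' @param state a \linkS4class{ScaffoldState}.
#' @return the updated state.
#' @export
applyMediaChange <- function(state) {
  state@glucose[] <- state@referenceGlucose
  state@mediumGlucose <- state@referenceGlucose
  state
}
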