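# Scaffold lattice: construction, geometry services, accessors.

.emptyRegistry <- function() {
  data.frame(id = integer(0), type = character(0), x = integer(0),
             y = integer(0), z = integer(0), birth = integer(0),
             last_division = integer(0), death = integer(0),
             present = logical(0), stringsAsFactors = FALSE)
}

#' Create an empty scaffold state
#'
#' Initialises the cubic lattice with uniform fields: glucose at the
#' fresh-medium concentration, oxygen at the incubator concentration and
#' Young's modulus at the initial scaffold stiffness; the cell grid is empty
#' and the external reservoir is full.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{ScaffoldState}.
#' @examples
#' st <- createState(defaultConfig("mdamb231"))
#' range(youngModulusField(st))   # uniform 47 kPa
#' @export
createState <- function(config) {
  validObject(config)
  n <- config@nLayers
  d <- config@diffusion
  mk <- function(v) array(v, dim = c(n, n, n))
  new("ScaffoldState",
      nLayers = n, voxelSize = config@voxelSize,
      cellGrid = mk(0L), glucose = mk(d@mediaGlucose),
      oxygen = mk(d@incubatorOxygen), youngModulus = mk(config@initialStiffness),
      mediumGlucose = d@mediaGlucose, mediumVolume = d@mediumVolume,
      referenceGlucose = d@mediaGlucose, referenceOxygen = d@incubatorOxygen,
      initialStiffness = config@initialStiffness,
      capacityPerSite = config@capacityPerSite, cells = .emptyRegistry())
}

.checkInBounds <- function(position, n) {
  if (length(position) != 3 || any(position < 0) || any(position >= n))
    stop(sprintf("position (%s) is out of bounds for a %d-layer lattice",
                 paste(position, collapse = ","), n), call. = FALSE)
}

#' Face-adjacent neighbourhood of a voxel
#'
#' Returns the 6-connected (face-adjacent) neighbours of a voxel, clipped at
#' the scaffold boundary, in the fixed order -x, +x, -y, +y, -z, +z.
#'
#' @param position 0-based voxel coordinate triple.
#' @param state a \linkS4class{ScaffoldState} (or an integer layer count).
#' @return a list of 0-based in-bounds voxel triples.
#' @examples
#' st <- createState(defaultConfig("mdamb231"))
#' length(neighbourhood(c(0, 0, 0), st))   # corner: 3 neighbours
#' @export
neighbourhood <- function(position, state) {
  n <- if (is(state, "ScaffoldState")) state@nLayers else as.integer(state)
  .checkInBounds(position, n)
  offsets <- list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                  c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  out <- list()
  for (off in offsets) {
    q <- position + off
    if (all(q >= 0) && all(q < n)) out[[length(out) + 1L]] <- q
  }
  out
}

#' Manhattan distance from a voxel center to the scaffold center
#'
#' Voxel centers sit at (i + 0.5) * voxel size (0-based i); the geometric
#' scaffold center is at side/2 on each axis. The L1 (Manhattan) distance is
#' used instead of the Euclidean radius because the cubic lattice is not
#' radially symmetric.
#'
#' @param position 0-based voxel coordinate triple.
#' @param state a \linkS4class{ScaffoldState}.
#' @return distance in mm.
#' @examples
#' st <- createState(defaultConfig("mdamb231"))
#' manhattanCenterDistance(c(0, 0, 0), st)   # 13.5 mm on the default lattice
#' @export
manhattanCenterDistance <- function(position, state) {
  .checkInBounds(position, state@nLayers)
  h <- state@voxelSize
  center <- state@nLayers * h / 2
  sum(abs((position + 0.5) * h - center))
}

# Manhattan center distance for every voxel, as an n^3 vector in array order.
.allCenterDistances <- function(n, voxelSize) {
  centers <- (seq_len(n) - 0.5) * voxelSize
  d1 <- abs(centers - n * voxelSize / 2)
  idx <- expand.grid(x = d1, y = d1, z = d1)
  idx$x + idx$y + idx$z
}

# Left-closed 1 mm distance bins (only bins that contain voxels are kept);
# returns list(edges, bin index per voxel, distances).
.shellBins <- function(n, voxelSize, width = 1) {
  d <- .allCenterDistances(n, voxelSize)
  allEdges <- seq(0, floor(max(d) / width) * width, by = width)
  raw <- findInterval(d, c(allEdges, Inf), rightmost.closed = FALSE)
  occupied <- sort(unique(raw))
  list(edges = allEdges[occupied], bin = match(raw, occupied), distances = d)
}

# Precomputed linear neighbour indices (including self as first entry) for
# every voxel of an n^3 lattice; used by the stiffening environmental rule.
.neighbourIndexList <- function(n) {
  coords <- as.matrix(expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n)))
  offsets <- rbind(c(0, 0, 0), c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                   c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  lapply(seq_len(nrow(coords)), function(i) {
    nb <- sweep(offsets, 2, coords[i, ], "+")
    ok <- rowSums(nb >= 1 & nb <= n) == 3
    nb <- nb[ok, , drop = FALSE]
    (nb[, 3] - 1) * n * n + (nb[, 2] - 1) * n + nb[, 1]
  })
}

#' @describeIn createState accessor: per-cell registry data.frame.
#' @param state a \linkS4class{ScaffoldState}.
#' @export
cellRecords <- function(state) state@cells

#' @describeIn createState accessor: glucose field (g/L).
#' @export
glucoseField <- function(state) state@glucose

#' @describeIn createState accessor: oxygen field (g/L).
#' @export
oxygenField <- function(state) state@oxygen

#' @describeIn createState accessor: Young's-modulus field (kPa).
#' @export
youngModulusField <- function(state) state@youngModulus

#' @describeIn createState accessor: integer occupancy grid (0 = empty).
#' @export
cellGrid <- function(state) state@cellGrid

setMethod("show", "ScaffoldState", function(object) {
  present <- object@cells$present
  cat(sprintf("ScaffoldState: %d^3 lattice, voxel %.3g mm\n",
              object@nLayers, object@voxelSize))
  cat(sprintf("  cells: %d present (%s)\n", sum(present),
              if (sum(present)) paste(sprintf("%s=%d",
                names(table(object@cells$type[present])),
                as.integer(table(object@cells$type[present]))), collapse = ", ")
              else "none"))
  cat(sprintf("  glucose: mean %.4g g/L | oxygen: mean %.4g g/L | stiffness: mean %.4g kPa\n",
              mean(object@glucose), mean(object@oxygen), mean(object@youngModulus)))
  cat(sprintf("  reservoir: %.4g g/L in %.3g mL\n",
              object@mediumGlucose, object@mediumVolume))
})
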