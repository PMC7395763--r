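#' @import methods
NULL

# Reserved identifier for an unoccupied lattice site in rule products.
.EMPTY_TYPE <- "empty"

# Context variable names usable in probability expressions (count variables
# `#T` are handled separately and mapped to internal `.count_T` symbols).
.CONTEXT_VARS <- c("TIME", "TD", "Glc", "O2", "AGE", "TLD", "YM")

# Whitelisted functions inside probability expressions.
.EXPR_FUNS <- c("min", "max", "exp", "(", "+", "-", "*", "/")

#' Behavioural rule
#'
#' A parsed statement of the form \code{ID: A -> B [+ C], expr} describing a
#' stochastic cell-state transition: a cell of type \code{A} becomes type
#' \code{B} (optionally producing a second entity of type \code{C}, used for
#' duplication and migration) with a probability given by an arithmetic
#' expression over the simulation context variables.
#'
#' @slot ruleId identifier token.
#' @slot sourceType cell type the rule applies to.
#' @slot productType resulting cell type (or \code{"empty"}).
#' @slot extraProduct optional second product (\code{NA} when absent).
#' @slot probabilityExpr expression text, context variables and literals only.
#' @slot expr the parsed expression (internal form, count variables renamed).
#' @export
setClass("BehaviouralRule", representation(
  ruleId = "character", sourceType = "character", productType = "character",
  extraProduct = "character", probabilityExpr = "character", expr = "ANY"
))

setValidity("BehaviouralRule", function(object) {
  if (!(is.language(object@expr) || is.numeric(object@expr)))
    return("expr must be a parsed expression or a numeric constant")
  TRUE
})

#' Environmental rule
#'
#' A parsed statement of the form \code{ID: A -> amount, environment(tag)}
#' describing a cell-environment exchange: glucose uptake, oxygen uptake or
#' local matrix stiffening. The reserved amount token \code{U} resolves to the
#' reference value of the tagged species (configuration parameters
#' \code{u_glu}, \code{u_o2}, \code{u_ym}).
#'
#' @slot ruleId identifier token.
#' @slot sourceType cell type the rule applies to.
#' @slot amount numeric amount (\code{NA} when the reference token U is used).
#' @slot amountIsReference \code{TRUE} when the amount was given as \code{U}.
#' @slot tag one of \code{"Glc"}, \code{"O2"}, \code{"YM"}.
#' @export
setClass("EnvironmentalRule", representation(
  ruleId = "character", sourceType = "character", amount = "numeric",
  amountIsReference = "logical", tag = "character"
))

setValidity("EnvironmentalRule", function(object) {
  if (!object@tag %in% c("Glc", "O2", "YM"))
    return(sprintf("unknown environment tag '%s'", object@tag))
  if (!object@amountIsReference && (is.na(object@amount) || object@amount < 0))
    return("amount must be a non-negative number or the reference token U")
  TRUE
})

#' Rule evaluation context
#'
#' Normalised per-cell, per-iteration variables available to probability
#' expressions: TIME (iteration / total), TD (death iteration / total, 0 for
#' living cells), Glc and O2 (local level / reference medium level), AGE and
#' TLD (cell age and time since last division, each / current iteration), YM
#' (local stiffness / initial scaffold stiffness) and per-type population
#' fractions (count / lattice capacity).
#'
#' @slot time,td,glc,o2,age,tld,ym scalar context variables.
#' @slot typeCounts named fractions of lattice capacity, one per cell type.
#' @export
setClass("RuleContext", representation(
  time = "numeric", td = "numeric", glc = "numeric", o2 = "numeric",
  age = "numeric", tld = "numeric", ym = "numeric", typeCounts = "numeric"
))

setValidity("RuleContext", function(object) {
  v <- c(object@time, object@td, object@glc, object@o2, object@age,
         object@tld, object@ym, object@typeCounts)
  if (any(!is.finite(v))) return("all context variables must be finite")
  if (any(v < 0)) return("all context variables must be non-negative")
  TRUE
})

#' Diffusion specification
#'
#' Physical constants and boundary handling for the two diffusing species.
#' Default diffusivities are free-diffusion values in water at 37 C
#' (glucose 2.412 mm^2/h, oxygen 10.8 mm^2/h); the scaffold material is
#' assumed not to hinder diffusion. Boundary modes: \code{"reservoir"}
#' (finite well-mixed external medium exchanging mass with the face voxels),
#' \code{"dirichlet"} (faces pinned to the external concentration) and
#' \code{"zero-flux"} (closed system).
#'
#' @slot dGlucose,dOxygen diffusivities, mm^2/h.
#' @slot mediaGlucose fresh-medium glucose, g/L.
#' @slot incubatorOxygen dissolved oxygen at incubator conditions, g/L.
#' @slot mediumVolume external medium volume, mL.
#' @slot glucoseBoundary,oxygenBoundary boundary mode per species.
#' @export
setClass("DiffusionSpec", representation(
  dGlucose = "numeric", dOxygen = "numeric", mediaGlucose = "numeric",
  incubatorOxygen = "numeric", mediumVolume = "numeric",
  glucoseBoundary = "character", oxygenBoundary = "character"
))

setValidity("DiffusionSpec", function(object) {
  modes <- c("reservoir", "dirichlet", "zero-flux")
  if (object@dGlucose <= 0 || object@dOxygen <= 0)
    return("diffusivities must be positive")
  if (object@mediaGlucose < 0 || object@incubatorOxygen < 0)
    return("medium concentrations must be non-negative")
  if (object@mediumVolume <= 0) return("medium volume must be positive")
  if (!object@glucoseBoundary %in% modes || !object@oxygenBoundary %in% modes)
    return("boundary modes must be reservoir, dirichlet or zero-flux")
  TRUE
})

#' Scaffold lattice state
#'
#' The cubic voxel lattice holding cell occupancy (integer cell identifiers,
#' 0 = empty), the three continuous per-voxel fields (glucose g/L, oxygen g/L,
#' Young's modulus kPa), the external medium reservoir and the per-cell
#' registry. Only stiffening is modelled, so the Young's-modulus field never
#' drops below the initial scaffold stiffness.
#'
#' @slot nLayers voxels per edge.
#' @slot voxelSize edge length of one voxel, mm.
#' @slot cellGrid integer array of cell ids (0 = empty).
#' @slot glucose,oxygen,youngModulus numeric arrays, same dimensions.
#' @slot mediumGlucose current reservoir glucose concentration, g/L.
#' @slot mediumVolume reservoir volume, mL.
#' @slot referenceGlucose fresh-medium glucose (normalisation), g/L.
#' @slot referenceOxygen incubator oxygen (normalisation), g/L.
#' @slot initialStiffness initial Young's modulus, kPa.
#' @slot capacityPerSite virtual cells per voxel (1 in this model).
#' @slot cells per-cell registry data.frame (id, type, x, y, z, birth,
#'   last_division, death, present).
#' @export
setClass("ScaffoldState", representation(
  nLayers = "integer", voxelSize = "numeric", cellGrid = "array",
  glucose = "array", oxygen = "array", youngModulus = "array",
  mediumGlucose = "numeric", mediumVolume = "numeric",
  referenceGlucose = "numeric", referenceOxygen = "numeric",
  initialStiffness = "numeric", capacityPerSite = "integer",
  cells = "data.frame"
))

setValidity("ScaffoldState", function(object) {
  n <- object@nLayers
  dims <- c(n, n, n)
  for (f in c("cellGrid", "glucose", "oxygen", "youngModulus"))
    if (!identical(dim(slot(object, f)), as.integer(dims)))
      return(sprintf("%s must be an %d^3 array", f, n))
  if (any(object@glucose < 0) || any(object@oxygen < 0))
    return("concentration fields must be non-negative")
  if (any(object@youngModulus < object@initialStiffness - 1e-9))
    return("Young's modulus cannot drop below the initial stiffness")
  if (object@mediumGlucose < 0) return("reservoir concentration must be non-negative")
  TRUE
})

#' Seeding scale factor
#'
#' Link between an in-vitro population and its virtual counterpart: the
#' fraction of scaffold volume initially occupied by biological cells is
#' preserved on the lattice, and each virtual cell aggregates
#' \code{aggregationRatio} biological cells (used to scale per-cell uptakes so
#' the total consumption matches the wet-lab experiment).
#'
#' @slot occupiedFraction dimensionless initial occupancy.
#' @slot nVirtual number of virtual cells to seed.
#' @slot aggregationRatio biological cells per virtual cell.
#' @export
setClass("ScaleFactor", representation(
  occupiedFraction = "numeric", nVirtual = "integer", aggregationRatio = "numeric"
))

#' Simulation configuration
#'
#' Complete description of one virtual 3D-culture experiment: scaffold
#' geometry and initial stiffness, diffusion specification, protocol (length,
#' step, media changes), initial population and composition, declared cell
#' types with their roles, the rule set and the named parameter set
#' (a, b, c, d, e, u_glu, u_o2, u_ym, s, lox).
#'
#' @slot nLayers lattice resolution (voxels per edge).
#' @slot voxelSize mm.
#' @slot initialStiffness kPa.
#' @slot diffusion a \linkS4class{DiffusionSpec}.
#' @slot hours total simulated time, h.
#' @slot dtHours iteration length, h.
#' @slot mediaChangeHours media-change period, h (0 = never).
#' @slot nVitro in-vitro population cardinality.
#' @slot cellVolume biological cell volume, mm^3.
#' @slot cellTypes named character: type name -> role
#'   (\code{proliferant}, \code{quiescent}, \code{dead}).
#' @slot composition named fractions of the initial population per type.
#' @slot parameters named numeric parameter set.
#' @slot ruleText raw rule lines (parameter names unsubstituted).
#' @slot rules parsed behavioural rules (coefficients substituted).
#' @slot envRules parsed environmental rules.
#' @slot seed default RNG seed.
#' @slot snapshotHours hours at which full field snapshots are stored.
#' @slot capacityPerSite virtual cells per voxel.
#' @export
setClass("SimulationConfig", representation(
  nLayers = "integer", voxelSize = "numeric", initialStiffness = "numeric",
  diffusion = "DiffusionSpec", hours = "numeric", dtHours = "numeric",
  mediaChangeHours = "numeric", nVitro = "numeric", cellVolume = "numeric",
  cellTypes = "character", composition = "numeric", parameters = "numeric",
  ruleText = "character", rules = "list", envRules = "list",
  seed = "integer", snapshotHours = "numeric", capacityPerSite = "integer"
))

setValidity("SimulationConfig", function(object) {
  if (object@nLayers < 3) return("n_layers must be >= 3")
  if (object@voxelSize <= 0 || object@initialStiffness <= 0)
    return("voxel size and initial stiffness must be positive")
  if (object@hours < 0 || object@dtHours <= 0)
    return("protocol hours must be >= 0 and dt > 0")
  if (abs(object@hours / object@dtHours - round(object@hours / object@dtHours)) > 1e-9)
    return("total hours must be divisible by the iteration length")
  roles <- c("proliferant", "quiescent", "dead")
  if (!all(object@cellTypes %in% roles))
    return(sprintf("cell-type roles must be one of: %s", paste(roles, collapse = ", ")))
  if (.EMPTY_TYPE %in% names(object@cellTypes))
    return("'empty' is reserved and cannot be declared as a cell type")
  if (length(object@composition) &&
      abs(sum(object@composition) - 1) > 1e-6)
    return("composition fractions must sum to 1")
  if (!all(names(object@composition) %in% names(object@cellTypes)))
    return("composition refers to undeclared cell types")
  p <- object@parameters
  need <- c("a", "b", "c", "d", "e", "u_glu", "u_o2", "u_ym", "s", "lox")
  if (!all(need %in% names(p)))
    return(sprintf("missing parameters: %s", paste(setdiff(need, names(p)), collapse = ", ")))
  if (any(p[c("a", "b", "c", "d", "e", "u_glu", "u_o2", "u_ym", "lox")] < 0))
    return("parameters a..e, uptakes and lox must be non-negative")
  if (p["s"] < 0 || p["s"] > 1) return("s must lie in [0, 1]")
  TRUE
})

#' Simulation result
#'
#' Per-iteration population counts and mean field values, per-iteration
#' Manhattan-shell means of every tracked quantity, full field snapshots at
#' configured hours, the per-cell event log and the run metadata needed to
#' reproduce the run (seed, configuration hash).
#'
#' @slot counts matrix (iterations + 1) x cell types.
#' @slot meanFields matrix of spatial mean glucose, oxygen, stiffness per hour.
#' @slot shellMeans list of matrices (hours x Manhattan-distance bins) for
#'   living-cell counts, glucose, oxygen and stiffness.
#' @slot shellBins left edges of the distance bins, mm.
#' @slot shellVoxelCounts voxels per bin.
#' @slot snapshots named list (hour -> list of field arrays).
#' @slot events event-log data.frame.
#' @slot initialCount virtual cells at hour 0.
#' @slot scale the \linkS4class{ScaleFactor} used.
#' @slot seed RNG seed of the run.
#' @slot configHash md5 of the canonical configuration text.
#' @slot config the \linkS4class{SimulationConfig}.
#' @export
setClass("SimulationResult", representation(
  counts = "matrix", meanFields = "matrix", shellMeans = "list",
  shellBins = "numeric", shellVoxelCounts = "integer", snapshots = "list",
  events = "data.frame", initialCount = "integer", scale = "ScaleFactor",
  seed = "integer", configHash = "character", config = "SimulationConfig"
))

#' Parameter space for sensitivity analysis
#'
#' Independent uniform ranges for a named parameter subset, by default
#' reference +/- 40 percent (the behavioural group a..e and the environmental
#' group u_glu, u_o2, u_ym, s are usually analysed separately).
#'
#' @slot parameters parameter names.
#' @slot reference reference values.
#' @slot lower,upper range bounds.
#' @export
setClass("ParameterSpace", representation(
  parameters = "character", reference = "numeric",
  lower = "numeric", upper = "numeric"
))

setValidity("ParameterSpace", function(object) {
  k <- length(object@parameters)
  if (length(object@reference) != k || length(object@lower) != k ||
      length(object@upper) != k)
    return("reference, lower and upper must match the number of parameters")
  if (any(object@upper <= object@lower))
    return("all parameter ranges must have positive width")
  TRUE
})

#' Radial profile
#'
#' Quantity means binned by Manhattan distance from the scaffold center
#' (rows) across simulation hours (columns). \code{values} is normalised per
#' the conventions of the analysis layer (cell counts to the initial per-bin
#' population, fields to their initial spatial average); \code{raw} holds the
#' unnormalised bin means.
#'
#' @slot quantity one of \code{density}, \code{Glc}, \code{O2}, \code{YM}.
#' @slot hours column coordinates, h.
#' @slot bins left edges of the 1 mm distance bins.
#' @slot values normalised matrix bins x hours.
#' @slot raw unnormalised matrix bins x hours.
#' @slot binVoxelCounts voxels per bin.
#' @export
setClass("RadialProfile", representation(
  quantity = "character", hours = "numeric", bins = "numeric",
  values = "matrix", raw = "matrix", binVoxelCounts = "integer"
))
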