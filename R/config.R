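# Configuration: programmatic construction, INI-style file dialect,
# shipped presets, result writing, canonical serialization and hashing.
#
# File dialect: [section] headers, key = value lines (decimal numbers,
# scientific notation allowed), verbatim rule statements in [rules]; a line
# whose first non-blank character is '#' is a comment. Parameter names from
# [parameters] appearing in rule probability expressions are substituted
# with their numeric values when the rule is parsed, so the parsed rules
# contain only context variables and literals while coefficients stay
# single-sourced in [parameters].

.DEFAULT_PARAMS <- c(a = 0.38, b = 0.005, c = 0.1, d = 0.15, e = 0.008,
                     u_glu = 16.7e-12, u_o2 = 2.93e-15, u_ym = 1050, s = 0.5,
                     lox = 3e-6)

.DEFAULT_RULES <- c(
  "dup: P -> P + P, a * min(Glc, O2)",
  "qui: P -> Q, d * (1 - Glc)",
  "rev: Q -> P, b * Glc",
  "die_p: P -> D, c * (1 - Glc) * (1 - min(O2, 1))",
  "die_q: Q -> D, c * (1 - Glc) * (1 - min(O2, 1))",
  "mig: P -> empty + P, e",
  "deg: D -> empty, a",
  "upt_glc_p: P -> U, environment (Glc)",
  "upt_glc_q: Q -> U, environment (Glc)",
  "upt_o2_p: P -> U, environment (O2)",
  "upt_o2_q: Q -> U, environment (O2)",
  "stiff: P -> U, environment (YM)")

# Substitute [parameters] names in a rule line with numeric literals.
.substituteParams <- function(line, params) {
  for (nm in names(params)) {
    pat <- sprintf("(?<![A-Za-z0-9_])%s(?![A-Za-z0-9_])", nm)
    line <- gsub(pat, sprintf("%.17g", params[[nm]]), line, perl = TRUE)
  }
  line
}

.parseRuleSet <- function(ruleText, params, cellTypes) {
  rules <- list()
  envRules <- list()
  errors <- character(0)
  for (line in ruleText) {
    parsed <- tryCatch(
      parseRule(.substituteParams(line, params), cellTypes = names(cellTypes)),
      error = function(e) conditionMessage(e))
    if (is.character(parsed)) {
      errors <- c(errors, parsed)
    } else if (is(parsed, "EnvironmentalRule")) {
      envRules[[length(envRules) + 1L]] <- parsed
    } else {
      rules[[length(rules) + 1L]] <- parsed
    }
  }
  list(rules = rules, envRules = envRules, errors = errors)
}

#' Construct a simulation configuration
#'
#' Programmatic equivalent of a configuration file. Rule statements are
#' given as raw text lines; parameter names occurring in their probability
#' expressions are substituted with the values in \code{parameters}.
#'
#' @param sideLength scaffold side, mm.
#' @param nLayers lattice resolution (voxels per edge).
#' @param initialStiffness initial Young's modulus, kPa.
#' @param hours,dtHours,mediaChangeHours protocol (h).
#' @param nVitro in-vitro population cardinality.
#' @param cellVolume biological cell volume, mm^3.
#' @param cellTypes named character vector: type name -> role.
#' @param composition named initial-population fractions.
#' @param parameters named parameter set (a..e, u_glu, u_o2, u_ym, s, lox).
#' @param rules character vector of rule statements.
#' @param dGlucose,dOxygen diffusivities, mm^2/h.
#' @param mediaGlucose,incubatorOxygen reference concentrations, g/L.
#' @param mediumVolume external medium volume, mL.
#' @param glucoseBoundary,oxygenBoundary boundary modes.
#' @param seed default RNG seed.
#' @param snapshotHours hours with full field snapshots (default 0 and the
#'   final hour).
#' @param capacityPerSite virtual cells per voxel.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(sideLength = 10, nLayers = 10L,
                             initialStiffness = 47, hours = 240, dtHours = 1,
                             mediaChangeHours = 24, nVitro = 5e6,
                             cellVolume = 4.2e-6,
                             cellTypes = c(P = "proliferant", Q = "quiescent",
                                           D = "dead"),
                             composition = c(P = 1),
                             parameters = .DEFAULT_PARAMS,
                             rules = .DEFAULT_RULES,
                             dGlucose = 2.412, dOxygen = 10.8,
                             mediaGlucose = 4.5, incubatorOxygen = 7.2e-3,
                             mediumVolume = 1,
                             glucoseBoundary = "reservoir",
                             oxygenBoundary = "dirichlet",
                             seed = 1L, snapshotHours = NULL,
                             capacityPerSite = 1L) {
  errors <- character(0)
  if (any(names(cellTypes) %in% names(parameters)))
    errors <- c(errors, "cell-type names must not collide with parameter names")
  parsed <- .parseRuleSet(rules, as.list(parameters), cellTypes)
  errors <- c(errors, parsed$errors)
  if (is.null(snapshotHours)) snapshotHours <- unique(c(0, hours))
  diff <- new("DiffusionSpec", dGlucose = dGlucose, dOxygen = dOxygen,
              mediaGlucose = mediaGlucose, incubatorOxygen = incubatorOxygen,
              mediumVolume = mediumVolume, glucoseBoundary = glucoseBoundary,
              oxygenBoundary = oxygenBoundary)
  cfg <- new("SimulationConfig",
             nLayers = as.integer(nLayers), voxelSize = sideLength / nLayers,
             initialStiffness = initialStiffness, diffusion = diff,
             hours = hours, dtHours = dtHours,
             mediaChangeHours = mediaChangeHours, nVitro = nVitro,
             cellVolume = cellVolume, cellTypes = cellTypes,
             composition = composition, parameters = parameters,
             ruleText = rules, rules = parsed$rules,
             envRules = parsed$envRules, seed = as.integer(seed),
             snapshotHours = snapshotHours,
             capacityPerSite = as.integer(capacityPerSite))
  v <- validObject(cfg, test = TRUE)
  if (is.character(v)) errors <- c(errors, v)
  if (length(errors))
    stop(paste(c("invalid configuration:", paste(" -", errors)),
               collapse = "\n"), call. = FALSE)
  cfg
}

#' Re-apply a modified parameter set
#'
#' Replaces the named parameters and re-substitutes them into the stored
#' rule text, re-parsing the rule set (used by the sensitivity module to
#' explore the parameter space).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param params named numeric vector of parameter values to replace.
#' @return the updated configuration.
#' @export
applyParameters <- function(config, params) {
  unknown <- setdiff(names(params), names(config@parameters))
  if (length(unknown))
    stop(sprintf("unknown parameters: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  p <- config@parameters
  p[names(params)] <- params
  config@parameters <- p
  parsed <- .parseRuleSet(config@ruleText, as.list(p), config@cellTypes)
  if (length(parsed$errors))
    stop(paste(parsed$errors, collapse = "\n"), call. = FALSE)
  config@rules <- parsed$rules
  config@envRules <- parsed$envRules
  validObject(config)
  config
}

.CONFIG_SECTIONS <- list(
  scaffold = c("side_mm", "n_layers", "young_modulus_kpa"),
  protocol = c("hours", "dt_hours", "media_change_hours"),
  population = c("n_vitro", "cell_volume_mm3", "seed"),
  celltypes = NULL, composition = NULL,
  diffusion = c("d_glucose_mm2_h", "d_oxygen_mm2_h", "media_glucose_g_l",
                "incubator_oxygen_g_l", "medium_volume_ml",
                "glucose_boundary", "oxygen_boundary"),
  parameters = c("a", "b", "c", "d", "e", "u_glu", "u_o2", "u_ym", "s", "lox"),
  rules = NULL, output = c("snapshot_hours", "capacity_per_site"))

#' Load a configuration file
#'
#' Parses and fully validates an INI-style configuration file; unknown
#' sections or keys are rejected and semantic errors (undeclared cell types,
#' malformed rules, out-of-range values) are aggregated and reported
#' together.
#'
#' @param path path to the configuration file.
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- loadConfig(system.file("extdata", "mdamb231.cfg",
#'                               package = "scaffoldsim"))
#' cfg@parameters[["a"]]
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  section <- NA_character_
  kv <- list()
  ruleLines <- character(0)
  typeLines <- character(0)
  compLines <- character(0)
  errors <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    trimmed <- .trim(ln)
    if (!nzchar(trimmed) || startsWith(trimmed, "#")) next
    if (grepl("^\\[.*\\]$", trimmed)) {
      section <- sub("^\\[(.*)\\]$", "\\1", trimmed)
      if (!section %in% names(.CONFIG_SECTIONS))
        errors <- c(errors, sprintf("line %d: unknown section [%s]", i, section))
      next
    }
    if (is.na(section)) {
      errors <- c(errors, sprintf("line %d: content before any [section]", i))
      next
    }
    if (section == "rules") {
      ruleLines <- c(ruleLines, trimmed)
      next
    }
    if (!grepl("=", trimmed, fixed = TRUE)) {
      errors <- c(errors, sprintf("line %d: expected key = value in [%s]",
                                  i, section))
      next
    }
    key <- .trim(sub("=.*$", "", trimmed))
    val <- .trim(sub("^[^=]*=", "", trimmed))
    if (section == "celltypes") {
      typeLines <- c(typeLines, stats::setNames(val, key))
    } else if (section == "composition") {
      compLines <- c(compLines, stats::setNames(val, key))
    } else {
      allowed <- .CONFIG_SECTIONS[[section]]
      if (!key %in% allowed) {
        errors <- c(errors, sprintf("line %d: unknown key '%s' in [%s]",
                                    i, key, section))
        next
      }
      kv[[paste(section, key, sep = ".")]] <- val
    }
  }
  if (length(errors))
    stop(paste(c("configuration parse errors:", paste(" -", errors)),
               collapse = "\n"), call. = FALSE)

  num <- function(key, default = NULL) {
    v <- kv[[key]]
    if (is.null(v)) {
      if (is.null(default)) {
        errors <<- c(errors, sprintf("missing required key %s", key))
        return(NA_real_)
      }
      return(default)
    }
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) errors <<- c(errors, sprintf("key %s: '%s' is not a number",
                                               key, v))
    x
  }
  str <- function(key, default) {
    v <- kv[[key]]
    if (is.null(v)) default else v
  }

  side <- num("scaffold.side_mm", 10)
  nLayers <- num("scaffold.n_layers", 10)
  stiff <- num("scaffold.young_modulus_kpa", 47)
  hours <- num("protocol.hours", 240)
  dtHours <- num("protocol.dt_hours", 1)
  mediaChange <- num("protocol.media_change_hours", 24)
  nVitro <- num("population.n_vitro")
  cellVol <- num("population.cell_volume_mm3", 4.2e-6)
  seed <- num("population.seed", 1)
  pnames <- .CONFIG_SECTIONS$parameters
  params <- stats::setNames(
    vapply(pnames, function(p) num(paste0("parameters.", p)), numeric(1)),
    pnames)
  snapHours <- str("output.snapshot_hours", NA)
  snapHours <- if (is.na(snapHours[1])) unique(c(0, hours)) else
    as.numeric(strsplit(.trim(snapHours), "\\s+")[[1]])
  cellTypes <- stats::setNames(as.character(typeLines), names(typeLines))
  composition <- stats::setNames(
    suppressWarnings(as.numeric(compLines)), names(compLines))
  if (anyNA(composition))
    errors <- c(errors, "composition fractions must be numeric")
  if (length(errors))
    stop(paste(c("configuration errors:", paste(" -", errors)),
               collapse = "\n"), call. = FALSE)

  simulationConfig(
    sideLength = side, nLayers = as.integer(nLayers),
    initialStiffness = stiff, hours = hours, dtHours = dtHours,
    mediaChangeHours = mediaChange, nVitro = nVitro, cellVolume = cellVol,
    cellTypes = cellTypes, composition = composition, parameters = params,
    rules = ruleLines,
    dGlucose = num("diffusion.d_glucose_mm2_h", 2.412),
    dOxygen = num("diffusion.d_oxygen_mm2_h", 10.8),
    mediaGlucose = num("diffusion.media_glucose_g_l", 4.5),
    incubatorOxygen = num("diffusion.incubator_oxygen_g_l", 7.2e-3),
    mediumVolume = num("diffusion.medium_volume_ml", 1),
    glucoseBoundary = str("diffusion.glucose_boundary", "reservoir"),
    oxygenBoundary = str("diffusion.oxygen_boundary", "dirichlet"),
    seed = as.integer(seed), snapshotHours = snapHours,
    capacityPerSite = as.integer(num("output.capacity_per_site", 1)))
}

# Canonical configuration text (stable key order; used for files and hashing).
.configText <- function(config) {
  d <- config@diffusion
  fmt <- function(x) sprintf("%.15g", x)
  c("# scaffoldsim configuration",
    "[scaffold]",
    paste("side_mm =", fmt(config@nLayers * config@voxelSize)),
    paste("n_layers =", config@nLayers),
    paste("young_modulus_kpa =", fmt(config@initialStiffness)),
    "", "[protocol]",
    paste("hours =", fmt(config@hours)),
    paste("dt_hours =", fmt(config@dtHours)),
    paste("media_change_hours =", fmt(config@mediaChangeHours)),
    "", "[population]",
    paste("n_vitro =", fmt(config@nVitro)),
    paste("cell_volume_mm3 =", fmt(config@cellVolume)),
    paste("seed =", config@seed),
    "", "[celltypes]",
    paste(names(config@cellTypes), "=", unname(config@cellTypes)),
    "", "[composition]",
    paste(names(config@composition), "=", fmt(unname(config@composition))),
    "", "[diffusion]",
    paste("d_glucose_mm2_h =", fmt(d@dGlucose)),
    paste("d_oxygen_mm2_h =", fmt(d@dOxygen)),
    paste("media_glucose_g_l =", fmt(d@mediaGlucose)),
    paste("incubator_oxygen_g_l =", fmt(d@incubatorOxygen)),
    paste("medium_volume_ml =", fmt(d@mediumVolume)),
    paste("glucose_boundary =", d@glucoseBoundary),
    paste("oxygen_boundary =", d@oxygenBoundary),
    "", "[parameters]",
    paste(names(config@parameters), "=", fmt(unname(config@parameters))),
    "", "[rules]",
    config@ruleText,
    "", "[output]",
    paste("snapshot_hours =", paste(fmt(config@snapshotHours), collapse = " ")),
    paste("capacity_per_site =", config@capacityPerSite))
}

#' Write a configuration file
#'
#' Serializes the configuration to its canonical INI form;
#' \code{loadConfig(writeConfig(cfg, path))} round-trips.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeConfig <- function(config, path) {
  writeLines(.configText(config), path)
  invisible(path)
}

#' Hash of the canonical configuration text
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return md5 hex digest of the canonical serialization.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".cfg")
  on.exit(unlink(tmp))
  writeLines(.configText(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Shipped default configurations
#'
#' Presets for the two breast-cancer cell lines (MCF7: slow-growing,
#' low-motility, negligible LOX expression; MDA-MB-231: aggressive,
#' motile, strong LOX-driven matrix stiffening) at the reference seeding of
#' 5 M in-vitro cells, plus reduced-cardinality variants (625 K, 1.25 M,
#' 2.5 M) used for seeding-density screens. Optional arguments override
#' protocol and geometry fields (used for small examples and tests).
#'
#' @param preset one of \code{"mcf7"}, \code{"mdamb231"},
#'   \code{"mcf7_625k"}, \code{"mcf7_1.25m"}, \code{"mcf7_2.5m"},
#'   \code{"mdamb231_625k"}, \code{"mdamb231_1.25m"}, \code{"mdamb231_2.5m"}.
#' @param nLayers,hours,mediaChangeHours,nVitro,seed,snapshotHours optional
#'   overrides.
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- defaultConfig("mcf7")
#' cfg@parameters[["b"]]
#' @export
defaultConfig <- function(preset = "mdamb231", nLayers = NULL, hours = NULL,
                          mediaChangeHours = NULL, nVitro = NULL, seed = NULL,
                          snapshotHours = NULL) {
  path <- system.file("extdata", paste0(preset, ".cfg"), package = "scaffoldsim")
  if (!nzchar(path))
    stop(sprintf("unknown preset '%s'", preset), call. = FALSE)
  cfg <- loadConfig(path)
  side <- cfg@nLayers * cfg@voxelSize
  changed <- FALSE
  if (!is.null(nLayers)) {
    cfg@nLayers <- as.integer(nLayers)
    cfg@voxelSize <- side / nLayers
    changed <- TRUE
  }
  if (!is.null(hours)) {
    cfg@hours <- hours
    cfg@snapshotHours <- unique(c(0, hours))
    changed <- TRUE
  }
  if (!is.null(mediaChangeHours)) { cfg@mediaChangeHours <- mediaChangeHours
    changed <- TRUE }
  if (!is.null(nVitro)) { cfg@nVitro <- nVitro; changed <- TRUE }
  if (!is.null(seed)) { cfg@seed <- as.integer(seed); changed <- TRUE }
  if (!is.null(snapshotHours)) { cfg@snapshotHours <- snapshotHours
    changed <- TRUE }
  if (changed) validObject(cfg)
  cfg
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d^3 lattice (%.3g mm voxels), %g h protocol\n",
              object@nLayers, object@voxelSize, object@hours))
  cat(sprintf("  population: %.3g in-vitro cells (%s)\n", object@nVitro,
              paste(sprintf("%s=%.2g", names(object@composition),
                            object@composition), collapse = ", ")))
  cat(sprintf("  parameters: %s\n",
              paste(sprintf("%s=%.3g", names(object@parameters),
                            object@parameters), collapse = " ")))
  cat(sprintf("  rules: %d behavioural, %d environmental\n",
              length(object@rules), length(object@envRules)))
})

#' Write simulation results as structured text files
#'
#' Emits \code{timeseries.tsv} (iteration, hour, per-type counts, mean field
#' values), \code{snapshots/<field>_<hour>.tsv} (0-based voxel indices and
#' value), \code{events.tsv} and \code{manifest.txt} (configuration echo,
#' seed, version, config hash). Output is byte-stable for identical inputs.
#'
#' @param result a \linkS4class{SimulationResult}.
#' @param outDir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
writeResults <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hours <- as.numeric(rownames(result@counts))
  ts <- data.frame(iteration = seq_along(hours) - 1L, hour = hours,
                   result@counts, result@meanFields, check.names = FALSE)
  utils::write.table(ts, file.path(outDir, "timeseries.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  snapDir <- file.path(outDir, "snapshots")
  dir.create(snapDir, showWarnings = FALSE)
  n <- result@config@nLayers
  coords <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  for (hour in names(result@snapshots)) {
    for (f in c("glucose", "oxygen", "youngModulus")) {
      df <- data.frame(coords, value = as.numeric(result@snapshots[[hour]][[f]]))
      utils::write.table(df, file.path(snapDir, sprintf("%s_%s.tsv", f, hour)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  utils::write.table(result@events, file.path(outDir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(sprintf("tool_version: %s",
                        as.character(utils::packageVersion("scaffoldsim"))),
               sprintf("seed: %d", result@seed),
               sprintf("config_hash: %s", result@configHash),
               "", "# configuration", .configText(result@config))
  writeLines(manifest, file.path(outDir, "manifest.txt"))
  invisible(outDir)
}
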