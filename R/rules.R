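# Rule grammar: parsing, formatting and evaluation.
#
# One rule per line:   ID: A -> B [+ C], D
# where A, B, C are declared cell-type names (or the reserved word "empty"
# in products) and D is either an arithmetic probability expression over the
# context variables (TIME, TD, Glc, O2, AGE, TLD, YM, #TYPE) or one of the
# environment tags environment(Glc) | environment(O2) | environment(YM).
# For environmental rules B is a non-negative amount or the reserved token U
# (reference uptake of the tagged species). A '#' introduces a comment only
# when it is the first non-blank character of a line, because '#TYPE' is the
# population-count context variable.

.IDENT_RE <- "^[A-Za-z_][A-Za-z0-9_]*$"

# Split `text` at top-level (paren depth 0) occurrences of a single character.
.splitTop <- function(text, sep, first = FALSE) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == sep && depth == 0L) {
      cuts <- c(cuts, i)
      if (first) break
    }
  }
  if (!length(cuts)) return(list(text))
  bounds <- c(0L, cuts, length(chars) + 1L)
  lapply(seq_len(length(bounds) - 1L), function(j)
    paste(chars[seq(bounds[j] + 1L, bounds[j + 1L] - 1L)], collapse = ""))
}

.trim <- function(x) gsub("^\\s+|\\s+$", "", x)

.ruleError <- function(line, col, msg) {
  stop(sprintf("rule syntax error at column %d: %s [in \"%s\"]", col, msg, line),
       call. = FALSE)
}

# Validate a parsed probability expression against the grammar whitelist.
# Returns the (possibly type-checked) expression invisibly; errors otherwise.
.checkExprAst <- function(e, cellTypes = NULL) {
  if (is.numeric(e) || is.integer(e)) return(invisible(e))
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm %in% .CONTEXT_VARS) return(invisible(e))
    if (startsWith(nm, ".count_")) {
      ty <- sub("^\\.count_", "", nm)
      if (!is.null(cellTypes) && !ty %in% cellTypes)
        stop(sprintf("unknown cell type '%s' in count variable #%s", ty, ty),
             call. = FALSE)
      return(invisible(e))
    }
    stop(sprintf("unknown context variable '%s'", nm), call. = FALSE)
  }
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (!fn %in% .EXPR_FUNS)
      stop(sprintf("function '%s' is not allowed in probability expressions", fn),
           call. = FALSE)
    for (i in seq_along(e)[-1]) .checkExprAst(e[[i]], cellTypes)
    return(invisible(e))
  }
  stop("unsupported construct in probability expression", call. = FALSE)
}

.parseProbabilityExpr <- function(text, cellTypes = NULL) {
  internal <- gsub("#([A-Za-z_][A-Za-z0-9_]*)", ".count_\\1", text)
  if (grepl("#", internal, fixed = TRUE))
    stop("stray '#' in probability expression", call. = FALSE)
  parsed <- tryCatch(parse(text = internal, keep.source = FALSE),
                     error = function(e) stop(sprintf(
                       "cannot parse probability expression '%s': %s",
                       text, conditionMessage(e)), call. = FALSE))
  if (length(parsed) != 1)
    stop("probability expression must be a single expression", call. = FALSE)
  e <- parsed[[1]]
  .checkExprAst(e, cellTypes)
  e
}

.checkTypeName <- function(name, cellTypes, what, line, allowEmpty = FALSE) {
  if (!grepl(.IDENT_RE, name))
    .ruleError(line, regexpr(name, line, fixed = TRUE)[1],
               sprintf("invalid %s identifier '%s'", what, name))
  if (allowEmpty && name == .EMPTY_TYPE) return(invisible(name))
  if (!allowEmpty && name == .EMPTY_TYPE)
    stop(sprintf("'%s' cannot be '%s'", what, .EMPTY_TYPE), call. = FALSE)
  if (!is.null(cellTypes) && !name %in% cellTypes)
    stop(sprintf("unknown cell type '%s' (%s)", name, what), call. = FALSE)
  invisible(name)
}

#' Parse one rule statement
#'
#' Parses a single line in the rule grammar and returns either a
#' \linkS4class{BehaviouralRule} or an \linkS4class{EnvironmentalRule}; the
#' statement is environmental exactly when its last term is one of the
#' recognised \code{environment(...)} tags.
#'
#' @param line a single non-empty rule statement.
#' @param cellTypes optional character vector of declared cell-type names;
#'   when supplied, all type identifiers in the rule are checked against it.
#' @return a \linkS4class{BehaviouralRule} or \linkS4class{EnvironmentalRule}.
#' @examples
#' parseRule("dup: P -> P + P, 0.44")
#' parseRule("upt: P -> U, environment (Glc)")
#' parseRule("mig: P -> empty + P, 0.01 * min(Glc, O2)")
#' @export
parseRule <- function(line, cellTypes = NULL) {
  raw <- line
  line <- .trim(line)
  if (!nzchar(line)) stop("empty rule statement", call. = FALSE)
  colon <- regexpr(":", line, fixed = TRUE)[1]
  if (colon < 0) .ruleError(raw, 1L, "missing ':' after rule id")
  ruleId <- .trim(substr(line, 1, colon - 1))
  if (!grepl(.IDENT_RE, ruleId)) .ruleError(raw, 1L, "invalid rule id")
  body <- substr(line, colon + 1, nchar(line))
  arrow <- regexpr("->", body, fixed = TRUE)[1]
  if (arrow < 0) .ruleError(raw, colon + 1L, "missing '->'")
  lhs <- .trim(substr(body, 1, arrow - 1))
  rhs <- substr(body, arrow + 2, nchar(body))
  parts <- .splitTop(rhs, ",", first = TRUE)
  if (length(parts) < 2)
    .ruleError(raw, colon + arrow + 2L, "missing ',' before the probability/tag term")
  products <- .trim(parts[[1]])
  dterm <- .trim(parts[[2]])
  if (!nzchar(products))
    .ruleError(raw, colon + arrow + 2L, "missing product term (B)")
  envTag <- regmatches(dterm,
    regexec("^environment\\s*\\(\\s*([A-Za-z0-9]+)\\s*\\)$", dterm))[[1]]
  .checkTypeName(lhs, cellTypes, "source type", raw)

  if (length(envTag)) {
    tag <- envTag[2]
    if (!tag %in% c("Glc", "O2", "YM"))
      stop(sprintf("unknown environment tag '%s' in rule '%s'", tag, ruleId),
           call. = FALSE)
    prodParts <- .trim(unlist(.splitTop(products, "+")))
    if (length(prodParts) != 1)
      stop(sprintf("environmental rule '%s' cannot have a '+ C' term", ruleId),
           call. = FALSE)
    isRef <- identical(prodParts, "U")
    amount <- NA_real_
    if (!isRef) {
      amount <- suppressWarnings(as.numeric(prodParts))
      if (is.na(amount) || amount < 0)
        stop(sprintf(
          "amount in environmental rule '%s' must be a non-negative number or U",
          ruleId), call. = FALSE)
    }
    return(new("EnvironmentalRule", ruleId = ruleId, sourceType = lhs,
               amount = amount, amountIsReference = isRef, tag = tag))
  }

  prodParts <- .trim(unlist(.splitTop(products, "+")))
  if (length(prodParts) > 2)
    .ruleError(raw, colon + arrow + 2L, "at most two product terms (B + C) allowed")
  if (any(!nzchar(prodParts)))
    .ruleError(raw, colon + arrow + 2L, "empty product term")
  .checkTypeName(prodParts[1], cellTypes, "product type", raw, allowEmpty = TRUE)
  extra <- NA_character_
  if (length(prodParts) == 2) {
    .checkTypeName(prodParts[2], cellTypes, "extra product", raw, allowEmpty = TRUE)
    extra <- prodParts[2]
  }
  expr <- .parseProbabilityExpr(dterm, cellTypes)
  canonical <- gsub(".count_", "#", paste(deparse(expr), collapse = " "), fixed = TRUE)
  new("BehaviouralRule", ruleId = ruleId, sourceType = lhs,
      productType = prodParts[1], extraProduct = extra,
      probabilityExpr = canonical, expr = expr)
}

#' Format a rule back to its canonical statement
#'
#' @param rule a parsed rule object.
#' @return a single character string; \code{parseRule(formatRule(r))} is
#'   identical to \code{r}.
#' @export
setGeneric("formatRule", function(rule) standardGeneric("formatRule"))

#' @rdname formatRule
#' @export
setMethod("formatRule", "BehaviouralRule", function(rule) {
  prods <- rule@productType
  if (!is.na(rule@extraProduct)) prods <- paste(prods, "+", rule@extraProduct)
  sprintf("%s: %s -> %s, %s", rule@ruleId, rule@sourceType, prods,
          rule@probabilityExpr)
})

#' @rdname formatRule
#' @export
setMethod("formatRule", "EnvironmentalRule", function(rule) {
  amt <- if (rule@amountIsReference) "U" else format(rule@amount, digits = 15)
  sprintf("%s: %s -> %s, environment (%s)", rule@ruleId, rule@sourceType,
          amt, rule@tag)
})

setMethod("show", "BehaviouralRule", function(object) {
  cat("BehaviouralRule:", formatRule(object), "\n")
})
setMethod("show", "EnvironmentalRule", function(object) {
  cat("EnvironmentalRule:", formatRule(object), "\n")
})

#' Construct a rule-evaluation context
#'
#' @param time,td,glc,o2,age,tld,ym scalar context variables (see
#'   \linkS4class{RuleContext}).
#' @param typeCounts named numeric vector of per-type population fractions.
#' @return a \linkS4class{RuleContext}.
#' @export
ruleContext <- function(time = 0, td = 0, glc = 1, o2 = 1, age = 0, tld = 0,
                        ym = 1, typeCounts = numeric(0)) {
  new("RuleContext", time = time, td = td, glc = glc, o2 = o2, age = age,
      tld = tld, ym = ym, typeCounts = typeCounts)
}

# Named value list for expression evaluation.
.contextValues <- function(ctx) {
  vals <- list(TIME = ctx@time, TD = ctx@td, Glc = ctx@glc, O2 = ctx@o2,
               AGE = ctx@age, TLD = ctx@tld, YM = ctx@ym)
  if (length(ctx@typeCounts)) {
    counts <- as.list(ctx@typeCounts)
    names(counts) <- paste0(".count_", names(ctx@typeCounts))
    vals <- c(vals, counts)
  }
  vals
}

#' Evaluate a behavioural rule's probability
#'
#' Evaluates the rule's probability expression on a context and clamps the
#' result into [0, 1]. Evaluation is a pure function of the context; division
#' by zero, missing variables and non-finite results are reported as errors
#' carrying the rule id.
#'
#' @param rule a \linkS4class{BehaviouralRule}.
#' @param ctx a \linkS4class{RuleContext} (or a named list of context values).
#' @return a probability in [0, 1].
#' @examples
#' r <- parseRule("dup: P -> P + P, 0.38")
#' evaluateProbability(r, ruleContext())
#' @export
evaluateProbability <- function(rule, ctx) {
  stopifnot(is(rule, "BehaviouralRule"))
  vals <- if (is(ctx, "RuleContext")) .contextValues(ctx) else as.list(ctx)
  needed <- all.vars(rule@expr)
  missing <- setdiff(needed, names(vals))
  if (length(missing))
    stop(sprintf("rule '%s': context does not supply %s", rule@ruleId,
                 paste(sub("^\\.count_", "#", missing), collapse = ", ")),
         call. = FALSE)
  p <- tryCatch(eval(rule@expr, envir = vals, enclos = baseenv()),
                error = function(e) stop(sprintf(
                  "rule '%s': evaluation error: %s", rule@ruleId,
                  conditionMessage(e)), call. = FALSE))
  if (!is.numeric(p) || length(p) != 1 || !is.finite(p))
    stop(sprintf("rule '%s': probability expression did not evaluate to a finite number",
                 rule@ruleId), call. = FALSE)
  .clamp(p)
}

#' Build the rule context for one cell
#'
#' Computes the normalised context variables for a registered cell at a given
#' iteration: TIME = iteration / total, Glc and O2 as local level over the
#' reference medium level, YM as local stiffness over the initial scaffold
#' stiffness, AGE and TLD as (iteration - birth) and (iteration - last
#' division) over the current iteration, TD as death iteration over total for
#' dead cells (0 otherwise) and per-type population fractions of the lattice
#' capacity. At iteration 0 the AGE/TLD denominators are undefined; a warning
#' is signalled and 0 is substituted.
#'
#' @param cellId integer id of a registered cell.
#' @param state a \linkS4class{ScaffoldState}.
#' @param iteration current iteration (>= 0).
#' @param totalIterations total number of iterations in the protocol.
#' @param cellTypes optional declared type names for the count variables
#'   (defaults to the types present in the registry).
#' @return a \linkS4class{RuleContext}.
#' @export
buildContext <- function(cellId, state, iteration, totalIterations,
                         cellTypes = NULL) {
  cells <- state@cells
  row <- match(cellId, cells$id)
  if (is.na(row) || !cells$present[row])
    stop(sprintf("cell %d is not registered in the scaffold state", cellId),
         call. = FALSE)
  if (iteration == 0)
    warning("AGE/TLD are undefined at iteration 0; substituting 0")
  if (is.null(cellTypes)) cellTypes <- sort(unique(cells$type))
  pos <- c(cells$x[row], cells$y[row], cells$z[row]) + 1L
  capacity <- as.numeric(state@nLayers)^3 * state@capacityPerSite
  present <- cells$present
  counts <- vapply(cellTypes, function(t) sum(present & cells$type == t),
                   numeric(1))
  dead <- !is.na(cells$death[row])
  ruleContext(
    time = if (totalIterations > 0) iteration / totalIterations else 0,
    td = if (dead && totalIterations > 0) cells$death[row] / totalIterations else 0,
    glc = state@glucose[pos[1], pos[2], pos[3]] / state@referenceGlucose,
    o2 = state@oxygen[pos[1], pos[2], pos[3]] / state@referenceOxygen,
    age = if (iteration > 0) (iteration - cells$birth[row]) / iteration else 0,
    tld = if (iteration > 0) (iteration - cells$last_division[row]) / iteration else 0,
    ym = state@youngModulus[pos[1], pos[2], pos[3]] / state@initialStiffness,
    typeCounts = counts / capacity
  )
}
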