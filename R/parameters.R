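## Parameter machinery: extraction of optimizable parameters from a
## procedure + config, assignment application (pure, version-incrementing),
## and the unit-box normalization used by every optimizer.

paramPath <- function(stepId, property) paste(stepId, property, sep = ".")

splitPath <- function(path) {
  i <- regexpr(".", path, fixed = TRUE)
  c(substr(path, 1, i - 1L), substr(path, i + 1L, nchar(path)))
}

#' Extract the parameters to be optimized
#'
#' Resolves every optimize-config entry against the procedure and returns
#' parameter specs in document order (order of the referenced steps in the
#' procedure; config order within a step) — stable across runs and
#' platforms.
#'
#' @param procedure a \code{Procedure}.
#' @param config list of entries \code{{step, property, lower, upper, unit,
#'   scale}} (see \code{\link{readOptimizeConfig}}).
#' @return list of \code{ParameterSpec}.
#' @export
extractParameters <- function(procedure, config) {
  if (length(config) == 0) return(list())
  ids <- stepIds(procedure)
  specs <- list()
  ord <- integer(0)
  for (e in config) {
    if (!e$step %in% ids)
      stop(sprintf("dangling path: no step '%s' in procedure '%s'",
                   e$step, procedure@procId), call. = FALSE)
    cur <- tryCatch(stepProperty(procedure, e$step, e$property),
                    error = function(err) NULL)
    if (is.null(cur))
      stop(sprintf("dangling path: step '%s' has no property '%s'",
                   e$step, e$property), call. = FALSE)
    if (!is(cur, "Quantity"))
      stop(sprintf("property '%s' of step '%s' is not numeric", e$property,
                   e$step), call. = FALSE)
    unit <- canonicalUnit(e$unit)
    if (unitDimension(unit) != unitDimension(cur@unit))
      stop(sprintf("bound unit mismatch for %s: '%s' vs property '%s'",
                   paramPath(e$step, e$property), unit, cur@unit),
           call. = FALSE)
    if (!(e$lower < e$upper))
      stop(sprintf("lower >= upper for %s", paramPath(e$step, e$property)),
           call. = FALSE)
    spec <- new("ParameterSpec", stepId = e$step, property = e$property,
                lower = quantity(e$lower, unit),
                upper = quantity(e$upper, unit),
                scale = e$scale, kind = "continuous")
    validObject(spec)
    v <- qIn(cur, unit)
    if (v < e$lower - 1e-12 || v > e$upper + 1e-12)
      stop(sprintf("current value %s of %s outside bounds [%s, %s]",
                   formatNumber(v), paramPath(e$step, e$property),
                   formatNumber(e$lower), formatNumber(e$upper)),
           call. = FALSE)
    specs[[length(specs) + 1L]] <- spec
    ord[length(ord) + 1L] <- match(e$step, ids)
  }
  specs[order(ord, seq_along(ord))]
}

#' Names ("step.property") of a spec list
#' @param specs list of \code{ParameterSpec}.
#' @export
specPaths <- function(specs)
  vapply(specs, function(s) paramPath(s@stepId, s@property), character(1))

#' Build a parameter assignment
#'
#' @param ... named values, names \code{"stepId.property"}; values are
#'   quantities or \code{"0.5 mL"}-style strings.
#' @return named list of \code{Quantity} with class "paramAssignment".
#' @export
paramAssignment <- function(...) {
  vals <- list(...)
  if (length(vals) == 1L && is.list(vals[[1]]) && is.null(names(vals)[1]))
    vals <- vals[[1]]
  out <- lapply(vals, function(v) {
    if (is(v, "Quantity")) return(v)
    q <- parseQuantityString(v)
    if (is.null(q)) stop("assignment values must be quantities", call. = FALSE)
    q
  })
  class(out) <- "paramAssignment"
  out
}

checkAssignment <- function(assignment, specs) {
  paths <- specPaths(specs)
  for (p in names(assignment)) {
    i <- match(p, paths)
    if (is.na(i)) stop(sprintf("unknown path '%s'", p), call. = FALSE)
    s <- specs[[i]]
    v <- qIn(assignment[[p]], s@lower@unit)
    if (v < s@lower@value - 1e-9 || v > qIn(s@upper, s@lower@unit) + 1e-9)
      stop(sprintf("value %s of '%s' out of bounds [%s, %s] %s",
                   formatNumber(v), p, formatNumber(s@lower@value),
                   formatNumber(qIn(s@upper, s@lower@unit)), s@lower@unit),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Apply a parameter assignment to a procedure
#'
#' Pure: returns a new procedure with version incremented by one; untouched
#' properties are carried over unchanged and the input procedure is not
#' modified.  An empty assignment still increments the version — every
#' executed iteration is a new version, so the campaign database maps one
#' iteration to one procedure file.
#'
#' @param procedure a \code{Procedure}.
#' @param assignment a \code{\link{paramAssignment}} (possibly empty).
#' @param specs optional list of \code{ParameterSpec}; when given, values
#'   are bounds-checked against it.
#' @return a new \code{Procedure}, version + 1.
#' @export
applyAssignment <- function(procedure, assignment = paramAssignment(),
                            specs = NULL) {
  if (!is.null(specs)) checkAssignment(assignment, specs)
  ids <- stepIds(procedure)
  for (p in names(assignment)) {
    sp <- splitPath(p)
    if (!sp[1] %in% ids)
      stop(sprintf("unknown path '%s'", p), call. = FALSE)
  }
  newSteps <- lapply(procedure@steps, applyToStep, assignment = assignment)
  procedure(procedure@procId, newSteps, version = procedure@version + 1L,
            metadata = procedure@metadata)
}

applyToStep <- function(s, assignment) {
  props <- s@properties
  for (p in names(assignment)) {
    sp <- splitPath(p)
    if (sp[1] == s@stepId) {
      old <- props[[sp[2]]]
      if (is.null(old) || !is(old, "Quantity"))
        stop(sprintf("unknown path '%s'", p), call. = FALSE)
      ## keep the property's original unit so untouched formatting survives
      props[[sp[2]]] <- convertQuantity(assignment[[p]], old@unit)
    }
  }
  new("Step", stepId = s@stepId, name = s@name, properties = props,
      children = lapply(s@children, applyToStep, assignment = assignment))
}

## ---- unit-box normalization ------------------------------------------

#' Map an assignment to the unit box and back
#'
#' Linear (or log, per spec scale) map of each parameter onto [0,1];
#' \code{denormalizeAssignment} is the exact inverse.  The log map sends
#' the geometric mean of the bounds to 0.5.
#'
#' @param assignment a \code{paramAssignment} covering every spec.
#' @param specs list of \code{ParameterSpec}.
#' @return numeric vector in [0,1]^d, named by spec paths.
#' @export
normalizeAssignment <- function(assignment, specs) {
  checkAssignment(assignment, specs)
  paths <- specPaths(specs)
  vapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    v <- qIn(assignment[[paths[i]]], s@lower@unit)
    lo <- s@lower@value; up <- qIn(s@upper, s@lower@unit)
    x <- if (s@scale == "log") (log(v) - log(lo)) / (log(up) - log(lo))
         else (v - lo) / (up - lo)
    min(1, max(0, x))
  }, numeric(1), USE.NAMES = FALSE) -> x
  names(x) <- paths
  x
}

#' @rdname normalizeAssignment
#' @param x numeric vector in [0,1]^d (spec order).
#' @export
denormalizeAssignment <- function(x, specs) {
  stopifnot(length(x) == length(specs))
  vals <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    lo <- s@lower@value; up <- qIn(s@upper, s@lower@unit)
    v <- if (s@scale == "log") exp(log(lo) + x[i] * (log(up) - log(lo)))
         else lo + x[i] * (up - lo)
    quantity(v, s@lower@unit)
  })
  names(vals) <- specPaths(specs)
  class(vals) <- "paramAssignment"
  vals
}
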