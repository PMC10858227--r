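## Operation registry ----------------------------------------------------
##
## Every step name the dialect accepts, with its required/optional
## properties and their dimensions ("text" for free-form strings).
## Unknown names are rejected at parse time.

.stepRegistry <- list(
  Add = list(required = c(reagent = "text", volume = "volume"),
             optional = c(rate = "flow")),
  Transfer = list(required = c(from = "text", to = "text", volume = "volume"),
                  optional = c(rate = "flow")),
  Stir = list(required = c(time = "time"), optional = c()),
  HeatChill = list(required = c(temp = "temperature"),
                   optional = c(time = "time")),
  Wait = list(required = c(time = "time"), optional = c()),
  Analyze = list(required = c(instrument = "text"),
                 optional = c(sample_volume = "volume")),
  DynamicAdd = list(required = c(reagent = "text", volume = "volume"),
                    optional = c(chunk_volume = "volume",
                                 temp_threshold = "temperature",
                                 hysteresis = "temperature",
                                 wait_quantum = "time", rate = "flow")),
  DynamicTransfer = list(required = c(from = "text", to = "text"),
                         optional = c(rate = "flow",
                                      k_empty = "dimensionless",
                                      max_volume = "volume")),
  DoUntil = list(required = c(sensor = "text", poll_interval = "time",
                              max_duration = "time"),
                 optional = c(smooth_width = "dimensionless",
                              grad_threshold = "dimensionless",
                              arm_threshold = "dimensionless"),
                 container = TRUE)
)

#' Registered operation names
#' @return character vector of step names the dialect accepts.
#' @export
stepRegistry <- function() names(.stepRegistry)

isContainerStep <- function(name) isTRUE(.stepRegistry[[name]]$container)

## ---- constructors -----------------------------------------------------

#' Build a procedure step
#'
#' @param id step identifier (letters, digits, \code{_}, \code{-}), unique
#'   within a procedure.
#' @param name registered operation name.
#' @param ... properties; numbers become dimensionless quantities, strings
#'   of the form \code{"0.2 mL"} become quantities, other strings stay text.
#'   \code{Quantity} objects pass through.
#' @param children list of child steps (container steps only).
#' @return a validated \code{Step}.
#' @examples
#' step("add1", "Add", reagent = "benzaldehyde", volume = "0.2 mL")
#' @export
step <- function(id, name, ..., children = list()) {
  props <- list(...)
  props <- lapply(props, function(v) {
    if (is(v, "Quantity")) return(v)
    q <- parseQuantityString(v)
    if (!is.null(q)) q else v
  })
  s <- new("Step", stepId = id, name = name, properties = props,
           children = children)
  checkStep(s)
  s
}

checkStep <- function(s) {
  if (!grepl("^[A-Za-z0-9_-]+$", s@stepId))
    stop(sprintf("invalid step id '%s'", s@stepId), call. = FALSE)
  reg <- .stepRegistry[[s@name]]
  if (is.null(reg))
    stop(sprintf("unknown step name '%s'", s@name), call. = FALSE)
  known <- c(names(reg$required), names(reg$optional))
  for (p in names(reg$required))
    if (is.null(s@properties[[p]]))
      stop(sprintf("step '%s' (%s): missing required property '%s'",
                   s@stepId, s@name, p), call. = FALSE)
  for (p in names(s@properties)) {
    dim <- c(reg$required, reg$optional)[[p]]
    v <- s@properties[[p]]
    if (is.null(dim)) next  # extra properties tolerated as annotations
    if (dim == "text") {
      if (!is.character(v))
        stop(sprintf("step '%s': property '%s' must be text", s@stepId, p),
             call. = FALSE)
      next
    }
    if (!is(v, "Quantity"))
      stop(sprintf("step '%s': property '%s' must be a quantity", s@stepId, p),
           call. = FALSE)
    if (dim != "any" && unitDimension(v@unit) != dim)
      stop(sprintf("step '%s': property '%s' has dimension %s, expected %s",
                   s@stepId, p, unitDimension(v@unit), dim), call. = FALSE)
    if (dim %in% c("time", "volume", "flow") && v@value < 0)
      stop(sprintf("step '%s': property '%s' must be >= 0", s@stepId, p),
           call. = FALSE)
  }
  if (length(s@children) > 0 && !isContainerStep(s@name))
    stop(sprintf("step '%s' (%s) cannot have children", s@stepId, s@name),
         call. = FALSE)
  if (isContainerStep(s@name) && length(s@children) == 0)
    stop(sprintf("container step '%s' needs at least one child", s@stepId),
         call. = FALSE)
  invisible(TRUE)
}

#' Build a procedure
#'
#' @param id procedure identifier.
#' @param steps list of \code{Step}.
#' @param version non-negative integer (0 for an initial procedure).
#' @param metadata list: title, reagents (list of name/role), hardware.
#' @return a validated \code{Procedure}.
#' @export
procedure <- function(id, steps, version = 0L, metadata = list()) {
  p <- new("Procedure", procId = id, version = as.integer(version),
           metadata = metadata, steps = steps)
  checkProcedure(p)
  p
}

checkProcedure <- function(p) {
  if (p@version < 0L) stop("version must be >= 0", call. = FALSE)
  ids <- vapply(flattenSteps(p@steps), function(s) s@stepId, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate step id '%s'", ids[duplicated(ids)][1]),
         call. = FALSE)
  for (s in flattenSteps(p@steps)) checkStep(s)
  invisible(TRUE)
}

## depth-first flattening of the step tree, document order
flattenSteps <- function(steps) {
  out <- list()
  for (s in steps) {
    out[[length(out) + 1L]] <- s
    if (length(s@children)) out <- c(out, flattenSteps(s@children))
  }
  out
}

## ---- accessors --------------------------------------------------------

#' Procedure accessors
#' @param object a \code{Procedure}.
#' @name procedureAccessors
NULL

#' @rdname procedureAccessors
setMethod("procId", "Procedure", function(object) object@procId)
#' @rdname procedureAccessors
setMethod("procVersion", "Procedure", function(object) object@version)
#' @rdname procedureAccessors
setMethod("steps", "Procedure", function(object) object@steps)
#' @rdname procedureAccessors
setMethod("stepIds", "Procedure", function(object)
  vapply(flattenSteps(object@steps), function(s) s@stepId, character(1)))

#' Find a step by id (searches the whole tree)
#' @param procedure a \code{Procedure}.
#' @param id step id.
#' @return the \code{Step}, or NULL.
#' @export
findStep <- function(procedure, id) {
  for (s in flattenSteps(procedure@steps)) if (s@stepId == id) return(s)
  NULL
}

#' Get a step property as a Quantity
#' @param procedure a \code{Procedure}.
#' @param stepId,property the path.
#' @export
stepProperty <- function(procedure, stepId, property) {
  s <- findStep(procedure, stepId)
  if (is.null(s)) stop(sprintf("no step '%s'", stepId), call. = FALSE)
  v <- s@properties[[property]]
  if (is.null(v))
    stop(sprintf("step '%s' has no property '%s'", stepId, property),
         call. = FALSE)
  v
}

setMethod("show", "Step", function(object) {
  props <- vapply(names(object@properties), function(p) {
    v <- object@properties[[p]]
    paste0(p, "=", if (is(v, "Quantity")) formatQuantity(v) else v)
  }, character(1))
  cat(sprintf("%s <%s> %s\n", object@name, object@stepId,
              paste(props, collapse = " ")))
  for (ch in object@children) { cat("  "); show(ch) }
})

setMethod("show", "Procedure", function(object) {
  cat(sprintf("Procedure '%s' v%d with %d top-level step(s)\n",
              object@procId, object@version, length(object@steps)))
  for (s in object@steps) show(s)
})
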