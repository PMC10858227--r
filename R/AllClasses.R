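#' @import methods
NULL

## ---- units ------------------------------------------------------------

## Closed unit enum with exact conversion factors to a per-dimension base
## unit (time base = s; everything else is its own base).  No general
## dimensional analysis: comparing across dimensions is an error.
.unitTable <- data.frame(
  unit      = c("mL", "mmol", "min", "h", "s", "degC", "mL/min", "mol/L",
                "dimensionless"),
  dimension = c("volume", "amount", "time", "time", "time", "temperature",
                "flow", "concentration", "dimensionless"),
  factor    = c(1, 1, 60, 3600, 1, 1, 1, 1, 1),
  stringsAsFactors = FALSE
)

.unitAliases <- c("°C" = "degC", "C" = "degC", "ml" = "mL",
                  "sec" = "s", "hr" = "h")

#' Quantity: a unit-carrying scalar
#'
#' A scalar physical value tagged with one of a closed set of units
#' (\code{mL}, \code{mmol}, \code{min}, \code{h}, \code{s}, \code{degC},
#' \code{mL/min}, \code{mol/L}, \code{dimensionless}).  Conversions are
#' exact within a dimension (h/min/s); quantities of different dimensions
#' never compare.
#'
#' @slot value numeric scalar.
#' @slot unit unit name, one of the closed enum above.
#' @export
setClass("Quantity", representation(value = "numeric", unit = "character"))

setValidity("Quantity", function(object) {
  if (length(object@value) != 1L || !is.finite(object@value))
    return("value must be a finite scalar")
  if (!(object@unit %in% .unitTable$unit))
    return(sprintf("unknown unit '%s'", object@unit))
  TRUE
})

## ---- procedure model --------------------------------------------------

#' Step: one chemical unit operation
#'
#' A node of a procedure tree.  \code{name} must come from the operation
#' registry (Add, Transfer, Stir, HeatChill, Wait, Analyze, DynamicAdd,
#' DynamicTransfer, DoUntil); \code{properties} maps property names to
#' \code{Quantity} or character values; \code{children} is non-empty only
#' for container steps (DoUntil).
#'
#' @slot stepId character identifier, unique within a procedure.
#' @slot name registered operation name.
#' @slot properties named list of Quantity or character.
#' @slot children list of child \code{Step}s.
#' @export
setClass("Step", representation(stepId = "character", name = "character",
                                properties = "list", children = "list"))

#' Procedure: a versioned tree of chemical unit operations
#'
#' @slot procId character identifier.
#' @slot version non-negative integer; incremented by
#'   \code{\link{applyAssignment}} on every optimization iteration.
#' @slot metadata list (title, reagents with roles, hardware names).
#' @slot steps ordered list of \code{Step}.
#' @export
setClass("Procedure", representation(procId = "character", version = "integer",
                                     metadata = "list", steps = "list"))

#' ParameterSpec: one optimizable procedure property with bounds
#'
#' @slot stepId,property the (step, property) path being optimized.
#' @slot lower,upper closed bounds, same unit.
#' @slot scale "linear" or "log" (log requires lower > 0).
#' @slot kind "continuous" or "discrete".
#' @export
setClass("ParameterSpec", representation(stepId = "character",
                                         property = "character",
                                         lower = "Quantity", upper = "Quantity",
                                         scale = "character", kind = "character"))

setValidity("ParameterSpec", function(object) {
  if (unitDimension(object@lower@unit) != unitDimension(object@upper@unit))
    return("lower and upper must share a dimension")
  lo <- object@lower@value
  up <- convertQuantity(object@upper, object@lower@unit)@value
  if (!(lo < up)) return("lower must be < upper")
  if (!object@scale %in% c("linear", "log")) return("scale must be linear|log")
  if (object@scale == "log" && lo <= 0) return("log scale requires lower > 0")
  if (!object@kind %in% c("continuous", "discrete"))
    return("kind must be continuous|discrete")
  TRUE
})

## ---- analytical data --------------------------------------------------

#' FID: a time-domain NMR signal
#'
#' @slot samples complex vector of time-domain samples.
#' @slot dwell dwell time between samples, seconds.
#' @slot frequencyMHz spectrometer frequency used for the Hz-to-ppm axis.
#' @export
setClass("FID", representation(samples = "complex", dwell = "numeric",
                               frequencyMHz = "numeric"))

setValidity("FID", function(object) {
  if (length(object@dwell) != 1L || object@dwell <= 0)
    return("dwell must be a positive scalar")
  if (length(object@frequencyMHz) != 1L || object@frequencyMHz <= 0)
    return("frequencyMHz must be a positive scalar")
  if (length(object@samples) < 2L) return("need at least 2 samples")
  TRUE
})

#' Spectrum: an (axis, intensity) analytical series
#'
#' Axis is stored strictly ascending; a descending rendering (ppm
#' convention) is presentation-layer only.
#'
#' @slot axis strictly increasing numeric axis.
#' @slot intensity numeric, same length as axis.
#' @slot kind axis kind: "ppm", "minutes" or "cm-1".
#' @slot metadata free-form list.
#' @export
setClass("Spectrum", representation(axis = "numeric", intensity = "numeric",
                                    kind = "character", metadata = "list"))

setValidity("Spectrum", function(object) {
  if (length(object@axis) != length(object@intensity))
    return("axis and intensity lengths differ")
  if (length(object@axis) >= 2L && any(diff(object@axis) <= 0))
    return("axis must be strictly increasing")
  if (!object@kind %in% c("ppm", "minutes", "cm-1"))
    return("kind must be ppm|minutes|cm-1")
  TRUE
})

## ---- simulated laboratory --------------------------------------------

#' ReactionSurface: a latent reaction response surface
#'
#' Latent per-product yields are sums of anisotropic Gaussian bumps on the
#' unit box, rescaled to the campaign's parameter bounds; yields are in
#' [0,1] and evaluation is deterministic given (assignment, seed).
#'
#' @slot name surface name (ugi, vanleusen, epoxidation, discovery).
#' @slot specs list of \code{ParameterSpec} giving the bounds.
#' @slot products named list of bump sets (centers, widths, amps in unit box).
#' @slot species named list describing starting materials and the internal
#'   standard (initial relative concentrations, which product consumes what).
#' @slot noiseSd observation noise on the latent yield.
#' @slot optimum list(assignment=, value=, product=): documented optimum.
#' @slot seed integer build seed.
#' @export
setClass("ReactionSurface", representation(name = "character", specs = "list",
                                           products = "list", species = "list",
                                           noiseSd = "numeric",
                                           optimum = "list", seed = "integer"))

#' Backend: the execution backend contract
#'
#' A backend executes primitive steps, serves sensor readings, and owns the
#' simulation clock.  \code{readSensor} is side-effect free; \code{now} is
#' non-decreasing.
#'
#' @export
setClass("Backend", representation("VIRTUAL", state = "environment"))

#' SimLabBackend: simulated laboratory backend
#'
#' Integrates an exotherm/colour/liquid sensor model with a fixed-step
#' (1 s) explicit Euler scheme and records full sensor traces.
#' @export
setClass("SimLabBackend", contains = "Backend")

#' ScriptedBackend: backend with scripted sensor sequences
#'
#' Serves pre-recorded sensor sequences; used for deterministic unit-level
#' exercises of dynamic steps (e.g. liquid-sensor transfer semantics).
#' @export
setClass("ScriptedBackend", contains = "Backend")
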