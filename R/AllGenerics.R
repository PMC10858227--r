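## Generics for the backend contract and small accessors.

#' Execute one primitive step on a backend
#'
#' @param backend a \code{Backend}.
#' @param step a primitive \code{Step}.
#' @param ... backend-specific options.
#' @return invisibly, a list describing the completion (at least
#'   \code{duration} in seconds).
#' @export
setGeneric("executePrimitive", function(backend, step, ...)
  standardGeneric("executePrimitive"))

#' Read one sensor (side-effect free)
#'
#' @param backend a \code{Backend}.
#' @param kind one of "temperature", "rgbc", "liquid", "environment".
#' @return list(kind=, time=, value=) — a sensor reading at the current
#'   simulation time.
#' @export
setGeneric("readSensor", function(backend, kind) standardGeneric("readSensor"))

#' Current simulation time in seconds
#' @param backend a \code{Backend}.
#' @export
setGeneric("backendNow", function(backend) standardGeneric("backendNow"))

#' Advance the simulation clock
#' @param backend a \code{Backend}.
#' @param dt seconds (non-negative).
#' @export
setGeneric("advanceTime", function(backend, dt) standardGeneric("advanceTime"))

#' Sensor trace recorded so far
#'
#' @param backend a \code{Backend}.
#' @param kind sensor kind.
#' @param from,to time window in seconds (defaults: full trace).
#' @return data.frame(time=, value=).
#' @export
setGeneric("sensorTrace", function(backend, kind, from = 0, to = Inf)
  standardGeneric("sensorTrace"))

#' @rdname procedureAccessors
#' @export
setGeneric("procId", function(object) standardGeneric("procId"))
#' @rdname procedureAccessors
#' @export
setGeneric("procVersion", function(object) standardGeneric("procVersion"))
#' @rdname procedureAccessors
#' @export
setGeneric("steps", function(object) standardGeneric("steps"))
#' @rdname procedureAccessors
#' @export
setGeneric("stepIds", function(object) standardGeneric("stepIds"))

#' @rdname spectrumAccessors
#' @export
setGeneric("specAxis", function(object) standardGeneric("specAxis"))
#' @rdname spectrumAccessors
#' @export
setGeneric("specIntensity", function(object) standardGeneric("specIntensity"))
#' @rdname spectrumAccessors
#' @export
setGeneric("axisKind", function(object) standardGeneric("axisKind"))
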