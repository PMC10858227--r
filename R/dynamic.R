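## Interpreter for procedures, including the feedback-controlled dynamic
## steps.  Each dynamic step exposes the three-method lifecycle
## (onStart / onContinue / onFinish), each returning a list of steps to be
## executed; the interpreter loops onContinue until it returns an empty
## list, then runs onFinish exactly once.  A max-iterations guard bounds
## non-terminating predicates.

.dynamicSteps <- c("DynamicAdd", "DynamicTransfer", "DoUntil")

#' Execute a procedure against a backend
#'
#' Static steps run in document order; dynamic steps expand at run time via
#' their lifecycle, with inserted steps logged as \code{inserted} events.
#' Identical (procedure, backend state, seed, config) give identical logs.
#'
#' @param procedure a \code{Procedure}.
#' @param backend a \code{Backend}.
#' @param seed integer seed (the simulated backend is deterministic; the
#'   seed is recorded for provenance and future stochastic backends).
#' @param config list of guards: \code{maxIterations} per dynamic step
#'   (default 1e4), \code{maxWaitTime} thermal-wait budget in s (default
#'   3600), \code{primingBudget} increments (default 10).
#' @return an execution log: data.frame(t, step, event, payload) where
#'   event is start/finish/inserted/sensor and payload is a list column.
#' @export
runProcedure <- function(procedure, backend, seed = 1L, config = list()) {
  checkProcedure(procedure)
  cfg <- execConfig(config)
  log <- newLog()
  for (s in procedure@steps) execStep(s, backend, log, cfg)
  logFrame(log)
}

execConfig <- function(config) {
  utils::modifyList(list(maxIterations = 10000L, maxWaitTime = 3600,
                         primingBudget = 10L), config)
}

newLog <- function() {
  lg <- new.env(parent = emptyenv())
  lg$rec <- vector("list", 64L)
  lg$n <- 0L
  lg
}

logEvent <- function(lg, t, step, event, payload = NULL) {
  i <- lg$n + 1L
  if (i > length(lg$rec)) lg$rec <- c(lg$rec, vector("list", length(lg$rec)))
  lg$rec[[i]] <- list(t = t, step = step, event = event, payload = payload)
  lg$n <- i
}

logFrame <- function(lg) {
  rec <- lg$rec[seq_len(lg$n)]
  data.frame(t = vapply(rec, `[[`, numeric(1), "t"),
             step = vapply(rec, `[[`, character(1), "step"),
             event = vapply(rec, `[[`, character(1), "event"),
             payload = I(lapply(rec, `[[`, "payload")))
}

execStep <- function(s, backend, lg, cfg, inserted = FALSE) {
  logEvent(lg, backendNow(backend), s@stepId,
           if (inserted) "inserted" else "start")
  if (s@name %in% .dynamicSteps) {
    runDynamic(s, backend, lg, cfg)
  } else {
    res <- withCallingHandlers(
      executePrimitive(backend, s),
      error = function(e) stop(errorCondition(
        sprintf("backend fault in step '%s': %s", s@stepId,
                conditionMessage(e)),
        class = c("backendFault", "chemloopError"),
        log = logFrame(lg))))
    res
  }
  logEvent(lg, backendNow(backend), s@stepId, "finish")
  invisible()
}

runDynamic <- function(s, backend, lg, cfg) {
  lc <- dynamicLifecycle(s, backend, cfg, lg)
  for (child in lc$onStart()) execStep(child, backend, lg, cfg, inserted = TRUE)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > cfg$maxIterations)
      stop(errorCondition(
        sprintf("dynamic step '%s' exceeded max-iterations guard (%d)",
                s@stepId, cfg$maxIterations),
        class = c("maxIterationsError", "chemloopError"),
        log = logFrame(lg)))
    out <- lc$onContinue()
    if (length(out) == 0) break
    for (child in out) execStep(child, backend, lg, cfg, inserted = TRUE)
  }
  for (child in lc$onFinish()) execStep(child, backend, lg, cfg,
                                        inserted = TRUE)
  invisible()
}

#' Three-method lifecycle of a dynamic step
#'
#' Returns the onStart/onContinue/onFinish closures for a dynamic step,
#' initialized from the step's properties.  Exposed so the expansion
#' behaviour can be driven and inspected directly; \code{runProcedure}
#' uses exactly this contract.
#'
#' @param s a dynamic \code{Step} (DynamicAdd, DynamicTransfer, DoUntil).
#' @param backend a \code{Backend}.
#' @param config execution guards (see \code{\link{runProcedure}}).
#' @param lg internal log handle (optional).
#' @return list(onStart=, onContinue=, onFinish=) closures; each returns a
#'   list of steps to execute.
#' @export
dynamicLifecycle <- function(s, backend, config = list(), lg = NULL) {
  cfg <- execConfig(config)
  if (is.null(lg)) lg <- newLog()
  switch(s@name,
         DynamicAdd = dynamicAddLifecycle(s, backend, cfg, lg),
         DynamicTransfer = dynamicTransferLifecycle(s, backend, cfg, lg),
         DoUntil = doUntilLifecycle(s, backend, cfg, lg),
         stop(sprintf("'%s' is not a dynamic step", s@name), call. = FALSE))
}

## ---- DynamicAdd: temperature-gated chunked addition -------------------
##
## The reagent is added in chunks at a controlled rate.  Before each chunk
## the internal temperature is polled; while it lacks one hysteresis band
## of headroom below the threshold, Wait(wait_quantum) steps are inserted.
## A chunk therefore starts only at T <= threshold - hysteresis, so the
## maximum never exceeds the threshold as long as a chunk's adiabatic rise
## stays within the band.  The chunk volumes sum to the total exactly (the
## last chunk is truncated).

dynamicAddLifecycle <- function(s, backend, cfg, lg) {
  p <- s@properties
  total <- qIn(p$volume, "mL")
  chunk <- if (!is.null(p$chunk_volume)) qIn(p$chunk_volume, "mL") else 1
  if (chunk > total + 1e-12) chunk <- total
  threshold <- if (!is.null(p$temp_threshold)) qIn(p$temp_threshold, "degC")
               else Inf
  hyst <- if (!is.null(p$hysteresis)) qIn(p$hysteresis, "degC") else 2
  quantum <- if (!is.null(p$wait_quantum)) qIn(p$wait_quantum, "s") else 30
  rate <- if (!is.null(p$rate)) p$rate else quantity(3, "mL/min")
  if (is.finite(threshold) &&
      !"temperature" %in% backendSensors(backend))
    stop(errorCondition(
      sprintf("step '%s': sensor unavailable: 'temperature'", s@stepId),
      class = c("sensorUnavailableError", "chemloopError")))
  st <- new.env(parent = emptyenv())
  st$remaining <- total
  st$i <- 0L
  st$waited <- 0
  list(
    onStart = function() list(),
    onContinue = function() {
      if (st$remaining <= 1e-12) return(list())
      if (is.finite(threshold)) {
        r <- readSensor(backend, "temperature")
        logEvent(lg, r$time, s@stepId, "sensor",
                 list(kind = "temperature", value = r$value))
        if (r$value > threshold - hyst) {
          if (st$waited + quantum > cfg$maxWaitTime)
            stop(errorCondition(
              sprintf(paste0("thermal runaway in step '%s': temperature ",
                             "%.1f degC still above %.1f degC after %.0f s ",
                             "wait budget"),
                     s@stepId, r$value, threshold - hyst, st$waited),
              class = c("thermalRunawayError", "chemloopError"),
              log = logFrame(lg)))
          st$waited <- st$waited + quantum
          return(list(step(sprintf("%s-wait%03d", s@stepId,
                                   as.integer(st$waited / quantum)),
                           "Wait", time = quantity(quantum, "s"))))
        }
        st$waited <- 0
      }
      vol <- min(chunk, st$remaining)
      st$remaining <- st$remaining - vol
      st$i <- st$i + 1L
      list(step(sprintf("%s-chunk%03d", s@stepId, st$i), "Add",
                reagent = p$reagent, volume = quantity(vol, "mL"),
                rate = rate))
    },
    onFinish = function() list())
}

## ---- DynamicTransfer: liquid-sensor-terminated transfer ---------------

dynamicTransferLifecycle <- function(s, backend, cfg, lg) {
  p <- s@properties
  kEmpty <- if (!is.null(p$k_empty)) as.integer(qValue(p$k_empty)) else 3L
  stopifnot(kEmpty >= 1L)
  rate <- if (!is.null(p$rate)) qIn(p$rate, "mL/min") / 60 else 0.5
  if (!"liquid" %in% backendSensors(backend))
    stop(errorCondition(
      sprintf("step '%s': sensor unavailable: 'liquid'", s@stepId),
      class = c("sensorUnavailableError", "chemloopError")))
  st <- new.env(parent = emptyenv())
  st$reads <- 0L
  st$zeros <- 0L
  st$filled <- 0L
  st$done <- FALSE
  st$primed <- FALSE
  st$pendingRead <- FALSE
  ## each onContinue call first consumes the line-sensor reading taken
  ## after the previous pump increment, then emits the next increment
  list(
    onStart = function() list(),
    onContinue = function() {
      if (st$done) return(list())
      if (st$pendingRead) {
        st$pendingRead <- FALSE
        r <- readSensor(backend, "liquid")
        st$reads <- st$reads + 1L
        logEvent(lg, r$time, s@stepId, "sensor",
                 list(kind = "liquid", value = r$value))
        if (r$value >= 0.5) {
          st$primed <- TRUE
          st$filled <- st$filled + 1L
          st$zeros <- 0L
        } else {
          st$zeros <- st$zeros + 1L
          if (!st$primed && st$reads >= cfg$primingBudget)
            stop(errorCondition(
              sprintf("priming failure in step '%s': no liquid within %d increments",
                      s@stepId, cfg$primingBudget),
              class = c("primingFailureError", "chemloopError"),
              log = logFrame(lg)))
          if (st$primed && st$zeros >= kEmpty) st$done <- TRUE
        }
        if (st$done) return(list())
      }
      st$pendingRead <- TRUE
      list(step(sprintf("%s-inc%04d", s@stepId, st$reads + 1L), "Transfer",
                from = s@properties$from, to = s@properties$to,
                volume = quantity(rate * 1, "mL"),
                rate = quantity(rate * 60, "mL/min")))
    },
    onFinish = function() {
      logEvent(lg, backendNow(backend), s@stepId, "sensor",
               list(kind = "transfer_summary", reads = st$reads,
                    filled = st$filled,
                    volume_mL = st$filled * rate * 1))
      list()
    })
}

#' Total volume a DynamicTransfer moved, from its execution log
#' @param log an execution log.
#' @param stepId the DynamicTransfer step id.
#' @return list(reads=, filled=, volume_mL=).
#' @export
transferSummary <- function(log, stepId) {
  rows <- which(log$step == stepId & log$event == "sensor")
  for (i in rev(rows)) {
    pl <- log$payload[[i]]
    if (identical(pl$kind, "transfer_summary")) return(pl)
  }
  NULL
}

## ---- DoUntil: monitored repetition until an endpoint ------------------

doUntilLifecycle <- function(s, backend, cfg, lg) {
  p <- s@properties
  sensor <- p$sensor
  poll <- qIn(p$poll_interval, "s")
  maxDur <- qIn(p$max_duration, "s")
  stopifnot(maxDur > 0)
  smoothWidth <- if (!is.null(p$smooth_width)) qValue(p$smooth_width) else 5
  gradThr <- if (!is.null(p$grad_threshold)) qValue(p$grad_threshold)
             else 1e-4
  armThr <- if (!is.null(p$arm_threshold)) qValue(p$arm_threshold)
            else 10 * gradThr
  if (!sensor %in% backendSensors(backend))
    stop(errorCondition(
      sprintf("step '%s': sensor unavailable: '%s'", s@stepId, sensor),
      class = c("sensorUnavailableError", "chemloopError")))
  st <- new.env(parent = emptyenv())
  st$t0 <- backendNow(backend)
  st$passes <- 0L
  st$stopped <- NULL
  list(
    onStart = function() list(),
    onContinue = function() {
      if (!is.null(st$stopped)) return(list())
      elapsed <- backendNow(backend) - st$t0
      if (st$passes > 0L) {
        if (elapsed >= maxDur - 1e-9) {
          st$stopped <- "max-duration"
          logEvent(lg, backendNow(backend), s@stepId, "sensor",
                   list(kind = "dountil_stop", reason = "max-duration",
                        passes = st$passes))
          return(list())
        }
        tr <- sensorTrace(backend, sensor, from = st$t0,
                          to = backendNow(backend))
        tr <- pollSample(tr, poll)
        fired <- nrow(tr) >= smoothWidth + 1 &&
          colourEndpointPredicate(tr, smoothWidth = smoothWidth,
                                  gradThreshold = gradThr,
                                  armThreshold = armThr)
        if (fired) {
          st$stopped <- "predicate"
          logEvent(lg, backendNow(backend), s@stepId, "sensor",
                   list(kind = "dountil_stop", reason = "predicate",
                        passes = st$passes))
          return(list())
        }
      }
      st$passes <- st$passes + 1L
      lapply(s@children, reId, suffix = sprintf("p%03d", st$passes))
    },
    onFinish = function() list())
}

## children re-run each pass; re-id them so log rows stay unambiguous
reId <- function(s, suffix) {
  new("Step", stepId = paste(s@stepId, suffix, sep = "-"), name = s@name,
      properties = s@properties,
      children = lapply(s@children, reId, suffix = suffix))
}

pollSample <- function(trace, poll) {
  if (nrow(trace) == 0) return(trace)
  keep <- !duplicated(floor((trace$time - trace$time[1]) / poll))
  trace[keep, , drop = FALSE]
}

#' Outcome recorded by a DoUntil step
#' @param log an execution log.
#' @param stepId the DoUntil step id.
#' @return list(reason=, passes=) or NULL.
#' @export
doUntilOutcome <- function(log, stepId) {
  rows <- which(log$step == stepId & log$event == "sensor")
  for (i in rev(rows)) {
    pl <- log$payload[[i]]
    if (identical(pl$kind, "dountil_stop")) return(pl)
  }
  NULL
}

## ---- colour-gradient endpoint predicate -------------------------------

#' Rate-of-change endpoint detection on a sensor trace
#'
#' Fires when the smoothed per-second gradient magnitude has previously
#' exceeded \code{armThreshold} within the window (the "armed" state: a
#' change was actually observed) and has now fallen below
#' \code{gradThreshold}.  Absolute signal levels are deliberately not used:
#' they drift with ambient conditions, while the rate of colour change
#' reliably marks the end of the process.
#'
#' @param trace data.frame(time, value), ordered in time.
#' @param smoothWidth centered moving-average width (readings); the window
#'   must hold at least this many readings.
#' @param gradThreshold fire when smoothed |gradient| drops below this.
#' @param armThreshold arm when smoothed |gradient| exceeds this.
#' @return TRUE when armed and currently quiescent.
#' @export
colourEndpointPredicate <- function(trace, smoothWidth = 5,
                                    gradThreshold = 1e-4,
                                    armThreshold = 10 * gradThreshold) {
  if (nrow(trace) < smoothWidth + 1)
    stop("window too short for the requested smoothing width", call. = FALSE)
  g <- diff(trace$value) / diff(trace$time)
  gs <- movingAverage(g, smoothWidth)
  armedAt <- which(abs(gs) > armThreshold)
  if (length(armedAt) == 0) return(FALSE)
  abs(gs[length(gs)]) < gradThreshold && armedAt[1] < length(gs)
}

movingAverage <- function(x, width) {
  if (width <= 1 || length(x) < width) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
  ## centered filter leaves NA ends; fall back to the raw values there
  idx <- is.na(y)
  y[idx] <- x[idx]
  y
}

## ---- log persistence --------------------------------------------------

#' Write / read an execution log as JSON Lines
#'
#' One record per event, schema \code{{t, step, event, payload}}.
#' @param log an execution log data.frame.
#' @param path output file.
#' @export
writeExecutionLog <- function(log, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    rec <- list(t = log$t[i], step = log$step[i], event = log$event[i],
                payload = log$payload[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"), con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname writeExecutionLog
#' @export
readExecutionLog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- lapply(lines, jsonlite::fromJSON)
  data.frame(t = vapply(rec, `[[`, numeric(1), "t"),
             step = vapply(rec, `[[`, character(1), "step"),
             event = vapply(rec, `[[`, character(1), "event"),
             payload = I(lapply(rec, function(r) r$payload)))
}

#' Maximum temperature recorded in an execution log or backend trace
#' @param backend a backend whose trace to inspect.
#' @export
maxLoggedTemperature <- function(backend)
  max(sensorTrace(backend, "temperature")$value)
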