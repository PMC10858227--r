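## Simulated laboratory backend.
##
## Physics: a single well-mixed vessel.  Temperature follows
##   dT/dt = -k (T - T_set) + q * (addition rate in mL/s)
## integrated by fixed-step explicit Euler at dt = 1 s.  The colour signal
## gains an impulse per mL of chromophore ("iodine"-role reagents) and
## decays first-order with time constant tau.  The liquid sensor is binary:
## 1 while a filled line is being pumped, 0 otherwise.

#' Exotherm / sensor scenario for the simulated laboratory
#'
#' @param ambient ambient and initial temperature, degC.
#' @param coolingK first-order cooling constant, 1/s.
#' @param heatPerML temperature impulse per mL of reagent added, degC/mL.
#' @param tau colour (chromophore consumption) time constant, s.
#' @param colourPerML colour impulse per mL of chromophore.
#' @param setpoint heater setpoint, degC (defaults to ambient = heater off).
#' @param plainRate pump rate of plain (ungated) Add steps, mL/s.
#' @param safeRange backend-declared safe temperature range, degC.
#' @return scenario list consumed by \code{\link{simLabBackend}}.
#' @export
exothermScenario <- function(ambient = 20, coolingK = 0.01, heatPerML = 7,
                             tau = 300, colourPerML = 1.0,
                             setpoint = ambient, plainRate = 2,
                             safeRange = c(-20, 250)) {
  stopifnot(coolingK > 0, tau > 0, plainRate > 0)
  list(ambient = ambient, coolingK = coolingK, heatPerML = heatPerML,
       tau = tau, colourPerML = colourPerML, setpoint = setpoint,
       plainRate = plainRate, safeRange = safeRange)
}

#' Create a simulated laboratory backend
#'
#' @param scenario an \code{\link{exothermScenario}}.
#' @param sources named numeric vector of available source volumes (mL) for
#'   transfers; the liquid sensor reads 0 once a pumped source is empty.
#' @param seed integer; reserved for stochastic sensor models (the default
#'   scenario is deterministic).
#' @return a \code{SimLabBackend}.
#' @export
simLabBackend <- function(scenario = exothermScenario(),
                          sources = c(flask = 25), seed = 1L) {
  st <- new.env(parent = emptyenv())
  st$t <- 0
  st$temp <- scenario$ambient
  st$setpoint <- scenario$setpoint
  st$colour <- 0
  st$liquid <- 0
  st$scenario <- scenario
  st$sources <- sources
  st$seed <- as.integer(seed)
  st$n <- 0L
  st$trTime <- numeric(0)
  st$trTemp <- numeric(0)
  st$trColour <- numeric(0)
  st$trLiquid <- numeric(0)
  st$sensors <- c("temperature", "rgbc", "liquid", "environment")
  recordTrace(st)
  new("SimLabBackend", state = st)
}

## trace storage grows by doubling; st$n is the live length
appendTrace <- function(st, times, temps, cols, liqs) {
  m <- length(times)
  need <- st$n + m
  if (need > length(st$trTime)) {
    newCap <- max(need, 2L * length(st$trTime), 256L)
    length(st$trTime) <- newCap
    length(st$trTemp) <- newCap
    length(st$trColour) <- newCap
    length(st$trLiquid) <- newCap
  }
  idx <- (st$n + 1L):need
  st$trTime[idx] <- times
  st$trTemp[idx] <- temps
  st$trColour[idx] <- cols
  st$trLiquid[idx] <- liqs
  st$n <- need
}

recordTrace <- function(st) appendTrace(st, st$t, st$temp, st$colour,
                                        st$liquid)

## one Euler step of `dt` seconds with given addition/colour rates
eulerStep <- function(st, dt, addRate = 0, colourRate = 0, liquid = 0) {
  sc <- st$scenario
  st$temp <- st$temp + dt * (-sc$coolingK * (st$temp - st$setpoint) +
                             sc$heatPerML * addRate)
  st$colour <- st$colour + dt * (-st$colour / sc$tau + colourRate)
  st$liquid <- liquid
  st$t <- st$t + dt
  recordTrace(st)
}

## integrate `duration` seconds in 1 s Euler steps (plus fractional
## remainder).  Passive segments (no addition) use the closed form of the
## same discrete recurrence, T_n = set + (T_0 - set) (1 - k)^n, evaluated
## at up to 600 sample times, so hour-long stirring steps stay cheap while
## remaining bit-identical to the per-second Euler sequence they sample.
integrateFor <- function(st, duration, addRate = 0, colourRate = 0,
                         liquid = 0) {
  if (duration <= 0) return(invisible())
  full <- floor(duration)
  if (full > 0) {
    if (addRate == 0 && colourRate == 0 && liquid == 0) {
      sc <- st$scenario
      npts <- min(full, 600)
      ts <- unique(ceiling(seq_len(npts) * (full / npts)))
      temps <- st$setpoint + (st$temp - st$setpoint) * (1 - sc$coolingK)^ts
      cols <- st$colour * (1 - 1 / sc$tau)^ts
      appendTrace(st, st$t + ts, temps, cols, numeric(length(ts)))
      st$temp <- temps[length(temps)]
      st$colour <- cols[length(cols)]
      st$liquid <- 0
      st$t <- st$t + full
    } else {
      for (i in seq_len(full)) eulerStep(st, 1, addRate, colourRate, liquid)
    }
  }
  rem <- duration - full
  if (rem > 1e-9) eulerStep(st, rem, addRate, colourRate, liquid)
  invisible()
}

setMethod("backendNow", "Backend", function(backend) backend@state$t)

setMethod("advanceTime", "SimLabBackend", function(backend, dt) {
  stopifnot(dt >= 0)
  integrateFor(backend@state, dt)
  invisible(backend)
})

setMethod("readSensor", "SimLabBackend", function(backend, kind) {
  st <- backend@state
  if (!kind %in% st$sensors)
    stop(sprintf("sensor unavailable: '%s'", kind), call. = FALSE)
  value <- switch(kind,
    temperature = st$temp,
    rgbc = st$colour,
    liquid = st$liquid,
    environment = st$scenario$ambient)
  list(kind = kind, time = st$t, value = value)
})

setMethod("sensorTrace", "SimLabBackend",
          function(backend, kind, from = 0, to = Inf) {
  st <- backend@state
  live <- seq_len(st$n)
  v <- switch(kind, temperature = st$trTemp, rgbc = st$trColour,
              liquid = st$trLiquid,
              stop(sprintf("sensor unavailable: '%s'", kind), call. = FALSE))
  tm <- st$trTime[live]
  v <- v[live]
  keep <- tm >= from & tm <= to
  data.frame(time = tm[keep], value = v[keep])
})

setMethod("executePrimitive", "SimLabBackend", function(backend, step, ...) {
  st <- backend@state
  sc <- st$scenario
  name <- step@name
  props <- step@properties
  dur <- 0
  if (name == "Add") {
    vol <- qIn(props$volume, "mL")
    rate <- if (!is.null(props$rate)) qIn(props$rate, "mL/min") / 60
            else sc$plainRate
    dur <- vol / rate
    chrom <- isChromophore(step)
    integrateFor(st, dur, addRate = rate,
                 colourRate = if (chrom) sc$colourPerML * rate else 0,
                 liquid = 1)
  } else if (name %in% c("Stir", "Wait")) {
    dur <- qIn(props$time, "s")
    integrateFor(st, dur)
  } else if (name == "HeatChill") {
    target <- qIn(props$temp, "degC")
    if (target < sc$safeRange[1] || target > sc$safeRange[2])
      stop(sprintf("setpoint %g degC outside backend safe range [%g, %g]",
                   target, sc$safeRange[1], sc$safeRange[2]), call. = FALSE)
    st$setpoint <- target
    dur <- if (!is.null(props$time)) qIn(props$time, "s") else 0
    integrateFor(st, dur)
  } else if (name == "Transfer") {
    vol <- qIn(props$volume, "mL")
    rate <- if (!is.null(props$rate)) qIn(props$rate, "mL/min") / 60 else 0.5
    src <- props$from
    dur <- vol / rate
    secs <- ceiling(dur)
    tracked <- src %in% names(st$sources)
    for (i in seq_len(secs)) {
      pump <- min(rate, vol - (i - 1) * rate)
      avail <- if (tracked) st$sources[[src]] else Inf
      if (tracked) st$sources[[src]] <- max(0, avail - pump)
      eulerStep(st, min(1, dur - (i - 1)),
                liquid = as.numeric(avail > 1e-12))
    }
  } else if (name == "Analyze") {
    dur <- 10
    integrateFor(st, dur)
  } else {
    stop(sprintf("backend cannot execute primitive '%s'", name),
         call. = FALSE)
  }
  if (st$temp > sc$safeRange[2] || st$temp < sc$safeRange[1])
    stop(sprintf("temperature %.1f degC outside backend safe range",
                 st$temp), call. = FALSE)
  invisible(list(duration = dur))
})

## chromophore reagents drive the colour trace (iodine-style additions)
isChromophore <- function(step) {
  r <- step@properties$reagent
  !is.null(r) && grepl("iodine|chromophore", r, ignore.case = TRUE)
}

## ---- scripted backend -------------------------------------------------

#' Create a backend with scripted sensor sequences
#'
#' Reading sensor \code{kind} at simulation time t returns the
#' \code{floor(t)}-th element of the script (the last element persists), so
#' readings are a pure function of the clock and \code{readSensor} stays
#' side-effect free.  Primitive steps only advance the clock.
#'
#' @param sensors named list of numeric vectors (one value per second).
#' @param stepSeconds seconds one pumped increment or unit step advances.
#' @return a \code{ScriptedBackend}.
#' @export
scriptedBackend <- function(sensors = list(), stepSeconds = 1) {
  st <- new.env(parent = emptyenv())
  st$t <- 0
  st$scripts <- sensors
  st$stepSeconds <- stepSeconds
  st$sensors <- names(sensors)
  new("ScriptedBackend", state = st)
}

setMethod("advanceTime", "ScriptedBackend", function(backend, dt) {
  stopifnot(dt >= 0)
  backend@state$t <- backend@state$t + dt
  invisible(backend)
})

setMethod("readSensor", "ScriptedBackend", function(backend, kind) {
  st <- backend@state
  sq <- st$scripts[[kind]]
  if (is.null(sq))
    stop(sprintf("sensor unavailable: '%s'", kind), call. = FALSE)
  idx <- min(length(sq), max(1L, as.integer(floor(st$t + 1e-9))))
  list(kind = kind, time = st$t, value = sq[idx])
})

setMethod("sensorTrace", "ScriptedBackend",
          function(backend, kind, from = 0, to = Inf) {
  st <- backend@state
  sq <- st$scripts[[kind]]
  if (is.null(sq))
    stop(sprintf("sensor unavailable: '%s'", kind), call. = FALSE)
  tm <- seq_along(sq)
  keep <- tm >= from & tm <= min(to, st$t)
  data.frame(time = tm[keep], value = sq[keep])
})

setMethod("executePrimitive", "ScriptedBackend", function(backend, step, ...) {
  st <- backend@state
  props <- step@properties
  dur <- if (!is.null(props$time)) qIn(props$time, "s") else st$stepSeconds
  st$t <- st$t + dur
  invisible(list(duration = dur))
})

backendSensors <- function(backend) backend@state$sensors
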