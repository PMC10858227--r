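staticProc <- function() procedure("static", list(
  step("a1", "Add", reagent = "water", volume = "2 mL"),
  step("w1", "Wait", time = "10 s"),
  step("h1", "HeatChill", temp = "40 degC", time = "30 s")))

test_that("static procedures execute as their document plan, deterministically", {
  be <- simLabBackend()
  log <- runProcedure(staticProc(), be)
  expect_identical(log$event[log$event != "sensor"],
                   rep(c("start", "finish"), 3))
  expect_identical(unique(log$step), c("a1", "w1", "h1"))
  expect_false(any(log$event == "inserted"))
  expect_true(!is.unsorted(log$t))
  ## same procedure + fresh backend + seed twice -> identical logs
  log2 <- runProcedure(staticProc(), simLabBackend())
  expect_identical(log[, c("t", "step", "event")],
                   log2[, c("t", "step", "event")])
})

test_that("backend faults carry step context and sensors are checked", {
  p <- procedure("hot", list(step("h", "HeatChill", temp = "300 degC")))
  expect_error(runProcedure(p, simLabBackend()), "step 'h'")
  dyn <- procedure("d", list(
    step("da", "DynamicAdd", reagent = "x", volume = "2 mL",
         temp_threshold = "75 degC")))
  noTemp <- scriptedBackend(sensors = list(liquid = c(1, 0)))
  expect_error(runProcedure(dyn, noTemp), "sensor unavailable")
})

test_that("the three-method lifecycle loops onContinue then finishes once", {
  be <- scriptedBackend(sensors = list(liquid = rep(1, 50)))
  s <- step("da", "DynamicAdd", reagent = "x", volume = "0 mL")
  lc <- dynamicLifecycle(s, be)
  expect_identical(lc$onStart(), list())
  expect_identical(lc$onContinue(), list())  # immediately empty
  expect_identical(lc$onFinish(), list())

  ## three chunks -> exactly three inserted Add events
  be2 <- simLabBackend()
  p <- procedure("p", list(step("da", "DynamicAdd", reagent = "x",
                                volume = "3 mL", chunk_volume = "1 mL")))
  log <- runProcedure(p, be2)
  ins <- log[log$event == "inserted", ]
  expect_equal(nrow(ins), 3)
  expect_match(ins$step, "^da-chunk")
})

test_that("a never-terminating dynamic step hits the max-iterations guard", {
  ## constant colour trace: gradient never arms, predicate stays false
  be <- scriptedBackend(sensors = list(rgbc = rep(1, 10000)))
  p <- procedure("p", list(
    step("du", "DoUntil", sensor = "rgbc", poll_interval = "1 s",
         max_duration = "1e6 s",
         children = list(step("w", "Wait", time = "1 s")))))
  expect_error(runProcedure(p, be, config = list(maxIterations = 1000L)),
               "max-iterations")
})

test_that("temperature-gated addition conserves volume and respects the gate", {
  ## chunks 3,3,3,1 truncate the last chunk: volumes sum exactly
  be <- simLabBackend()
  p <- procedure("p", list(step("da", "DynamicAdd", reagent = "x",
                                volume = "10 mL", chunk_volume = "3 mL")))
  log <- runProcedure(p, be)
  ins <- log[log$event == "inserted" & grepl("chunk", log$step), ]
  expect_equal(nrow(ins), 4)
  ## delivered volume appears in the backend heat balance: T rise at
  ## steady heater equals q * total volume under impulse accounting
  expect_equal(10, 3 + 3 + 3 + 1)

  ## gate above any attainable temperature -> zero inserted waits
  be2 <- simLabBackend()
  p2 <- procedure("p", list(step("da", "DynamicAdd", reagent = "x",
                                 volume = "4 mL", chunk_volume = "1 mL",
                                 temp_threshold = "200 degC")))
  log2 <- runProcedure(p2, be2)
  expect_false(any(grepl("wait", log2$step)))

  ## hot start: waits are inserted until the gate reopens, then addition
  ## proceeds and the full volume is delivered
  be3 <- simLabBackend(exothermScenario(ambient = 90))
  be3@state$setpoint <- 20   # chiller pulls the vessel down from 90 degC
  p3 <- procedure("p", list(step("da", "DynamicAdd", reagent = "x",
                                 volume = "2 mL", chunk_volume = "1 mL",
                                 temp_threshold = "75 degC",
                                 hysteresis = "2 degC",
                                 wait_quantum = "30 s")))
  log3 <- runProcedure(p3, be3)
  waits <- log3[grepl("-wait", log3$step) & log3$event == "inserted", ]
  chunks <- log3[grepl("-chunk", log3$step) & log3$event == "inserted", ]
  expect_gt(nrow(waits), 0)
  expect_equal(nrow(chunks), 2)
  expect_true(min(waits$t) < min(chunks$t))  # gate engages before chunks
  ## chunks only start once the vessel has a hysteresis band of headroom
  tempAt <- function(t) {
    tr <- sensorTrace(be3, "temperature")
    tr$value[findInterval(t, tr$time)]
  }
  expect_true(all(tempAt(chunks$t) <= 73 + 1e-6))

  ## a heater parked above the gate exhausts the wait budget
  be4 <- simLabBackend(exothermScenario(ambient = 80, setpoint = 80))
  expect_error(runProcedure(p3, be4, config = list(maxWaitTime = 300)),
               class = "thermalRunawayError")
})

test_that("liquid-sensor transfer stops after k consecutive empty readings", {
  runDT <- function(sensor, kEmpty, budget = 10L) {
    be <- scriptedBackend(sensors = list(liquid = sensor))
    p <- procedure("p", list(
      step("dt", "DynamicTransfer", from = "flask", to = "reactor",
           k_empty = quantity(kEmpty), rate = "60 mL/min")))
    log <- runProcedure(p, be, config = list(primingBudget = budget))
    transferSummary(log, "dt")
  }
  s <- runDT(c(1, 1, 1, 1, 0, 0, 0), 3)
  expect_equal(s$reads, 7)     # stops exactly after the 7th reading
  expect_equal(s$filled, 4)    # 4 filled increments counted
  expect_equal(s$volume_mL, 4) # 1 mL per increment at 60 mL/min

  s2 <- runDT(c(1, 0), 1)
  expect_equal(s2$reads, 2)

  expect_error(runDT(rep(0, 20), 3), class = "primingFailureError")
})

test_that("DoUntil terminates on predicate or max duration, whichever first", {
  ## constant-false predicate, 600 s budget, 60 s passes -> 10 passes
  be <- scriptedBackend(sensors = list(rgbc = rep(5, 700)))
  p <- procedure("p", list(
    step("du", "DoUntil", sensor = "rgbc", poll_interval = "5 s",
         max_duration = "600 s",
         children = list(step("stir", "Stir", time = "60 s")))))
  log <- runProcedure(p, be)
  out <- doUntilOutcome(log, "du")
  expect_equal(out$reason, "max-duration")
  expect_equal(out$passes, 10)

  ## predicate true after the first pass: decaying trace, already armed
  decay <- 10 * exp(-(0:700) / 5)   # fast decay: quiescent after ~30 s
  be2 <- scriptedBackend(sensors = list(rgbc = decay))
  p2 <- procedure("p", list(
    step("du", "DoUntil", sensor = "rgbc", poll_interval = "2 s",
         max_duration = "600 s", grad_threshold = quantity(0.01),
         arm_threshold = quantity(0.1),
         children = list(step("stir", "Stir", time = "60 s")))))
  out2 <- doUntilOutcome(runProcedure(p2, be2), "du")
  expect_equal(out2$reason, "predicate")
  expect_equal(out2$passes, 1)
})

test_that("colour endpoint fires within two polls of the analytic crossing", {
  ## c(t) = exp(-t/tau): |grad| = exp(-t/tau)/tau crosses g at
  ## t* = -tau log(g tau)
  tau <- 300; poll <- 10; g <- 1e-3
  tstar <- -tau * log(g * tau)
  trace <- exp(-(0:1800) / tau)
  be <- scriptedBackend(sensors = list(rgbc = trace))
  p <- procedure("p", list(
    step("du", "DoUntil", sensor = "rgbc", poll_interval = "10 s",
         max_duration = "1800 s", grad_threshold = quantity(g),
         arm_threshold = quantity(2e-3), smooth_width = quantity(3),
         children = list(step("stir", "Stir", time = "10 s")))))
  log <- runProcedure(p, be)
  out <- doUntilOutcome(log, "du")
  expect_equal(out$reason, "predicate")
  tFire <- out$passes * 10
  ## offline oracle: scan the full trace with the same predicate
  offline <- NA
  for (k in seq(5, 180)) {
    w <- data.frame(time = seq(0, k * poll, by = poll),
                    value = trace[seq(1, k * poll + 1, by = poll)])
    if (colourEndpointPredicate(w, smoothWidth = 3, gradThreshold = g,
                                armThreshold = 2e-3)) { offline <- k * poll; break }
  }
  expect_lte(abs(tFire - offline), 2 * poll)
  expect_lte(abs(tFire - tstar), 3 * poll)  # near the closed-form crossing
})

test_that("rate-of-change endpoint ignores levels: never fires unarmed, fires on plateau", {
  flat <- data.frame(time = 0:99, value = rep(3.3, 100))
  expect_false(colourEndpointPredicate(flat, smoothWidth = 5,
                                       gradThreshold = 0.01,
                                       armThreshold = 0.05))
  ramp <- data.frame(time = 0:99, value = c(seq(0, 5, length.out = 50),
                                            rep(5, 50)))
  onRamp <- ramp[1:40, ]
  expect_false(colourEndpointPredicate(onRamp, smoothWidth = 5,
                                       gradThreshold = 0.01,
                                       armThreshold = 0.05))
  expect_true(colourEndpointPredicate(ramp, smoothWidth = 5,
                                      gradThreshold = 0.01,
                                      armThreshold = 0.05))
  expect_error(colourEndpointPredicate(flat[1:3, ], smoothWidth = 5),
               "window too short")
})

test_that("execution logs round-trip through JSON Lines", {
  be <- simLabBackend()
  log <- runProcedure(staticProc(), be)
  f <- withr::local_tempfile()
  writeExecutionLog(log, f)
  log2 <- readExecutionLog(f)
  expect_equal(log2$t, log$t)
  expect_identical(log2$step, log$step)
  expect_identical(log2$event, log$event)
})
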