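smallSchedule <- function(budget) {
  data.frame(kind = c("random", "explore", "exploit"),
             count = c(max(1L, budget - 4L), 2L, 2L))
}

test_that("a budget-N campaign writes N+1 procedure versions and N records", {
  d <- withr::local_tempdir()
  cfg <- campaignConfig("ugi", d, budget = 6,
                        strategy = strategyConfig("random"), seed = 11)
  out <- runCampaign(cfg)
  files <- list.files(d, pattern = "chemdsl\\.yaml$")
  expect_length(files, 7)                        # v0 ... v6
  expect_length(out$records, 6)
  expect_identical(vapply(out$records, `[[`, numeric(1), "iteration"),
                   as.numeric(1:6))
  vs <- vapply(out$records, `[[`, numeric(1), "version")
  expect_identical(vs, as.numeric(1:6))          # 1 iteration = 1 version
  ## every record's procedure file exists and parses to its version
  for (rec in out$records) {
    p <- readProcedure(file.path(d, rec$procedureFile))
    expect_equal(procVersion(p), as.integer(rec$version))
  }
})

test_that("the staged campaign records its stage sequence", {
  d <- withr::local_tempdir()
  cfg <- campaignConfig("ugi", d, budget = 30,
                        strategy = strategyConfig("smbo"), seed = 5,
                        executeProcedures = FALSE)
  out <- runCampaign(cfg)
  stages <- vapply(out$records, `[[`, character(1), "stage")
  expect_identical(stages, rep(c("random", "explore", "balanced",
                                 "exploit"), times = c(5, 14, 5, 6)))
})

test_that("a killed-and-resumed campaign matches the uninterrupted database", {
  mk <- function(dir, budget) campaignConfig(
    "vanleusen", dir, budget = budget,
    strategy = strategyConfig("smbo", stageSchedule = smallSchedule(10)),
    seed = 23, executeProcedures = FALSE)
  dFull <- withr::local_tempdir()
  runCampaign(mk(dFull, 10))
  dKill <- withr::local_tempdir()
  runCampaign(mk(dKill, 6))                      # "killed" after 6
  expect_length(readCampaignRecords(dKill), 6)
  runCampaign(mk(dKill, 10))                     # resume to the full budget
  expect_true(campaignDatabasesEqual(dFull, dKill))
})

test_that("parallel batches change timing only, never the chemistry", {
  d2 <- withr::local_tempdir()
  cfg2 <- campaignConfig("vanleusen", d2, budget = 8, parallelism = 2,
                         strategy = strategyConfig("random"), seed = 9,
                         executeProcedures = FALSE)
  out2 <- runCampaign(cfg2)
  ## serial re-evaluation of the same suggestion sequence gives identical
  ## objectives
  fx <- campaignFixture("vanleusen")
  specs <- extractParameters(fx$procedure, fx$optimizeConfig)
  for (rec in out2$records) {
    a <- paramAssignment(lapply(rec$assignment, function(e)
      quantity(e$value, e$unit)))
    comp <- evaluateReaction(fx$surface, a, seed = rec$seedDigest)
    sp <- synthSpectrum(comp, fx$model, seed = rec$seedDigest)
    res <- evaluateObjective(fx$objective, sp)
    expect_equal(res$value, rec$objective, tolerance = 1e-12)
  }
})

test_that("campaign reports tabulate parameters, bests and terciles", {
  d <- withr::local_tempdir()
  out <- runCampaign(campaignConfig("ugi", d, budget = 9,
                                    strategy = strategyConfig("random"),
                                    seed = 2, executeProcedures = FALSE))
  rep <- campaignReport(out$records)
  expect_equal(nrow(rep$parameters), 9)
  expect_true(all(c("add_amine.volume", "stir_rxn.time", "stage",
                    "objective", "tercile") %in% names(rep$parameters)))
  expect_equal(nrow(rep$cumulativeBest), 9)
  expect_true(all(diff(rep$cumulativeBest$best) >= 0))
  sizes <- table(rep$parameters$tercile)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(campaignReport(list()), "empty")
  f <- withr::local_tempdir()
  paths <- writeReportCsv(out$records, f)
  expect_true(all(file.exists(file.path(f, c("parameters.csv",
                                             "cumulative_best.csv")))))
})

test_that("restarting with expanded bounds warm-starts consistently", {
  d <- withr::local_tempdir()
  cfg <- campaignConfig("ugi", d, budget = 8,
                        strategy = strategyConfig(
                          "smbo", stageSchedule = smallSchedule(16)),
                        seed = 17, executeProcedures = FALSE)
  out1 <- runCampaign(cfg)
  ## temperature lower bound expanded 25 -> 0 degC
  expanded <- lapply(cfg$fixture$optimizeConfig, function(e) {
    if (e$step == "heat_rxn") e$lower <- 0
    e
  })
  ## shrunken bounds are rejected
  shrunk <- lapply(cfg$fixture$optimizeConfig, function(e) {
    if (e$step == "heat_rxn") e$lower <- 30
    e
  })
  expect_error(twoStageRestart(cfg, shrunk, budget = 12),
               "do not contain")
  out2 <- twoStageRestart(cfg, expanded, budget = 12)
  expect_length(out2$records, 12)
  ## old observations renormalized into the expanded box: the refit GP
  ## reproduces the old posterior means at the old points within 1e-3
  newSpecs <- extractParameters(cfg$fixture$procedure, expanded)
  oldSpecs <- extractParameters(cfg$fixture$procedure,
                                cfg$fixture$optimizeConfig)
  oldH <- newHistory(); newH <- newHistory()
  for (rec in out1$records) {
    a <- paramAssignment(lapply(rec$assignment, function(e)
      quantity(e$value, e$unit)))
    oldH <- addObservation(oldH, normalizeAssignment(a, oldSpecs),
                           rec$objective, FALSE, rec$stage)
    newH <- addObservation(newH, normalizeAssignment(a, newSpecs),
                           rec$objective, FALSE, rec$stage)
  }
  gpOld <- fitSurrogate(oldH$X, oldH$y)
  gpNew <- fitSurrogate(newH$X, newH$y)
  expect_lt(max(abs(predictSurrogate(gpOld, oldH$X)$mean -
                    predictSurrogate(gpNew, newH$X)$mean)), 1e-3)
  ## identical expansion behaves exactly like a resume
  dA <- withr::local_tempdir(); dB <- withr::local_tempdir()
  cfgA <- campaignConfig("ugi", dA, budget = 8,
                         strategy = cfg$strategy, seed = 17,
                         executeProcedures = FALSE)
  runCampaign(cfgA)
  outA <- twoStageRestart(cfgA, cfgA$fixture$optimizeConfig, budget = 12)
  cfgB <- campaignConfig("ugi", dB, budget = 8,
                         strategy = cfg$strategy, seed = 17,
                         executeProcedures = FALSE)
  runCampaign(cfgB)
  cfgB$budget <- 12L
  outB <- runCampaign(cfgB)
  expect_true(campaignDatabasesEqual(dA, dB))
})

test_that("the discovery pipeline catalogues products and improves them", {
  out <- exploreThenOptimize(seed = 42, phase1Budget = 25, phases = 1)
  expect_true(nrow(out$catalogue) >= 1)
  ## every catalogued position is near a latent product band
  truth <- discoveryProductPositions()
  for (p in out$catalogue$position)
    expect_lt(min(abs(p - truth)), 0.5)
  ## with every product pre-listed as known, nothing novel remains
  known <- lapply(unname(truth), region, tolerance = 0.5)
  out0 <- exploreThenOptimize(seed = 42, phase1Budget = 10, phases = 1,
                              knownRegions = known)
  expect_equal(nrow(out0$catalogue), 0)
})
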