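test_that("unit-box normalization is exact, including the log scale", {
  fx <- campaignFixture("epoxidation")
  specs <- extractParameters(fx$procedure, fx$optimizeConfig)
  paths <- specPaths(specs)
  ## lower bound -> 0, upper -> 1
  lo <- denormalizeAssignment(rep(0, 5), specs)
  hi <- denormalizeAssignment(rep(1, 5), specs)
  for (i in seq_along(specs)) {
    expect_equal(qValue(lo[[paths[i]]]), qValue(specs[[i]]@lower))
    expect_equal(qValue(hi[[paths[i]]]), qValue(specs[[i]]@upper))
  }
  ## log-scale addition rate: the geometric mean maps to 0.5
  x <- rep(0.3, 5)
  i <- match("add_h2o2.rate", paths)
  a <- denormalizeAssignment(x, specs)
  a[[paths[i]]] <- quantity(sqrt(0.04 * 10), "mL/min")
  expect_equal(unname(normalizeAssignment(a, specs)[i]), 0.5,
               tolerance = 1e-12)
  ## round trip on random points
  set.seed(11)
  for (k in 1:1000) {
    x <- stats::runif(5)
    back <- normalizeAssignment(denormalizeAssignment(x, specs), specs)
    expect_lt(max(abs(back - x)), 1e-12)
  }
  expect_error(normalizeAssignment(paramAssignment(
    "add_h2o2.rate" = quantity(20, "mL/min"),
    "add_mnso4.volume" = "1 mL", "add_nahco3.volume" = "1 mL",
    "add_h2o2.volume" = "2 mL", "stir_rxn.time" = "2 h"), specs),
    "out of bounds")
})

test_that("Latin hypercube designs stratify every marginal", {
  for (n in c(5, 8)) {
    des <- doeLhs(n, 2, seed = 4)
    expect_equal(dim(des), c(n, 2))
    for (j in 1:2)
      expect_identical(sort(unique(floor(des[, j] * n))),
                       as.numeric(0:(n - 1)))
  }
  ## deterministic given the seed
  expect_identical(doeLhs(8, 3, seed = 9), doeLhs(8, 3, seed = 9))
})

test_that("the GP surrogate interpolates noiseless data", {
  set.seed(5)
  X <- lhs::randomLHS(5, 2)
  y <- 2 + 3 * X[, 1] - 1.5 * X[, 2]          # linear test function
  gp <- fitSurrogate(X, y, noiseFloor = 1e-6)
  p <- predictSurrogate(gp, X)
  expect_lt(max(abs(p$mean - y)), 1e-4)
  ## posterior sd at a training point is below sd far away
  far <- matrix(c(0.99, 0.01), 1)
  expect_lt(p$sd[1], predictSurrogate(gp, far)$sd)
  ## duplicating a point never increases posterior sd on a grid (fixed
  ## kernel; a nonlinear function keeps the lengthscale well conditioned)
  Xn <- lhs::randomLHS(8, 2)
  yn <- sin(2 * pi * Xn[, 1]) * cos(pi * Xn[, 2])
  gpn <- fitSurrogate(Xn, yn, noiseFloor = 1e-6)
  grid <- as.matrix(expand.grid(seq(0, 1, 0.1), seq(0, 1, 0.1)))
  sd1 <- predictSurrogate(gpn, grid)$sd
  gp2 <- fitSurrogate(rbind(Xn, Xn[3, ]), c(yn, yn[3]), noiseFloor = 1e-6,
                      hyper = list(ell = gpn$ell, sigma2 = gpn$sigma2))
  sd2 <- predictSurrogate(gp2, grid)$sd
  expect_true(all(sd2 <= sd1 + 1e-6))
  expect_error(fitSurrogate(X[1, , drop = FALSE], y[1]), "insufficient")
})

test_that("acquisitions match dense-grid oracles in 1-D", {
  X <- matrix(c(0.2, 0.8), ncol = 1)
  y <- c(0.3, 0.5)
  gp <- fitSurrogate(X, y, noiseFloor = 1e-6)
  grid <- matrix(seq(0, 1, length.out = 1001), ncol = 1)
  ## explore: the argmax of sd sits far from both training points
  sdg <- acquisition(gp, "explore")(grid)
  gridBest <- grid[which.max(sdg), 1]
  found <- optimizeAcquisition(acquisition(gp, "explore"), 1, seed = 2)
  expect_lt(abs(found - gridBest), 0.02)
  expect_true(min(abs(gridBest - c(0, 0.5, 1))) < 0.05)
  ## exploit: argmax of the mean near the best observed region
  mg <- acquisition(gp, "exploit")(grid)
  foundE <- optimizeAcquisition(acquisition(gp, "exploit"), 1, seed = 2)
  expect_lt(abs(foundE - grid[which.max(mg), 1]), 0.02)
  ## EI at a noiseless training point equal to the incumbent is ~0
  ei <- acquisition(gp, "balanced", incumbent = max(y))
  expect_lt(ei(matrix(0.8, 1, 1)), 1e-3)
})

test_that("the staged schedule maps iteration indices to stages", {
  sched <- defaultStageSchedule()
  expect_identical(vapply(c(1, 5, 6, 19, 20, 24, 25, 30),
                          function(i) stageForIteration(sched, i),
                          character(1)),
                   c("random", "random", "explore", "explore", "balanced",
                     "balanced", "exploit", "exploit"))
  expect_error(stageForIteration(sched, 31), class = "scheduleExhausted")
})

test_that("every strategy suggests in-bounds, deterministic points", {
  fx <- campaignFixture("ugi", noiseSd = 0)
  specs <- extractParameters(fx$procedure, fx$optimizeConfig)
  strategies <- list(
    random = strategyConfig("random"),
    lhs = strategyConfig("doe_lhs"),
    smbo = strategyConfig("smbo"),
    ga = strategyConfig("ga"),
    adapter = strategyConfig("adapter",
                             suggestFn = function(h, s) rep(0.25, 6)))
  set.seed(99)
  for (nm in names(strategies)) {
    h <- newHistory()
    for (i in 1:8) {
      sug <- suggestNext(h, specs, strategies[[nm]], seed = 21L)
      expect_true(all(sug$x >= 0 & sug$x <= 1))
      ## determinism given (history, config, seed)
      again <- suggestNext(h, specs, strategies[[nm]], seed = 21L)
      expect_identical(again$x, sug$x)
      h <- addObservation(h, sug$x, stats::runif(1), FALSE, sug$stage)
    }
  }
  ## iteration 6 of the staged schedule is an explore suggestion
  h5 <- newHistory()
  for (i in 1:5) {
    sug <- suggestNext(h5, specs, strategies$smbo, seed = 3L)
    expect_identical(sug$stage, "random")
    h5 <- addObservation(h5, sug$x, stats::runif(1), FALSE, sug$stage)
  }
  expect_identical(suggestNext(h5, specs, strategies$smbo, seed = 3L)$stage,
                   "explore")
})

test_that("the genetic step respects elitism and stays in the box", {
  h <- newHistory()
  set.seed(8)
  for (i in 1:10) h <- addObservation(h, stats::runif(3),
                                      stats::runif(1), FALSE, "ga")
  ## mutation off + elite: the incumbent comes back unchanged
  inc <- h$X[which.max(h$y), ]
  expect_identical(gaStep(h, 3, list(tournament = 3, mutationSd = 0,
                                     elite = 1), seed = 5), inc)
  for (s in 1:20) {
    x <- gaStep(h, 3, list(tournament = 3, mutationSd = 0.3, elite = 1),
                seed = s)
    expect_true(all(x >= 0 & x <= 1))
  }
})

test_that("staged SMBO beats random search on a 1-D quadratic", {
  ## f(x) = 1 - (x - 0.3)^2, noiseless; budget 20
  f <- function(x) 1 - (x - 0.3)^2
  spec1 <- list(new("ParameterSpec", stepId = "s", property = "p",
                    lower = quantity(0), upper = quantity(1),
                    scale = "linear", kind = "continuous"))
  sched <- data.frame(kind = c("random", "explore", "balanced", "exploit"),
                      count = c(4L, 6L, 4L, 6L))
  runOne <- function(seed, strat) {
    h <- newHistory()
    for (i in 1:20) {
      sug <- suggestNext(h, spec1, strat, seed = seed)
      h <- addObservation(h, sug$x, f(sug$x), FALSE, sug$stage)
    }
    h$X[which.max(h$y), 1]
  }
  smbo <- strategyConfig("smbo", stageSchedule = sched)
  rnd <- strategyConfig("random")
  wins <- 0; okBest <- 0
  nSeeds <- 40
  for (s in seq_len(nSeeds)) {
    bS <- runOne(1000 + s, smbo)
    bR <- runOne(1000 + s, rnd)
    if (abs(bS - 0.3) <= abs(bR - 0.3)) wins <- wins + 1
    if (abs(bS - 0.3) <= 0.02) okBest <- okBest + 1
  }
  expect_gte(wins / nSeeds, 0.8)     # SMBO at least matches random
  expect_gte(okBest / nSeeds, 0.8)   # and lands within 0.02 of the optimum
})
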