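## hand-built peak tables and synthetic spectra for objective identities

twoPeakSpectrum <- function(concs, positions, width = 0.08) {
  x <- seq(min(positions) - 5, max(positions) + 5, length.out = 4000)
  y <- numeric(length(x))
  for (i in seq_along(concs))
    y <- y + concs[i] * width^2 / ((x - positions[i])^2 + width^2)
  spectrum(x, y, "ppm")
}

test_that("area ratio recovers composition ratios and flags failures", {
  ## areas 3.0 / 1.5 -> 2.0 (explicit synthetic bands)
  sp <- twoPeakSpectrum(c(3, 1.5), c(0, 4))
  r <- aucRatio(sp, region(0, 1), region(4, 1),
                peakOptions = list(minHeight = 0.05, minProminence = 0.02))
  expect_lt(abs(r$value - 2), 2 * 0.02)  # 2% on the ratio
  ## product absent: 0 with a product-not-found flag, not an error
  spRef <- twoPeakSpectrum(1.5, 4)
  r2 <- aucRatio(spRef, region(0, 1), region(4, 1),
                 peakOptions = list(minHeight = 0.05, minProminence = 0.02))
  expect_equal(r2$value, 0)
  expect_identical(r2$components$flag, "product-not-found")
  expect_false(r2$failed)
  ## reference absent: invalid-reference failure
  spProd <- twoPeakSpectrum(3, 0)
  r3 <- aucRatio(spProd, region(0, 1), region(4, 1),
                 peakOptions = list(minHeight = 0.05, minProminence = 0.02))
  expect_true(r3$failed)
  expect_identical(r3$reason, "invalid-reference")
  ## synthetic mixture at concentration ratio 0.8 to the standard
  fx <- campaignFixture("ugi", noiseSd = 0)
  comp <- c(ugi_product = 0.8, fluorobenzoic_acid = 0.2,
            difluorobenzene = 1)
  res <- evaluateObjective(fx$objective, synthSpectrum(comp, fx$model))
  expect_lt(abs(res$value - 0.8), 0.8 * 0.02)
})

test_that("purity is the product share of total peak area", {
  pk <- data.frame(position = c(1, 2, 3), height = c(6, 3, 1),
                   left = c(0.5, 1.5, 2.5), right = c(1.5, 2.5, 3.5),
                   area = c(60, 30, 10))
  expect_equal(purity(pk, region(1, 0.2)), 0.60)
  expect_equal(purity(pk[1, ], region(1, 0.2)), 1.0)
  ## purities of all peaks sum to one
  expect_equal(sum(vapply(pk$position, function(p)
    purity(pk, region(p, 0.2)), numeric(1))), 1.0)
  expect_error(purity(pk[0, ], region(1, 0.2)), "empty")
})

test_that("desirability is a convex combination of scaled objectives", {
  expect_equal(desirability(c(0.8, 0.4), c(0.5, 0.5)), 0.6)
  expect_equal(desirability(c(0.8, 0.4), c(1, 0)), 0.8)
  expect_error(desirability(c(0.5), c(0.5, 0.5)), "length")
  expect_error(desirability(c(0.5, 0.5), c(0.6, 0.5)), "sum to 1")
  ## fuzz: always within [min, max] of the components
  set.seed(42)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    v <- stats::runif(k)
    w <- stats::runif(k); w <- w / sum(w)
    dd <- desirability(v, w)
    expect_gte(dd, min(v) - 1e-12)
    expect_lte(dd, max(v) + 1e-12)
  }
})

test_that("Raman conversion tracks starting-material depletion", {
  fx <- campaignFixture("epoxidation", noiseSd = 0)
  t0 <- synthSpectrum(c(epoxide = 0, styrene_sulfonate = 1,
                        acetonitrile = 1), fx$model)
  ## r(t) = r(0) -> conversion 0
  r0 <- ramanConversion(t0, t0)
  expect_equal(r0$value, 0)
  ## starting-material band gone -> conversion 1
  done <- synthSpectrum(c(epoxide = 1, styrene_sulfonate = 0,
                          acetonitrile = 1), fx$model)
  expect_equal(ramanConversion(done, t0)$value, 1)
  ## latent yield 0.5 -> conversion 0.5 within 2%
  half <- synthSpectrum(c(epoxide = 0.5, styrene_sulfonate = 0.5,
                          acetonitrile = 1), fx$model)
  expect_lt(abs(ramanConversion(half, t0)$value - 0.5), 0.5 * 0.02)
  ## standard band absent -> failure, not a crash
  noStd <- synthSpectrum(c(epoxide = 0.5, styrene_sulfonate = 0.5,
                           acetonitrile = 0), fx$model)
  expect_true(ramanConversion(noStd, t0)$failed)
})

test_that("novelty counts only unexplained peaks and shrinks as regions grow", {
  sp <- twoPeakSpectrum(c(1, 0.8, 0.6), c(0, 3, 6))
  opts <- list(minHeight = 0.05, minProminence = 0.02)
  all3 <- noveltyScore(sp, knownRegions = list(), peakOptions = opts)
  expect_equal(all3$count, 3)
  one <- noveltyScore(sp, knownRegions = list(region(0, 0.5)),
                      peakOptions = opts)
  expect_equal(one$count, 2)
  expect_equal(sort(one$novel$position), c(3, 6), tolerance = 0.01)
  none <- noveltyScore(sp, knownRegions = lapply(c(0, 3, 6), region,
                                                 tolerance = 0.5),
                       peakOptions = opts)
  expect_equal(none$count, 0)
  ## monotone: growing known regions never increases the count
  set.seed(7)
  prev <- all3$count
  known <- list()
  for (p in sample(c(0, 3, 6))) {
    known <- c(known, list(region(p, 0.5)))
    cnt <- noveltyScore(sp, knownRegions = known, peakOptions = opts)$count
    expect_lte(cnt, prev)
    prev <- cnt
  }
})

test_that("composite dispatch equals the hand-computed weighted formula", {
  ## main product up (w=1), two side products down (w=0.5 each),
  ## all areas normalized by the internal standard
  fx <- campaignFixture("discovery", noiseSd = 0)
  comp <- c(cf3_adduct_1 = 0.6, cf3_adduct_2 = 0.3, cf3_adduct_3 = 0.2,
            cf3_source = 0.1, fluoroacetophenone_sm = 1, fluorobenzene = 1)
  sp <- synthSpectrum(comp, fx$model)
  pos <- discoveryProductPositions()
  spec <- objectiveSpec("composite",
    regions = list(std = region(-113.1, 0.3)), reference = "std",
    components = list(
      main = list(region = region(pos[["cf3_adduct_1"]], 0.3),
                  direction = "maximize", weight = 1),
      s1 = list(region = region(pos[["cf3_adduct_2"]], 0.3),
                direction = "minimize", weight = 0.5),
      s2 = list(region = region(pos[["cf3_adduct_3"]], 0.3),
                direction = "minimize", weight = 0.5)))
  res <- evaluateObjective(spec, sp)
  hand <- 1 * 0.6 - 0.5 * 0.3 - 0.5 * 0.2
  expect_lt(abs(res$value - hand), 0.02)
  ## single maximized component with weight 1 equals that component
  spec1 <- objectiveSpec("composite",
    regions = list(std = region(-113.1, 0.3)), reference = "std",
    components = list(main = list(region = region(pos[["cf3_adduct_1"]],
                                                  0.3),
                                  direction = "maximize", weight = 1)))
  res1 <- evaluateObjective(spec1, sp)
  expect_equal(res1$value, res1$components$main)
  ## missing reference -> failed iteration marker
  noRef <- synthSpectrum(comp[names(comp) != "fluorobenzene"], fx$model)
  expect_true(evaluateObjective(spec, noRef)$failed)
})

test_that("objectives are invariant to global intensity scaling", {
  scaleSpec <- function(sp, f) spectrum(specAxis(sp),
                                        f * specIntensity(sp),
                                        axisKind(sp))
  fx <- campaignFixture("ugi", noiseSd = 0)
  comp <- c(ugi_product = 0.5, fluorobenzoic_acid = 0.5,
            difluorobenzene = 1)
  sp <- synthSpectrum(comp, fx$model)
  v1 <- evaluateObjective(fx$objective, sp)$value
  v2 <- evaluateObjective(fx$objective, scaleSpec(sp, 7.3))$value
  expect_lt(abs(v2 / v1 - 1), 1e-6)
  ## novelty with a reference region is scale-invariant too
  fd <- campaignFixture("discovery", noiseSd = 0)
  compd <- c(cf3_adduct_1 = 0.5, cf3_adduct_2 = 0, cf3_adduct_3 = 0,
             cf3_source = 0.5, fluoroacetophenone_sm = 1,
             fluorobenzene = 1)
  spd <- synthSpectrum(compd, fd$model)
  n1 <- evaluateObjective(fd$objective, spd)$value
  n2 <- evaluateObjective(fd$objective, scaleSpec(spd, 7.3))$value
  expect_equal(n1, n2)
})

test_that("chemically empty spectra yield failed results, never errors", {
  fx <- campaignFixture("ugi", noiseSd = 0)
  empty <- spectrum(seq(-130, -100, length.out = 500), numeric(500), "ppm")
  res <- evaluateObjective(fx$objective, empty)
  expect_true(res$failed)
  expect_equal(res$value, 0)
})
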