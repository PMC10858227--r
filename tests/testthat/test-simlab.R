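test_that("surfaces carry the campaigns' parameter bounds", {
  s <- makeSurface("epoxidation")
  paths <- specPaths(s@specs)
  i <- match("add_h2o2.rate", paths)
  expect_equal(qValue(s@specs[[i]]@lower), 0.04)
  expect_equal(qValue(s@specs[[i]]@upper), 10.00)
  expect_identical(s@specs[[i]]@scale, "log")
  expect_length(makeSurface("ugi")@specs, 6)
  expect_length(makeSurface("vanleusen")@specs, 4)
  expect_length(makeSurface("discovery")@specs, 4)
  expect_error(makeSurface("alchemy"), "arg")
})

test_that("surfaces are deterministic and their documented optimum is real", {
  for (kind in c("ugi", "vanleusen", "epoxidation", "discovery")) {
    s1 <- makeSurface(kind, seed = 7)
    s2 <- makeSurface(kind, seed = 7)
    expect_identical(s1@optimum, s2@optimum)
    sNF <- makeSurface(kind, noiseSd = 0)
    yOpt <- latentYields(sNF, sNF@optimum$assignment)[[sNF@optimum$product]]
    expect_lt(abs(yOpt - sNF@optimum$value), 1e-9)
    ## optimum beats every corner of the box (2^d corner enumeration)
    d <- length(sNF@specs)
    corners <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))
    yCorners <- apply(corners, 1, function(x)
      latentYields(sNF, as.numeric(x))[[sNF@optimum$product]])
    expect_true(all(yOpt > yCorners))
  }
})

test_that("composition bookkeeping: standard fixed, substrates gate products", {
  s <- makeSurface("discovery", noiseSd = 0)
  ## zero substrate volume -> its product is absent, SM pool undepleted
  a0 <- denormalizeAssignment(c(0, 0.5, 0.5, 0.5), s@specs)
  comp0 <- evaluateReaction(s, a0)
  expect_equal(comp0[["cf3_adduct_1"]], 0)
  ## internal standard identical across any two assignments
  a1 <- denormalizeAssignment(c(0.9, 0.1, 0.2, 0.3), s@specs)
  expect_equal(comp0[["fluorobenzene"]], 1)
  expect_equal(evaluateReaction(s, a1)[["fluorobenzene"]], 1)
  ## determinism per (assignment, seed)
  sN <- makeSurface("ugi", noiseSd = 0.05)
  aa <- denormalizeAssignment(rep(0.4, 6), sN@specs)
  expect_identical(evaluateReaction(sN, aa, seed = 3),
                   evaluateReaction(sN, aa, seed = 3))
  expect_false(identical(evaluateReaction(sN, aa, seed = 3),
                         evaluateReaction(sN, aa, seed = 4)))
})

test_that("band areas are linear in concentration with closed-form area", {
  m <- spectrumModel("nmr19f")
  sp1 <- synthSpectrum(c(ugi_product = 0.4), m)
  pk1 <- pickPeaks(sp1, minHeight = 0.05, minProminence = 0.02)
  expect_equal(nrow(pk1), 1)
  expect_lt(abs(pk1$position + 111.2), diff(specAxis(sp1)[1:2]) + 1e-9)
  ## numeric area over +/- 20 widths vs analytic Lorentzian area
  num <- integrateRegion(sp1, -111.2 - 20 * 0.08, -111.2 + 20 * 0.08)
  analytic <- 0.4 * pi * 0.08 * (2 / pi) * atan(20)
  expect_lt(abs(num / analytic - 1), 0.02)
  ## doubling concentration doubles the band area
  sp2 <- synthSpectrum(c(ugi_product = 0.8), m)
  num2 <- integrateRegion(sp2, -111.2 - 20 * 0.08, -111.2 + 20 * 0.08)
  expect_lt(abs(num2 / num - 2), 0.01)
  ## empty composition: baseline only, no peaks at default prominence
  spe <- synthSpectrum(stats::setNames(numeric(0), character(0)), m)
  expect_equal(nrow(pickPeaks(spe, minHeight = 0.05,
                              minProminence = 0.02)), 0)
  ## species without a line assignment is an error
  expect_error(synthSpectrum(c(mystery = 1), m), "no line assignment")
})

test_that("synthetic FIDs transform to the expected frequencies and ratios", {
  fid <- synthFid(c(a = 1), c(a = 100), dwell = 1e-3, points = 2048,
                  t2 = 0.3)
  sp <- fidToSpectrum(fid)
  hz <- sp@metadata$hzAxis
  expect_lt(abs(hz[which.max(specIntensity(sp))] - 100),
            1 / (2048 * 1e-3) + 1e-9)
  ## zero species: pure-noise FID has |signal| on the order of its sd
  fid0 <- synthFid(stats::setNames(numeric(0), character(0)),
                   numeric(0), points = 4096, noiseSd = 0.01)
  expect_lt(abs(mean(Mod(fid0@samples)) - 0.01 * sqrt(pi / 2)), 2e-3)
  ## 2:1 amplitude ratio -> 2:1 integrated areas (zero noise)
  fid2 <- synthFid(c(a = 2, b = 1), c(a = -400, b = 350), dwell = 2.5e-4,
                   points = 8192, t2 = 0.3)
  sp2 <- processFid(fid2, lineBroadening = 1, baseline = TRUE)
  hz2 <- (specAxis(sp2)) * fid2@frequencyMHz
  win <- 60
  area <- function(f0) integrateRegion(sp2, (f0 - win) / fid2@frequencyMHz,
                                       (f0 + win) / fid2@frequencyMHz)
  expect_lt(abs(area(-400) / area(350) - 2), 2 * 0.02)
})

test_that("sensor traces follow the exotherm model and its closed forms", {
  sc <- exothermScenario()
  ## no additions at ambient setpoint: constant temperature
  tr <- synthSensorTraces(sc, horizon = 120)
  expect_true(all(tr$temperature == sc$ambient))
  expect_true(all(tr$colour == 0))
  ## single fast bolus peaks strictly higher than 4 gated chunks + waits
  bolus <- synthSensorTraces(sc, list(
    list(time = 10, type = "add", volume = 10, rate = 2)), horizon = 400)
  chunks <- synthSensorTraces(sc, lapply(0:3, function(k)
    list(time = 10 + k * 120, type = "add", volume = 2.5, rate = 0.05)),
    horizon = 800)
  expect_gt(max(bolus$temperature), max(chunks$temperature))
  ## consumption decay matches exp(-t/tau): below 5% after 3 tau
  dec <- synthSensorTraces(sc, list(
    list(time = 0, type = "add", volume = 1, rate = 1,
         chromophore = TRUE)), horizon = 1000)
  c0 <- max(dec$colour)
  expect_lt(dec$colour[dec$time == 901], 0.05 * c0)
  ## liquid trace is 1 exactly while pumping
  expect_equal(sum(bolus$liquid), 5)  # 10 mL at 2 mL/s
})

test_that("exotherm response is monotone in heat-per-mL and bolus size", {
  peak <- function(q, vol) {
    sc <- exothermScenario(heatPerML = q)
    max(synthSensorTraces(sc, list(list(time = 5, type = "add",
                                        volume = vol, rate = 2)),
                          horizon = 120)$temperature)
  }
  expect_true(peak(4, 10) < peak(7, 10))
  expect_true(peak(7, 5) < peak(7, 10))
})

test_that("spectra export to two-column CSV and read back", {
  m <- spectrumModel("raman")
  sp <- synthSpectrum(c(styrene_sulfonate = 0.7, acetonitrile = 1), m)
  f <- withr::local_tempfile(fileext = ".csv")
  writeSpectrumCsv(sp, f)
  sp2 <- readSpectrumCsv(f)
  expect_identical(axisKind(sp2), "cm-1")
  expect_equal(specAxis(sp2), specAxis(sp), tolerance = 1e-9)
  expect_equal(specIntensity(sp2), specIntensity(sp), tolerance = 1e-9)
})
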