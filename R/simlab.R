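## Simulated laboratory: reaction response surfaces, synthetic spectra and
## FIDs, and sensor traces emulating four closed-loop campaigns (Ugi
## four-component condensation, Van Leusen oxazole synthesis,
## manganese-catalysed epoxidation monitored by Raman, and a
## trifluoromethylation discovery space).  Parameter bounds mirror the
## campaigns' published ranges; the latent response landscapes are
## synthetic stand-ins (sums of anisotropic Gaussian bumps on the unit box
## with documented optima) since the real landscapes are unknown.

paramSpec <- function(stepId, property, lower, upper, unit,
                      scale = "linear") {
  s <- new("ParameterSpec", stepId = stepId, property = property,
           lower = quantity(lower, unit), upper = quantity(upper, unit),
           scale = scale, kind = "continuous")
  validObject(s)
  s
}

## bump sets live on the unit box; yields are clipped to [0,1]
.surfaceDefs <- list(
  ugi = list(
    specs = list(
      c("add_amine", "volume", 0.10, 1.00, "mL"),
      c("prestir", "time", 0.0, 30.0, "min"),
      c("add_acid", "volume", 0.50, 3.00, "mL"),
      c("add_isocyanide", "volume", 0.10, 1.00, "mL"),
      c("stir_rxn", "time", 2.0, 18.0, "h"),
      c("heat_rxn", "temp", 25.0, 60.0, "degC")),
    products = list(ugi_product = list(bumps = list(list(
      center = c(0.72, 0.35, 0.60, 0.55, 0.70, 0.80),
      width = c(0.35, 0.60, 0.40, 0.35, 0.45, 0.30), amp = 0.85)),
      gate = 0L)),
    species = list(standard = "difluorobenzene",
                   sm = c("fluorobenzoic_acid"),
                   consumes = list(ugi_product = "fluorobenzoic_acid")),
    modality = "nmr19f"),
  vanleusen = list(
    specs = list(
      c("add_tosmic", "volume", 4.10, 6.15, "mL"),
      c("add_dbu", "volume", 0.15, 0.31, "mL"),
      c("stir_rxn", "time", 30, 180, "min"),
      c("heat_rxn", "temp", 25.0, 75.0, "degC")),
    products = list(
      oxazole = list(bumps = list(list(center = c(0.60, 0.70, 0.65, 0.55),
                                       width = c(0.35, 0.35, 0.40, 0.35),
                                       amp = 0.80)), gate = 0L),
      impurity = list(bumps = list(list(center = c(0.20, 0.15, 0.85, 0.95),
                                        width = c(0.45, 0.40, 0.50, 0.45),
                                        amp = 0.60)), gate = 0L)),
    species = list(standard = "naphthalene", sm = c("tosmic"),
                   consumes = list(oxazole = "tosmic", impurity = "tosmic")),
    modality = "hplc_dad"),
  epoxidation = list(
    specs = list(
      c("add_mnso4", "volume", 0.5, 5.0, "mL"),
      c("add_nahco3", "volume", 0.5, 5.0, "mL"),
      c("add_h2o2", "volume", 1.0, 5.0, "mL"),
      c("add_h2o2", "rate", 0.04, 10.00, "mL/min", "log"),
      c("stir_rxn", "time", 1.0, 10.0, "h")),
    products = list(epoxide = list(bumps = list(
      list(center = c(0.55, 0.50, 0.65, 0.35, 0.70),
           width = c(0.40, 0.45, 0.40, 0.25, 0.45), amp = 0.93),
      list(center = c(0.10, 0.90, 0.20, 0.90, 0.15),
           width = rep(0.12, 5), amp = 0.25)), gate = 0L)),
    species = list(standard = "acetonitrile", sm = c("styrene_sulfonate"),
                   consumes = list(epoxide = "styrene_sulfonate")),
    modality = "raman"),
  discovery = list(
    specs = list(
      c("add_cyclohexenone", "volume", 0.0, 2.0, "mL"),
      c("add_fluoroacetophenone", "volume", 0.0, 2.0, "mL"),
      c("add_butyrolactone", "volume", 0.0, 2.0, "mL"),
      c("add_myrtenal", "volume", 0.0, 2.0, "mL")),
    products = list(
      cf3_adduct_1 = list(bumps = list(list(
        center = c(0.80, 0.20, 0.30, 0.20),
        width = c(0.35, 0.45, 0.50, 0.45), amp = 0.75)), gate = 1L),
      cf3_adduct_2 = list(bumps = list(list(
        center = c(0.20, 0.80, 0.20, 0.30),
        width = c(0.45, 0.35, 0.45, 0.50), amp = 0.70)), gate = 2L),
      cf3_adduct_3 = list(bumps = list(list(
        center = c(0.30, 0.25, 0.80, 0.25),
        width = c(0.50, 0.45, 0.35, 0.45), amp = 0.65)), gate = 3L)),
    species = list(standard = "fluorobenzene",
                   sm = c("fluoroacetophenone_sm", "cf3_source"),
                   consumes = list(cf3_adduct_1 = "cf3_source",
                                   cf3_adduct_2 = "cf3_source",
                                   cf3_adduct_3 = "cf3_source")),
    modality = "nmr19f_discovery")
)

#' Build a documented reaction response surface
#'
#' Bounds match the campaign the surface emulates: \code{ugi} (6
#' continuous dimensions), \code{vanleusen} (4 dimensions, product and
#' impurity objectives), \code{epoxidation} (5 dimensions including an
#' oxidant addition rate of 0.04--10.00 mL/min on a log scale) and
#' \code{discovery} (4 substrate amounts feeding 3 latent products with
#' disjoint optimal regions).
#'
#' @param kind surface name.
#' @param seed integer seed controlling observation noise draws.
#' @param noiseSd observation noise on the latent yield (default 0.01).
#' @return a \code{ReactionSurface}; its \code{optimum} slot documents the
#'   location and noise-free value of the global optimum of the first
#'   (main) product.
#' @export
makeSurface <- function(kind = c("ugi", "vanleusen", "epoxidation",
                                 "discovery"), seed = 1L, noiseSd = 0.01) {
  kind <- match.arg(kind)
  def <- .surfaceDefs[[kind]]
  specs <- lapply(def$specs, function(a)
    paramSpec(a[1], a[2], as.numeric(a[3]), as.numeric(a[4]), a[5],
              if (length(a) >= 6) a[6] else "linear"))
  main <- def$products[[1]]
  best <- main$bumps[[which.max(vapply(main$bumps, `[[`, numeric(1),
                                       "amp"))]]
  optX <- best$center
  optVal <- productYield(optX, main, specs)
  optAssign <- denormalizeAssignment(optX, specs)
  new("ReactionSurface", name = kind, specs = specs,
      products = def$products,
      species = c(def$species, list(modality = def$modality)),
      noiseSd = noiseSd,
      optimum = list(assignment = optAssign, value = optVal,
                     product = names(def$products)[1]),
      seed = as.integer(seed))
}

bumpValue <- function(x, bumps) {
  v <- sum(vapply(bumps, function(b)
    b$amp * exp(-0.5 * sum(((x - b$center) / b$width)^2)), numeric(1)))
  min(1, max(0, v))
}

## a gated product vanishes when its substrate volume is zero: the bump
## value is multiplied by 1 - exp(-(v / 0.3 mL)^2) of the physical
## substrate volume, ~1 everywhere except near the zero boundary
productYield <- function(x, product, specs) {
  v <- bumpValue(x, product$bumps)
  g <- product$gate
  if (!is.null(g) && g > 0) {
    s <- specs[[g]]
    lo <- s@lower@value
    up <- qIn(s@upper, s@lower@unit)
    phys <- lo + x[g] * (up - lo)
    v <- v * (1 - exp(-(phys / 0.3)^2))
  }
  v
}

#' Noise-free latent yield of each product at an assignment
#' @param surface a \code{ReactionSurface}.
#' @param assignment a \code{paramAssignment} (or unit-box numeric vector).
#' @return named numeric vector of yields in [0,1].
#' @export
latentYields <- function(surface, assignment) {
  x <- if (is.numeric(assignment)) assignment
       else normalizeAssignment(assignment, surface@specs)
  vapply(surface@products, function(p) productYield(x, p, surface@specs),
         numeric(1))
}

## deterministic per-(assignment, seed) noise stream
mixSeed <- function(seed, vals) {
  h <- as.numeric(seed) %% 2147483563
  for (v in vals) {
    h <- (h * 31 + (floor(abs(v) * 1e6) %% 1000003)) %% 2147483563
  }
  as.integer(h)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Run the simulated reaction at an assignment
#'
#' @param surface a \code{ReactionSurface}.
#' @param assignment a \code{paramAssignment} within bounds.
#' @param seed integer; the composition is deterministic per
#'   (assignment, seed).
#' @return named numeric vector of relative concentrations: products at
#'   their (noisy) yields, starting materials depleted accordingly, and
#'   the internal standard fixed at 1.
#' @export
evaluateReaction <- function(surface, assignment, seed = 1L) {
  x <- normalizeAssignment(assignment, surface@specs)
  y <- latentYields(surface, x)
  if (surface@noiseSd > 0) {
    eps <- withSeed(mixSeed(seed, x),
                    stats::rnorm(length(y), 0, surface@noiseSd))
    y[] <- pmin(1, pmax(0, y + eps))
  }
  sp <- surface@species
  comp <- y
  for (sm in sp$sm) {
    consumed <- 0
    for (pn in names(sp$consumes))
      if (identical(sp$consumes[[pn]], sm)) consumed <- consumed + y[[pn]]
    comp[[sm]] <- max(0, 1 - consumed)
  }
  comp[[sp$standard]] <- 1.0
  comp
}

## ---- spectrum models --------------------------------------------------

.spectrumModels <- list(
  nmr19f = list(modality = "nmr19f", kind = "ppm",
                axis = seq(-130, -100, length.out = 3000),
                lines = data.frame(
                  species = c("ugi_product", "fluorobenzoic_acid",
                              "difluorobenzene"),
                  position = c(-111.2, -107.0, -120.0),
                  width = c(0.08, 0.08, 0.08), shape = "lorentzian",
                  response = 1, stringsAsFactors = FALSE),
                baselineAmp = 0, noiseSd = 0),
  hplc_dad = list(modality = "hplc_dad", kind = "minutes",
                  axis = seq(0, 10, length.out = 2000),
                  lines = data.frame(
                    species = c("tosmic", "oxazole", "impurity",
                                "naphthalene"),
                    position = c(2.8, 4.2, 5.1, 6.5),
                    width = 0.06, shape = "gaussian", response = 1,
                    stringsAsFactors = FALSE),
                  baselineAmp = 0, noiseSd = 0),
  raman = list(modality = "raman", kind = "cm-1",
               axis = seq(400, 3200, length.out = 2800),
               lines = data.frame(
                 species = c("styrene_sulfonate", "epoxide", "acetonitrile"),
                 position = c(1633, 1260, 2250),
                 width = 12, shape = "gaussian", response = 1,
                 stringsAsFactors = FALSE),
               baselineAmp = 0, noiseSd = 0),
  nmr19f_discovery = list(modality = "nmr19f_discovery", kind = "ppm",
                          axis = seq(-130, -50, length.out = 4000),
                          lines = data.frame(
                            species = c("cf3_adduct_1", "cf3_adduct_2",
                                        "cf3_adduct_3", "cf3_source",
                                        "fluoroacetophenone_sm",
                                        "fluorobenzene"),
                            position = c(-78.5, -72.3, -65.8, -66.9,
                                         -106.2, -113.1),
                            width = 0.15, shape = "lorentzian", response = 1,
                            stringsAsFactors = FALSE),
                          baselineAmp = 0, noiseSd = 0)
)

#' Spectrum model for a modality
#'
#' @param modality "nmr19f", "hplc_dad", "raman" or "nmr19f_discovery".
#' @param baselineAmp baseline drift amplitude added to the model.
#' @param noiseSd Gaussian intensity noise sd.
#' @return a spectrum model list (axis, line table, noise settings).
#' @export
spectrumModel <- function(modality, baselineAmp = NULL, noiseSd = NULL) {
  m <- .spectrumModels[[modality]]
  if (is.null(m)) stop(sprintf("unknown modality '%s'", modality),
                       call. = FALSE)
  if (!is.null(baselineAmp)) m$baselineAmp <- baselineAmp
  if (!is.null(noiseSd)) m$noiseSd <- noiseSd
  m
}

#' Synthesize a spectrum from a composition
#'
#' Intensity is the sum over species of response x concentration x unit
#' lineshape, plus a smooth baseline drift and Gaussian noise.  Before
#' noise, each species' band area is proportional to its concentration.
#'
#' @param composition named concentrations (see
#'   \code{\link{evaluateReaction}}); every species present must have a
#'   line assignment in the model.
#' @param model a \code{\link{spectrumModel}}.
#' @param seed integer controlling the noise draw.
#' @return a \code{Spectrum}.
#' @export
synthSpectrum <- function(composition, model, seed = 1L) {
  ax <- model$axis
  y <- numeric(length(ax))
  for (sp in names(composition)) {
    row <- model$lines[model$lines$species == sp, , drop = FALSE]
    if (nrow(row) == 0)
      stop(sprintf("species '%s' has no line assignment", sp), call. = FALSE)
    conc <- composition[[sp]]
    if (conc <= 0) next
    for (j in seq_len(nrow(row)))
      y <- y + conc * row$response[j] *
        lineshape(ax, row$position[j], row$width[j], row$shape[j])
  }
  if (model$baselineAmp > 0) {
    span <- diff(range(ax))
    y <- y + model$baselineAmp *
      (0.5 + 0.5 * sin(2 * pi * (ax - ax[1]) / span) +
       0.3 * (ax - ax[1]) / span)
  }
  if (model$noiseSd > 0)
    y <- y + withSeed(mixSeed(seed, c(length(ax), unlist(composition))),
                      stats::rnorm(length(ax), 0, model$noiseSd))
  new("Spectrum", axis = ax, intensity = y, kind = model$kind,
      metadata = list(modality = model$modality))
}

lineshape <- function(x, pos, width, shape) {
  if (shape == "lorentzian") width^2 / ((x - pos)^2 + width^2)
  else exp(-(x - pos)^2 / (2 * width^2))
}

## closed-form area of a unit-height lineshape
lineshapeArea <- function(width, shape) {
  if (shape == "lorentzian") pi * width else width * sqrt(2 * pi)
}

#' Synthesize a free induction decay
#'
#' FID(t) = sum_k a_k exp(2 pi i f_k t - t / T2_k) plus complex Gaussian
#' noise.
#'
#' @param amplitudes named numeric amplitudes per species.
#' @param frequencies named numeric offsets in Hz (same names).
#' @param dwell dwell time, s.
#' @param points number of complex points (>= 2).
#' @param t2 transverse relaxation time(s), s (scalar or per species).
#' @param noiseSd complex noise sd per quadrature component.
#' @param frequencyMHz spectrometer frequency for the ppm axis.
#' @param seed integer noise seed.
#' @return an \code{FID}.
#' @export
synthFid <- function(amplitudes, frequencies, dwell = 1e-3, points = 2048,
                     t2 = 0.5, noiseSd = 0, frequencyMHz = 75.4, seed = 1L) {
  stopifnot(points >= 2, dwell > 0)
  t <- (seq_len(points) - 1) * dwell
  sig <- complex(real = numeric(points), imaginary = numeric(points))
  t2 <- rep_len(t2, length(amplitudes))
  for (i in seq_along(amplitudes)) {
    f <- frequencies[[names(amplitudes)[i]]]
    sig <- sig + amplitudes[[i]] *
      exp(complex(imaginary = 2 * pi * f * t) - t / t2[i])
  }
  if (noiseSd > 0) {
    sig <- sig + withSeed(mixSeed(seed, c(points, unlist(amplitudes))), {
      complex(real = stats::rnorm(points, 0, noiseSd),
              imaginary = stats::rnorm(points, 0, noiseSd))
    })
  }
  new("FID", samples = sig, dwell = dwell, frequencyMHz = frequencyMHz)
}

## ---- sensor traces ----------------------------------------------------

#' Simulate sensor traces for an action schedule
#'
#' Temperature follows dT/dt = -k (T - T_set) + q r(t), colour gains
#' chromophore impulses and decays first-order, the liquid trace is 1
#' while any addition is pumping; all integrated by fixed-step explicit
#' Euler at dt = 1 s.
#'
#' @param scenario an \code{\link{exothermScenario}}.
#' @param schedule list of actions: \code{list(time=, type="add", volume=,
#'   rate=, chromophore=FALSE)} or \code{list(time=, type="setpoint",
#'   value=)}; times in s, volume mL, rate mL/s.
#' @param horizon total simulated time, s.
#' @param seed integer (deterministic model; recorded only).
#' @return data.frame(time, temperature, colour, liquid).
#' @export
synthSensorTraces <- function(scenario, schedule = list(), horizon = 600,
                              seed = 1L) {
  times <- vapply(schedule, `[[`, numeric(1), "time")
  stopifnot(!is.unsorted(times))
  n <- as.integer(horizon)
  temp <- colour <- liquid <- numeric(n + 1)
  temp[1] <- scenario$ambient
  setpt <- scenario$setpoint
  ## remaining volume of each addition action
  vols <- vapply(schedule, function(a)
    if (a$type == "add") a$volume else 0, numeric(1))
  for (i in seq_len(n)) {
    t <- i - 1
    addRate <- 0; colourRate <- 0; pumping <- 0
    for (j in seq_along(schedule)) {
      a <- schedule[[j]]
      if (a$type == "setpoint" && t >= a$time) setpt <- a$value
      if (a$type == "add" && t >= a$time && vols[j] > 1e-12) {
        r <- min(a$rate, vols[j])
        vols[j] <- vols[j] - r
        addRate <- addRate + r
        pumping <- 1
        if (isTRUE(a$chromophore))
          colourRate <- colourRate + scenario$colourPerML * r
      }
    }
    temp[i + 1] <- temp[i] + (-scenario$coolingK * (temp[i] - setpt) +
                              scenario$heatPerML * addRate)
    colour[i + 1] <- colour[i] + (-colour[i] / scenario$tau + colourRate)
    liquid[i + 1] <- pumping
  }
  data.frame(time = 0:n, temperature = temp, colour = colour,
             liquid = liquid)
}
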