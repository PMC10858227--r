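## Ready-made campaign fixtures: an initial (literature-conditions)
## procedure, the optimize config with the campaign's parameter bounds,
## the matching simulated response surface, spectrum model and objective.

#' Fixture bundle for a simulated campaign
#'
#' @param kind "ugi", "vanleusen", "epoxidation" or "discovery".
#' @param noiseSd surface observation noise (default 0.01).
#' @return list(procedure=, optimizeConfig=, surface=, model=, objective=).
#' @export
campaignFixture <- function(kind = c("ugi", "vanleusen", "epoxidation",
                                     "discovery"), noiseSd = 0.01) {
  kind <- match.arg(kind)
  surface <- makeSurface(kind, noiseSd = noiseSd)
  proc <- fixtureProcedure(kind)
  cfgEntries <- lapply(.surfaceDefs[[kind]]$specs, function(a)
    list(step = a[1], property = a[2], lower = as.numeric(a[3]),
         upper = as.numeric(a[4]), unit = a[5],
         scale = if (length(a) >= 6) a[6] else "linear"))
  list(procedure = proc, optimizeConfig = cfgEntries, surface = surface,
       model = spectrumModel(.surfaceDefs[[kind]]$modality),
       objective = fixtureObjective(kind))
}

fixtureProcedure <- function(kind) {
  switch(kind,
    ugi = procedure("ugi", list(
      step("add_ald", "Add", reagent = "benzaldehyde", volume = "0.2 mL"),
      step("add_amine", "Add", reagent = "benzylamine", volume = "0.5 mL"),
      step("prestir", "Stir", time = "5 min"),
      step("add_acid", "Add", reagent = "fluorobenzoic_acid",
           volume = "1.0 mL"),
      step("add_isocyanide", "Add", reagent = "isocyanide",
           volume = "0.42 mL"),
      step("heat_rxn", "HeatChill", temp = "25 degC"),
      step("stir_rxn", "Stir", time = "4 h"),
      step("add_std", "Add", reagent = "difluorobenzene", volume = "5 mL"),
      step("analyze", "Analyze", instrument = "nmr",
           sample_volume = "2.5 mL")),
      metadata = list(title = "Four-component condensation")),
    vanleusen = procedure("vanleusen", list(
      step("add_tosmic", "Add", reagent = "tosmic", volume = "4.1 mL"),
      step("add_ald", "Add", reagent = "formylbenzonitrile",
           volume = "4.1 mL"),
      step("add_dbu", "Add", reagent = "dbu", volume = "0.15 mL"),
      step("add_meoh", "Add", reagent = "methanol", volume = "5 mL"),
      step("heat_rxn", "HeatChill", temp = "25 degC"),
      step("stir_rxn", "Stir", time = "60 min"),
      step("analyze", "Analyze", instrument = "hplc",
           sample_volume = "5 mL")),
      metadata = list(title = "Oxazole synthesis")),
    epoxidation = procedure("epoxidation", list(
      step("add_mnso4", "Add", reagent = "mnso4", volume = "0.5 mL"),
      step("add_sm", "Add", reagent = "styrene_sulfonate",
           volume = "5.0 mL"),
      step("add_nahco3", "Add", reagent = "nahco3", volume = "0.5 mL"),
      step("add_h2o2", "Add", reagent = "h2o2", volume = "1.0 mL",
           rate = "1.0 mL/min"),
      step("stir_rxn", "Stir", time = "2 h"),
      step("analyze", "Analyze", instrument = "raman")),
      metadata = list(title = "Catalytic epoxidation")),
    discovery = procedure("discovery", list(
      step("add_cyclohexenone", "Add", reagent = "cyclohexenone",
           volume = "0.20 mL"),
      step("add_fluoroacetophenone", "Add", reagent = "fluoroacetophenone",
           volume = "0.23 mL"),
      step("add_butyrolactone", "Add", reagent = "butyrolactone",
           volume = "0.16 mL"),
      step("add_myrtenal", "Add", reagent = "myrtenal", volume = "0.30 mL"),
      step("add_cf3", "Add", reagent = "cf3_source", volume = "0.9 mL"),
      step("stir_rxn", "Stir", time = "5 min"),
      step("add_std", "Add", reagent = "fluorobenzene", volume = "2 mL"),
      step("analyze", "Analyze", instrument = "nmr",
           sample_volume = "2.5 mL")),
      metadata = list(title = "Trifluoromethylation exploration")))
}

## regions in native axis units of the fixture's modality
fixtureObjective <- function(kind) {
  switch(kind,
    ugi = objectiveSpec("auc_ratio",
      regions = list(product = region(-111.2, 0.5),
                     std = region(-120.0, 0.5)),
      reference = "std"),
    vanleusen = objectiveSpec("desirability",
      regions = list(product = region(4.2, 0.3),
                     impurity = region(5.1, 0.3),
                     std = region(6.5, 0.3)),
      reference = "std", weights = c(0.5, 0.5),
      components = list(
        product_ratio = list(kind = "scaled_ratio", region = region(4.2, 0.3)),
        purity = list(kind = "purity", region = region(4.2, 0.3)))),
    epoxidation = objectiveSpec("raman_conversion",
      regions = list(product = region(1633, 30), std = region(2250, 30)),
      reference = "std"),
    discovery = objectiveSpec("novelty",
      regions = list(cf3_source = region(-66.9, 0.3),
                     fluoroacetophenone_sm = region(-106.2, 0.3),
                     std = region(-113.1, 0.3)),
      reference = "std"))
}

#' Spectrum positions of the discovery surface's latent products
#' @return named numeric vector of apex positions (ppm).
#' @export
discoveryProductPositions <- function() {
  lines <- .spectrumModels$nmr19f_discovery$lines
  idx <- grepl("^cf3_adduct_", lines$species)
  stats::setNames(lines$position[idx], lines$species[idx])
}

## noise-free time-zero composition (all yields 0) for conversion targets
timeZeroComposition <- function(surface) {
  comp <- stats::setNames(numeric(length(surface@products)),
                          names(surface@products))
  for (sm in surface@species$sm) comp[[sm]] <- 1
  comp[[surface@species$standard]] <- 1
  comp
}
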