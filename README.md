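# chemloop

Closed-loop ("self-driving laboratory") chemistry engines couple a
programmable synthesis platform to in-line analytics and an optimizer:
a procedure is executed with sensor feedback, the reaction outcome is
quantified from a spectrum, an algorithm suggests the next conditions,
and the updated, versioned procedure runs again. chemloop implements
that whole loop at desk scale in R, for method developers and
automation researchers who want to study, test or teach closed-loop
reaction development without a robot: every component — procedure
dialect, dynamic execution, spectra, objectives, optimizer, scheduler,
campaign database — runs against a simulated laboratory and is
reproducible from a seed on one CPU.

The package provides:

- a **procedure dialect**: YAML documents of chemical unit operations
  (`Add`, `Stir`, `HeatChill`, `Analyze`, ...) with unit-carrying
  quantities, canonical byte-stable serialization, and pure
  version-incrementing parameter updates (`proc_v0 ... proc_vN`);
- **dynamic steps** with a three-method lifecycle
  (start/continue/finish): temperature-gated chunked addition
  (`DynamicAdd`), rate-of-change colour endpoint detection (`DoUntil`),
  and binary liquid-sensor transfers (`DynamicTransfer`);
- a **simulated laboratory**: an exotherm model
  dT/dt = −k(T − T_set) + q·r(t) integrated by 1 s explicit Euler,
  colour and liquid sensor traces, documented reaction response
  surfaces mirroring the parameter ranges of four literature
  campaigns, and
  synthetic NMR / HPLC / Raman spectra and FIDs whose band areas are
  linear in concentration;
- an **analytical chain**: zero-filling, exponential apodization,
  Fourier transform, asymmetric-least-squares baseline, prominence
  peak picking, trapezoidal integration;
- **objectives**: product/standard area ratio, purity, desirability,
  conversion (1 − r(t)/r(0)), novelty counting, weighted composites —
  all internal-standard normalized and crash-free on failed analyses;
- **optimizers** behind one interface: staged Gaussian-process SMBO
  (Matérn-5/2 surrogate; posterior-sd / expected-improvement /
  posterior-mean acquisitions over a 5/14/5/6
  random-explore-balanced-exploit schedule), random search, Latin
  hypercube designs, a genetic algorithm, and an adapter contract for
  external frameworks;
- a **scheduler and lock manager** for parallel reactors sharing a
  liquid-handling backbone and an analyzer (greedy list scheduling,
  ordered all-or-nothing locking, replay checking);
- a **campaign driver** with an append-only JSONL database, exact
  kill-and-resume, two-campaign restarts in expanded parameter spaces,
  a three-phase exploration-to-optimization discovery pipeline, and
  report tables for parallel-coordinates and best-so-far plots.

## Worked example: a 30-iteration optimization campaign

The bundled fixture mirrors a six-parameter four-component condensation
(amine, pre-stir time, acid, isocyanide, reaction time, temperature)
whose target is the product peak area relative to an internal standard
on a ¹⁹F NMR spectrum:

```r
library(chemloop)

proc <- readProcedure(system.file("extdata", "ugi_v0.chemdsl.yaml",
                                  package = "chemloop"))
cfg  <- readOptimizeConfig(system.file("extdata", "ugi_optimize.yaml",
                                       package = "chemloop"))
length(extractParameters(proc, cfg))
#> [1] 6

camp <- campaignConfig("ugi", dir = file.path(tempdir(), "ugi-demo"),
                       budget = 30, strategy = strategyConfig("smbo"),
                       seed = 42)
out <- runCampaign(camp)
sprintf("best %.4f at iteration %d (stage %s)",
        out$best$objective, out$best$iteration, out$best$stage)
#> [1] "best 0.7607 at iteration 29 (stage exploit)"
```

The objective is the product-to-standard area ratio, so 0.7607 means
the product band integrates to ~76% of the internal-standard band —
found by an exploitation-stage suggestion (52.4 degC, 12.6 h, amine
0.775 mL) after 5 random, 14 exploration and 5 balanced iterations; the
literature-style starting conditions score 0. The campaign directory
now holds `ugi_v0 ... ugi_v30.chemdsl.yaml` and `records.jsonl`;
`campaignReport(out$records)` tabulates all parameters per iteration
(with objective terciles) and the non-decreasing best-so-far series.

Feedback-controlled execution, standalone:

```r
be <- simLabBackend()   # exotherm: 7 degC/mL, cooling 0.01 1/s
runProcedure(procedure("b", list(
  step("a", "Add", reagent = "h2o2", volume = "10 mL"))), be)
maxLoggedTemperature(be)
#> [1] 88.6         # a plain 10 mL bolus overshoots
```

whereas the same volume through `DynamicAdd` with a 75 degC gate stays
at 50.3 degC while delivering all ten 1 mL chunks (see
`scripts/acceptance.R` below).

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/chemloop run --kind vanleusen --dir camp \
        --budget 8 --algorithm random --seed 4
# campaign 'vanleusen': 8 iterations, best objective 0.3033 (iteration 8)
Rscript inst/scripts/chemloop discover --seed 3 --budget 12
# catalogued 3 product region(s) ...
```

## Package layout

| module | contents |
|---|---|
| `R/quantity.R`, `R/procedure.R`, `R/parse.R`, `R/parameters.R` | dialect, units, parameter machinery |
| `R/backend.R`, `R/dynamic.R` | simulated backend and dynamic interpreter |
| `R/simlab.R`, `R/fixtures.R` | surfaces, spectra/FID generators, campaign fixtures |
| `R/spectra-*.R` | Spectrum/FID classes and the processing chain |
| `R/objectives.R` | spectrum-to-scalar objectives |
| `R/gp.R`, `R/optimize.R` | GP surrogate, acquisitions, strategies |
| `R/scheduler.R`, `R/locking.R` | parallel scheduling and locking |
| `R/campaign.R`, `R/discovery.R`, `R/report.R` | campaign loop, restarts, discovery, reports |

The methods vignette (`vignettes/chemloop-methods.Rmd`) documents the
models, defaults and design decisions in detail.
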