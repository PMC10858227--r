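---
title: "Models and methods behind chemloop"
author: "chemloop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemloop)
```

chemloop is a desk-scale implementation of a closed-loop ("self-driving
laboratory") chemistry engine: procedures written in a structured dialect
are executed with sensor feedback, analysed by a synthetic-spectroscopy
chain, scored by spectrum-derived objectives, and improved by staged
model-based optimization — all against a simulated laboratory, so every
result in this package is reproducible from a seed on a single CPU.
This vignette documents the models, the defaults, and the choices made
where the design was genuinely open.

## The procedure dialect and versioning

Procedures are trees of chemical unit operations (`Add`, `Transfer`,
`Stir`, `HeatChill`, `Wait`, `Analyze`, and the dynamic steps
`DynamicAdd`, `DynamicTransfer`, `DoUntil`).  Every numeric property is
a `Quantity` carrying one unit from a closed enum (mL, mmol, min, h, s,
degC, mL/min, mol/L, dimensionless) with exact conversions inside each
dimension; there is deliberately no general dimensional-analysis engine
— the closed enum covers all operations this domain needs and keeps
conversions exact.  Serialization is canonical (fixed key order, six
significant digits, ASCII unit names, "." decimal point), so that
versioned procedure files diff cleanly and byte-compare across
platforms.  `applyAssignment` is pure and bumps the version on *every*
iteration, including an empty assignment: the campaign database then
maps one iteration to exactly one `*_v<k>.chemdsl.yaml` file, which is
what makes the audit trail and the resume semantics trivial to verify.

The dialect is YAML-structured rather than XML: the document model
(steps, unit-carrying properties, children) is the portable part, and a
plain-text canonical form keeps it diffable and round-trip exact; an
XML import shim would add surface without substance.

## Dynamic execution

Dynamic steps follow a three-method lifecycle — `onStart`, `onContinue`,
`onFinish`, each returning a list of steps to execute — and the
interpreter loops `onContinue` until it returns nothing, then runs
`onFinish` once.  A guard of $10^4$ expansions per dynamic step bounds
non-terminating predicates.

**Temperature-gated addition** (`DynamicAdd`).  The reagent is delivered
in chunks (default 1 mL) at a controlled pump rate (default 3 mL/min);
before each chunk the internal temperature is polled and `Wait` steps
(default 30 s) are inserted while the vessel lacks one hysteresis band
(default 2 degC) of headroom below the threshold.  Requiring headroom —
rather than gating at the threshold itself — is a deliberate choice:
a chunk that starts at the threshold would overshoot it by its own
adiabatic rise, whereas with the headroom rule the logged maximum stays
at or below the threshold whenever a chunk's rise is within the
hysteresis band.  The same band suppresses chattering of the bang-bang
controller.  If the gate stays closed for a configurable wait budget
(default 1 h) the step aborts with a thermal-runaway error and the log
intact.

**Endpoint detection** (`DoUntil` with the colour-gradient predicate).
Absolute sensor levels drift with ambient light, so the predicate uses
the *rate* of colour change: the per-second gradient is smoothed by a
centered moving average (width 5 readings), the predicate "arms" once
the smoothed magnitude exceeds `armThreshold` (change was actually
observed) and fires when it has fallen below `gradThreshold`.  On a
first-order consumption trace $c(t) = e^{-t/\tau}$ the noiseless
gradient crosses a threshold $g$ at $t^\ast = -\tau\log(g\tau)$, and the
tests verify firing within two polling intervals of an offline scan of
the same trace.

**Liquid-sensor transfer** (`DynamicTransfer`).  The line sensor is
binary (1 = filled, 0 = empty).  Transfer proceeds in 1 s pump
increments and stops after `k_empty` consecutive empty readings
(default 3); a line that never primes within 10 increments is an error.
Transferred volume is increments times increment volume.

## The simulated laboratory

The backend models one well-mixed vessel with

$$\frac{dT}{dt} = -k\,(T - T_{set}) + q\,r(t),$$

where $k$ is a first-order cooling constant (default 0.01 s$^{-1}$),
$q$ a heat impulse per mL added (default 7 degC/mL) and $r(t)$ the
addition rate in mL/s; colour gains impulses from chromophore additions
and decays with time constant $\tau$ (default 300 s).  Integration is
fixed-step explicit Euler at $dt = 1$ s — adaptive solvers buy nothing
at these time scales.  Passive segments (no addition) use the closed
form of the same discrete recurrence, sampled at up to 600 points, so
hour-long stirring steps cost microseconds while remaining bit-identical
to the per-second Euler sequence.  Plain `Add` steps pump at 2 mL/s
(a fast manual pour); with $q = 7$ degC/mL a 10 mL bolus from 20 degC
then peaks near 88 degC, while the gated dynamic addition stays around
50 degC — the headroom that makes the thermal-control demonstration
meaningful rather than marginal.

**Response surfaces.**  Four documented surfaces mirror the parameter
ranges of four literature campaigns: a six-parameter four-component condensation
(amine 0.10–1.00 mL, pre-stir 0–30 min, acid 0.50–3.00 mL, isocyanide
0.10–1.00 mL, 2–18 h, 25–60 degC), a four-parameter oxazole synthesis
(two objectives: product and impurity), a five-parameter catalytic
epoxidation (including an oxidant addition rate of 0.04–10.00 mL/min,
log-scaled because it spans 2.4 decades), and a four-substrate discovery
space feeding three latent products.  Latent yields are sums of 1–3
anisotropic Gaussian bumps on the unit box, rescaled to the physical
bounds.  This family was chosen because it is smooth, nontrivial for an
optimizer (anisotropic, off-center optima), and has *documented* optima:
with a single dominant bump the optimum is its center by construction
and is verified in the tests against all $2^d$ corners.  The initial
(literature-style) procedure conditions sit well below each optimum.
Discovery products carry a substrate gate
$1 - \exp(-(v/0.3\,\mathrm{mL})^2)$ so a product vanishes when its
substrate volume is zero and "appears" only where its substrate
dominates.  Observation noise (default sd 0.01 on the yield scale) is
drawn from a stream keyed on (assignment, seed), making every
composition a pure function of its inputs.

What these surfaces do **not** emulate: real reaction kinetics,
side-product networks, drift between runs, or instrument artefacts.
Passing tests therefore demonstrate the correctness of the *engine* —
control, quantification, optimization, bookkeeping — not chemical
accuracy of any particular landscape.

**Spectra.**  Each species has a line assignment (position, Lorentzian
or Gaussian shape, width, response factor); intensity is the sum of
concentration-scaled unit lineshapes, plus optional baseline drift and
Gaussian noise, so band area is exactly linear in concentration before
noise.  Time-domain NMR signals are synthesized as
$\sum_k a_k e^{2\pi i f_k t - t/T_2}$ with complex noise.

## The analytical chain

The default NMR route is zero-fill (x2) → exponential apodization →
magnitude spectrum → asymmetric-least-squares baseline → peak picking →
trapezoidal integration.  Magnitude mode suffices for the area *ratios*
the objectives consume (both bands lose the same wing fraction over
equal windows); a phased mode (0th/1st order, minimizing imaginary
content in the spectrum edges) exists for width measurements.  Baseline
correction is Eilers-style ALS with $\lambda = 10^5$, $p = 0.01$, 10
iterations by default.  Peak picking filters local maxima by height,
topographic prominence and separation; integration bounds sit at 1% of
apex height or the midpoint to the nearest neighbour, whichever is
closer — this bounds heuristic is the package's own choice.
Objectives re-integrate matched bands over a symmetric window (apex ±
region tolerance): with asymmetric peak bounds a Lorentzian's fat wings
are truncated differently for product and reference, biasing the ratio;
the symmetric window makes the truncation cancel, and the chain then
recovers known composition ratios within 2% at zero noise (verified
from 10% to 95% product concentration).

## Objectives

All quantitative objectives are built on internal-standard-normalized
areas and are therefore invariant to global intensity scaling (tested by
multiplying spectra by 7.3): the product/reference area ratio; purity
(product area over the sum of all picked peak areas); desirability (a
convex combination of objectives pre-scaled to [0,1]; unbounded ratios
are squashed as $r/(1+r)$); conversion
$1 - r(t)/r(0)$ with $r$ the starting-material-to-standard area ratio,
clipped to [0,1]; and a novelty score.  No standard definition of a novelty score
exists, so the implemented one — the count of picked peaks whose apex
falls in no known or excluded region, with the spectrum
height-normalized to the internal standard and the novel regions
returned for cataloguing — is this package's own documented choice.  Composite objectives
reference-normalize every component and combine
$\sum w^+ c - \sum w^- c$ (default weights 1 for the product, 0.5 per
penalized peak).  Failed analyses (missing standard, empty spectrum)
return a failed result that scores the objective floor (0) instead of
raising, so campaigns never crash on a bad reaction and budget
accounting stays exact; the floored observation still enters the
surrogate, keeping it aware of bad regions.

## Optimization

All strategies operate on the unit box ([0,1] per parameter, log-mapped
where a spec says so) and are deterministic given (history, config,
seed).  The staged sequential model-based optimizer mirrors the
published campaign schedule — 5 random initialization experiments, 14
exploration, 5 balanced, 6 exploitation — with a Gaussian-process
surrogate: Matérn-5/2 kernel, isotropic lengthscale and signal variance
refit by marginal likelihood at every iteration (a per-iteration refit
is the simplest defensible schedule for budgets of tens of runs),
outputs standardized, observation noise clamped at a floor of $10^{-6}$
so noiseless data are interpolated to $10^{-4}$.  Acquisitions:
posterior sd (explore), expected improvement over the incumbent
(balanced), posterior mean (exploit).  The acquisition is maximized by
multi-start search — 64 Latin-hypercube starts, the best eight refined
by cyclic coordinate line searches over grids shrunk 1× → 8× → 64×
(final resolution ≈ 0.002) — because a gradient-free, fully vectorized
scheme is robust to the kink EI develops at the incumbent and costs a
few milliseconds per suggestion.  Random search, Latin hypercube
designs (one point per marginal bin by construction) and a genetic
algorithm (tournament selection over the history, blend crossover,
Gaussian mutation clipped to the box; with mutation off and elitism on
the incumbent is resubmitted) sit behind the same interface, as does an
adapter contract — `function(history, specs) -> point` — for external
suggestion frameworks, which are intentionally not reimplemented.

## Scheduling and locking

Steps request resource sets (reactor, liquid-handling backbone,
analyzer) with nominal durations.  The scheduler is greedy list
scheduling — earliest feasible start among ready steps, FIFO then
procedure id on ties — chosen over exact search because makespan
minimization is NP-hard and greedy is provably near-optimal; an exhaustive-interleaving
oracle over ≤ 8-step paired-reactor instances doubles as a test that
greedy is optimal on that family and always within the classical 2×
list-scheduling bound.  The lock manager grants a step's full resource
set atomically in a fixed lexicographic order; all-or-nothing
acquisition removes hold-and-wait, so the contract is deadlock-free by
construction, and a replay checker re-validates every acquisition log
against capacities ($10^4$ randomized concurrent runs in the tests).

## Campaigns, restarts, discovery

A campaign iterates suggest → apply (new procedure version) → execute →
synthesize spectrum → evaluate → append a JSON record.  Every random
draw is keyed on (master seed, iteration), and the optimizer history is
grown from the parsed JSON record — the exact view a resumed campaign
reconstructs — so a killed-and-resumed campaign is byte-identical to an
uninterrupted one (wall-clock field aside).  Early stopping exists but
is off by default; the emulated campaigns run fixed budgets.
Parallelism batches suggestions with a constant-liar fill-in at the
incumbent value, the simplest standard batching; scheduling changes
timing, never chemistry.  A two-campaign restart re-expresses the old
history in an expanded parameter box (bounds must contain the
originals) and continues the iteration count, mirroring a
second-campaign-with-relaxed-constraints workflow.

The discovery pipeline runs three phases: (1) exploration of the
substrate space scoring novelty, with every novel peak immediately added
to the known regions so later iterations chase genuinely new signals —
random search drives this phase because novelty is integer-valued and
its own reward structure collapses as regions are catalogued, which
starves a surrogate of signal; (2) cataloguing by single-linkage
clustering of novel positions (0.5 ppm tolerance); (3) one
composite-objective campaign per catalogued product, warm-started from
the exploration history re-scored under that product's composite, then
driven by the staged optimizer.

## Problem sizes and numerical defaults

The shipped tests and the acceptance analysis use desk-scale sizes
chosen to keep the full suite within a few minutes on one CPU: 30-50
iteration campaigns, 50-seed optimizer comparisons, 100-seed discovery
sweeps, spectra of 2000-4000 points, $10^4$-run lock stress.  Key
numeric defaults: Euler $dt = 1$ s; GP noise floor $10^{-6}$;
hysteresis 2 degC; ALS $(\lambda, p) = (10^5, 0.01)$; peak bounds at 1%
of apex; six-significant-digit canonical number formatting; all seeds
32-bit.

## Known limitations

Response surfaces are synthetic stand-ins, not kinetic models; the
novelty heuristic is a documented reimplementation choice; the
GP lengthscale is isotropic (sufficient on these surfaces, cheaper to
fit from ≤ 50 points than per-dimension lengthscales); magnitude-mode
NMR slightly widens lines, so widths should be measured in phased mode;
the multi-worker contract is in-process (the network layer of a real
platform is out of scope), and no camera-based failure detection is
modelled.
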