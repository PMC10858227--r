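## Exploration-to-optimization discovery pipeline.  Phase 1 explores the
## substrate space maximizing the novelty score, with every novel peak
## found added to the known regions so later iterations chase genuinely
## new signals.  Phase 2 clusters the recorded novel positions into a
## product catalogue.  Phase 3 runs one composite-objective campaign per
## catalogued product (maximize its band, penalize the other catalogued
## bands), warm-started from the re-scored exploration history.

#' Run the discovery pipeline on the simulated substrate space
#'
#' @param seed integer master seed.
#' @param phase1Budget exploration iterations (default 30).
#' @param phase3Schedule stage schedule for each per-product campaign
#'   (default 4 explore / 3 balanced / 5 exploit on top of the warm
#'   start).
#' @param clusterTol position tolerance (ppm) when merging novel peaks
#'   into catalogue regions (default 0.5).
#' @param phases run only the first n phases (1, or 3 for all; default 3).
#' @param knownRegions extra regions treated as already known.
#' @param noiseSd surface observation noise.
#' @return list(catalogue=, phase1=, products=): the catalogued regions
#'   (data.frame position/n/name), the exploration trace, and per-product
#'   campaign summaries (bestComposite, phase1Best, history).
#' @export
exploreThenOptimize <- function(seed = 1L, phase1Budget = 30L,
                                phase3Schedule = data.frame(
                                  kind = c("explore", "balanced", "exploit"),
                                  count = c(4L, 3L, 5L)),
                                clusterTol = 0.5, phases = 3L,
                                knownRegions = list(), noiseSd = 0.01) {
  fx <- campaignFixture("discovery", noiseSd = noiseSd)
  specs <- extractParameters(fx$procedure, fx$optimizeConfig)
  ## starting materials and the internal standard are known from the off
  known <- c(fx$objective$regions, knownRegions)
  ref <- fx$objective$regions[[fx$objective$reference]]

  ## phase 1: explore, growing the known-region list as peaks are found
  history <- newHistory()
  found <- numeric(0)
  trace <- list()
  for (i in seq_len(phase1Budget)) {
    sug <- suggestNext(history, specs, strategyConfig("random"), seed)
    comp <- evaluateReaction(fx$surface, sug$assignment,
                             seed = mixSeed(seed, i))
    spec <- synthSpectrum(comp, fx$model, seed = mixSeed(seed, i))
    ns <- noveltyScore(spec, knownRegions = known, reference = ref)
    if (ns$count > 0) {
      found <- c(found, ns$novel$position)
      known <- c(known, lapply(ns$novel$position, region,
                               tolerance = clusterTol))
    }
    history <- addObservation(history, sug$x, as.numeric(ns$count), FALSE,
                              "explore")
    trace[[i]] <- list(iteration = i, novelty = ns$count,
                       positions = ns$novel$position)
  }

  catalogue <- cataloguePositions(found, clusterTol)
  out <- list(catalogue = catalogue,
              phase1 = list(history = history, trace = trace,
                            knownRegions = known))
  if (phases < 3L || nrow(catalogue) == 0) {
    out$products <- list()
    return(out)
  }

  ## phase 3: one composite campaign per catalogued region
  out$products <- lapply(seq_len(nrow(catalogue)), function(k) {
    target <- catalogue$position[k]
    others <- catalogue$position[-k]
    comps <- c(list(main = list(region = region(target, clusterTol),
                                direction = "maximize", weight = 1)),
               if (length(others) > 0)
                 stats::setNames(lapply(others, function(p)
                   list(region = region(p, clusterTol),
                        direction = "minimize", weight = 0.5)),
                   sprintf("side%d", seq_along(others))))
    objective <- objectiveSpec("composite", regions = list(std = ref),
                               reference = "std", components = comps)
    scoreAt <- function(assignment, iterSeed) {
      compn <- evaluateReaction(fx$surface, assignment, seed = iterSeed)
      spec <- synthSpectrum(compn, fx$model, seed = iterSeed)
      res <- evaluateObjective(objective, spec)
      if (res$failed) 0 else res$value
    }
    ## warm start: re-score the exploration points under this composite
    warm <- newHistory()
    for (i in seq_len(phase1Budget)) {
      a <- denormalizeAssignment(history$X[i, ], specs)
      warm <- addObservation(warm, history$X[i, ],
                             scoreAt(a, mixSeed(seed, i)), FALSE, "warm")
    }
    phase1Best <- max(warm$y)
    strat <- strategyConfig("smbo", stageSchedule = rbind(
      data.frame(kind = "random", count = phase1Budget), phase3Schedule))
    h <- warm
    budget3 <- sum(phase3Schedule$count)
    for (j in seq_len(budget3)) {
      sug <- suggestNext(h, specs, strat, mixSeed(seed, 7919L + k))
      y <- scoreAt(sug$assignment, mixSeed(seed, 1000L * k + j))
      h <- addObservation(h, sug$x, y, FALSE, sug$stage)
    }
    list(position = target, phase1Best = phase1Best,
         bestComposite = max(h$y[-seq_len(phase1Budget)]),
         history = h)
  })
  out
}

## single-linkage 1-d clustering: sort, split at gaps > tol
cataloguePositions <- function(positions, tol) {
  if (length(positions) == 0)
    return(data.frame(position = numeric(0), n = integer(0)))
  p <- sort(positions)
  grp <- cumsum(c(1, diff(p) > tol))
  agg <- vapply(split(p, grp), stats::median, numeric(1))
  data.frame(position = unname(agg),
             n = as.integer(table(grp)))
}
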