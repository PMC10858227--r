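## Suggestion strategies behind one interface: random search, Latin
## hypercube designs, staged GP-based sequential model-based optimization
## and a genetic algorithm.  All strategies work on the unit box and emit
## in-bounds assignments; (history, config, seed) fully determine the
## suggestion.

#' Configure a suggestion strategy
#'
#' @param algorithm "random", "doe_lhs", "smbo", "ga" or "adapter".
#' @param stageSchedule for smbo: data.frame(kind, count) with kinds from
#'   \{random, explore, balanced, exploit\}; the default is the staged
#'   schedule used for the six-parameter condensation campaign: 5 random
#'   initialization experiments, 14 exploration (uncertainty-minimizing),
#'   5 balanced and 6 exploitation experiments.
#' @param surrogate list(noiseFloor=) GP settings.
#' @param ga list(tournament=, mutationSd=, elite=) genetic settings.
#' @param suggestFn for "adapter": function(history, specs) returning a
#'   unit-box point — the contract external frameworks plug into.
#' @export
strategyConfig <- function(algorithm = c("smbo", "random", "doe_lhs", "ga",
                                         "adapter"),
                           stageSchedule = defaultStageSchedule(),
                           surrogate = list(noiseFloor = 1e-6),
                           ga = list(tournament = 3L, mutationSd = 0.1,
                                     elite = 1L),
                           suggestFn = NULL) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "smbo") {
    stopifnot(is.data.frame(stageSchedule), all(stageSchedule$count >= 1),
              all(stageSchedule$kind %in% c("random", "explore", "balanced",
                                            "exploit")))
  }
  if (algorithm == "adapter") stopifnot(is.function(suggestFn))
  structure(list(algorithm = algorithm, stageSchedule = stageSchedule,
                 surrogate = surrogate, ga = ga, suggestFn = suggestFn),
            class = "strategyConfig")
}

#' The staged schedule: 5 random / 14 explore / 5 balanced / 6 exploit
#' @export
defaultStageSchedule <- function()
  data.frame(kind = c("random", "explore", "balanced", "exploit"),
             count = c(5L, 14L, 5L, 6L), stringsAsFactors = FALSE)

#' Search stage for an iteration index
#'
#' @param schedule data.frame(kind, count).
#' @param iteration 1-based iteration index.
#' @return the stage kind; signals a schedule-exhausted error past the
#'   budget the schedule describes.
#' @export
stageForIteration <- function(schedule, iteration) {
  ends <- cumsum(schedule$count)
  i <- which(iteration <= ends)
  if (length(i) == 0)
    stop(errorCondition(sprintf("schedule exhausted at iteration %d",
                                iteration),
                        class = c("scheduleExhausted", "chemloopError")))
  schedule$kind[i[1]]
}

## ---- history ----------------------------------------------------------

#' Optimization history (append-only)
#'
#' @return an empty history: list(X=, y=, failed=, stage=) with
#'   contiguous iteration indices given by row order.
#' @export
newHistory <- function() {
  structure(list(X = NULL, y = numeric(0), failed = logical(0),
                 stage = character(0)), class = "optHistory")
}

#' @rdname newHistory
#' @param history an optHistory.
#' @param x unit-box point.
#' @param y observed objective (the floor value for failed iterations).
#' @param failed logical failure flag.
#' @param stage stage label used for the suggestion.
#' @export
addObservation <- function(history, x, y, failed = FALSE, stage = "") {
  history$X <- rbind(history$X, matrix(x, nrow = 1))
  history$y <- c(history$y, y)
  history$failed <- c(history$failed, failed)
  history$stage <- c(history$stage, stage)
  history
}

historySize <- function(history) length(history$y)

## ---- strategies -------------------------------------------------------

#' Suggest the next parameter assignment
#'
#' The iteration index (one past the history size) selects the stage from
#' the schedule; the suggestion is deterministic given (history, config,
#' seed) and always lies inside the parameter box.
#'
#' @param history an \code{\link{newHistory}} object.
#' @param specs list of \code{ParameterSpec}.
#' @param strategy a \code{\link{strategyConfig}}.
#' @param seed integer seed.
#' @return list(assignment=, x=, stage=): the denormalized assignment, the
#'   unit-box point and the stage used.
#' @export
suggestNext <- function(history, specs, strategy, seed = 1L) {
  d <- length(specs)
  iter <- historySize(history) + 1L
  res <- switch(strategy$algorithm,
    random = list(x = withSeed(mixSeed(seed, iter), stats::runif(d)),
                  stage = "random"),
    doe_lhs = {
      n <- max(iter, sum(strategy$stageSchedule$count))
      des <- doeLhs(n, d, seed)
      list(x = des[iter, ], stage = "doe_lhs")
    },
    ga = list(x = gaStep(history, d, strategy$ga,
                         mixSeed(seed, iter)),
              stage = "ga"),
    adapter = list(x = pmin(1, pmax(0, strategy$suggestFn(history, specs))),
                   stage = "adapter"),
    smbo = suggestSmbo(history, d, strategy, seed, iter))
  list(assignment = denormalizeAssignment(res$x, specs), x = res$x,
       stage = res$stage)
}

suggestSmbo <- function(history, d, strategy, seed, iter) {
  stage <- stageForIteration(strategy$stageSchedule, iter)
  n <- historySize(history)
  if (stage == "random" || n < 2)
    return(list(x = withSeed(mixSeed(seed, iter), stats::runif(d)),
                stage = stage))
  gp <- fitSurrogate(history$X, history$y,
                     noiseFloor = strategy$surrogate$noiseFloor)
  acq <- acquisition(gp, stage, incumbent = max(history$y))
  x <- optimizeAcquisition(acq, d, seed = mixSeed(seed, iter))
  list(x = x, stage = stage)
}

#' Latin hypercube design on the unit box
#'
#' Every dimension's marginal stratifies into n bins with exactly one
#' point per bin.
#'
#' @param n number of points (>= 1).
#' @param d dimension.
#' @param seed integer seed.
#' @return n x d matrix in [0,1]^d.
#' @export
doeLhs <- function(n, d, seed = 1L) {
  stopifnot(n >= 1)
  withSeed(mixSeed(seed, c(n, d)), lhs::randomLHS(n, d))
}

#' One genetic-algorithm suggestion
#'
#' Tournament selection over the history, blend (BLX-0.5) crossover and
#' Gaussian mutation clipped to the box.  With mutation disabled and
#' elitism on, the elite (incumbent) is resubmitted unchanged.
#'
#' @param history an optHistory with >= 1 record.
#' @param d dimension.
#' @param settings list(tournament=, mutationSd=, elite=).
#' @param seed integer seed.
#' @return unit-box point.
#' @export
gaStep <- function(history, d, settings, seed = 1L) {
  n <- historySize(history)
  if (n == 0) return(withSeed(seed, stats::runif(d)))
  best <- history$X[which.max(history$y), ]
  if (settings$mutationSd == 0 && settings$elite >= 1) return(best)
  withSeed(seed, {
    tour <- function() {
      k <- sample.int(n, min(settings$tournament, n))
      history$X[k[which.max(history$y[k])], ]
    }
    p1 <- tour(); p2 <- tour()
    u <- stats::runif(d, -0.5, 1.5)
    child <- p1 + u * (p2 - p1) +
      stats::rnorm(d, 0, settings$mutationSd)
    pmin(1, pmax(0, child))
  })
}
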