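## The closed loop: suggest -> update procedure -> execute -> acquire
## spectrum -> evaluate objective -> record, repeated to a fixed budget.
## The campaign directory is an append-only audit trail: versioned
## procedure files proc_v0... plus a records.jsonl database, so a killed
## campaign resumes to a byte-identical database (wall-clock timestamps
## excluded) and every iteration maps to exactly one procedure file.

#' Configure a campaign
#'
#' @param kind fixture kind ("ugi", "vanleusen", "epoxidation",
#'   "discovery"); supplies procedure, bounds, surface, model, objective.
#' @param dir campaign directory (created on demand).
#' @param budget number of iterations (>= 1).
#' @param strategy a \code{\link{strategyConfig}}.
#' @param seed integer master seed; every per-iteration random draw is
#'   derived from (seed, iteration), so reruns and resumes reproduce the
#'   same assignment and objective sequences.
#' @param parallelism number of simulated reactors (>= 1); batches of
#'   suggestions use a constant-liar fill-in for pending points.
#' @param noiseSd surface observation noise.
#' @param spectrumNoiseSd intensity noise added to synthetic spectra.
#' @param executeProcedures run each versioned procedure on the simulated
#'   backend (TRUE); FALSE skips the execution log for speed-sensitive
#'   sweeps, the chemistry is unaffected.
#' @param fixture optional pre-built \code{\link{campaignFixture}} to use
#'   instead of building one from \code{kind}.
#' @export
campaignConfig <- function(kind, dir, budget = 30L,
                           strategy = strategyConfig("smbo"),
                           seed = 1L, parallelism = 1L, noiseSd = 0.01,
                           spectrumNoiseSd = 0, executeProcedures = TRUE,
                           fixture = NULL) {
  stopifnot(budget >= 1, parallelism >= 1)
  if (is.null(fixture)) fixture <- campaignFixture(kind, noiseSd = noiseSd)
  if (spectrumNoiseSd > 0) fixture$model$noiseSd <- spectrumNoiseSd
  structure(list(kind = kind, dir = dir, budget = as.integer(budget),
                 strategy = strategy, seed = as.integer(seed),
                 parallelism = as.integer(parallelism),
                 fixture = fixture,
                 executeProcedures = isTRUE(executeProcedures)),
            class = "campaignConfig")
}

procFileName <- function(dir, id, version)
  file.path(dir, sprintf("%s_v%d.chemdsl.yaml", id, version))

recordsFile <- function(dir) file.path(dir, "records.jsonl")

#' Run (or resume) a closed-loop campaign
#'
#' Writes \code{proc_v0 ... proc_vN} procedure files and appends one JSON
#' record per iteration to \code{records.jsonl}.  If the directory already
#' holds records, the campaign resumes after the last completed iteration;
#' an uninterrupted run and a killed-and-resumed run produce byte-identical
#' databases apart from the wall-clock field.
#'
#' @param config a \code{\link{campaignConfig}}.
#' @return list(best=, records=, history=, dir=): the best record, all
#'   records, the optimization history and the campaign directory.
#' @export
runCampaign <- function(config) {
  fx <- config$fixture
  dir.create(config$dir, recursive = TRUE, showWarnings = FALSE)
  specs <- extractParameters(fx$procedure, fx$optimizeConfig)
  v0 <- procFileName(config$dir, fx$procedure@procId, 0)
  if (!file.exists(v0)) writeProcedure(fx$procedure, v0)
  records <- readCampaignRecords(config$dir)
  history <- rebuildHistory(records, specs, fx$objective)
  proc <- if (length(records) == 0) fx$procedure else
    readProcedure(procFileName(config$dir, fx$procedure@procId,
                               length(records)))
  i <- length(records)
  while (i < config$budget) {
    batch <- min(config$parallelism, config$budget - i)
    sugs <- suggestBatch(history, specs, config$strategy, config$seed,
                         batch)
    for (b in seq_len(batch)) {
      i <- i + 1L
      sug <- sugs[[b]]
      proc <- applyAssignment(proc, sug$assignment, specs)
      writeProcedure(proc, procFileName(config$dir, proc@procId,
                                        proc@version))
      if (config$executeProcedures) {
        backend <- simLabBackend()
        runProcedure(proc, backend, seed = mixSeed(config$seed, i))
      }
      ev <- evaluateIteration(fx, sug$assignment, mixSeed(config$seed, i))
      rec <- list(iteration = i, version = proc@version, stage = sug$stage,
                  assignment = assignmentJson(sug$assignment),
                  objective = ev$y, failed = ev$failed,
                  components = ev$components,
                  novelPositions = ev$novelPositions,
                  procedureFile = basename(procFileName(config$dir,
                                                        proc@procId,
                                                        proc@version)),
                  seedDigest = mixSeed(config$seed, i),
                  walltime = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
      line <- appendRecord(config$dir, rec)
      ## the optimizer history is grown from the parsed JSON record --
      ## the exact view a resumed campaign reconstructs -- so resumes are
      ## bit-identical to uninterrupted runs
      parsed <- jsonlite::fromJSON(line)
      history <- addObservation(
        history, normalizeAssignment(assignmentFromJson(parsed$assignment),
                                     specs),
        parsed$objective, isTRUE(parsed$failed), parsed$stage)
      records[[length(records) + 1L]] <- parsed
    }
  }
  best <- records[[which.max(vapply(records, `[[`, numeric(1),
                                    "objective"))]]
  list(best = best, records = records, history = history, dir = config$dir)
}

## constant-liar batching: pending suggestions enter a shadow history at
## the incumbent value so one optimizer update serves the whole batch
suggestBatch <- function(history, specs, strategy, seed, batch) {
  sugs <- vector("list", batch)
  shadow <- history
  liar <- if (historySize(history) > 0) max(history$y) else 0
  for (b in seq_len(batch)) {
    sugs[[b]] <- suggestNext(shadow, specs, strategy, seed)
    shadow <- addObservation(shadow, sugs[[b]]$x, liar, FALSE,
                             sugs[[b]]$stage)
  }
  sugs
}

## simulate chemistry + analysis for one assignment
evaluateIteration <- function(fx, assignment, iterSeed) {
  comp <- evaluateReaction(fx$surface, assignment, seed = iterSeed)
  spectra <- list(main = synthSpectrum(comp, fx$model, seed = iterSeed))
  if (fx$objective$kind == "raman_conversion")
    spectra$t0 <- synthSpectrum(timeZeroComposition(fx$surface), fx$model,
                                seed = iterSeed + 1L)
  res <- evaluateObjective(fx$objective, spectra)
  scalar <- Filter(function(v) is.numeric(v) && length(v) == 1,
                   res$components)
  novel <- NULL
  if (fx$objective$kind == "novelty" && !res$failed &&
      !is.null(res$components$novel) && nrow(res$components$novel) > 0)
    novel <- round(res$components$novel$position, 4)
  list(y = if (res$failed) 0 else res$value, failed = res$failed,
       components = scalar, novelPositions = novel, result = res)
}

assignmentJson <- function(assignment)
  lapply(assignment, function(q) list(value = qValue(q), unit = qUnit(q)))

assignmentFromJson <- function(x) {
  out <- lapply(x, function(e) quantity(e$value, e$unit))
  class(out) <- "paramAssignment"
  out
}

appendRecord <- function(dir, rec) {
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                           null = "null")
  con <- file(recordsFile(dir), open = "ab")
  on.exit(close(con))
  writeLines(line, con, useBytes = TRUE)
  invisible(as.character(line))
}

#' Read the campaign database
#' @param dir campaign directory.
#' @return list of records (possibly empty).
#' @export
readCampaignRecords <- function(dir) {
  f <- recordsFile(dir)
  if (!file.exists(f)) return(list())
  lapply(readLines(f, warn = FALSE), jsonlite::fromJSON)
}

## history is rebuilt from stored assignments (not stored unit-box points)
## so a restart under expanded bounds renormalizes transparently
rebuildHistory <- function(records, specs, objective) {
  h <- newHistory()
  for (rec in records) {
    a <- assignmentFromJson(rec$assignment)
    h <- addObservation(h, normalizeAssignment(a, specs), rec$objective,
                        isTRUE(rec$failed), rec$stage)
  }
  h
}

#' Compare two campaign databases ignoring wall-clock timestamps
#'
#' @param dirA,dirB campaign directories.
#' @return TRUE when records and every versioned procedure file agree
#'   byte-for-byte once the walltime field is stripped.
#' @export
campaignDatabasesEqual <- function(dirA, dirB) {
  strip <- function(dir) gsub(",\"walltime\":\"[^\"]*\"", "",
                              readLines(recordsFile(dir), warn = FALSE))
  if (!identical(strip(dirA), strip(dirB))) return(FALSE)
  pf <- function(dir) sort(grep("chemdsl\\.yaml$", list.files(dir),
                                value = TRUE))
  if (!identical(pf(dirA), pf(dirB))) return(FALSE)
  all(vapply(pf(dirA), function(f)
    identical(readLines(file.path(dirA, f), warn = FALSE),
              readLines(file.path(dirB, f), warn = FALSE)), logical(1)))
}

#' Continue a campaign in an expanded parameter space
#'
#' The prior history is renormalized into the expanded box and warm-starts
#' the surrogate; iteration indices continue.  Every expanded bound must
#' contain the original bound.
#'
#' @param config the original \code{\link{campaignConfig}} (its directory
#'   holds the first campaign).
#' @param expandedConfig optimize-config entries with the expanded bounds.
#' @param budget new total iteration budget (> iterations already done).
#' @param strategy optional strategy for the continuation.
#' @return the continued campaign result (see \code{\link{runCampaign}}).
#' @export
twoStageRestart <- function(config, expandedConfig, budget,
                            strategy = NULL) {
  fx <- config$fixture
  oldSpecs <- extractParameters(fx$procedure, fx$optimizeConfig)
  oldPaths <- specPaths(oldSpecs)
  for (e in expandedConfig) {
    i <- match(paramPath(e$step, e$property), oldPaths)
    if (is.na(i)) stop(sprintf("expanded config adds unknown path '%s'",
                               paramPath(e$step, e$property)),
                       call. = FALSE)
    s <- oldSpecs[[i]]
    lo <- qIn(s@lower, e$unit); up <- qIn(s@upper, e$unit)
    if (e$lower > lo + 1e-9 || e$upper < up - 1e-9)
      stop(sprintf("expanded bounds for '%s' do not contain the originals",
                   oldPaths[i]), call. = FALSE)
  }
  fx$optimizeConfig <- expandedConfig
  ## the surface keeps its own (original) box; widen its specs so points
  ## in the expansion evaluate instead of erroring
  fx$surface <- expandSurface(fx$surface, expandedConfig)
  cfg2 <- config
  cfg2$fixture <- fx
  cfg2$budget <- as.integer(budget)
  if (!is.null(strategy)) cfg2$strategy <- strategy
  runCampaign(cfg2)
}

## re-express the surface bumps in the expanded box so the latent
## chemistry at any original point is unchanged
expandSurface <- function(surface, expandedConfig) {
  oldSpecs <- surface@specs
  paths <- specPaths(oldSpecs)
  newSpecs <- lapply(seq_along(oldSpecs), function(i) {
    s <- oldSpecs[[i]]
    e <- Find(function(e) paramPath(e$step, e$property) == paths[i],
              expandedConfig)
    if (is.null(e)) return(s)
    paramSpec(s@stepId, s@property, e$lower, e$upper, e$unit,
              if (is.null(e$scale)) s@scale else e$scale)
  })
  ## map each bump center/width from the old unit box to the new one
  tr <- lapply(seq_along(oldSpecs), function(i) {
    o <- oldSpecs[[i]]; n <- newSpecs[[i]]
    u <- o@lower@unit
    oldLo <- o@lower@value; oldUp <- qIn(o@upper, u)
    newLo <- qIn(n@lower, u); newUp <- qIn(n@upper, u)
    if (o@scale == "log") {
      list(scale = (log(oldUp) - log(oldLo)) / (log(newUp) - log(newLo)),
           shift = (log(oldLo) - log(newLo)) / (log(newUp) - log(newLo)))
    } else {
      list(scale = (oldUp - oldLo) / (newUp - newLo),
           shift = (oldLo - newLo) / (newUp - newLo))
    }
  })
  remap <- function(p) {
    p$bumps <- lapply(p$bumps, function(b) {
      for (i in seq_along(tr)) {
        b$center[i] <- tr[[i]]$shift + tr[[i]]$scale * b$center[i]
        b$width[i] <- tr[[i]]$scale * b$width[i]
      }
      b
    })
    p
  }
  products <- lapply(surface@products, remap)
  main <- products[[1]]
  best <- main$bumps[[which.max(vapply(main$bumps, `[[`, numeric(1),
                                       "amp"))]]
  new("ReactionSurface", name = surface@name, specs = newSpecs,
      products = products, species = surface@species,
      noiseSd = surface@noiseSd,
      optimum = list(assignment = denormalizeAssignment(best$center,
                                                        newSpecs),
                     value = productYield(best$center, main, newSpecs),
                     product = names(products)[1]),
      seed = surface@seed)
}
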