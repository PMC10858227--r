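## Resource-constrained parallel scheduling: allocate procedure steps
## across reactors and shared resources (liquid-handling backbone,
## analytical instrument), minimizing total duration with greedy list
## scheduling.  Greedy is within 2x of the optimum (classical
## list-scheduling bound); an exhaustive-interleaving oracle over tiny
## instances backs that empirically in the tests.

#' Describe the laboratory resource graph
#'
#' @param capacities named integer vector, resource name -> capacity
#'   (e.g. \code{c(backbone = 1, reactor = 2, analyzer = 1)}).
#' @return a resourceGraph object.
#' @export
resourceGraph <- function(capacities) {
  stopifnot(length(capacities) >= 1, all(capacities >= 1),
            !is.null(names(capacities)), all(nzchar(names(capacities))))
  structure(list(capacities = capacities), class = "resourceGraph")
}

#' Schedule procedure steps across shared resources
#'
#' Greedy list scheduling: repeatedly take, among the ready steps (the
#' first unscheduled step of each procedure), the one that can start
#' earliest given resource capacities; ties break FIFO among ready steps
#' and then by procedure id.  Step order within one procedure is always
#' preserved and no resource is ever over-subscribed.
#'
#' @param jobs named list (names = procedure ids); each element is a
#'   data.frame(step, resources, duration) where \code{resources} is a
#'   comma-separated resource set and \code{duration} is in seconds.
#' @param graph a \code{\link{resourceGraph}}.
#' @return a schedule: data.frame(procedure, step, resources, start, end),
#'   ordered by start time.
#' @export
scheduleProcedures <- function(jobs, graph) {
  if (length(jobs) == 0)
    return(data.frame(procedure = character(0), step = character(0),
                      resources = character(0), start = numeric(0),
                      end = numeric(0)))
  stopifnot(!is.null(names(jobs)))
  caps <- graph$capacities
  for (jb in jobs) for (rs in strsplit(jb$resources, ","))
    for (r in trimws(rs)) if (!r %in% names(caps))
      stop(sprintf("step requires nonexistent resource '%s'", r),
           call. = FALSE)
  nxt <- stats::setNames(rep(1L, length(jobs)), names(jobs))
  done <- stats::setNames(rep(0, length(jobs)), names(jobs))
  ## busy intervals per resource
  busy <- stats::setNames(vector("list", length(caps)), names(caps))
  out <- list()
  queue <- names(jobs)  # FIFO arrival order
  repeat {
    ready <- queue[vapply(queue, function(p) nxt[[p]] <= nrow(jobs[[p]]),
                          logical(1))]
    if (length(ready) == 0) break
    cand <- lapply(ready, function(p) {
      row <- jobs[[p]][nxt[[p]], ]
      res <- trimws(strsplit(row$resources, ",")[[1]])
      s <- earliestStart(done[[p]], row$duration, res, busy, caps)
      list(proc = p, row = row, res = res, start = s)
    })
    starts <- vapply(cand, `[[`, numeric(1), "start")
    ## earliest feasible start; FIFO order then procedure id on ties
    pick <- cand[[order(starts, match(ready, queue), ready)[1]]]
    s <- pick$start; e <- s + pick$row$duration
    for (r in pick$res) busy[[r]] <- append(busy[[r]], list(c(s, e)))
    done[[pick$proc]] <- e
    nxt[[pick$proc]] <- nxt[[pick$proc]] + 1L
    out[[length(out) + 1L]] <-
      data.frame(procedure = pick$proc, step = pick$row$step,
                 resources = pick$row$resources, start = s, end = e)
  }
  sched <- do.call(rbind, out)
  sched[order(sched$start, sched$procedure), , drop = FALSE]
}

## earliest start >= t0 at which all resources in `res` have spare
## capacity throughout a window of `dur` seconds
earliestStart <- function(t0, dur, res, busy, caps) {
  bounds <- t0
  for (r in res) for (iv in busy[[r]]) if (iv[2] > t0)
    bounds <- c(bounds, iv[2])
  for (s in sort(unique(bounds))) {
    ok <- all(vapply(res, function(r)
      capacityFree(busy[[r]], caps[[r]], s, s + dur), logical(1)))
    if (ok) return(s)
  }
  max(bounds)
}

capacityFree <- function(intervals, cap, s, e) {
  if (length(intervals) == 0) return(TRUE)
  edges <- sort(unique(c(s, vapply(intervals, `[[`, numeric(1), 1),
                         vapply(intervals, `[[`, numeric(1), 2))))
  edges <- edges[edges >= s & edges < e]
  for (t in edges) {
    n <- sum(vapply(intervals, function(iv) iv[1] <= t && iv[2] > t,
                    logical(1)))
    if (n + 1 > cap) return(FALSE)
  }
  TRUE
}

#' Total duration of a schedule
#' @param schedule a schedule from \code{\link{scheduleProcedures}}.
#' @export
makespan <- function(schedule) if (nrow(schedule) == 0) 0 else
  max(schedule$end)

#' Validate a schedule against capacities and step order
#'
#' Replay checker: verifies that at no instant any resource has more
#' concurrent holders than its capacity, and that every procedure's steps
#' run in order with end - start equal to the declared duration.
#'
#' @param schedule a schedule data.frame.
#' @param graph a \code{\link{resourceGraph}}.
#' @param jobs optional job list to check durations/order against.
#' @return TRUE, or a character vector of violations.
#' @export
checkSchedule <- function(schedule, graph, jobs = NULL) {
  bad <- character(0)
  caps <- graph$capacities
  for (r in names(caps)) {
    rows <- grepl(paste0("(^|, ?)", r, "($|, ?)"), schedule$resources)
    iv <- schedule[rows, , drop = FALSE]
    if (nrow(iv) == 0) next
    for (t in sort(unique(iv$start))) {
      n <- sum(iv$start <= t & iv$end > t)
      if (n > caps[[r]])
        bad <- c(bad, sprintf("resource '%s' over capacity at t=%g (%d > %d)",
                              r, t, n, caps[[r]]))
    }
  }
  for (p in unique(schedule$procedure)) {
    rows <- schedule[schedule$procedure == p, , drop = FALSE]
    ord <- rows[order(rows$start), ]
    if (!is.null(jobs)) {
      want <- jobs[[p]]$step
      if (!identical(as.character(ord$step), as.character(want)))
        bad <- c(bad, sprintf("procedure '%s' steps out of order", p))
      durs <- jobs[[p]]$duration[match(ord$step, jobs[[p]]$step)]
      if (any(abs((ord$end - ord$start) - durs) > 1e-9))
        bad <- c(bad, sprintf("procedure '%s' duration mismatch", p))
    }
  }
  if (length(bad) == 0) TRUE else bad
}

#' Derive a schedulable job table from a procedure
#'
#' Maps each top-level step to its resource requirements: additions and
#' transfers hold the liquid-handling backbone plus the reactor, stirring
#' and heating hold only the reactor, analyses hold the analyzer plus the
#' backbone for sampling.
#'
#' @param procedure a \code{Procedure}.
#' @param reactor resource name of the reactor running this procedure.
#' @return data.frame(step, resources, duration) for
#'   \code{\link{scheduleProcedures}}.
#' @export
procedureJob <- function(procedure, reactor = "reactor") {
  rows <- lapply(procedure@steps, function(s) {
    res <- switch(s@name,
      Add = , Transfer = , DynamicAdd = ,
      DynamicTransfer = paste("backbone", reactor, sep = ","),
      Analyze = paste("backbone,analyzer", reactor, sep = ","),
      reactor)
    data.frame(step = s@stepId, resources = res,
               duration = stepDuration(s))
  })
  do.call(rbind, rows)
}

## nominal duration in seconds used for scheduling (not execution)
stepDuration <- function(s) {
  p <- s@properties
  if (!is.null(p$time)) return(qIn(p$time, "s"))
  if (!is.null(p$volume)) {
    rate <- if (!is.null(p$rate)) qIn(p$rate, "mL/min") / 60 else 2
    return(qIn(p$volume, "mL") / rate)
  }
  if (!is.null(p$max_duration)) return(qIn(p$max_duration, "s"))
  if (s@name == "Analyze") return(60)
  30
}
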