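## Ordered locking for shared laboratory resources.  A holder requests all
## resources for a step atomically; acquisition is all-or-nothing and
## internally processed in a fixed global resource order (lexicographic
## name), so hold-and-wait never occurs and the contract is deadlock-free
## by construction.  A replay checker proves no capacity violation over
## any acquisition log.

#' Create a lock manager over a resource graph
#'
#' @param graph a \code{\link{resourceGraph}}.
#' @return a lockManager object with an internal state environment.
#' @export
lockManager <- function(graph) {
  st <- new.env(parent = emptyenv())
  st$caps <- graph$capacities
  st$held <- stats::setNames(rep(0L, length(graph$capacities)),
                             names(graph$capacities))
  st$holders <- list()   # holder -> character vector of resources
  st$log <- list()       # acquisition/release event log
  st$clock <- 0L
  structure(list(state = st), class = "lockManager")
}

#' Attempt an atomic all-or-nothing acquisition
#'
#' Either every requested resource is granted (in lexicographic order) or
#' none is and \code{FALSE} is returned, so a blocked holder never holds a
#' partial set.
#'
#' @param lm a \code{\link{lockManager}}.
#' @param holder holder identifier.
#' @param resources character vector of resource names.
#' @return TRUE if granted, FALSE if the request would exceed a capacity.
#' @export
tryAcquire <- function(lm, holder, resources) {
  st <- lm$state
  resources <- sort(unique(resources))  # global lock order
  if (!all(resources %in% names(st$caps)))
    stop(sprintf("unknown resource '%s'",
                 setdiff(resources, names(st$caps))[1]), call. = FALSE)
  if (!is.null(st$holders[[holder]]))
    stop(sprintf("holder '%s' already holds resources", holder),
         call. = FALSE)
  free <- all(st$held[resources] + 1L <= st$caps[resources])
  st$clock <- st$clock + 1L
  if (!free) {
    st$log[[length(st$log) + 1L]] <-
      list(t = st$clock, holder = holder, event = "blocked",
           resources = resources)
    return(FALSE)
  }
  st$held[resources] <- st$held[resources] + 1L
  st$holders[[holder]] <- resources
  st$log[[length(st$log) + 1L]] <-
    list(t = st$clock, holder = holder, event = "acquire",
         resources = resources)
  TRUE
}

#' Release every resource a holder holds
#'
#' @param lm a \code{\link{lockManager}}.
#' @param holder holder identifier.
#' @export
releaseHolder <- function(lm, holder) {
  st <- lm$state
  res <- st$holders[[holder]]
  if (is.null(res)) stop(sprintf("holder '%s' holds nothing", holder),
                         call. = FALSE)
  st$held[res] <- st$held[res] - 1L
  st$holders[[holder]] <- NULL
  st$clock <- st$clock + 1L
  st$log[[length(st$log) + 1L]] <-
    list(t = st$clock, holder = holder, event = "release", resources = res)
  invisible(TRUE)
}

#' Blocking acquisition with a timeout
#'
#' Retries \code{tryAcquire} while other (simulated) holders release; a
#' request that cannot be granted within \code{timeout} attempts raises a
#' scheduling-fault with a full state dump attached.
#'
#' @param lm a \code{\link{lockManager}}.
#' @param holder holder identifier.
#' @param resources resource names.
#' @param waitFn called between attempts (e.g. advances a co-routine
#'   driver); defaults to a no-op.
#' @param timeout maximum attempts.
#' @export
acquireBlocking <- function(lm, holder, resources, waitFn = function() NULL,
                            timeout = 1000L) {
  for (i in seq_len(timeout)) {
    if (tryAcquire(lm, holder, resources)) return(invisible(TRUE))
    waitFn()
  }
  stop(errorCondition(
    sprintf("scheduling fault: holder '%s' timed out acquiring [%s]",
            holder, paste(resources, collapse = ", ")),
    class = c("schedulingFault", "chemloopError"),
    state = lockState(lm)))
}

#' Snapshot of the lock manager state
#' @param lm a \code{\link{lockManager}}.
#' @return list(held=, holders=, log length).
#' @export
lockState <- function(lm) {
  st <- lm$state
  list(held = st$held, holders = st$holders, events = length(st$log))
}

#' Replay-check a lock event log for capacity violations
#'
#' Replays acquire/release events against the declared capacities and
#' reports any instant at which a resource exceeded its capacity.
#'
#' @param lm a \code{\link{lockManager}} (its internal log is replayed).
#' @return TRUE, or a character vector of violations.
#' @export
checkLockLog <- function(lm) {
  st <- lm$state
  held <- stats::setNames(rep(0L, length(st$caps)), names(st$caps))
  bad <- character(0)
  for (ev in st$log) {
    if (ev$event == "acquire") held[ev$resources] <- held[ev$resources] + 1L
    if (ev$event == "release") held[ev$resources] <- held[ev$resources] - 1L
    over <- held > st$caps
    if (any(over))
      bad <- c(bad, sprintf("t=%d: resource '%s' over capacity", ev$t,
                            names(held)[over][1]))
    if (any(held < 0))
      bad <- c(bad, sprintf("t=%d: negative holder count", ev$t))
  }
  if (length(bad) == 0) TRUE else bad
}
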