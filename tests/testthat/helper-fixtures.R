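## Shared helpers: generators and independent oracles used across tests.

## random valid procedure for round-trip property tests
randomProcedure <- function(seed) {
  set.seed(seed)
  n <- sample(1:6, 1)
  mk <- function(i) {
    kind <- sample(c("Add", "Stir", "Wait", "HeatChill", "Transfer"), 1)
    id <- sprintf("s%02d", i)
    switch(kind,
      Add = step(id, "Add", reagent = sample(c("water", "methanol",
                                               "acid solution 2.0 M"), 1),
                 volume = quantity(round(runif(1, 0.1, 20), 3), "mL")),
      Stir = step(id, "Stir", time = quantity(round(runif(1, 1, 300), 2),
                                              sample(c("s", "min", "h"), 1))),
      Wait = step(id, "Wait", time = quantity(round(runif(1, 1, 60), 1),
                                              "s")),
      HeatChill = step(id, "HeatChill",
                       temp = quantity(round(runif(1, 0, 120), 1), "degC")),
      Transfer = step(id, "Transfer", from = "flask", to = "reactor",
                      volume = quantity(round(runif(1, 0.5, 10), 2), "mL")))
  }
  procedure(sprintf("proc%d", seed), lapply(seq_len(n), mk),
            version = sample(0:5, 1),
            metadata = list(title = "generated"))
}

## brute-force local-maxima oracle for peak picking: every interior point
## strictly above its left neighbour and at least its right neighbour,
## filtered by height only
bruteForceMaxima <- function(y, minHeight) {
  n <- length(y)
  idx <- which(vapply(seq_len(n), function(i)
    i > 1 && i < n && y[i] > y[i - 1] && y[i] >= y[i + 1] &&
      y[i] >= minHeight, logical(1)))
  idx
}

## independent exhaustive-scheduling oracle: minimal makespan over every
## interleaving of job steps (steps placed at the earliest feasible time
## in the chosen order)
exhaustiveMakespan <- function(jobs, capacities) {
  nsteps <- vapply(jobs, nrow, integer(1))
  bestEnv <- new.env()
  bestEnv$best <- Inf
  place <- function(nxt, ready, busy) {
    if (all(nxt > nsteps)) {
      bestEnv$best <- min(bestEnv$best, max(ready))
      return(invisible())
    }
    for (j in seq_along(jobs)) {
      if (nxt[j] > nsteps[j]) next
      row <- jobs[[j]][nxt[j], ]
      res <- trimws(strsplit(row$resources, ",")[[1]])
      ## earliest time >= ready[j] with all resources under capacity
      cand <- sort(unique(c(ready[j], unlist(lapply(busy[res], function(b)
        if (length(b)) vapply(b, `[[`, numeric(1), 2) else numeric(0))))))
      cand <- cand[cand >= ready[j]]
      s <- NA
      for (t in cand) {
        ok <- all(vapply(res, function(r) {
          edges <- c(t, unlist(lapply(busy[[r]], function(iv)
            iv[iv >= t & iv < t + row$duration])))
          all(vapply(unique(edges), function(tt)
            sum(vapply(busy[[r]], function(iv)
              iv[1] <= tt && iv[2] > tt, logical(1))) < capacities[[r]],
            logical(1)))
        }, logical(1)))
        if (ok) { s <- t; break }
      }
      if (is.na(s)) s <- max(cand)
      nb <- busy
      for (r in res) nb[[r]] <- append(nb[[r]], list(c(s, s + row$duration)))
      nr <- ready; nr[j] <- s + row$duration
      nn <- nxt; nn[j] <- nxt[j] + 1L
      if (max(nr) < bestEnv$best) place(nn, nr, nb)
    }
  }
  busy0 <- stats::setNames(vector("list", length(capacities)),
                           names(capacities))
  place(rep(1L, length(jobs)), rep(0, length(jobs)), busy0)
  bestEnv$best
}

## paired-reactor instance family: two identical procedures, dedicated
## reactors, shared exclusive backbone and analyzer
pairedJobs <- function(durations) {
  mk <- function(reactor) data.frame(
    step = c("add", "stir", "analyze", "workup")[seq_along(durations)],
    resources = c(paste0("backbone,", reactor), reactor,
                  paste0("analyzer,", reactor),
                  reactor)[seq_along(durations)],
    duration = durations)
  list(p1 = mk("r1"), p2 = mk("r2"))
}
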