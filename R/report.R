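## Reporting: tidy tables for parallel-coordinates plots (one row per
## iteration with every parameter and the objective, grouped into
## objective terciles) and the iteration-versus-best curve.

#' Tabulate a campaign database for plotting
#'
#' @param records campaign records (from \code{\link{readCampaignRecords}}
#'   or \code{runCampaign()$records}); must be non-empty.
#' @return list(parameters=, cumulativeBest=): \code{parameters} has one
#'   row per iteration with all parameter values, the stage, the
#'   objective and a tercile group (low/mid/high, sizes differing by at
#'   most 1); \code{cumulativeBest} is data.frame(iteration, best) with a
#'   non-decreasing best column.
#' @export
campaignReport <- function(records) {
  if (length(records) == 0) stop("empty database", call. = FALSE)
  paths <- names(records[[1]]$assignment)
  rows <- lapply(records, function(rec) {
    vals <- vapply(rec$assignment, function(e) e$value, numeric(1))
    df <- as.data.frame(as.list(vals))
    names(df) <- paths
    df$stage <- rec$stage
    df$objective <- rec$objective
    df$iteration <- rec$iteration
    df
  })
  params <- do.call(rbind, rows)
  params <- params[, c("iteration", paths, "stage", "objective")]
  params$tercile <- tercileGroups(params$objective)
  best <- cummax(params$objective)
  list(parameters = params,
       cumulativeBest = data.frame(iteration = params$iteration,
                                   best = best))
}

## rank-based thirds; group sizes differ by at most one
tercileGroups <- function(y) {
  n <- length(y)
  sizes <- rep(n %/% 3, 3) + c(rep(1, n %% 3), rep(0, 3 - n %% 3))
  lab <- rep(c("low", "mid", "high"), times = sizes)
  out <- character(n)
  out[order(y)] <- lab
  factor(out, levels = c("low", "mid", "high"))
}

#' Write the report tables as CSV
#'
#' @param records campaign records.
#' @param dir output directory (created on demand).
#' @return invisibly, the written paths.
#' @export
writeReportCsv <- function(records, dir) {
  rep <- campaignReport(records)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "parameters.csv")
  p2 <- file.path(dir, "cumulative_best.csv")
  utils::write.csv(rep$parameters, p1, row.names = FALSE)
  utils::write.csv(rep$cumulativeBest, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
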