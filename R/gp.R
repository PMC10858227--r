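## Gaussian-process surrogate on the unit box: Matern-5/2 kernel,
## standardized outputs, isotropic lengthscale and signal variance fitted
## by marginal likelihood each refit, observation noise clamped at a
## configurable floor so noiseless data are interpolated.

matern52 <- function(X1, X2, ell, sigma2) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  r <- sqrt(pmax(d2, 0)) / ell
  s5r <- sqrt(5) * r
  sigma2 * (1 + s5r + 5 * r^2 / 3) * exp(-s5r)
}

#' Fit the GP surrogate to optimization history
#'
#' @param X n x d matrix of unit-box points (>= 2 rows).
#' @param y objective values (failed iterations already at the floor).
#' @param noiseFloor observation noise variance (default 1e-6: noiseless
#'   training data are reproduced to ~1e-4).
#' @param hyper optional fixed kernel hyperparameters list(ell=, sigma2=);
#'   when given, the marginal-likelihood fit is skipped (used e.g. to
#'   compare posteriors across datasets under one kernel).
#' @return a gpSurrogate object usable with \code{\link{predictSurrogate}}.
#' @export
fitSurrogate <- function(X, y, noiseFloor = 1e-6, hyper = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("insufficient history: need >= 2 observations",
                  call. = FALSE)
  mu <- mean(y)
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy < 1e-12) sdy <- 1
  z <- (y - mu) / sdy
  nll <- function(par) {
    ell <- exp(par[1]); sigma2 <- exp(par[2])
    K <- matern52(X, X, ell, sigma2) + diag(noiseFloor, n)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    alpha <- backsolve(L, forwardsolve(t(L), z))
    0.5 * sum(z * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  }
  if (is.null(hyper)) {
    fit <- stats::optim(c(log(0.5), log(1)), nll, method = "L-BFGS-B",
                        lower = c(log(0.05), log(1e-3)),
                        upper = c(log(10), log(1e3)))
    ell <- exp(fit$par[1]); sigma2 <- exp(fit$par[2])
  } else {
    ell <- hyper$ell; sigma2 <- hyper$sigma2
  }
  K <- matern52(X, X, ell, sigma2) + diag(noiseFloor, n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), z))
  structure(list(X = X, yMean = mu, ySd = sdy, ell = ell, sigma2 = sigma2,
                 L = L, alpha = alpha, noise = noiseFloor),
            class = "gpSurrogate")
}

#' Posterior mean and sd at query points
#'
#' @param gp a gpSurrogate.
#' @param Xnew m x d matrix (or length-d vector) of unit-box points.
#' @return list(mean=, sd=) on the original objective scale.
#' @export
predictSurrogate <- function(gp, Xnew) {
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1)
  Ks <- matern52(Xnew, gp$X, gp$ell, gp$sigma2)
  mu <- as.numeric(Ks %*% gp$alpha)
  V <- forwardsolve(t(gp$L), t(Ks))
  var <- pmax(gp$sigma2 - colSums(V^2), 0)
  list(mean = gp$yMean + gp$ySd * mu, sd = gp$ySd * sqrt(var))
}

#' Acquisition score function for a search stage
#'
#' explore maximizes posterior sd (uncertainty reduction), exploit the
#' posterior mean, balanced the expected improvement over the incumbent.
#'
#' @param gp a gpSurrogate.
#' @param stage "explore", "balanced" or "exploit".
#' @param incumbent best observed objective value (balanced stage).
#' @return vectorized function: m x d matrix -> m scores.
#' @export
acquisition <- function(gp, stage, incumbent = NULL) {
  switch(stage,
    explore = function(X) predictSurrogate(gp, X)$sd,
    exploit = function(X) predictSurrogate(gp, X)$mean,
    balanced = {
      if (is.null(incumbent)) stop("balanced stage needs the incumbent",
                                   call. = FALSE)
      function(X) {
        p <- predictSurrogate(gp, X)
        z <- ifelse(p$sd > 0, (p$mean - incumbent) / p$sd, 0)
        ei <- (p$mean - incumbent) * stats::pnorm(z) +
          p$sd * stats::dnorm(z)
        ifelse(p$sd > 0, pmax(ei, 0), 0)
      }
    },
    stop(sprintf("unknown stage '%s'", stage), call. = FALSE))
}

#' Maximize an acquisition over the unit box
#'
#' Multi-start search: a low-discrepancy (Latin hypercube) start set of
#' \code{nStarts} points is scored, the best eight are refined by cyclic
#' coordinate-wise line search (two sweeps, 17-point grids per
#' coordinate), all evaluations vectorized.
#'
#' @param acqFn vectorized score function (matrix -> scores).
#' @param d dimension.
#' @param seed integer seed for the start set.
#' @param nStarts start-set size (default 64).
#' @return the best point found (length-d vector in [0,1]^d).
#' @export
optimizeAcquisition <- function(acqFn, d, seed = 1L, nStarts = 64L) {
  starts <- withSeed(seed, lhs::randomLHS(nStarts, d))
  sc <- acqFn(starts)
  top <- starts[order(sc, decreasing = TRUE)[seq_len(min(8, nStarts))], ,
                drop = FALSE]
  ## multi-scale line searches: a box-covering 17-point grid per
  ## coordinate, then grids shrunk 8x and 64x around the incumbent
  for (scale in c(2, 1 / 4, 1 / 32)) {
    for (sweep in 1:2) {
      for (j in seq_len(d)) {
        for (i in seq_len(nrow(top))) {
          grid <- top[i, j] + scale * seq(-0.5, 0.5, length.out = 17)
          grid <- pmin(1, pmax(0, grid))
          cand <- top[rep(i, length(grid)), , drop = FALSE]
          cand[, j] <- grid
          s <- acqFn(cand)
          top[i, j] <- grid[which.max(s)]
        }
      }
    }
    if (scale == 2) top <- top[!duplicated(round(top, 6)), , drop = FALSE]
  }
  final <- acqFn(top)
  top[which.max(final), ]
}
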