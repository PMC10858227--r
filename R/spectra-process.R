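## Analytical processing chain: zero-fill -> apodize -> Fourier transform
## -> baseline correction -> peak picking -> integration.  The default NMR
## chain uses twofold zero-filling, exponential apodization and the
## magnitude spectrum, which suffices for the area ratios the objectives
## consume.

#' Zero-fill an FID
#'
#' Appends zeros to \code{factor} times the original length; the original
#' samples are unchanged.  Zero-filling interpolates the transformed
#' spectrum without shifting peak positions.
#'
#' @param fid an \code{FID}.
#' @param factor 1, 2 or 4.
#' @export
zeroFill <- function(fid, factor = 2L) {
  if (!factor %in% c(1L, 2L, 4L)) stop("factor must be 1, 2 or 4",
                                       call. = FALSE)
  n <- length(fid@samples)
  out <- c(fid@samples, complex(real = numeric(n * (factor - 1L))))
  new("FID", samples = out, dwell = fid@dwell,
      frequencyMHz = fid@frequencyMHz)
}

#' Exponential apodization (line broadening)
#'
#' Multiplies the sample at time t by exp(-pi lb t), adding \code{lb} Hz
#' to every Lorentzian full width at half maximum.
#'
#' @param fid an \code{FID}.
#' @param lineBroadening lb in Hz, >= 0.
#' @export
apodize <- function(fid, lineBroadening) {
  if (lineBroadening < 0) stop("line broadening must be >= 0", call. = FALSE)
  t <- (seq_along(fid@samples) - 1) * fid@dwell
  new("FID", samples = fid@samples * exp(-pi * lineBroadening * t),
      dwell = fid@dwell, frequencyMHz = fid@frequencyMHz)
}

#' Fourier transform an FID into a spectrum
#'
#' Discrete Fourier transform with an fftshifted frequency axis converted
#' from Hz to ppm via the spectrometer frequency.  \code{magnitude} mode
#' (default) takes the modulus; \code{phased} applies the zeroth/first
#' order phase pair that minimizes the absolute imaginary content in the
#' baseline region (outer 10% of points) and returns the real part.
#'
#' @param fid an \code{FID}.
#' @param mode "magnitude" or "phased".
#' @return a \code{Spectrum} with kind "ppm".
#' @export
fidToSpectrum <- function(fid, mode = c("magnitude", "phased")) {
  mode <- match.arg(mode)
  n <- length(fid@samples)
  sp <- stats::fft(fid@samples)
  ## fftshift: map bin k to frequency (k - n/2)/ (n dwell)
  half <- floor(n / 2)
  sp <- c(sp[(half + 1):n], sp[1:half])
  freq <- (seq_len(n) - 1 - (n - half)) / (n * fid@dwell)
  ppm <- freq / fid@frequencyMHz
  intensity <- if (mode == "magnitude") Mod(sp) else phaseSpectrum(sp)
  spectrum(ppm, intensity, "ppm",
           metadata = list(mode = mode, frequencyMHz = fid@frequencyMHz,
                           hzAxis = freq))
}

phaseSpectrum <- function(sp) {
  n <- length(sp)
  edge <- c(seq_len(max(2, n %/% 10)), (n - max(2, n %/% 10) + 1):n)
  obj <- function(p) {
    ph <- exp(complex(imaginary = -(p[1] + p[2] * seq_len(n) / n)))
    sum(abs(Im(sp[edge] * ph[edge])))
  }
  p <- stats::optim(c(0, 0), obj, method = "Nelder-Mead")$par
  Re(sp * exp(complex(imaginary = -(p[1] + p[2] * seq_len(n) / n))))
}

#' Asymmetric-least-squares baseline correction
#'
#' Eilers-style ALS: iteratively reweighted smoothing with a second
#' difference penalty; points above the running baseline get weight
#' \code{p}, points below get \code{1 - p}, so peaks are ignored while
#' drift is followed.  The estimated baseline is subtracted.
#'
#' @param spec a \code{Spectrum} with finite intensities.
#' @param lambda smoothness penalty (default 1e5).
#' @param p asymmetry (default 0.01).
#' @param iterations reweighting iterations (default 10).
#' @return the corrected \code{Spectrum} (same axis).
#' @export
baselineCorrect <- function(spec, lambda = 1e5, p = 0.01, iterations = 10L) {
  y <- spec@intensity
  if (!all(is.finite(y))) stop("non-finite intensities", call. = FALSE)
  n <- length(y)
  if (n < 4 || all(y == 0)) return(spec)
  D <- Matrix::bandSparse(n - 2, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(iterations)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  new("Spectrum", axis = spec@axis, intensity = y - z, kind = spec@kind,
      metadata = spec@metadata)
}

#' Pick peaks in a spectrum
#'
#' Local maxima filtered by height, prominence (height above the higher of
#' the two flanking valleys down to the stronger neighbouring maximum) and
#' minimum separation; integration bounds are set where the intensity
#' falls to 1% of the apex height, or at the midpoint to the nearest
#' neighbouring peak, whichever is closer.
#'
#' @param spec a baseline-corrected \code{Spectrum}.
#' @param minHeight absolute apex height threshold.
#' @param minProminence prominence threshold (same units as intensity).
#' @param minSeparation minimum apex separation in axis units.
#' @return data.frame(position, height, left, right, area), sorted by
#'   position.
#' @export
pickPeaks <- function(spec, minHeight = 0.05, minProminence = 0.02,
                      minSeparation = 0) {
  x <- spec@axis
  y <- spec@intensity
  n <- length(y)
  if (n < 3) return(emptyPeaks())
  apex <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  apex <- apex[y[apex] >= minHeight & y[apex] > 0]
  if (length(apex) == 0) return(emptyPeaks())
  prom <- vapply(apex, prominence, numeric(1), y = y)
  apex <- apex[prom >= minProminence]
  if (length(apex) == 0) return(emptyPeaks())
  ## enforce separation, keeping the taller peak
  if (minSeparation > 0 && length(apex) > 1) {
    keep <- rep(TRUE, length(apex))
    ord <- order(y[apex], decreasing = TRUE)
    for (i in ord) {
      if (!keep[i]) next
      close <- abs(x[apex] - x[apex[i]]) < minSeparation & seq_along(apex) != i
      keep[close & y[apex] <= y[apex[i]]] <- FALSE
    }
    apex <- apex[keep]
  }
  apex <- sort(apex)
  peaks <- lapply(seq_along(apex), function(k) {
    i <- apex[k]
    cutoff <- 0.01 * y[i]
    li <- i; while (li > 1 && y[li] > cutoff) li <- li - 1
    ri <- i; while (ri < n && y[ri] > cutoff) ri <- ri + 1
    left <- x[li]; right <- x[ri]
    if (k > 1) left <- max(left, (x[apex[k - 1]] + x[i]) / 2)
    if (k < length(apex)) right <- min(right, (x[i] + x[apex[k + 1]]) / 2)
    data.frame(position = x[i], height = y[i], left = left, right = right,
               area = integrateRegion(spec, left, right))
  })
  do.call(rbind, peaks)
}

emptyPeaks <- function()
  data.frame(position = numeric(0), height = numeric(0), left = numeric(0),
             right = numeric(0), area = numeric(0))

## topographic prominence of the local maximum at index i
prominence <- function(i, y) {
  n <- length(y)
  h <- y[i]
  ## walk left until a higher point; track the lowest valley on the way
  lv <- h
  j <- i - 1L
  while (j >= 1 && y[j] <= h) { lv <- min(lv, y[j]); j <- j - 1L }
  leftValley <- if (j >= 1) lv else min(lv, y[1])
  rv <- h
  j <- i + 1L
  while (j <= n && y[j] <= h) { rv <- min(rv, y[j]); j <- j + 1L }
  rightValley <- if (j <= n) rv else min(rv, y[n])
  h - max(leftValley, rightValley)
}

#' Trapezoidal integration over an axis region
#'
#' Area of the intensity over [left, right] on the native grid, with
#' linear interpolation at the two cut points.  Additive over adjacent
#' regions and linear in intensity.
#'
#' @param spec a \code{Spectrum}.
#' @param left,right region bounds within the axis range, left < right.
#' @export
integrateRegion <- function(spec, left, right) {
  x <- spec@axis
  y <- spec@intensity
  if (!(left < right)) stop("left must be < right", call. = FALSE)
  if (left < x[1] - 1e-12 || right > x[length(x)] + 1e-12)
    stop("bounds outside axis", call. = FALSE)
  yi <- stats::approx(x, y, xout = c(left, right))$y
  inside <- x > left & x < right
  xs <- c(left, x[inside], right)
  ys <- c(yi[1], y[inside], yi[2])
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Match a peak near an expected position
#'
#' Nearest picked peak with |apex - expected| <= tolerance; ties at equal
#' distance break toward the larger area.
#'
#' @param peaks a peak table from \code{\link{pickPeaks}}.
#' @param expected expected apex position (axis units).
#' @param tolerance positive tolerance.
#' @return one-row peak data.frame, or NULL if no candidate.
#' @export
matchPeak <- function(peaks, expected, tolerance) {
  stopifnot(tolerance > 0)
  if (nrow(peaks) == 0) return(NULL)
  d <- abs(peaks$position - expected)
  cand <- which(d <= tolerance)
  if (length(cand) == 0) return(NULL)
  best <- cand[order(d[cand], -peaks$area[cand])][1]
  peaks[best, , drop = FALSE]
}

#' Default NMR processing chain
#'
#' zero-fill (x2) -> exponential apodization -> magnitude spectrum ->
#' ALS baseline correction.
#'
#' @param fid an \code{FID}.
#' @param lineBroadening lb in Hz.
#' @param zeroFillFactor 1, 2 or 4.
#' @param baseline apply ALS baseline correction (default TRUE).
#' @return a \code{Spectrum} (ppm axis).
#' @export
processFid <- function(fid, lineBroadening = 1, zeroFillFactor = 2L,
                       baseline = TRUE) {
  sp <- fidToSpectrum(apodize(zeroFill(fid, zeroFillFactor),
                              lineBroadening))
  if (baseline) baselineCorrect(sp) else sp
}
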