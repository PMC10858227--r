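## Spectrum -> scalar optimization targets.  Every objective is built on
## internal-standard-normalized peak areas, so a global intensity scaling
## of the spectrum never changes the value.  Failed analyses (missing
## reference band, empty spectra) return a failed result with the
## objective floor instead of raising, so campaigns keep running.

#' Define a region of interest on a spectrum axis
#' @param position expected position (native axis units).
#' @param tolerance positive matching tolerance.
#' @export
region <- function(position, tolerance) {
  stopifnot(tolerance > 0)
  list(position = position, tolerance = tolerance)
}

#' Define an optimization objective
#'
#' @param kind "auc_ratio", "purity", "desirability", "raman_conversion",
#'   "novelty" or "composite".
#' @param regions named list of \code{\link{region}}s (product, reference,
#'   known/excluded species, composite components).
#' @param reference name of the internal-standard region in \code{regions}.
#' @param weights non-negative weights (desirability weights must sum to 1).
#' @param direction "maximize" or "minimize"; minimize-direction objectives
#'   are negated before any optimizer sees them, so optimizers always
#'   maximize.
#' @param components for composite/desirability kinds: named list, each
#'   \code{list(region=, direction=, weight=)} or
#'   \code{list(kind="purity"|"scaled_ratio", region=)}.
#' @param peakOptions list passed to \code{\link{pickPeaks}} (minHeight,
#'   minProminence, minSeparation).
#' @export
objectiveSpec <- function(kind, regions = list(), reference = NULL,
                          weights = NULL, direction = "maximize",
                          components = NULL, peakOptions = list()) {
  stopifnot(kind %in% c("auc_ratio", "purity", "desirability",
                        "raman_conversion", "novelty", "composite"))
  if (kind == "desirability") {
    stopifnot(!is.null(weights), abs(sum(weights) - 1) < 1e-9)
  }
  if (kind == "composite") stopifnot(length(components) >= 1)
  structure(list(kind = kind, regions = regions, reference = reference,
                 weights = weights, direction = direction,
                 components = components, peakOptions = peakOptions),
            class = "objectiveSpec")
}

objResult <- function(value, components = list(), peaksUsed = NULL,
                      failed = FALSE, reason = NULL) {
  structure(list(value = value, components = components,
                 peaksUsed = peaksUsed, failed = failed, reason = reason),
            class = "objectiveResult")
}

pickWith <- function(spec, opts) {
  do.call(pickPeaks, c(list(spec), opts))
}

## area of the band matched to a region, integrated over a symmetric
## window (apex +/- tolerance, clipped to the axis): both product and
## reference bands then lose the same wing fraction, so area ratios are
## unbiased by the peak-bound truncation heuristic
regionArea <- function(spec, peaks, rg) {
  pk <- matchPeak(peaks, rg$position, rg$tolerance)
  if (is.null(pk)) return(NULL)
  ax <- specAxis(spec)
  lo <- max(ax[1], pk$position - rg$tolerance)
  hi <- min(ax[length(ax)], pk$position + rg$tolerance)
  pk$area <- integrateRegion(spec, lo, hi)
  pk
}

#' Product-to-reference area ratio
#'
#' Ratio of the product band area to the internal-standard band area.  A
#' missing product peak scores 0 (flagged "product-not-found"); a missing
#' or non-positive reference is an invalid-reference failure.
#'
#' @param spec a processed \code{Spectrum}.
#' @param productRegion,referenceRegion \code{\link{region}}s.
#' @param peakOptions options for \code{\link{pickPeaks}}.
#' @return an objectiveResult with the ratio as value.
#' @export
aucRatio <- function(spec, productRegion, referenceRegion,
                     peakOptions = list()) {
  peaks <- pickWith(spec, peakOptions)
  ref <- regionArea(spec, peaks, referenceRegion)
  if (is.null(ref) || ref$area <= 0)
    return(objResult(0, failed = TRUE, reason = "invalid-reference"))
  prod <- regionArea(spec, peaks, productRegion)
  if (is.null(prod))
    return(objResult(0, components = list(product = 0,
                                          reference = ref$area,
                                          flag = "product-not-found"),
                     peaksUsed = peaks))
  objResult(prod$area / ref$area,
            components = list(product = prod$area, reference = ref$area),
            peaksUsed = rbind(prod, ref))
}

#' Purity: product area over the sum of all peak areas
#'
#' @param peaks a peak table from \code{\link{pickPeaks}} (>= 1 row).
#' @param productRegion \code{\link{region}} locating the product peak.
#' @return purity in [0, 1].
#' @export
purity <- function(peaks, productRegion) {
  if (nrow(peaks) == 0) stop("empty peak list", call. = FALSE)
  prod <- matchPeak(peaks, productRegion$position, productRegion$tolerance)
  if (is.null(prod)) return(0)
  prod$area / sum(peaks$area)
}

#' Weighted-average desirability
#'
#' Convex combination of objectives pre-scaled to [0, 1]; always lies
#' between the smallest and largest component.
#'
#' @param values numeric vector of scaled objective values.
#' @param weights non-negative weights summing to 1 (tolerance 1e-9).
#' @export
desirability <- function(values, weights) {
  if (length(values) != length(weights)) stop("length mismatch",
                                              call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be >= 0 and sum to 1", call. = FALSE)
  sum(values * weights)
}

#' Conversion from Raman starting-material depletion
#'
#' r(t) = A_sm / A_std (e.g. the 1633 cm-1 alkene band over the 2250 cm-1
#' nitrile band of the internal standard); conversion = 1 - r(t)/r(0),
#' clipped to [0, 1].
#'
#' @param spec end-point \code{Spectrum}.
#' @param t0Spec time-zero \code{Spectrum}.
#' @param smRegion starting-material band (default 1633 cm-1, tol 30).
#' @param stdRegion internal-standard band (default 2250 cm-1, tol 30).
#' @param peakOptions options for \code{\link{pickPeaks}}.
#' @return an objectiveResult with conversion as value.
#' @export
ramanConversion <- function(spec, t0Spec,
                            smRegion = region(1633, 30),
                            stdRegion = region(2250, 30),
                            peakOptions = list()) {
  r <- function(s) {
    peaks <- pickWith(s, peakOptions)
    std <- regionArea(s, peaks, stdRegion)
    if (is.null(std) || std$area <= 0) return(NULL)
    sm <- regionArea(s, peaks, smRegion)
    (if (is.null(sm)) 0 else sm$area) / std$area
  }
  r0 <- r(t0Spec)
  rt <- r(spec)
  if (is.null(r0) || is.null(rt))
    return(objResult(0, failed = TRUE, reason = "standard-band-absent"))
  if (r0 <= 0)
    return(objResult(0, failed = TRUE, reason = "invalid-reference"))
  objResult(min(1, max(0, 1 - rt / r0)),
            components = list(r0 = r0, rt = rt))
}

#' Count novel peaks for discovery campaigns
#'
#' Picked peaks whose apex lies in neither the known regions (starting
#' materials, internal standard, previously catalogued products) nor the
#' exclusion regions are counted as novel; the novel regions are returned
#' so a campaign can catalogue them.  When \code{reference} is given the
#' spectrum is rescaled so the standard apex height is 1 before picking,
#' making the count invariant to global intensity scaling.
#'
#' @param spec a \code{Spectrum}.
#' @param knownRegions,exclusionRegions lists of \code{\link{region}}s.
#' @param reference optional \code{\link{region}} of the internal standard.
#' @param peakOptions options for \code{\link{pickPeaks}}.
#' @return list(count=, novel=data.frame(position, height, area),
#'   peaks=all picked peaks).
#' @export
noveltyScore <- function(spec, knownRegions = list(),
                         exclusionRegions = list(), reference = NULL,
                         peakOptions = list()) {
  if (!is.null(reference)) {
    peaks0 <- pickWith(spec, peakOptions)
    std <- regionArea(spec, peaks0, reference)
    if (!is.null(std) && std$height > 0)
      spec <- new("Spectrum", axis = spec@axis,
                  intensity = spec@intensity / std$height,
                  kind = spec@kind, metadata = spec@metadata)
  }
  peaks <- pickWith(spec, peakOptions)
  if (nrow(peaks) == 0)
    return(list(count = 0L, novel = emptyPeaks(), peaks = peaks))
  inAny <- function(pos, regions) any(vapply(regions, function(rg)
    abs(pos - rg$position) <= rg$tolerance, logical(1)))
  novel <- vapply(peaks$position, function(pos)
    !inAny(pos, knownRegions) && !inAny(pos, exclusionRegions), logical(1))
  list(count = sum(novel), novel = peaks[novel, , drop = FALSE],
       peaks = peaks)
}

#' Evaluate an objective spec on spectra
#'
#' Dispatches on the spec kind.  Composite objectives reference-normalize
#' every component area, then combine
#' sum(w+ * maximized) - sum(w- * minimized).  Minimize-direction
#' objectives are negated so the optimizer always maximizes.  Component
#' failures surface as a failed result (value at the objective floor),
#' never as an error.
#'
#' @param objSpec an \code{\link{objectiveSpec}}.
#' @param spectra named list of \code{Spectrum}s; "main" is the end-point
#'   spectrum, "t0" the time-zero spectrum for conversion objectives.
#' @return an objectiveResult.
#' @export
evaluateObjective <- function(objSpec, spectra) {
  spec <- if (is(spectra, "Spectrum")) spectra else spectra$main
  res <- tryCatch(switch(objSpec$kind,
    auc_ratio = aucRatio(spec, objSpec$regions$product,
                         objSpec$regions[[objSpec$reference]],
                         objSpec$peakOptions),
    purity = {
      peaks <- pickWith(spec, objSpec$peakOptions)
      if (nrow(peaks) == 0)
        objResult(0, failed = TRUE, reason = "no-peaks")
      else objResult(purity(peaks, objSpec$regions$product),
                     peaksUsed = peaks)
    },
    desirability = evaluateDesirability(objSpec, spec),
    raman_conversion = ramanConversion(spec, spectra$t0,
                                       objSpec$regions$product,
                                       objSpec$regions[[objSpec$reference]],
                                       objSpec$peakOptions),
    novelty = {
      ## every listed region -- starting materials, catalogued products
      ## AND the internal standard -- counts as known
      ns <- noveltyScore(spec, knownRegions = objSpec$regions,
                         reference = objSpec$regions[[objSpec$reference]],
                         peakOptions = objSpec$peakOptions)
      objResult(as.numeric(ns$count),
                components = list(novel = ns$novel), peaksUsed = ns$peaks)
    },
    composite = evaluateComposite(objSpec, spec)),
    error = function(e) objResult(0, failed = TRUE,
                                  reason = conditionMessage(e)))
  if (identical(objSpec$direction, "minimize") && !res$failed)
    res$value <- -res$value
  res
}

evaluateDesirability <- function(objSpec, spec) {
  peaks <- pickWith(spec, objSpec$peakOptions)
  ref <- regionArea(spec, peaks, objSpec$regions[[objSpec$reference]])
  if (is.null(ref) || ref$area <= 0)
    return(objResult(0, failed = TRUE, reason = "invalid-reference"))
  vals <- vapply(objSpec$components, function(cmp) {
    if (identical(cmp$kind, "purity")) {
      if (nrow(peaks) == 0) 0 else purity(peaks, cmp$region)
    } else {  # scaled_ratio: r / (1 + r) maps [0, Inf) onto [0, 1)
      pk <- regionArea(spec, peaks, cmp$region)
      r <- if (is.null(pk)) 0 else pk$area / ref$area
      r / (1 + r)
    }
  }, numeric(1))
  objResult(desirability(vals, objSpec$weights),
            components = as.list(stats::setNames(vals,
                                                 names(objSpec$components))),
            peaksUsed = peaks)
}

evaluateComposite <- function(objSpec, spec) {
  peaks <- pickWith(spec, objSpec$peakOptions)
  ref <- regionArea(spec, peaks, objSpec$regions[[objSpec$reference]])
  if (is.null(ref) || ref$area <= 0)
    return(objResult(0, failed = TRUE, reason = "invalid-reference"))
  comps <- list()
  val <- 0
  for (nm in names(objSpec$components)) {
    cmp <- objSpec$components[[nm]]
    pk <- regionArea(spec, peaks, cmp$region)
    a <- if (is.null(pk)) 0 else pk$area / ref$area
    comps[[nm]] <- a
    val <- val + if (identical(cmp$direction, "minimize")) -cmp$weight * a
                 else cmp$weight * a
  }
  objResult(val, components = comps, peaksUsed = peaks)
}
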