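## Spectrum / FID accessors, constructors and plain-text I/O.

#' Construct a spectrum
#'
#' @param axis numeric axis values (any order; stored ascending).
#' @param intensity matching intensities.
#' @param kind "ppm", "minutes" or "cm-1".
#' @param metadata free-form list.
#' @export
spectrum <- function(axis, intensity, kind, metadata = list()) {
  o <- order(axis)
  new("Spectrum", axis = axis[o], intensity = intensity[o], kind = kind,
      metadata = metadata)
}

#' Spectrum accessors
#' @param object a \code{Spectrum}.
#' @name spectrumAccessors
NULL

#' @rdname spectrumAccessors
setMethod("specAxis", "Spectrum", function(object) object@axis)
#' @rdname spectrumAccessors
setMethod("specIntensity", "Spectrum", function(object) object@intensity)
#' @rdname spectrumAccessors
setMethod("axisKind", "Spectrum", function(object) object@kind)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum (%s): %d points, axis [%g, %g]\n", object@kind,
              length(object@axis), object@axis[1],
              object@axis[length(object@axis)]))
})

setMethod("show", "FID", function(object) {
  cat(sprintf("FID: %d complex points, dwell %g s, %.1f MHz\n",
              length(object@samples), object@dwell, object@frequencyMHz))
})

#' Length of an FID in points
#' @param x an \code{FID}.
#' @export
setMethod("length", "FID", function(x) length(x@samples))

#' Write / read a spectrum as two-column CSV
#'
#' Header lines \code{# kind: <kind>} precede an \code{axis,intensity}
#' table, so generated spectra stay plain text and diff cleanly.
#' @param spec a \code{Spectrum}.
#' @param path file path.
#' @export
writeSpectrumCsv <- function(spec, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# kind: %s", spec@kind), "axis,intensity"), con,
             useBytes = TRUE)
  writeLines(sprintf("%.10g,%.10g", spec@axis, spec@intensity), con,
             useBytes = TRUE)
  invisible(path)
}

#' @rdname writeSpectrumCsv
#' @export
readSpectrumCsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kind <- sub("^# kind: *", "", lines[1])
  dat <- utils::read.csv(text = lines[-1], header = TRUE)
  spectrum(dat$axis, dat$intensity, kind)
}
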