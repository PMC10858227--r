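#' Create a unit-carrying quantity
#'
#' @param value finite numeric scalar.
#' @param unit one of \code{mL}, \code{mmol}, \code{min}, \code{h}, \code{s},
#'   \code{degC} (alias \code{°C}), \code{mL/min}, \code{mol/L},
#'   \code{dimensionless}.
#' @return a \code{Quantity}.
#' @examples
#' quantity(0.2, "mL")
#' convertQuantity(quantity(2, "h"), "min")
#' @export
quantity <- function(value, unit = "dimensionless") {
  unit <- canonicalUnit(unit)
  new("Quantity", value = as.numeric(value), unit = unit)
}

canonicalUnit <- function(unit) {
  if (unit %in% names(.unitAliases)) unit <- unname(.unitAliases[unit])
  if (!unit %in% .unitTable$unit)
    stop(sprintf("malformed unit '%s'", unit), call. = FALSE)
  unit
}

#' Dimension of a unit
#' @param unit unit name (aliases accepted).
#' @return one of volume, amount, time, temperature, flow, concentration,
#'   dimensionless.
#' @export
unitDimension <- function(unit) {
  unit <- canonicalUnit(unit)
  .unitTable$dimension[match(unit, .unitTable$unit)]
}

#' Exact unit conversion within a dimension
#' @param q a \code{Quantity}.
#' @param unit target unit of the same dimension.
#' @export
convertQuantity <- function(q, unit) {
  unit <- canonicalUnit(unit)
  if (unitDimension(q@unit) != unitDimension(unit))
    stop(sprintf("cannot convert '%s' to '%s': different dimensions",
                 q@unit, unit), call. = FALSE)
  f <- .unitTable$factor[match(q@unit, .unitTable$unit)] /
    .unitTable$factor[match(unit, .unitTable$unit)]
  quantity(q@value * f, unit)
}

#' @rdname quantity
#' @param q a \code{Quantity}.
#' @export
qValue <- function(q) q@value

#' @rdname quantity
#' @export
qUnit <- function(q) q@unit

## numeric value of q expressed in `unit`
qIn <- function(q, unit) convertQuantity(q, unit)@value

setMethod("show", "Quantity", function(object) {
  cat(formatQuantity(object), "\n")
})

#' Compare or combine quantities dimension-safely
#'
#' Arithmetic and comparison for quantities of the same dimension; the
#' result of \code{+}/\code{-} carries the left operand's unit.  Mixing
#' dimensions is an error.
#' @param e1,e2 \code{Quantity} objects.
#' @export
setMethod("Ops", signature("Quantity", "Quantity"), function(e1, e2) {
  v2 <- qIn(e2, e1@unit)
  r <- callGeneric(e1@value, v2)
  if (is.logical(r)) r else quantity(r, e1@unit)
})

## canonical 6-significant-digit, locale-independent rendering
formatNumber <- function(x) {
  s <- sprintf("%.6g", x)
  ## strip redundant exponent zeros for byte stability across platforms
  sub("e([+-])0*(\\d\\d+)", "e\\1\\2", s)
}

formatQuantity <- function(q) {
  if (q@unit == "dimensionless") formatNumber(q@value)
  else paste(formatNumber(q@value), q@unit)
}

## parse "0.2 mL" (or bare number) into a Quantity; NULL if not quantity-like
parseQuantityString <- function(x) {
  if (is.numeric(x)) return(quantity(x))
  if (!is.character(x) || length(x) != 1L) return(NULL)
  m <- regmatches(x, regexec(
    "^\\s*([-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)\\s+(\\S+)\\s*$", x))[[1]]
  if (length(m) != 3L) return(NULL)
  unit <- tryCatch(canonicalUnit(m[3]), error = function(e) NULL)
  if (is.null(unit)) return(NULL)
  quantity(as.numeric(m[2]), unit)
}
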