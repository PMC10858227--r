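## Canonical procedure dialect: YAML documents with top-level keys
## {id, version, metadata, steps}; steps as {id, name, properties, children}.
## Serialization is byte-stable: fixed key order, 6-significant-digit
## numbers, "." decimal point, ASCII unit names (degC, not the degree sign).

#' Parse a procedure document
#'
#' @param text document text (YAML dialect), or NULL when \code{file} given.
#' @param file path to a \code{*.chemdsl.yaml} file.
#' @return a validated \code{Procedure}; version defaults to 0 when the
#'   document carries no \code{version} key.
#' @examples
#' p <- parseProcedure(text = "
#' id: demo
#' steps:
#'   - id: a1
#'     name: Add
#'     properties: {reagent: water, volume: 0.2 mL}
#'   - id: s1
#'     name: Stir
#'     properties: {time: 5 min}
#' ")
#' procVersion(p)
#' @export
parseProcedure <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(yaml::yaml.load(text),
                  error = function(e) stop(sprintf("syntax error: %s",
                                                   conditionMessage(e)),
                                           call. = FALSE))
  if (!is.list(doc) || is.null(doc$id))
    stop("document must be a mapping with an 'id' key", call. = FALSE)
  if (is.null(doc$steps) || length(doc$steps) == 0)
    stop("document has no steps", call. = FALSE)
  procedure(id = as.character(doc$id),
            steps = lapply(doc$steps, parseStepNode),
            version = if (is.null(doc$version)) 0L else as.integer(doc$version),
            metadata = if (is.null(doc$metadata)) list() else doc$metadata)
}

parseStepNode <- function(node) {
  if (is.null(node$id) || is.null(node$name))
    stop("every step needs 'id' and 'name'", call. = FALSE)
  props <- if (is.null(node$properties)) list() else node$properties
  kids <- if (is.null(node$children)) list()
          else lapply(node$children, parseStepNode)
  do.call(step, c(list(id = as.character(node$id),
                       name = as.character(node$name)),
                  props, list(children = kids)))
}

#' Serialize a procedure to its canonical byte-stable text
#'
#' Serializing the same procedure twice yields identical bytes, and
#' \code{parseProcedure(serializeProcedure(p))} equals \code{p}, so
#' versioned procedure files diff cleanly.
#'
#' @param procedure a \code{Procedure}.
#' @return a single character string (ends with newline).
#' @export
serializeProcedure <- function(procedure) {
  checkProcedure(procedure)
  ln <- c(sprintf("id: %s", yamlScalar(procedure@procId)),
          sprintf("version: %d", procedure@version))
  if (length(procedure@metadata)) {
    ln <- c(ln, "metadata:", emitYaml(procedure@metadata, indent = 2L))
  }
  ln <- c(ln, "steps:")
  for (s in procedure@steps) ln <- c(ln, emitStep(s, indent = 2L))
  paste0(paste(ln, collapse = "\n"), "\n")
}

#' Write / read procedure files
#' @param procedure a \code{Procedure}.
#' @param path file path (conventionally \code{<id>_v<version>.chemdsl.yaml}).
#' @export
writeProcedure <- function(procedure, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(serializeProcedure(procedure), con, sep = "", useBytes = TRUE)
  invisible(path)
}

#' @rdname writeProcedure
#' @export
readProcedure <- function(path) parseProcedure(file = path)

emitStep <- function(s, indent) {
  pad <- strrep(" ", indent)
  ln <- c(sprintf("%s- id: %s", pad, yamlScalar(s@stepId)),
          sprintf("%s  name: %s", pad, s@name))
  if (length(s@properties)) {
    ln <- c(ln, sprintf("%s  properties:", pad))
    for (p in sort(names(s@properties))) {
      v <- s@properties[[p]]
      val <- if (is(v, "Quantity")) quantityScalar(v) else yamlScalar(v)
      ln <- c(ln, sprintf("%s    %s: %s", pad, p, val))
    }
  }
  if (length(s@children)) {
    ln <- c(ln, sprintf("%s  children:", pad))
    for (ch in s@children) ln <- c(ln, emitStep(ch, indent + 4L))
  }
  ln
}

## dimensionless quantities round-trip as plain YAML numbers
quantityScalar <- function(q) {
  if (q@unit == "dimensionless") formatNumber(q@value)
  else yamlScalar(formatQuantity(q))
}

yamlScalar <- function(x) {
  if (is.numeric(x)) return(formatNumber(x))
  x <- as.character(x)
  if (grepl("^[A-Za-z0-9][A-Za-z0-9 _.,()/°=-]*$", x) &&
      !grepl("^(true|false|yes|no|null)$", tolower(x)) && !grepl("  ", x) &&
      !grepl("[ ]$", x))
    x
  else paste0("'", gsub("'", "''", x), "'")
}

## minimal canonical YAML emitter for metadata: scalars, flat lists,
## lists of flat maps; keys alphabetical
emitYaml <- function(x, indent) {
  pad <- strrep(" ", indent)
  out <- character(0)
  for (k in sort(names(x))) {
    v <- x[[k]]
    if (is.list(v)) {
      out <- c(out, sprintf("%s%s:", pad, k))
      for (item in v) {
        if (is.list(item)) {
          ks <- sort(names(item))
          first <- TRUE
          for (ik in ks) {
            lead <- if (first) sprintf("%s  - ", pad) else
              sprintf("%s    ", pad)
            out <- c(out, sprintf("%s%s: %s", lead, ik, yamlScalar(item[[ik]])))
            first <- FALSE
          }
        } else out <- c(out, sprintf("%s  - %s", pad, yamlScalar(item)))
      }
    } else out <- c(out, sprintf("%s%s: %s", pad, k, yamlScalar(v)))
  }
  out
}

#' Read an optimization config
#'
#' A YAML list of entries \code{{step, property, lower, upper, unit, scale}}
#' naming the procedure properties to optimize and their bounds.
#'
#' @param file path, or \code{text=} for inline YAML.
#' @param text inline YAML.
#' @return list of config entries (used by \code{\link{extractParameters}}).
#' @export
readOptimizeConfig <- function(file = NULL, text = NULL) {
  doc <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(file)
  if (is.null(doc)) return(list())
  lapply(doc, function(e) {
    stopifnot(!is.null(e$step), !is.null(e$property),
              !is.null(e$lower), !is.null(e$upper), !is.null(e$unit))
    e$scale <- if (is.null(e$scale)) "linear" else e$scale
    e
  })
}
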