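#' Declare a cohort variable
#'
#' A variable specification records the name, measurement kind and, for
#' binary/categorical variables, which category carries the risk (the value a
#' pattern condition such as \code{urgent_pci = Yes} refers to).
#'
#' @param name Variable name; must match a CSV column header.
#' @param kind One of \code{"numeric"}, \code{"binary"}, \code{"categorical"}.
#' @param units Free-text units (e.g. \code{"ml"}, \code{"ml/min"},
#'   \code{"umol/L"}); informational only.
#' @param positive_category For binary/categorical variables, the category
#'   treated as risk-bearing (e.g. \code{"Yes"}). Must be \code{NULL} for
#'   numeric variables.
#' @return An object of class \code{variable_spec}.
#' @export
#' @examples
#' variable_spec("age", "numeric", units = "years")
#' variable_spec("urgent_pci", "binary", positive_category = "Yes")
variable_spec <- function(name, kind = c("numeric", "binary", "categorical"),
                          units = "", positive_category = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "numeric" && !is.null(positive_category)) {
    stop("positive_category is only meaningful for binary/categorical variables")
  }
  if (!is.null(positive_category)) {
    stopifnot(is.character(positive_category), length(positive_category) == 1L)
  }
  structure(
    list(name = name, kind = kind, units = units,
         positive_category = positive_category),
    class = "variable_spec"
  )
}

#' Build a cohort schema from variable specifications
#'
#' @param ... \code{variable_spec} objects (or a single list of them).
#' @return A named list of class \code{cohort_schema}; names are variable names.
#' @export
cohort_schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1L]], "variable_spec")) {
    specs <- specs[[1L]]
  }
  ok <- vapply(specs, inherits, logical(1L), "variable_spec")
  if (!all(ok)) stop("all schema entries must be variable_spec objects")
  nms <- vapply(specs, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate variable names in schema: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(specs) <- nms
  structure(specs, class = "cohort_schema")
}

#' Read a variable schema from a YAML or JSON config file
#'
#' The file holds a list of \code{{name, kind, units, positive_category}}
#' entries. Format is chosen by extension (\code{.yaml}/\code{.yml} vs
#' \code{.json}).
#'
#' @param path Path to the schema file.
#' @return A \code{cohort_schema}.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    stop("unsupported schema format: .", ext, " (use .yaml, .yml or .json)")
  }
  specs <- lapply(raw, function(entry) {
    if (is.null(entry$name) || is.null(entry$kind)) {
      stop("schema entries need at least 'name' and 'kind' fields")
    }
    variable_spec(entry$name, entry$kind,
                  units = if (is.null(entry$units)) "" else entry$units,
                  positive_category = entry$positive_category)
  })
  cohort_schema(specs)
}

#' Write a schema to YAML or JSON
#'
#' @param schema A \code{cohort_schema}.
#' @param path Output path; extension selects the format.
#' @return \code{path}, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "cohort_schema"))
  entries <- lapply(unname(schema), function(s) {
    e <- list(name = s$name, kind = s$kind, units = s$units)
    if (!is.null(s$positive_category)) e$positive_category <- s$positive_category
    e
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(entries, path)
  } else if (ext == "json") {
    jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    stop("unsupported schema format: .", ext)
  }
  invisible(path)
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s [%s]%s%s\n", x$name, x$kind,
              if (nzchar(x$units)) paste0(" units=", x$units) else "",
              if (!is.null(x$positive_category))
                paste0(" positive=", x$positive_category) else ""))
  invisible(x)
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat(sprintf("<cohort_schema> %d variables\n", length(x)))
  for (s in x) print(s)
  invisible(x)
}
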