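#' A single pattern condition
#'
#' One variable-value comparison: \code{<=} or \code{>} against a numeric
#' threshold, or \code{==} against a category. \code{<=} is inclusive,
#' \code{>} exclusive, exactly as the conditions read.
#'
#' @param variable Variable name.
#' @param comparator One of \code{"<="}, \code{">"}, \code{"=="}.
#' @param value Numeric threshold (for \code{<=}/\code{>}) or category string
#'   (for \code{==}).
#' @return An object of class \code{pattern_condition}.
#' @export
#' @examples
#' condition("lvef", "<=", 56.6)
#' condition("urgent_pci", "==", "Yes")
condition <- function(variable, comparator = c("<=", ">", "=="), value) {
  comparator <- match.arg(comparator)
  stopifnot(is.character(variable), length(variable) == 1L, nzchar(variable))
  if (comparator %in% c("<=", ">")) {
    if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
      stop("comparator '", comparator, "' requires a single numeric value")
    }
    value <- as.numeric(value)
  } else {
    if (length(value) != 1L || is.na(value)) {
      stop("comparator '==' requires a single category value")
    }
    value <- as.character(value)
  }
  structure(list(variable = variable, comparator = comparator, value = value),
            class = "pattern_condition")
}

#' @export
print.pattern_condition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.pattern_condition <- function(x, ...) {
  val <- if (is.numeric(x$value)) format(x$value) else x$value
  comp <- if (x$comparator == "==") "=" else x$comparator
  sprintf("%s %s %s", x$variable, comp, val)
}

#' Construct a risk pattern
#'
#' A pattern predicts its target class for any record matching at least
#' \code{min_matches} (k) of its \code{m} conditions. The matching threshold
#' is displayed to users as a percentage ratio (see
#' \code{\link{display_ratio}}) but k itself is authoritative.
#'
#' @param target_variable Outcome variable name.
#' @param conditions List of \code{\link{condition}} objects over distinct
#'   variables.
#' @param min_matches Integer k with \code{1 <= k <= m}.
#' @param positive_class Label of the predicted class (display only).
#' @param mode_tag Which knowledge-incorporation stage produced the pattern:
#'   \code{"pre"} (data-driven), \code{"in"} (clinician edit + data-driven
#'   threshold), \code{"post"} (data-free refinement).
#' @param history List of history entries (see
#'   \code{\link{history_entry}}); maintained by the discovery and editing
#'   functions.
#' @return An object of class \code{risk_pattern}.
#' @export
pattern <- function(target_variable, conditions, min_matches,
                    positive_class = "Yes",
                    mode_tag = c("pre", "in", "post"),
                    history = list()) {
  mode_tag <- match.arg(mode_tag)
  ok <- vapply(conditions, inherits, logical(1L), "pattern_condition")
  if (length(conditions) < 1L || !all(ok)) {
    stop("conditions must be a non-empty list of pattern_condition objects")
  }
  vars <- vapply(conditions, `[[`, character(1L), "variable")
  if (anyDuplicated(vars)) {
    stop("pattern variables must be distinct; duplicated: ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "))
  }
  m <- length(conditions)
  min_matches <- as.integer(min_matches)
  if (is.na(min_matches) || min_matches < 1L || min_matches > m) {
    stop("min_matches must be an integer in [1, ", m, "]")
  }
  structure(
    list(target = list(variable = target_variable,
                       positive_class = positive_class),
         conditions = conditions, min_matches = min_matches,
         mode_tag = mode_tag, history = history),
    class = "risk_pattern"
  )
}

#' @export
print.risk_pattern <- function(x, ...) {
  m <- length(x$conditions)
  cat(sprintf("<risk_pattern> %s = %s  [%s-mode]\n",
              x$target$variable, x$target$positive_class, x$mode_tag))
  cat(sprintf("  match at least %d of %d conditions (matching ratio %d%%):\n",
              x$min_matches, m, display_ratio(x$min_matches, m)))
  for (cond in x$conditions) cat("   -", format(cond), "\n")
  if (length(x$history)) {
    cat(sprintf("  history: %d entr%s\n", length(x$history),
                if (length(x$history) == 1L) "y" else "ies"))
  }
  invisible(x)
}

#' Convert a matching ratio to a minimum match count
#'
#' The matching ratio is the user-facing percentage form of the k-of-m
#' threshold. Parsing uses the ceiling: a ratio of 18\% on an 11-condition
#' pattern requires at least \code{ceiling(0.18 * 11) = 2} matches, and 27\%
#' requires 3.
#'
#' @param ratio Proportion in (0, 1].
#' @param m Number of conditions, \code{m >= 1}.
#' @return Integer k in \code{[1, m]}.
#' @export
#' @examples
#' min_matches_from_ratio(0.18, 11)  # 2
#' min_matches_from_ratio(0.27, 11)  # 3
min_matches_from_ratio <- function(ratio, m) {
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) ||
      ratio <= 0 || ratio > 1) {
    stop("ratio must be in (0, 1]")
  }
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be a positive integer")
  k <- as.integer(ceiling(ratio * m - 1e-9))
  min(max(k, 1L), m)
}

#' Display a k-of-m threshold as a percentage matching ratio
#'
#' Display uses the floor percent: 2 of 11 shows as 18\%, 3 of 11 as 27\%.
#' Together with the ceiling used by \code{\link{min_matches_from_ratio}}
#' this makes display and parse mutually inverse, which plain rounding would
#' break.
#'
#' @param k Minimum match count.
#' @param m Number of conditions.
#' @return Integer percentage.
#' @export
display_ratio <- function(k, m) {
  k <- as.integer(k)
  m <- as.integer(m)
  if (is.na(k) || is.na(m) || m < 1L || k < 1L || k > m) {
    stop("require 1 <= k <= m")
  }
  as.integer(floor(100 * k / m + 1e-9))
}

# n x m logical matrix of per-record condition matches over a data.frame.
# A missing value never matches; a variable absent from the data never
# matches (unknown variables in a record are simply not satisfied).
condition_match_matrix <- function(conditions, data) {
  n <- nrow(data)
  m <- length(conditions)
  out <- matrix(FALSE, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    cond <- conditions[[j]]
    if (!cond$variable %in% names(data)) next
    v <- data[[cond$variable]]
    hit <- switch(cond$comparator,
      "<=" = as.numeric(v) <= cond$value,
      ">"  = as.numeric(v) > cond$value,
      "==" = as.character(v) == cond$value)
    hit[is.na(hit)] <- FALSE
    out[, j] <- hit
  }
  colnames(out) <- vapply(conditions, `[[`, character(1L), "variable")
  out
}

record_as_df <- function(record) {
  if (inherits(record, "cohort")) return(record$data)
  if (is.data.frame(record)) return(record)
  if (is.list(record)) return(as.data.frame(record, stringsAsFactors = FALSE))
  stop("record must be a cohort, data.frame or named list")
}

#' Count matched conditions per record
#'
#' A missing value satisfies no condition; \code{<=} is inclusive and
#' \code{>} exclusive at the boundary.
#'
#' @param pattern A \code{risk_pattern}.
#' @param record A named list (single record), data.frame, or \code{cohort}.
#' @return Integer vector of matched-condition counts (one per record).
#' @export
match_count <- function(pattern, record) {
  stopifnot(inherits(pattern, "risk_pattern"))
  df <- record_as_df(record)
  as.integer(rowSums(condition_match_matrix(pattern$conditions, df)))
}

#' Matched fraction per record
#'
#' \code{match_count / m}, the natural continuous score of a k-of-m pattern,
#' used for its ROC curve and AUC.
#'
#' @inheritParams match_count
#' @return Numeric vector in \code{[0, 1]}.
#' @export
match_fraction <- function(pattern, record) {
  match_count(pattern, record) / length(pattern$conditions)
}

#' Predict with a risk pattern
#'
#' @param object A \code{risk_pattern}.
#' @param newdata A \code{cohort}, data.frame or named list of records.
#' @param type \code{"class"} for the binary k-of-m prediction,
#'   \code{"score"} for the matched fraction, \code{"count"} for the raw
#'   match count.
#' @param ... Unused.
#' @return Logical, numeric or integer vector, one element per record.
#' @export
predict.risk_pattern <- function(object, newdata,
                                 type = c("class", "score", "count"), ...) {
  type <- match.arg(type)
  counts <- match_count(object, newdata)
  switch(type,
         class = counts >= object$min_matches,
         score = counts / length(object$conditions),
         count = counts)
}
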