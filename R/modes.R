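#' A single pattern edit
#'
#' Edits are the unit of clinician interaction: adding or removing a
#' condition, changing a condition's value or comparator, or (post-mode
#' only) overriding the matching threshold.
#'
#' @param action One of \code{"add_variable"}, \code{"remove_variable"},
#'   \code{"set_value"}, \code{"set_comparator"}, \code{"set_min_matches"}.
#' @param variable Variable the edit refers to (not used by
#'   \code{set_min_matches}).
#' @param payload Action-dependent: for \code{add_variable} either
#'   \code{NULL} (in-mode derives the cutoff from training data) or a list
#'   with \code{comparator} and \code{value}; for \code{set_value} the new
#'   value; for \code{set_comparator} the new comparator; for
#'   \code{set_min_matches} the new k.
#' @return A list of class \code{pattern_edit}.
#' @export
#' @examples
#' pattern_edit("set_comparator", "age", ">")
#' pattern_edit("set_value", "contrast_volume", 100)
pattern_edit <- function(action = c("add_variable", "remove_variable",
                                    "set_value", "set_comparator",
                                    "set_min_matches"),
                         variable = NULL, payload = NULL) {
  action <- match.arg(action)
  if (action != "set_min_matches" &&
      (is.null(variable) || !nzchar(variable))) {
    stop("edit action '", action, "' requires a variable name")
  }
  if (action %in% c("set_value", "set_comparator", "set_min_matches") &&
      is.null(payload)) {
    stop("edit action '", action, "' requires a payload")
  }
  # normalize numeric payloads to double so JSON round-trips compare equal
  if (is.numeric(payload)) payload <- as.numeric(payload)
  if (is.list(payload) && is.numeric(payload$value)) {
    payload$value <- as.numeric(payload$value)
  }
  structure(list(action = action, variable = variable, payload = payload),
            class = "pattern_edit")
}

#' Read / write an edit list as JSON
#'
#' The edit file is the headless counterpart of interactive editing: a JSON
#' array of \code{{action, variable, payload}} objects.
#'
#' @param path Path to the edit JSON.
#' @return \code{read_edits}: list of \code{\link{pattern_edit}} objects.
#' @export
read_edits <- function(path) {
  if (!file.exists(path)) stop("edit file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(doc, function(e) {
    if (is.null(e$action)) stop("edit entry missing field 'action'")
    pattern_edit(e$action, variable = e$variable, payload = e$payload)
  })
}

#' @rdname read_edits
#' @param edits List of \code{pattern_edit} objects.
#' @export
write_edits <- function(edits, path) {
  jsonlite::write_json(lapply(edits, unclass), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# Apply an edit list to a condition list. `schema`/`train` are optional: when
# present (in-mode) they enable type checking and data-derived cutoffs; when
# absent (post-mode, history replay) edits must be fully explicit.
# Returns list(conditions, k_override).
apply_edit_list <- function(conditions, edits, schema = NULL, train = NULL) {
  k_override <- NULL
  vars <- function() vapply(conditions, `[[`, character(1L), "variable")
  check_kind <- function(variable, comparator, value) {
    if (!is.null(schema)) {
      if (!variable %in% names(schema)) {
        stop("edit refers to unknown variable '", variable, "'")
      }
      kind <- schema[[variable]]$kind
      if (kind == "numeric" && comparator == "==") {
        stop("variable '", variable, "' is numeric; use '<=' or '>'")
      }
      if (kind != "numeric" && comparator != "==") {
        stop("variable '", variable, "' is ", kind, "; use '=='")
      }
      if (kind == "numeric" && !is.numeric(value)) {
        stop("variable '", variable, "' is numeric; got non-numeric value '",
             value, "'")
      }
    } else {
      if (comparator %in% c("<=", ">") && !is.numeric(value)) {
        stop("comparator '", comparator,
             "' requires a numeric value for variable '", variable, "'")
      }
    }
  }
  for (e in edits) {
    stopifnot(inherits(e, "pattern_edit"))
    if (e$action == "set_min_matches") {
      k_override <- as.integer(e$payload)
      next
    }
    at <- match(e$variable, vars())
    if (e$action == "add_variable") {
      if (!is.na(at)) {
        stop("variable '", e$variable, "' is already in the pattern")
      }
      cond <- build_added_condition(e, schema, train)
      conditions[[length(conditions) + 1L]] <- cond
    } else if (e$action == "remove_variable") {
      if (is.na(at)) {
        stop("variable '", e$variable, "' is not in the pattern")
      }
      if (length(conditions) == 1L) {
        stop("cannot remove the last remaining condition")
      }
      conditions[[at]] <- NULL
    } else if (e$action == "set_value") {
      if (is.na(at)) {
        stop("variable '", e$variable, "' is not in the pattern")
      }
      old <- conditions[[at]]
      check_kind(e$variable, old$comparator, e$payload)
      conditions[[at]] <- condition(old$variable, old$comparator, e$payload)
    } else if (e$action == "set_comparator") {
      if (is.na(at)) {
        stop("variable '", e$variable, "' is not in the pattern")
      }
      old <- conditions[[at]]
      check_kind(e$variable, e$payload, old$value)
      conditions[[at]] <- condition(old$variable, e$payload, old$value)
    }
  }
  list(conditions = conditions, k_override = k_override)
}

build_added_condition <- function(e, schema, train) {
  payload <- e$payload
  has_value <- !is.null(payload) && !is.null(payload$value)
  if (has_value) {
    comp <- payload$comparator
    if (is.null(comp)) {
      if (!is.null(schema) && schema[[e$variable]]$kind != "numeric") {
        comp <- "=="
      } else {
        stop("add_variable for '", e$variable,
             "' needs an explicit comparator")
      }
    }
    if (!is.null(schema)) {
      if (!e$variable %in% names(schema)) {
        stop("edit refers to unknown variable '", e$variable, "'")
      }
      kind <- schema[[e$variable]]$kind
      if (kind == "numeric" && comp == "==") {
        stop("variable '", e$variable, "' is numeric; use '<=' or '>'")
      }
      if (kind != "numeric" && comp != "==") {
        stop("variable '", e$variable, "' is ", kind, "; use '=='")
      }
      if (kind == "numeric" && !is.numeric(payload$value)) {
        stop("variable '", e$variable,
             "' is numeric; got non-numeric value '", payload$value, "'")
      }
    }
    return(condition(e$variable, comp, payload$value))
  }
  # no explicit value: derive from training data (in-mode only)
  if (is.null(train)) {
    stop("add_variable for '", e$variable,
         "' needs an explicit value when no training data is available")
  }
  if (!e$variable %in% names(train$schema)) {
    stop("edit refers to unknown variable '", e$variable, "'")
  }
  spec <- train$schema[[e$variable]]
  labels <- cohort_labels(train)
  v <- train$data[[e$variable]]
  if (spec$kind == "numeric") {
    rule <- best_split(v, labels, e$variable)
    if (is.null(rule)) {
      stop("no informative cutoff found for '", e$variable, "'")
    }
    ok <- !is.na(v)
    rate_le <- mean(labels[ok & v <= rule$cutoff])
    rate_gt <- mean(labels[ok & v > rule$cutoff])
    comp <- if (isTRUE(rate_gt > rate_le)) ">" else "<="
    condition(e$variable, comp, rule$cutoff)
  } else if (!is.null(spec$positive_category)) {
    condition(e$variable, "==", spec$positive_category)
  } else {
    stop("add_variable for categorical '", e$variable,
         "' needs an explicit category value")
  }
}

#' In-mode: apply clinician edits and re-optimize the threshold on data
#'
#' The edited conditions are taken exactly as the clinician specified - no
#' data-driven revision touches any condition the edit list did not name.
#' The matching threshold k is then re-optimized on the training cohort, so
#' the pattern "rediscovers" its operating point around the injected
#' knowledge. (With \code{config$rediscover = TRUE} the full greedy search
#' is re-run with the edited conditions pinned; off by default.)
#'
#' @param pattern A \code{risk_pattern}.
#' @param edits List of \code{\link{pattern_edit}}s; \code{set_min_matches}
#'   is not allowed here (the threshold is data-optimized in this mode).
#' @param train Training \code{cohort}.
#' @param config A \code{\link{discovery_config}}.
#' @return The edited \code{risk_pattern}, tagged \code{in}, with one new
#'   history entry; the updated training metrics are attached as
#'   \code{attr(, "training_metrics")}.
#' @export
apply_in_mode <- function(pattern, edits, train,
                          config = discovery_config()) {
  stopifnot(inherits(pattern, "risk_pattern"), inherits(train, "cohort"))
  actions <- vapply(edits, `[[`, character(1L), "action")
  if (any(actions == "set_min_matches")) {
    stop("set_min_matches is only legal in post-mode; ",
         "in-mode re-optimizes the threshold from the training data")
  }
  res <- apply_edit_list(pattern$conditions, edits,
                         schema = train$schema, train = train)
  conds <- res$conditions
  if (config$rediscover) {
    rediscovered <- discover_pattern(train, config, pinned = conds)
    conds <- rediscovered$conditions
  }
  k <- suppressWarnings(optimize_threshold(conds, train, config$objective))
  entry <- history_entry("in", m = length(conds), k = as.integer(k),
                         edits = edits, objective = attr(k, "objective"))
  out <- pattern(pattern$target$variable, conds, as.integer(k),
                 positive_class = pattern$target$positive_class,
                 mode_tag = "in", history = c(pattern$history, list(entry)))
  attr(out, "training_metrics") <- evaluate_pattern(out, train)
  out
}

#' Post-mode: data-free refinement
#'
#' Applies the clinician's overrides verbatim - condition values,
#' comparators, added/removed variables, and optionally the matching
#' threshold itself - with no access to any cohort and no re-optimization.
#' This is the knowledge-only stage after the pattern has been exported.
#'
#' @param pattern A \code{risk_pattern}.
#' @param edits List of \code{\link{pattern_edit}}s; \code{add_variable}
#'   needs explicit comparator and value here.
#' @return The refined \code{risk_pattern}, tagged \code{post}, with one new
#'   history entry. If the (possibly overridden) threshold falls outside
#'   \code{[1, m]} after the edits, an error is raised.
#' @export
apply_post_mode <- function(pattern, edits) {
  stopifnot(inherits(pattern, "risk_pattern"))
  res <- apply_edit_list(pattern$conditions, edits,
                         schema = NULL, train = NULL)
  m <- length(res$conditions)
  k <- if (is.null(res$k_override)) pattern$min_matches else res$k_override
  if (k < 1L || k > m) {
    stop("matching threshold ", k, " is outside [1, ", m,
         "] after the edits")
  }
  entry <- history_entry("post", m = m, k = k, edits = edits,
                         objective = NA_real_)
  pattern(pattern$target$variable, res$conditions, k,
          positive_class = pattern$target$positive_class,
          mode_tag = "post", history = c(pattern$history, list(entry)))
}
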