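#' Create a pattern history entry
#'
#' The history is an append-only log of how the pattern came to be: the first
#' entry is always the data-driven (pre-mode) discovery, and each subsequent
#' edit session appends exactly one entry. Entries record the mode, the edits
#' applied, the resulting pattern size m and threshold k, the training
#' objective value (absent for data-free post-mode), and - for the first
#' entry - a snapshot of the discovered conditions, so that the full pattern
#' can be reconstructed by replaying the history.
#'
#' @param mode \code{"pre"}, \code{"in"} or \code{"post"}.
#' @param m,k Pattern size and threshold after the step.
#' @param edits List of \code{\link{pattern_edit}} objects applied (empty for
#'   the discovery entry).
#' @param objective Training objective value, or \code{NA} when no data was
#'   used.
#' @param conditions Condition snapshot (discovery entry only).
#' @param timestamp ISO-8601 string; empty string for deterministic output.
#' @return A list of class \code{history_entry}.
#' @export
history_entry <- function(mode, m, k, edits = list(), objective = NA_real_,
                          conditions = NULL, timestamp = NULL) {
  if (is.null(timestamp)) {
    timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  structure(
    list(mode = mode, timestamp = timestamp, edits = edits,
         m = as.integer(m), k = as.integer(k),
         objective = as.numeric(objective), conditions = conditions),
    class = "history_entry"
  )
}

condition_to_list <- function(cond) {
  list(variable = cond$variable, comparator = cond$comparator,
       value = cond$value)
}

condition_from_list <- function(x) {
  for (f in c("variable", "comparator", "value")) {
    if (is.null(x[[f]])) stop("condition entry missing field '", f, "'")
  }
  condition(x$variable, x$comparator, x$value)
}

history_to_list <- function(h) {
  lapply(h, function(e) {
    out <- list(mode = e$mode, timestamp = e$timestamp,
                edits = lapply(e$edits, unclass),
                m = e$m, k = e$k, objective = e$objective)
    if (!is.null(e$conditions)) {
      out$conditions <- lapply(e$conditions, condition_to_list)
    }
    out
  })
}

history_from_list <- function(x) {
  lapply(x, function(e) {
    for (f in c("mode", "m", "k")) {
      if (is.null(e[[f]])) stop("history entry missing field '", f, "'")
    }
    history_entry(
      mode = e$mode, m = e$m, k = e$k,
      edits = lapply(e$edits, function(ed) {
        pattern_edit(ed$action, variable = ed$variable, payload = ed$payload)
      }),
      objective = if (is.null(e$objective)) NA_real_ else e$objective,
      conditions = if (is.null(e$conditions)) NULL else
        lapply(e$conditions, condition_from_list),
      timestamp = if (is.null(e$timestamp)) "" else e$timestamp
    )
  })
}

#' Serialize a pattern to a list / JSON
#'
#' The JSON document stores the authoritative threshold \code{min_matches};
#' the percentage \code{matching_ratio} is written for human readers and
#' derived again on read. The round-trip is lossless, including mode tag,
#' history and any attached arcs.
#'
#' @param x A \code{risk_pattern}.
#' @return \code{pattern_to_list}: a plain list mirroring the JSON layout.
#' @export
pattern_to_list <- function(x) {
  stopifnot(inherits(x, "risk_pattern"))
  out <- list(
    target = list(variable = x$target$variable,
                  positive_class = x$target$positive_class),
    conditions = lapply(x$conditions, condition_to_list),
    min_matches = x$min_matches,
    matching_ratio = display_ratio(x$min_matches, length(x$conditions)),
    mode_tag = x$mode_tag,
    history = history_to_list(x$history)
  )
  if (!is.null(attr(x, "arcs"))) {
    out$arcs <- attr(x, "arcs")
  }
  out
}

#' @rdname pattern_to_list
#' @param path Output JSON path.
#' @return \code{write_pattern}: \code{path}, invisibly.
#' @export
write_pattern <- function(x, path) {
  jsonlite::write_json(pattern_to_list(x), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a pattern from JSON
#'
#' @param path Path to a pattern JSON document.
#' @return A \code{risk_pattern}. Malformed documents raise an error naming
#'   the offending field.
#' @export
read_pattern <- function(path) {
  if (!file.exists(path)) stop("pattern file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  pattern_from_list(doc)
}

#' @rdname read_pattern
#' @param doc A list as produced by \code{\link{pattern_to_list}}.
#' @export
pattern_from_list <- function(doc) {
  if (is.null(doc$target) || is.null(doc$target$variable)) {
    stop("pattern document missing field 'target.variable'")
  }
  if (is.null(doc$conditions) || length(doc$conditions) == 0L) {
    stop("pattern document missing field 'conditions'")
  }
  if (is.null(doc$min_matches)) {
    stop("pattern document missing field 'min_matches'")
  }
  if (is.null(doc$mode_tag)) {
    stop("pattern document missing field 'mode_tag'")
  }
  conds <- lapply(doc$conditions, condition_from_list)
  p <- pattern(
    target_variable = doc$target$variable,
    conditions = conds,
    min_matches = doc$min_matches,
    positive_class = if (is.null(doc$target$positive_class)) "Yes" else
      doc$target$positive_class,
    mode_tag = doc$mode_tag,
    history = if (is.null(doc$history)) list() else
      history_from_list(doc$history)
  )
  if (!is.null(doc$arcs)) attr(p, "arcs") <- doc$arcs
  p
}

#' Reconstruct a pattern by replaying its history
#'
#' Starting from the condition snapshot and threshold of the first
#' (discovery) entry, each later entry's edits are re-applied and its
#' recorded threshold restored. The result equals the pattern the history
#' belongs to, which makes the log auditable.
#'
#' @param x A \code{risk_pattern} whose first history entry is a discovery
#'   entry carrying a condition snapshot.
#' @return The reconstructed \code{risk_pattern}.
#' @export
replay_history <- function(x) {
  stopifnot(inherits(x, "risk_pattern"))
  h <- x$history
  if (length(h) == 0L) stop("pattern has no history to replay")
  first <- h[[1L]]
  if (first$mode != "pre" || is.null(first$conditions)) {
    stop("first history entry must be a pre-mode discovery snapshot")
  }
  cur <- pattern(x$target$variable, first$conditions, first$k,
                 positive_class = x$target$positive_class,
                 mode_tag = "pre", history = h[1L])
  for (i in seq_along(h)[-1L]) {
    e <- h[[i]]
    conds <- apply_edit_list(cur$conditions, e$edits, schema = NULL,
                             train = NULL)$conditions
    cur <- pattern(x$target$variable, conds, e$k,
                   positive_class = x$target$positive_class,
                   mode_tag = e$mode, history = h[seq_len(i)])
  }
  cur
}
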