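#' Discovery configuration
#'
#' Controls the greedy pattern search. The default objective is the training
#' F-score, which balances precision and sensitivity and is the usual choice
#' for rare outcomes; G-mean is available as an alternative.
#'
#' @param objective \code{"f_score"} or \code{"g_mean"}, optimized on the
#'   training data.
#' @param max_conditions Upper bound on pattern size m.
#' @param min_improvement Minimum objective gain required to keep growing
#'   the pattern (default \code{1e-6}, i.e. any strict improvement).
#' @param seed Integer, reserved for stochastic extensions; the search
#'   itself is deterministic.
#' @param rediscover If \code{TRUE}, in-mode editing re-runs the full greedy
#'   search with the edited conditions pinned, instead of only re-optimizing
#'   the matching threshold. Off by default: an edited pattern keeps exactly
#'   the clinician's variable-value pairs.
#' @return A list of class \code{discovery_config}.
#' @export
discovery_config <- function(objective = c("f_score", "g_mean"),
                             max_conditions = 16L,
                             min_improvement = 1e-6,
                             seed = NULL,
                             rediscover = FALSE) {
  objective <- match.arg(objective)
  max_conditions <- as.integer(max_conditions)
  if (is.na(max_conditions) || max_conditions < 1L) {
    stop("max_conditions must be >= 1")
  }
  if (!is.numeric(min_improvement) || min_improvement < 0) {
    stop("min_improvement must be >= 0")
  }
  structure(
    list(objective = objective, max_conditions = max_conditions,
         min_improvement = min_improvement, seed = seed,
         rediscover = isTRUE(rediscover)),
    class = "discovery_config"
  )
}

# point objective from a confusion; internal, shared by search and threshold
# optimization
objective_from_pred <- function(pred, labels, objective) {
  tp <- sum(pred & labels)
  if (objective == "f_score") {
    den <- 2 * tp + sum(pred & !labels) + sum(!pred & labels)
    if (tp == 0L) 0 else 2 * tp / den
  } else {
    fn <- sum(!pred & labels)
    fp <- sum(pred & !labels)
    tn <- sum(!pred & !labels)
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    sqrt(sens * spec)
  }
}

# exhaustive scan of k = 1..m over a per-record match-count vector;
# ties go to the larger (stricter) k
opt_k <- function(counts, labels, m, objective) {
  best_k <- 1L
  best_val <- -Inf
  vals <- numeric(m)
  for (k in seq_len(m)) {
    v <- objective_from_pred(counts >= k, labels, objective)
    vals[k] <- v
    if (v >= best_val) {
      best_val <- v
      best_k <- k
    }
  }
  list(k = best_k, value = best_val, values = vals)
}

#' Generate candidate conditions from training data
#'
#' Numeric variables contribute their best information-gain cutoff, with the
#' comparator pointing at the side with the higher positive-class rate (so
#' conditions read as risk factors, e.g. \code{contrast_volume > 79.5}).
#' Binary and categorical variables contribute one equality condition per
#' observed category. Variables with no valid split (constant, or zero gain)
#' are omitted.
#'
#' @param train A \code{cohort} containing both outcome classes.
#' @return List of \code{pattern_condition} objects.
#' @export
generate_candidates <- function(train) {
  stopifnot(inherits(train, "cohort"))
  labels <- cohort_labels(train)
  if (all(labels) || !any(labels)) {
    stop("candidate generation needs both classes in the training data")
  }
  out <- list()
  for (spec in train$schema) {
    v <- train$data[[spec$name]]
    if (spec$kind == "numeric") {
      rule <- best_split(v, labels, spec$name)
      if (is.null(rule)) next
      ok <- !is.na(v)
      rate_le <- mean(labels[ok & v <= rule$cutoff])
      rate_gt <- mean(labels[ok & v > rule$cutoff])
      comp <- if (isTRUE(rate_gt > rate_le)) ">" else "<="
      out[[length(out) + 1L]] <- condition(spec$name, comp, rule$cutoff)
    } else {
      cats <- sort(unique(v[!is.na(v)]))
      if (length(cats) < 2L) next
      for (cat in cats) {
        out[[length(out) + 1L]] <- condition(spec$name, "==", cat)
      }
    }
  }
  out
}

#' Optimize the k-of-m matching threshold on training data
#'
#' Exhaustively evaluates every threshold k = 1..m by predicting on the
#' training cohort and scoring the objective, and returns the maximizer.
#' Ties are broken toward the larger k (the stricter pattern). If the
#' objective is zero for every k, m is returned with a warning.
#'
#' @param conditions List of \code{pattern_condition}s (all over distinct
#'   variables).
#' @param train A \code{cohort}.
#' @param objective \code{"f_score"} or \code{"g_mean"}.
#' @return Integer k with attributes \code{objective} (its training value)
#'   and \code{objectives} (the full k-indexed vector).
#' @export
optimize_threshold <- function(conditions, train,
                               objective = c("f_score", "g_mean")) {
  objective <- match.arg(objective)
  stopifnot(inherits(train, "cohort"), length(conditions) >= 1L)
  counts <- rowSums(condition_match_matrix(conditions, train$data))
  res <- opt_k(counts, cohort_labels(train), length(conditions), objective)
  if (all(res$values == 0)) {
    warning("objective is zero for every threshold; returning k = m")
    res$k <- length(conditions)
  }
  structure(res$k, objective = res$values[res$k], objectives = res$values)
}

#' Greedy pattern discovery (pre-mode)
#'
#' Heuristic forward search: starting from the empty pattern, each step
#' tentatively adds every unused candidate condition, re-optimizes the
#' matching threshold for the enlarged set, and keeps the addition with the
#' best training objective. The search stops when the improvement falls
#' below \code{min_improvement}, the candidates are exhausted, or
#' \code{max_conditions} is reached. Deterministic: objective ties are broken
#' by the candidate's chi-square association with the target, then by
#' variable name.
#'
#' @param train A \code{cohort} with both outcome classes.
#' @param config A \code{\link{discovery_config}}.
#' @param pinned Optional list of conditions forced into the pattern before
#'   the search starts (used by in-mode re-discovery).
#' @return A \code{risk_pattern} tagged \code{pre} with a discovery history
#'   entry; its training objective is available as
#'   \code{attr(, "objective")}.
#' @export
discover_pattern <- function(train, config = discovery_config(),
                             pinned = NULL) {
  stopifnot(inherits(train, "cohort"), inherits(config, "discovery_config"))
  labels <- cohort_labels(train)
  candidates <- generate_candidates(train)
  if (!is.null(pinned)) {
    pinned_vars <- vapply(pinned, `[[`, character(1L), "variable")
    candidates <- Filter(function(cd) !(cd$variable %in% pinned_vars),
                         candidates)
  }
  if (length(candidates) == 0L && is.null(pinned)) {
    stop("no candidate conditions could be generated from the training data")
  }
  M <- condition_match_matrix(candidates, train$data)
  cand_vars <- vapply(candidates, `[[`, character(1L), "variable")
  cand_chi <- vapply(seq_along(candidates), function(j) {
    indicator_chi2(M[, j], labels)
  }, numeric(1L))

  selected <- integer(0)
  sel_counts <- if (is.null(pinned)) {
    rep(0, nrow(train$data))
  } else {
    rowSums(condition_match_matrix(pinned, train$data))
  }
  n_pinned <- length(pinned)
  cur_obj <- if (n_pinned > 0L) {
    opt_k(sel_counts, labels, n_pinned, config$objective)$value
  } else {
    0
  }
  repeat {
    m_now <- n_pinned + length(selected)
    if (m_now >= config$max_conditions) break
    pool <- setdiff(seq_along(candidates), selected)
    # one pattern variable per candidate variable already selected
    used_vars <- cand_vars[selected]
    pool <- pool[!(cand_vars[pool] %in% used_vars)]
    if (length(pool) == 0L) break
    best <- NULL
    for (j in pool) {
      res <- opt_k(sel_counts + M[, j], labels, m_now + 1L, config$objective)
      cand_rec <- list(j = j, k = res$k, value = res$value)
      if (is.null(best) || better_candidate(cand_rec, best, cand_chi,
                                            cand_vars)) {
        best <- cand_rec
      }
    }
    improvement <- best$value - cur_obj
    if (length(selected) + n_pinned >= 1L &&
        improvement < config$min_improvement) break
    selected <- c(selected, best$j)
    sel_counts <- sel_counts + M[, best$j]
    cur_obj <- best$value
  }
  conds <- c(pinned, candidates[selected])
  if (length(conds) == 0L) stop("discovery selected no conditions")
  final <- opt_k(rowSums(condition_match_matrix(conds, train$data)),
                 labels, length(conds), config$objective)
  entry <- history_entry("pre", m = length(conds), k = final$k,
                         objective = final$value, conditions = conds)
  p <- pattern(train$target, conds, final$k, positive_class = "Yes",
               mode_tag = "pre", history = list(entry))
  attr(p, "objective") <- final$value
  p
}

# strict "is a better greedy addition" ordering:
# objective, then candidate-target chi-square, then variable name, then index
better_candidate <- function(a, b, cand_chi, cand_vars) {
  if (a$value > b$value + 1e-12) return(TRUE)
  if (a$value < b$value - 1e-12) return(FALSE)
  ca <- cand_chi[a$j]
  cb <- cand_chi[b$j]
  if (ca > cb + 1e-12) return(TRUE)
  if (ca < cb - 1e-12) return(FALSE)
  va <- cand_vars[a$j]
  vb <- cand_vars[b$j]
  if (va != vb) return(va < vb)
  a$j < b$j
}

# Yates-corrected chi-square statistic of a binary indicator against the
# labels; 0 when either margin is degenerate
indicator_chi2 <- function(indicator, labels) {
  if (length(unique(indicator)) < 2L || length(unique(labels)) < 2L) return(0)
  tab <- table(indicator, labels)
  unname(suppressWarnings(stats::chisq.test(tab, correct = TRUE))$statistic)
}

#' Chi-square association arcs between pattern variables
#'
#' For every unordered pair of pattern conditions, tests independence of the
#' two per-record match indicators over the supplied cohort (2x2 chi-square
#' with continuity correction). Arcs with p below \code{alpha} are flagged
#' significant; in the interactive display they connect dependent pattern
#' variables.
#'
#' @param pattern A \code{risk_pattern}.
#' @param table A \code{cohort}.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame with columns \code{var1}, \code{var2}, \code{chi2},
#'   \code{p}, \code{significant}; empty when the pattern has fewer than two
#'   conditions.
#' @export
compute_arcs <- function(pattern, table, alpha = 0.05) {
  stopifnot(inherits(pattern, "risk_pattern"), inherits(table, "cohort"))
  m <- length(pattern$conditions)
  empty <- data.frame(var1 = character(), var2 = character(),
                      chi2 = numeric(), p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (m < 2L) return(empty)
  M <- condition_match_matrix(pattern$conditions, table$data)
  vars <- vapply(pattern$conditions, `[[`, character(1L), "variable")
  rows <- list()
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      xi <- M[, i]
      xj <- M[, j]
      if (length(unique(xi)) < 2L || length(unique(xj)) < 2L) {
        stat <- 0
        p <- 1
      } else {
        ct <- suppressWarnings(stats::chisq.test(table(xi, xj),
                                                 correct = TRUE))
        stat <- unname(ct$statistic)
        p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        var1 = vars[i], var2 = vars[j], chi2 = stat, p = p,
        significant = p < alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
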