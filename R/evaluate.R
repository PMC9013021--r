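#' Confusion counts from binary predictions
#'
#' @param predictions Logical (or 0/1) predictions.
#' @param labels Logical (or 0/1) reference labels, same length.
#' @return Object of class \code{confusion_counts}: list with \code{tp},
#'   \code{fp}, \code{tn}, \code{fn}.
#' @export
confusion <- function(predictions, labels) {
  predictions <- as.logical(predictions)
  labels <- as.logical(labels)
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have the same length")
  }
  if (length(labels) == 0L) stop("empty input")
  confusion_counts(
    tp = sum(predictions & labels),
    fp = sum(predictions & !labels),
    tn = sum(!predictions & !labels),
    fn = sum(!predictions & labels)
  )
}

#' @rdname confusion
#' @param tp,fp,tn,fn Nonnegative integer counts.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn))
  if (any(unlist(counts) < 0)) stop("confusion counts must be nonnegative")
  structure(counts, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Imbalance-aware point metrics from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), precision =
#' TP/(TP+FP) (0 when TP+FP = 0), F-score = 2*precision*recall /
#' (precision+recall) with F = 0 whenever TP = 0, and G-mean =
#' sqrt(sensitivity * specificity). A metric whose denominator is zero is
#' reported as 0 so that every value stays in [0, 1].
#'
#' @param counts A \code{confusion_counts}.
#' @param auc Optional AUC to carry in the report.
#' @param threshold Optional threshold/cutoff the counts were taken at.
#' @return Object of class \code{metrics_report}.
#' @export
metrics_from_confusion <- function(counts, auc = NA_real_,
                                   threshold = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(num, den) if (den > 0) num / den else 0
  sens <- safe_div(counts$tp, counts$tp + counts$fn)
  spec <- safe_div(counts$tn, counts$tn + counts$fp)
  prec <- safe_div(counts$tp, counts$tp + counts$fp)
  f <- if (counts$tp > 0) 2 * prec * sens / (prec + sens) else 0
  structure(
    list(sensitivity = sens, specificity = spec, precision = prec,
         f_score = f, g_mean = sqrt(sens * spec),
         auc = auc, threshold = threshold, counts = counts),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("<metrics_report>\n")
  vals <- c(AUC = x$auc, Sensitivity = x$sensitivity,
            Specificity = x$specificity, Precision = x$precision,
            `F-score` = x$f_score, `G-mean` = x$g_mean)
  for (nm in names(vals)) {
    if (!is.na(vals[[nm]])) cat(sprintf("  %-12s %.*f\n", nm, digits, vals[[nm]]))
  }
  if (!is.na(x$threshold)) cat("  threshold   ", format(x$threshold), "\n")
  invisible(x)
}

#' ROC curve with tie grouping
#'
#' Vertices are placed at each distinct score value, scanned in decreasing
#' order, with a prediction rule of \emph{score >= cutoff}; tied scores
#' produce a single vertex. Endpoints (0,0) (cutoff \code{Inf}) and (1,1)
#' are always present.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical labels; both classes must be present.
#' @return A data.frame of class \code{roc_curve} with columns \code{cutoff},
#'   \code{fpr}, \code{tpr}, \code{tp}, \code{fp}, and attributes
#'   \code{n_pos}, \code{n_neg}.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length")
  }
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs both classes present in the labels")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last_of_group <- which(diff(s) != 0)
  idx <- c(last_of_group, length(s))
  tp <- cumsum(y)[idx]
  fp <- cumsum(!y)[idx]
  out <- data.frame(
    cutoff = c(Inf, s[idx]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos),
    tp = c(0L, tp),
    fp = c(0L, fp)
  )
  structure(out, class = c("roc_curve", "data.frame"),
            n_pos = n_pos, n_neg = n_neg)
}

#' Area under a ROC curve (trapezoidal rule)
#'
#' @param x A \code{roc_curve}, or a numeric score vector (in which case
#'   \code{labels} must be given and a curve is built first).
#' @param labels Labels, when \code{x} is a score vector.
#' @param ... Unused.
#' @return AUC in [0, 1]. With tie grouping this equals the pairwise
#'   concordance probability counting ties as 1/2 (the Mann-Whitney
#'   statistic).
#' @export
auc <- function(x, ...) UseMethod("auc")

#' @rdname auc
#' @export
auc.roc_curve <- function(x, ...) {
  sum(diff(x$fpr) * (utils::head(x$tpr, -1) + utils::tail(x$tpr, -1)) / 2)
}

#' @rdname auc
#' @export
auc.default <- function(x, labels, ...) {
  auc(roc_curve(x, labels))
}

#' Optimal ROC operating point (Youden's J)
#'
#' Returns the curve vertex maximizing J = sensitivity + specificity - 1;
#' ties are broken toward higher specificity (the stricter cutoff). Used to
#' give externally published risk scores their best possible operating point
#' rather than their (population-specific) published threshold.
#'
#' @param curve A \code{roc_curve}.
#' @return List with \code{cutoff}, \code{j}, \code{sensitivity},
#'   \code{specificity} and the \code{confusion_counts} at the vertex.
#' @export
optimal_roc_point <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  n_pos <- attr(curve, "n_pos")
  n_neg <- attr(curve, "n_neg")
  j <- curve$tpr - curve$fpr
  best_j <- max(j)
  cand <- which(j >= best_j - 1e-12)
  best <- cand[which.min(curve$fpr[cand])]  # higher specificity on ties
  counts <- confusion_counts(
    tp = curve$tp[best], fp = curve$fp[best],
    tn = n_neg - curve$fp[best], fn = n_pos - curve$tp[best]
  )
  list(cutoff = curve$cutoff[best], j = best_j,
       sensitivity = curve$tpr[best], specificity = 1 - curve$fpr[best],
       counts = counts)
}

#' Evaluate a pattern on a cohort
#'
#' Point metrics come from the k-of-m prediction at the pattern's own
#' threshold; the AUC comes from the matched-fraction score.
#'
#' @param pattern A \code{risk_pattern}.
#' @param table A \code{cohort} whose target matches the pattern's.
#' @return A \code{metrics_report} with \code{threshold} = k.
#' @export
evaluate_pattern <- function(pattern, table) {
  stopifnot(inherits(pattern, "risk_pattern"), inherits(table, "cohort"))
  labels <- cohort_labels(table)
  counts <- match_count(pattern, table)
  cm <- confusion(counts >= pattern$min_matches, labels)
  metrics_from_confusion(
    cm,
    auc = auc(counts / length(pattern$conditions), labels),
    threshold = pattern$min_matches
  )
}

#' Evaluate an external score column
#'
#' For published risk scores supplied as precomputed columns. Point metrics
#' are taken at the given cutoff with a configurable comparator
#' (\code{">="} by default, matching ">= threshold"-style published rules),
#' or at the optimal ROC point when \code{cutoff = "optimal"}.
#'
#' @param scores Numeric score vector.
#' @param labels Logical labels; both classes required.
#' @param cutoff Numeric cutoff, or \code{"optimal"}.
#' @param comparator \code{">="} or \code{">"} for calling a record positive.
#' @return A \code{metrics_report} (with the cutoff used as
#'   \code{threshold}).
#' @export
evaluate_scores <- function(scores, labels, cutoff = "optimal",
                            comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  labels <- as.logical(labels)
  curve <- roc_curve(scores, labels)
  if (identical(cutoff, "optimal")) {
    pt <- optimal_roc_point(curve)
    return(metrics_from_confusion(pt$counts, auc = auc(curve),
                                  threshold = pt$cutoff))
  }
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  pred <- if (comparator == ">=") scores >= cutoff else scores > cutoff
  metrics_from_confusion(confusion(pred, labels), auc = auc(curve),
                         threshold = cutoff)
}

#' Compare training and test cohorts variable by variable
#'
#' Mirrors the usual baseline table of a chronological-split study: numeric
#' variables are summarized as mean (SD) and compared by two-group one-way
#' ANOVA (equal-variance F test); binary/categorical variables and the
#' outcome are summarized as n (\%) and compared by the chi-square test of
#' independence, with Yates continuity correction on 2x2 tables. Missing
#' values are excluded per variable.
#'
#' @param train,test Two \code{cohort}s with identical schemas.
#' @return A data.frame with one row per variable (outcome last): columns
#'   \code{variable}, \code{kind}, \code{train}, \code{test} (summary
#'   strings), \code{statistic}, \code{p_value}.
#' @export
compare_cohorts <- function(train, test) {
  stopifnot(inherits(train, "cohort"), inherits(test, "cohort"))
  if (!identical(names(train$schema), names(test$schema))) {
    stop("train and test cohorts must share the same schema")
  }
  rows <- lapply(names(train$schema), function(nm) {
    spec <- train$schema[[nm]]
    a <- train$data[[nm]]
    b <- test$data[[nm]]
    if (spec$kind == "numeric") {
      compare_numeric_row(nm, a, b)
    } else {
      compare_categorical_row(nm, spec$kind, a, b, spec$positive_category)
    }
  })
  tgt <- compare_categorical_row(
    train$target, "binary",
    ifelse(cohort_labels(train), "Yes", "No"),
    ifelse(cohort_labels(test), "Yes", "No"), "Yes")
  out <- do.call(rbind, c(rows, list(tgt)))
  rownames(out) <- NULL
  out
}

compare_numeric_row <- function(nm, a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("too few values for '", nm, "'")
  values <- c(a, b)
  group <- factor(rep(c("train", "test"), c(length(a), length(b))))
  fit <- stats::oneway.test(values ~ group, var.equal = TRUE)
  data.frame(
    variable = nm, kind = "numeric",
    train = sprintf("%.2f (%.2f)", mean(a), stats::sd(a)),
    test = sprintf("%.2f (%.2f)", mean(b), stats::sd(b)),
    statistic = unname(fit$statistic), p_value = fit$p.value,
    stringsAsFactors = FALSE
  )
}

compare_categorical_row <- function(nm, kind, a, b, positive_category) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("no values for '", nm, "'")
  lev <- sort(unique(c(a, b)))
  tab <- rbind(train = table(factor(a, levels = lev)),
               test = table(factor(b, levels = lev)))
  summarize <- function(x) {
    if (!is.null(positive_category)) {
      n <- sum(x == positive_category)
      sprintf("%d (%.1f%%)", n, 100 * n / length(x))
    } else {
      paste(sprintf("%s:%d", lev, table(factor(x, levels = lev))),
            collapse = " ")
    }
  }
  if (length(lev) < 2L) {
    stat <- 0
    p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    stat <- unname(ct$statistic)
    p <- ct$p.value
  }
  data.frame(
    variable = nm, kind = kind,
    train = summarize(a), test = summarize(b),
    statistic = stat, p_value = p,
    stringsAsFactors = FALSE
  )
}

#' Tabulate several evaluation reports
#'
#' Builds the familiar model-comparison layout: one row per model with AUC,
#' sensitivity, specificity, F-score and G-mean.
#'
#' @param reports Named list of \code{metrics_report} objects.
#' @return A data.frame with columns \code{model}, \code{auc},
#'   \code{sensitivity}, \code{specificity}, \code{f_score}, \code{g_mean}.
#' @export
report_table <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 1L)
  if (is.null(names(reports))) names(reports) <- paste0("model_", seq_along(reports))
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, auc = r$auc, sensitivity = r$sensitivity,
               specificity = r$specificity, f_score = r$f_score,
               g_mean = r$g_mean, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
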