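#' Shannon entropy of a binary label set
#'
#' Base-2 entropy of the positive fraction, with the convention
#' \code{0 * log2(0) = 0}.
#'
#' @param labels Logical (or 0/1) vector; must be non-empty and free of
#'   \code{NA}.
#' @return Entropy in bits, in \code{[0, 1]}.
#' @export
#' @examples
#' entropy(c(TRUE, FALSE))   # 1 bit
#' entropy(rep(TRUE, 5))     # 0 bits
entropy <- function(labels) {
  labels <- as.logical(labels)
  if (length(labels) == 0L) stop("entropy of an empty label set is undefined")
  if (anyNA(labels)) stop("labels must not contain NA")
  binary_entropy(mean(labels))
}

# entropy of a Bernoulli(p); vectorized over p
binary_entropy <- function(p) {
  h <- numeric(length(p))
  inner <- p > 0 & p < 1
  pi <- p[inner]
  h[inner] <- -pi * log2(pi) - (1 - pi) * log2(1 - pi)
  h
}

#' Information gain of a partition for binary labels
#'
#' \code{H(labels) - sum_b (n_b / n) * H(labels in block b)}. Empty blocks
#' contribute nothing (weight zero).
#'
#' @param labels Logical labels.
#' @param partition Block assignment of the same length (any atomic vector or
#'   factor; its distinct values index the blocks).
#' @return Gain in bits, nonnegative up to floating error.
#' @export
information_gain <- function(labels, partition) {
  labels <- as.logical(labels)
  if (length(labels) != length(partition)) {
    stop("labels and partition must have the same length")
  }
  if (length(labels) == 0L) stop("empty label set")
  n <- length(labels)
  h <- entropy(labels)
  cond <- 0
  for (b in unique(partition)) {
    block <- labels[partition == b]
    if (length(block)) cond <- cond + (length(block) / n) * entropy(block)
  }
  h - cond
}

#' Best binary split of a numeric variable by information gain
#'
#' All distinct observed values are sorted in ascending order and candidate
#' cutoffs are placed at the midpoints between consecutive distinct values;
#' the cutoff maximizing the information gain of the induced
#' \code{<= x} / \code{> x} partition of the labels is returned. Records with
#' a missing value are excluded from the scan. Integer-valued inputs thus
#' yield half-unit cutoffs (e.g. 58.5, 79.5). Ties in gain are broken toward
#' the smaller cutoff for determinism.
#'
#' @param values Numeric vector (may contain \code{NA}).
#' @param labels Logical labels aligned with \code{values}.
#' @param variable Optional variable name recorded in the rule.
#' @return A \code{split_rule} (list with \code{variable}, \code{cutoff},
#'   \code{gain}), or \code{NULL} when fewer than two distinct values remain
#'   or no cutoff achieves positive gain.
#' @export
#' @examples
#' best_split(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))  # cutoff 2.5, 1 bit
best_split <- function(values, labels, variable = NA_character_) {
  if (length(values) != length(labels)) {
    stop("values and labels must have the same length")
  }
  labels <- as.logical(labels)
  ok <- !is.na(values) & !is.na(labels)
  v <- values[ok]
  y <- labels[ok]
  if (length(v) == 0L) return(NULL)
  ord <- order(v)
  v <- v[ord]
  y <- y[ord]
  n <- length(v)
  # boundaries between consecutive distinct sorted values
  cut_at <- which(diff(v) > 0)
  if (length(cut_at) == 0L) return(NULL)
  cum_pos <- cumsum(y)
  n_pos <- cum_pos[n]
  h <- binary_entropy(n_pos / n)
  n_left <- cut_at
  pos_left <- cum_pos[cut_at]
  n_right <- n - n_left
  pos_right <- n_pos - pos_left
  gain <- h -
    (n_left / n) * binary_entropy(pos_left / n_left) -
    (n_right / n) * binary_entropy(pos_right / n_right)
  best <- which.max(gain)  # first max = smallest cutoff on ties
  if (gain[best] <= 1e-12) return(NULL)
  cutoff <- (v[cut_at[best]] + v[cut_at[best] + 1L]) / 2
  split_rule(variable, cutoff, gain[best])
}

#' @rdname best_split
#' @param cutoff Numeric cutoff.
#' @param gain Information gain at the cutoff, in bits.
#' @export
split_rule <- function(variable, cutoff, gain) {
  structure(list(variable = variable, cutoff = cutoff, gain = gain),
            class = "split_rule")
}

#' @export
print.split_rule <- function(x, ...) {
  cat(sprintf("<split_rule> %s <= %g vs > %g (gain %.4f bits)\n",
              x$variable, x$cutoff, x$cutoff, x$gain))
  invisible(x)
}

#' Apply a split rule to numeric values
#'
#' The left category is inclusive (\code{value <= cutoff}); missing values
#' stay missing.
#'
#' @param rule A \code{split_rule}.
#' @param values Numeric vector.
#' @return Character vector with values \code{"<=x"}, \code{">x"} or
#'   \code{NA}.
#' @export
apply_split <- function(rule, values) {
  stopifnot(inherits(rule, "split_rule"))
  out <- ifelse(values <= rule$cutoff, "<=x", ">x")
  out[is.na(values)] <- NA_character_
  out
}
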