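#' Construct a cohort table
#'
#' A cohort is an ordered table of patient records (rows are chronological),
#' a schema describing each predictor, and a binary outcome column. The
#' outcome is normalized to logical (\code{TRUE} = positive/event). Missing
#' predictor values are retained as \code{NA}; no imputation is performed,
#' since downstream pattern matching treats a missing value as a non-match.
#'
#' @param data A data.frame with one row per patient, in chronological order,
#'   containing every schema column plus the target column.
#' @param schema A \code{cohort_schema}.
#' @param target Name of the binary outcome column.
#' @param order_index Optional 0-based chronological positions (defaults to
#'   row order).
#' @return An object of class \code{cohort}.
#' @export
cohort <- function(data, schema, target, order_index = NULL) {
  stopifnot(is.data.frame(data), inherits(schema, "cohort_schema"))
  n <- nrow(data)
  if (n < 1L) stop("cohort needs at least one record")
  if (!target %in% names(data)) {
    stop("target column not found in data: ", target)
  }
  missing_cols <- setdiff(names(schema), names(data))
  if (length(missing_cols)) {
    stop("schema column(s) missing from data: ",
         paste(missing_cols, collapse = ", "))
  }
  data[[target]] <- normalize_binary_target(data[[target]], target)
  for (s in schema) {
    col <- data[[s$name]]
    if (s$kind == "numeric") {
      if (!is.numeric(col)) {
        stop("column '", s$name, "' declared numeric but is not numeric")
      }
    } else {
      data[[s$name]] <- as.character(col)
    }
  }
  if (is.null(order_index)) order_index <- seq_len(n) - 1L
  stopifnot(length(order_index) == n)
  structure(
    list(data = data, schema = schema, target = target,
         order_index = as.integer(order_index)),
    class = "cohort"
  )
}

# Map a raw target column onto logical TRUE/FALSE; anything outside the
# recognized binary encodings is a validation error.
normalize_binary_target <- function(x, name) {
  if (is.logical(x)) {
    if (anyNA(x)) stop("target column '", name, "' contains missing values")
    return(x)
  }
  raw <- tolower(trimws(as.character(x)))
  if (anyNA(x) || any(!nzchar(raw))) {
    stop("target column '", name, "' contains missing values")
  }
  pos <- c("1", "yes", "y", "true", "t")
  neg <- c("0", "no", "n", "false", "f")
  bad <- setdiff(unique(raw), c(pos, neg))
  if (length(bad)) {
    stop("target column '", name, "' is not binary; offending value(s): ",
         paste(bad, collapse = ", "))
  }
  raw %in% pos
}

#' @export
print.cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("<cohort> %d records, %d variables, target '%s' (%d positive, %.1f%%)\n",
              nrow(x$data), length(x$schema), x$target,
              sum(lab), 100 * mean(lab)))
  invisible(x)
}

#' Number of records in a cohort
#' @param x A \code{cohort}.
#' @return Integer record count.
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "cohort"))
  nrow(x$data)
}

#' Outcome labels of a cohort
#' @param x A \code{cohort}.
#' @return Logical vector, \code{TRUE} for positive records.
#' @export
cohort_labels <- function(x) {
  stopifnot(inherits(x, "cohort"))
  x$data[[x$target]]
}

#' Read a cohort CSV
#'
#' The file must have a header naming every schema variable and the target;
#' rows are taken as chronological order (first row = earliest). Empty cells
#' become missing values. Numeric columns are parsed as decimals; a cell that
#' fails to parse is a hard error reporting the data row number.
#'
#' @param path CSV path.
#' @param schema A \code{cohort_schema} (or path to a schema file).
#' @param target_name Name of the binary outcome column.
#' @return A \code{cohort} with \code{order_index} 0..n-1 in file order.
#' @export
read_cohort <- function(path, schema, target_name) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (is.character(schema)) schema <- read_schema(schema)
  stopifnot(inherits(schema, "cohort_schema"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", colClasses = "character",
                         check.names = FALSE)
  needed <- c(names(schema), target_name)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (s in schema) {
    if (s$kind == "numeric") {
      col <- raw[[s$name]]
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop("column '", s$name, "': cannot parse value '", col[bad[1L]],
             "' as numeric (data row ", bad[1L], ")")
      }
      raw[[s$name]] <- num
    }
  }
  cohort(raw, schema, target_name)
}

#' Write a cohort to CSV
#'
#' Inverse of \code{\link{read_cohort}}: one row per patient in chronological
#' order, empty cell for missing, logical target written as 1/0.
#'
#' @param x A \code{cohort}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  out <- x$data
  out[[x$target]] <- as.integer(out[[x$target]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Chronological train/test split
#'
#' The first \code{floor(train_fraction * n)} records by chronological order
#' form the training cohort, the remainder the test cohort. No shuffling:
#' this deliberately exposes the model to concept drift between the training
#' period and the later test period, unlike cross-validation.
#'
#' @param x A \code{cohort} with at least 2 records.
#' @param train_fraction Proportion in (0, 1).
#' @return A list with elements \code{train} and \code{test}.
#' @export
#' @examples
#' # a 10-record cohort at fraction 0.7 splits 7 / 3
chronological_split <- function(x, train_fraction = 0.7) {
  stopifnot(inherits(x, "cohort"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  n <- nrow(x$data)
  if (n < 2L) stop("need at least 2 records to split")
  ord <- order(x$order_index)
  n_train <- floor(train_fraction * n)
  if (n_train < 1L) n_train <- 1L
  if (n_train >= n) n_train <- n - 1L
  idx_train <- ord[seq_len(n_train)]
  idx_test <- ord[seq.int(n_train + 1L, n)]
  list(train = subset_cohort(x, idx_train),
       test = subset_cohort(x, idx_test))
}

# Row subset preserving schema/target; order_index kept from the parent so a
# split remains traceable to original chronology.
subset_cohort <- function(x, idx) {
  structure(
    list(data = x$data[idx, , drop = FALSE],
         schema = x$schema, target = x$target,
         order_index = x$order_index[idx]),
    class = "cohort"
  )
}

#' Label acute kidney injury from a creatinine pair
#'
#' Applies the AKIN creatinine criterion: positive when the peak exceeds
#' baseline by at least 0.3 mg/dL, or reaches at least 1.5 times baseline.
#' Vectorized over records.
#'
#' @param baseline Pre-procedure baseline serum creatinine.
#' @param peak Post-procedure peak serum creatinine (same units as baseline).
#' @param units \code{"mg/dL"} (default) or \code{"umol/L"}; micromolar values
#'   are converted at 88.4 umol/L per mg/dL before applying the absolute
#'   threshold.
#' @return Logical vector, \code{TRUE} = AKI.
#' @export
#' @examples
#' label_aki(1.0, 1.3)            # TRUE: absolute rise of 0.3
#' label_aki(0.5, 0.76)           # TRUE: 1.52-fold despite rise of 0.26
#' label_aki(1.0, 1.0)            # FALSE
label_aki <- function(baseline, peak, units = c("mg/dL", "umol/L")) {
  units <- match.arg(units)
  stopifnot(is.numeric(baseline), is.numeric(peak),
            length(baseline) == length(peak))
  if (any(!is.na(baseline) & baseline <= 0)) {
    stop("baseline creatinine must be positive")
  }
  if (any(!is.na(peak) & peak < 0)) stop("peak creatinine must be nonnegative")
  if (units == "umol/L") {
    baseline <- baseline / 88.4
    peak <- peak / 88.4
  }
  (peak - baseline >= 0.3) | (peak >= 1.5 * baseline)
}

#' Resample a cohort to a 1:1 class ratio
#'
#' Random up-sampling draws positive records with replacement until they
#' match the negative count; down-sampling subsamples negative records
#' without replacement to the positive count. Used to give conventional
#' learners a balanced training set; pattern discovery itself trains on the
#' imbalanced data.
#'
#' @param x A \code{cohort} containing both classes.
#' @param direction \code{"up"} or \code{"down"}.
#' @param seed Integer seed; the operation is deterministic given the seed.
#' @return A \code{cohort} with exactly as many positives as negatives.
#'   Chronological order is not meaningful in the result.
#' @export
resample_balanced <- function(x, direction = c("up", "down"), seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(inherits(x, "cohort"))
  lab <- cohort_labels(x)
  pos <- which(lab)
  neg <- which(!lab)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("resampling needs both classes present")
  }
  if (length(pos) > length(neg)) {
    stop("resample_balanced expects positives to be the minority class")
  }
  idx <- with_seed(seed, {
    if (direction == "up") {
      extra <- sample(pos, length(neg) - length(pos), replace = TRUE)
      c(neg, pos, extra)
    } else {
      keep <- sample(neg, length(pos), replace = FALSE)
      c(keep, pos)
    }
  })
  subset_cohort(x, sort(idx))
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
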