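#' Synthetic variable descriptors
#'
#' Marginal distributions for the cohort generator, with optionally shifted
#' test-period parameters to emulate covariate drift between the training
#' period and the later test period.
#'
#' @param name Variable name.
#' @param mean,sd Training-period normal parameters.
#' @param mean_test,sd_test Test-period parameters (default: no shift).
#' @param units Free-text units.
#' @return A list consumed by \code{\link{synth_config}}.
#' @export
synth_numeric <- function(name, mean, sd, mean_test = mean, sd_test = sd,
                          units = "") {
  stopifnot(sd > 0, sd_test > 0)
  list(name = name, kind = "numeric", units = units,
       mean = mean, sd = sd, mean_test = mean_test, sd_test = sd_test)
}

#' @rdname synth_numeric
#' @param p_positive Training-period probability of the positive category.
#' @param p_positive_test Test-period probability.
#' @param positive_category Label of the risk-bearing category.
#' @param negative_category Label of the other category.
#' @export
synth_binary <- function(name, p_positive, p_positive_test = p_positive,
                         positive_category = "Yes",
                         negative_category = "No") {
  stopifnot(p_positive >= 0, p_positive <= 1,
            p_positive_test >= 0, p_positive_test <= 1)
  list(name = name, kind = "binary", units = "",
       p_positive = p_positive, p_positive_test = p_positive_test,
       positive_category = positive_category,
       negative_category = negative_category)
}

#' Configure the synthetic cohort generator
#'
#' The generator draws each variable independently from its marginal (test
#' records from the shifted marginals), then draws the binary outcome per
#' record with probability
#' \code{baseline_risk + risk_per_match * match_count(planted_pattern)},
#' clamped to [0, 1]. The additive risk-per-matched-condition model makes
#' the planted pattern exactly the structure k-of-m matching detects and
#' keeps the prevalence arithmetic transparent. A train/test difference in
#' \code{baseline_risk} emulates outcome-prevalence drift.
#'
#' @param variables List of \code{\link{synth_numeric}} /
#'   \code{\link{synth_binary}} descriptors.
#' @param planted_pattern A \code{risk_pattern} whose match count drives the
#'   outcome risk; its variables must appear in \code{variables}.
#' @param baseline_risk Outcome probability at zero matches; length 1, or
#'   length 2 as c(train, test) for prevalence drift.
#' @param risk_per_match Added outcome probability per matched condition.
#' @param n_train,n_test Cohort sizes.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(variables, planted_pattern,
                         baseline_risk = 0.073, risk_per_match = 0,
                         n_train = 1791L, n_test = 769L, seed = 1L) {
  stopifnot(inherits(planted_pattern, "risk_pattern"),
            n_train >= 1L, n_test >= 1L)
  if (length(baseline_risk) == 1L) baseline_risk <- rep(baseline_risk, 2L)
  if (any(baseline_risk < 0 | baseline_risk > 1) ||
      risk_per_match < 0 || risk_per_match > 1) {
    stop("baseline_risk and risk_per_match must be probabilities in [0, 1]")
  }
  var_names <- vapply(variables, `[[`, character(1L), "name")
  if (anyDuplicated(var_names)) stop("duplicate synthetic variable names")
  pat_vars <- vapply(planted_pattern$conditions, `[[`, character(1L),
                     "variable")
  missing_vars <- setdiff(pat_vars, var_names)
  if (length(missing_vars)) {
    stop("planted pattern uses undeclared variable(s): ",
         paste(missing_vars, collapse = ", "))
  }
  structure(
    list(variables = variables, planted_pattern = planted_pattern,
         baseline_risk = baseline_risk, risk_per_match = risk_per_match,
         n_train = as.integer(n_train), n_test = as.integer(n_test),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Default configuration emulating the AKI case-study cohort
#'
#' Sixteen pre-/in-operative variables with the marginal means, SDs and
#' category percentages of the case-study baseline table (training column;
#' test column where a drift was reported), a planted 4-condition risk
#' pattern (high contrast volume, low LVEF, high baseline creatinine,
#' anemia), and train/test baseline risks calibrated so that the expected
#' outcome prevalence is about 8.3\% in training and 5.2\% in test - the
#' reported concept drift.
#'
#' @param seed Integer seed.
#' @param n_train,n_test Cohort sizes (defaults: the case-study split
#'   1791/769).
#' @return A \code{synth_config}.
#' @export
aki_synth_config <- function(seed = 1L, n_train = 1791L, n_test = 769L) {
  variables <- list(
    synth_numeric("age", 64.37, 11.07, 64.21, 11.00, units = "years"),
    synth_binary("male", 0.664, 0.671),
    synth_binary("anemia", 0.018, 0.035),
    synth_binary("diabetes", 0.437, 0.448),
    synth_binary("heart_failure", 0.071, 0.082),
    synth_binary("hypotension", 0.011, 0.010),
    synth_binary("mi_history", 0.071, 0.064),
    synth_binary("hypercholesterolemia", 0.861, 0.888),
    synth_binary("urgent_pci", 0.114, 0.148),
    synth_binary("hypertension", 0.698, 0.719),
    synth_binary("iabp", 0.005, 0.007),
    synth_numeric("contrast_volume", 135.23, 71.17, 124.46, 63.90,
                  units = "ml"),
    synth_numeric("gfr", 77.76, 26.44, 82.56, 26.86, units = "ml/min"),
    synth_numeric("hdl_c", 1.02, 0.26, 1.02, 0.25, units = "mmol/L"),
    synth_numeric("pre_peak_creatinine", 109.78, 18.80, 106.76, 19.58,
                  units = "umol/L"),
    synth_numeric("lvef", 66.27, 11.37, 66.36, 10.96, units = "%")
  )
  planted <- pattern(
    "aki",
    conditions = list(
      condition("contrast_volume", ">", 200),
      condition("lvef", "<=", 45),
      condition("pre_peak_creatinine", ">", 140),
      condition("anemia", "==", "Yes")
    ),
    min_matches = 1L
  )
  synth_config(variables, planted,
               baseline_risk = c(0.026, 0.007), risk_per_match = 0.2,
               n_train = n_train, n_test = n_test, seed = seed)
}

#' Generate a synthetic train/test cohort pair
#'
#' Records are ordered training period first, then test period, emulating a
#' chronological registry; the test cohort's \code{order_index} continues
#' after the training cohort's.
#'
#' @param config A \code{\link{synth_config}}.
#' @return List with \code{cohort}s \code{train} and \code{test}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    train <- draw_period(config, "train")
    test <- draw_period(config, "test")
  })
  test$order_index <- test$order_index + config$n_train
  list(train = train, test = test)
}

draw_period <- function(config, period) {
  n <- if (period == "train") config$n_train else config$n_test
  cols <- list()
  specs <- list()
  for (v in config$variables) {
    if (v$kind == "numeric") {
      mu <- if (period == "train") v$mean else v$mean_test
      sg <- if (period == "train") v$sd else v$sd_test
      cols[[v$name]] <- stats::rnorm(n, mu, sg)
      specs[[length(specs) + 1L]] <-
        variable_spec(v$name, "numeric", units = v$units)
    } else {
      p <- if (period == "train") v$p_positive else v$p_positive_test
      cols[[v$name]] <- ifelse(stats::runif(n) < p,
                               v$positive_category, v$negative_category)
      specs[[length(specs) + 1L]] <-
        variable_spec(v$name, "binary",
                      positive_category = v$positive_category)
    }
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  planted <- config$planted_pattern
  counts <- rowSums(condition_match_matrix(planted$conditions, df))
  b <- config$baseline_risk[if (period == "train") 1L else 2L]
  risk <- b + config$risk_per_match * counts
  clamped <- risk > 1 | risk < 0
  if (mean(clamped) > 0.05) {
    warning(sprintf(
      "outcome risk clamped to [0,1] on %.1f%% of %s records",
      100 * mean(clamped), period))
  }
  risk <- pmin(pmax(risk, 0), 1)
  df[[planted$target$variable]] <- stats::rbinom(n, 1L, risk) == 1L
  cohort(df, cohort_schema(specs), planted$target$variable)
}

#' Mask cohort cells at random
#'
#' Each non-target cell is independently set missing with the given
#' probability; the outcome column is never masked. Used to exercise the
#' tolerance of pattern matching to incomplete records.
#'
#' @param table A \code{cohort}.
#' @param rate Missingness probability in [0, 1).
#' @param seed Integer seed.
#' @return The masked \code{cohort}.
#' @export
missingness_mask <- function(table, rate, seed = 1L) {
  stopifnot(inherits(table, "cohort"))
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("rate must be in [0, 1)")
  }
  if (rate == 0) return(table)
  n <- nrow(table$data)
  with_seed(seed, {
    for (nm in names(table$schema)) {
      mask <- stats::runif(n) < rate
      table$data[[nm]][mask] <- NA
    }
  })
  table
}
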