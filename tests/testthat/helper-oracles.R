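# Independent brute-force oracles, deliberately written without reusing any
# package internals, so oracle agreement tests stay two-route.

# Shannon entropy via table(), base 2
oracle_entropy <- function(labels) {
  n <- length(labels)
  p <- as.vector(table(labels)) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

# exhaustive midpoint scan for the best <=x />x split
oracle_best_split <- function(values, labels) {
  keep <- !is.na(values)
  v <- values[keep]
  y <- labels[keep]
  u <- sort(unique(v))
  if (length(u) < 2) return(NULL)
  mids <- (u[-1] + u[-length(u)]) / 2
  h <- oracle_entropy(y)
  gains <- vapply(mids, function(x) {
    left <- y[v <= x]
    right <- y[v > x]
    h - length(left) / length(y) * oracle_entropy(left) -
      length(right) / length(y) * oracle_entropy(right)
  }, numeric(1))
  best <- which.max(gains)
  if (gains[best] <= 1e-12) return(NULL)
  list(cutoff = mids[best], gain = gains[best])
}

# pairwise-concordance AUC (Mann-Whitney, ties counted 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# record-by-record condition evaluation + exhaustive k scan maximizing the
# F-score, ties to larger k
oracle_match_one <- function(conditions, record) {
  sum(vapply(conditions, function(cond) {
    val <- record[[cond$variable]]
    if (is.null(val) || is.na(val)) return(FALSE)
    if (cond$comparator == "<=") return(as.numeric(val) <= cond$value)
    if (cond$comparator == ">") return(as.numeric(val) > cond$value)
    as.character(val) == cond$value
  }, logical(1)))
}

oracle_opt_k <- function(conditions, data, labels) {
  m <- length(conditions)
  counts <- vapply(seq_len(nrow(data)), function(i) {
    oracle_match_one(conditions, as.list(data[i, , drop = FALSE]))
  }, numeric(1))
  fs <- vapply(seq_len(m), function(k) {
    pred <- counts >= k
    tp <- sum(pred & labels)
    if (tp == 0) return(0)
    prec <- tp / sum(pred)
    rec <- tp / sum(labels)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  best <- max(fs)
  list(k = max(which(fs >= best - 1e-12)), value = best, values = fs)
}

# ---- shared fixtures -------------------------------------------------------

# the ten printed conditions of the published data-driven AKI pattern
printed_conditions <- function() {
  list(
    condition("lvef", "<=", 56.6),
    condition("pre_peak_creatinine", ">", 160),
    condition("gfr", "<=", 31.5),
    condition("urgent_pci", "==", "Yes"),
    condition("iabp", "==", "Yes"),
    condition("contrast_volume", ">", 79.5),
    condition("age", "<=", 58.5),
    condition("hdl_c", "<=", 0.695),
    condition("hypertension", "==", "Yes"),
    condition("anemia", "==", "Yes")
  )
}

printed_pattern <- function(k = 2L) {
  pattern("aki", printed_conditions(), k)
}

# small mixed-type cohort built in code
toy_cohort <- function(n = 40, seed = 99) {
  set.seed(seed)
  df <- data.frame(
    age = round(rnorm(n, 60, 10)),
    lvef = round(rnorm(n, 60, 8), 1),
    urgent_pci = sample(c("Yes", "No"), n, TRUE, c(0.2, 0.8)),
    stringsAsFactors = FALSE
  )
  df$aki <- (df$lvef < 55 | df$urgent_pci == "Yes") & runif(n) < 0.8
  if (!any(df$aki)) df$aki[1] <- TRUE
  if (all(df$aki)) df$aki[2] <- FALSE
  sch <- cohort_schema(
    variable_spec("age", "numeric", units = "years"),
    variable_spec("lvef", "numeric", units = "%"),
    variable_spec("urgent_pci", "binary", positive_category = "Yes")
  )
  cohort(df, sch, "aki")
}

# strong-signal generator config for recovery studies: three planted
# conditions each with ~10% marginal match probability, near-deterministic
# risk per match, negligible baseline risk
strong_synth_config <- function(seed, n_train = 2000, n_test = 1000) {
  synth_config(
    variables = list(
      synth_numeric("x1", 0, 1),
      synth_numeric("x2", 50, 10),
      synth_numeric("x3", 10, 2),
      synth_numeric("x4", 0, 1),
      synth_binary("b1", 0.10),
      synth_binary("b2", 0.50),
      synth_binary("b3", 0.30)
    ),
    planted_pattern = pattern("y", list(
      condition("x1", ">", qnorm(0.9)),
      condition("x2", "<=", qnorm(0.1, 50, 10)),
      condition("b1", "==", "Yes")
    ), 1L),
    baseline_risk = 0.01, risk_per_match = 0.9,
    n_train = n_train, n_test = n_test, seed = seed
  )
}
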