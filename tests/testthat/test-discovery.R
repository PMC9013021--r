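test_that("candidate conditions point at the risk-enriched side", {
  set.seed(3)
  n <- 300
  df <- data.frame(
    dose = runif(n, 0, 10),
    flag = sample(c("Yes", "No"), n, TRUE),
    const = rep("A", n),
    stringsAsFactors = FALSE
  )
  df$y <- runif(n) < ifelse(df$dose > 5, 0.7, 0.1)
  sch <- cohort_schema(variable_spec("dose", "numeric"),
                       variable_spec("flag", "binary", positive_category = "Yes"),
                       variable_spec("const", "categorical"))
  tab <- cohort(df, sch, "y")
  cands <- generate_candidates(tab)
  vars <- vapply(cands, `[[`, character(1), "variable")

  dose_cand <- cands[[which(vars == "dose")]]
  expect_equal(dose_cand$comparator, ">")          # positives sit above the cutoff
  expect_equal(sum(vars == "flag"), 2L)            # one candidate per category
  expect_setequal(vapply(cands[vars == "flag"], `[[`, character(1), "value"),
                  c("Yes", "No"))
  expect_false("const" %in% vars)                  # constant variable omitted

  pure <- cohort(data.frame(x = rnorm(10), y = rep(TRUE, 10)),
                 cohort_schema(variable_spec("x", "numeric")), "y")
  expect_error(generate_candidates(pure), "both classes")
})

test_that("optimize_threshold equals the exhaustive brute-force scan", {
  single <- toy_cohort()
  k1 <- optimize_threshold(list(condition("lvef", "<=", 55)), single)
  expect_equal(as.integer(k1), 1L)

  set.seed(13)
  for (rep in 1:6) {
    m <- sample(3:8, 1)
    n <- 60
    df <- as.data.frame(matrix(rnorm(n * m), n),
                        stringsAsFactors = FALSE)
    names(df) <- paste0("v", seq_len(m))
    df$y <- runif(n) < 0.2 + 0.3 * (df$v1 > 0)
    sch <- cohort_schema(lapply(paste0("v", seq_len(m)),
                                variable_spec, kind = "numeric"))
    tab <- cohort(df, sch, "y")
    conds <- lapply(seq_len(m), function(j) {
      condition(paste0("v", j), sample(c("<=", ">"), 1), rnorm(1))
    })
    got <- optimize_threshold(conds, tab)
    want <- oracle_opt_k(conds, df, df$y)
    expect_equal(as.integer(got), want$k)
    expect_equal(attr(got, "objective"), want$value, tolerance = 1e-12)
    expect_equal(attr(got, "objectives"), want$values, tolerance = 1e-12)
  }

  # degenerate objective: no threshold ever predicts a true positive
  bad <- pattern("aki", list(condition("lvef", "<=", -999)), 1L)
  expect_warning(
    kd <- optimize_threshold(bad$conditions, toy_cohort()),
    "zero for every threshold")
  expect_equal(as.integer(kd), 1L)
})

test_that("greedy discovery recovers planted single and conjunctive signals", {
  set.seed(8)
  n <- 500
  df <- data.frame(x1 = runif(n, 0, 10), x2 = runif(n, 0, 10),
                   noise = rnorm(n), stringsAsFactors = FALSE)
  df$y <- df$x1 > 5
  sch <- cohort_schema(variable_spec("x1", "numeric"),
                       variable_spec("x2", "numeric"),
                       variable_spec("noise", "numeric"))
  pat <- discover_pattern(cohort(df, sch, "y"))
  expect_equal(length(pat$conditions), 1L)
  expect_equal(pat$conditions[[1]]$variable, "x1")
  expect_equal(pat$conditions[[1]]$comparator, ">")
  expect_gt(pat$conditions[[1]]$value, 4.5)
  expect_lte(pat$conditions[[1]]$value, 5.5)
  expect_equal(pat$min_matches, 1L)
  expect_equal(attr(pat, "objective"), 1.0)
  expect_equal(pat$mode_tag, "pre")
  expect_equal(length(pat$history), 1L)

  # conjunction: both variables recovered with k = 2
  df2 <- data.frame(x1 = runif(n, 0, 10),
                    flag = sample(c("Yes", "No"), n, TRUE),
                    noise = rnorm(n), stringsAsFactors = FALSE)
  df2$y <- df2$x1 > 5 & df2$flag == "Yes"
  sch2 <- cohort_schema(variable_spec("x1", "numeric"),
                        variable_spec("flag", "binary", positive_category = "Yes"),
                        variable_spec("noise", "numeric"))
  pat2 <- discover_pattern(cohort(df2, sch2, "y"))
  expect_setequal(vapply(pat2$conditions, `[[`, character(1), "variable"),
                  c("x1", "flag"))
  expect_equal(pat2$min_matches, 2L)
  expect_equal(attr(pat2, "objective"), 1.0)
})

test_that("discovery is deterministic and stops early without signal", {
  pair <- generate_cohort(strong_synth_config(seed = 123, n_train = 600,
                                              n_test = 50))
  a <- discover_pattern(pair$train)
  b <- discover_pattern(pair$train)
  a$history <- b$history <- NULL  # timestamps differ
  expect_equal(a, b)

  # no signal: search stops almost immediately at a near-baseline objective
  null_cfg <- strong_synth_config(seed = 5, n_train = 800, n_test = 50)
  null_cfg$risk_per_match <- 0
  null_cfg$baseline_risk <- c(0.073, 0.073)
  pn <- generate_cohort(null_cfg)
  pat <- discover_pattern(pn$train, discovery_config(min_improvement = 0.01))
  baseline_f <- {
    p <- mean(cohort_labels(pn$train))
    2 * p / (1 + p)  # F-score of the predict-everyone-positive rule
  }
  expect_lte(length(pat$conditions), 3L)
  expect_lt(attr(pat, "objective"), baseline_f + 0.1)
})

test_that("association arcs flag dependent pairs and skip degenerate patterns", {
  set.seed(77)
  n <- 200
  flag <- sample(c("Yes", "No"), n, TRUE)
  df <- data.frame(a = flag, b = flag,  # identical indicators
                   y = runif(n) < 0.5, stringsAsFactors = FALSE)
  sch <- cohort_schema(variable_spec("a", "binary", positive_category = "Yes"),
                       variable_spec("b", "binary", positive_category = "Yes"))
  tab <- cohort(df, sch, "y")
  pat <- pattern("y", list(condition("a", "==", "Yes"),
                           condition("b", "==", "Yes")), 1L)
  arcs <- compute_arcs(pat, tab)
  expect_equal(nrow(arcs), 1L)
  expect_lt(arcs$p[1], 1e-10)
  expect_true(arcs$significant[1])

  single <- pattern("y", list(condition("a", "==", "Yes")), 1L)
  expect_equal(nrow(compute_arcs(single, tab)), 0L)
})
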