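# Pooled count test, CADD aggregation, logistic burden test, Bonferroni.

test_that("pooled count test is a symmetric 1-df equal-split goodness of fit", {
  r <- pooled_count_test(30, 12)
  s <- pooled_count_test(12, 30)
  expect_equal(r$chi_square, s$chi_square)
  expect_equal(r$p_value, s$p_value)
  expect_equal(r$df, 1L)
  # equal counts give exactly zero
  for (k in c(1, 7, 50)) {
    eq <- pooled_count_test(k, k)
    expect_equal(eq$chi_square, 0)
    expect_equal(eq$p_value, 1)
  }
  # strictly increasing in |a-b| at fixed total
  tot <- 60
  stats <- sapply(30:55, function(a) pooled_count_test(a, tot - a)$chi_square)
  expect_true(all(diff(stats) > 0))
  expect_error(pooled_count_test(0, 0), "zero")
})

test_that("pooled count test matches the closed form without continuity correction", {
  set.seed(71)
  for (i in 1:50) {
    a <- sample.int(100, 1); b <- sample.int(100, 1)
    E <- (a + b) / 2
    x2 <- (a - E)^2 / E + (b - E)^2 / E
    r <- pooled_count_test(a, b)
    expect_equal(r$chi_square, x2)
    expect_equal(r$p_value, pchisq(x2, 1, lower.tail = FALSE))
  }
})

test_that("CADD aggregation sums per-individual scores, zeros in full mode", {
  ev <- rbind(make_event(sample_id = "P1", pos = 1L, scaled_cadd = 10),
              make_event(sample_id = "P1", pos = 2L, scaled_cadd = 20),
              make_event(sample_id = "D1", pos = 3L, carrier = "parent",
                         scaled_cadd = 5))
  agg <- aggregate_cadd(ev, mode = "carriers")
  expect_equal(agg$cadd_sum[agg$sample_id == "P1"], 30)
  expect_equal(agg$cadd_sum[agg$sample_id == "D1"], 5)

  roster <- tibble::tibble(sample_id = c("P1", "P2", "D1", "D2"),
                           role = c("proband", "proband", "parent", "parent"))
  full <- aggregate_cadd(ev, mode = "full", individuals = roster)
  expect_equal(nrow(full), 4L)
  expect_equal(full$cadd_sum[full$sample_id == "P2"], 0)
  expect_equal(full$cadd_sum[full$sample_id == "D2"], 0)

  ev_na <- make_event(scaled_cadd = NA_real_)
  expect_error(aggregate_cadd(ev_na), "no CADD score")
  expect_equal(nrow(aggregate_cadd(ev_na, missing_score = "drop")), 0L)
})

test_that("aggregation equals brute-force recomputation on a synthetic cohort", {
  co <- generate_cohort(small_params(seed = 23))
  vq <- call_quality_filter(co$variants)
  ev <- detect_events(co$pedigrees, filter_cnv_calls(co$cnv_calls), co$genes,
                      vq[vq$qc_pass, ])
  agg <- aggregate_cadd(ev, mode = "carriers")
  truth1 <- co$truth[co$truth$scenario == 1L, ]
  brute <- tapply(truth1$scaled_cadd, truth1$sample_id, sum)
  expect_equal(agg$cadd_sum, as.numeric(brute[agg$sample_id]))
})

test_that("logistic burden test matches a direct maximum-likelihood oracle", {
  set.seed(81)
  n <- 300
  score <- rexp(n, 1 / 15)
  beta_true <- 0.08
  y <- rbinom(n, 1, plogis(-1 + beta_true * score))
  labels <- ifelse(y == 1, "proband", "parent")
  fit <- logistic_burden_test(score, labels)
  expect_true(fit$converged)
  # independent oracle: optimize the binomial log-likelihood directly
  nll <- function(par) {
    eta <- par[1] + par[2] * score
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0), nll, method = "BFGS")
  expect_equal(fit$beta, opt$par[2], tolerance = 1e-4)
})

test_that("null scores give a near-zero coefficient; separation is flagged", {
  set.seed(91)
  n <- 400
  score <- rexp(n, 1 / 10)
  labels <- sample(rep(c("proband", "parent"), n / 2))
  fit <- logistic_burden_test(score, labels)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta), 2.5 * fit$standard_error + 0.05)

  sep <- logistic_burden_test(c(1, 2, 3, 10, 11, 12),
                              c(rep("parent", 3), rep("proband", 3)))
  expect_false(sep$converged)
  expect_true(is.na(sep$beta))

  expect_error(logistic_burden_test(1:4, rep("proband", 4)), "both labels")
  expect_error(logistic_burden_test(c(1, Inf), c("proband", "parent")),
               "finite")
})

test_that("burden test coverage: planted beta within 2 SE in most replicates", {
  set.seed(101)
  beta_true <- 0.1
  hits <- vapply(1:60, function(i) {
    n <- 300
    score <- rexp(n, 1 / 15)
    y <- rbinom(n, 1, plogis(-1.2 + beta_true * score))
    if (length(unique(y)) < 2) return(NA)
    fit <- logistic_burden_test(score, ifelse(y == 1, "proband", "parent"))
    if (!fit$converged) return(NA)
    abs(fit$beta - beta_true) <= 2 * fit$standard_error
  }, logical(1))
  expect_gt(mean(hits, na.rm = TRUE), 0.85)
})

test_that("Bonferroni threshold and decision helper", {
  expect_equal(bonferroni_threshold(0.05, 3), 0.05 / 3)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_true(is_significant(0.0097, 0.05, 3))
  expect_false(is_significant(0.02, 0.05, 3))
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
  expect_error(bonferroni_threshold(1.5, 3), "alpha")
})
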