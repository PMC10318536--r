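test_that("effect-size conversion chain reproduces the printed values", {
  # z = -4.917 with groups 208 + 100: r = |z|/sqrt(308), d = 2r/sqrt(1-r^2)
  r <- abs(-4.917) / sqrt(308)
  expect_equal(effect_r_to_d(r), 0.583, tolerance = 2e-3)  # printed precision
  # H = 93.0, k = 3, n = 388: eta2 = (H-k+1)/(n-k), d = 2*sqrt(eta2/(1-eta2))
  eta2 <- (93.0 - 3 + 1) / (388 - 3)
  expect_equal(round(eta2_to_d(eta2), 3), 1.113)
  # d(r) strictly increasing with d(0) = 0
  grid <- seq(0, 0.99, by = 0.01)
  d <- effect_r_to_d(grid)
  expect_equal(d[1], 0)
  expect_true(all(diff(d) > 0))
})

test_that("spearman association: monotone transforms, nulls, errors", {
  x <- rnorm(100)
  out <- spearman_assoc(x, exp(2 * x + 1))
  expect_equal(out$rho, 1)
  set.seed(5)
  out2 <- spearman_assoc(rnorm(10000), rnorm(10000))
  expect_lt(abs(out2$rho), 0.03)
  expect_warning(res <- spearman_assoc(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(res$rho))
  expect_error(spearman_assoc(1:3, 1:3), "at least 5")
  expect_equal(out$label, "very strong")   # rho = 1 band
})

test_that("two-group comparison: symmetry null and study arithmetic", {
  g1 <- c(1, 2, 3, 4, 5, 6, 7, 8)
  out <- group_compare(c(g1, g1), rep(c("a", "b"), each = 8))
  expect_equal(out$statistic, 8 * 8 / 2)    # U = n1 n2 / 2
  expect_equal(out$cohens_d, 0)
  # the Mann-Whitney z matches the printed conversion when recomputed
  set.seed(6)
  m <- c(rnorm(208, 1), rnorm(100))
  g <- rep(c("No falls", "Falls >=1"), c(208, 100))
  out2 <- group_compare(m, g)
  expect_equal(out2$cohens_d, effect_r_to_d(abs(out2$z) / sqrt(308)))
})

test_that("k-group comparison: eta2 conversion, permutation invariance, post-hocs", {
  set.seed(7)
  m <- c(rnorm(60, 0), rnorm(60, 0.6), rnorm(60, 1.2))
  g <- rep(c("lo", "mid", "hi"), each = 60)
  out <- group_compare(m, g)
  expect_equal(out$k, 3L)
  expect_equal(out$cohens_d, eta2_to_d(out$eta2))
  expect_equal(out$eta2, (out$statistic - 3 + 1) / (length(m) - 3))
  expect_equal(nrow(out$posthoc), 3L)
  expect_true(all(out$posthoc$p_bonferroni >= out$posthoc$p))
  # permutation of labels leaves H unchanged
  perm <- sample(length(m))
  out2 <- group_compare(m[perm], g[perm])
  expect_equal(out2$statistic, out$statistic)
  # the alternative eta2 variant is available behind a flag
  out3 <- group_compare(m, g, eta2_variant = "H/(n-1)")
  expect_equal(out3$eta2, out$statistic / (length(m) - 1))
})

test_that("normality check: known distributions and synthetic measures", {
  set.seed(8)
  x <- rnorm(100000)
  expect_warning(nc <- normality_check(x), "n > 5000")
  expect_lt(abs(nc$skewness), 0.05)
  expect_lt(abs(nc$kurtosis - 3), 0.05)
  expect_true(is.na(nc$shapiro))          # n > 5000
  e <- rexp(100000)
  expect_lt(abs(skewness(e) - 2), 0.05)
  expect_lt(abs(kurtosis(e) - 9), 0.4)
  # right-skewed synthetic measures are detectably non-normal
  rm <- sim_rm(1000, 61)
  p <- suppressWarnings(estimate_item_parameters(rm))
  ct <- score_conversion_table(p)
  meas <- ct$scaled[total_scores(rm) + 1]
  expect_lt(normality_check(meas)$shapiro_p, 0.05)
  expect_error(normality_check(rep(1, 20)), "constant")
})

test_that("external validity battery reproduces the design's groupings", {
  cfg <- simulation_config(n_patients = 600, seed = 71)
  rec <- simulate_dataset(cfg)
  one <- select_one_per_patient(rec, seed = 72)
  rm <- to_response_matrix(one)
  p <- suppressWarnings(estimate_item_parameters(rm))
  ct <- score_conversion_table(p)
  ev <- external_validity(one, ct)
  expect_lt(ev$convergent$edss$rho, -0.3)
  expect_gt(ev$convergent$abc$rho, 0.3)
  expect_named(ev$discriminant, c("edss3", "abc40", "abc5080", "falls1", "falls2"))
  expect_equal(ev$discriminant$edss3$k, 3L)
  expect_gt(ev$discriminant$falls1$cohens_d, 0)
  # missing covariates are dropped per-analysis
  one$abc[1:200] <- NA
  ev2 <- external_validity(one, ct)
  expect_equal(ev2$convergent$abc$n, sum(!is.na(one$abc)))
})
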