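test_that("item-trait chi-square bookkeeping matches the design", {
  rm <- fx_rm288()
  p <- fx_par288()
  f <- suppressWarnings(fit_statistics(rm, p, n_class_intervals = 5))
  expect_equal(f$n_class_intervals, 5L)
  expect_equal(f$total_df, 56L)                 # 14 items x (5 - 1)
  expect_equal(f$total_chi2, sum(f$item_chi2))
  expect_equal(f$total_df, sum(f$item_df))
  expect_equal(f$bonferroni_cutoff, 0.05 / 14)
  # default class-interval rule: clamp(floor(n/50), 2, 10) -> 5 at n = 288
  f2 <- suppressWarnings(fit_statistics(rm, p))
  expect_equal(f2$n_class_intervals, 5L)
  # two testlets: Bonferroni cut-off 0.025
  trm <- build_testlets(rm, testlet_spec())
  pt <- suppressWarnings(estimate_item_parameters(trm))
  ft <- suppressWarnings(fit_statistics(trm, pt))
  expect_equal(ft$bonferroni_cutoff, 0.025)
})

test_that("correctly specified data fit the model (single-seed smoke)", {
  rm <- fx_rm288()
  p <- fx_par288()
  f <- suppressWarnings(fit_statistics(rm, p))
  expect_gt(f$total_p, f$bonferroni_cutoff)
  expect_lte(f$item_fit_sd, 1.4)
  expect_lte(f$person_fit_sd, 1.4)
  expect_length(f$flagged_items, 0)
})

test_that("threshold disorder is counted as a percentage of items", {
  mk_tau <- function(disordered)
    if (disordered) c(0.5, -0.5, 0.2, -0.2) else c(-1.2, -0.4, 0.4, 1.2)
  tau <- lapply(1:14, function(i) { t <- mk_tau(i <= 12); t - mean(t) })
  p <- bbsms:::new_item_parameters(rep(0, 14), tau)
  rm <- sim_rm(100, 71)
  f <- suppressWarnings(fit_statistics(rm, p, n_class_intervals = 2))
  expect_length(f$disordered_threshold_items, 12)
  expect_equal(round(f$disordered_pct, 1), 85.7)   # 12 of 14
})

test_that("residual structure: LDRC definition and clean-data behaviour", {
  rm <- fx_rm288()
  p <- fx_par288()
  rs <- suppressWarnings(residual_structure(rm, p))
  off <- rs$residual_corr[lower.tri(rs$residual_corr)]
  expect_equal(rs$ldrc, mean(off) + 0.2)
  expect_equal(rs$residual_corr, t(rs$residual_corr))
  expect_lt(rs$pst, 10)
  expect_lte(rs$bci_lower, rs$pst)
  # configurable offset feeds straight through
  rs2 <- suppressWarnings(residual_structure(rm, p, ld_offset = 0.5))
  expect_equal(rs2$ldrc, mean(off) + 0.5)
})

test_that("within-testlet dependence is detected above the LDRC", {
  cfg <- simulation_config(n_patients = 400, seed = 301, testlet_sd = 1.0,
                           obs_sd = 0, obs_per_patient_probs = c(1, 0, 0))
  rm <- to_response_matrix(simulate_dataset(cfg))
  p <- suppressWarnings(estimate_item_parameters(rm))
  rs <- suppressWarnings(residual_structure(rm, p))
  expect_false(is.null(rs$ld_pairs))
  cl <- bbsms:::DEFAULT_TESTLETS
  within <- mapply(function(a, b) cl[match(a, p$labels)] == cl[match(b, p$labels)],
                   rs$ld_pairs$item1, rs$ld_pairs$item2)
  expect_true(any(within))
})

test_that("conditional LR statistic: identical groups give ~0", {
  rm <- sim_rm(120, 81)
  # duplicated sample, groups = the two copies: identical class intervals
  both <- response_matrix(rbind(unclass(rm), unclass(rm)),
                          attr(rm, "item_max"))
  grp <- rep(c("a", "b"), each = nrow(rm))
  out <- suppressWarnings(conditional_total_chi2(both, groups = grp, n_boot = 0))
  expect_lt(out$statistic, 1e-4)
})

test_that("conditional Monte Carlo p-values are uniform under the model", {
  # scaled down from 20 seeds at n = 500: the Monte Carlo reference is exact
  # by construction, so uniformity is structural; this guards the plumbing
  ps <- numeric(8)
  for (s in 1:8) {
    trm <- build_testlets(sim_rm(250, 180 + s), testlet_spec())
    set.seed(s)
    ps[s] <- suppressWarnings(conditional_total_chi2(trm, n_boot = 39))$p
  }
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.05)
  expect_true(all(ps >= 1 / 40 & ps <= 1))
})

test_that("anchoring: exact parameter transfer and idempotence", {
  rm <- fx_rm288()
  p <- fx_par288()
  res <- suppressWarnings(anchor_and_refit(rm, p))
  # anchored parameters are the exported ones, bit for bit
  expect_identical(res$params$delta, p$delta)
  expect_identical(res$params$tau, p$tau)
  # anchoring a sample to its own calibration reproduces person estimates
  pm <- estimate_person_measures(rm, p)
  expect_equal(res$persons$theta, pm$theta)
  # confirmation sample simulated from the same world fits when anchored
  rm2 <- sim_rm(288, 85)
  res2 <- suppressWarnings(anchor_and_refit(rm2, p))
  expect_gt(res2$fit$total_p, res2$fit$bonferroni_cutoff)
  expect_error(anchor_and_refit(rm2[, 1:13], p), "cover")
})

test_that("anchored estimation frees only the requested items", {
  rm <- sim_rm(300, 86)
  p <- suppressWarnings(estimate_item_parameters(rm))
  p5 <- suppressWarnings(estimate_item_parameters(rm, anchor = p,
                                                  fixed_items = setdiff(1:14, 5)))
  expect_equal(p5$delta[-5], p$delta[-5], tolerance = 1e-9)
  expect_lt(abs(p5$delta[5] - p$delta[5]), 0.2)
})
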