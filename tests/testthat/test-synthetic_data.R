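test_that("simulation is reproducible from its seed", {
  cfg <- pure_config(50, 7)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("ability law matches its configured moments", {
  cfg0 <- simulation_config(n_patients = 10000, seed = 3,
                            ability = list(mean = 0.75, sd = 1.3, skew = 0))
  th0 <- simulate_persons(cfg0)$theta
  expect_lt(abs(skewness(th0)), 0.05)
  expect_lt(abs(mean(th0) - 0.75), 0.05)
  cfg1 <- simulation_config(n_patients = 10000, seed = 4,
                            ability = list(mean = 0.75, sd = 1.3, skew = 0.22))
  th1 <- simulate_persons(cfg1)$theta
  expect_lt(abs(skewness(th1) - 0.22), 0.08)
  expect_lt(abs(sd(th1) - 1.3), 0.05)
})

test_that("config validation rejects inconsistent worlds", {
  expect_error(simulation_config(obs_per_patient_probs = c(0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(simulation_config(item_locations = rep(1, 14)), "sum to zero")
  expect_error(simulation_config(testlet_sd = -1), "testlet_sd")
  expect_error(simulation_config(ability = list(mean = 0, sd = 1, skew = 2)),
               "skew")
})

test_that("saturated ability produces only top categories", {
  cfg <- pure_config(20, 5)
  per <- simulate_persons(cfg)
  per$theta <- rep(10, nrow(per))
  rec <- simulate_responses(per, cfg)
  expect_true(all(as.matrix(as.data.frame(rec)[, sprintf("BBS%02d", 1:14)]) == 4L))
})

test_that("covariate links are monotone and calibrated", {
  # deterministic link, no discretization: exact monotone transform
  cfg <- simulation_config(n_patients = 200, seed = 11,
                           covariate_link = list(
                             edss = list(rho = -1, discretize = FALSE),
                             abc = list(rho = 1, discretize = FALSE),
                             falls = list(intercept = 0.1, slope = -0.6)))
  per <- simulate_covariates(simulate_persons(cfg), cfg)
  # ties can arise only from clamping at the scale bounds
  expect_lt(cor(per$theta, per$edss, method = "spearman"), -0.999)
  expect_gt(cor(per$theta, per$abc, method = "spearman"), 0.999)
  # default calibration targets rho ~= -0.57 (EDSS) and ~= +0.52 (ABC)
  cfg2 <- simulation_config(n_patients = 2000, seed = 12)
  per2 <- simulate_covariates(simulate_persons(cfg2), cfg2)
  expect_lt(abs(cor(per2$theta, per2$edss, method = "spearman") - (-0.573)), 0.05)
  expect_lt(abs(cor(per2$theta, per2$abc, method = "spearman") - 0.523), 0.05)
  expect_lt(cor(per2$theta, per2$falls, method = "spearman"), -0.3)
})

test_that("observation counts follow the configured distribution", {
  cfg <- simulation_config(n_patients = 814, seed = 9)
  rec <- simulate_dataset(cfg)
  tb <- table(table(rec$patient_id))
  expect_equal(sort(unique(rec$obs_index)), seq_len(max(rec$obs_index)))
  # 477:268:69 proportions, loosely
  expect_gt(tb[["1"]], tb[["2"]])
  expect_gt(tb[["2"]], tb[["3"]])
})

test_that("parameter recovery from simulated data (reduced n)", {
  cfg <- pure_config(800, 21)
  rm <- to_response_matrix(simulate_dataset(cfg))
  p <- suppressWarnings(estimate_item_parameters(rm))
  rmse <- sqrt(mean((unlist(p$tau) - unlist(cfg$item_thresholds))^2))
  expect_lt(rmse, 0.25)   # the n = 2000 bound of 0.15 is asserted in acceptance
  expect_lt(sqrt(mean((p$delta - cfg$item_locations)^2)), 0.15)
})
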