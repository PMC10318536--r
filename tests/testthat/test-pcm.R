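test_that("category probabilities: symmetry, dichotomy, normalization", {
  expect_equal(unname(pcm_category_probs(0, 0, c(0, 0, 0, 0))), rep(0.2, 5))
  expect_equal(unname(pcm_category_probs(1.3, 1.3, 0)[2]), 0.5)  # theta = delta
  set.seed(2)
  for (i in 1:20) {
    th <- rnorm(1, 0, 3); d <- rnorm(1); tau <- rnorm(4); tau <- tau - mean(tau)
    expect_equal(sum(pcm_category_probs(th, d, tau)), 1)
  }
  # vectorized over abilities
  p <- pcm_category_probs(c(-1, 0, 1), 0.5, c(-1, 1))
  expect_equal(dim(p), c(3L, 3L))
  expect_equal(rowSums(p), rep(1, 3))
})

test_that("CML matches a brute-force grid on a two-item instance", {
  # two dichotomous items: a single free location split d
  set.seed(3)
  th <- rnorm(30, 0, 1.5)
  x <- cbind(rbinom(30, 1, plogis(th - 0.8)), rbinom(30, 1, plogis(th + 0.8)))
  # ensure both categories observed and mixed totals present
  x[1, ] <- c(0, 1); x[2, ] <- c(1, 0); x[3, ] <- c(1, 1); x[4, ] <- c(0, 0)
  rm <- response_matrix(x, c(1, 1))
  est <- estimate_item_parameters(rm)
  grid <- seq(-3, 3, by = 0.001)
  cll <- vapply(grid, function(d) oracle_cll_2dich(x, d), 0)
  d_grid <- grid[which.max(cll)]
  expect_lt(abs((est$delta[2] - est$delta[1]) - d_grid), 0.01)
})

test_that("person ML matches a likelihood grid and is sufficient/monotone", {
  rm <- fx_rm288()
  p <- fx_par288()
  pm <- estimate_person_measures(rm, p)
  # sufficiency: equal raw totals -> identical estimates, exactly
  expect_true(all(tapply(pm$theta, pm$raw, function(v) diff(range(v))) == 0))
  # strict monotonicity in the raw score
  ord <- order(unique(pm$raw))
  expect_true(all(diff(unique(cbind(pm$raw, pm$theta))[ord, 2]) > 0))
  # grid oracle on a handful of non-extreme persons
  grid <- seq(-8, 8, by = 0.001)
  idx <- which(!pm$extreme)[c(1, 50, 150)]
  rmc <- bbsms:::conform_rm(rm, p)
  for (v in idx) {
    opt <- oracle_person_grid(unclass(rmc)[v, ], p$delta, p$tau, grid)
    expect_lt(abs(pm$theta[v] - opt), 0.005)
  }
  # extremes are flagged and finite
  expect_true(all(is.finite(pm$theta)))
  expect_equal(pm$extreme, pm$raw %in% c(0, sum(p$item_max)))
})

test_that("estimates are invariant to person relabeling", {
  rm <- sim_rm(150, 61)
  p1 <- suppressWarnings(estimate_item_parameters(rm))
  set.seed(62)
  perm <- sample(nrow(rm))
  p2 <- suppressWarnings(estimate_item_parameters(
    response_matrix(unclass(rm)[perm, ], attr(rm, "item_max"))))
  expect_equal(p1$delta, p2$delta, tolerance = 1e-8)
  expect_equal(p1$tau, p2$tau, tolerance = 1e-8)
})

test_that("sum-zero constraints hold after estimation", {
  p <- fx_par288()
  expect_lt(abs(sum(p$delta)), 1e-8)
  for (t in p$tau) expect_lt(abs(sum(t)), 1e-8)
})

test_that("null categories collapse with a warning and a score map", {
  x <- unclass(sim_rm(120, 63))
  x[, 2][x[, 2] == 0] <- 1L            # category 0 of item 2 never observed
  expect_warning(p <- estimate_item_parameters(response_matrix(x, rep(4, 14))),
                 "null categories")
  expect_equal(p$item_max[2], 3L)
  expect_equal(p$score_map[[2]], 1:4)
})

test_that("conversion table: monotone, exact endpoints, sufficiency oracle", {
  p <- fx_par288()
  ct <- score_conversion_table(p)
  expect_equal(nrow(ct), sum(p$item_max) + 1L)   # collapsed categories allowed
  expect_true(all(diff(ct$theta) > 0))
  expect_equal(ct$scaled[c(1, nrow(ct))], c(0, 100))
  expect_true(all(ct$se > 0))
  # theta(r) equals the person estimate of any pattern with total r
  rm <- fx_rm288()
  pm <- estimate_person_measures(rm, p)
  expect_equal(pm$theta, ct$theta[pm$raw + 1], tolerance = 1e-6)
})

test_that("item parameter text round-trip preserves the calibration", {
  p <- fx_par288()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_item_parameters(p, path)
  q <- read_item_parameters(path)
  expect_equal(q$delta, p$delta, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(unlist(q$tau)), unname(unlist(p$tau)), tolerance = 1e-12)
})
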