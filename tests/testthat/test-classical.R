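test_that("Cronbach alpha: perfect consistency, independence, closed form", {
  set.seed(1)
  x <- sample(0:4, 60, TRUE)
  two <- response_matrix(cbind(a = x, b = x), c(4, 4))
  expect_equal(classical_item_stats(two)$alpha, 1)
  # mutually independent items
  ind <- response_matrix(matrix(sample(0:4, 5000 * 14, TRUE), 5000, 14),
                         rep(4, 14))
  expect_lt(abs(classical_item_stats(ind)$alpha), 0.05)
  # closed-form cross-check on arbitrary integer matrices
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(sample(0:4, 40 * 6, TRUE), 40, 6)
    k <- ncol(m)
    direct <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
    expect_equal(classical_item_stats(response_matrix(m, rep(4, 6)))$alpha,
                 direct)
  }
})

test_that("zero-variance items are reported undefined with a warning", {
  m <- cbind(a = rep(2L, 30), b = sample(0:4, 30, TRUE), c = sample(0:4, 30, TRUE))
  expect_warning(st <- classical_item_stats(response_matrix(m, rep(4, 3))),
                 "zero-variance")
  expect_true(is.na(st$item_rest_rho[["a"]]))
})

test_that("Mokken coefficients: Guttman maximum and brute-force oracle", {
  # perfect Guttman (comonotone) polytomous data
  th <- sort(rep(0:4, each = 4))
  g <- response_matrix(cbind(th, th, th), rep(4, 3))
  mk <- mokken_coefficients(g)
  expect_equal(mk$H, 1)
  # 3-item 6-person toy table vs enumeration oracle
  toy <- response_matrix(rbind(c(0, 1, 0), c(1, 1, 0), c(2, 3, 1), c(3, 2, 2),
                               c(4, 3, 2), c(4, 4, 3)), rep(4, 3))
  mk2 <- mokken_coefficients(toy)
  x <- unclass(toy)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(mk2$Hij[i, j], oracle_hij(x[, i], x[, j]))
})

test_that("H >= min(Hj) on any dataset", {
  for (s in 1:8) {
    rm <- sim_rm(60, 1000 + s)
    mk <- mokken_coefficients(rm)
    expect_gte(mk$H, min(mk$Hj) - 1e-12)
  }
})

test_that("AISP scales strong items together and isolates a deviant item", {
  rm <- sim_rm(400, 31)                       # one latent trait: one scale
  expect_true(all(mokken_aisp(rm) == 1L))
  # an item negatively related to the others ends up unscalable
  set.seed(32)
  x <- unclass(sim_rm(300, 32))
  x[, 14] <- 4L - x[, 1]                       # reversed item
  part <- mokken_aisp(response_matrix(x, rep(4, 14)))
  expect_identical(unname(part[14]), 0L)
  expect_true(all(part[1:13] == 1L))
})

test_that("bivariate normal CDF matches the integration oracle", {
  for (case in list(c(0, 0, 0.5), c(1, -0.5, 0.3), c(-1.2, 0.4, -0.7),
                    c(0.3, 0.3, 0.95))) {
    expect_equal(bbsms:::pbvnorm(case[1], case[2], case[3]),
                 oracle_pbvnorm(case[1], case[2], case[3]), tolerance = 1e-6)
  }
})

test_that("polychoric correlation recovers the latent correlation", {
  set.seed(41)
  n <- 5000
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  cuts <- c(-1.2, -0.4, 0.4, 1.2)
  x <- findInterval(z1, cuts); y <- findInterval(z2, cuts)
  rho <- bbsms:::polychoric_pair(x, y)
  expect_lt(abs(rho - 0.5), 0.05)
  # independent items: estimate near zero
  y2 <- findInterval(rnorm(n), cuts)
  expect_lt(abs(bbsms:::polychoric_pair(x, y2)), 0.05)
  # matrix is symmetric with unit diagonal
  rm <- sim_rm(150, 43)[, 1:5]
  R <- polychoric_matrix(response_matrix(unclass(rm), rep(4, 5)))
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 5))
})

test_that("one-factor ULS fit: truth, perfect input, and misfit flagging", {
  # data from a true one-factor ordinal model
  set.seed(51)
  n <- 2000; p <- 8
  lam <- seq(0.55, 0.85, length.out = p)
  f <- rnorm(n)
  z <- sapply(lam, function(l) l * f + sqrt(1 - l^2) * rnorm(n))
  x <- apply(z, 2, findInterval, vec = c(-1, 0, 1))
  S <- polychoric_matrix(response_matrix(x, rep(3, p)))
  fit <- cfa_onefactor_fit(S, n)
  expect_lt(fit$rmsea, 0.06)
  expect_gt(fit$cfi, 0.95)
  # model-implied matrix fed back: perfect fit
  Sig <- tcrossprod(lam); diag(Sig) <- 1
  dimnames(Sig) <- list(paste0("i", 1:p), paste0("i", 1:p))
  fit2 <- cfa_onefactor_fit(Sig, 500)
  expect_equal(fit2$srmr, 0, tolerance = 1e-4)
  # two-cluster structure: flagged as misfit, cluster pairs surfaced
  blk <- matrix(0.15, p, p)
  blk[1:4, 1:4] <- 0.8; blk[5:8, 5:8] <- 0.8; diag(blk) <- 1
  dimnames(blk) <- dimnames(Sig)
  fit3 <- cfa_onefactor_fit(blk, 1000)
  expect_gt(fit3$rmsea, 0.06)
  expect_true(!is.null(fit3$flagged_pairs))
  in_cluster <- with(fit3$flagged_pairs,
                     (item1 %in% paste0("i", 1:4) & item2 %in% paste0("i", 1:4)) |
                     (item1 %in% paste0("i", 5:8) & item2 %in% paste0("i", 5:8)))
  expect_true(any(in_cluster))
  # correlated uniquenesses recover the fit
  cp <- t(utils::combn(1:4, 2))
  cp <- rbind(cp, t(utils::combn(5:8, 2)) )
  fit4 <- cfa_onefactor_fit(blk, 1000, correlated_pairs = cp)
  expect_lt(fit4$rmsea, fit3$rmsea)
})
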