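# Shared fixtures and independent oracles.  Heavy objects are memoized so
# multiple test files can reuse one calibration.

memo <- local({
  cache <- new.env(parent = emptyenv())
  function(key, fn) {
    if (!exists(key, cache)) assign(key, fn(), cache)
    get(key, cache)
  }
})

# A correctly specified partial credit world: one observation per patient,
# no observation noise, no testlets, no DIF.
pure_config <- function(n, seed, ...) {
  simulation_config(n_patients = n, seed = seed, testlet_sd = 0, obs_sd = 0,
                    obs_per_patient_probs = c(1, 0, 0), ...)
}

sim_rm <- function(n, seed, ...) {
  to_response_matrix(simulate_dataset(pure_config(n, seed, ...)))
}

# n = 288 calibration shared by the fit/DIF tests
fx_rm288 <- function() memo("rm288", function() sim_rm(288, 42))
fx_par288 <- function() memo("par288", function()
  suppressWarnings(estimate_item_parameters(fx_rm288())))

# Long-format records with valid covariates for IO / sampling tests
make_records <- function(n_single = 20, n_double = 10, n_triple = 5, seed = 1) {
  set.seed(seed)
  pid <- c(sprintf("S%03d", seq_len(n_single)),
           rep(sprintf("D%03d", seq_len(n_double)), each = 2),
           rep(sprintf("T%03d", seq_len(n_triple)), each = 3))
  obs <- c(rep(1L, n_single), rep(1:2, n_double), rep(1:3, n_triple))
  n <- length(pid)
  df <- data.frame(
    patient_id = pid, center = sample(c("MI", "BO", "GE"), n, TRUE),
    obs_index = obs,
    gender = sample(c("female", "male"), n, TRUE),
    age = round(runif(n, 20, 80), 1),
    course = sample(c("RR", "SP", "PP"), n, TRUE),
    duration = round(runif(n, 0, 40), 1),
    edss = sample(seq(0, 10, 0.5), n, TRUE),
    abc = round(runif(n, 0, 100)), falls = rpois(n, 1),
    stringsAsFactors = FALSE)
  for (it in sprintf("BBS%02d", 1:14)) df[[it]] <- sample(0:4, n, TRUE)
  as_bbs_records(df)
}

# ---- independent oracles ----------------------------------------------------

# Conditional log-likelihood of a two-dichotomous-item dataset at location
# split d (delta = c(-d/2, +d/2)), by direct enumeration.
oracle_cll_2dich <- function(x, d) {
  # P(x1, x2 | r = 1) = exp(-b1 x1 - b2 x2)/(exp(-b1) + exp(-b2)), b_i = delta_i
  b <- c(-d / 2, d / 2)
  keep <- rowSums(x) == 1
  sum(-b[1] * x[keep, 1] - b[2] * x[keep, 2]) -
    sum(keep) * log(exp(-b[1]) + exp(-b[2]))
}

# Likelihood of one response pattern over a theta grid (for the person ML
# oracle); returns grid argmax.
oracle_person_grid <- function(pattern, delta, tau, grid) {
  ll <- vapply(grid, function(th) {
    sum(vapply(seq_along(delta), function(i) {
      p <- pcm_category_probs(th, delta[i], tau[[i]])
      log(p[pattern[i] + 1])
    }, 0))
  }, 0)
  grid[which.max(ll)]
}

# Brute-force Mokken pair coefficients: covariance and its maximum given the
# marginals (comonotone arrangement), population (n) divisor.
oracle_hij <- function(x, y) {
  n <- length(x)
  cv <- mean(x * y) - mean(x) * mean(y)
  cm <- mean(sort(x) * sort(y)) - mean(x) * mean(y)
  cv / cm
}

# Bivariate normal rectangle probability by 2D numerical integration
# (independent of the package's quadrature path).
oracle_pbvnorm <- function(h, k, rho) {
  f <- function(x) stats::pnorm((k - rho * x) / sqrt(1 - rho^2)) * stats::dnorm(x)
  stats::integrate(f, -Inf, h, rel.tol = 1e-10)$value
}
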