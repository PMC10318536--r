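# Synthetic assessment data with the statistical structure the analysis
# assumes: a right-skewed (mistargeted) person ability distribution, two item
# clusters with within-cluster local dependence, optional uniform DIF, one to
# three observations per patient with within-person correlation, and disease
# covariates monotonically linked to ability.

DEFAULT_TESTLETS <- c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 2L, 2L, 2L)

default_item_locations <- function() {
  d <- seq(-1.9, 1.9, length.out = N_ITEMS)
  d - mean(d)
}

default_item_thresholds <- function() {
  base <- c(-1.5, -0.5, 0.5, 1.5)
  lapply(seq_len(N_ITEMS), function(i) {
    tau <- base * (0.85 + 0.3 * (i - 1) / (N_ITEMS - 1))
    tau - mean(tau)
  })
}

# Skew-normal (xi, omega, alpha) matching a target mean, SD and skewness g1.
sn_from_moments <- function(mean, sd, skew) {
  if (abs(skew) >= 0.995)
    stopf("skew-normal cannot reach |skewness| >= 0.995 (got %.3f)", skew)
  if (sd <= 0) stopf("ability sd must be positive")
  if (abs(skew) < 1e-12) {
    muz <- 0
  } else {
    g <- function(muz) (4 - pi) / 2 * muz^3 / (1 - muz^2)^1.5 - abs(skew)
    muz <- stats::uniroot(g, c(1e-9, sqrt(2 / pi) - 1e-9))$root
  }
  muz <- muz * sign(skew)
  d <- muz / sqrt(2 / pi)
  alpha <- if (abs(d) >= 1) sign(d) * 1e6 else d / sqrt(1 - d^2)
  omega <- sd / sqrt(1 - muz^2)
  list(xi = mean - omega * muz, omega = omega, alpha = alpha)
}

rskewnorm <- function(n, xi, omega, alpha) {
  d <- alpha / sqrt(1 + alpha^2)
  z0 <- stats::rnorm(n); z1 <- stats::rnorm(n)
  xi + omega * (d * abs(z0) + sqrt(1 - d^2) * z1)
}

#' Simulation configuration
#'
#' The defaults state the emulated world: 814 patients with 1-3 observations
#' each in the proportions of the study cohort, ability skew-normal with mean
#' +0.75 logits above the item mean, SD 1.3 and skewness 0.22 (a mistargeted
#' sample), sum-zero item locations spanning about 3.8 logits with centred
#' ordered thresholds, the two-cluster testlet structure, no DIF, and
#' covariate links calibrated for Spearman correlations of about -0.57 (EDSS)
#' and +0.52 (ABC) with ability.
#'
#' @param n_patients number of patients.
#' @param obs_per_patient_probs probabilities of 1, 2 and 3 observations.
#' @param ability list with `mean`, `sd`, `skew` (Fisher g1) of the ability law.
#' @param item_locations sum-zero vector of item locations delta (logits).
#' @param item_thresholds list of centred threshold vectors tau per item.
#' @param testlet_assignment item -> cluster integer map.
#' @param testlet_sd SD (logits) of the cluster-specific person random effect.
#' @param dif optional uniform DIF: `list(item=, factor=, level=, shift=)`;
#'   the item becomes `shift` logits harder for persons at `level`.
#' @param obs_sd SD (logits) of the observation-level ability perturbation.
#' @param covariate_link per-covariate link parameters; see Details.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#'
#' @details `covariate_link` has components `edss = list(rho, discretize)`,
#' `abc = list(rho, discretize)` and `falls = list(intercept, slope)`.  `rho`
#' is the latent Gaussian correlation with standardized ability (negative for
#' EDSS); with `discretize = FALSE` and `|rho| = 1` the link is an exact
#' monotone transform.  Falls are Poisson with log-rate
#' `intercept + slope * scale(theta)`.
#'
#' @return `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 814L,
                              obs_per_patient_probs = c(477, 268, 69) / 814,
                              ability = list(mean = 0.75, sd = 1.3, skew = 0.22),
                              item_locations = default_item_locations(),
                              item_thresholds = default_item_thresholds(),
                              testlet_assignment = DEFAULT_TESTLETS,
                              testlet_sd = 0,
                              dif = NULL,
                              obs_sd = 0.3,
                              covariate_link = list(
                                edss = list(rho = -0.60, discretize = TRUE),
                                abc = list(rho = 0.55, discretize = TRUE),
                                falls = list(intercept = 0.1, slope = -0.6)),
                              seed = NULL) {
  if (abs(sum(obs_per_patient_probs) - 1) > 1e-8)
    stopf("obs_per_patient_probs must sum to 1")
  if (abs(sum(item_locations)) > 1e-8)
    stopf("item_locations must sum to zero")
  if (any(vapply(item_thresholds, function(t) abs(sum(t)) > 1e-8, TRUE)))
    stopf("each item's thresholds must sum to zero")
  if (length(item_locations) != length(item_thresholds) ||
      length(item_locations) != length(testlet_assignment))
    stopf("item parameter lengths disagree")
  if (testlet_sd < 0) stopf("testlet_sd must be >= 0")
  if (obs_sd < 0) stopf("obs_sd must be >= 0")
  # validates the moment conversion early
  sn_from_moments(ability$mean, ability$sd, ability$skew)
  structure(list(n_patients = as.integer(n_patients),
                 obs_per_patient_probs = obs_per_patient_probs,
                 ability = ability, item_locations = item_locations,
                 item_thresholds = item_thresholds,
                 testlet_assignment = as.integer(testlet_assignment),
                 testlet_sd = testlet_sd, dif = dif, obs_sd = obs_sd,
                 covariate_link = covariate_link, seed = seed),
            class = "simulation_config")
}

config_params <- function(config)
  new_item_parameters(config$item_locations, config$item_thresholds)

#' Simulate the person table
#'
#' Ability is drawn from the configured skew-normal law; demographics from
#' marginals close to the multi-centre cohort (66% female, age ~ N(51.5,
#' 11.8^2) truncated at 18, disease course RR/SP/PP in proportions
#' 0.39/0.47/0.14, duration gamma with mean 12.5 and SD 9.1 years).
#'
#' @param config `simulation_config`.
#' @return data frame: `patient_id`, `theta`, `gender`, `age`, `course`,
#'   `duration`, `center`.
#' @export
simulate_persons <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  sn <- sn_from_moments(config$ability$mean, config$ability$sd, config$ability$skew)
  theta <- rskewnorm(n, sn$xi, sn$omega, sn$alpha)
  age <- pmax(18, stats::rnorm(n, 51.5, 11.8))
  shp <- (12.5 / 9.1)^2
  data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    theta = theta,
    gender = sample(c("female", "male"), n, TRUE, c(0.661, 0.339)),
    age = round(age, 1),
    course = sample(c("RR", "SP", "PP"), n, TRUE, c(0.391, 0.465, 0.144)),
    duration = round(stats::rgamma(n, shape = shp, scale = 12.5 / shp), 1),
    center = sample(c("MI", "BO", "GE"), n, TRUE, c(0.377, 0.374, 0.249)),
    stringsAsFactors = FALSE)
}

#' Simulate disease covariates from ability
#'
#' EDSS decreases monotonically with ability (Gaussian copula, discretized to
#' 0.5 steps), ABC increases, and the falls count is Poisson with a log-rate
#' decreasing in ability.
#'
#' @param persons person table carrying `theta`.
#' @param config `simulation_config`.
#' @return `persons` with `edss`, `abc`, `falls` columns appended.
#' @export
simulate_covariates <- function(persons, config) {
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  n <- nrow(persons)
  z <- as.numeric(scale(persons$theta))
  lat <- function(rho) rho * z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  lk <- config$covariate_link
  e <- 5.5 + 1.7 * lat(lk$edss$rho)
  persons$edss <- if (isTRUE(lk$edss$discretize)) clamp(round(e * 2) / 2, 0, 10) else clamp(e, 0, 10)
  a <- 54 + 25 * lat(lk$abc$rho)
  persons$abc <- if (isTRUE(lk$abc$discretize)) clamp(round(a), 0, 100) else clamp(a, 0, 100)
  persons$falls <- stats::rpois(n, exp(lk$falls$intercept + lk$falls$slope * z))
  persons
}

#' Simulate item responses
#'
#' Each item score is drawn from partial credit category probabilities at the
#' effective ability `theta_person + obs perturbation + cluster random effect
#' + DIF shift`.  The cluster (testlet) random effect is a person-level trait
#' shared by all items of a cluster; with `testlet_sd = 0` the data satisfy
#' local independence exactly.
#'
#' @param persons person table from [simulate_persons()] (optionally with
#'   covariates).
#' @param config `simulation_config`.
#' @return `bbs_records` with one row per observation.
#' @export
simulate_responses <- function(persons, config) {
  if (nrow(persons) == 0) stopf("persons is empty")
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  n <- nrow(persons)
  K <- length(config$item_locations)
  nobs <- sample(seq_along(config$obs_per_patient_probs), n, TRUE,
                 config$obs_per_patient_probs)
  clusters <- sort(unique(config$testlet_assignment))
  u <- matrix(stats::rnorm(n * length(clusters), 0, config$testlet_sd),
              n, length(clusters))
  dif <- config$dif
  rows <- vector("list", n)
  beta0 <- lapply(seq_len(K), function(i)
    beta_from_dt(config$item_locations[i], config$item_thresholds[[i]]))
  for (v in seq_len(n)) {
    dif_shift <- numeric(K)
    if (!is.null(dif) && persons[[dif$factor]][v] == dif$level)
      dif_shift[dif$item] <- dif$shift
    obs <- vector("list", nobs[v])
    for (o in seq_len(nobs[v])) {
      th_obs <- persons$theta[v] + stats::rnorm(1, 0, config$obs_sd)
      x <- integer(K)
      for (i in seq_len(K)) {
        th_eff <- th_obs + u[v, match(config$testlet_assignment[i], clusters)]
        m <- length(beta0[[i]])
        # uniform DIF adds to delta, hence k * shift to the cumulative beta
        uvec <- c(0, seq_len(m) * th_eff - (beta0[[i]] + seq_len(m) * dif_shift[i]))
        p <- exp(uvec - max(uvec)); p <- p / sum(p)
        x[i] <- sample(0:m, 1L, prob = p)
      }
      obs[[o]] <- x
    }
    rows[[v]] <- do.call(rbind, obs)
  }
  items <- do.call(rbind, rows)
  colnames(items) <- item_labels(K)
  idx <- rep(seq_len(n), nobs)
  df <- data.frame(
    patient_id = persons$patient_id[idx],
    center = persons$center[idx],
    obs_index = unlist(lapply(nobs, seq_len)),
    gender = persons$gender[idx],
    age = persons$age[idx],
    course = persons$course[idx],
    duration = persons$duration[idx],
    edss = if ("edss" %in% names(persons)) persons$edss[idx] else NA_real_,
    abc = if ("abc" %in% names(persons)) persons$abc[idx] else NA_real_,
    falls = if ("falls" %in% names(persons)) persons$falls[idx] else NA_integer_,
    stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(items))
  as_bbs_records(df)
}

#' Simulate a complete assessment dataset
#'
#' Persons, covariates and responses in one call, reproducible from
#' `config$seed`.
#'
#' @param config `simulation_config`.
#' @return `bbs_records`.
#' @export
simulate_dataset <- function(config) {
  persons <- simulate_persons(config)
  persons <- simulate_covariates(persons, config)
  simulate_responses(persons, config)
}
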