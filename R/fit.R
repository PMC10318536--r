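# Model-fit battery: standardized response residuals, Wilson-Hilferty fit
# residuals, item-trait chi-square over ability class intervals, threshold
# ordering, residual correlation structure with the relative local-dependence
# cut-off (LDRC), the principal-component unidimensionality t-test, and an
# Andersen-type conditional likelihood-ratio fit statistic.

default_class_intervals <- function(n) as.integer(clamp(floor(n / 50), 2, 10))

# Expected score, variance and 4th central moment per (person, item), using
# the sufficiency of the raw total: moments are computed once per distinct
# ability value.
cell_moments <- function(rm, params, persons) {
  beta <- params_beta(params)
  th <- persons$theta
  uth <- sort(unique(th))
  K <- length(beta)
  E <- V <- M4 <- matrix(NA_real_, nrow(rm), K)
  pos <- match(th, uth)
  for (i in seq_len(K)) {
    mom <- pcm_item_moments(uth, beta[[i]], central4 = TRUE)
    E[, i] <- mom$e[pos]; V[, i] <- mom$v[pos]; M4[, i] <- mom$m4[pos]
  }
  list(E = E, V = V, M4 = M4)
}

# Standardized residual matrix z = (x - E)/sqrt(V) for non-extreme persons.
standardized_residuals <- function(rm, params, persons) {
  rm <- conform_rm(rm, params)
  keep <- !persons$extreme
  mom <- cell_moments(rm_subset(rm, keep), params, persons[keep, ])
  z <- (unclass(rm)[keep, , drop = FALSE] - mom$E) / sqrt(mom$V)
  list(z = z, keep = keep, E = mom$E, V = mom$V, M4 = mom$M4)
}

# Wilson-Hilferty standardization of a sum of squared residuals U with exact
# first two moments (Satterthwaite effective df).
wh_fitres <- function(U, EU, VU) {
  if (!is.finite(VU) || VU <= 1e-10 || EU <= 0) return(0)
  d <- 2 * EU^2 / VU
  if (d < 2) return((U - EU) / sqrt(VU))   # cube root unstable at tiny df
  ((U / EU)^(1/3) - (1 - 2 / (9 * d))) / sqrt(2 / (9 * d))
}

# Exact conditional-on-total moments of the squared standardized residuals.
# Residuals are standardized with the unconditional item moments at
# theta(r), but for complete data the total score is fixed, so E[z^2 | r]
# is well below 1 (severely so for few items); calibrated fit residuals
# therefore standardize U = sum z^2 by its conditional moments, computed
# exactly from the ESF conditional category probabilities.
# Returns, for each total in `rs`: Ez2, Vz2 (K x length(rs)) and the
# conditional variance of the per-person sum U_v (length(rs)).
cond_z2_moments <- function(params, rs, theta_r) {
  beta <- params_beta(params)
  K <- length(beta)
  eps <- lapply(beta, function(b) c(1, exp(-b)))
  gam <- esf(eps)
  R <- length(rs)
  # unconditional moments at theta(r) and squared-residual values per category
  z2 <- vector("list", K)          # [[i]]: (m_i+1) x R matrix of z^2 values
  for (i in seq_len(K)) {
    mom <- pcm_item_moments(theta_r, beta[[i]])
    k <- 0:params$item_max[i]
    z2[[i]] <- (outer(k, mom$e, "-"))^2 / rep(mom$v, each = length(k))
  }
  # conditional category probabilities per item and total
  cond_p <- vector("list", K)
  for (i in seq_len(K)) {
    gi <- esf_excluding(eps, i)
    P <- matrix(0, params$item_max[i] + 1L, R)
    for (ki in 0:params$item_max[i]) {
      idx <- rs - ki
      ok <- idx >= 0 & idx <= (length(gi) - 1L)
      P[ki + 1L, ok] <- eps[[i]][ki + 1L] * gi[idx[ok] + 1L] / gam[rs[ok] + 1L]
    }
    cond_p[[i]] <- P
  }
  Ez2 <- t(vapply(seq_len(K), function(i) colSums(cond_p[[i]] * z2[[i]]), numeric(R)))
  Ez4 <- t(vapply(seq_len(K), function(i) colSums(cond_p[[i]] * z2[[i]]^2), numeric(R)))
  Vz2 <- pmax(Ez4 - Ez2^2, 0)
  # person-level variance of U = sum_i z_i^2 needs the pairwise conditional
  # covariances (items are dependent given the total)
  VU <- colSums(Vz2)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    gij <- esf_excluding(eps, c(i, j))
    Eij <- numeric(R)
    for (ki in 0:params$item_max[i]) for (kj in 0:params$item_max[j]) {
      idx <- rs - ki - kj
      ok <- idx >= 0 & idx <= (length(gij) - 1L)
      if (any(ok)) {
        pj <- numeric(R)
        pj[ok] <- eps[[i]][ki + 1L] * eps[[j]][kj + 1L] *
          gij[idx[ok] + 1L] / gam[rs[ok] + 1L]
        Eij <- Eij + pj * z2[[i]][ki + 1L, ] * z2[[j]][kj + 1L, ]
      }
    }
    VU <- VU + 2 * (Eij - Ez2[i, ] * Ez2[j, ])
  }
  list(Ez2 = Ez2, Vz2 = Vz2, VU = pmax(VU, 0))
}

#' Fit statistics for a partial credit calibration
#'
#' Computes standardized response residuals, item and person fit residuals
#' (Wilson-Hilferty-standardized residual sums of squares), the item-trait
#' interaction chi-square over ability class intervals with its Bonferroni
#' cut-off, threshold-ordering flags, and observed-vs-expected class-interval
#' means for item characteristic curves.
#'
#' @param rm `response_matrix`.
#' @param params `item_parameters`.
#' @param persons optional person estimates (computed if missing).
#' @param n_class_intervals number of ability class intervals; default
#'   `clamp(floor(n/50), 2, 10)` over non-extreme persons.
#' @param fitres_flag flag threshold for individual item fit residuals
#'   (default 2.5).
#' @return `fit_report` list; see the elements of the returned object.
#' @export
fit_statistics <- function(rm, params, persons = NULL, n_class_intervals = NULL,
                           fitres_flag = 2.5) {
  rm <- conform_rm(rm, params)
  persons <- persons %||% estimate_person_measures(rm, params)
  sr <- standardized_residuals(rm, params, persons)
  z <- sr$z
  K <- ncol(z); N <- nrow(z)
  n_ci <- n_class_intervals %||% default_class_intervals(N)

  # standardize the squared-residual sums by their exact conditional-on-total
  # moments (the total is fixed given complete data)
  totals <- total_scores(rm)[sr$keep]
  rs <- sort(unique(totals))
  st <- score_table(params)
  cm <- cond_z2_moments(params, rs, st$theta[rs + 1L])
  pos <- match(totals, rs)
  item_fitres <- vapply(seq_len(K), function(i)
    wh_fitres(sum(z[, i]^2), sum(cm$Ez2[i, pos]), sum(cm$Vz2[i, pos])), 0)
  person_fitres <- vapply(seq_len(N), function(v)
    wh_fitres(sum(z[v, ]^2), sum(cm$Ez2[, pos[v]]), cm$VU[pos[v]]), 0)

  # class intervals by ability over non-extreme persons (quantile cuts,
  # merged when ties make intervals empty or near-empty)
  th <- persons$theta[sr$keep]
  ci <- cut_class_intervals(th, n_ci)
  n_ci_eff <- nlevels(ci)

  x <- unclass(rm)[sr$keep, , drop = FALSE]
  item_chi2 <- numeric(K); icc <- vector("list", K)
  for (i in seq_len(K)) {
    O <- tapply(x[, i], ci, sum)
    E <- tapply(sr$E[, i], ci, sum)
    V <- tapply(sr$V[, i], ci, sum)
    item_chi2[i] <- sum((O - E)^2 / V)
    icc[[i]] <- data.frame(interval = levels(ci), n = as.integer(table(ci)),
                           mean_theta = as.numeric(tapply(th, ci, mean)),
                           observed = as.numeric(O / table(ci)),
                           expected = as.numeric(E / table(ci)))
  }
  item_df <- rep(n_ci_eff - 1L, K)
  item_p <- stats::pchisq(item_chi2, item_df, lower.tail = FALSE)
  total_chi2 <- sum(item_chi2); total_df <- sum(item_df)

  disordered <- vapply(seq_len(K), function(i) any(diff(params$tau[[i]]) <= 0) &&
                         params$item_max[i] > 1, TRUE)

  structure(list(
    item_fit_residuals = stats::setNames(item_fitres, params$labels),
    person_fit_residuals = person_fitres,
    item_fit_mean = mean(item_fitres), item_fit_sd = stats::sd(item_fitres),
    person_fit_mean = mean(person_fitres), person_fit_sd = stats::sd(person_fitres),
    item_chi2 = stats::setNames(item_chi2, params$labels),
    item_df = item_df, item_p = item_p,
    total_chi2 = total_chi2, total_df = total_df,
    total_p = stats::pchisq(total_chi2, total_df, lower.tail = FALSE),
    bonferroni_cutoff = 0.05 / K,
    n_class_intervals = n_ci_eff, n_persons = N,
    flagged_items = params$labels[abs(item_fitres) > fitres_flag],
    disordered_threshold_items = params$labels[disordered],
    disordered_pct = 100 * mean(disordered),
    icc_data = stats::setNames(icc, params$labels)),
    class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report: %d persons, %d class intervals\n", x$n_persons,
              x$n_class_intervals))
  cat(sprintf("  item FitRes mean %.3f SD %.3f | person FitRes mean %.3f SD %.3f\n",
              x$item_fit_mean, x$item_fit_sd, x$person_fit_mean, x$person_fit_sd))
  cat(sprintf("  total chi2 = %.1f, df = %d, p = %.4f (Bonferroni cut-off %.4f)\n",
              x$total_chi2, x$total_df, x$total_p, x$bonferroni_cutoff))
  cat(sprintf("  disordered thresholds: %s (%.1f%%)\n",
              paste(x$disordered_threshold_items, collapse = ","), x$disordered_pct))
  invisible(x)
}

# Quantile-based class intervals; merges intervals with < 2 members.
cut_class_intervals <- function(theta, n) {
  br <- unique(stats::quantile(theta, probs = seq(0, 1, length.out = n + 1)))
  if (length(br) < 3) br <- c(min(theta) - 1e-9, stats::median(theta), max(theta))
  ci <- cut(theta, br, include.lowest = TRUE)
  tab <- table(ci)
  while (any(tab < 2) && nlevels(ci) > 2) {
    warnf("class interval with < 2 persons; intervals merged")
    j <- which(tab < 2)[1]
    br <- br[-(j + if (j == length(tab)) 0 else 1)]
    ci <- cut(theta, br, include.lowest = TRUE)
    tab <- table(ci)
  }
  droplevels(ci)
}

#' Residual correlation structure and unidimensionality t-test
#'
#' Pearson correlations of standardized item residuals, the relative local
#' dependence cut-off (mean off-diagonal residual correlation + 0.2), the
#' first principal component of the residual correlation matrix, and the
#' per-person t-test comparing ability estimated from the positively
#' (loading > 0.3) versus negatively (< -0.3) loading item subsets, with the
#' proportion of significant tests (PST) and the lower bound of its 95%
#' binomial confidence interval.  When the strict loading cut-offs leave
#' fewer than two items on a side, the split falls back to the loading sign
#' (`strict = FALSE` in the result).
#'
#' @param rm `response_matrix`.
#' @param params `item_parameters`.
#' @param persons optional person estimates.
#' @param ld_offset offset added to the mean off-diagonal residual
#'   correlation to form the relative cut-off (default 0.2).
#' @return `residual_structure` list.
#' @export
residual_structure <- function(rm, params, persons = NULL, ld_offset = 0.2) {
  rm <- conform_rm(rm, params)
  persons <- persons %||% estimate_person_measures(rm, params)
  sr <- standardized_residuals(rm, params, persons)
  rc <- stats::cor(sr$z)
  off <- rc[lower.tri(rc)]
  ldrc <- mean(off) + ld_offset
  ev <- eigen(rc, symmetric = TRUE)
  pc1 <- ev$vectors[, 1] * sqrt(max(ev$values[1], 0))
  names(pc1) <- params$labels
  pos <- which(pc1 > 0.3); neg <- which(pc1 < -0.3)
  strict <- TRUE
  if (!length(pos) || !length(neg)) {
    strict <- FALSE
    pos <- which(pc1 > 0); neg <- which(pc1 <= 0)
  }
  pst <- bci <- NA_real_; tvals <- NULL
  # singleton subsets are admissible for polytomous super-items (testlets)
  computable <- length(pos) >= 1 && length(neg) >= 1
  if (computable) {
    mp <- person_measures_subset(rm, params, pos)
    mn <- person_measures_subset(rm, params, neg)
    tvals <- (mp$theta - mn$theta) / sqrt(mp$se^2 + mn$se^2)
    sig <- abs(tvals) > 1.96
    pst <- 100 * mean(sig)
    phat <- mean(sig)
    bci <- 100 * max(0, phat - 1.96 * sqrt(phat * (1 - phat) / length(sig)))
  }
  pairs <- which(rc > ldrc & upper.tri(rc), arr.ind = TRUE)
  structure(list(residual_corr = rc, ldrc = ldrc, pc1_loadings = pc1,
                 pos_items = pos, neg_items = neg, strict_split = strict,
                 t_values = tvals, pst = pst, bci_lower = bci,
                 ld_pairs = if (nrow(pairs)) data.frame(
                   item1 = params$labels[pairs[, 1]],
                   item2 = params$labels[pairs[, 2]],
                   r = rc[pairs]) else NULL),
            class = "residual_structure")
}

#' @export
print.residual_structure <- function(x, ...) {
  cat(sprintf("residual_structure: LDRC = %.3f, %d pair(s) above cut-off\n",
              x$ldrc, if (is.null(x$ld_pairs)) 0L else nrow(x$ld_pairs)))
  cat(sprintf("  PST = %.1f%%, lower BCI = %.1f%% (%s split)\n", x$pst,
              x$bci_lower, if (x$strict_split) "strict" else "sign"))
  invisible(x)
}

# Sample responses conditional on each person's total score from the fitted
# conditional distribution (sequential item-by-item sampling with suffix
# ESFs).  The person parameters drop out entirely, so the draw is exact.
rcond_responses <- function(params, totals) {
  beta <- params_beta(params)
  K <- length(beta)
  eps <- lapply(beta, function(b) c(1, exp(-b)))
  # suffix ESFs: gam_suf[[i]] = ESF of items i..K
  gam_suf <- vector("list", K + 1L)
  gam_suf[[K + 1L]] <- 1
  for (i in K:1) gam_suf[[i]] <- poly_conv(gam_suf[[i + 1L]], eps[[i]])
  n <- length(totals)
  out <- matrix(0L, n, K)
  for (v in seq_len(n)) {
    t <- totals[v]
    for (i in seq_len(K - 1L)) {
      ks <- 0:min(params$item_max[i], t)
      gs <- gam_suf[[i + 1L]]
      idx <- t - ks
      pr <- eps[[i]][ks + 1L] *
        ifelse(idx <= length(gs) - 1L, gs[pmin(idx, length(gs) - 1L) + 1L], 0)
      x <- sample(ks, 1L, prob = pr)
      out[v, i] <- x
      t <- t - x
    }
    out[v, K] <- t
  }
  out
}

#' Conditional (Andersen-type) total fit statistic
#'
#' Splits the sample into raw-score class intervals, refits the conditional
#' likelihood within each, and compares the sum of the group maxima against
#' the pooled fit with a likelihood-ratio statistic.  For polytomous
#' super-items many category parameters sit near the boundary within a score
#' group, so the chi-square reference is unreliable; the p-value is therefore
#' computed by exact conditional Monte Carlo (responses resampled given each
#' person's total under the pooled calibration) when `n_boot > 0` (the
#' default), with the asymptotic chi-square p reported alongside.
#'
#' @param rm `response_matrix` (typically the testlet super-items).
#' @param params ignored (the pooled calibration is re-estimated internally;
#'   retained for interface stability).
#' @param n_groups number of raw-score groups (default 2, median split).
#' @param groups optional explicit group factor (overrides score grouping).
#' @param min_count pooled categories rarer than this are merged first.
#' @param n_boot conditional Monte Carlo replicates (0 = asymptotic only).
#' @return list with `statistic`, `df`, `p` (Monte Carlo when `n_boot > 0`),
#'   `p_asymptotic`, `group_sizes`, `n_boot`.
#' @export
conditional_total_chi2 <- function(rm, params = NULL, n_groups = 2L,
                                   groups = NULL, min_count = 5L,
                                   n_boot = 199L) {
  r <- total_scores(rm)
  Rmax <- sum(item_max_of(rm))
  keep <- r > 0 & r < Rmax                     # extremes carry no information
  rk <- r[keep]
  if (is.null(groups)) {
    qs <- unique(stats::quantile(rk, probs = seq(0, 1, length.out = n_groups + 1)))
    grp <- cut(rk, qs, include.lowest = TRUE)
    # merge groups too small to calibrate
    while (nlevels(grp) > 1 && any(table(grp) < 30)) {
      qs <- qs[-(which.min(table(grp)) + 1)]
      grp <- cut(rk, unique(qs), include.lowest = TRUE)
    }
  } else {
    grp <- droplevels(factor(groups[keep]))
  }
  # merge pooled sparse categories once; the LR is then computed on a fixed
  # category space for both the observed data and the Monte Carlo draws
  cl <- collapse_sparse_categories(unclass(rm)[keep, , drop = FALSE],
                                   item_max_of(rm), min_count)
  lr_stat <- function(values) {
    rmk <- response_matrix(values, cl$item_max)
    pool <- estimate_item_parameters(rmk)
    ll_pool <- cml_loglik(rmk, pool)
    ll_g <- 0; df_g <- 0L
    for (g in levels(grp)) {
      sub <- values[grp == g, , drop = FALSE]
      scl <- collapse_null_categories(sub, cl$item_max)
      sub <- response_matrix(scl$values, scl$item_max)
      ll_g <- ll_g + cml_loglik(sub, estimate_item_parameters(sub))
      df_g <- df_g + sum(item_max_of(sub)) - 1L
    }
    list(stat = max(0, 2 * (ll_g - ll_pool)),
         df = df_g - (sum(cl$item_max) - 1L))
  }
  obs <- suppressWarnings(lr_stat(cl$values))
  p_asym <- if (obs$df > 0) stats::pchisq(obs$stat, obs$df, lower.tail = FALSE) else NA_real_
  p <- p_asym
  if (n_boot > 0) {
    pool <- suppressWarnings(estimate_item_parameters(
      response_matrix(cl$values, cl$item_max)))
    totals <- rowSums(cl$values)
    exceed <- 0L
    for (b in seq_len(n_boot)) {
      vb <- rcond_responses(pool, totals)
      sb <- tryCatch(suppressWarnings(lr_stat(vb)$stat), error = function(e) NA)
      if (!is.na(sb) && sb >= obs$stat) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_boot + 1)
  }
  list(statistic = obs$stat, df = obs$df, p = p, p_asymptotic = p_asym,
       group_sizes = as.integer(table(grp)), n_boot = n_boot)
}

# Conditional log-likelihood of a response matrix at given parameters.
cml_loglik <- function(rm, params) {
  rm <- conform_rm(rm, params)
  beta <- params_beta(params)
  eps <- lapply(beta, function(b) c(1, exp(-b)))
  gam <- esf(eps)
  values <- unclass(rm)
  r <- rowSums(values)
  ll <- -sum(vapply(seq_along(beta), function(i) {
    k <- values[, i]
    sum(beta[[i]][k[k > 0]])
  }, 0))
  ll - sum(log(gam[r + 1L]))
}
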