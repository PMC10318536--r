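# Partial credit model engine.
#
# Item parameters are estimated by conditional maximum likelihood (CML): the
# total score is sufficient for person ability, so conditioning on it removes
# the person parameters exactly.  The conditional likelihood is evaluated
# through elementary symmetric functions (ESFs) of the category terms
# eps_{ik} = exp(-beta_{ik}), beta_{ik} = k*delta_i + sum_{j<=k} tau_{ij},
# and maximized by Newton iterations with an analytic gradient and Hessian
# (exponential-family identities: the Hessian is minus the sum of conditional
# covariances).  Person measures are maximum likelihood given the items, with
# the usual 0.3 raw-score adjustment for extreme scores.

# ---- category probabilities -------------------------------------------------

#' Partial credit category probabilities
#'
#' P(X = x | theta) is proportional to exp(sum_{k<=x} (theta - delta - tau_k)),
#' with the empty sum for x = 0 equal to zero.
#'
#' @param theta person ability (logits); may be a vector.
#' @param delta item location (logits).
#' @param tau centred threshold vector (length = maximum category).
#' @return for scalar `theta` a probability vector over categories `0..m`;
#'   for vector `theta` a matrix with one row per ability.
#' @export
pcm_category_probs <- function(theta, delta, tau) {
  beta <- cumsum(delta + tau)            # beta_k, k = 1..m
  k <- seq_along(beta)
  u <- outer(theta, k) - rep(beta, each = length(theta))  # k*theta - beta_k
  u <- cbind(0, u)
  u <- u - apply(u, 1, max)
  p <- exp(u)
  p <- p / rowSums(p)
  colnames(p) <- as.character(0:length(beta))
  if (length(theta) == 1L) drop(p) else p
}

# Cumulative category parameters from (delta, tau); beta_0 = 0 implicit.
beta_from_dt <- function(delta, tau) cumsum(delta + tau)

# Moments of one item at one or more abilities; beta excludes beta_0.
# Returns list of matrices (rows = abilities): p (m+1 cols), e, v, m3, m4
pcm_item_moments <- function(theta, beta, central3 = FALSE, central4 = FALSE) {
  m <- length(beta)
  k <- 0:m
  u <- cbind(0, outer(theta, seq_len(m)) - rep(beta, each = length(theta)))
  u <- u - apply(u, 1, max)
  p <- exp(u); p <- p / rowSums(p)
  e <- drop(p %*% k)
  v <- drop(p %*% k^2) - e^2
  out <- list(p = p, e = e, v = v)
  dev <- function(pow)
    rowSums(p * sweep(matrix(k, nrow = length(theta), ncol = m + 1,
                             byrow = TRUE), 1, e)^pow)
  if (central3) out$m3 <- dev(3)
  if (central4) out$m4 <- dev(4)
  out
}

# ---- elementary symmetric functions ----------------------------------------

poly_conv <- function(g, e) {
  out <- numeric(length(g) + length(e) - 1L)
  for (k in seq_along(e)) {
    idx <- k:(k + length(g) - 1L)
    out[idx] <- out[idx] + e[k] * g
  }
  out
}

# eps_list: per item, vector of length m_i + 1 with leading 1 (category 0).
esf <- function(eps_list) Reduce(poly_conv, eps_list, accumulate = FALSE)

esf_excluding <- function(eps_list, drop) {
  keep <- setdiff(seq_along(eps_list), drop)
  if (!length(keep)) return(1)
  Reduce(poly_conv, eps_list[keep])
}

# ---- item parameter container ----------------------------------------------

new_item_parameters <- function(delta, tau, labels = NULL, score_map = NULL,
                                convergence = NULL) {
  K <- length(delta)
  stopifnot(length(tau) == K)
  labels <- labels %||% item_labels(K)
  structure(list(delta = stats::setNames(delta, labels),
                 tau = stats::setNames(tau, labels),
                 item_max = vapply(tau, length, 1L),
                 labels = labels, score_map = score_map,
                 convergence = convergence),
            class = "item_parameters")
}

#' @export
print.item_parameters <- function(x, ...) {
  cat(sprintf("item_parameters: %d items, sum(delta) = %.2e\n",
              length(x$delta), sum(x$delta)))
  for (i in seq_along(x$delta))
    cat(sprintf("  %s  delta = %7.3f  tau = %s\n", x$labels[i], x$delta[i],
                paste(sprintf("%.3f", x$tau[[i]]), collapse = ", ")))
  invisible(x)
}

params_beta <- function(params)
  lapply(seq_along(params$delta),
         function(i) beta_from_dt(params$delta[i], params$tau[[i]]))

# Collapse null response categories so each category 0..m is observed.
# Returns list(values, item_max, score_map) where score_map[[i]] gives the
# original category value for each collapsed category (NULL if untouched).
collapse_null_categories <- function(values, item_max) {
  score_map <- vector("list", ncol(values))
  changed <- FALSE
  for (i in seq_len(ncol(values))) {
    obs <- sort(unique(values[, i]))
    full <- 0:item_max[i]
    if (length(obs) < 2L)
      stopf("item %d has a single observed category; cannot be calibrated", i)
    if (!identical(as.integer(obs), full)) {
      warnf("item %d: null categories {%s} collapsed",
            i, paste(setdiff(full, obs), collapse = ","))
      values[, i] <- match(values[, i], obs) - 1L
      item_max[i] <- length(obs) - 1L
      score_map[[i]] <- obs
      changed <- TRUE
    }
  }
  list(values = values, item_max = item_max,
       score_map = if (changed) score_map else NULL)
}

# Merge categories observed fewer than min_count times with a neighbour
# (downward, upward for category 0).  Used by diagnostics whose chi-square
# asymptotics suffer from near-boundary category parameters.
collapse_sparse_categories <- function(values, item_max, min_count) {
  for (i in seq_len(ncol(values))) {
    repeat {
      cnt <- tabulate(values[, i] + 1L, nbins = item_max[i] + 1L)
      k <- which(cnt < min_count)
      if (!length(k) || item_max[i] < 2L) break
      k <- k[1] - 1L                       # category value to merge
      x <- values[, i]
      if (k == 0L) x[x >= 1L] <- x[x >= 1L] - 1L
      else x[x >= k] <- x[x >= k] - 1L
      values[, i] <- x
      item_max[i] <- item_max[i] - 1L
    }
  }
  list(values = values, item_max = item_max)
}

# Bring a response matrix into the (possibly collapsed) category space of
# previously estimated parameters.
conform_rm <- function(rm, params) {
  if (isTRUE(attr(rm, "conformed"))) {            # idempotent
    if (!identical(as.integer(item_max_of(rm)), as.integer(params$item_max)))
      stopf("response matrix does not match the item parameterization")
    return(rm)
  }
  values <- unclass(rm)
  imax <- item_max_of(rm)
  if (!is.null(params$score_map)) {
    for (i in seq_len(ncol(values))) {
      mp <- params$score_map[[i]]
      if (!is.null(mp)) {
        if (!all(values[, i] %in% mp)) {
          # categories never observed during calibration carry no calibrated
          # parameters; map them to the nearest calibrated category
          warnf("item %d: uncalibrated categories mapped to nearest calibrated score", i)
          values[, i] <- vapply(values[, i],
                                function(v) mp[which.min(abs(mp - v))], 0L)
        }
        values[, i] <- match(values[, i], mp) - 1L
        imax[i] <- length(mp) - 1L
      }
    }
  }
  if (!identical(as.integer(imax), as.integer(params$item_max)))
    stopf("response matrix does not match the item parameterization")
  out <- response_matrix(values, imax, meta_of(rm))
  attr(out, "conformed") <- TRUE
  out
}

# ---- conditional maximum likelihood ----------------------------------------

#' Estimate partial credit item parameters by conditional ML
#'
#' Conditional maximum likelihood over the total score, evaluated with
#' elementary symmetric functions and maximized by Newton iterations
#' (analytic gradient and Hessian) until the gradient norm drops below
#' `tol`.  The sum of item locations is constrained to zero and thresholds
#' are centred within item.  Extreme-scoring persons carry no conditional
#' information and drop out automatically.  Unobserved ("null") categories
#' are collapsed with a warning and recorded in `score_map` so raw totals
#' remain interpretable.
#'
#' @param rm `response_matrix`.
#' @param anchor optional `item_parameters` supplying fixed values for the
#'   items in `fixed_items`.
#' @param fixed_items integer indices of items held at their `anchor` values
#'   (default: all items free).
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return `item_parameters` (sum-zero `delta`, per-item centred `tau`).
#' @export
estimate_item_parameters <- function(rm, anchor = NULL, fixed_items = integer(0),
                                     tol = 1e-6, max_iter = 200L) {
  values <- unclass(rm)
  imax <- item_max_of(rm)
  if (length(fixed_items)) {
    if (is.null(anchor)) stopf("fixed_items requires an anchor")
    # anchored calibrations keep the anchor's category space
    cl <- list(values = values, item_max = imax, score_map = anchor$score_map)
    if (!is.null(anchor$score_map)) {
      rm2 <- conform_rm(rm, anchor)
      cl$values <- unclass(rm2); cl$item_max <- item_max_of(rm2)
    }
  } else {
    cl <- collapse_null_categories(values, imax)
  }
  values <- cl$values; imax <- cl$item_max
  K <- ncol(values)
  free <- setdiff(seq_len(K), fixed_items)
  if (!length(free)) stopf("no free items to estimate")

  r <- as.integer(rowSums(values))
  Rmax <- sum(imax)
  Nr <- tabulate(r + 1L, nbins = Rmax + 1L)          # counts by total 0..Rmax
  # category counts n_{ik}, k = 1..m_i
  nik <- lapply(seq_len(K), function(i)
    vapply(seq_len(imax[i]), function(k) sum(values[, i] == k), 0))

  # initial values: anchored items from anchor, free items from PROX-like zeros
  beta <- vector("list", K)
  for (i in seq_len(K)) beta[[i]] <- numeric(imax[i])
  if (!is.null(anchor)) {
    ab <- params_beta(anchor)
    for (i in fixed_items) beta[[i]] <- ab[[i]]
  }

  free_idx <- unlist(lapply(free, function(i) cbind(i, seq_len(imax[i]))[, 1]))
  free_cat <- unlist(lapply(free, function(i) seq_len(imax[i])))
  npar <- length(free_cat)
  anchored <- length(fixed_items) > 0L

  pack <- function(beta) unlist(lapply(free, function(i) beta[[i]]))
  unpack <- function(p, beta) {
    pos <- 0L
    for (i in free) {
      beta[[i]] <- p[pos + seq_len(imax[i])]
      pos <- pos + imax[i]
    }
    beta
  }

  loglik <- function(beta) {
    eps <- lapply(beta, function(b) c(1, exp(-b)))
    gam <- esf(eps)
    obs <- sum(vapply(free, function(i) -sum(nik[[i]] * beta[[i]]), 0)) +
      if (anchored) sum(vapply(fixed_items, function(i) -sum(nik[[i]] * beta[[i]]), 0)) else 0
    obs - sum(Nr[Nr > 0] * log(gam[which(Nr > 0)]))
  }

  grad_hess <- function(beta) {
    eps <- lapply(beta, function(b) c(1, exp(-b)))
    gam <- esf(eps)
    rs <- which(Nr > 0) - 1L                   # totals present in the data
    w <- Nr[rs + 1L]
    # conditional P(X_i = k | r) for every item, category, total
    gam_i <- lapply(seq_len(K), function(i) esf_excluding(eps, i))
    pmat <- vector("list", K)                  # [[i]]: (m_i+1) x length(rs)
    for (i in seq_len(K)) {
      gi <- gam_i[[i]]
      P <- matrix(0, imax[i] + 1L, length(rs))
      for (ki in 0:imax[i]) {
        idx <- rs - ki
        ok <- idx >= 0 & idx <= (length(gi) - 1L)
        P[ki + 1L, ok] <- eps[[i]][ki + 1L] * gi[idx[ok] + 1L] / gam[rs[ok] + 1L]
      }
      pmat[[i]] <- P
    }
    g <- numeric(npar)
    pos <- 0L
    for (i in free) {
      Ecount <- pmat[[i]][-1L, , drop = FALSE] %*% w   # expected category counts
      g[pos + seq_len(imax[i])] <- -nik[[i]] + drop(Ecount)
      pos <- pos + imax[i]
    }
    # Hessian = -sum_r w_r Cov_r(indicators)
    H <- matrix(0, npar, npar)
    off <- integer(K); pos <- 0L
    for (i in free) { off[i] <- pos; pos <- pos + imax[i] }
    for (a in seq_along(free)) {
      i <- free[a]
      Pi <- pmat[[i]][-1L, , drop = FALSE]
      # same-item block
      blk <- matrix(0, imax[i], imax[i])
      for (k in seq_len(imax[i])) for (l in seq_len(imax[i])) {
        same <- if (k == l) Pi[k, ] else 0
        blk[k, l] <- -sum(w * (same - Pi[k, ] * Pi[l, ]))
      }
      H[off[i] + seq_len(imax[i]), off[i] + seq_len(imax[i])] <- blk
      if (a < length(free)) for (b in (a + 1L):length(free)) {
        j <- free[b]
        gij <- esf_excluding(eps, c(i, j))
        Pj <- pmat[[j]][-1L, , drop = FALSE]
        blk <- matrix(0, imax[i], imax[j])
        for (k in seq_len(imax[i])) for (l in seq_len(imax[j])) {
          idx <- rs - k - l
          ok <- idx >= 0 & idx <= (length(gij) - 1L)
          pj <- numeric(length(rs))
          pj[ok] <- eps[[i]][k + 1L] * eps[[j]][l + 1L] *
            gij[idx[ok] + 1L] / gam[rs[ok] + 1L]
          blk[k, l] <- -sum(w * (pj - Pi[k, ] * Pj[l, ]))
        }
        H[off[i] + seq_len(imax[i]), off[j] + seq_len(imax[j])] <- blk
        H[off[j] + seq_len(imax[j]), off[i] + seq_len(imax[i])] <- t(blk)
      }
    }
    list(g = g, H = H)
  }

  vdir <- free_cat                       # score-shift invariance direction
  ll <- loglik(beta)
  iter <- 0L; gnorm <- Inf
  repeat {
    iter <- iter + 1L
    gh <- grad_hess(beta)
    gnorm <- max(abs(gh$g))
    if (gnorm < tol || iter > max_iter) break
    Hreg <- gh$H
    if (!anchored) Hreg <- Hreg - tcrossprod(vdir) / sum(vdir^2)
    step <- tryCatch(solve(Hreg, gh$g), error = function(e) NULL)
    if (is.null(step))
      step <- solve(Hreg - diag(1e-8, npar), gh$g)
    # Newton for a maximum: beta_new = beta - H^{-1} g
    sc <- 1
    p0 <- pack(beta)
    repeat {
      cand <- unpack(p0 - sc * step, beta)
      llc <- loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      sc <- sc / 2
      if (sc < 1e-6) stopf("conditional ML did not converge (step collapse)")
    }
    beta <- cand; ll <- llc
    if (!anchored) {   # recentre along the invariant direction: sum(delta) = 0
      d <- vapply(seq_len(K), function(i) beta[[i]][imax[i]] / imax[i], 0)
      shift <- mean(d)
      for (i in seq_len(K)) beta[[i]] <- beta[[i]] - shift * seq_len(imax[i])
    }
  }
  if (iter > max_iter)
    stopf("conditional ML did not converge in %d iterations (|grad| = %.2e)",
          max_iter, gnorm)

  delta <- vapply(seq_len(K), function(i) beta[[i]][imax[i]] / imax[i], 0)
  tau <- lapply(seq_len(K), function(i) diff(c(0, beta[[i]])) - delta[i])
  labels <- colnames(values) %||% item_labels(K)
  new_item_parameters(delta, tau, labels = labels, score_map = cl$score_map,
                      convergence = list(iterations = iter, grad_norm = gnorm))
}

# ---- person measures --------------------------------------------------------

# theta and SE for each raw total 0..Rmax under fixed item parameters.
# method "mle": maximum likelihood with extremes shifted inward by
# `extreme_adjust` raw-score points.  method "wle": Warm's weighted
# likelihood (bias-corrected; finite at extremes without adjustment),
# used for short item subsets where the ML outward bias matters.
score_table <- function(params, extreme_adjust = 0.3, lim = 15,
                        method = c("mle", "wle")) {
  method <- match.arg(method)
  beta <- params_beta(params)
  Rmax <- sum(params$item_max)
  mom <- function(th) {
    M <- vapply(beta, function(b) {
      m <- pcm_item_moments(th, b, central3 = TRUE)
      c(m$e, m$v, m$m3)
    }, numeric(3))
    rowSums(M)
  }
  th <- se <- numeric(Rmax + 1L)
  for (r in 0:Rmax) {
    if (method == "mle") {
      r_eff <- if (r == 0) extreme_adjust else if (r == Rmax) Rmax - extreme_adjust else r
      f <- function(x) mom(x)[1] - r_eff
    } else {
      # score equation of the weighted likelihood: S(th) + I'(th)/(2 I(th))
      f <- function(x) { m <- mom(x); r - m[1] + m[3] / (2 * m[2]) }
    }
    th[r + 1L] <- stats::uniroot(f, c(-lim, lim), tol = 1e-9,
                                 extendInt = if (method == "mle") "upX" else "downX")$root
    info <- mom(th[r + 1L])[2]
    se[r + 1L] <- 1 / sqrt(info)
  }
  data.frame(raw = 0:Rmax, theta = th, se = se,
             extreme = (0:Rmax) %in% c(0L, Rmax))
}

#' Person ability estimates given item parameters
#'
#' Maximum likelihood of theta per person (complete data, so the raw total is
#' sufficient and estimation reduces to one solve per observed total).
#' Extreme raw scores (0 or the maximum) are shifted inward by
#' `extreme_adjust` raw-score points before solving and flagged.
#'
#' @param rm `response_matrix`.
#' @param params `item_parameters`.
#' @param extreme_adjust raw-score adjustment for extreme totals.
#' @return data frame with `raw`, `theta`, `se`, `extreme` (one row per person).
#' @export
estimate_person_measures <- function(rm, params, extreme_adjust = 0.3) {
  rm <- conform_rm(rm, params)
  st <- score_table(params, extreme_adjust)
  r <- total_scores(rm)
  out <- st[r + 1L, ]
  rownames(out) <- NULL
  out
}

# Person measures from a subset of items (used by the unidimensionality
# t-test and the testlet subscale indices).  Defaults to weighted-likelihood
# estimation: subsets are short, where the ML outward bias is material.
person_measures_subset <- function(rm, params, items, extreme_adjust = 0.3,
                                   method = "wle") {
  rm <- conform_rm(rm, params)
  sub <- new_item_parameters(params$delta[items], params$tau[items],
                             labels = params$labels[items])
  st <- score_table(sub, extreme_adjust, method = method)
  r <- as.integer(rowSums(unclass(rm)[, items, drop = FALSE]))
  out <- st[r + 1L, ]
  rownames(out) <- NULL
  out
}

# ---- raw score to measure conversion ---------------------------------------

#' Raw-score-to-measure conversion table
#'
#' For every raw total under the (anchored) calibration: the logit measure,
#' its standard error and confidence interval, and a linear 0-100 rescaling
#' whose endpoints are exactly `rescale[1]` and `rescale[2]`.
#'
#' @param params `item_parameters`.
#' @param rescale two-vector giving the rescaled endpoints (default 0, 100).
#' @param level confidence level (default 0.95).
#' @param extreme_adjust raw-score adjustment for extreme totals.
#' @return `conversion_table` data frame with columns `raw`, `theta`, `se`,
#'   `ci_lo`, `ci_hi`, `scaled`, `scaled_lo`, `scaled_hi`.
#' @export
score_conversion_table <- function(params, rescale = c(0, 100), level = 0.95,
                                   extreme_adjust = 0.3) {
  st <- score_table(params, extreme_adjust)
  z <- stats::qnorm(1 - (1 - level) / 2)
  st$ci_lo <- st$theta - z * st$se
  st$ci_hi <- st$theta + z * st$se
  th0 <- st$theta[1]; th1 <- st$theta[nrow(st)]
  sc <- function(x) (x - th0) / (th1 - th0) * diff(rescale) + rescale[1]
  st$scaled <- sc(st$theta)
  st$scaled_lo <- sc(st$ci_lo)
  st$scaled_hi <- sc(st$ci_hi)
  class(st) <- c("conversion_table", "data.frame")
  st
}
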