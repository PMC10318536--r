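# Preliminary unidimensionality assessment: classical item statistics,
# Mokken scalability coefficients with the automated item selection
# procedure, polychoric correlations, and a one-factor ordinal factor
# analysis fitted by unweighted least squares.

#' Classical item statistics
#'
#' Cronbach's alpha (variance-ratio formula), alpha if an item is deleted,
#' the Spearman correlation of each item with its rest score (total minus the
#' item), and the mean of the pairwise inter-item Spearman correlations.
#' Rank correlations use average ranks for ties throughout.
#'
#' @param rm `response_matrix` (>= 2 items, >= 3 persons, complete).
#' @return `classical_item_stats` list.
#' @export
classical_item_stats <- function(rm) {
  x <- unclass(rm)
  if (ncol(x) < 2 || nrow(x) < 3) stopf("need >= 2 items and >= 3 persons")
  K <- ncol(x)
  zero_var <- apply(x, 2, stats::var) == 0
  if (any(zero_var))
    warnf("zero-variance item(s): %s; their correlations are undefined",
          paste(colnames(x)[zero_var], collapse = ","))
  alpha <- cronbach_alpha(x)
  # alpha-if-deleted needs >= 2 remaining items
  alpha_drop <- if (K > 2)
    vapply(seq_len(K), function(i) cronbach_alpha(x[, -i]), 0)
  else rep(NA_real_, K)
  tot <- rowSums(x)
  item_rest <- vapply(seq_len(K), function(i) {
    if (zero_var[i]) return(NA_real_)
    suppressWarnings(stats::cor(x[, i], tot - x[, i], method = "spearman"))
  }, 0)
  sp <- suppressWarnings(stats::cor(x, method = "spearman"))
  structure(list(alpha = alpha,
                 alpha_if_deleted = stats::setNames(alpha_drop, colnames(x)),
                 item_rest_rho = stats::setNames(item_rest, colnames(x)),
                 mean_interitem_rho = mean(sp[lower.tri(sp)], na.rm = TRUE)),
            class = "classical_item_stats")
}

#' @export
print.classical_item_stats <- function(x, ...) {
  cat(sprintf("alpha = %.3f, mean inter-item rho = %.3f\n",
              x$alpha, x$mean_interitem_rho))
  cat("item-rest rho:\n"); print(round(x$item_rest_rho, 3))
  invisible(x)
}

# ---- Mokken scalability -----------------------------------------------------

# Maximum covariance between two ordinal variables given their marginals:
# attained by the comonotone (sorted) arrangement.
cov_max_pair <- function(x, y) stats::cov(sort(x), sort(y))

#' Mokken scalability coefficients
#'
#' Hij = cov(Xi, Xj) / covmax(Xi, Xj), the covariance normed by its maximum
#' attainable value given the two marginals (the comonotone arrangement);
#' Hj and H are the correspondingly normed covariance sums for item-vs-rest
#' and for the whole scale.  Perfect Guttman (comonotone) data give H = 1.
#'
#' @param rm `response_matrix`.
#' @return `mokken_result` list with `H`, `Hj`, `Hij`.
#' @export
mokken_coefficients <- function(rm) {
  x <- unclass(rm)
  K <- ncol(x)
  cv <- stats::cov(x)
  cm <- matrix(NA_real_, K, K, dimnames = dimnames(cv))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    cm[i, j] <- cm[j, i] <- cov_max_pair(x[, i], x[, j])
  }
  degen <- apply(x, 2, stats::var) == 0
  if (any(degen)) {
    warnf("degenerate marginal(s): %s; coefficients undefined",
          paste(colnames(x)[degen], collapse = ","))
    cm[degen, ] <- cm[, degen] <- NA
  }
  Hij <- cv / cm; diag(Hij) <- NA
  Hj <- vapply(seq_len(K), function(i)
    sum(cv[i, -i]) / sum(cm[i, -i]), 0)
  lt <- lower.tri(cv)
  H <- sum(cv[lt]) / sum(cm[lt])
  structure(list(H = H, Hj = stats::setNames(Hj, colnames(x)), Hij = Hij),
            class = "mokken_result")
}

#' Automated item selection procedure (AISP)
#'
#' Iteratively grows Mokken scales: each scale starts from the admissible
#' item pair with the largest Hij (requiring Hij >= `lower_bound`), then
#' repeatedly adds the unselected item maximizing the scale's H among those
#' with positive Hij with all current members and Hj >= `lower_bound` with
#' respect to the scale.  Items fitting no scale are labelled 0
#' (unscalable).
#'
#' @param rm `response_matrix`.
#' @param lower_bound scalability lower bound c (default 0.3).
#' @return integer vector: scale number per item, 0 = unscalable.
#' @export
mokken_aisp <- function(rm, lower_bound = 0.3) {
  x <- unclass(rm)
  K <- ncol(x)
  cv <- stats::cov(x)
  cm <- matrix(NA_real_, K, K)
  for (i in seq_len(K - 1)) for (j in (i + 1):K)
    cm[i, j] <- cm[j, i] <- cov_max_pair(x[, i], x[, j])
  Hij <- cv / cm
  scale_H <- function(items) {
    sub_cv <- cv[items, items]; sub_cm <- cm[items, items]
    sum(sub_cv[lower.tri(sub_cv)]) / sum(sub_cm[lower.tri(sub_cm)])
  }
  Hj_in <- function(i, items)
    sum(cv[i, items]) / sum(cm[i, items])
  assign <- integer(K)
  remaining <- seq_len(K)
  s <- 0L
  repeat {
    if (length(remaining) < 2) break
    cand <- Hij[remaining, remaining, drop = FALSE]
    cand[lower.tri(cand, diag = TRUE)] <- NA
    if (all(is.na(cand)) || max(cand, na.rm = TRUE) < lower_bound) break
    s <- s + 1L
    ij <- which(cand == max(cand, na.rm = TRUE), arr.ind = TRUE)[1, ]
    scale_items <- remaining[c(ij[1], ij[2])]
    remaining <- setdiff(remaining, scale_items)
    repeat {
      ok <- remaining[vapply(remaining, function(i)
        all(Hij[i, scale_items] > 0) && Hj_in(i, scale_items) >= lower_bound,
        TRUE)]
      if (!length(ok)) break
      Hs <- vapply(ok, function(i) scale_H(c(scale_items, i)), 0)
      best <- ok[which.max(Hs)]
      scale_items <- c(scale_items, best)
      remaining <- setdiff(remaining, best)
    }
    assign[scale_items] <- s
  }
  stats::setNames(assign, colnames(x))
}

# ---- polychoric correlations ------------------------------------------------

# Bivariate standard normal CDF P(X <= h, Y <= k) by Gauss-Legendre
# quadrature on the correlation path (Drezner-Wesolowsky identity).
pbvnorm <- function(h, k, rho) {
  if (!is.finite(h) && h > 0) return(stats::pnorm(k))
  if (!is.finite(k) && k > 0) return(stats::pnorm(h))
  if (!is.finite(h) || !is.finite(k)) return(0)
  if (abs(rho) < 1e-12) return(stats::pnorm(h) * stats::pnorm(k))
  gl <- gauss_legendre_32
  t <- rho / 2 * (gl$x + 1)          # nodes on [0, rho]
  w <- rho / 2 * gl$w
  f <- exp(-(h^2 - 2 * t * h * k + k^2) / (2 * (1 - t^2))) / sqrt(1 - t^2)
  stats::pnorm(h) * stats::pnorm(k) + sum(w * f) / (2 * pi)
}

# 32-point Gauss-Legendre rule on [-1, 1], computed once at load time.
gauss_legendre_nodes <- function(n) {
  # Golub-Welsch: eigen decomposition of the Jacobi matrix
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(x = e$values[idx], w = 2 * e$vectors[1, idx]^2)
}
gauss_legendre_32 <- gauss_legendre_nodes(32L)

# Two-step polychoric correlation for one pair of ordinal variables.
polychoric_pair <- function(x, y) {
  tab <- table(factor(x, sort(unique(x))), factor(y, sort(unique(y))))
  if (any(tab == 0)) tab <- tab + 0.5 * (tab == 0)   # continuity correction
  px <- rowSums(tab) / sum(tab); py <- colSums(tab) / sum(tab)
  a <- c(-Inf, stats::qnorm(cumsum(px)[-length(px)]), Inf)
  b <- c(-Inf, stats::qnorm(cumsum(py)[-length(py)]), Inf)
  nr <- length(px); nc <- length(py)
  cellp <- function(rho) {
    Phi <- matrix(0, nr + 1, nc + 1)
    for (r in seq_len(nr + 1)) for (s in seq_len(nc + 1))
      Phi[r, s] <- pbvnorm(a[r], b[s], rho)
    P <- Phi[-1, -1] - Phi[-(nr + 1), -1] - Phi[-1, -(nc + 1)] +
      Phi[-(nr + 1), -(nc + 1)]
    pmax(P, 1e-12)
  }
  nll <- function(rho) -sum(tab * log(cellp(rho)))
  stats::optimize(nll, c(-0.999, 0.999))$minimum
}

#' Polychoric correlation matrix
#'
#' Two-step estimator: thresholds from the marginal cumulative proportions
#' via the normal quantile, then per-pair maximum likelihood for the latent
#' correlation (bivariate-normal cell probabilities).  Zero cells receive a
#' continuity correction of 0.5.
#'
#' @param rm `response_matrix` (every item with >= 2 observed categories).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
polychoric_matrix <- function(rm) {
  x <- unclass(rm)
  K <- ncol(x)
  if (any(apply(x, 2, function(c) length(unique(c))) < 2))
    stopf("every item needs >= 2 observed categories")
  R <- diag(K)
  for (i in seq_len(K - 1)) for (j in (i + 1):K)
    R[i, j] <- R[j, i] <- polychoric_pair(x[, i], x[, j])
  dimnames(R) <- list(colnames(x), colnames(x))
  R
}

# ---- one-factor ordinal CFA (ULS) ------------------------------------------

#' One-factor ordinal CFA on a polychoric matrix
#'
#' Fits a single-factor model (optionally with correlated uniquenesses for
#' listed item pairs) to a polychoric correlation matrix by unweighted least
#' squares; fit indices are computed from the ULS discrepancy scaled by
#' (n - 1).  Pairs whose absolute residual correlation exceeds 0.1 are
#' flagged as locally dependent.
#'
#' @param S polychoric correlation matrix.
#' @param n number of observations behind `S`.
#' @param correlated_pairs optional 2-column matrix / data frame of item
#'   index pairs given correlated error terms.
#' @param resid_flag residual threshold for flagging pairs (default 0.1).
#' @return `ordinal_factor_fit` list: `chi2`, `df`, `p`, `rmsea`, `srmr`,
#'   `cfi`, `tli`, `loadings`, `residuals`, `flagged_pairs`.
#' @export
cfa_onefactor_fit <- function(S, n, correlated_pairs = NULL, resid_flag = 0.1) {
  p <- ncol(S)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 0) {      # smooth a non-PSD matrix
    ev$values <- pmax(ev$values, 1e-6)
    S <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
    S <- stats::cov2cor(S)
  }
  cp <- if (!is.null(correlated_pairs)) as.matrix(correlated_pairs) else
    matrix(integer(0), 0, 2)
  npairs <- nrow(cp)
  lam0 <- ev$vectors[, 1] * sqrt(ev$values[1])
  if (mean(lam0) < 0) lam0 <- -lam0
  start <- c(clamp(lam0, -0.9, 0.9), rep(0, npairs))
  lt <- lower.tri(S)
  implied <- function(par) {
    lam <- par[seq_len(p)]
    Sig <- tcrossprod(lam)
    if (npairs) for (q in seq_len(npairs))
      Sig[cp[q, 1], cp[q, 2]] <- Sig[cp[q, 2], cp[q, 1]] <-
        Sig[cp[q, 1], cp[q, 2]] + par[p + q]
    diag(Sig) <- 1
    Sig
  }
  objective <- function(par) {
    R <- S - implied(par)
    sum(R[lt]^2)
  }
  opt <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = c(rep(-0.995, p), rep(-1, npairs)),
                      upper = c(rep(0.995, p), rep(1, npairs)),
                      control = list(maxit = 2000, factr = 1e4))
  if (opt$convergence != 0)
    stopf("one-factor ULS fit did not converge (code %d: %s)",
          opt$convergence, opt$message %||% "")
  lam <- opt$par[seq_len(p)]
  Sig <- implied(opt$par)
  R <- S - Sig
  Fmin <- opt$value
  df <- p * (p - 1) / 2 - p - npairs
  chi2 <- (n - 1) * Fmin
  F0 <- sum(S[lt]^2)
  chi2_0 <- (n - 1) * F0; df0 <- p * (p - 1) / 2
  pval <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * (n - 1))) else NA_real_
  srmr <- sqrt(sum(R[lower.tri(R, diag = TRUE)]^2) / (p * (p + 1) / 2))
  cfi <- 1 - max(chi2 - df, 0) / max(chi2_0 - df0, chi2 - df, .Machine$double.eps)
  tli <- ((chi2_0 / df0) - (chi2 / df)) / ((chi2_0 / df0) - 1)
  flg <- which(abs(R) > resid_flag & upper.tri(R), arr.ind = TRUE)
  flagged <- if (nrow(flg)) data.frame(item1 = rownames(S)[flg[, 1]] %||% flg[, 1],
                                       item2 = colnames(S)[flg[, 2]] %||% flg[, 2],
                                       residual = R[flg]) else NULL
  structure(list(polychoric = S, chi2 = chi2, df = df, p = pval, rmsea = rmsea,
                 srmr = srmr, cfi = cfi, tli = tli,
                 loadings = stats::setNames(lam, colnames(S)),
                 residuals = R, flagged_pairs = flagged),
            class = "ordinal_factor_fit")
}

#' @export
print.ordinal_factor_fit <- function(x, ...) {
  cat(sprintf("one-factor ULS fit: chi2 = %.1f (df %d, p %.4f)\n", x$chi2,
              x$df, x$p))
  cat(sprintf("  RMSEA %.3f | SRMR %.3f | CFI %.3f | TLI %.3f | %d flagged pair(s)\n",
              x$rmsea, x$srmr, x$cfi, x$tli,
              if (is.null(x$flagged_pairs)) 0L else nrow(x$flagged_pairs)))
  invisible(x)
}

#' Accession checks against the deposited study data
#'
#' Given a local copy of the deposited multi-centre dataset (not shipped with
#' the package), recomputes the pooled classical and Mokken headline values:
#' Cronbach's alpha, the Mokken scale coefficient H, the item-rest
#' correlation of item 3, and the pooled median total score.
#'
#' @param path path to the deposited long-format CSV.
#' @param schema column mapping for [read_assessments()].
#' @return list with `alpha`, `H`, `bbs03_item_rest`, `median_total`,
#'   `n_records`, `n_excluded`.
#' @export
accession_checks <- function(path, schema = assessment_schema()) {
  rec <- read_assessments(path, schema)
  rm <- to_response_matrix(rec)
  cs <- classical_item_stats(rm)
  mk <- mokken_coefficients(rm)
  list(alpha = cs$alpha, H = mk$H,
       bbs03_item_rest = unname(cs$item_rest_rho["BBS03"]),
       median_total = stats::median(total_scores(rm)),
       n_records = nrow(rm), n_excluded = attr(rec, "n_excluded"))
}
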