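# External construct validity: rank correlations, two- and k-group
# non-parametric comparisons with post-hoc tests, the effect-size conversion
# chain r = |z|/sqrt(N), d = 2r/sqrt(1-r^2) (and its eta-squared analogue),
# and normality assessment.

interpret_rho <- function(rho) {
  a <- abs(rho)
  if (a < 0.10) "negligible" else if (a < 0.30) "weak" else
    if (a < 0.50) "moderate" else if (a < 0.80) "strong" else "very strong"
}

#' Convert a non-parametric effect size r to Cohen's d
#' @param r effect size in \[0, 1).
#' @return Cohen's d `2r / sqrt(1 - r^2)`.
#' @export
effect_r_to_d <- function(r) 2 * r / sqrt(1 - r^2)

#' Convert eta-squared to Cohen's d
#' @param eta2 eta-squared in \[0, 1).
#' @return Cohen's d `2 * sqrt(eta2 / (1 - eta2))`.
#' @export
eta2_to_d <- function(eta2) 2 * sqrt(eta2 / (1 - eta2))

#' Spearman association between two measure series
#'
#' Average-rank ties handling; pairs with a missing value are dropped.
#'
#' @param x,y numeric series of equal length.
#' @return list with `rho`, `p`, `n`, `label` (strength band).
#' @export
spearman_assoc <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stopf("need at least 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("constant series; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, label = NA_character_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       label = interpret_rho(unname(ct$estimate)))
}

# Mann-Whitney U with tie-corrected normal approximation.
mann_whitney <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2); N <- n1 + n2
  r <- rank(c(x1, x2))
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x1, x2))
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sig2 > 0) (U1 - mu) / sqrt(sig2) else 0
  list(U = U1, z = z, p = 2 * stats::pnorm(-abs(z)), N = N)
}

#' Compare a measure across groups non-parametrically
#'
#' Two groups: Mann-Whitney U with tie-corrected normal approximation z,
#' effect size r = |z|/sqrt(N) and Cohen's d = 2r/sqrt(1-r^2).  Three or more
#' groups: Kruskal-Wallis H (tie-corrected), eta^2 = (H - k + 1)/(n - k)
#' (alternative `eta2_variant = "H/(n-1)"` available), d = 2*sqrt(eta^2 /
#' (1 - eta^2)), plus Bonferroni-corrected pairwise Mann-Whitney post-hocs.
#'
#' @param measures numeric measure series.
#' @param groups group labels (coerced to factor; NAs dropped pairwise).
#' @param eta2_variant `"(H-k+1)/(n-k)"` (default) or `"H/(n-1)"`.
#' @return `group_comparison` list.
#' @export
group_compare <- function(measures, groups, eta2_variant = c("(H-k+1)/(n-k)", "H/(n-1)")) {
  eta2_variant <- match.arg(eta2_variant)
  keep <- !is.na(measures) & !is.na(groups)
  m <- measures[keep]; g <- droplevels(factor(groups[keep]))
  k <- nlevels(g)
  if (k < 2) stopf("need at least 2 non-empty groups")
  sizes <- table(g)
  if (any(sizes < 2)) warnf("group(s) with < 2 members: %s",
                            paste(names(sizes)[sizes < 2], collapse = ","))
  medians <- tapply(m, g, stats::median)
  if (k == 2) {
    mw <- mann_whitney(m[g == levels(g)[1]], m[g == levels(g)[2]])
    r <- abs(mw$z) / sqrt(mw$N)
    out <- list(k = 2L, n = as.integer(sizes), medians = medians,
                statistic = mw$U, z = mw$z, p = mw$p,
                effect_r = r, cohens_d = effect_r_to_d(r), posthoc = NULL)
  } else {
    kw <- stats::kruskal.test(m, g)
    H <- unname(kw$statistic); n <- length(m)
    eta2 <- if (eta2_variant == "(H-k+1)/(n-k)") (H - k + 1) / (n - k) else H / (n - 1)
    eta2 <- max(eta2, 0)
    pairs <- utils::combn(levels(g), 2)
    ph <- apply(pairs, 2, function(pr) {
      mw <- mann_whitney(m[g == pr[1]], m[g == pr[2]])
      r <- abs(mw$z) / sqrt(mw$N)
      data.frame(group1 = pr[1], group2 = pr[2], U = mw$U, z = mw$z,
                 p = mw$p, p_bonferroni = min(1, mw$p * ncol(pairs)),
                 cohens_d = effect_r_to_d(r))
    })
    out <- list(k = k, n = as.integer(sizes), medians = medians,
                statistic = H, z = NA_real_, p = kw$p.value,
                eta2 = eta2, cohens_d = eta2_to_d(eta2),
                posthoc = do.call(rbind, ph))
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$k == 2)
    cat(sprintf("Mann-Whitney: U = %.1f, z = %.3f, p = %.4g, d = %.3f\n",
                x$statistic, x$z, x$p, x$cohens_d))
  else
    cat(sprintf("Kruskal-Wallis: H = %.1f (k = %d), p = %.4g, eta2 = %.3f, d = %.3f\n",
                x$statistic, x$k, x$p, x$eta2, x$cohens_d))
  invisible(x)
}

#' Normality assessment of a measure series
#'
#' Fisher skewness g1, Pearson (non-excess) kurtosis, Kolmogorov-Smirnov
#' against the fitted normal, and Shapiro-Wilk (sample sizes above 5000 are
#' outside the Shapiro-Wilk range; NA returned with a warning).
#'
#' @param x numeric series, n >= 8.
#' @return list with `skewness`, `kurtosis`, `ks`, `ks_p`, `shapiro`,
#'   `shapiro_p`, `n`.
#' @export
normality_check <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stopf("need n >= 8")
  if (stats::sd(x) == 0) stopf("constant series; normality undefined")
  ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  if (n <= 5000) {
    sw <- stats::shapiro.test(x)
    swv <- unname(sw$statistic); swp <- sw$p.value
  } else {
    warnf("Shapiro-Wilk undefined for n > 5000; reported as NA")
    swv <- swp <- NA_real_
  }
  list(skewness = skewness(x), kurtosis = kurtosis(x),
       ks = unname(ks$statistic), ks_p = ks$p.value,
       shapiro = swv, shapiro_p = swp, n = n)
}

#' External validity battery on one observation per patient
#'
#' Convergent validity (Spearman with EDSS and ABC) and the discriminant
#' comparisons of the study design: EDSS 0-3.5 / 4-5.5 / >= 6; ABC < 40 vs
#' >= 40; ABC < 50 / 50-80 / > 80; no falls vs >= 1; <= 1 vs >= 2 falls.
#' Covariates missing for a record are dropped per-analysis.
#'
#' @param records `bbs_records` (one observation per patient; see
#'   [select_one_per_patient()]).
#' @param conversion `conversion_table` mapping raw totals to measures.
#' @param scale which measure scale to analyse: `"scaled"` (0-100) or
#'   `"theta"`.
#' @return list with `normality`, `convergent`, `discriminant`.
#' @export
external_validity <- function(records, conversion, scale = c("scaled", "theta")) {
  scale <- match.arg(scale)
  tot <- rowSums(records[, item_labels(N_ITEMS)])
  meas <- conversion[[scale]][match(tot, conversion$raw)]
  conv <- list(
    edss = if (any(!is.na(records$edss))) spearman_assoc(meas, records$edss) else NULL,
    abc = if (any(!is.na(records$abc))) spearman_assoc(meas, records$abc) else NULL)
  grp <- list()
  if (any(!is.na(records$edss))) {
    g <- cut(records$edss, c(-Inf, 3.5, 5.5, Inf),
             labels = c("EDSS 0-3.5", "EDSS 4-5.5", "EDSS >=6"))
    grp$edss3 <- group_compare(meas, g)
  }
  if (any(!is.na(records$abc))) {
    grp$abc40 <- group_compare(meas, factor(records$abc < 40,
                                            c(TRUE, FALSE),
                                            c("ABC <40", "ABC >=40")))
    lv <- c("ABC <50", "ABC 50-80", "ABC >80")
    g <- factor(ifelse(records$abc < 50, lv[1],
                       ifelse(records$abc <= 80, lv[2], lv[3])), lv)
    grp$abc5080 <- group_compare(meas, g)
  }
  if (any(!is.na(records$falls))) {
    grp$falls1 <- group_compare(meas, factor(records$falls >= 1,
                                             c(FALSE, TRUE),
                                             c("No falls", "Falls >=1")))
    grp$falls2 <- group_compare(meas, factor(records$falls >= 2,
                                             c(FALSE, TRUE),
                                             c("Falls <=1", "Falls >=2")))
  }
  list(normality = normality_check(meas), convergent = conv,
       discriminant = grp, measures = meas)
}
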