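# Testlet (super-item) construction for local dependence, and the subscale
# indices (c, r, A) computed after the testlet re-fit.

#' Testlet specification
#'
#' Defaults to the two clusters identified for the BBS in MS: items
#' 1-6 and 8-11 (postural changes, transfers, sitting, static/dynamic
#' standing) versus items 7, 12, 13, 14 (restricted support base, alternate
#' stepping, tandem, one-leg standing).
#'
#' @param groups named list of item index vectors; must partition `1..n_items`.
#' @param n_items total number of items (default 14).
#' @return `testlet_spec` object.
#' @export
testlet_spec <- function(groups = list(T1 = c(1:6, 8:11), T2 = c(7, 12:14)),
                         n_items = N_ITEMS) {
  all_items <- sort(unlist(groups))
  if (!identical(as.integer(all_items), seq_len(n_items)))
    stopf("testlet groups must partition items 1..%d", n_items)
  if (is.null(names(groups))) names(groups) <- paste0("T", seq_along(groups))
  structure(groups, class = "testlet_spec")
}

#' Sum items into testlet super-items
#'
#' Each testlet score is the sum of its member item scores, a polytomous
#' super-item with maximum equal to the sum of member maxima.  The person
#' total score is preserved exactly.
#'
#' @param rm `response_matrix`.
#' @param spec `testlet_spec`.
#' @return `response_matrix` of super-items.
#' @export
build_testlets <- function(rm, spec) {
  vals <- unclass(rm)
  m <- vapply(spec, function(g) as.integer(rowSums(vals[, g, drop = FALSE])),
              integer(nrow(vals)))
  if (nrow(vals) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(spec)))
  colnames(m) <- names(spec)
  imax <- vapply(spec, function(g) sum(item_max_of(rm)[g]), 0L)
  response_matrix(m, imax, meta_of(rm))
}

#' Subscale indices after a testlet re-fit
#'
#' From the two testlet-specific person-measure series, with observed
#' variances V_k, error variances E_k (mean squared SE), true variances
#' T_k = V_k - E_k and common true covariance C = cov(t1, t2):
#' `r` is the disattenuated latent correlation C / sqrt(T1 T2) (capped to
#' \[-1, 1\]), `A` the non-error variance common to the subscales,
#' C / mean(V_k), and `c` the average unique (non-common, non-error) variance
#' proportion, mean((T_k - C) / V_k).  Extreme scorers on either subscale are
#' excluded.
#'
#' @param rm the original item-level `response_matrix`.
#' @param spec `testlet_spec` with exactly two groups.
#' @param params_testlet `item_parameters` of the testlet calibration.
#' @return list with `c`, `r`, `A`.
#' @export
subscale_indices <- function(rm, spec, params_testlet) {
  if (length(spec) != 2) stopf("subscale indices are defined for two testlets")
  trm <- build_testlets(rm, spec)
  m1 <- person_measures_subset(trm, params_testlet, 1L)
  m2 <- person_measures_subset(trm, params_testlet, 2L)
  keep <- !(m1$extreme | m2$extreme)
  if (sum(keep) < 3) stopf("too few non-extreme persons for subscale indices")
  t1 <- m1$theta[keep]; t2 <- m2$theta[keep]
  V1 <- stats::var(t1); V2 <- stats::var(t2)
  E1 <- mean(m1$se[keep]^2); E2 <- mean(m2$se[keep]^2)
  T1 <- max(V1 - E1, 0); T2 <- max(V2 - E2, 0)
  C <- stats::cov(t1, t2)
  r <- if (T1 > 0 && T2 > 0) clamp(C / sqrt(T1 * T2), -1, 1) else NA_real_
  list(c = mean(pmax(c((T1 - C) / V1, (T2 - C) / V2), 0)),
       r = r,
       A = C / mean(c(V1, V2)))
}
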