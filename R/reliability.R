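# Reliability and targeting: person separation index, SEM, targeting index,
# floor/ceiling, the distribution-free count of distinct levels of
# performance ability (DLPA), the distribution-independent PSI, and anchored
# re-analysis of confirmation samples.

#' Distribution-independent PSI from a strata count
#'
#' `G` statistically distinct ability strata give a reliability of
#' G^2 / (1 + G^2).
#'
#' @param G number of distinct levels of performance ability.
#' @return reliability in \[0, 1).
#' @export
di_psi <- function(G) G^2 / (1 + G^2)

# Greedy distribution-free strata count over the raw-score-to-measure table:
# walk the score measures in ascending order and accept a score whenever its
# measure exceeds the last accepted one by at least z * the SE of the
# difference.
dlpa_count <- function(score_tab, z = 1.96) {
  if (nrow(score_tab) < 3) stopf("too few raw scores for DLPA")
  acc_theta <- score_tab$theta[1]; acc_se <- score_tab$se[1]
  g <- 1L
  for (j in 2:nrow(score_tab)) {
    if (score_tab$theta[j] - acc_theta >=
        z * sqrt(acc_se^2 + score_tab$se[j]^2)) {
      g <- g + 1L
      acc_theta <- score_tab$theta[j]; acc_se <- score_tab$se[j]
    }
  }
  g
}

#' Reliability and targeting summary
#'
#' Computes the person separation index with and without extreme scorers,
#' Cronbach's alpha on the raw item scores, the standard error of measurement
#' `SD * sqrt(1 - PSI_with_extremes)`, the targeting index (mean person
#' measure / SEM, items centred at 0), floor and ceiling percentages, the
#' distribution-free DLPA count and the distribution-independent PSI
#' G^2/(1+G^2).
#'
#' @param persons person estimates (from [estimate_person_measures()]).
#' @param params `item_parameters`.
#' @param rm optional `response_matrix` for Cronbach's alpha (NA otherwise).
#' @return `reliability_targeting` list.
#' @export
reliability_targeting <- function(persons, params, rm = NULL) {
  psi_of <- function(p) {
    v <- stats::var(p$theta)
    max(0, (v - mean(p$se^2)) / v)
  }
  psi_with <- psi_of(persons)
  nonx <- persons[!persons$extreme, ]
  psi_without <- if (nrow(nonx) > 2) psi_of(nonx) else NA_real_
  alpha <- if (!is.null(rm)) cronbach_alpha(unclass(rm)) else NA_real_
  sdp <- stats::sd(persons$theta)
  sem <- sdp * sqrt(1 - psi_with)
  ti <- mean(persons$theta) / sem
  rmax <- sum(params$item_max)
  st <- score_table(params)
  G <- dlpa_count(st)
  structure(list(
    psi = psi_without, psi_with_extremes = psi_with, alpha = alpha,
    sem = sem, targeting_index = ti,
    floor_pct = 100 * mean(persons$raw == 0),
    ceiling_pct = 100 * mean(persons$raw == rmax),
    dlpa = G, di_psi = di_psi(G)),
    class = "reliability_targeting")
}

#' @export
print.reliability_targeting <- function(x, ...) {
  cat(sprintf(paste0("reliability_targeting: PSI %.3f (with extremes %.3f), ",
                     "alpha %s\n  SEM %.3f, TI %.3f, floor %.1f%%, ceiling %.1f%%, ",
                     "DLPA %d, DI-PSI %.3f\n"),
              x$psi, x$psi_with_extremes,
              if (is.na(x$alpha)) "N/A" else sprintf("%.3f", x$alpha),
              x$sem, x$targeting_index, x$floor_pct, x$ceiling_pct,
              x$dlpa, x$di_psi))
  invisible(x)
}

#' Anchored re-analysis of a confirmation sample
#'
#' Holds the exported item parameters fixed exactly, re-estimates persons,
#' and recomputes the full fit battery and the reliability/targeting summary
#' on the confirmation sample.
#'
#' @param rm confirmation-sample `response_matrix`.
#' @param anchored `item_parameters` exported from the validation sample.
#' @param n_class_intervals class intervals for the fit battery.
#' @return list with `params` (the anchor, unchanged), `persons`, `fit`,
#'   `residuals`, `reliability`.
#' @export
anchor_and_refit <- function(rm, anchored, n_class_intervals = NULL) {
  if (ncol(rm) != length(anchored$delta))
    stopf("anchor does not cover the sample's items")
  rm <- conform_rm(rm, anchored)
  persons <- estimate_person_measures(rm, anchored)
  fit <- fit_statistics(rm, anchored, persons, n_class_intervals)
  res <- residual_structure(rm, anchored, persons)
  # alpha is reported on item-level scores only, not on super-items
  rel <- reliability_targeting(persons, anchored,
                               rm = if (max(item_max_of(rm)) <= 4) rm else NULL)
  list(params = anchored, persons = persons, fit = fit, residuals = res,
       reliability = rel)
}

#' Export / import item parameters as delimited text
#'
#' The text round-trip is exact to the printed precision (15 significant
#' digits), so anchored runs reproduce the exported calibration bit-for-bit
#' for all practical purposes.
#'
#' @param params `item_parameters`.
#' @param path output path (TSV).
#' @export
write_item_parameters <- function(params, path) {
  m <- max(params$item_max)
  tau <- t(vapply(params$tau, function(t) c(t, rep(NA, m - length(t))), numeric(m)))
  df <- data.frame(item = params$labels, delta = params$delta, tau,
                   check.names = FALSE)
  names(df) <- c("item", "delta", paste0("tau", seq_len(m)))
  utils::write.table(format(df, digits = 15), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_item_parameters
#' @param path path to a file written by [write_item_parameters()].
#' @return `item_parameters`.
#' @export
read_item_parameters <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  tau <- lapply(seq_len(nrow(df)), function(i) {
    t <- suppressWarnings(as.numeric(df[i, -(1:2)]))   # "NA" padding cells
    t[!is.na(t)]
  })
  new_item_parameters(as.numeric(df$delta), tau, labels = df$item)
}
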