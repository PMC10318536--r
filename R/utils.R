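# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample skewness (Fisher g1) and Pearson kurtosis
#'
#' `skewness()` returns the moment coefficient g1 = m3 / m2^(3/2);
#' `kurtosis()` returns the Pearson (non-excess) coefficient m4 / m2^2, so a
#' normal sample gives a value near 3.
#'
#' @param x numeric vector (NAs dropped).
#' @return scalar coefficient.
#' @export
skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

#' @rdname skewness
#' @export
kurtosis <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^4) / m2^2
}

# Cronbach's alpha by the variance-ratio formula on an items matrix.
cronbach_alpha <- function(x) {
  k <- ncol(x)
  vi <- apply(x, 2, stats::var)
  vt <- stats::var(rowSums(x))
  if (vt <= 0) return(NA_real_)
  k / (k - 1) * (1 - sum(vi) / vt)
}

item_labels <- function(k) sprintf("BBS%02d", seq_len(k))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
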