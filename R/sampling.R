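# Time-independence sampling: build subsamples containing at most one
# observation per patient (Mallinson procedure), check their balance, and
# pick the validation subsample by score range.

#' Split observations into time-independent subsamples
#'
#' Patients with a single observation are divided evenly between groups A and
#' B (forced floor/ceiling balance); for two-observation patients one random
#' observation goes to A and the other to B; for three-observation patients
#' one goes to A, one to B and the leftover to C.  A and B are then each
#' halved at random into (A1, A2) and (B1, B2).  C is flagged excluded when
#' its size falls below `min_size`.
#'
#' @param records `bbs_records` with 1-3 observations per patient.
#' @param seed integer RNG seed (mandatory: the split is random).
#' @param min_size minimum subsample size below which C is excluded from
#'   analysis (default 250, the study's lower bound).
#' @return `subsample_split`: list with `assignment` (data frame
#'   `patient_id`, `obs_index`, `subsample`), `sizes`, `c_excluded`, `seed`.
#' @export
split_time_independent <- function(records, seed, min_size = 250L) {
  stopifnot(is.numeric(seed))
  tb <- table(records$patient_id)
  if (any(tb > 3)) stopf("more than 3 observations for patient(s): %s",
                         paste(utils::head(names(tb)[tb > 3]), collapse = ", "))
  set.seed(seed)
  key <- split(records$obs_index, records$patient_id)
  a <- b <- list(); cc <- list()
  singles <- names(key)[lengths(key) == 1L]
  singles <- sample(singles)                         # shuffle, then force balance
  nA <- floor(length(singles) / 2)
  for (p in singles[seq_len(nA)]) a[[p]] <- key[[p]]
  for (p in singles[setdiff(seq_along(singles), seq_len(nA))]) b[[p]] <- key[[p]]
  for (p in names(key)[lengths(key) == 2L]) {
    o <- sample(key[[p]])
    a[[p]] <- o[1]; b[[p]] <- o[2]
  }
  for (p in names(key)[lengths(key) == 3L]) {
    o <- sample(key[[p]])
    a[[p]] <- o[1]; b[[p]] <- o[2]; cc[[p]] <- o[3]
  }
  halve <- function(x, lab1, lab2) {
    ids <- sample(names(x))
    n1 <- ceiling(length(ids) / 2)
    s <- stats::setNames(rep(lab2, length(ids)), ids)
    s[ids[seq_len(n1)]] <- lab1
    s
  }
  as_block <- function(x, labels) data.frame(
    patient_id = names(x), obs_index = as.integer(unlist(x)),
    subsample = unname(labels[names(x)]), stringsAsFactors = FALSE)
  assignment <- rbind(
    as_block(a, halve(a, "A1", "A2")),
    as_block(b, halve(b, "B1", "B2")),
    if (length(cc)) as_block(cc, stats::setNames(rep("C", length(cc)), names(cc))))
  sizes <- table(factor(assignment$subsample, c("A1", "A2", "B1", "B2", "C")))
  structure(list(assignment = assignment, sizes = sizes,
                 c_excluded = sizes[["C"]] < min_size, seed = seed),
            class = "subsample_split")
}

#' @export
print.subsample_split <- function(x, ...) {
  cat("subsample split (seed ", x$seed, "):\n", sep = "")
  print(x$sizes)
  if (x$c_excluded) cat("C excluded (below minimum size)\n")
  invisible(x)
}

#' Extract the records of one subsample
#'
#' @param records `bbs_records` used to build the split.
#' @param split `subsample_split`.
#' @param label one of `"A1"`, `"A2"`, `"B1"`, `"B2"`, `"C"`.
#' @return `bbs_records` of that subsample (one observation per patient).
#' @export
subsample_records <- function(records, split, label) {
  sel <- split$assignment[split$assignment$subsample == label, ]
  idx <- match(paste(sel$patient_id, sel$obs_index),
               paste(records$patient_id, records$obs_index))
  out <- records[idx[!is.na(idx)], ]
  rownames(out) <- NULL
  structure(out, class = c("bbs_records", "data.frame"))
}

#' Compare subsamples on clinical and demographic characteristics
#'
#' Chi-square tests for categorical variables (gender, disease course) and
#' Kruskal-Wallis tests for continuous ones (age, disease duration, BBS total
#' score), mirroring the balance table of a randomization check.
#'
#' @param subsamples named list of `bbs_records`.
#' @return data frame: `variable`, `test`, `statistic`, `df`, `p`.
#' @export
balance_check <- function(subsamples) {
  if (length(subsamples) < 2) stopf("need at least 2 subsamples")
  lab <- rep(names(subsamples), vapply(subsamples, nrow, 1L))
  all <- do.call(rbind, lapply(subsamples, as.data.frame))
  all$bbs_total <- rowSums(all[, item_labels(N_ITEMS)])
  spec <- list(gender = "chisq", course = "chisq",
               age = "kruskal", duration = "kruskal", bbs_total = "kruskal")
  out <- list()
  for (v in names(spec)) {
    x <- all[[v]]
    if (all(is.na(x))) { warnf("variable %s absent in all subsamples; skipped", v); next }
    keep <- !is.na(x)
    res <- if (spec[[v]] == "chisq") {
      tt <- suppressWarnings(stats::chisq.test(table(lab[keep], x[keep])))
      c(tt$statistic, tt$parameter, tt$p.value)
    } else {
      tt <- stats::kruskal.test(x[keep], factor(lab[keep]))
      c(tt$statistic, tt$parameter, tt$p.value)
    }
    out[[v]] <- data.frame(variable = v, test = spec[[v]], statistic = res[1],
                           df = res[2], p = res[3], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Choose the validation subsample
#'
#' Returns the label of the subsample with the largest observed total-score
#' range (max - min); ties are broken by label order.
#'
#' @param subsamples named list of `bbs_records`.
#' @return character label.
#' @export
select_validation_sample <- function(subsamples) {
  if (length(subsamples) < 1) stopf("no subsamples")
  rng <- vapply(subsamples, function(s) {
    tot <- rowSums(s[, item_labels(N_ITEMS)])
    diff(range(tot))
  }, 0)
  names(subsamples)[which.max(rng)]     # which.max keeps the first on ties
}

#' Select one observation per patient
#'
#' Used for the external-validity stage, which analyses a single randomly
#' chosen observation per subject.
#'
#' @param records `bbs_records`.
#' @param seed integer RNG seed.
#' @return `bbs_records` with one row per patient.
#' @export
select_one_per_patient <- function(records, seed) {
  set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(records)), records$patient_id),
                       function(ix) if (length(ix) == 1) ix else sample(ix, 1)))
  out <- records[sort(unname(idx)), ]
  rownames(out) <- NULL
  structure(out, class = c("bbs_records", "data.frame"))
}
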