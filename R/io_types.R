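# Data model and delimited-text IO for long-format balance assessments.
#
# One row per patient-observation: identifiers, demographics, disease
# covariates, and the 14 BBS item scores (each ordinal 0..4).  Records with a
# missing item score are excluded at read time (the analysis operates on
# complete assessments only); missing covariates are retained and handled
# per-analysis downstream.

N_ITEMS <- 14L
ITEM_MAX <- 4L

CANONICAL_COLS <- c(
  "patient_id", "center", "obs_index", "gender", "age", "course",
  "duration", "edss", "abc", "falls"
)

#' Column-name mapping for assessment tables
#'
#' Maps the canonical column names used internally to the headers present in
#' a source file, so exports from arbitrary systems can be read without
#' renaming.  Unnamed arguments are ignored; unspecified columns default to
#' their canonical names, and items default to `BBS01`..`BBS14`.
#'
#' @param ... named character scalars, e.g. `patient_id = "ID"`.
#' @param items character vector of length 14 with the item column headers.
#' @return named list mapping canonical name -> source header.
#' @export
assessment_schema <- function(..., items = item_labels(N_ITEMS)) {
  stopifnot(length(items) == N_ITEMS)
  sch <- as.list(stats::setNames(CANONICAL_COLS, CANONICAL_COLS))
  dots <- list(...)
  bad <- setdiff(names(dots), CANONICAL_COLS)
  if (length(bad)) stopf("unknown schema field(s): %s", paste(bad, collapse = ", "))
  sch[names(dots)] <- dots
  sch$items <- as.character(items)
  sch
}

#' Read a long-format assessment table
#'
#' Reads a delimited text file (comma by default, tab accepted), maps its
#' headers through `schema`, validates every record, and drops — with a
#' count — records having any missing item score.  Item scores outside the
#' 0..4 range raise an error naming the offending row and item.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param schema column mapping from [assessment_schema()].
#' @param sep field separator; `NULL` picks `\t` for `.tsv` files, `,` otherwise.
#' @return a `bbs_records` data frame with canonical columns and items
#'   `BBS01`..`BBS14`; attribute `n_excluded` counts dropped incomplete
#'   records.
#' @export
read_assessments <- function(path, schema = assessment_schema(), sep = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = "UTF-8")
  wanted <- c(unlist(schema[CANONICAL_COLS], use.names = FALSE), schema$items)
  missing_cols <- setdiff(wanted, names(raw))
  if (length(missing_cols))
    stopf("column(s) not resolvable via schema: %s", paste(missing_cols, collapse = ", "))
  df <- raw[, wanted]
  names(df) <- c(CANONICAL_COLS, item_labels(N_ITEMS))
  as_bbs_records(df)
}

#' Coerce and validate a data frame of assessment records
#'
#' @param df data frame with canonical columns and `BBS01`..`BBS14`.
#' @return validated `bbs_records`; attribute `n_excluded` counts records
#'   dropped for missing item scores.
#' @export
as_bbs_records <- function(df) {
  need <- c(CANONICAL_COLS, item_labels(N_ITEMS))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("missing column(s): %s", paste(missing_cols, collapse = ", "))
  df <- df[, need]
  it <- as.matrix(df[, item_labels(N_ITEMS)])
  storage.mode(it) <- "double"
  bad <- which(!is.na(it) & (it < 0 | it > ITEM_MAX | it != round(it)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("invalid item score %s at row %d, item %s (must be an integer in 0..%d)",
          format(it[bad[1, , drop = FALSE]]), bad[1, 1],
          item_labels(N_ITEMS)[bad[1, 2]], ITEM_MAX)
  incomplete <- rowSums(is.na(it)) > 0
  n_excluded <- sum(incomplete)
  df <- df[!incomplete, , drop = FALSE]
  if (anyDuplicated(df[, c("patient_id", "obs_index")]))
    stopf("obs_index must be unique within patient")
  if (any(!is.na(df$edss) & (df$edss < 0 | df$edss > 10 | (df$edss * 2) != round(df$edss * 2))))
    stopf("edss must lie in [0, 10] in steps of 0.5")
  if (any(!is.na(df$abc) & (df$abc < 0 | df$abc > 100)))
    stopf("abc must lie in [0, 100]")
  if (any(!is.na(df$falls) & (df$falls < 0 | df$falls != round(df$falls))))
    stopf("falls must be a non-negative integer count")
  rownames(df) <- NULL
  structure(df, n_excluded = n_excluded, class = c("bbs_records", "data.frame"))
}

#' Write assessment records to delimited text
#'
#' Round-trips losslessly through [read_assessments()].
#'
#' @param records `bbs_records`.
#' @param path output path; `.tsv` extension selects tab separation unless
#'   `sep` is given.
#' @param sep field separator (default chosen from the extension).
#' @export
write_assessments <- function(records, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(records, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a response matrix from assessment records
#'
#' One row per record (observation); repeated observations per patient are a
#' sampling concern, handled by [split_time_independent()], not here.
#'
#' @param records `bbs_records` (non-empty).
#' @return a `response_matrix`: integer matrix persons x 14 with columns
#'   `BBS01`..`BBS14`, attributes `item_max` (per-item maximum category) and
#'   `meta` (the non-item columns).
#' @export
to_response_matrix <- function(records) {
  if (nrow(records) == 0) stopf("no records")
  values <- as.matrix(records[, item_labels(N_ITEMS)])
  storage.mode(values) <- "integer"
  response_matrix(values, item_max = rep(ITEM_MAX, N_ITEMS),
                  meta = records[, CANONICAL_COLS])
}

#' Construct a response matrix
#'
#' The general ordinal-response container used throughout: a persons x items
#' integer matrix with a per-item maximum category.  Testlet super-items use
#' the same container with larger maxima.
#'
#' @param values integer matrix, `values[v, i]` in `0..item_max[i]`, no NAs.
#' @param item_max integer vector of per-item maxima.
#' @param meta optional data frame of person metadata (one row per person).
#' @return `response_matrix` object.
#' @export
response_matrix <- function(values, item_max, meta = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stopf("response_matrix does not admit missing cells")
  item_max <- as.integer(item_max)
  if (length(item_max) != ncol(values)) stopf("item_max length must equal ncol(values)")
  if (any(values < 0) || any(values > rep(item_max, each = nrow(values))))
    stopf("scores outside 0..item_max")
  if (!is.null(meta) && nrow(meta) != nrow(values))
    stopf("meta must have one row per person")
  structure(values, item_max = item_max, meta = meta,
            class = c("response_matrix", class(values)))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d persons x %d items (maxima: %s)\n",
              nrow(x), ncol(x), paste(attr(x, "item_max"), collapse = ",")))
  invisible(x)
}

item_max_of <- function(rm) attr(rm, "item_max")
meta_of <- function(rm) attr(rm, "meta")

#' Total raw scores of a response matrix
#' @param rm `response_matrix`.
#' @return integer vector of per-person totals.
#' @export
total_scores <- function(rm) as.integer(rowSums(unclass(rm)))

# Subset persons, keeping attributes consistent (including conformity to a
# calibration's collapsed category space).
rm_subset <- function(rm, rows, items = NULL) {
  items <- items %||% seq_len(ncol(rm))
  m <- unclass(rm)[rows, items, drop = FALSE]
  meta <- meta_of(rm)
  if (!is.null(meta)) meta <- meta[rows, , drop = FALSE]
  out <- response_matrix(m, item_max_of(rm)[items], meta)
  attr(out, "conformed") <- attr(rm, "conformed")
  out
}
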