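#' Construct a survival dataset
#'
#' The cohort container consumed by every fitting function: right-censored
#' survival records with an optional delayed-entry (left-truncation) time and
#' named numeric covariate columns.  Covariates may contain `NA`; they must be
#' removed with [complete_case_filter()] before any column is used in a model.
#'
#' @param exit_time numeric vector of exit times, strictly positive.
#' @param status event indicator, 0 = censored, 1 = event.
#' @param entry_time optional numeric vector of entry times (counting-process
#'   data); `NULL` means all records enter at 0.  Must satisfy
#'   `entry_time < exit_time` row-wise.
#' @param covariates data frame of numeric covariate columns (may be empty).
#'
#' @return An object of class `survival_dataset`: a list with elements
#'   `entry_time`, `exit_time`, `status`, `covariates`, `n`, `n_events`.
#' @export
survival_dataset <- function(exit_time, status, entry_time = NULL,
                             covariates = NULL) {
  exit_time <- as.numeric(exit_time)
  n <- length(exit_time)
  if (n == 0L) hs_stop("dataset has no records")
  if (anyNA(exit_time)) hs_stop("exit_time contains missing values")
  if (any(exit_time <= 0)) hs_stop("exit_time must be strictly positive")
  status <- as.numeric(status)
  if (length(status) != n) hs_stop("status length differs from exit_time")
  if (anyNA(status) || !all(status %in% c(0, 1)))
    hs_stop("status must contain only 0 and 1")
  if (!is.null(entry_time)) {
    entry_time <- as.numeric(entry_time)
    if (length(entry_time) != n) hs_stop("entry_time length differs")
    if (anyNA(entry_time)) hs_stop("entry_time contains missing values")
    if (any(entry_time < 0)) hs_stop("entry_time must be nonnegative")
    bad <- which(exit_time <= entry_time)
    if (length(bad))
      hs_stop(sprintf("exit_time <= entry_time in row %d", bad[1L]))
  } else {
    entry_time <- rep(0, n)
  }
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_len(n))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) hs_stop("covariates row count differs")
  for (nm in names(covariates)) {
    if (!is.numeric(covariates[[nm]]))
      hs_stop(sprintf("covariate '%s' is not numeric", nm))
  }
  structure(list(entry_time = entry_time, exit_time = exit_time,
                 status = status, covariates = covariates,
                 n = n, n_events = sum(status)),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("survival_dataset: %d records, %d events", x$n, x$n_events))
  if (any(x$entry_time > 0)) cat(" (delayed entry)")
  cat("\n")
  if (ncol(x$covariates))
    cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.survival_dataset <- function(x, ...) {
  out <- data.frame(entry_time = x$entry_time, exit_time = x$exit_time,
                    status = x$status)
  if (ncol(x$covariates)) out <- cbind(out, x$covariates)
  out
}

# A column read as character is classified as numeric (all non-missing values
# parse), categorical (none parse), or an error (mixed) -- silent coercion of
# a typo like "1O3" to NA would hide data bugs.
parse_column <- function(vals, name) {
  miss <- is.na(vals) | vals == "" | vals == "NA"
  suppressWarnings(num <- as.numeric(vals))
  parses <- !is.na(num) | miss
  if (all(parses)) {
    num[miss] <- NA_real_
    return(list(type = "numeric", values = num))
  }
  if (any(!is.na(num) & !miss))
    hs_stop(sprintf("column '%s' mixes numeric and non-numeric values (e.g. '%s')",
                    name, vals[!parses][1L]))
  f <- vals
  f[miss] <- NA_character_
  list(type = "categorical", values = f)
}

# Reference-coded indicator expansion; the first observed level is reference.
expand_categorical <- function(vals, name) {
  lev <- unique(vals[!is.na(vals)])
  out <- list()
  for (l in lev[-1L]) {
    col <- as.numeric(vals == l)
    col[is.na(vals)] <- NA_real_
    out[[paste(name, l, sep = "_")]] <- col
  }
  out
}

#' Read a survival table from a delimited text file
#'
#' Reads a header-ed CSV (or tab-delimited) file and returns a validated
#' [survival_dataset()].  With `time2_col` given, `time_col` is the entry time
#' and `time2_col` the exit time (counting-process convention); otherwise
#' `time_col` is the exit time and entry is 0.  Empty fields and `"NA"` are
#' treated as missing; any other non-numeric value in an otherwise numeric
#' column is an error.  Columns whose values are all non-numeric are treated
#' as categorical and expanded to reference-coded indicator columns
#' (`<col>_<level>`, first observed level is the reference).
#'
#' @param path file path.
#' @param time_col name of the time column (exit, or entry when `time2_col`
#'   is given).
#' @param status_col name of the 0/1 event-status column.
#' @param time2_col optional name of the exit-time column for counting-process
#'   data.
#' @param covariate_cols character vector of covariate column names; `NULL`
#'   (default) uses every remaining column.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A [survival_dataset()] (covariates may contain `NA`; apply
#'   [complete_case_filter()] before fitting).
#' @export
read_survival_data <- function(path, time_col, status_col, time2_col = NULL,
                               covariate_cols = NULL, sep = NULL) {
  if (!file.exists(path)) hs_stop(sprintf("file not found: %s", path))
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  need <- c(time_col, status_col, time2_col)
  for (nm in need)
    if (!nm %in% names(raw)) hs_stop(sprintf("missing column '%s'", nm))
  if (is.null(covariate_cols))
    covariate_cols <- setdiff(names(raw), need)
  for (nm in covariate_cols)
    if (!nm %in% names(raw)) hs_stop(sprintf("missing column '%s'", nm))

  num_col <- function(nm) {
    p <- parse_column(raw[[nm]], nm)
    if (p$type != "numeric")
      hs_stop(sprintf("column '%s' must be numeric", nm))
    if (anyNA(p$values))
      hs_stop(sprintf("missing values in required column '%s'", nm))
    p$values
  }
  status <- num_col(status_col)
  if (!all(status %in% c(0, 1)))
    hs_stop(sprintf("status column '%s' must contain only 0 and 1", status_col))
  if (is.null(time2_col)) {
    exit <- num_col(time_col); entry <- NULL
  } else {
    entry <- num_col(time_col); exit <- num_col(time2_col)
  }

  covs <- list()
  for (nm in covariate_cols) {
    p <- parse_column(raw[[nm]], nm)
    if (p$type == "numeric") covs[[nm]] <- p$values
    else covs <- c(covs, expand_categorical(p$values, nm))
  }
  covariates <- if (length(covs)) as.data.frame(covs, check.names = FALSE)
                else NULL
  survival_dataset(exit_time = exit, status = status, entry_time = entry,
                   covariates = covariates)
}

#' Restrict a dataset to complete cases
#'
#' Drops every record carrying a missing value in any of `used_cols` and
#' reports how many were removed (the "observations deleted due to
#' missingness" of a model printout).  Idempotent.
#'
#' @param dataset a [survival_dataset()].
#' @param used_cols covariate columns entering the model; `NULL` means all.
#' @return list with elements `dataset` (filtered) and `n_dropped`.
#' @export
complete_case_filter <- function(dataset, used_cols = NULL) {
  stopifnot(inherits(dataset, "survival_dataset"))
  if (is.null(used_cols)) used_cols <- names(dataset$covariates)
  missing_cols <- setdiff(used_cols, names(dataset$covariates))
  if (length(missing_cols))
    hs_stop(sprintf("unknown covariate column '%s'", missing_cols[1L]))
  if (length(used_cols) == 0L) return(list(dataset = dataset, n_dropped = 0L))
  keep <- stats::complete.cases(dataset$covariates[used_cols])
  n_dropped <- sum(!keep)
  if (all(!keep)) hs_stop("empty cohort after filtering")
  if (n_dropped > 0L) {
    message(sprintf("%d observations deleted due to missingness", n_dropped))
    dataset <- survival_dataset(
      exit_time = dataset$exit_time[keep],
      status = dataset$status[keep],
      entry_time = if (any(dataset$entry_time > 0)) dataset$entry_time[keep],
      covariates = dataset$covariates[keep, , drop = FALSE])
  }
  list(dataset = dataset, n_dropped = n_dropped)
}

#' Write a survival dataset to CSV
#'
#' Numeric fields are written with 17 significant digits so that a write/read
#' round trip reproduces the dataset exactly.
#'
#' @param dataset a [survival_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survival_data <- function(dataset, path) {
  stopifnot(inherits(dataset, "survival_dataset"))
  df <- as.data.frame(dataset)
  fmt <- function(v) {
    out <- vapply(v, function(x)
      if (is.na(x)) "NA" else sprintf("%.17g", x), character(1L))
    out
  }
  txt <- as.data.frame(lapply(df, fmt), check.names = FALSE)
  utils::write.table(txt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
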