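## TSV readers/writers for the pipeline's table contracts. All day
## coordinates are 1-based inclusive in [1, 365]; intervals are [t, t+1].

#' Write a data frame as tab-separated values
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table, checking required columns
#'
#' @param path file path.
#' @param required column names that must be present.
#' @return data frame.
#' @export
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stopf("malformed TSV '%s': %s", path, conditionMessage(e)))
  if (!is.null(required) && !all(required %in% names(x)))
    stopf("'%s' lacks required column(s): %s", path,
          paste(setdiff(required, names(x)), collapse = ", "))
  x
}

#' @rdname read_tsv
#' @export
read_visits <- function(path) {
  v <- read_tsv(path, required = c("sample_id", "subject_id", "day_of_year"))
  check_days(v$day_of_year)
  v
}

#' @rdname read_tsv
#' @export
read_feature_table <- function(path) {
  read_tsv(path, required = c("sample_id", "feature_id", "value"))
}

#' Read a samples x taxa count matrix from TSV
#'
#' First column must be the sample id; remaining columns are taxa.
#' @param path file path.
#' @return integer matrix with sample rownames.
#' @export
read_count_matrix <- function(path) {
  x <- read_tsv(path)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read standardized curves (long TSV: curve_id, day, value) as a matrix
#'
#' @param path file path.
#' @return curves x 365 matrix.
#' @export
read_curves <- function(path) {
  x <- read_tsv(path, required = c("curve_id", "day", "value"))
  ids <- unique(x$curve_id)
  m <- matrix(NA_real_, length(ids), 365, dimnames = list(ids, NULL))
  m[cbind(match(x$curve_id, ids), x$day)] <- x$value
  if (anyNA(m)) stopf("'%s' does not cover days 1..365 for every curve", path)
  m
}

## long form of a curves matrix
curves_to_long <- function(m) {
  data.frame(curve_id = rep(rownames(m), each = ncol(m)),
             day = rep(seq_len(ncol(m)), nrow(m)),
             value = as.vector(t(m)), stringsAsFactors = FALSE)
}
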