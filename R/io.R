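# Readers/writers for the family-pool dataset and result formats.
#
# Dataset TSV (UTF-8, header row, tab separators, '.' decimal):
#   family_id  s1  s2  depth  phenotype  [s1_B  s2_B]
# one row per family; a family with no reads has s1 = s2 = depth = 0 and
# is retained, flagged missing downstream. Numbers are written with 6
# significant digits in TSV; JSON results keep full precision.

DATASET_COLUMNS <- c("family_id", "s1", "s2", "depth", "phenotype")

#' Read a family-pool dataset
#'
#' Reads the tab-separated per-SNP table (one row per family: identifier,
#' reference- and alternate-allele read counts, total depth, phenotype)
#' and computes the observed pool frequency `g_obs = s1 / depth`,
#' `NA` for zero-depth families, which are retained.
#'
#' @param path Path to a TSV file written by [write_pool_dataset()] (or
#'   assembled externally with the same header).
#' @return A data frame with the file's columns plus `g_obs`.
#' @export
read_pool_dataset <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("dataset file not found: %s", path), call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  missing_cols <- setdiff(DATASET_COLUMNS, header)
  if (length(missing_cols) > 0L) {
    stop(sprintf("malformed dataset header: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  counts <- c("s1", "s2", "depth",
              intersect(c("s1_B", "s2_B"), header))
  classes <- c(stats::setNames(rep("integer", length(counts)), counts),
               phenotype = "numeric")
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = classes,
                         stringsAsFactors = FALSE)
  for (col in c("s1", "s2", "depth", if ("s1_B" %in% names(x)) c("s1_B", "s2_B"))) {
    bad <- which(!is.finite(x[[col]]) | x[[col]] < 0)
    if (length(bad) > 0L) {
      stop(sprintf("invalid %s at line %d: counts must be non-negative",
                   col, bad[1L] + 1L), call. = FALSE)  # +1 for header line
    }
  }
  bad <- which(x$depth != x$s1 + x$s2)
  if (length(bad) > 0L) {
    stop(sprintf("depth != s1 + s2 at line %d", bad[1L] + 1L),
         call. = FALSE)
  }
  x$g_obs <- ifelse(x$depth > 0, x$s1 / x$depth, NA_real_)
  x
}

#' Write a family-pool dataset
#'
#' Writes the TSV dataset format (see [read_pool_dataset()]); numeric
#' phenotypes are serialized with 6 significant digits, counts exactly.
#'
#' @param x Data frame with columns `family_id`, `s1`, `s2`, `depth`,
#'   `phenotype` (and optionally `s1_B`, `s2_B`), e.g. from
#'   [simulate_pool_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pool_dataset <- function(x, path) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(DATASET_COLUMNS, names(x))
  if (length(missing_cols) > 0L) {
    stop(sprintf("dataset is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  cols <- c(DATASET_COLUMNS, intersect(c("s1_B", "s2_B"), names(x)))
  out <- x[cols]
  out$phenotype <- formatC(out$phenotype, format = "g", digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write an association result
#'
#' Serializes a `"pool_assoc"` fit as a one-record JSON object (full
#' precision) or a one-row TSV (6 significant digits).
#'
#' @param fit A `"pool_assoc"` object.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_assoc_result <- function(fit, path, format = c("json", "tsv")) {
  stopifnot(inherits(fit, "pool_assoc"))
  format <- match.arg(format)
  df <- as.data.frame(fit)
  if (format == "json") {
    jsonlite::write_json(as.list(df), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) formatC(v, format = "g",
                                                   digits = 6))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Write a power table
#'
#' @param x Data frame of power results (from [fixed_budget_grid()],
#'   [error_stacking_study()] or rows of `as.data.frame(run_power(...))`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_power_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) formatC(v, format = "g", digits = 6))
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
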