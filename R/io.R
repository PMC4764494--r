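#' Read a measurement table from delimited text
#'
#' Two dialects are supported.  *Long* format (canonical) has a header
#' `batch,sample,value` and one measurement per row.  *Wide* format mirrors a
#' gel/plate layout sheet: the first column holds batch identifiers, the
#' header row holds sample identifiers, and each cell holds zero or more
#' semicolon-separated replicate values (an empty cell means "not measured",
#' never zero).
#'
#' @param path file to read.
#' @param format `"long_csv"`, `"long_tsv"` or `"wide_csv"`.
#' @return A [measurement_table()].
#' @export
read_measurements <- function(path, format = c("long_csv", "long_tsv", "wide_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format %in% c("long_csv", "long_tsv")) {
    sep <- if (format == "long_csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            colClasses = c("character", "character", "character"),
                            stringsAsFactors = FALSE, strip.white = TRUE)
    if (!identical(tolower(names(df))[1:3], c("batch", "sample", "value"))) {
      stop("long-format header must be 'batch", sep, "sample", sep, "value'")
    }
    val <- suppressWarnings(as.numeric(df[[3L]]))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad) > 0L) {
      stop(sprintf("malformed numeric value '%s' at data row %d of %s",
                   df[[3L]][bad[1L]], bad[1L], path))
    }
    return(measurement_table(df[[1L]], df[[2L]], val))
  }
  # wide format
  raw <- utils::read.table(path, header = FALSE, sep = ",",
                           colClasses = "character",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (nrow(raw) < 2L || ncol(raw) < 2L) stop("wide table needs a header row and a batch column")
  sample_ids <- as.character(raw[1L, -1L])
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id in wide header: ",
         sample_ids[duplicated(sample_ids)][1L])
  }
  batch <- character(0); smp <- character(0); value <- numeric(0)
  for (r in 2L:nrow(raw)) {
    b <- raw[r, 1L]
    for (cc in 2L:ncol(raw)) {
      cell <- raw[r, cc]
      if (is.na(cell) || !nzchar(trimws(cell))) next
      parts <- trimws(strsplit(cell, ";", fixed = TRUE)[[1L]])
      parts <- parts[nzchar(parts)]
      v <- suppressWarnings(as.numeric(parts))
      if (anyNA(v)) {
        stop(sprintf("malformed numeric cell '%s' at row %d, column %d of %s",
                     cell, r, cc, path))
      }
      batch <- c(batch, rep(b, length(v)))
      smp <- c(smp, rep(sample_ids[cc - 1L], length(v)))
      value <- c(value, v)
    }
  }
  measurement_table(batch, smp, value)
}

#' Write a measurement table as long-format delimited text
#'
#' @param table a [measurement_table()].
#' @param path output file.
#' @param sep field separator (`","` or `"\t"`).
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path, sep = ",") {
  table <- as_measurement_table(table)
  df <- as.data.frame(table)
  df$value <- format(df$value, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a standard set from two-column delimited text
#'
#' Expects rows of `sample_id,known_amount`; a header line is detected and
#' skipped if its second field is not numeric.
#'
#' @param path file to read.
#' @return A [standard_set()].
#' @export
read_standards <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = ",",
                          colClasses = "character",
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(df) < 2L) stop("standards file needs two columns: sample, amount")
  if (nrow(df) >= 1L && is.na(suppressWarnings(as.numeric(df[2L][[1L]][1L])))) {
    df <- df[-1L, , drop = FALSE]  # header line
  }
  if (nrow(df) == 0L) stop("at least one standard required")
  amounts <- suppressWarnings(as.numeric(df[[2L]]))
  bad <- which(!is.finite(amounts))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite standard amount '%s' at row %d", df[[2L]][bad[1L]], bad[1L]))
  }
  standard_set(stats::setNames(amounts, df[[1L]]))
}

#' Write calibration results to a directory of delimited files
#'
#' Writes three files: `samples.csv` (sample, x, sd, se, n_used — standards
#' appear with their known amounts and empty sd/se), `batches.csv` (batch,
#' a, b, sd_a, sd_b, se_a, se_b, n_used), and `summary.csv` (method, sigma,
#' chi2, dof, iterations, removal counts, plus one row per removed batch or
#' sample with its reason).  Values are written at full precision; columns
#' are in fixed order so the files diff cleanly.
#'
#' @param fit a `"calibration"` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_result <- function(fit, dir) {
  stopifnot(inherits(fit, "calibration"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- fit$table
  n_j <- tabulate(match(tab$sample, tab$samples), length(tab$samples))
  n_i <- tabulate(match(tab$batch, tab$batches), length(tab$batches))
  num <- function(v) ifelse(is.na(v), "", format(v, digits = 17, trim = TRUE))

  samples <- data.frame(sample = tab$samples,
                        x = num(as.numeric(fit$x)),
                        sd = num(as.numeric(fit$sd_x)),
                        se = num(as.numeric(fit$se_x)),
                        n_used = n_j, stringsAsFactors = FALSE)
  utils::write.table(samples, file.path(dir, "samples.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)

  batches <- data.frame(batch = tab$batches,
                        a = num(as.numeric(fit$a)), b = num(as.numeric(fit$b)),
                        sd_a = num(as.numeric(fit$sd_a)),
                        sd_b = num(as.numeric(fit$sd_b)),
                        se_a = num(as.numeric(fit$se_a)),
                        se_b = num(as.numeric(fit$se_b)),
                        n_used = n_i, stringsAsFactors = FALSE)
  utils::write.table(batches, file.path(dir, "batches.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)

  summary <- rbind(
    data.frame(key = c("method", "sigma", "chi2", "dof", "iterations",
                       "n_measurements", "n_removed_batches", "n_removed_samples"),
               value = c(fit$method, num(fit$sigma), num(fit$chi2), fit$dof,
                         fit$iterations, fit$n_used,
                         nrow(fit$removed_batches), nrow(fit$removed_samples)),
               stringsAsFactors = FALSE),
    if (nrow(fit$removed_batches) > 0L)
      data.frame(key = "removed_batch",
                 value = paste(fit$removed_batches$id,
                               fit$removed_batches$reason, sep = ": "),
                 stringsAsFactors = FALSE),
    if (nrow(fit$removed_samples) > 0L)
      data.frame(key = "removed_sample",
                 value = paste(fit$removed_samples$id,
                               fit$removed_samples$reason, sep = ": "),
                 stringsAsFactors = FALSE))
  utils::write.table(summary, file.path(dir, "summary.csv"), sep = ",",
                     row.names = FALSE, quote = TRUE)
  invisible(dir)
}
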