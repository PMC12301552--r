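#' Long-format study tables of per-animal measurements
#'
#' A `study_table` is the ingest container of the package: one row per
#' (animal, measurand) observation with the partition labels (such as sex)
#' needed for partitioned reporting.  Required columns are `animal_id`,
#' `sex`, `measurand`, `unit` and `value`; any extra columns are preserved as
#' metadata.  Values arrive as printed text and may carry thousand
#' separators ("9,900"); they are normalized to numeric at ingest, and
#' non-numeric or empty cells are dropped with a per-measurand logged count.
#'
#' @param x A data.frame with the required columns.
#' @return A validated `study_table` (a data.frame subclass).  The attribute
#'   `"drop_log"` records how many cells were dropped per measurand.
#' @seealso [read_study_table()], [extract_series()]
#' @export
study_table <- function(x) {
  required <- c("animal_id", "sex", "measurand", "unit", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$animal_id <- as.character(x$animal_id)
  x$sex <- as.character(x$sex)
  x$measurand <- as.character(x$measurand)
  x$unit <- as.character(x$unit)

  raw <- x$value
  if (is.character(raw)) raw <- parse_numeric(raw)
  keep <- !is.na(raw) & is.finite(raw)
  dropped <- x$measurand[!keep]
  drop_log <- if (length(dropped) > 0) table(dropped) else table(character(0))
  x <- x[keep, , drop = FALSE]
  x$value <- as.numeric(raw[keep])
  rownames(x) <- NULL

  dup <- duplicated(x[, c("animal_id", "measurand")])
  if (any(dup)) {
    stop("integrity error: duplicate (animal_id, measurand) pair(s), e.g. ",
         x$animal_id[dup][1], " / ", x$measurand[dup][1], call. = FALSE)
  }
  units_per <- tapply(x$unit, x$measurand, function(u) length(unique(u)))
  if (any(units_per > 1)) {
    bad <- names(units_per)[units_per > 1][1]
    stop("integrity error: measurand '", bad,
         "' recorded in more than one unit", call. = FALSE)
  }

  attr(x, "drop_log") <- as.list(drop_log)
  class(x) <- c("study_table", "data.frame")
  x
}

# "9,900" -> 9900; blank / non-numeric -> NA (dropped upstream with a count)
parse_numeric <- function(s) {
  s <- gsub(",", "", trimws(s), fixed = TRUE)
  s[s == ""] <- NA_character_
  suppressWarnings(as.numeric(s))
}

#' Read a long-format study table from a delimited text file
#'
#' The delimiter is inferred from the extension (`.tsv`/`.txt` tab, otherwise
#' comma).  Missing and non-numeric value cells are dropped with a logged
#' per-measurand count (missingness is handled per measurand, not per animal,
#' because panels routinely have different n per measurand for one cohort).
#'
#' @param path Path to a CSV/TSV file with header columns `animal_id`,
#'   `sex`, `measurand`, `unit`, `value`; extra columns are kept.
#' @param sep Field delimiter; `NULL` (default) infers it from the extension.
#' @return A `study_table`.
#' @export
read_study_table <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  study_table(raw)
}

#' Write a study table back to delimited text
#'
#' Inverse of [read_study_table()]: a written table reads back with the same
#' records up to row order.
#'
#' @param table A `study_table`.
#' @param path Output path (`.tsv` writes tab-delimited, otherwise CSV).
#' @return `path`, invisibly.
#' @export
write_study_table <- function(table, path) {
  stopifnot(inherits(table, "study_table"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(table), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("<study_table> %d records | %d animals | %d measurands | partitions: %s\n",
              nrow(x), length(unique(x$animal_id)),
              length(unique(x$measurand)),
              paste(sort(unique(x$sex)), collapse = ", ")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

#' One measurand's values for one partition
#'
#' The unit of analysis of the pipeline: a finite numeric vector together
#' with the measurand name, unit and partition label.  Missing entries are
#' not allowed (they are removed, and counted, at ingest).
#'
#' @param measurand Measurand name.
#' @param unit Unit string.
#' @param partition Partition label (e.g. `"All"`, `"M"`, `"F"`).
#' @param values Finite numeric vector (may be empty).
#' @return A `measurand_series`.
#' @export
measurand_series <- function(measurand, unit, partition, values) {
  values <- as.numeric(values)
  if (anyNA(values) || (length(values) > 0 && !all(is.finite(values)))) {
    stop("measurand_series values must be finite and non-missing", call. = FALSE)
  }
  structure(list(measurand = as.character(measurand),
                 unit = as.character(unit),
                 partition = as.character(partition),
                 values = values),
            class = "measurand_series")
}

#' @export
print.measurand_series <- function(x, ...) {
  cat(sprintf("<measurand_series> %s (%s), partition %s, n = %d\n",
              x$measurand, x$unit, x$partition, length(x$values)))
  invisible(x)
}

#' Extract one measurand/partition series from a study table
#'
#' `partition = "All"` pools every record of the measurand; any other label
#' selects the matching subset of the `sex` column (or of `partition_var`).
#' A label that exists in the table but has no records for this measurand
#' yields an empty series, not an error -- the banded method selection then
#' reports nothing for it.
#'
#' @param table A `study_table`.
#' @param measurand Measurand name (must exist in the table).
#' @param partition `"All"` or a partition label present in the table.
#' @param partition_var Column holding the partition labels (default
#'   `"sex"`; any label column works, partitioning is not hardcoded to sex).
#' @return A [measurand_series()].
#' @examples
#' tab <- study_table(data.frame(
#'   animal_id = c("a1", "a2", "a3"), sex = c("M", "M", "F"),
#'   measurand = "Hb", unit = "g/dL", value = c(11.2, 12.0, 13.1)))
#' length(extract_series(tab, "Hb", "All")$values)
#' length(extract_series(tab, "Hb", "F")$values)
#' @export
extract_series <- function(table, measurand, partition = "All",
                           partition_var = "sex") {
  stopifnot(inherits(table, "study_table"))
  if (!measurand %in% table$measurand) {
    stop("unknown measurand: ", measurand, call. = FALSE)
  }
  if (!partition_var %in% names(table)) {
    stop("unknown partition variable: ", partition_var, call. = FALSE)
  }
  rows <- table[table$measurand == measurand, , drop = FALSE]
  if (!identical(partition, "All")) {
    if (!partition %in% table[[partition_var]]) {
      stop("unknown partition label: ", partition, call. = FALSE)
    }
    rows <- rows[rows[[partition_var]] == partition, , drop = FALSE]
  }
  measurand_series(measurand,
                   if (nrow(rows) > 0) rows$unit[1] else unique(table$unit[table$measurand == measurand])[1],
                   partition, rows$value)
}

#' Descriptive statistics of a numeric sample
#'
#' @param values Numeric vector, `n >= 1`.
#' @return A `descriptive_stats` list with `n`, `mean`, `sd` (n-1
#'   denominator; 0 for n = 1), `median`, `min`, `max`.
#' @export
descriptive_stats <- function(values) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  structure(list(n = length(values),
                 mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else 0,
                 median = stats::median(values),
                 min = min(values),
                 max = max(values)),
            class = "descriptive_stats")
}

#' @export
print.descriptive_stats <- function(x, ...) {
  cat(sprintf("n = %d | mean %.4g | sd %.4g | median %.4g | range [%.4g, %.4g]\n",
              x$n, x$mean, x$sd, x$median, x$min, x$max))
  invisible(x)
}
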