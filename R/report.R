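#' Compile a full-study reference-interval report
#'
#' Runs [analyze_measurand()] for every measurand in the table, first on the
#' pooled sample (partition `"All"`) and then for each partition label, and
#' computes the between-partition comparison (attached to the pooled row)
#' when exactly two partition labels are present.  Row order is
#' deterministic: measurand input order, then `"All"` followed by the
#' partition labels in order of first appearance.
#'
#' @param table A [study_table()].
#' @param policy An [ri_policy()].
#' @param partition_var Column holding the partition labels (default
#'   `"sex"`).
#' @return A data.frame of class `ri_report`, one row per (measurand,
#'   partition), with full-precision numeric columns (`n`, `mean`, `sd`,
#'   `median`, `min`, `max`, `outliers_removed`, `lower`, `upper`, CI
#'   bounds, CI/RI ratios, `normality_p`, `partition_p`) and label columns
#'   (`distribution`, `method`).  The per-row run log (screening audit) is
#'   attached as attribute `"log"`.
#' @export
compile_report <- function(table, policy = ri_policy(), partition_var = "sex") {
  stopifnot(inherits(table, "study_table"), nrow(table) > 0)
  measurands <- unique(table$measurand)
  labels <- unique(table[[partition_var]])
  rows <- list()
  log <- list()
  for (m in measurands) {
    results <- list()
    for (part in c("All", labels)) {
      series <- extract_series(table, m, part, partition_var)
      results[[part]] <- analyze_measurand(series, policy)
    }
    comparison <- NULL
    if (length(labels) == 2) {
      a <- results[[labels[1]]]
      b <- results[[labels[2]]]
      if (!is.null(a$screen) && !is.null(b$screen)) {
        comparison <- compare_partitions(a$screen$retained, b$screen$retained,
                                         policy)
      }
    }
    for (part in c("All", labels)) {
      r <- results[[part]]
      rows[[length(rows) + 1L]] <- result_to_row(
        r, if (identical(part, "All") && !is.null(comparison)) {
          comparison$p_value
        } else NA_real_)
      log[[length(log) + 1L]] <- list(
        measurand = m, partition = part,
        n_before = if (is.null(r$screen)) 0L else {
          length(r$screen$retained) + nrow(r$screen$removed)
        },
        n_after = if (is.null(r$screen)) 0L else length(r$screen$retained),
        outliers_removed = if (is.null(r$screen)) 0L else nrow(r$screen$removed),
        screen_iterations = if (is.null(r$screen)) 0L else r$screen$iterations,
        method = r$method, seed = policy$rng_seed)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "log") <- log
  class(report) <- c("ri_report", "data.frame")
  report
}

result_to_row <- function(r, partition_p = NA_real_) {
  d <- r$descriptive
  data.frame(
    measurand = r$measurand, unit = r$unit, partition = r$partition,
    n = if (is.null(d)) 0L else d$n,
    mean = if (is.null(d)) NA_real_ else d$mean,
    sd = if (is.null(d)) NA_real_ else d$sd,
    median = if (is.null(d)) NA_real_ else d$median,
    min = if (is.null(d)) NA_real_ else d$min,
    max = if (is.null(d)) NA_real_ else d$max,
    outliers_removed = if (is.null(r$screen)) 0L else nrow(r$screen$removed),
    lower = r$lower_limit, upper = r$upper_limit,
    lrl_ci_low = if (is.null(r$lrl_ci)) NA_real_ else r$lrl_ci[["low"]],
    lrl_ci_high = if (is.null(r$lrl_ci)) NA_real_ else r$lrl_ci[["high"]],
    url_ci_low = if (is.null(r$url_ci)) NA_real_ else r$url_ci[["low"]],
    url_ci_high = if (is.null(r$url_ci)) NA_real_ else r$url_ci[["high"]],
    lrl_ratio = r$lrl_ratio, url_ratio = r$url_ratio,
    normality_p = if (is.null(r$normality)) NA_real_ else r$normality$p_value,
    distribution = if (is.na(r$distribution_label)) NA_character_ else r$distribution_label,
    method = method_label(r$method),
    partition_p = partition_p)
}

# table-style label: P / NP (the min-max RI is a nonparametric estimate) / NA
method_label <- function(method) {
  switch(method,
         parametric = "P",
         nonparametric = "NP",
         minmax = "NP",
         NA_character_)
}

#' Render a compiled report to delimited and markdown tables
#'
#' Writes `report.csv` (machine-readable: the formatted columns, one row per
#' (measurand, partition)) and `report.md` (a human-readable table).
#' Display formatting: numeric cells at 2 decimal places, RI and CI cells as
#' `"lower-upper"`, absent cells as `"-"`.
#'
#' @param report An `ri_report` from [compile_report()].
#' @param out_dir Output directory (created if needed).
#' @param formats Character subset of `c("csv", "md")`.
#' @return Named character vector of the files written, invisibly.
#' @export
render_tables <- function(report, out_dir, formats = c("csv", "md")) {
  stopifnot(inherits(report, "ri_report"), nrow(report) > 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fr <- format_report(report)
  written <- character(0)
  if ("csv" %in% formats) {
    f <- file.path(out_dir, "report.csv")
    utils::write.csv(fr, f, row.names = FALSE, quote = TRUE)
    written["csv"] <- f
  }
  if ("md" %in% formats) {
    f <- file.path(out_dir, "report.md")
    header <- paste0("| ", paste(names(fr), collapse = " | "), " |")
    rule <- paste0("|", paste(rep("---", ncol(fr)), collapse = "|"), "|")
    body <- apply(fr, 1, function(row) {
      paste0("| ", paste(row, collapse = " | "), " |")
    })
    writeLines(c(header, rule, body), f)
    written["md"] <- f
  }
  invisible(written)
}

#' Format a compiled report for display
#'
#' @param report An `ri_report`.
#' @return A data.frame of character columns: numbers at 2 dp, intervals as
#'   `"lower-upper"`, absent values as `"-"`.
#' @export
format_report <- function(report) {
  num <- function(v) ifelse(is.na(v), "-", formatC(v, format = "f", digits = 2))
  pval <- function(v) ifelse(is.na(v), "-", formatC(v, format = "g", digits = 4))
  interval <- function(lo, hi) ifelse(is.na(lo), "-", paste0(num(lo), "-", num(hi)))
  chr <- function(v) ifelse(is.na(v), "-", v)
  data.frame(
    measurand = report$measurand, unit = chr(report$unit),
    partition = report$partition, n = as.character(report$n),
    mean = num(report$mean), sd = num(report$sd), median = num(report$median),
    min = num(report$min), max = num(report$max),
    ri = interval(report$lower, report$upper),
    lrl_ci = interval(report$lrl_ci_low, report$lrl_ci_high),
    url_ci = interval(report$url_ci_low, report$url_ci_high),
    normality_p = pval(report$normality_p),
    distribution = chr(report$distribution),
    method = chr(report$method),
    partition_p = pval(report$partition_p),
    stringsAsFactors = FALSE)
}

#' Parse a rendered report.csv back into its formatted fields
#'
#' Inverse of the CSV branch of [render_tables()]; used for round-trip
#' checks.
#'
#' @param path Path to a `report.csv`.
#' @return A data.frame of character columns identical to
#'   [format_report()]'s output.
#' @export
parse_report <- function(path) {
  utils::read.csv(path, colClasses = "character", check.names = FALSE)
}

#' Frequency histograms of every measurand
#'
#' One frequency histogram per measurand (pooled across partitions), with
#' Freedman-Diaconis binning.  Constant measurands (zero spread) have no
#' distribution to show and are skipped with a message.
#'
#' @param table A [study_table()].
#' @param out_dir Output directory for the image files.
#' @param format `"png"` or `"pdf"`.
#' @return Character vector of files written, invisibly.
#' @export
plot_histograms <- function(table, out_dir, format = c("png", "pdf")) {
  stopifnot(inherits(table, "study_table"), nrow(table) > 0)
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (m in unique(table$measurand)) {
    x <- table$value[table$measurand == m]
    if (length(unique(x)) < 2) {
      message("skipping constant measurand: ", m)
      next
    }
    safe <- gsub("[^A-Za-z0-9._-]", "_", m)
    f <- file.path(out_dir, paste0(safe, ".", format))
    if (format == "png") {
      grDevices::png(f, width = 600, height = 450)
    } else {
      grDevices::pdf(f, width = 6, height = 4.5)
    }
    graphics::hist(x, breaks = "FD", main = m,
                   xlab = unique(table$unit[table$measurand == m])[1],
                   ylab = "Frequency", col = "grey80")
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}
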