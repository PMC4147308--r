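#' Significance stars at the conventional cutoffs
#'
#' `"*"` for P < 0.05, `"**"` for P < 0.01, `"ns"` otherwise; a pure
#' function of the p-value and the two cutoffs.
#'
#' @param p p-value(s).
#' @param cutoffs two descending cutoffs, default `c(0.05, 0.01)`.
#' @return character vector of `"ns"`, `"*"`, `"**"` (NA stays NA).
#' @export
significance_stars <- function(p, cutoffs = c(0.05, 0.01)) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < cutoffs[2], "**", ifelse(p < cutoffs[1], "*", "ns")))
}

#' Two-tailed Student's t comparison of two cell groups
#'
#' The study-level statistical unit is the individual cell; groups are the
#' per-cell values of one metric under two conditions. Classic
#' equal-variance Student's t by default, Welch by flag. Means and
#' standard errors of the mean accompany the test. When both groups have
#' zero variance and equal means the p-value is undefined and reported
#' `NA` (flag `"degenerate"`) rather than fabricated.
#'
#' @param values_a,values_b numeric vectors, each with >= 2 finite values
#'   (non-finite values are dropped and counted).
#' @param labels condition labels `c(A, B)`.
#' @param metric metric name carried into the output row.
#' @param equal_variance `TRUE` for classic Student (default), `FALSE`
#'   for Welch.
#' @return one-row data.frame: `metric`, `condition_a`, `condition_b`,
#'   `n_a`, `n_b`, `dropped_a`, `dropped_b`, `mean_a`, `mean_b`, `sem_a`,
#'   `sem_b`, `t_statistic`, `p_value`, `stars`, `flags`.
#' @export
compare_groups <- function(values_a, values_b, labels = c("A", "B"),
                           metric = NA_character_, equal_variance = TRUE) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  dropped <- c(length(values_a) - length(a), length(values_b) - length(b))
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 finite values for a t-test")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  flags <- character(0)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # t.test refuses constant data; with equal means the statistic is 0/0
    if (mean(a) == mean(b)) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
      flags <- c(flags, "degenerate")
    } else {
      tt <- list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0)
      flags <- c(flags, "zero_variance")
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = equal_variance,
                        alternative = "two.sided")
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  data.frame(metric = metric, condition_a = labels[1],
             condition_b = labels[2], n_a = length(a), n_b = length(b),
             dropped_a = dropped[1], dropped_b = dropped[2],
             mean_a = mean(a), mean_b = mean(b),
             sem_a = sem(a), sem_b = sem(b),
             t_statistic = tt$statistic, p_value = tt$p.value,
             stars = significance_stars(tt$p.value),
             flags = paste(flags, collapse = ";"))
}

#' Batch comparison report over per-cell metric tables
#'
#' For every metric column and every pair of conditions, runs
#' [compare_groups()] and assembles the study-style report (mean ± s.e.m
#' per group, t, p, stars). Cell counts outside the 10-40 cells-per-
#' condition regime typical of per-cell quantitative microscopy raise a
#' warning (not an error). With a single condition, descriptive statistics
#' only. No multiple-testing correction is applied by default, matching
#' the single-comparison convention of per-panel reporting; set
#' `p_adjust = "BH"` to get Benjamini-Hochberg adjusted p-values (stars
#' then follow the adjusted values).
#'
#' @param metrics data.frame with a `cell_id` column and numeric metric
#'   columns.
#' @param conditions data.frame mapping `cell_id` to `condition`.
#' @param metric_cols which columns to compare; default all numeric
#'   columns except `cell_id`.
#' @param equal_variance passed to [compare_groups()].
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return list with `comparisons` (data.frame, may have 0 rows) and
#'   `descriptives` (per condition x metric: n, mean, sem).
#' @export
batch_report <- function(metrics, conditions, metric_cols = NULL,
                         equal_variance = TRUE,
                         p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot("cell_id" %in% names(metrics),
            all(c("cell_id", "condition") %in% names(conditions)))
  unknown <- setdiff(metrics$cell_id, conditions$cell_id)
  if (length(unknown) > 0)
    stop("cells without a condition label: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  df <- merge(metrics, conditions, by = "cell_id")
  if (is.null(metric_cols))
    metric_cols <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                           "cell_id")
  conds <- sort(unique(df$condition))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  desc <- do.call(rbind, lapply(conds, function(cnd) {
    do.call(rbind, lapply(metric_cols, function(m) {
      v <- df[[m]][df$condition == cnd]
      v <- v[is.finite(v)]
      data.frame(condition = cnd, metric = m, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) > 1) sem(v) else NA_real_)
    }))
  }))
  counts <- table(df$condition[!duplicated(df$cell_id)])
  if (any(counts < 10 | counts > 40))
    warning("cell count per condition outside the usual 10-40 regime: ",
            paste(names(counts), counts, sep = "=", collapse = ", "))
  comps <- list()
  if (length(conds) >= 2) {
    for (i in seq_len(length(conds) - 1L)) for (j in (i + 1L):length(conds))
      for (m in metric_cols) {
        va <- df[[m]][df$condition == conds[i]]
        vb <- df[[m]][df$condition == conds[j]]
        if (sum(is.finite(va)) < 2 || sum(is.finite(vb)) < 2) next
        comps[[length(comps) + 1L]] <-
          compare_groups(va, vb, labels = c(conds[i], conds[j]),
                         metric = m, equal_variance = equal_variance)
      }
  }
  comparisons <- if (length(comps)) do.call(rbind, comps) else
    data.frame()
  if (p_adjust == "BH" && nrow(comparisons) > 0) {
    comparisons$p_adjusted <- stats::p.adjust(comparisons$p_value, "BH")
    comparisons$stars <- significance_stars(comparisons$p_adjusted)
  }
  list(comparisons = comparisons, descriptives = desc)
}

#' Write a report bundle to disk
#'
#' Byte-stable CSV + JSON serialization of a [batch_report()] result for
#' fixed inputs.
#'
#' @param report a [batch_report()] list.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    comparisons = file.path(dir, "report_comparisons.csv"),
    descriptives = file.path(dir, "report_descriptives.csv"),
    json = file.path(dir, "report.json")
  )
  utils::write.csv(report$comparisons, paths["comparisons"],
                   row.names = FALSE)
  utils::write.csv(report$descriptives, paths["descriptives"],
                   row.names = FALSE)
  jsonlite::write_json(report, paths["json"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
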