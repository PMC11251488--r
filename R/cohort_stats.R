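# Descriptive comparison of slow vs fast decliners (Table-1-style).

#' Pearson chi-squared test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts from the margins, no
#' continuity correction, `df = (r-1)(c-1)`, p-value from the upper tail.
#'
#' @param contingency Counts matrix (>= 2 rows and columns).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_squared_test <- function(contingency) {
  m <- as.matrix(contingency)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least a 2x2 table")
  if (any(m < 0)) stop("counts must be non-negative")
  if (sum(m) <= 0) stop("table total must be positive")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0))
    stop("empty row margin at level ",
         paste(which(rs == 0), collapse = ", "))
  if (any(cs == 0))
    stop("empty column margin at level ",
         paste(which(cs == 0), collapse = ", "))
  ct <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Two-sample t-test
#'
#' Welch's unequal-variance t-test by default (`var_equal = TRUE` gives
#' Student's); two-sided. When both groups are constant with equal means the
#' statistic is 0 and p = 1 by convention (with a warning) rather than an
#' error.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2; NAs dropped).
#' @param var_equal Assume equal variances (default `FALSE` = Welch).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
t_test_groups <- function(group_a, group_b, var_equal = FALSE) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      warning("both groups constant with equal means; p = 1 by convention")
      return(list(statistic = 0, df = NA_real_, p_value = 1))
    }
    stop("both groups constant with different means; t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

TABLE_ONE_VARS <- list(
  sex = "categorical", age = "continuous", cag = "continuous",
  isced = "continuous", marital = "categorical", residence = "categorical",
  alcohol_units = "continuous", tobacco = "categorical",
  coffee = "categorical", drugs = "categorical", bmi = "continuous",
  cmb_cardio = "categorical", cmb_metab = "categorical",
  cmb_neuro = "categorical", cmb_psych = "categorical",
  cmb_other = "categorical", rx_anx = "categorical", rx_dep = "categorical",
  cuhdrs = "continuous", tfc = "continuous", tms = "continuous",
  sdmt = "continuous", swr = "continuous", followup_years = "continuous")

#' Table-1-style comparison of slow vs fast decliners
#'
#' One row per cohort variable: categorical variables summarised as n (%)
#' per level and compared with Pearson's chi-squared test; continuous
#' variables summarised as mean (SD) and compared with a t-test (Welch by
#' default). Baseline covariates are taken from the baseline table;
#' cUHDRS, its four components (at the subject's first visit), and
#' follow-up duration from the visits table.
#'
#' @param visits,baseline Cohort tables.
#' @param labels Data frame `subjid`, `label` from [classify_decliners()];
#'   subjects with `NA` labels are dropped.
#' @param var_equal Passed to [t_test_groups()].
#' @return Data frame of class `"table_one"`: `variable`, `level`, `type`,
#'   per-group `n`/`percent` or `mean`/`sd`, `test`, `statistic`, `p_value`
#'   (test results on the first row of each variable).
#' @export
build_table_one <- function(visits, baseline, labels, var_equal = FALSE) {
  if (!"cuhdrs" %in% names(visits)) visits <- score_visits(visits, warn_range = FALSE)
  lab <- labels[!is.na(labels$label), c("subjid", "label")]
  d <- merge(baseline, lab, by = "subjid")
  ord <- order(visits$subjid, visits$visit_age)
  visits <- visits[ord, , drop = FALSE]
  fv <- visits[!duplicated(visits$subjid),
               c("subjid", "visit_age", "cuhdrs", "tfc", "tms", "sdmt", "swr")]
  names(fv)[names(fv) == "visit_age"] <- "age"
  d <- merge(d, fv, by = "subjid", all.x = TRUE)
  fu <- delta_cuhdrs_per_time(visits)
  d <- merge(d, fu[, c("subjid", "followup_years")], by = "subjid",
             all.x = TRUE)

  rows <- list()
  for (v in names(TABLE_ONE_VARS)) {
    if (!v %in% names(d)) next
    type <- TABLE_ONE_VARS[[v]]
    slow <- d[[v]][d$label == "slow"]
    fast <- d[[v]][d$label == "fast"]
    if (type == "continuous") {
      res <- tryCatch(t_test_groups(slow, fast, var_equal = var_equal),
                      error = function(e) list(statistic = NA_real_,
                                               df = NA_real_,
                                               p_value = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_, type = type,
        slow_n = sum(!is.na(slow)), slow_mean = mean(slow, na.rm = TRUE),
        slow_sd = stats::sd(slow, na.rm = TRUE),
        fast_n = sum(!is.na(fast)), fast_mean = mean(fast, na.rm = TRUE),
        fast_sd = stats::sd(fast, na.rm = TRUE),
        slow_percent = NA_real_, fast_percent = NA_real_,
        test = "t_test", statistic = res$statistic, p_value = res$p_value,
        stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(d[[v]]), d$label)
      if (nrow(tab) < 2 || any(rowSums(tab) == 0)) {
        res <- list(statistic = NA_real_, p_value = NA_real_)
      } else {
        # small-expected-count caveats are a property of small tables, not
        # worth a warning per variable in a descriptive summary
        res <- tryCatch(suppressWarnings(chi_squared_test(tab)),
                        error = function(e) list(statistic = NA_real_,
                                                 p_value = NA_real_))
      }
      lev <- rownames(tab)
      for (li in seq_along(lev)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lev[li], type = type,
          slow_n = tab[li, "slow"], slow_mean = NA_real_, slow_sd = NA_real_,
          fast_n = tab[li, "fast"], fast_mean = NA_real_, fast_sd = NA_real_,
          slow_percent = 100 * tab[li, "slow"] / sum(tab[, "slow"]),
          fast_percent = 100 * tab[li, "fast"] / sum(tab[, "fast"]),
          test = "chi_squared",
          statistic = if (li == 1) res$statistic else NA_real_,
          p_value = if (li == 1) res$p_value else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("table_one", "data.frame")
  out
}

#' Render a table-one as aligned plain text
#'
#' @param x A `"table_one"` data frame.
#' @param file Optional path; when given, the text is written there.
#' @return The text lines, invisibly when `file` is given.
#' @export
format_table_one <- function(x, file = NULL) {
  fmt_row <- function(r) {
    desc <- if (r$type == "continuous")
      sprintf("%.2f (%.2f) | %.2f (%.2f)",
              r$slow_mean, r$slow_sd, r$fast_mean, r$fast_sd)
    else
      sprintf("%d (%.1f%%) | %d (%.1f%%)",
              r$slow_n, r$slow_percent, r$fast_n, r$fast_percent)
    name <- if (is.na(r$level)) r$variable else
      paste0(r$variable, " = ", r$level)
    p <- if (is.na(r$p_value)) "" else
      if (r$p_value < 0.001) "p < 0.001" else sprintf("p = %.3f", r$p_value)
    sprintf("%-28s %-34s %s", name, desc, p)
  }
  lines <- c(sprintf("%-28s %-34s %s", "variable", "slow | fast", "test"),
             vapply(seq_len(nrow(x)), function(i) fmt_row(x[i, ]), ""))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
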