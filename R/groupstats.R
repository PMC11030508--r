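# Two-group comparisons used throughout the study: Welch's t-test on the
# means and the F-test on the variances, plus longitudinal per-week
# contrasts over a feature table.

group_comparison <- function(test, statistic, df, p, n1, n2, flag = NA_character_) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_two_tailed = p, n1 = n1, n2 = n2, flag = flag),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  dftxt <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("%s: statistic %.4g, df (%s), two-tailed p = %.4g%s\n",
              x$test, x$statistic, dftxt, x$p_two_tailed,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Two-tailed unpaired t-test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom).  Degenerate zero-variance
#' inputs are handled explicitly: equal means give t = 0, p = 1; unequal
#' means give p = 0 with a flag.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return a `group_comparison`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stopf("each sample needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(group_comparison("welch_t", 0, Inf, 1, length(x), length(y)))
    return(group_comparison("welch_t", sign(mean(x) - mean(y)) * Inf, Inf, 0,
                            length(x), length(y), flag = "zero-variance, unequal means"))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  group_comparison("welch_t", unname(tt$statistic), unname(tt$parameter),
                   tt$p.value, length(x), length(y))
}

#' Two-tailed F-test for equality of variances
#'
#' F = s1^2 / s2^2 with (n1-1, n2-1) degrees of freedom; the two-tailed p
#' is 2 min(P(F' <= F), P(F' >= F)) under the null F distribution.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return a `group_comparison`.
#' @export
variance_f_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stopf("each sample needs n >= 2")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v2 == 0) stopf("denominator sample has zero variance")
  f <- v1 / v2
  df <- c(length(x) - 1, length(y) - 1)
  cdf <- stats::pf(f, df[1], df[2])
  group_comparison("variance_f", f, df, min(1, 2 * min(cdf, 1 - cdf)),
                   length(x), length(y))
}

#' Per-week group comparisons and pre/post-switch summaries
#'
#' For each feature and week with at least `min_n` organoids per group,
#' compares control vs experimental organoid-level means (tiles are
#' averaged within organoid first) with Welch's t-test and the variance
#' F-test.  Also pools each group's organoid means before and after the
#' differentiation switch.
#'
#' @param ft a `feature_table` (or plain data.frame) with columns `group`
#'   (`"control"`/`"experimental"`), `week`, `organoid`, plus feature
#'   columns.
#' @param features which features to compare (default: all).
#' @param switch_week the week of the medium switch; weeks strictly greater
#'   are "post".
#' @param min_n minimum organoids per group per week (default 2); weeks
#'   below it are skipped and listed in `skipped`.
#' @return object of class `longitudinal_comparison`: list with `per_week`
#'   (data.frame of test results), `prepost` (pooled distribution
#'   summaries) and `skipped`.
#' @export
longitudinal_compare <- function(ft, features = NULL, switch_week = 2,
                                 min_n = 2) {
  need <- c("group", "week", "organoid")
  if (!all(need %in% names(ft)))
    stopf("feature table must have columns %s", paste(need, collapse = ", "))
  if (is.null(features)) features <- feature_names(ft)
  features <- intersect(features, names(ft))
  # organoid-level means
  agg <- stats::aggregate(ft[features],
                          by = list(group = ft$group, week = ft$week,
                                    organoid = ft$organoid), FUN = mean)
  res <- NULL; skipped <- NULL
  for (w in sort(unique(agg$week))) {
    aw <- agg[agg$week == w, ]
    xc <- aw[aw$group == "control", ]
    xe <- aw[aw$group == "experimental", ]
    if (nrow(xc) < min_n || nrow(xe) < min_n) {
      skipped <- rbind(skipped, data.frame(week = w, n_control = nrow(xc),
                                           n_experimental = nrow(xe)))
      next
    }
    for (f in features) {
      wt <- welch_t_test(xc[[f]], xe[[f]])
      ftst <- tryCatch(variance_f_test(xc[[f]], xe[[f]]),
                       error = function(e) NULL)
      res <- rbind(res, data.frame(
        feature = f, week = w, phase = if (w > switch_week) "post" else "pre",
        n_control = nrow(xc), n_experimental = nrow(xe),
        mean_control = mean(xc[[f]]), mean_experimental = mean(xe[[f]]),
        t_statistic = wt$statistic, t_df = wt$df, t_p = wt$p_two_tailed,
        f_statistic = if (is.null(ftst)) NA_real_ else ftst$statistic,
        f_p = if (is.null(ftst)) NA_real_ else ftst$p_two_tailed))
    }
  }
  prepost <- NULL
  for (f in features) for (g in unique(agg$group)) for (ph in c("pre", "post")) {
    sel <- agg$group == g &
      (if (ph == "post") agg$week > switch_week else agg$week <= switch_week)
    v <- agg[sel, f]
    if (!length(v)) next
    prepost <- rbind(prepost, data.frame(
      feature = f, group = g, phase = ph, n = length(v), mean = mean(v),
      sd = if (length(v) > 1) stats::sd(v) else NA_real_,
      q25 = unname(stats::quantile(v, 0.25)),
      q75 = unname(stats::quantile(v, 0.75))))
  }
  structure(list(per_week = res, prepost = prepost, skipped = skipped,
                 switch_week = switch_week),
            class = "longitudinal_comparison")
}

#' @export
print.longitudinal_comparison <- function(x, ...) {
  cat(sprintf("longitudinal comparison: %d feature x week contrasts (switch week %s)\n",
              if (is.null(x$per_week)) 0L else nrow(x$per_week), x$switch_week))
  if (!is.null(x$skipped))
    cat(sprintf("  skipped weeks (insufficient group size): %s\n",
                paste(x$skipped$week, collapse = ", ")))
  invisible(x)
}

#' Benjamini-Hochberg adjustment of a per-week comparison table
#' @param lc a `longitudinal_comparison`.
#' @param column `"t_p"` or `"f_p"`.
#' @return the `per_week` data.frame with an added `<column>_bh` column.
#' @export
adjust_bh <- function(lc, column = "t_p") {
  pw <- lc$per_week
  pw[[paste0(column, "_bh")]] <- stats::p.adjust(pw[[column]], "BH")
  pw
}
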