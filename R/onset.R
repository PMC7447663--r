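#' Summarize time to onset
#'
#' Median and quartiles (linear interpolation between order statistics,
#' quantile type 7), proportions within the bins (0, 12], (12, 24],
#' (24, 48], (48, Inf) weeks, and cumulative proportions at the 12, 24 and
#' 48 week cutoffs. Zero-week onsets fall in the first bin (the bins close
#' on the right, and a zero is "within 12 weeks").
#'
#' @param weeks Numeric vector of onset times in weeks (non-negative);
#'   missing values are dropped with a count kept.
#' @param cutoffs Cumulative cutoffs in weeks.
#' @return Object of class `onset_summary`: `n`, `median_weeks`,
#'   `q1_weeks`, `q3_weeks`, `bin_proportions`, `cumulative`.
#' @examples
#' summarize_onset(c(3, 5, 9, 13, 25))
#' @export
summarize_onset <- function(weeks, cutoffs = c(12, 24, 48)) {
  weeks <- weeks[!is.na(weeks)]
  if (any(weeks < 0)) stop("onset weeks must be >= 0", call. = FALSE)
  n <- length(weeks)
  edges <- c(0, 12, 24, 48, Inf)
  if (n == 0L) {
    out <- list(n = 0L, median_weeks = NA_real_, q1_weeks = NA_real_,
                q3_weeks = NA_real_,
                bin_proportions = stats::setNames(rep(NA_real_, 4),
                  c("(0,12]", "(12,24]", "(24,48]", "(48,Inf)")),
                cumulative = stats::setNames(rep(NA_real_, length(cutoffs)),
                                             paste0("<=", cutoffs)))
    class(out) <- "onset_summary"
    return(out)
  }
  q <- stats::quantile(weeks, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  bins <- cut(weeks, breaks = edges, right = TRUE, include.lowest = TRUE,
              labels = c("(0,12]", "(12,24]", "(24,48]", "(48,Inf)"))
  out <- list(
    n = n,
    median_weeks = q[2], q1_weeks = q[1], q3_weeks = q[3],
    bin_proportions = table(bins) / n,
    cumulative = stats::setNames(
      vapply(cutoffs, function(cc) mean(weeks <= cc), numeric(1)),
      paste0("<=", cutoffs))
  )
  out$bin_proportions <- stats::setNames(as.numeric(out$bin_proportions),
                                         names(out$bin_proportions))
  class(out) <- "onset_summary"
  out
}

#' @export
print.onset_summary <- function(x, ...) {
  if (x$n == 0L) {
    cat("Onset summary: no recorded onsets\n")
    return(invisible(x))
  }
  cat(sprintf("Onset summary: n = %d, median %.1f weeks (IQR %.1f-%.1f)\n",
              x$n, x$median_weeks, x$q1_weeks, x$q3_weeks))
  cat("  bins   :", paste(sprintf("%s %.1f%%", names(x$bin_proportions),
                                  100 * x$bin_proportions),
                          collapse = ", "), "\n")
  cat("  within :", paste(sprintf("%s wk %.1f%%",
                                  sub("<=", "", names(x$cumulative)),
                                  100 * x$cumulative), collapse = ", "), "\n")
  invisible(x)
}

# Log-transform onsets; same-day (zero-week) onsets are set to half a week,
# half the resolution unit, so they stay in the analysis.
log_onset <- function(weeks) {
  weeks <- weeks[!is.na(weeks)]
  if (any(weeks < 0)) stop("onset weeks must be >= 0", call. = FALSE)
  log(pmax(weeks, 0.5))
}

#' Compare time to onset between two groups
#'
#' Onset times are compared on the natural-log scale. A two-sided F test of
#' variance equality at `alpha = 0.05` selects the test: pooled two-sample
#' t when the gate does not reject, Welch's t otherwise. Two-sided p value.
#'
#' @param group_a,group_b Numeric vectors of onset weeks; each needs at
#'   least two usable values.
#' @param alpha Level of the variance gate.
#' @return Object of class `onset_test`: `test_name` (`pooled_t` or
#'   `welch_t`), `statistic`, `df`, `p_value`, `variance_gate_p`, `n`.
#' @examples
#' compare_onset_two(c(2, 4, 8), c(16, 32, 64))  # |t| = 3.674, p = 0.0213
#' @export
compare_onset_two <- function(group_a, group_b, alpha = 0.05) {
  la <- log_onset(group_a)
  lb <- log_onset(group_b)
  if (length(la) < 2L || length(lb) < 2L) {
    stop("insufficient data: each group needs >= 2 recorded onsets",
         call. = FALSE)
  }
  gate <- stats::var.test(la, lb)
  equal <- is.nan(gate$p.value) || gate$p.value >= alpha
  tt <- stats::t.test(la, lb, var.equal = equal)
  out <- list(test_name = if (equal) "pooled_t" else "welch_t",
              statistic = unname(tt$statistic),
              df = unname(tt$parameter),
              p_value = tt$p.value,
              variance_gate_p = gate$p.value,
              n = c(length(la), length(lb)))
  class(out) <- "onset_test"
  out
}

#' Compare time to onset across three or more groups
#'
#' One-way analysis of variance of log onset weeks: F statistic on
#' (k - 1, N - k) degrees of freedom.
#'
#' @param groups List of at least three numeric vectors of onset weeks,
#'   each with two or more usable values.
#' @return Object of class `onset_test` with `test_name = "anova"`.
#' @export
compare_onset_many <- function(groups) {
  if (!is.list(groups) || length(groups) < 3L) {
    stop("need >= 3 groups; use compare_onset_two() for two groups",
         call. = FALSE)
  }
  logs <- lapply(groups, log_onset)
  if (any(lengths(logs) < 2L)) {
    stop("insufficient data: each group needs >= 2 recorded onsets",
         call. = FALSE)
  }
  y <- unlist(logs)
  g <- factor(rep(seq_along(logs), lengths(logs)))
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  out <- list(test_name = "anova",
              statistic = unname(fit$statistic),
              df = unname(fit$parameter),
              p_value = fit$p.value,
              variance_gate_p = NA_real_,
              n = lengths(logs))
  class(out) <- "onset_test"
  out
}

#' @export
print.onset_test <- function(x, ...) {
  lab <- switch(x$test_name,
                pooled_t = "Two-sample t test (pooled variance)",
                welch_t = "Welch's t test",
                anova = "One-way ANOVA")
  cat(lab, "on log onset weeks\n")
  stat <- if (x$test_name == "anova") "F" else "t"
  cat(sprintf("  %s = %.3f, df = %s, p = %.4g\n", stat, x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p_value))
  if (!is.na(x$variance_gate_p)) {
    cat(sprintf("  variance gate (F test) p = %.4g\n", x$variance_gate_p))
  }
  invisible(x)
}
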