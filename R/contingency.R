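#' 2x2 case/non-case contingency table
#'
#' The unit of counting is the de-duplicated report. Cell `a` counts
#' reports with the selected exposure that match the event query, `b`
#' exposed non-matching, `c` unexposed matching, `d` neither. The expected
#' count under independence is `n_expected = (a + b) (a + c) / n`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return Object of class `contingency_2x2` with the four cells, `n` and
#'   `n_expected`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  n <- sum(cells)
  structure(list(a = a, b = b, c = c, d = d, n = n,
                 n_expected = if (n > 0) (a + b) * (a + c) / n else 0),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("exposed", "unexposed"),
                              c("event", "no event")))
  print(m)
  cat(sprintf("n = %d, expected a under independence = %.4g\n",
              x$n, x$n_expected))
  invisible(x)
}

#' Build the case/non-case table for one exposure and one event query
#'
#' Partitions a de-duplicated report set into the four cells of the
#' case/non-case design: rows by the exposure selector, columns by whether
#' the report matches the event query. Every report falls in exactly one
#' cell; a report with several matching terms counts once.
#'
#' @param reports A de-duplicated [icsr_set()].
#' @param exposure Either a logical vector (one per report) or a selector
#'   function mapping the `icsr_set` to such a vector.
#' @param catalog A [term_catalog()].
#' @param query A group name, term, or character vector of terms; see
#'   [resolve_query()].
#' @return A [contingency_table()].
#' @export
build_contingency <- function(reports, exposure, catalog, query) {
  stopifnot(is_icsr_set(reports))
  exposed <- if (is.function(exposure)) exposure(reports) else exposure
  exposed <- as.logical(exposed)
  if (length(exposed) != nrow(reports) || anyNA(exposed)) {
    stop("exposure must yield one non-missing logical per report",
         call. = FALSE)
  }
  hit <- match_query(reports, catalog, query)
  contingency_table(a = sum(exposed & hit),
                    b = sum(exposed & !hit),
                    c = sum(!exposed & hit),
                    d = sum(!exposed & !hit))
}

#' Information component of a 2x2 reporting table
#'
#' The shrinkage observed-to-expected measure of the BCPNN framework,
#' `IC = log2((a + 0.5) / (n_expected + 0.5))`, in bits. The additive 0.5
#' keeps the statistic defined at `a = 0` and pulls small-count
#' associations toward zero.
#'
#' @param table A [contingency_table()].
#' @return IC point estimate in bits.
#' @examples
#' information_component(contingency_table(50, 950, 150, 98850))
#' @export
information_component <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  if (table$n < 1) stop("undefined for an empty table", call. = FALSE)
  log2((table$a + 0.5) / (table$n_expected + 0.5))
}

#' Credibility bounds for the information component
#'
#' The default `"approx"` method is the asymptotic expansion used for
#' routine screening of large spontaneous-report databases:
#' \deqn{IC_{025} = IC - 3.3 (a + 0.5)^{-1/2} - 2 (a + 0.5)^{-3/2}}
#' \deqn{IC_{975} = IC + 2.4 (a + 0.5)^{-1/2} - 0.5 (a + 0.5)^{-3/2}}
#' A positive lower bound (`ic025 > 0`) is the conventional signal
#' threshold. Method `"gamma"` instead takes `log2` of the 2.5% and 97.5%
#' quantiles of a Gamma(`a + 0.5`, rate `n_expected + 0.5`) distribution
#' and is provided as a cross-check; it requires `n_expected`.
#'
#' @param ic IC point estimate in bits.
#' @param a Observed cell count (non-negative).
#' @param method `"approx"` (default) or `"gamma"`.
#' @param n_expected Expected count, needed for `method = "gamma"`.
#' @return Named numeric vector `c(ic025, ic975)`.
#' @examples
#' ic_credible_bounds(6.74, 747)   # reproduces a 6.62 lower bound
#' @export
ic_credible_bounds <- function(ic, a, method = c("approx", "gamma"),
                               n_expected = NULL) {
  method <- match.arg(method)
  if (any(a < 0)) stop("a must be non-negative", call. = FALSE)
  if (method == "approx") {
    s <- (a + 0.5)^-0.5
    s3 <- (a + 0.5)^-1.5
    c(ic025 = ic - 3.3 * s - 2 * s3,
      ic975 = ic + 2.4 * s - 0.5 * s3)
  } else {
    if (is.null(n_expected)) {
      stop("method 'gamma' needs n_expected", call. = FALSE)
    }
    q <- stats::qgamma(c(0.025, 0.975), shape = a + 0.5,
                       rate = n_expected + 0.5)
    c(ic025 = log2(q[1]), ic975 = log2(q[2]))
  }
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = (a d) / (b c)`; the 95% interval is
#' `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. With any zero cell
#' the ratio is flagged non-estimable rather than continuity-corrected —
#' screening applies a minimum-count rule instead.
#'
#' @param table A [contingency_table()].
#' @return Named list `ror`, `ror_low`, `ror_high`, `estimable`.
#' @examples
#' reporting_odds_ratio(contingency_table(20, 80, 10, 160))
#' @export
reporting_odds_ratio <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells == 0)) {
    return(list(ror = NA_real_, ror_low = NA_real_, ror_high = NA_real_,
                estimable = FALSE))
  }
  ror <- (table$a * table$d) / (table$b * table$c)
  half <- 1.96 * sqrt(sum(1 / cells))
  list(ror = ror,
       ror_low = exp(log(ror) - half),
       ror_high = exp(log(ror) + half),
       estimable = TRUE)
}

#' Signal-strength category from the IC lower bound
#'
#' Thresholds at 0, 3 and 5 bits, the boundaries recovered by 3-means
#' clustering of positive lower bounds across an endocrine screening run:
#' `none` (lower bound at or below 0), `weak` (between 0 and 3),
#' `moderate` (3 up to 5) and `strong` (5 and above).
#'
#' @param ic025 Numeric vector of IC lower bounds.
#' @return Factor with levels `none`, `weak`, `moderate`, `strong`.
#' @export
classify_signal <- function(ic025) {
  lab <- ifelse(is.na(ic025), NA_character_,
         ifelse(ic025 <= 0, "none",
         ifelse(ic025 < 3, "weak",
         ifelse(ic025 < 5, "moderate", "strong"))))
  factor(lab, levels = c("none", "weak", "moderate", "strong"))
}

#' Cluster positive IC lower bounds into three strength bands
#'
#' One-dimensional 3-means clustering with deterministic initialization at
#' the minimum, median and maximum of the distinct values (Lloyd
#' iterations), returning the two boundaries between adjacent clusters as
#' midpoints between neighbouring cluster extremes. This is the procedure
#' that motivates the fixed 3 and 5 bit thresholds of [classify_signal()].
#'
#' @param values Numeric vector of positive IC lower bounds with at least
#'   three distinct values.
#' @return List with `boundaries` (length 2), `centers` (length 3) and
#'   `cluster` (integer assignment, 1 = weakest band).
#' @examples
#' cluster_ic025(c(1.0, 1.1, 3.9, 4.0, 6.9, 7.0))$boundaries  # 2.5, 5.45
#' @export
cluster_ic025 <- function(values) {
  values <- as.numeric(values)
  if (any(values <= 0) || anyNA(values)) {
    stop("values must be positive IC lower bounds", call. = FALSE)
  }
  u <- sort(unique(values))
  if (length(u) < 3L) {
    stop("insufficient data: need at least 3 distinct positive values",
         call. = FALSE)
  }
  init <- c(min(u), stats::median(u), max(u))
  if (anyDuplicated(init)) init <- u[round(c(1, length(u) / 2, length(u)))]
  fit <- stats::kmeans(values, centers = matrix(init, ncol = 1),
                       algorithm = "Lloyd", iter.max = 100L)
  ord <- order(fit$centers[, 1])
  cluster <- match(fit$cluster, ord)
  boundaries <- vapply(1:2, function(k) {
    (max(values[cluster == k]) + min(values[cluster == k + 1])) / 2
  }, numeric(1))
  list(boundaries = boundaries,
       centers = sort(fit$centers[, 1]),
       cluster = cluster)
}
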