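#' Fit a case/non-case disproportionality model
#'
#' The central estimator of the package: for one exposure definition and
#' one adverse-event query it builds the 2x2 case/non-case table over the
#' whole loaded report set (the "full database" plays the contrast role),
#' computes the information component with its 95% credibility bounds, the
#' reporting odds ratio with its Woolf 95% confidence interval, applies the
#' significance rules — `ic025 > 0` for the IC; lower CI bound above 1
#' together with a minimum observed count `a >= min_count` for the ROR —
#' and assigns the signal-strength category of [classify_signal()].
#'
#' @param reports A de-duplicated [icsr_set()].
#' @param exposure Logical vector or selector function; see
#'   [build_contingency()].
#' @param query Group name, preferred term, or character vector of terms.
#' @param catalog A [term_catalog()]; defaults to the shipped endocrine
#'   catalog.
#' @param ic_method `"approx"` (default) or `"gamma"`; see
#'   [ic_credible_bounds()].
#' @param min_count Minimum observed count for ROR significance (default 3).
#' @param exposure_label Optional label stored in the result.
#' @return An object of class `disprop`: a list with the contingency
#'   `table`, `ic`, `ic025`, `ic975`, `ror`, `ror_low`, `ror_high`,
#'   `ror_estimable`, `ic_significant`, `ror_significant`, `category`,
#'   and the labels. Supported methods: `print`, `summary`, `coef`,
#'   `confint`.
#' @examples
#' cat <- builtin_endocrine_catalog()
#' x <- icsr_set(sprintf("R%02d", 1:12),
#'               drugs = rep(list("nivolumab", "warfarin"), 6),
#'               events = c(rep("hypophysitis", 4),
#'                          rep("thyroiditis", 8)))
#' fit <- disprop(x, function(r) vapply(r$drugs, function(d)
#'                  "nivolumab" %in% d, logical(1)), "hypophysitis", cat)
#' fit
#' coef(fit)
#' @export
disprop <- function(reports, exposure, query,
                    catalog = builtin_endocrine_catalog(),
                    ic_method = c("approx", "gamma"),
                    min_count = 3,
                    exposure_label = "exposure") {
  ic_method <- match.arg(ic_method)
  tab <- build_contingency(reports, exposure, catalog, query)
  q <- resolve_query(catalog, query)
  disprop_from_table(tab, ic_method = ic_method, min_count = min_count,
                     exposure_label = exposure_label, query_label = q$name)
}

# Statistics layer shared by disprop(), screen_spectrum(), compare_subgroups().
disprop_from_table <- function(table, ic_method = "approx", min_count = 3,
                               exposure_label = "exposure",
                               query_label = "query") {
  ic <- if (table$n >= 1) information_component(table) else NA_real_
  bounds <- if (is.na(ic)) c(ic025 = NA_real_, ic975 = NA_real_) else {
    ic_credible_bounds(ic, table$a, method = ic_method,
                       n_expected = table$n_expected)
  }
  ror <- reporting_odds_ratio(table)
  out <- list(
    exposure = exposure_label,
    query = query_label,
    table = table,
    ic = ic,
    ic025 = unname(bounds[1]),
    ic975 = unname(bounds[2]),
    ror = ror$ror,
    ror_low = ror$ror_low,
    ror_high = ror$ror_high,
    ror_estimable = ror$estimable,
    ic_significant = !is.na(bounds[1]) && bounds[1] > 0,
    ror_significant = isTRUE(ror$estimable) && ror$ror_low > 1 &&
      table$a >= min_count,
    category = classify_signal(unname(bounds[1])),
    ic_method = ic_method,
    min_count = min_count
  )
  class(out) <- "disprop"
  out
}

#' @export
print.disprop <- function(x, ...) {
  cat("Disproportionality signal: ", x$exposure, " ~ ", x$query, "\n", sep = "")
  cat(sprintf("  a = %d (expected %.2f), n = %d\n",
              x$table$a, x$table$n_expected, x$table$n))
  cat(sprintf("  IC  = %.2f bits, 95%% CI (%.2f, %.2f)%s\n",
              x$ic, x$ic025, x$ic975,
              if (x$ic_significant) " *" else ""))
  if (x$ror_estimable) {
    cat(sprintf("  ROR = %.2f, 95%% CI (%.2f, %.2f)%s\n",
                x$ror, x$ror_low, x$ror_high,
                if (x$ror_significant) " *" else ""))
  } else {
    cat("  ROR not estimable (zero cell)\n")
  }
  cat("  category:", as.character(x$category), "\n")
  invisible(x)
}

#' @export
summary.disprop <- function(object, ...) {
  print(object$table)
  print(object)
  invisible(object)
}

#' @export
coef.disprop <- function(object, ...) {
  c(ic = object$ic, ror = object$ror)
}

#' @export
confint.disprop <- function(object, parm = c("ic", "ror"), level = 0.95, ...) {
  if (!isTRUE(all.equal(level, 0.95))) {
    stop("only the 95% level is computed", call. = FALSE)
  }
  parm <- match.arg(parm, several.ok = TRUE)
  m <- rbind(ic = c(object$ic025, object$ic975),
             ror = c(object$ror_low, object$ror_high))
  colnames(m) <- c("2.5 %", "97.5 %")
  m[parm, , drop = FALSE]
}

as_row <- function(fit) {
  data.frame(exposure = fit$exposure, query = fit$query,
             a = fit$table$a, b = fit$table$b, c = fit$table$c,
             d = fit$table$d, n_expected = fit$table$n_expected,
             ic = fit$ic, ic025 = fit$ic025, ic975 = fit$ic975,
             ror = fit$ror, ror_low = fit$ror_low, ror_high = fit$ror_high,
             ic_significant = fit$ic_significant,
             ror_significant = fit$ror_significant,
             category = as.character(fit$category),
             stringsAsFactors = FALSE)
}

#' Screen a reporting database for disproportionality signals
#'
#' Runs [disprop()] for every (exposure selector, query) pair and returns
#' one row per pair, sorted by descending IC lower bound. By default the
#' queries are every group of the catalog plus every individual preferred
#' term, giving the full toxicity spectrum for each exposure.
#'
#' @param reports A de-duplicated [icsr_set()].
#' @param catalog A [term_catalog()].
#' @param exposures Named list of selector functions (or logical vectors);
#'   see [exposure_selectors()].
#' @param queries Character vector of group names and/or terms screened for
#'   each exposure; defaults to all groups then all terms.
#' @inheritParams disprop
#' @return Data frame of class `signal_screen` with columns `exposure`,
#'   `query`, the four cells, `n_expected`, `ic`, `ic025`, `ic975`, `ror`,
#'   `ror_low`, `ror_high`, `ic_significant`, `ror_significant`,
#'   `category`.
#' @export
screen_spectrum <- function(reports, catalog = builtin_endocrine_catalog(),
                            exposures = exposure_selectors(),
                            queries = c(names(catalog$groups), catalog$terms),
                            ic_method = c("approx", "gamma"),
                            min_count = 3) {
  ic_method <- match.arg(ic_method)
  stopifnot(is_icsr_set(reports), length(exposures) > 0,
            !is.null(names(exposures)))
  hits <- vapply(queries,
                 function(q) match_query(reports, catalog, q),
                 logical(nrow(reports)))
  if (nrow(reports) == 1L) hits <- matrix(hits, nrow = 1L)
  rows <- vector("list", length(exposures) * length(queries))
  k <- 0L
  for (ex in names(exposures)) {
    sel <- exposures[[ex]]
    exposed <- if (is.function(sel)) sel(reports) else as.logical(sel)
    for (j in seq_along(queries)) {
      hit <- hits[, j]
      tab <- contingency_table(sum(exposed & hit), sum(exposed & !hit),
                               sum(!exposed & hit), sum(!exposed & !hit))
      fit <- disprop_from_table(tab, ic_method = ic_method,
                                min_count = min_count,
                                exposure_label = ex,
                                query_label = queries[j])
      k <- k + 1L
      rows[[k]] <- as_row(fit)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$ic025, out$exposure, out$query), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signal_screen", "data.frame")
  out
}

#' @export
print.signal_screen <- function(x, n = 10L, ...) {
  cat("Disproportionality screen:", nrow(x), "(exposure, query) pairs;",
      sum(x$ic_significant), "with ic025 > 0\n")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 3)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' Compare event reporting between two disjoint exposure subgroups
#'
#' Restricts the analysis to reports selected by either subgroup and puts
#' subgroup A in the "selected" row and subgroup B in the contrast row of
#' the 2x2 table, so the ROR measures how much more often the query is
#' reported under A than under B. The `a >= min_count` rule applies as in
#' screening.
#'
#' @param reports A de-duplicated [icsr_set()].
#' @param selector_a,selector_b Disjoint selector functions or logical
#'   vectors defining the two subgroups.
#' @inheritParams disprop
#' @param labels Character vector of length 2 naming the subgroups.
#' @return A `disprop` object for the A-vs-B contrast.
#' @export
compare_subgroups <- function(reports, selector_a, selector_b, query,
                              catalog = builtin_endocrine_catalog(),
                              ic_method = c("approx", "gamma"),
                              min_count = 3,
                              labels = c("group_a", "group_b")) {
  ic_method <- match.arg(ic_method)
  stopifnot(is_icsr_set(reports))
  in_a <- if (is.function(selector_a)) selector_a(reports) else
    as.logical(selector_a)
  in_b <- if (is.function(selector_b)) selector_b(reports) else
    as.logical(selector_b)
  if (any(in_a & in_b)) {
    stop("design error: subgroup selectors overlap", call. = FALSE)
  }
  sub <- reports[in_a | in_b, , drop = FALSE]
  class(sub) <- c("icsr_set", "data.frame")
  fit <- disprop(sub, exposure = in_a[in_a | in_b], query = query,
                 catalog = catalog, ic_method = ic_method,
                 min_count = min_count,
                 exposure_label = paste(labels[1], "vs", labels[2]))
  fit
}
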