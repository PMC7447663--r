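#' Descriptive summary of a report set by exposure stratum
#'
#' Counts and percentages per stratum (total plus each exposure class that
#' occurs) for year, gender, age group, region, notifier, indication and
#' final outcome. Denominators follow the n/N convention: for each field
#' only reports with a known value enter the denominator, so percentages
#' within a field sum to 100 up to rounding. Also reports the
#' male-to-female ratio (rounded to one decimal), the fraction of reports
#' with a medically critical ("fatal-type") outcome among reports with any
#' final outcome recorded, and the recovered fraction on the same
#' denominator.
#'
#' @param reports A de-duplicated [icsr_set()].
#' @param exposure Optional factor of exposure labels (defaults to
#'   [classify_exposure()]).
#' @return Object of class `icsr_descriptive`: list with `n`, `strata`
#'   (per-stratum list of per-field count/percent data frames),
#'   `male_female_ratio`, `fatal_fraction`, `recovered_fraction`, and
#'   `outcome_n` (reports with a final outcome recorded).
#' @export
descriptive_summary <- function(reports, exposure = NULL) {
  stopifnot(is_icsr_set(reports))
  if (is.null(exposure)) exposure <- classify_exposure(reports)
  exposure <- as.factor(exposure)
  stopifnot(length(exposure) == nrow(reports))

  field_table <- function(values) {
    known <- !is.na(values) & values != "unknown"
    denom <- sum(known)
    tab <- table(values[known])
    data.frame(level = names(tab),
               n = as.integer(tab),
               denominator = rep(denom, length(tab)),
               percent = if (denom > 0) round(100 * as.integer(tab) / denom,
                                              1) else rep(NA_real_,
                                                          length(tab)),
               stringsAsFactors = FALSE)
  }

  final_outcome <- function(x) {
    # one final-outcome label per report for tabulation: fatal-type beats
    # not_recovered beats recovered; unknown when nothing recorded
    critical <- c("death", "life_threatening", "hospitalization",
                  "other_medically_critical")
    vapply(x$outcomes, function(o) {
      if (any(o %in% critical)) "fatal"
      else if ("not_recovered" %in% o) "not_recovered"
      else if ("recovered" %in% o) "recovered"
      else "unknown"
    }, character(1))
  }

  summarize_stratum <- function(x) {
    list(n = nrow(x),
         year = field_table(ifelse(is.na(x$year), "unknown",
                                   as.character(x$year))),
         gender = field_table(x$gender),
         age_group = field_table(x$age_group),
         region = field_table(x$region),
         notifier = field_table(x$notifier),
         indication = field_table(x$indication),
         outcome = field_table(final_outcome(x)))
  }

  strata <- c(list(total = reports),
              split(as.data.frame(reports), exposure, drop = TRUE))
  strata <- lapply(strata, function(s) {
    class(s) <- c("icsr_set", "data.frame")
    summarize_stratum(s)
  })

  n_male <- sum(reports$gender == "male")
  n_female <- sum(reports$gender == "female")
  fo <- final_outcome(reports)
  outcome_n <- sum(fo != "unknown")
  out <- list(
    n = nrow(reports),
    strata = strata,
    male_female_ratio = if (n_female > 0) round(n_male / n_female, 1)
                        else NA_real_,
    fatal_fraction = if (outcome_n > 0) sum(fo == "fatal") / outcome_n
                     else NA_real_,
    recovered_fraction = if (outcome_n > 0) sum(fo == "recovered") / outcome_n
                         else NA_real_,
    outcome_n = outcome_n
  )
  class(out) <- "icsr_descriptive"
  out
}

#' @export
print.icsr_descriptive <- function(x, ...) {
  cat("Descriptive summary:", x$n, "de-duplicated reports\n")
  if (!is.na(x$male_female_ratio)) {
    cat(sprintf("  male:female ratio %.1f:1\n", x$male_female_ratio))
  }
  if (x$outcome_n > 0) {
    cat(sprintf("  final outcome recorded for %d; fatal-type %.1f%%, recovered %.1f%%\n",
                x$outcome_n, 100 * x$fatal_fraction,
                100 * x$recovered_fraction))
  }
  cat("  strata:", paste(names(x$strata), collapse = ", "), "\n")
  invisible(x)
}

# Flatten the descriptive summary to one long exportable data frame.
descriptive_to_frame <- function(desc) {
  rows <- list()
  for (s in names(desc$strata)) {
    st <- desc$strata[[s]]
    for (f in setdiff(names(st), "n")) {
      tab <- st[[f]]
      if (!nrow(tab)) next
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(stratum = s, field = f,
                         stringsAsFactors = FALSE), tab)
    }
  }
  if (!length(rows)) {
    return(data.frame(stratum = character(), field = character(),
                      level = character(), n = integer(),
                      denominator = integer(), percent = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
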