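#' Configuration for the synthetic ICSR generator
#'
#' Builds and validates the configuration consumed by [simulate_icsr()].
#' The defaults emulate, at desk scale, the structure of a worldwide
#' spontaneous-report database restricted to the checkpoint-inhibitor era:
#' a large background of non-ICI reports, five ICI drugs with prevalences
#' ordered as in real reporting (nivolumab > pembrolizumab > ipilimumab >
#' anti-PD-L1), a combination-therapy arm (ipilimumab plus an
#' anti-PD-1/PD-L1), endocrine event terms at low baseline reporting
#' probabilities, and planted relative-reporting-rate multipliers that
#' reproduce the qualitative toxicity pattern (anti-CTLA-4 toward
#' hypophysitis/adrenal insufficiency, anti-PD-1 toward thyroid dysfunction
#' and insulin-deficient diabetes). Demographic marginals, missingness
#' rates and outcome proportions follow the descriptive profile of
#' ICI endocrinopathy reports.
#'
#' @param n_reports Number of base reports (before duplicate injection).
#' @param drug_menu Data frame with columns `drug`, `class`
#'   (`CTLA4`/`PD1`/`PDL1`/`other`), `prob` (marginal exposure
#'   probability).
#' @param event_menu Data frame with columns `event`, `prob` (baseline
#'   reporting probability per report).
#' @param signal_specs Data frame with columns `drug`, `event`,
#'   `multiplier`; when the drug is present the event probability becomes
#'   `min(1, baseline * multiplier)`. Multipliers for several present drugs
#'   combine by maximum.
#' @param combo_probability Probability that a report is forced to carry
#'   ipilimumab plus one anti-PD-1/PD-L1 drug.
#' @param onset_model Named list of `c(meanlog, sdlog)` pairs keyed
#'   `"<exposure class>:<group>"`, plus a `default` entry; onset weeks are
#'   log-normal.
#' @param duplicate_rate Probability a report is emitted twice under the
#'   same ID (see [inject_duplicates()]); applied by [simulate_icsr()]
#'   after generation.
#' @param missing_rates Named numeric vector of per-field missingness
#'   probabilities (fields `year`, `gender`, `age_group`, `region`,
#'   `notifier`, `indication`, `onset_weeks`, `outcomes`).
#' @param seed Integer master seed; every draw derives from it.
#' @return Object of class `icsr_sim_config`.
#' @export
simulate_config <- function(n_reports = 50000,
                            drug_menu = default_drug_menu(),
                            event_menu = default_event_menu(),
                            signal_specs = default_signal_specs(),
                            combo_probability = 0.004,
                            onset_model = default_onset_model(),
                            duplicate_rate = 0.02,
                            missing_rates = default_missing_rates(),
                            seed = 20110101) {
  stopifnot(n_reports >= 1,
            is.data.frame(drug_menu),
            all(c("drug", "class", "prob") %in% names(drug_menu)),
            is.data.frame(event_menu),
            all(c("event", "prob") %in% names(event_menu)))
  probs <- c(drug_menu$prob, event_menu$prob, combo_probability,
             duplicate_rate, missing_rates)
  if (any(probs < 0 | probs > 1 | is.na(probs))) {
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(signal_specs) && nrow(signal_specs)) {
    stopifnot(all(c("drug", "event", "multiplier") %in% names(signal_specs)))
    if (any(!is.finite(signal_specs$multiplier)) ||
        any(signal_specs$multiplier < 0)) {
      stop("config error: multipliers must be finite and >= 0",
           call. = FALSE)
    }
  }
  sd_ok <- vapply(onset_model, function(p) is.finite(p[2]) && p[2] > 0,
                  logical(1))
  if (!all(sd_ok) || is.null(onset_model$default)) {
    stop("config error: onset_model needs positive sdlog and a default",
         call. = FALSE)
  }
  structure(list(n_reports = as.integer(n_reports),
                 drug_menu = drug_menu, event_menu = event_menu,
                 signal_specs = signal_specs,
                 combo_probability = combo_probability,
                 onset_model = onset_model,
                 duplicate_rate = duplicate_rate,
                 missing_rates = missing_rates,
                 seed = as.integer(seed)),
            class = "icsr_sim_config")
}

#' @rdname simulate_config
#' @export
default_drug_menu <- function() {
  data.frame(
    drug = c("ipilimumab", "nivolumab", "pembrolizumab", "atezolizumab",
             "durvalumab",
             "comparator_a", "comparator_b", "comparator_c", "comparator_d"),
    class = c("CTLA4", "PD1", "PD1", "PDL1", "PDL1",
              "other", "other", "other", "other"),
    prob = c(0.010, 0.022, 0.013, 0.002, 0.002,
             0.30, 0.25, 0.20, 0.15),
    stringsAsFactors = FALSE
  )
}

#' @rdname simulate_config
#' @export
default_event_menu <- function() {
  cat <- builtin_endocrine_catalog()
  rare <- c("thyrotoxic crisis", "basedow's disease",
            "lymphocytic hypophysitis", "pituitary enlargement",
            "acute adrenocortical insufficiency", "diabetes insipidus",
            "hypoparathyroidism", "hypogonadism",
            "inappropriate antidiuretic hormone secretion")
  data.frame(
    event = c(cat$terms, "nausea", "rash", "fatigue", "headache"),
    prob = c(ifelse(cat$terms %in% rare, 0.0002, 0.001),
             0.10, 0.08, 0.07, 0.06),
    stringsAsFactors = FALSE
  )
}

#' @rdname simulate_config
#' @export
default_signal_specs <- function() {
  rbind(
    expand.grid(drug = "ipilimumab",
                event = c("hypophysitis", "hypopituitarism",
                          "adrenal insufficiency",
                          "lymphocytic hypophysitis"),
                multiplier = 60, stringsAsFactors = FALSE),
    expand.grid(drug = c("nivolumab", "pembrolizumab"),
                event = c("hypothyroidism", "hyperthyroidism",
                          "thyroiditis"),
                multiplier = 25, stringsAsFactors = FALSE),
    expand.grid(drug = c("nivolumab", "pembrolizumab"),
                event = c("type 1 diabetes mellitus",
                          "fulminant type 1 diabetes mellitus",
                          "diabetic ketoacidosis"),
                multiplier = 20, stringsAsFactors = FALSE),
    expand.grid(drug = c("atezolizumab", "durvalumab"),
                event = c("hypothyroidism", "hyperthyroidism"),
                multiplier = 15, stringsAsFactors = FALSE)
  )
}

#' @rdname simulate_config
#' @export
default_onset_model <- function() {
  list(
    default = c(meanlog = log(12), sdlog = 0.9),
    `ipilimumab_mono:hypophysitis_hypopituitarism` =
      c(meanlog = log(9), sdlog = 0.5),
    `ipilimumab_mono:thyroid_dysfunction` = c(meanlog = log(9), sdlog = 0.5),
    `ipilimumab_mono:adrenal_insufficiency_group` =
      c(meanlog = log(10), sdlog = 0.5),
    `nivolumab_mono:thyroid_dysfunction` = c(meanlog = log(8), sdlog = 0.9),
    `nivolumab_mono:ICI-DM` = c(meanlog = log(17), sdlog = 1.0),
    `pembrolizumab_mono:ICI-DM` = c(meanlog = log(13), sdlog = 0.9),
    `combination:thyroid_dysfunction` = c(meanlog = log(7), sdlog = 0.7),
    `combination:adrenal_insufficiency_group` =
      c(meanlog = log(13), sdlog = 0.7)
  )
}

#' @rdname simulate_config
#' @export
default_missing_rates <- function() {
  c(year = 0.005, gender = 0.06, age_group = 0.26, region = 0.01,
    notifier = 0.03, indication = 0.12, onset_weeks = 0.55,
    outcomes = 0.41)
}

# Run code under a derived RNG substream without touching the caller's RNG.
with_substream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% 2147483647L)
  force(code)
}

#' Generate a synthetic ICSR database
#'
#' Draws `n_reports` reports under the configured model: per-drug
#' independent Bernoulli exposure (empty draws rejection-resampled), a
#' forced combination-therapy arm, per-term independent Bernoulli events
#' whose probability is the baseline times the largest applicable signal
#' multiplier (clipped to 1; empty draws resampled), log-normal onset
#' weeks per (exposure class, event group), demographic fields from fixed
#' marginals, field-level missingness, and finally duplicate injection at
#' `duplicate_rate`. Fully reproducible from `config$seed`; the caller's
#' RNG state is left untouched.
#'
#' @param config An [simulate_config()] object.
#' @return An [icsr_set()] (with duplicates if `duplicate_rate > 0`).
#' @export
simulate_icsr <- function(config) {
  stopifnot(inherits(config, "icsr_sim_config"))
  n <- config$n_reports
  dm <- config$drug_menu
  em <- config$event_menu

  drug_mat <- with_substream(config$seed, 1L, {
    m <- matrix(stats::runif(n * nrow(dm)), n) <
      matrix(dm$prob, n, nrow(dm), byrow = TRUE)
    combo <- stats::runif(n) < config$combo_probability
    if (any(combo)) {
      partners <- which(dm$class %in% c("PD1", "PDL1"))
      ipi <- which(dm$drug == "ipilimumab")
      if (length(ipi) && length(partners)) {
        m[combo, ipi] <- TRUE
        pick <- partners[sample.int(length(partners), sum(combo),
                                    replace = TRUE)]
        m[cbind(which(combo), pick)] <- TRUE
      }
    }
    # rejection-resample reports with no drug at all
    for (iter in 1:100) {
      empty <- !rowSums(m)
      if (!any(empty)) break
      m[empty, ] <- matrix(stats::runif(sum(empty) * nrow(dm)),
                           sum(empty)) <
        matrix(dm$prob, sum(empty), nrow(dm), byrow = TRUE)
    }
    m[!rowSums(m), which.max(dm$prob)] <- TRUE  # pathological configs
    m
  })

  event_mat <- with_substream(config$seed, 2L, {
    p <- matrix(em$prob, n, nrow(em), byrow = TRUE)
    ss <- config$signal_specs
    if (!is.null(ss) && nrow(ss)) {
      for (i in seq_len(nrow(ss))) {
        di <- match(ss$drug[i], dm$drug)
        ei <- match(ss$event[i], em$event)
        if (is.na(di) || is.na(ei)) next
        rows <- drug_mat[, di]
        p[rows, ei] <- pmax(p[rows, ei],
                            pmin(1, em$prob[ei] * ss$multiplier[i]))
      }
    }
    m <- matrix(stats::runif(n * nrow(em)), n) < p
    for (iter in 1:100) {
      empty <- !rowSums(m)
      if (!any(empty)) break
      m[empty, ] <- matrix(stats::runif(sum(empty) * nrow(em)),
                           sum(empty)) < p[empty, , drop = FALSE]
    }
    m[!rowSums(m), which.max(em$prob)] <- TRUE
    m
  })

  listcol <- function(mat, names) {
    idx <- which(mat, arr.ind = TRUE)
    unname(split(names[idx[, 2]],
                 factor(idx[, 1], levels = seq_len(nrow(mat)))))
  }
  drugs <- listcol(drug_mat, dm$drug)
  events <- listcol(event_mat, em$event)

  demo <- with_substream(config$seed, 3L, {
    list(
      year = sample(2011:2019, n, replace = TRUE,
                    prob = c(0.004, 0.013, 0.013, 0.029, 0.067, 0.111,
                             0.262, 0.429, 0.073)),
      gender = sample(c("male", "female"), n, TRUE, prob = c(0.60, 0.40)),
      age_group = sample(c("under65", "over65"), n, TRUE,
                         prob = c(0.50, 0.50)),
      region = sample(c("Europe", "Americas", "Asia", "Oceania", "Africa"),
                      n, TRUE, prob = c(0.44, 0.30, 0.23, 0.028, 0.002)),
      notifier = sample(c("health_professional", "other"), n, TRUE,
                        prob = c(0.884, 0.116)),
      indication = sample(c("malignant melanoma", "lung cancer",
                            "renal cell carcinoma", "other tumor"),
                          n, TRUE, prob = c(0.435, 0.358, 0.062, 0.145)),
      outcomes = sample(c("recovered", "not_recovered", "death",
                          "life_threatening"),
                        n, TRUE, prob = c(0.695, 0.287, 0.012, 0.006))
    )
  })

  onset <- with_substream(config$seed, 4L, {
    tmp <- icsr_set(report_id = sprintf("R%07d", seq_len(n)),
                    drugs = drugs, events = events)
    cls <- as.character(classify_exposure(tmp))
    cat <- builtin_endocrine_catalog()
    grp <- rep("other", n)
    for (g in rev(setdiff(names(cat$groups), "endocrine_all"))) {
      hit <- match_query(tmp, cat, g)
      grp[hit] <- g
    }
    key <- paste(cls, grp, sep = ":")
    pars <- config$onset_model[key]
    miss <- vapply(pars, is.null, logical(1))
    pars[miss] <- list(config$onset_model$default)
    meanlog <- vapply(pars, `[`, numeric(1), 1L)
    sdlog <- vapply(pars, `[`, numeric(1), 2L)
    stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
  })

  masked <- with_substream(config$seed, 5L, {
    mr <- config$missing_rates
    lapply(stats::setNames(nm = names(mr)),
           function(f) stats::runif(n) < mr[[f]])
  })
  if (!is.null(masked$year)) demo$year[masked$year] <- NA
  for (f in c("gender", "age_group", "region", "notifier", "indication")) {
    if (!is.null(masked[[f]])) demo[[f]][masked[[f]]] <- "unknown"
  }
  if (!is.null(masked$onset_weeks)) onset[masked$onset_weeks] <- NA
  if (!is.null(masked$outcomes)) demo$outcomes[masked$outcomes] <- "unknown"

  out <- icsr_set(report_id = sprintf("R%07d", seq_len(n)),
                  drugs = drugs, events = events,
                  year = demo$year, gender = demo$gender,
                  age_group = demo$age_group, region = demo$region,
                  notifier = demo$notifier, indication = demo$indication,
                  onset_weeks = onset,
                  outcomes = as.list(demo$outcomes))
  if (config$duplicate_rate > 0) {
    out <- inject_duplicates(out, config$duplicate_rate,
                             seed = config$seed + 6L)
  }
  out
}

#' Inject duplicate report records
#'
#' Re-emits each selected report under the same `report_id` with one extra
#' field masked in the copy (so the original is always at least as
#' complete), appending the copies after the originals.
#' [deduplicate_reports()] recovers a set of the original size and content.
#'
#' @param reports An [icsr_set()].
#' @param rate Probability that a report is duplicated.
#' @param seed Integer seed for the selection and masking draws.
#' @return An `icsr_set` with the duplicate records appended.
#' @export
inject_duplicates <- function(reports, rate, seed = 1L) {
  stopifnot(is_icsr_set(reports), rate >= 0, rate <= 1)
  if (rate == 0 || nrow(reports) == 0L) return(reports)
  with_substream(seed, 0L, {
    pick <- which(stats::runif(nrow(reports)) < rate)
    copies <- reports[pick, , drop = FALSE]
    maskable <- c("year", "gender", "age_group", "region", "notifier",
                  "indication", "onset_weeks", "outcomes")
    which_mask <- if (length(pick)) sample(maskable, length(pick),
                                           replace = TRUE) else character()
    for (i in seq_along(pick)) {
      f <- which_mask[i]
      if (f == "year") copies$year[i] <- NA_integer_
      else if (f == "onset_weeks") copies$onset_weeks[i] <- NA_real_
      else if (f == "outcomes") copies$outcomes[[i]] <- "unknown"
      else copies[[f]][i] <- "unknown"
    }
    out <- rbind(as.data.frame(reports), as.data.frame(copies))
    rownames(out) <- NULL
    class(out) <- c("icsr_set", "data.frame")
    out
  })
}
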