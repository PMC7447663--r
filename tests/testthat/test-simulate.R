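test_that("generation is reproducible from the seed and leaves the caller RNG alone", {
  cfg <- simulate_config(n_reports = 300, seed = 7, duplicate_rate = 0.1)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  a <- simulate_icsr(cfg)
  b <- simulate_icsr(cfg)
  expect_identical(a, b)
  expect_equal(runif(1), before)  # caller stream not consumed
  cfg2 <- simulate_config(n_reports = 300, seed = 8, duplicate_rate = 0.1)
  expect_false(identical(simulate_icsr(cfg2), a))
})

test_that("every generated report has a drug, an event, and valid fields", {
  db <- simulate_icsr(simulate_config(n_reports = 500, seed = 3))
  expect_true(all(lengths(db$drugs) >= 1))
  expect_true(all(lengths(db$events) >= 1))
  expect_true(all(is.na(db$onset_weeks) | db$onset_weeks >= 0))
  expect_true(all(db$gender %in% c("male", "female", "unknown")))
})

test_that("invalid configurations are rejected", {
  expect_error(simulate_config(n_reports = 100, combo_probability = 1.5),
               "probabilities")
  expect_error(simulate_config(
    signal_specs = data.frame(drug = "a", event = "b", multiplier = -2)),
    "multipliers")
  expect_error(simulate_config(
    onset_model = list(default = c(meanlog = 1, sdlog = 0))), "sdlog")
})

test_that("empirical exposure frequencies converge to the configured marginals", {
  # a near-certain filler drug makes empty draws (and hence the conditioning
  # introduced by rejection resampling) negligible, so the law-of-large-
  # numbers check against the raw marginals is valid
  n <- 60000
  menu <- data.frame(drug = c("filler", "nivolumab", "ipilimumab"),
                     class = c("other", "PD1", "CTLA4"),
                     prob = c(0.995, 0.02, 0.008), stringsAsFactors = FALSE)
  cfg <- simulate_config(n_reports = n, seed = 11, duplicate_rate = 0,
                         combo_probability = 0, drug_menu = menu,
                         signal_specs = NULL)
  db <- simulate_icsr(cfg)
  for (drug in c("nivolumab", "ipilimumab")) {
    p <- menu$prob[menu$drug == drug]
    obs <- mean(vapply(db$drugs, function(d) drug %in% d, logical(1)))
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs - p), 3 * se + 1e-4)
  }
})

test_that("onset samples track the configured log-normal location", {
  cfg <- simulate_config(
    n_reports = 30000, seed = 5, duplicate_rate = 0,
    missing_rates = c(onset_weeks = 0))
  db <- simulate_icsr(cfg)
  cls <- classify_exposure(db)
  cat <- builtin_endocrine_catalog()
  hit <- match_query(db, cat, "hypophysitis_hypopituitarism") &
    cls == "ipilimumab_mono"
  lw <- log(db$onset_weeks[hit])
  pars <- cfg$onset_model[["ipilimumab_mono:hypophysitis_hypopituitarism"]]
  se <- pars[["sdlog"]] * sqrt(pi / (2 * length(lw)))
  expect_gt(length(lw), 30)
  expect_lt(abs(median(lw) - pars[["meanlog"]]), 3 * se)
})

test_that("duplicate injection doubles selected IDs and dedup recovers the set", {
  x <- deduplicate_reports(random_reports(50, seed = 2))
  expect_identical(inject_duplicates(x, 0, seed = 1), x)
  all_dup <- inject_duplicates(x, 1, seed = 1)
  expect_equal(nrow(all_dup), 100L)
  expect_equal(length(unique(all_dup$report_id)), 50L)
  for (rate in c(0.3, 0.7)) {
    y <- inject_duplicates(x, rate, seed = 99)
    d <- deduplicate_reports(y)
    expect_equal(nrow(d), nrow(x))
    expect_setequal(d$report_id, x$report_id)
    # originals are at least as complete, so dedup restores the originals
    d <- d[match(x$report_id, d$report_id), ]
    expect_equal(d$gender, x$gender)
    expect_equal(d$onset_weeks, x$onset_weeks)
  }
})

test_that("a planted signal propagates to the downstream estimate", {
  menu_d <- data.frame(drug = c("sig", "bg1", "bg2"),
                       class = rep("other", 3),
                       prob = c(0.05, 0.6, 0.5), stringsAsFactors = FALSE)
  menu_e <- data.frame(event = c("target", "noise1", "noise2"),
                       prob = c(0.001, 0.05, 0.05), stringsAsFactors = FALSE)
  cfg <- simulate_config(
    n_reports = 50000, seed = 31,
    drug_menu = menu_d, event_menu = menu_e,
    signal_specs = data.frame(drug = "sig", event = "target",
                              multiplier = 10, stringsAsFactors = FALSE),
    combo_probability = 0, duplicate_rate = 0)
  db <- simulate_icsr(cfg)
  cat <- term_catalog(menu_e$event, groups = list(q = "target"))
  fit <- disprop(db, has_drug("sig"), "q", catalog = cat)
  expect_true(fit$ic_significant)
  expect_gt(fit$ror, 10 / 1.5)
  expect_lt(fit$ror, 10 * 1.5)
})
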