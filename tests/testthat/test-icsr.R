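test_that("long-form CSV rows aggregate into one report per ID, order-independently", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- data.frame(
    report_id = c("R1", "R1", "R1", "R2"),
    drug = c("Nivolumab", "nivolumab", "ipilimumab", "aspirin"),
    event = c("hypothyroidism", "thyroiditis", "thyroiditis", "rash"),
    year = "2018", gender = "male", age_group = "under65",
    region = "Europe", notifier = "health_professional",
    indication = "lung cancer", onset_weeks = c("4", "4", "4", ""),
    outcomes = c("recovered", "recovered", "recovered", "unknown"),
    stringsAsFactors = FALSE)
  write.csv(rows, path, row.names = FALSE)
  x <- read_icsr(path)
  expect_equal(nrow(x), 2L)
  r1 <- x[x$report_id == "R1", ]
  expect_setequal(r1$drugs[[1]], c("nivolumab", "ipilimumab"))
  expect_setequal(r1$events[[1]], c("hypothyroidism", "thyroiditis"))
  expect_equal(r1$onset_weeks, 4)
  expect_true(is.na(x$onset_weeks[x$report_id == "R2"]))

  # shuffling rows must not change the aggregated result
  write.csv(rows[c(4, 2, 3, 1), ], path, row.names = FALSE)
  y <- read_icsr(path)
  y <- y[match(x$report_id, y$report_id), ]
  for (f in c("report_id", "year", "gender", "onset_weeks")) {
    expect_equal(y[[f]], x[[f]])
  }
  expect_setequal(y$drugs[[1]], x$drugs[[1]])
  expect_setequal(y$events[[1]], x$events[[1]])
})

test_that("empty files and schema violations are handled explicitly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("report_id,drug,event", path)
  expect_equal(nrow(read_icsr(path)), 0L)

  writeLines(c("report_id,drug", "R1,nivolumab"), path)
  expect_error(read_icsr(path), "event")

  writeLines(c("report_id,drug,event,onset_weeks",
               "R1,nivolumab,rash,abc"), path)
  expect_error(read_icsr(path), "onset_weeks")
})

test_that("both dialects round-trip a report set field by field", {
  x <- deduplicate_reports(random_reports(40, seed = 11))
  for (ext in c(".csv", ".jsonl")) {
    path <- withr::local_tempfile(fileext = ext)
    write_icsr(x, path)
    y <- read_icsr(path)
    expect_equal(nrow(y), nrow(x))
    y <- y[match(x$report_id, y$report_id), ]
    expect_equal(y$report_id, x$report_id)
    expect_equal(y$onset_weeks, x$onset_weeks)
    expect_equal(y$gender, x$gender)
    for (i in seq_len(nrow(x))) {
      expect_setequal(y$drugs[[i]], x$drugs[[i]])
      expect_setequal(y$events[[i]], x$events[[i]])
      expect_setequal(y$outcomes[[i]], x$outcomes[[i]])
    }
  }
})

test_that("deduplication keeps the most complete record and is idempotent", {
  x <- icsr_set(
    report_id = c("R1", "R1", "R2", "R3", "R3"),
    drugs = "nivolumab", events = "thyroiditis",
    gender = c("unknown", "male", "female", "male", "male"),
    onset_weeks = c(NA, 3, 1, NA, NA))
  d <- deduplicate_reports(x)
  expect_equal(d$report_id, c("R1", "R2", "R3"))
  expect_equal(d$gender[d$report_id == "R1"], "male")  # completeness wins
  expect_equal(d$onset_weeks[d$report_id == "R1"], 3)
  expect_identical(deduplicate_reports(d), d)          # idempotent

  # ties broken by first occurrence
  tie <- icsr_set(report_id = c("T1", "T1"), drugs = "a", events = "E",
                  gender = c("male", "female"))
  expect_equal(deduplicate_reports(tie)$gender, "male")

  # already-unique input is returned unchanged
  u <- deduplicate_reports(random_reports(25, seed = 3))
  expect_identical(deduplicate_reports(u), u)
})

test_that("exposure classification follows the combination rule and ignores co-medication", {
  x <- icsr_set(
    report_id = paste0("R", 1:6),
    drugs = list("ipilimumab",
                 c("ipilimumab", "nivolumab"),
                 c("nivolumab", "pembrolizumab"),
                 c("pembrolizumab", "aspirin", "metformin"),
                 c("ipilimumab", "durvalumab"),
                 c("warfarin", "aspirin")),
    events = "hypophysitis")
  cls <- as.character(classify_exposure(x))
  expect_equal(cls, c("ipilimumab_mono", "combination", "other_multi_ici",
                      "pembrolizumab_mono", "combination", "non_ici"))

  # invariance to adding non-ICI drugs
  y <- x
  y$drugs <- lapply(x$drugs, c, "acetaminophen")
  class(y) <- class(x)
  expect_equal(as.character(classify_exposure(y)), cls)
})

test_that("fatal-type outcome flag is a set intersection", {
  x <- icsr_set(paste0("R", 1:4), drugs = "d", events = "E",
                outcomes = list("death", "recovered",
                                c("hospitalization", "recovered"),
                                "unknown"))
  expect_equal(flag_fatal(x), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("invalid reports are rejected", {
  expect_error(icsr_set("R1", drugs = list(character()), events = "E"),
               "drug")
  expect_error(icsr_set("R1", drugs = "d", events = "E", onset_weeks = -1),
               "onset")
  expect_error(icsr_set("", drugs = "d", events = "E"), "report_id")
})
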