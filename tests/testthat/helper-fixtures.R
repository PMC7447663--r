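# Shared fixtures and independent brute-force oracles.

# Small fully-specified report set used across modules.
toy_reports <- function() {
  icsr_set(
    report_id = paste0("R", 1:6),
    drugs = list("x", "x", "y", "y", "x", "y"),
    events = list("E", "F", "E", "F", c("E", "F"), "F"),
    year = c(2015L, 2016L, 2017L, 2018L, 2018L, 2019L),
    gender = c("male", "female", "male", "unknown", "female", "male"),
    onset_weeks = c(2, 10, NA, 30, 5, 50)
  )
}

toy_catalog <- function() {
  term_catalog(terms = c("E", "F", "G"),
               groups = list(qE = "E", qF = "F", qEF = c("E", "F")))
}

# Exhaustive per-report loop: the oracle for contingency construction.
loop_contingency <- function(reports, exposed, members) {
  a <- b <- c2 <- d <- 0L
  for (i in seq_len(nrow(reports))) {
    hit <- any(reports$events[[i]] %in% members)
    if (exposed[i] && hit) a <- a + 1L
    else if (exposed[i]) b <- b + 1L
    else if (hit) c2 <- c2 + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c2, d = d)
}

# Random small report set for property tests.
random_reports <- function(n, seed) {
  set.seed(seed)
  icsr_set(
    report_id = sprintf("P%04d", seq_len(n)),
    drugs = replicate(n, sample(letters[1:5], sample(1:3, 1)),
                      simplify = FALSE),
    events = replicate(n, sample(c("E", "F", "G", "H"), sample(1:3, 1)),
                       simplify = FALSE),
    onset_weeks = ifelse(runif(n) < 0.3, NA, round(rlnorm(n, log(10), 1), 1))
  )
}

has_drug <- function(drug) {
  force(drug)
  function(reports) vapply(reports$drugs, function(d) drug %in% d, logical(1))
}
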