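test_that("contingency construction matches the exhaustive loop on the worked fixture", {
  x <- toy_reports()
  cat <- toy_catalog()
  tab <- build_contingency(x, has_drug("x"), cat, "qE")
  expect_equal(c(a = tab$a, b = tab$b, c = tab$c, d = tab$d),
               c(a = 2L, b = 1L, c = 1L, d = 2L))
  expect_equal(tab$n, 6L)
  expect_equal(tab$n_expected, 3 * 3 / 6)
})

test_that("contingency edge cases: empty set and empty exposure", {
  cat <- toy_catalog()
  empty <- deduplicate_reports(random_reports(5, 1)[0, ])
  tab0 <- build_contingency(empty, logical(0), cat, "qE")
  expect_equal(tab0$n, 0L)
  x <- toy_reports()
  tab <- build_contingency(x, rep(FALSE, 6), cat, "qE")
  expect_equal(tab$a + tab$b, 0L)
  expect_equal(tab$c + tab$d, 6L)
})

test_that("contingency equals the loop oracle on random fixtures", {
  for (s in 1:25) {
    x <- random_reports(sample(20:200, 1), seed = 1000 + s)
    members <- sample(c("E", "F", "G", "H"), sample(1:2, 1))
    cat <- term_catalog(c("E", "F", "G", "H"), groups = list(q = members))
    exposed <- has_drug(sample(letters[1:5], 1))(x)
    tab <- build_contingency(x, exposed, cat, "q")
    expect_equal(c(a = tab$a, b = tab$b, c = tab$c, d = tab$d),
                 loop_contingency(x, exposed, members))
  }
})

test_that("information component matches hand evaluations and is zero at independence", {
  expect_equal(information_component(contingency_table(10, 10, 10, 10)), 0)
  expect_equal(information_component(contingency_table(50, 950, 150, 98850)),
               log2(50.5 / 2.5), tolerance = 1e-12)
  expect_equal(round(information_component(
    contingency_table(50, 950, 150, 98850)), 4), round(log2(20.2), 4))
  expect_equal(round(information_component(
    contingency_table(0, 100, 50, 99850)), 4), -0.1375)
  expect_error(information_component(contingency_table(0, 0, 0, 0)),
               "empty")
})

test_that("IC credibility bounds reproduce the closed-form evaluation", {
  b <- ic_credible_bounds(2.0, 4)
  expect_equal(round(unname(b), 4), c(0.2349, 3.0790))
  expect_error(ic_credible_bounds(1, -1), "non-negative")
  # interval width shrinks as the observed count grows, ic held fixed
  widths <- vapply(c(3, 10, 50, 200, 1000), function(a) {
    diff(ic_credible_bounds(2, a))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("gamma-quantile bounds agree with the asymptotic bounds at large counts", {
  tab <- contingency_table(747, 5342, 18000, 13276684)
  ic <- information_component(tab)
  approx <- ic_credible_bounds(ic, tab$a)
  gamma <- ic_credible_bounds(ic, tab$a, method = "gamma",
                              n_expected = tab$n_expected)
  expect_equal(unname(gamma), unname(approx), tolerance = 0.02)
  expect_error(ic_credible_bounds(1, 5, method = "gamma"), "n_expected")
})

test_that("ROR matches hand evaluations and flags zero cells", {
  expect_equal(reporting_odds_ratio(contingency_table(10, 20, 5, 10))$ror, 1)
  expect_equal(round(reporting_odds_ratio(
    contingency_table(30, 70, 10, 90))$ror, 4), 3.8571)
  r <- reporting_odds_ratio(contingency_table(20, 80, 10, 160))
  expect_equal(r$ror, 4)
  expect_equal(round(r$ror_low, 3), 1.788)
  expect_equal(round(r$ror_high, 3), 8.948)
  z <- reporting_odds_ratio(contingency_table(0, 80, 10, 160))
  expect_false(z$estimable)
  expect_true(is.na(z$ror))
})

test_that("signal categories follow the 0/3/5 bit thresholds", {
  expect_equal(as.character(classify_signal(c(8.05, 4.52, 1.14, -0.5, 0))),
               c("strong", "moderate", "weak", "none", "none"))
  expect_equal(as.character(classify_signal(c(3, 5))),
               c("moderate", "strong"))  # left-closed upper bands
})

test_that("ROR and IC agree in sign of association on non-degenerate tables", {
  set.seed(77)
  for (i in 1:50) {
    cells <- rpois(4, lambda = c(30, 200, 60, 800)) + 5
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    ror <- reporting_odds_ratio(tab)$ror
    ic_pos <- tab$a > tab$n_expected
    expect_equal(ror > 1, ic_pos)
    expect_equal(information_component(tab) > 0, ic_pos)
  }
})

test_that("disprop fit bundles statistics consistently with its parts", {
  x <- toy_reports()
  cat <- toy_catalog()
  fit <- disprop(x, has_drug("x"), "qE", catalog = cat)
  tab <- build_contingency(x, has_drug("x"), cat, "qE")
  expect_s3_class(fit, "disprop")
  expect_equal(fit$ic, information_component(tab))
  expect_equal(c(fit$ic025, fit$ic975),
               unname(ic_credible_bounds(fit$ic, tab$a)))
  expect_equal(fit$ror, reporting_odds_ratio(tab)$ror)
  expect_equal(unname(coef(fit)), c(fit$ic, fit$ror))
  ci <- confint(fit)
  expect_equal(unname(ci["ic", ]), c(fit$ic025, fit$ic975))
  expect_equal(unname(ci["ror", ]), c(fit$ror_low, fit$ror_high))
  expect_output(print(fit), "IC")
})

test_that("ROR significance enforces the minimum-count rule", {
  # a = 2 with an extreme association: CI would exclude 1, the rule vetoes
  x <- icsr_set(paste0("R", 1:100), drugs = c(rep("s", 4), rep("z", 96)),
                events = c("E", "E", "G", "G", rep("E", 6), rep("F", 90)))
  cat <- term_catalog(c("E", "F", "G"), groups = list(q = "E"))
  fit <- disprop(x, has_drug("s"), "q", catalog = cat)
  expect_equal(fit$table$a, 2)
  expect_false(fit$ror_significant)
  fit3 <- disprop(x, has_drug("s"), "q", catalog = cat, min_count = 2)
  expect_equal(fit3$ror_significant, fit3$ror_low > 1)
})

test_that("spectrum screening equals per-pair fits and sorts by ic025", {
  x <- random_reports(150, seed = 9)
  cat <- term_catalog(c("E", "F", "G", "H"),
                      groups = list(q1 = c("E", "F"), q2 = "G"))
  sel <- list(da = has_drug("a"), db = has_drug("b"))
  sc <- screen_spectrum(x, cat, sel, queries = c("q1", "q2", "H"))
  expect_equal(nrow(sc), 6L)
  expect_true(all(diff(sc$ic025) <= 0))
  for (i in seq_len(nrow(sc))) {
    fit <- disprop(x, sel[[sc$exposure[i]]], sc$query[i], catalog = cat)
    expect_equal(sc$ic[i], fit$ic)
    expect_equal(sc$ic025[i], fit$ic025)
    expect_equal(sc$a[i], fit$table$a)
    expect_equal(sc$ror[i], fit$ror)
    expect_equal(sc$category[i], as.character(fit$category))
  }
})

test_that("subgroup comparison restricts to the two groups and checks disjointness", {
  # group A: event E in 30/100; group B: in 10/100 -> ROR 3.857
  x <- icsr_set(paste0("R", 1:200),
                drugs = c(rep("a", 100), rep("b", 100)),
                events = c(rep("E", 30), rep("F", 70),
                           rep("E", 10), rep("F", 90)))
  cat <- term_catalog(c("E", "F"), groups = list(q = "E"))
  fit <- compare_subgroups(x, has_drug("a"), has_drug("b"), "q",
                           catalog = cat)
  expect_equal(round(fit$ror, 3), 3.857)
  expect_equal(fit$table$n, 200L)
  # identical proportions give ROR 1
  y <- icsr_set(paste0("S", 1:40), drugs = rep(c("a", "b"), each = 20),
                events = rep(c(rep("E", 5), rep("F", 15)), 2))
  fit1 <- compare_subgroups(y, has_drug("a"), has_drug("b"), "q",
                            catalog = cat)
  expect_equal(fit1$ror, 1)
  expect_error(compare_subgroups(x, has_drug("a"), has_drug("a"), "q",
                                 catalog = cat), "overlap")
})

test_that("1-D 3-means clustering recovers band boundaries deterministically", {
  cl <- cluster_ic025(c(1.0, 1.1, 3.9, 4.0, 6.9, 7.0))
  expect_equal(cl$boundaries, c(2.5, 5.45))
  expect_equal(cl$cluster, c(1, 1, 2, 2, 3, 3))
  cl2 <- cluster_ic025(c(1, 1, 1, 4, 4, 4, 9, 9, 9))
  expect_equal(cl2$boundaries, c(2.5, 6.5))
  # clusters are contiguous in sorted order for arbitrary input
  set.seed(12)
  v <- runif(40, 0.01, 9)
  cl3 <- cluster_ic025(v)
  expect_true(all(diff(cl3$cluster[order(v)]) >= 0))
  expect_error(cluster_ic025(c(1, 1, 2)), "insufficient")
  expect_error(cluster_ic025(c(-1, 2, 3)), "positive")
})
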