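test_that("session success rates and improvement print like the study", {
  expect_equal(success_rate(33, 56), 58.9)
  expect_equal(success_rate(50, 56), 89.3)
  expect_equal(success_rate(0, 56), 0)
  expect_error(success_rate(3, 0), "total")
  expect_error(success_rate(-1, 10), "correct")
  expect_equal(improvement_pp(c(33, 56), c(50, 56)), 30.4)
  expect_equal(improvement_pp(c(10, 56), c(10, 56)), 0)
  expect_equal(improvement_pp(c(0, 56), c(56, 56)), 100)
  expect_error(improvement_pp(c(10, 56), c(10, 54)), "equal totals")
})

test_that("exact McNemar agrees with closed forms and the summation oracle", {
  expect_equal(mcnemar_exact(paired_table(10, 17, 0, 5)), 2 * 0.5^17,
               tolerance = 1e-12)
  expect_equal(mcnemar_exact(paired_table(0, 5, 5, 0)), 1)
  expect_equal(mcnemar_exact(paired_table(8, 0, 0, 3)), 1)
  for (b in 0:25) for (cc in 0:(25 - b)) {
    got <- mcnemar_exact(paired_table(1, b, cc, 1))
    expect_equal(got, mcnemar_sum_oracle(b, cc), tolerance = 1e-12)
    expect_equal(got, mcnemar_exact(paired_table(1, cc, b, 1)))  # symmetry
    expect_gt(got, 0)
    expect_lte(got, 1)
  }
  # spot check against the stats package's binomial test
  for (bc in list(c(20, 3), c(12, 5), c(9, 9))) {
    expect_equal(mcnemar_exact(paired_table(0, bc[1], bc[2], 0)),
                 binom.test(bc[1], sum(bc), 0.5)$p.value, tolerance = 1e-9)
  }
})

test_that("chi-square McNemar matches the reference implementation", {
  t1 <- paired_table(10, 17, 0, 5)
  expect_equal(mcnemar_chi2(t1, continuity = FALSE)$statistic, 17)
  expect_equal(mcnemar_chi2(t1, continuity = TRUE)$statistic, 256 / 17)
  expect_error(mcnemar_chi2(paired_table(5, 0, 0, 5)), "discordant")
  for (bc in list(c(17, 0), c(20, 3), c(7, 12))) {
    tab <- paired_table(4, bc[1], bc[2], 6)
    m <- matrix(c(tab$a, tab$b, tab$c, tab$d), 2)
    for (corr in c(TRUE, FALSE)) {
      ref <- stats::mcnemar.test(m, correct = corr)
      got <- mcnemar_chi2(tab, continuity = corr)
      expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
    }
  }
})

test_that("ICC(A,k) matches the explicit sum-of-squares oracle", {
  # perfect agreement between raters, subjects differ -> ICC = 1
  perfect <- matrix(rep(c(1, 2, 3, 4), 3), ncol = 3)
  expect_equal(icc_a_k(perfect)$icc, 1)
  # degrees-of-freedom contract for the 14-subject, 7-rater layout
  set.seed(33)
  m <- matrix(rnorm(14 * 7), 14, 7)
  r <- icc_a_k(m)
  expect_equal(r$df1, 13)
  expect_equal(r$df2, 78)
  expect_error(icc_a_k(matrix(5, 4, 3)), "degenerate")
  expect_error(icc_a_k(matrix(1, 1, 3)), "at least 2")
  set.seed(101)
  for (i in 1:50) {
    n <- sample(3:10, 1); k <- sample(2:5, 1)
    x <- matrix(sample(0:8, n * k, TRUE) + rnorm(n * k, 0, 0.01), n, k)
    got <- icc_a_k(x)
    want <- icc_oracle(x)
    expect_equal(got$icc, want$icc, tolerance = 1e-9)
    expect_equal(got$f_value, want$f, tolerance = 1e-9)
    expect_equal(c(got$ci_low, got$ci_high), want$ci, tolerance = 1e-9)
    if (got$icc >= 0) {
      expect_lte(got$ci_low, got$icc + 1e-9)
      expect_gte(got$ci_high, got$icc - 1e-9)
    }
  }
})

test_that("ICC values fall in the standard reliability bands", {
  expect_equal(interpret_icc(0.675), "moderate")
  expect_equal(interpret_icc(0.3), "poor")
  expect_equal(interpret_icc(0.9), "excellent")
  expect_equal(interpret_icc(0.75), "good")
  expect_error(interpret_icc(1.2), "<= 1")
  grid <- seq(-0.5, 1, by = 0.01)
  lev <- factor(vapply(grid, interpret_icc, ""),
                levels = c("poor", "moderate", "good", "excellent"))
  expect_true(all(diff(as.integer(lev)) >= 0))  # monotone step function
})

test_that("exact McNemar power is valid under the null and matches Monte Carlo", {
  # the exact test is conservative, so its size sits just below the nominal
  # level rather than at it
  size <- mcnemar_power_exact(0.2, 0.2, 56, 0.05)
  expect_gte(size, 0.025)
  expect_lte(size, 0.05)
  expect_equal(mcnemar_power_exact(0.3, 0.1, 0, 0.05), 0)
  expect_error(mcnemar_power_exact(0.8, 0.4, 56), "p01")

  mc_power <- function(p01, p10, n, alpha, reps = 1e5) {
    d <- rbinom(reps, n, p01 + p10)
    b <- rbinom(reps, d, p01 / (p01 + p10))
    lo <- pbinom(pmin(b, d - b), d, 0.5)
    hi <- pbinom(pmax(b, d - b) - 1, d, 0.5, lower.tail = FALSE)
    pv <- ifelse(d == 0, 1, pmin(1, 2 * pmin(lo, hi)))
    mean(pv <= alpha)
  }
  set.seed(55)
  for (pp in list(c(0.4, 0.0), c(0.3, 0.1), c(0.2, 0.05))) {
    exact <- mcnemar_power_exact(pp[1], pp[2], 56, 0.05)
    mc <- mc_power(pp[1], pp[2], 56, 0.05)
    se <- sqrt(mc * (1 - mc) / 1e5) + 1e-6
    expect_lt(abs(exact - mc), 3 * se + 1e-4)
  }
})

test_that("the simulated study reproduces the 8 x 14 x 2 bookkeeping", {
  st <- simulate_study(8, 14, seed = 4)
  expect_equal(nrow(st$records), 112)
  expect_equal(sum(st$records$session == "before"), 56)
  expect_true(all(table(st$records$rater_id) == 14))
  expect_identical(simulate_study(8, 14, seed = 4)$records, st$records)
  expect_false(identical(simulate_study(8, 14, seed = 5)$records, st$records))
  expect_error(simulate_study(8, 13), "even")
  expect_error(simulate_study(8, 14, p_before = 1.4), "probabilities")
  all_ok <- simulate_study(4, 6, p_before = 1, p_after = 1, seed = 1)
  expect_true(all(all_ok$records$score == "Correct"))
  # law of large numbers at 200 raters
  big <- simulate_study(200, 14, p_before = 0.589, p_after = 0.893, seed = 7)
  rates <- with(big$records, tapply(score == "Correct", session, mean))
  expect_lt(abs(rates[["before"]] - 0.589), 0.03)
  expect_lt(abs(rates[["after"]] - 0.893), 0.03)
})

test_that("pair tabulation matches direct enumeration", {
  all_c <- simulate_study(3, 4, p_before = 1, p_after = 1, seed = 1)
  tab <- tabulate_pairs(all_c)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(6, 0, 0, 0))
  flip <- simulate_study(3, 4, p_before = 0, p_after = 1, seed = 1)
  tab <- tabulate_pairs(flip)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(0, 6, 0, 0))

  st <- simulate_study(5, 6, p_before = 0.5, p_after = 0.7, seed = 12)
  tab <- tabulate_pairs(st)
  rec <- st$records
  hand <- c(a = 0, b = 0, c = 0, d = 0)
  for (r in unique(rec$rater_id)) {
    bef <- rec[rec$rater_id == r & rec$session == "before", ]
    aft <- rec[rec$rater_id == r & rec$session == "after", ]
    bef <- bef[order(bef$scapula_id), ]
    aft <- aft[order(aft$scapula_id), ]
    for (i in seq_len(nrow(bef))) {
      key <- if (bef$score[i] == "Correct" && aft$score[i] == "Correct") "a"
      else if (bef$score[i] != "Correct" && aft$score[i] == "Correct") "b"
      else if (bef$score[i] == "Correct") "c" else "d"
      hand[key] <- hand[key] + 1
    }
  }
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), unname(hand))
  expect_equal(tab$n, 15)  # 5 raters x 3 scapula ranks
})

test_that("the exact test holds its size over seeded null replicates", {
  hits <- 0
  reps <- 2000
  for (s in seq_len(reps)) {
    st <- simulate_study(8, 14, p_before = 0.6, p_after = 0.6, seed = s)
    if (mcnemar_exact(tabulate_pairs(st)) <= 0.05) hits <- hits + 1
  }
  frac <- hits / reps
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(frac, 0.05 + 3 * se)
})

test_that("records survive the CSV roundtrip and feed the full report", {
  st <- simulate_study(8, 14, seed = 2)
  p <- file.path(withr::local_tempdir(), "records.csv")
  records_to_csv(st, p)
  back <- records_from_csv(p)
  expect_equal(back$records, st$records)
  rep <- study_report(st)
  expect_equal(rep$before$total, 56)
  expect_equal(rep$after$total, 56)
  expect_equal(rep$improvement_pp,
               improvement_pp(c(rep$before$correct, 56),
                              c(rep$after$correct, 56)))
  js <- jsonlite::fromJSON(report_to_json(rep))
  expect_equal(js$mcnemar$p_exact, rep$mcnemar$p_exact, tolerance = 1e-12)
})
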