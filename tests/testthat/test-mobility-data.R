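test_that("eligibility filters remove minors, the enrolled and incomplete records", {
  d <- data.frame(origin = "low", destination = "high", outcome = 1,
                  age = c(17, 30, 30, 30), enrolled = c(0, 1, 0, 0))
  d$outcome[4] <- NA
  res <- apply_eligibility_filters(d)
  expect_equal(res$report$n_removed_age, 1L)
  expect_equal(res$report$n_removed_enrolled, 1L)
  expect_equal(res$report$n_removed_missing, 1L)
  expect_equal(res$report$n_retained, 1L)
})

test_that("an identity filter retains every valid record", {
  d <- quick_cohort(10)
  res <- apply_eligibility_filters(d)
  expect_equal(res$report$n_retained, 10L)
  expect_equal(res$report$n_removed_age + res$report$n_removed_enrolled +
                 res$report$n_removed_missing, 0L)
})

test_that("filter counts reconcile on randomised inputs", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(20:100, 1)
    d <- data.frame(
      origin = sample(c(education_levels(), NA), n, replace = TRUE),
      destination = sample(education_levels(), n, replace = TRUE),
      outcome = sample(c(0L, 1L, NA), n, replace = TRUE),
      age = sample(c(15:60, NA), n, replace = TRUE),
      enrolled = sample(0:1, n, replace = TRUE))
    rpt <- tryCatch(apply_eligibility_filters(d)$report,
                    error = function(e) NULL)
    if (is.null(rpt)) next  # everything filtered out: degenerate-data error
    expect_equal(rpt$n_input,
                 rpt$n_retained + rpt$n_removed_age +
                   rpt$n_removed_enrolled + rpt$n_removed_missing)
  }
})

test_that("an empty retained set is a degenerate-data error", {
  d <- data.frame(origin = "low", destination = "low", outcome = 1, age = 12)
  expect_error(apply_eligibility_filters(d), "no records")
})

test_that("tabulation counts respondents per origin-destination cell", {
  d <- data.frame(origin = "low", destination = "low", outcome = 0)
  tab <- mobility_table(d)
  expect_equal(tab$counts["low", "low"], 1L)
  expect_equal(sum(tab$counts), 1L)
  expect_equal(tab$grand_total, 1L)
})

test_that("packaged mobility-count fixtures reproduce every printed cell and margin", {
  male <- nl2009_mobility_counts("male")
  expect_equal(unname(male$counts),
               matrix(c(361L, 68L, 17L, 341L, 220L, 112L, 142L, 137L, 171L),
                      nrow = 3))
  expect_equal(unname(male$row_totals), c(844L, 425L, 300L))
  expect_equal(unname(male$col_totals), c(446L, 673L, 450L))
  expect_equal(male$grand_total, 1569L)
  female <- nl2009_mobility_counts("female")
  expect_equal(unname(female$counts),
               matrix(c(347L, 68L, 18L, 414L, 324L, 103L, 126L, 172L, 199L),
                      nrow = 3))
  expect_equal(female$grand_total, 1771L)
  expect_equal(unname(female$row_totals), c(887L, 564L, 320L))
  expect_equal(unname(female$col_totals), c(433L, 841L, 497L))
})

test_that("covariate centring returns a zero-mean vector and the subtracted mean", {
  cc <- center_covariate(c(30, 40))
  expect_equal(cc$centered, c(-5, 5))
  expect_equal(cc$mean, 35)
  cc0 <- center_covariate(c(20, 20, 20))
  expect_equal(cc0$centered, c(0, 0, 0))
  expect_equal(cc0$mean, 20)
  cw <- center_covariate(c(1, 2), weights = c(3, 1))
  expect_equal(cw$mean, 1.25)
  expect_lt(abs(sum(cw$centered * c(3, 1))), 1e-10)
})

test_that("simulated ages centre near the configured population mean", {
  d <- quick_cohort(1e5, seed = 11)
  cc <- center_covariate(d$age)
  se <- sd(d$age) / sqrt(nrow(d))
  expect_lt(abs(cc$mean - 34.95), 3 * se + 0.05)
  expect_lt(abs(mean(cc$centered)), 1e-10)
})

test_that("CSV round trip preserves table counts and fitted models", {
  d <- quick_cohort(800, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mobility_csv(d, path)
  d2 <- read_mobility_csv(path)
  expect_equal(mobility_table(d2)$counts, mobility_table(d)$counts)
  f1 <- fit_drm(d, mobility = "downward", compute_vcov = FALSE)
  f2 <- fit_drm(d2, mobility = "downward", compute_vcov = FALSE)
  expect_equal(f2$w, f1$w, tolerance = 1e-10)
  expect_equal(f2$gamma, f1$gamma, tolerance = 1e-10)
})

test_that("outcome is derived from height and weight when absent", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("origin,destination,height_cm,weight_kg,age",
               "low,high,170,80,30",    # BMI 27.7 -> 1
               "high,low,180,70,40"),   # BMI 21.6 -> 0
             path)
  d <- read_mobility_csv(path)
  expect_equal(d$outcome, c(1L, 0L))
  expect_error(read_mobility_csv("no/such/file.csv"), "no/such/file.csv")
})
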