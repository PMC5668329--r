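test_that("the conditional design interpolates origin and destination indicators", {
  d <- data.frame(origin = c("low", "low", "medium"),
                  destination = c("low", "high", "medium"),
                  outcome = c(1, 0, 1))
  # immobile record: 1 in its level column regardless of w
  for (w in c(0, 0.3, 1)) {
    X <- build_conditional_design(d, w)$X
    expect_equal(unname(X[1, "diag_low"]), 1)
    expect_equal(unname(X[3, "diag_medium"]), 1)
  }
  X1 <- build_conditional_design(d, 1)$X
  expect_equal(unname(X1[2, c("diag_low", "diag_high")]), c(1, 0))
  X5 <- build_conditional_design(d, 0.5)$X
  expect_equal(unname(X5[2, c("diag_low", "diag_high")]), c(0.5, 0.5))
})

test_that("levels absent from both margins are an unidentifiable-level error", {
  d <- data.frame(origin = c("low", "medium"),
                  destination = c("medium", "low"), outcome = c(1, 0))
  expect_error(build_conditional_design(d, 0.5), "high")
})

test_that("profile likelihood is symmetric under origin/destination relabelling", {
  d <- quick_cohort(1500, seed = 13)
  ds <- d
  ds$origin <- d$destination
  ds$destination <- d$origin
  w <- c(0.2, 0.35, 0.8)
  p1 <- drm_profile(d, w)
  p2 <- drm_profile(ds, 1 - w)
  expect_lt(max(abs(p1$loglik - rev(p2$loglik))), 1e-9)
  expect_true(all(p1$loglik <= 0))
  expect_true(all(diff(p1$w) > 0))
})

test_that("fitting a transposed table reflects the origin weight", {
  d <- quick_cohort(4000, seed = 17)
  f1 <- fit_drm(d, compute_vcov = FALSE)
  ds <- d
  ds$origin <- d$destination
  ds$destination <- d$origin
  f2 <- fit_drm(ds, compute_vcov = FALSE)
  expect_lt(abs(f2$w - (1 - f1$w)), 1e-5)
  expect_equal(f2$gamma, f1$gamma, tolerance = 1e-6)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("data generated ignoring destination push w to the upper boundary", {
  cfg <- default_sim_config("male", n = 5e4)
  cfg$w_true <- 1
  d <- simulate_cohort(cfg, seed = 19)
  pl <- drm_profile(d, c(0, 1))
  expect_gte(pl$loglik[2], pl$loglik[1])
  f <- fit_drm(d, compute_vcov = FALSE)
  expect_gt(f$w, 0.9)
})

test_that("the bounded optimiser lands on the grid argmax", {
  d <- quick_cohort(2000, seed = 23)
  f <- fit_drm(d, compute_vcov = FALSE)
  grid <- drm_profile(d, seq(0, 1, by = 1e-3))
  expect_lt(abs(f$w - grid$w[which.max(grid$loglik)]), 1e-3)
  # monotone refinement: the optimum dominates every grid point
  expect_gte(f$loglik, max(grid$loglik) - 1e-10)
  expect_gte(f$loglik, max(f$profile$loglik))
})

test_that("perfectly balanced cells give a flat profile handled explicitly", {
  yes <- matrix(5, 3, 3)
  no <- matrix(5, 3, 3)
  d <- cell_count_data(yes, no)
  f <- suppressWarnings(fit_drm(d))
  expect_true(f$convergence$flat_profile)
  expect_equal(f$w, 0.5)  # midpoint of the argmax set
  expect_equal(unname(f$gamma), c(0, 0, 0), tolerance = 1e-7)
  expect_equal(f$loglik, nrow(d) * log(0.5), tolerance = 1e-8)
})

test_that("an all-diagonal table makes w unidentifiable", {
  d <- data.frame(origin = rep(education_levels(), each = 10),
                  destination = rep(education_levels(), each = 10),
                  outcome = rep(c(0, 1), 15))
  expect_error(fit_drm(d), "unidentifiable")
})

test_that("parameters are recovered at the default generating values", {
  cfg <- default_sim_config("male", n = 5e4)
  d <- simulate_cohort(cfg, seed = 29)
  f <- fit_drm(d, mobility = "downward")
  expect_lt(abs(f$w - 0.35), 0.05 + 2 * f$w_se)
  expect_true(all(abs(f$diagonal$odds / c(0.73, 0.74, 0.41) - 1) < 0.1))
  expect_true(f$convergence$converged)
  # vcov is symmetric with positive diagonal
  expect_equal(f$vcov, t(f$vcov), tolerance = 1e-8)
  expect_true(all(diag(f$vcov) > 0))
})

test_that("diagonal-cell predictions are independent of w", {
  d <- quick_cohort(2000, seed = 37)
  f <- fit_drm(d, compute_vcov = FALSE)
  base <- predict_cell(f, "medium", "medium")
  f2 <- f
  f2$w <- 0.9
  alt <- predict_cell(f2, "medium", "medium")
  expect_lt(abs(base$eta - alt$eta), 1e-12)
  expect_equal(base$odds, f$diagonal$odds[2])
})

test_that("cell predictions follow the fitted interpolation", {
  d <- quick_cohort(2000, seed = 41)
  f <- fit_drm(d, compute_vcov = FALSE)
  f$w <- 0.7
  pr <- predict_cell(f, "high", "low")
  expect_equal(pr$eta,
               unname(0.7 * f$gamma["high"] + 0.3 * f$gamma["low"]))
  expect_equal(pr$probability, plogis(pr$eta))
  # w = 0: prediction depends on destination only
  f$w <- 0
  expect_equal(predict_cell(f, "high", "low")$eta,
               predict_cell(f, "medium", "low")$eta)
  expect_error(predict_cell(f, "phd", "low"), "unknown education level")
})

test_that("the supplementary w test is plain Wald arithmetic", {
  d <- quick_cohort(3000, seed = 44)
  f <- fit_drm(d)
  tw <- test_w_against(f, null = f$w)
  expect_equal(tw$z, 0)
  expect_equal(tw$p_value, 1)
  f$w <- 0.35
  f$w_se <- 0.24
  tw2 <- test_w_against(f, 0.5)
  expect_equal(tw2$z, -0.625, tolerance = 1e-12)
  expect_equal(tw2$p_value, 2 * pnorm(-0.625), tolerance = 1e-12)
  f$convergence$boundary <- TRUE
  expect_error(test_w_against(f), "refused")
})

test_that("the w test is calibrated when origin and destination weigh equally", {
  cfg <- default_sim_config("male", n = 5000)
  cfg$w_true <- 0.5
  set.seed(53)
  seeds <- sample.int(1e6, 250)
  rej <- vapply(seeds, function(s) {
    f <- fit_drm(simulate_cohort(cfg, seed = s))
    if (f$convergence$boundary) return(NA)
    test_w_against(f, 0.5)$p_value < 0.05
  }, logical(1))
  rate <- mean(rej, na.rm = TRUE)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
})

test_that("profile-likelihood CI for w inverts the likelihood ratio inside [0, 1]", {
  d <- quick_cohort(2500, seed = 131)
  f <- fit_drm(d)
  expect_identical(confint(f), f$w_ci)
  ci <- confint(f, method = "profile", data = d)
  expect_true(ci[1] >= 0 && ci[2] <= 1)
  expect_true(ci[1] <= f$w && f$w <= ci[2])
  # endpoints sit at the chi-square cutoff when interior
  cut <- f$loglik - qchisq(0.95, 1) / 2
  for (e in ci[ci > 1e-9 & ci < 1 - 1e-9]) {
    expect_lt(abs(drm_profile(d, e)$loglik - cut), 1e-3)
  }
})

test_that("odds-scale interpolation reproduces expository arithmetic", {
  expect_equal(interpolate_odds(0.35, 0.41, 0.73), 0.618)
  # and differs from the link-scale combination used by the model
  expect_equal(exp(0.35 * log(0.41) + 0.65 * log(0.73)), 0.5965,
               tolerance = 1e-4)
})

test_that("the linear (identity-link) variant recovers a continuous surface", {
  cfg <- default_sim_config("male", n = 2e4)
  d <- simulate_cohort(cfg, seed = 59)
  # continuous outcome from the same interpolation structure
  mu <- drm_linear_predictor(d$origin, d$destination, cfg)
  set.seed(60)
  d$outcome <- mu + rnorm(nrow(d), sd = 0.5)
  f <- fit_drm(d, link = "identity", compute_vcov = FALSE)
  expect_lt(abs(f$w - cfg$w_true), 0.1)
  expect_lt(max(abs(f$gamma - cfg$gamma)), 0.05)
})
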