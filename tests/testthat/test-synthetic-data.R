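test_that("default cell probabilities are the packaged counts normalised", {
  pm <- default_cell_probs("male")
  expect_equal(pm["low", "low"], 361 / 1569)
  expect_equal(sum(pm), 1)
  pf <- default_cell_probs("female")
  expect_equal(pf["high", "high"], 199 / 1771)
  expect_equal(sum(pf), 1)
})

test_that("default parameters match the reference analysis by sex", {
  cm <- default_sim_config("male")
  expect_equal(unname(cm$gamma), log(c(0.73, 0.74, 0.41)))
  expect_equal(cm$w_true, 0.35)
  expect_equal(cm$n, 1569L)
  cf <- default_sim_config("female")
  expect_equal(unname(cf$gamma), log(c(0.98, 0.55, 0.31)))
  expect_equal(cf$w_true, 0.32)
  expect_equal(cf$n, 1771L)
  expect_equal(cm$age_mean, 34.95)
  expect_equal(cm$age_sd, 6.88)
  expect_equal(cm$p_native, 0.526)
  expect_equal(cm$marital_probs, c(0.191, 0.564, 0.170, 0.075))
  expect_true(all(cm$beta == 0))
})

test_that("configuration invariants are enforced", {
  p <- default_cell_probs("male")
  expect_error(sim_config(10, p * 2, gamma = c(0, 0, 0), w_true = 0.5),
               "sum to 1")
  expect_error(sim_config(10, p, gamma = c(0, 0, 0), w_true = 1.2),
               "\\[0, 1\\]")
  expect_error(sim_config(10, p, gamma = c(0, 0, 0), w_true = 0.5,
                          beta = c(bmi = 1)), "unknown beta")
})

test_that("the generating linear predictor interpolates diagonal log-odds", {
  cfg <- default_sim_config("male")
  # diagonal identity: eta = gamma_k for any w
  for (w in c(0, 0.35, 1)) {
    cfg$w_true <- w
    expect_equal(unname(drm_linear_predictor("medium", "medium", cfg)),
                 unname(cfg$gamma["medium"]))
  }
  cfg$w_true <- 1
  expect_equal(unname(drm_linear_predictor("low", "high", cfg)),
               unname(cfg$gamma["low"]))
  cfg$w_true <- 0.7
  expect_equal(unname(drm_linear_predictor("high", "low", cfg)),
               unname(0.7 * cfg$gamma["high"] + 0.3 * cfg$gamma["low"]))
})

test_that("the same seed reproduces the same cohort", {
  cfg <- default_sim_config("male", n = 500)
  expect_identical(simulate_cohort(cfg, seed = 3),
                   simulate_cohort(cfg, seed = 3))
})

test_that("cell-wise outcome odds converge to the configured DRM surface", {
  cfg <- default_sim_config("male", n = 2e5)
  d <- simulate_cohort(cfg, seed = 21)
  # immobile-high: closed-form P = odds/(1+odds) with odds 0.41
  ih <- d$outcome[d$origin == "high" & d$destination == "high"]
  p0 <- 0.41 / 1.41
  expect_lt(abs(mean(ih) - p0), 3 * sqrt(p0 * (1 - p0) / length(ih)))
  # whole surface on the log-odds scale
  err <- sapply(education_levels(), function(o) {
    sapply(education_levels(), function(dd) {
      y <- d$outcome[d$origin == o & d$destination == dd]
      emp <- qlogis(mean(y))
      truth <- drm_linear_predictor(o, dd, cfg)
      abs(emp - truth)
    })
  })
  expect_lt(max(err), 0.05)
})

test_that("a homogeneous model yields the marginal logistic rate", {
  cfg <- default_sim_config("male", n = 5e4)
  cfg$gamma[] <- -0.3
  cfg$w_true <- 0.5
  d <- simulate_cohort(cfg, seed = 8)
  p0 <- plogis(-0.3)
  expect_lt(abs(mean(d$outcome) - p0),
            3 * sqrt(p0 * (1 - p0) / nrow(d)))
})

test_that("empirical cell frequencies match cell_probs (chi-square GOF)", {
  cfg <- default_sim_config("male", n = 1e5)
  for (seed in c(2, 12, 22)) {
    d <- simulate_cohort(cfg, seed = seed)
    obs <- as.vector(table(d$origin, d$destination))
    gof <- suppressWarnings(
      chisq.test(obs, p = as.vector(cfg$cell_probs)))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("covariate marginals match the configuration within Monte-Carlo error", {
  d <- quick_cohort(1e5, seed = 31)
  expect_lt(abs(mean(d$native) - 0.526), 3 * sqrt(0.526 * 0.474 / 1e5))
  shares <- prop.table(table(d$marital_status))
  expect_lt(max(abs(shares - c(0.191, 0.564, 0.170, 0.075))), 0.006)
  expect_true(all(d$age >= 18 & d$age <= 45))
})

test_that("degenerate sampling configurations are flagged", {
  cfg <- default_sim_config("male", n = 100)
  cfg$cell_probs[] <- 0
  diag(cfg$cell_probs) <- 1 / 3
  cfg$delta_down <- 0.5
  expect_error(simulate_cohort(cfg, seed = 1), "unidentifiable")
  cfg2 <- default_sim_config("male", n = 100)
  cfg2$cell_probs[, "high"] <- 0
  cfg2$cell_probs["high", ] <- 0
  cfg2$cell_probs <- cfg2$cell_probs / sum(cfg2$cell_probs)
  expect_warning(simulate_cohort(cfg2, seed = 1), "zero sampling mass")
})

test_that("covariate effects propagate through the generator", {
  cfg <- default_sim_config("male", n = 8e4, beta = realistic_betas())
  d <- simulate_cohort(cfg, seed = 41)
  # natives should have lower OWOB odds (OR 0.68 in the DGP)
  or_native <- (mean(d$outcome[d$native == 1]) /
                  (1 - mean(d$outcome[d$native == 1]))) /
    (mean(d$outcome[d$native == 0]) / (1 - mean(d$outcome[d$native == 0])))
  expect_lt(or_native, 0.85)
})
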