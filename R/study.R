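#' Per-replicate substreams from a master seed
#'
#' One master seed expands to independent per-replicate seeds so each
#' replicate is individually reproducible.
#' @param master_seed Integer.
#' @param n_reps Number of replicates.
#' @return Integer vector of seeds.
#' @keywords internal
replicate_seeds <- function(master_seed, n_reps) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n_reps)
}

study_methods <- function() {
  c("drm_down", "drm_up", "conv_groups", "conv_groups_holm",
    "conv_origin_control")
}

# One replicate: simulate, fit the selected methods, return the rejection
# decisions (NA = fit did not converge, excluded from rate denominators).
study_replicate <- function(config, seed, methods, alpha, covariates) {
  dat <- simulate_cohort(config, seed = seed)
  dec <- stats::setNames(rep(NA, length(methods)), methods)
  for (m in intersect(methods, c("drm_down", "drm_up"))) {
    mob <- if (m == "drm_down") "downward" else "upward"
    fit <- tryCatch(
      suppressWarnings(fit_drm(dat, mobility = mob, covariates = covariates)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$convergence$converged &&
        !fit$convergence$separation) {
      dec[m] <- fit$covariates$p_value[fit$covariates$term == mob] < alpha
    }
  }
  if (any(c("conv_groups", "conv_groups_holm") %in% methods)) {
    tab <- tryCatch(
      suppressWarnings(fit_mobility_group_model(dat, covariates)),
      error = function(e) NULL)
    if (!is.null(tab)) {
      p <- mobility_p_values(tab)
      if ("conv_groups" %in% methods) dec["conv_groups"] <- any(p < alpha)
      if ("conv_groups_holm" %in% methods) {
        dec["conv_groups_holm"] <- any(stats::p.adjust(p, "holm") < alpha)
      }
    }
  }
  if ("conv_origin_control" %in% methods) {
    tab <- tryCatch(
      suppressWarnings(fit_origin_control_model(dat, covariates)),
      error = function(e) NULL)
    if (!is.null(tab)) {
      dec["conv_origin_control"] <- any(mobility_p_values(tab) < alpha)
    }
  }
  dec
}

#' Type-I-error study: spurious mobility effects under a null DRM
#'
#' Generates replicate cohorts from a DRM data-generating process with no
#' true mobility effect (delta = 0) and records, per method, how often a
#' mobility effect is declared at level alpha: for the DRM, the Wald test of
#' the mobility covariate; for the mobility-group design, "any of the six
#' mobile-group dummies significant" (with a Holm-adjusted variant); for the
#' origin-control design, "any mobility-status term significant". Under a
#' social gradient in the diagonal intercepts the conventional designs
#' conflate position with mobility and over-reject, while the DRM test stays
#' near nominal.
#'
#' @param config A [sim_config()] with \code{delta_down = delta_up = 0}.
#' @param n_reps Number of replicate cohorts.
#' @param alpha Test level.
#' @param methods Subset of \code{drm_down}, \code{drm_up},
#'   \code{conv_groups}, \code{conv_groups_holm},
#'   \code{conv_origin_control}.
#' @param covariates Covariate columns passed to every fitter.
#' @param master_seed Master seed; replicates use derived substreams.
#' @return A \code{mobility_study}: list with \code{rates} (method,
#'   rejection_rate, mc_se, n_used, n_failed), the per-replicate
#'   \code{decisions} matrix (the audit trail from which every rate is
#'   recomputable), \code{alpha}, \code{config}, \code{master_seed}.
#' @export
run_type1_study <- function(config, n_reps = 1000, alpha = 0.05,
                            methods = c("drm_down", "conv_groups",
                                        "conv_groups_holm",
                                        "conv_origin_control"),
                            covariates = character(), master_seed = 1) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1,
            alpha > 0, alpha < 1)
  methods <- match.arg(methods, study_methods(), several.ok = TRUE)
  if (config$delta_down != 0 || config$delta_up != 0) {
    stop("type-I study requires delta_down = delta_up = 0 (got a non-null ",
         "mobility effect in the generating model)")
  }
  seeds <- replicate_seeds(master_seed, n_reps)
  decisions <- do.call(rbind, lapply(seeds, function(s) {
    study_replicate(config, s, methods, alpha, covariates)
  }))
  rates <- summarize_decisions(decisions)
  structure(list(rates = rates, decisions = decisions, alpha = alpha,
                 config = config, master_seed = master_seed,
                 kind = "type1"),
            class = "mobility_study")
}

summarize_decisions <- function(decisions) {
  out <- lapply(colnames(decisions), function(m) {
    d <- decisions[, m]
    used <- sum(!is.na(d))
    r <- mean(d, na.rm = TRUE)
    data.frame(method = m, rejection_rate = r,
               mc_se = sqrt(r * (1 - r) / used),
               n_used = used, n_failed = sum(is.na(d)))
  })
  do.call(rbind, out)
}

#' @export
print.mobility_study <- function(x, ...) {
  cat(sprintf("Mobility-effect simulation study (%s), %d replicates, alpha = %g\n",
              x$kind, nrow(x$decisions), x$alpha))
  print(format(x$rates, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Power study of the DRM mobility test
#'
#' Sweeps the true mobility log-odds-ratio (and optionally the cohort size)
#' and records the DRM rejection rate at each grid point. The delta = 0
#' point reduces to the type-I rate.
#'
#' @param config Base [sim_config()].
#' @param delta_grid True mobility log-odds-ratios.
#' @param direction \code{"downward"} or \code{"upward"}: which mobility
#'   effect is generated and tested.
#' @param n_grid Cohort sizes to sweep (default: the configured n).
#' @param n_reps Replicates per grid point.
#' @param alpha Test level.
#' @param master_seed Master seed.
#' @return A \code{mobility_study} whose \code{rates} has one row per
#'   (delta, n) grid point.
#' @export
run_power_study <- function(config, delta_grid,
                            direction = c("downward", "upward"),
                            n_grid = NULL, n_reps = 500, alpha = 0.05,
                            master_seed = 1) {
  direction <- match.arg(direction)
  if (is.null(n_grid)) n_grid <- config$n
  grid <- expand.grid(delta = delta_grid, n = n_grid)
  method <- if (direction == "downward") "drm_down" else "drm_up"
  res <- vector("list", nrow(grid))
  all_dec <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cf <- config
    cf$n <- as.integer(grid$n[g])
    if (direction == "downward") cf$delta_down <- grid$delta[g] else
      cf$delta_up <- grid$delta[g]
    seeds <- replicate_seeds(master_seed + g - 1L, n_reps)
    dec <- vapply(seeds, function(s) {
      study_replicate(cf, s, method, alpha, character())[[1]]
    }, logical(1))
    used <- sum(!is.na(dec))
    r <- mean(dec, na.rm = TRUE)
    res[[g]] <- data.frame(delta = grid$delta[g], n = grid$n[g],
                           method = method, rejection_rate = r,
                           mc_se = sqrt(r * (1 - r) / used),
                           n_used = used, n_failed = sum(is.na(dec)))
    all_dec[[g]] <- dec
  }
  structure(list(rates = do.call(rbind, res),
                 decisions = all_dec, alpha = alpha, config = config,
                 master_seed = master_seed, kind = "power"),
            class = "mobility_study")
}

#' Parameter-recovery study for the DRM
#'
#' Simulates cohorts over a grid of true origin weights, fits the DRM with
#' a mobility covariate, and reports bias, RMSE and 95% CI coverage for the
#' origin weight, the diagonal odds, and the mobility log-odds-ratio.
#'
#' @param config Base [sim_config()]; its delta values are the truth whose
#'   CI coverage is scored.
#' @param w_grid True origin weights to sweep (default: the configured one).
#' @param n Cohort size (default: the configured one).
#' @param n_reps Replicates per grid point.
#' @param mobility Mobility covariate included in the fitted model.
#' @param master_seed Master seed.
#' @return A \code{mobility_study} whose \code{rates} has, per w_true:
#'   mean/bias/RMSE of what, coverage of the w and delta CIs, mean
#'   diagonal odds, and failure counts. The per-replicate estimates are in
#'   \code{estimates}.
#' @export
run_recovery_study <- function(config, w_grid = NULL, n = NULL,
                               n_reps = 200,
                               mobility = c("downward", "upward"),
                               master_seed = 1) {
  mobility <- match.arg(mobility)
  if (is.null(w_grid)) w_grid <- config$w_true
  if (is.null(n)) n <- config$n
  delta_true <- if (mobility == "downward") config$delta_down else
    config$delta_up
  res <- vector("list", length(w_grid))
  ests <- vector("list", length(w_grid))
  for (g in seq_along(w_grid)) {
    cf <- config
    cf$w_true <- w_grid[g]
    cf$n <- as.integer(n)
    seeds <- replicate_seeds(master_seed + g - 1L, n_reps)
    rep_est <- lapply(seeds, function(s) {
      dat <- simulate_cohort(cf, seed = s)
      fit <- tryCatch(
        suppressWarnings(fit_drm(dat, mobility = mobility)),
        error = function(e) NULL)
      if (is.null(fit) || !fit$convergence$converged) return(NULL)
      zq <- stats::qnorm(0.975)
      drow <- fit$covariates[fit$covariates$term == mobility, ]
      data.frame(w_hat = fit$w,
                 w_covered = fit$w_ci[1] <= cf$w_true &&
                   cf$w_true <= fit$w_ci[2],
                 odds_low = fit$diagonal$odds[1],
                 odds_medium = fit$diagonal$odds[2],
                 odds_high = fit$diagonal$odds[3],
                 delta_hat = log(drow$odds_ratio),
                 delta_covered = drow$ci_low <= exp(delta_true) &&
                   exp(delta_true) <= drow$ci_high,
                 boundary = fit$convergence$boundary)
    })
    ok <- !vapply(rep_est, is.null, logical(1))
    e <- do.call(rbind, rep_est[ok])
    res[[g]] <- data.frame(
      w_true = w_grid[g], n = n,
      w_mean = mean(e$w_hat),
      w_bias = mean(e$w_hat) - w_grid[g],
      w_rmse = sqrt(mean((e$w_hat - w_grid[g])^2)),
      w_coverage = mean(e$w_covered[!e$boundary]),
      odds_low_mean = mean(e$odds_low),
      odds_medium_mean = mean(e$odds_medium),
      odds_high_mean = mean(e$odds_high),
      delta_mean = mean(e$delta_hat),
      delta_coverage = mean(e$delta_covered),
      n_used = nrow(e), n_failed = sum(!ok))
    ests[[g]] <- e
  }
  structure(list(rates = do.call(rbind, res), estimates = ests,
                 config = config, master_seed = master_seed,
                 kind = "recovery"),
            class = "mobility_study")
}
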