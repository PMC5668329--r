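#' Default origin-by-destination cell probabilities
#'
#' The packaged mobility counts (see [nl2009_mobility_counts()]) normalised
#' by their grand total, giving the joint distribution of (origin,
#' destination) used by the simulator.
#'
#' @param sex \code{"male"} or \code{"female"}.
#' @return K x K matrix of probabilities summing to 1 (rows = origin).
#' @export
default_cell_probs <- function(sex = c("male", "female")) {
  tab <- nl2009_mobility_counts(match.arg(sex))
  tab$counts / tab$grand_total
}

#' Simulation configuration for synthetic mobility cohorts
#'
#' Parameterises the data-generating process: a logistic diagonal reference
#' model with diagonal log-odds \code{gamma}, origin weight \code{w_true},
#' additional mobility log-odds-ratios \code{delta_down}/\code{delta_up},
#' covariate log-odds-ratios \code{beta}, and the marginal distributions of
#' the covariates.
#'
#' @param n Cohort size.
#' @param cell_probs K x K joint (origin, destination) probabilities,
#'   rows = origin; must sum to 1.
#' @param gamma Length-K diagonal intercepts on the log-odds scale
#'   (log odds of the outcome for immobile individuals at each level).
#' @param w_true Origin weight in [0, 1].
#' @param delta_down,delta_up Log-odds-ratios for having moved downward /
#'   upward (0 = no true mobility effect).
#' @param beta Named numeric vector of covariate log-odds-ratios:
#'   \code{age} (per centred year), \code{native}, and one entry per
#'   non-reference marital category (\code{married_cohab},
#'   \code{unmarried_cohab}, \code{no_cohabitation}). Defaults to all zero
#'   so structural tests are not confounded by covariates.
#' @param age_mean,age_sd,age_range Age distribution: normal truncated to
#'   \code{age_range}, with the underlying location and scale solved so the
#'   \emph{truncated} distribution has mean \code{age_mean} and standard
#'   deviation \code{age_sd} (the observable sample moments).
#' @param p_native Probability of being native-born.
#' @param marital_probs Length-4 probabilities over [marital_levels()].
#' @param levels Education level labels.
#' @param sex Label attached to the cohort (\code{"male"}/\code{"female"}).
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n,
                       cell_probs,
                       gamma,
                       w_true,
                       delta_down = 0,
                       delta_up = 0,
                       beta = NULL,
                       age_mean = 34.95,
                       age_sd = 6.88,
                       age_range = c(18, 45),
                       p_native = 0.526,
                       marital_probs = c(0.191, 0.564, 0.170, 0.075),
                       levels = education_levels(),
                       sex = "male") {
  K <- length(levels)
  cell_probs <- as.matrix(cell_probs)
  stopifnot(n > 0, nrow(cell_probs) == K, ncol(cell_probs) == K,
            all(cell_probs >= 0), length(gamma) == K,
            length(marital_probs) == 4)
  if (abs(sum(cell_probs) - 1) > 1e-12) {
    stop("cell_probs must sum to 1 (got ", sum(cell_probs), ")")
  }
  if (w_true < 0 || w_true > 1) stop("w_true must lie in [0, 1]")
  if (abs(sum(marital_probs) - 1) > 1e-8) {
    stop("marital_probs must sum to 1")
  }
  beta_full <- c(age = 0, native = 0,
                 married_cohab = 0, unmarried_cohab = 0, no_cohabitation = 0)
  if (!is.null(beta)) {
    bad <- setdiff(names(beta), names(beta_full))
    if (length(bad)) stop("unknown beta name(s): ", paste(bad, collapse = ", "))
    beta_full[names(beta)] <- beta
  }
  dimnames(cell_probs) <- list(origin = levels, destination = levels)
  structure(
    list(n = as.integer(n), cell_probs = cell_probs,
         gamma = stats::setNames(as.numeric(gamma), levels),
         w_true = w_true, delta_down = delta_down, delta_up = delta_up,
         beta = beta_full, age_mean = age_mean, age_sd = age_sd,
         age_range = age_range, p_native = p_native,
         marital_probs = marital_probs, levels = levels, sex = sex),
    class = "sim_config")
}

#' Default simulation parameters by sex
#'
#' Diagonal odds and origin weight from the package's reference analysis of
#' Dutch adults: males (0.73, 0.74, 0.41) with w = 0.35 on cohorts of 1569;
#' females (0.98, 0.55, 0.31) with w = 0.32 on cohorts of 1771. Mobility and
#' covariate effects default to zero; covariate marginals are age ~ 34.95
#' (SD 6.88) truncated to 18-45, 52.6% native, marital shares
#' 19.1/56.4/17.0/7.5%.
#'
#' @param sex \code{"male"} or \code{"female"}.
#' @param n Cohort size override (default: the reference sample size).
#' @param ... Further overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
default_sim_config <- function(sex = c("male", "female"), n = NULL, ...) {
  sex <- match.arg(sex)
  if (sex == "male") {
    gamma <- log(c(0.73, 0.74, 0.41))
    w <- 0.35
    n0 <- 1569L
  } else {
    gamma <- log(c(0.98, 0.55, 0.31))
    w <- 0.32
    n0 <- 1771L
  }
  sim_config(n = if (is.null(n)) n0 else n,
             cell_probs = default_cell_probs(sex),
             gamma = gamma, w_true = w, sex = sex, ...)
}

#' Realistic covariate effect preset
#'
#' Covariate log-odds-ratios near typical adult-cohort estimates (age OR
#' 1.05 per year, native 0.68, marital 2.38/1.42/1.36 vs no partner), for
#' integration tests where covariate structure matters.
#'
#' @return Named numeric vector suitable for the \code{beta} argument of
#'   [sim_config()].
#' @export
realistic_betas <- function() {
  c(age = log(1.05), native = log(0.68),
    married_cohab = log(2.38), unmarried_cohab = log(1.42),
    no_cohabitation = log(1.36))
}

#' Linear predictor of the generating diagonal reference model
#'
#' eta = w * gamma[origin] + (1 - w) * gamma[destination]
#'       + delta_down * 1[downward] + delta_up * 1[upward] + x' beta,
#' with the weighted combination taken on the log-odds scale so that the
#' generative model coincides with the fitted logistic DRM.
#'
#' @param origin,destination Education levels.
#' @param config A [sim_config()].
#' @param age_c Centred age (default 0).
#' @param native 0/1 (default 0).
#' @param marital_status Marital category (default reference,
#'   \code{no_partner}).
#' @return Numeric vector of linear predictors (log-odds).
#' @export
drm_linear_predictor <- function(origin, destination, config,
                                 age_c = 0, native = 0,
                                 marital_status = "no_partner") {
  origin <- as_education(origin, config$levels)
  destination <- as_education(destination, config$levels)
  status <- classify_mobility(origin, destination)
  b <- config$beta
  marital_status <- factor(as.character(marital_status),
                           levels = marital_levels())
  mar_beta <- c(no_partner = 0, b[c("married_cohab", "unmarried_cohab",
                                    "no_cohabitation")])
  config$w_true * config$gamma[as.integer(origin)] +
    (1 - config$w_true) * config$gamma[as.integer(destination)] +
    config$delta_down * (status == "downward") +
    config$delta_up * (status == "upward") +
    b["age"] * age_c + b["native"] * native +
    unname(mar_beta[as.integer(marital_status)])
}

trunc_norm_moments <- function(mu, s, a, b) {
  al <- (a - mu) / s; be <- (b - mu) / s
  Z <- stats::pnorm(be) - stats::pnorm(al)
  m <- mu + s * (stats::dnorm(al) - stats::dnorm(be)) / Z
  v <- s^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / Z -
                ((stats::dnorm(al) - stats::dnorm(be)) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Location/scale of the underlying normal whose truncation to `range` has
# the requested mean and sd, so the generated marginal matches the target
# moments rather than the pre-truncation ones.
trunc_norm_params <- function(mean, sd, range) {
  obj <- function(p) {
    sum((trunc_norm_moments(p[1], exp(p[2]), range[1], range[2]) -
           c(mean, sd))^2)
  }
  o <- stats::optim(c(mean, log(sd)), obj,
                    control = list(reltol = 1e-14, maxit = 5000))
  if (o$value > 1e-6) {
    warning("target age moments not attainable under truncation to [",
            range[1], ", ", range[2], "]; using closest match")
  }
  c(mu = o$par[1], sigma = exp(o$par[2]))
}

rtrunc_norm <- function(n, mean, sd, range) {
  p <- trunc_norm_params(mean, sd, range)
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), p["mu"], p["sigma"])
    ok <- draw >= range[1] & draw <= range[2]
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a synthetic mobility cohort
#'
#' Draws (origin, destination) pairs from the configured joint cell
#' probabilities, covariates from their marginals (age truncated-normal and
#' then centred at the configured mean; native Bernoulli; marital
#' categorical), and the binary outcome from the logistic diagonal reference
#' model defined by the configuration. Fully reproducible given \code{seed}.
#' The generating parameters travel with the data as the \code{"truth"}
#' attribute for recovery scoring.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return Data frame with columns \code{origin}, \code{destination},
#'   \code{outcome}, \code{age}, \code{age_c}, \code{native},
#'   \code{marital_status}, \code{weight}, \code{enrolled}, \code{sex};
#'   attribute \code{"truth"} holds the configuration.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  K <- length(config$levels)
  p <- as.vector(config$cell_probs)
  never <- rowSums(config$cell_probs) + colSums(config$cell_probs) == 0
  if (any(never)) {
    warning("level(s) with zero sampling mass: ",
            paste(config$levels[never], collapse = ", "))
  }
  off_mass <- sum(config$cell_probs) - sum(diag(config$cell_probs))
  if (off_mass <= 0 && (config$delta_down != 0 || config$delta_up != 0)) {
    stop("all probability mass on the diagonal: mobility effects are ",
         "unidentifiable")
  }
  idx <- sample.int(K * K, config$n, replace = TRUE, prob = p)
  oi <- ((idx - 1L) %% K) + 1L       # row index = origin
  di <- ((idx - 1L) %/% K) + 1L      # column index = destination
  origin <- as_education(config$levels[oi], config$levels)
  destination <- as_education(config$levels[di], config$levels)
  age <- rtrunc_norm(config$n, config$age_mean, config$age_sd,
                     config$age_range)
  age_c <- age - config$age_mean
  native <- stats::rbinom(config$n, 1L, config$p_native)
  marital <- factor(sample(marital_levels(), config$n, replace = TRUE,
                           prob = config$marital_probs),
                    levels = marital_levels())
  eta <- drm_linear_predictor(origin, destination, config,
                              age_c = age_c, native = native,
                              marital_status = marital)
  outcome <- stats::rbinom(config$n, 1L, stats::plogis(eta))
  out <- data.frame(origin = origin, destination = destination,
                    outcome = outcome, age = age, age_c = age_c,
                    native = native, marital_status = marital,
                    weight = 1, enrolled = 0L, sex = config$sex)
  attr(out, "truth") <- config
  out
}
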