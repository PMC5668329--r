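#' Weighted maximum-likelihood logistic fit by IRLS
#'
#' Bernoulli-logit maximum likelihood with case weights multiplying the
#' log-likelihood contributions, solved by iteratively reweighted least
#' squares. This is the inner solver of the diagonal reference model:
#' conditional on the origin weight w the DRM is an ordinary logistic GLM on
#' the constructed design, so the profile search needs nothing more than
#' repeated calls to this routine. Convergence is declared when the maximum
#' absolute score drops below \code{tol_score} or the relative
#' log-likelihood change below \code{tol_loglik}.
#'
#' @param X Design matrix (no intercept is added).
#' @param y 0/1 response.
#' @param weights Positive case weights (default all 1).
#' @param tol_score,tol_loglik Convergence tolerances.
#' @param max_iter Iteration cap.
#' @param start Optional starting coefficients (e.g. the solution at a
#'   nearby profile point); defaults to zero.
#' @return List with \code{coefficients}, \code{loglik}, \code{vcov}
#'   (inverse observed information of the conditional fit), \code{fitted}
#'   (probabilities), \code{iterations}, \code{converged}, and
#'   \code{separation} (TRUE when a coefficient diverged beyond 15 on the
#'   logit scale, with the offending columns in
#'   \code{separation_columns}).
#' @export
logit_irls <- function(X, y, weights = NULL,
                       tol_score = 1e-8, tol_loglik = 1e-10,
                       max_iter = 50L, start = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, all(y %in% c(0, 1)))
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(all(weights > 0))
  if (qr(X)$rank < p) {
    stop("design matrix is rank deficient (", p, " columns, rank ",
         qr(X)$rank, ")")
  }
  b <- if (is.null(start)) numeric(p) else start
  stopifnot(length(b) == p)
  ll_old <- -Inf
  converged <- FALSE
  sep_cols <- character()
  it <- 0L
  repeat {
    it <- it + 1L
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-12)
    W <- weights * v
    z <- eta + (y - mu) / v
    sw <- sqrt(W)
    b <- .lm.fit(X * sw, z * sw)$coefficients
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    ll <- bernoulli_loglik(y, eta, weights)
    score <- drop(crossprod(X, weights * (y - mu)))
    diverged <- abs(b) > 15
    if (any(diverged)) {
      sep_cols <- colnames(X)[diverged]
      if (is.null(sep_cols)) sep_cols <- paste0("V", which(diverged))
      warning("possible separation: coefficient(s) diverging for column(s) ",
              paste(sep_cols, collapse = ", "))
      break
    }
    if (max(abs(score)) < tol_score ||
        abs(ll - ll_old) < tol_loglik * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_old <- ll
  }
  v <- pmax(mu * (1 - mu), 1e-12)
  XtWX <- crossprod(X * sqrt(weights * v))
  vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e) MASS::ginv(XtWX))
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(b, colnames(X)),
       loglik = ll, vcov = vc, fitted = mu,
       iterations = it, converged = converged,
       separation = length(sep_cols) > 0,
       separation_columns = sep_cols)
}

# Numerically stable sum of weighted Bernoulli log-likelihood terms
bernoulli_loglik <- function(y, eta, weights) {
  # log(1 + exp(eta)) computed without overflow for large |eta|
  lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  sum(weights * (y * eta - lse))
}

#' Weighted least-squares fit (identity link)
#'
#' Gaussian inner solver for the linear diagonal reference model variant
#' (continuous outcomes such as BMI itself).
#'
#' @inheritParams logit_irls
#' @return List in the shape of [logit_irls()]'s value; \code{loglik} is the
#'   Gaussian profile log-likelihood at the MLE of the residual variance.
#' @export
gaussian_wls <- function(X, y, weights = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  sw <- sqrt(weights)
  fit <- .lm.fit(X * sw, y * sw)
  b <- fit$coefficients
  res <- y - drop(X %*% b)
  wn <- sum(weights)
  sigma2 <- sum(weights * res^2) / wn
  ll <- -0.5 * wn * (log(2 * pi * sigma2) + 1)
  XtWX <- crossprod(X * sw)
  vc <- tryCatch(chol2inv(chol(XtWX)) * sigma2,
                 error = function(e) MASS::ginv(XtWX) * sigma2)
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(b, colnames(X)),
       loglik = ll, vcov = vc, fitted = drop(X %*% b),
       iterations = 1L, converged = TRUE,
       separation = FALSE, separation_columns = character())
}
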