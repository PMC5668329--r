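#' Mobility-group table order
#'
#' The nine origin-destination groups in the canonical reporting order:
#' the always-advantaged immobile (reference) first, then the remaining
#' immobile by descending position, the downwardly mobile, and the upwardly
#' mobile.
#' @return Character vector of "origin-destination" labels.
#' @export
mobility_group_levels <- function() {
  c("high-high", "medium-medium", "low-low",
    "high-medium", "medium-low", "high-low",
    "medium-high", "low-medium", "low-high")
}

#' Conventional design 1: mobility-group dummies
#'
#' Logistic regression of the outcome on eight dummy variables for the nine
#' origin-by-destination groups (reference: the immobile high group, the
#' "always advantaged"), plus an intercept and covariates. Because each
#' mobile group differs from the reference in position of origin and/or
#' destination as well as in having moved, its dummy conflates position and
#' mobility effects — the phenomenon the DRM resolves.
#'
#' @param data Data frame of mobility records.
#' @param covariates Character vector of covariate column names.
#' @param weights Case weights: a column name or numeric vector.
#' @return An \code{or_table} data frame (term, odds_ratio, ci_low,
#'   ci_high, p_value, is_reference, block) with the fitted
#'   \code{\link[stats]{glm}} in attribute \code{"fit"}. Mobile-group rows
#'   carry block \code{"downward"} or \code{"upward"}.
#' @export
fit_mobility_group_model <- function(data, covariates = character(),
                                     weights = NULL) {
  origin <- as_education(data$origin)
  destination <- as_education(data$destination)
  group <- factor(paste(origin, destination, sep = "-"),
                  levels = mobility_group_levels())
  empty <- setdiff(mobility_group_levels(), unique(as.character(group)))
  if (length(empty)) {
    warning("empty mobility group(s) dropped: ", paste(empty, collapse = ", "))
    group <- droplevels(group)
  }
  glm_fit <- conventional_glm(data, cbind(group_dummies(group)),
                              covariates, weights)
  rows <- or_rows(glm_fit)
  lab_block <- function(lab) {
    g <- sub("^group", "", lab)
    as.character(classify_mobility(sub("-.*", "", g), sub(".*-", "", g)))
  }
  out <- build_or_table(rows, reference = "high-high",
                        ref_block = "immobile",
                        term_block = lab_block,
                        design = "groups")
  attr(out, "fit") <- glm_fit
  out
}

#' Conventional design 2: mobility status controlling for origin
#'
#' Logistic regression of the outcome on mobility status (reference:
#' immobile) and origin dummies (reference: high), plus an intercept and
#' covariates. Controlling for origin makes the mobility coefficients
#' independent of origin but not of destination, so they remain conflated
#' with destination effects.
#'
#' @inheritParams fit_mobility_group_model
#' @return An \code{or_table}; the mobility-status rows carry block
#'   \code{"mobility"}, the origin rows block \code{"origin"}.
#' @export
fit_origin_control_model <- function(data, covariates = character(),
                                     weights = NULL) {
  status <- classify_mobility(data$origin, data$destination)
  origin <- factor(as.character(as_education(data$origin)),
                   levels = c("high", "medium", "low"))
  Xm <- stats::model.matrix(~status)[, -1, drop = FALSE]
  colnames(Xm) <- paste0("mobility", levels(status)[-1])
  Xo <- stats::model.matrix(~origin)[, -1, drop = FALSE]
  colnames(Xo) <- paste0("origin", levels(origin)[-1])
  glm_fit <- conventional_glm(data, cbind(Xm, Xo), covariates, weights)
  rows <- or_rows(glm_fit)
  lab_block <- function(lab) {
    ifelse(grepl("^mobility", lab), "mobility",
           ifelse(grepl("^origin", lab), "origin", "covariate"))
  }
  out <- build_or_table(rows, reference = "immobile", ref_block = "mobility",
                        term_block = lab_block, design = "origin_control",
                        extra_reference = c(origin_high = "origin"))
  attr(out, "fit") <- glm_fit
  out
}

group_dummies <- function(group) {
  mm <- stats::model.matrix(~group)[, -1, drop = FALSE]
  mm
}

# Shared glm backend: intercept + supplied dummy block + covariates.
conventional_glm <- function(data, dummies, covariates, weights) {
  Xc <- build_covariate_matrix(data, covariates)
  X <- cbind(dummies, Xc)
  df <- data.frame(outcome = data$outcome, X, check.names = FALSE)
  if (is.character(weights)) weights <- data[[weights]]
  if (is.null(weights)) weights <- rep(1, nrow(df))
  df$`(w)` <- weights
  f <- stats::as.formula(paste(
    "outcome ~", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit_call <- function() stats::glm(f, family = stats::binomial(),
                                    data = df, weights = `(w)`)
  if (all(weights == round(weights))) fit_call() else
    suppressWarnings(fit_call())
}

or_rows <- function(glm_fit, ci_level = 0.95) {
  sm <- summary(glm_fit)$coefficients
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  data.frame(term = rownames(sm),
             estimate = sm[, 1],
             odds_ratio = exp(sm[, 1]),
             ci_low = exp(sm[, 1] - zq * sm[, 2]),
             ci_high = exp(sm[, 1] + zq * sm[, 2]),
             p_value = sm[, 4],
             row.names = NULL)
}

build_or_table <- function(rows, reference, ref_block, term_block, design,
                           extra_reference = NULL) {
  rows$term <- gsub("`", "", rows$term)
  lab <- rows$term
  block <- rep("covariate", nrow(rows))
  block[lab == "(Intercept)"] <- "intercept"
  known <- grepl("^(group|mobility|origin)", lab)
  block[known] <- vapply(lab[known], term_block, character(1))
  rows$term[known] <- sub("^(group|mobility|origin)", "", rows$term[known])
  rows$block <- block
  rows$is_reference <- FALSE
  ref_row <- data.frame(term = reference, estimate = NA, odds_ratio = NA,
                        ci_low = NA, ci_high = NA, p_value = NA,
                        block = ref_block, is_reference = TRUE)
  out <- rbind(rows[1, , drop = FALSE], ref_row, rows[-1, , drop = FALSE])
  if (!is.null(extra_reference)) {
    for (nm in names(extra_reference)) {
      out <- rbind(out, data.frame(
        term = sub("^origin_", "", nm), estimate = NA, odds_ratio = NA,
        ci_low = NA, ci_high = NA, p_value = NA,
        block = extra_reference[[nm]], is_reference = TRUE))
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("or_table", "data.frame"), design = design)
}

#' Mobility-term p-values of a conventional fit
#'
#' Extracts the p-values of the terms that a conventional analysis would
#' read as "mobility effects": the six mobile-group dummies for the
#' group design, or the two mobility-status terms for the origin-control
#' design. These are the family over which the simulation study evaluates
#' the any-significant rejection rule.
#'
#' @param x An \code{or_table}.
#' @return Named numeric vector of p-values.
#' @export
mobility_p_values <- function(x) {
  stopifnot(inherits(x, "or_table"))
  keep <- !x$is_reference & x$block %in% c("downward", "upward", "mobility")
  stats::setNames(x$p_value[keep], x$term[keep])
}

#' Structural rank deficiency of the naive mobility design
#'
#' Builds the design a researcher would need to estimate origin,
#' destination and mobility effects jointly in ordinary regression and
#' reports its column rank. With the classical coding of mobility as the
#' number of levels moved (\code{mobility_coding = "score"}, the default),
#' the mobility column is exactly the destination score minus the origin
#' score, so the design — intercept, origin dummies, destination dummies,
#' mobility score — is rank deficient on \emph{every} dataset containing
#' all levels: the dependency is structural, not numerical, which is
#' exactly why the diagonal reference model is needed. The same holds for
#' any full set of trajectory dummies alongside origin and destination
#' (\code{"trajectory"}). Coding mobility as two up/down indicators
#' (\code{"status"}) happens to leave a 3-level design numerically full
#' rank because the indicators are not additive in origin and destination;
#' that design is reported as found — its problem is conflation and
#' near-saturation, not rank.
#'
#' @param data Data frame with \code{origin} and \code{destination}.
#' @param mobility_coding How the mobility regressor is coded:
#'   \code{"score"} (levels moved), \code{"trajectory"} (one dummy per
#'   off-diagonal origin-destination pair) or \code{"status"} (up/down
#'   indicators).
#' @return A \code{rank_report}: list with \code{n_columns}, \code{rank},
#'   \code{full_rank}, and \code{dependent} (labels of columns that the
#'   pivoted QR factorisation marks as linearly dependent on the others).
#' @export
demonstrate_linear_dependency <- function(data,
                                          mobility_coding = c("score",
                                                              "trajectory",
                                                              "status")) {
  mobility_coding <- match.arg(mobility_coding)
  origin <- as_education(data$origin)
  destination <- as_education(data$destination)
  Xo <- stats::model.matrix(~origin)[, -1, drop = FALSE]
  Xd <- stats::model.matrix(~destination)[, -1, drop = FALSE]
  Xm <- switch(mobility_coding,
    score = cbind(mobility_score =
                    as.integer(destination) - as.integer(origin)),
    status = {
      status <- classify_mobility(origin, destination)
      stats::model.matrix(~status)[, -1, drop = FALSE]
    },
    trajectory = {
      traj <- factor(paste(origin, destination, sep = "-"))
      mm <- stats::model.matrix(~traj)[, -1, drop = FALSE]
      mm[, grepl("-", sub("^traj", "", colnames(mm))) &
           !sub("^traj", "", colnames(mm)) %in%
             paste(levels(origin), levels(origin), sep = "-"),
         drop = FALSE]
    })
  X <- cbind(`(Intercept)` = 1, Xo, Xd, Xm)
  design_rank(X)
}

#' Column-rank report for a design matrix
#'
#' @param X Numeric design matrix with column names.
#' @return A \code{rank_report} (see [demonstrate_linear_dependency()]).
#' @export
design_rank <- function(X) {
  X <- as.matrix(X)
  qd <- qr(X)
  r <- qd$rank
  dep <- if (r < ncol(X)) colnames(X)[qd$pivot[(r + 1):ncol(X)]] else character()
  structure(list(n_columns = ncol(X), rank = r,
                 full_rank = r == ncol(X), dependent = dep),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, ...) {
  cat(sprintf("Design rank: %d of %d columns%s\n", x$rank, x$n_columns,
              if (x$full_rank) " (full rank)" else ""))
  if (length(x$dependent)) {
    cat("linearly dependent column(s): ",
        paste(x$dependent, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
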