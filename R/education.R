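#' Education level helpers
#'
#' The package works with a three-level ordered classification of educational
#' attainment, \code{low < medium < high}, obtained by collapsing ISCED 2011
#' categories. Both the position of origin (highest parental education) and
#' the position of destination (own attainment) use the same level set.
#'
#' @return Character vector of the default level labels, in ascending order.
#' @export
education_levels <- function() c("low", "medium", "high")

#' Coerce to an ordered education factor
#'
#' @param x Character or factor values drawn from the level set.
#' @param levels Level labels in ascending order of attainment.
#' @return An ordered factor.
#' @export
as_education <- function(x, levels = education_levels()) {
  out <- factor(as.character(x), levels = levels, ordered = TRUE)
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("unknown education level(s): ",
         paste(unique(as.character(x)[bad]), collapse = ", "))
  }
  out
}

#' Collapse ISCED 2011 codes to low/medium/high
#'
#' Codes 1-2 map to \code{low}, 3-4 to \code{medium} and 6-8 to \code{high}.
#' ISCED 0 (early childhood) and 5 (short-cycle tertiary) sit outside that
#' scheme; by default 0 joins \code{low} and 5 joins \code{high} (short-cycle
#' tertiary is tertiary), each with a warning so the choice is auditable.
#' Both defaults are overridable.
#'
#' @param code Integer vector of ISCED 2011 codes in 0..8.
#' @param isced0 Level assigned to code 0 (default \code{"low"}).
#' @param isced5 Level assigned to code 5 (default \code{"high"}).
#' @param quiet Suppress the warning emitted when codes 0 or 5 are present.
#' @return Ordered education factor of the same length as \code{code}.
#' @examples
#' recode_isced(c(2, 4, 7))
#' @export
recode_isced <- function(code, isced0 = "low", isced5 = "high", quiet = FALSE) {
  if (!is.numeric(code) || any(!is.na(code) & code != round(code))) {
    stop("ISCED codes must be integers in [0, 8]")
  }
  bad <- !is.na(code) & (code < 0 | code > 8)
  if (any(bad)) {
    stop("invalid ISCED code(s): ", paste(unique(code[bad]), collapse = ", "),
         " (must be in [0, 8])")
  }
  isced0 <- match.arg(isced0, education_levels())
  isced5 <- match.arg(isced5, education_levels())
  map <- c(isced0, "low", "low", "medium", "medium", isced5,
           "high", "high", "high")
  if (!quiet && any(code %in% c(0L, 5L))) {
    warning("ISCED codes 0 and/or 5 present; mapped to '", isced0, "'/'",
            isced5, "' by policy (configurable via isced0/isced5)")
  }
  as_education(map[code + 1L])
}

#' Derive the position of origin from parental education
#'
#' The default (\code{mode = "highest"}) takes the level of the parent with
#' the highest qualification, ignoring a missing parent; \code{"father_only"}
#' uses the father's level alone (a common sensitivity analysis). Records for
#' which the required inputs are all missing yield \code{NA} and are flagged
#' for listwise exclusion downstream.
#'
#' @param mother,father Education levels (coercible via [as_education()]),
#'   possibly \code{NA}.
#' @param mode \code{"highest"} or \code{"father_only"}.
#' @return Ordered education factor.
#' @export
derive_parental_education <- function(mother, father,
                                      mode = c("highest", "father_only")) {
  mode <- match.arg(mode)
  mother <- as_education(mother)
  father <- as_education(father)
  if (mode == "father_only") return(father)
  rm_ <- as.integer(mother)
  rf <- as.integer(father)
  hi <- pmax(rm_, rf, na.rm = TRUE)
  hi[is.na(rm_) & is.na(rf)] <- NA_integer_
  as_education(education_levels()[hi])
}

#' Classify mobility status from origin and destination
#'
#' @param origin,destination Education levels from the same level set.
#' @return Factor with levels \code{immobile}, \code{downward}, \code{upward}:
#'   \code{immobile} if origin equals destination, \code{upward} if the
#'   destination outranks the origin, \code{downward} otherwise.
#' @export
classify_mobility <- function(origin, destination) {
  origin <- as_education(origin)
  destination <- as_education(destination)
  d <- as.integer(destination) - as.integer(origin)
  out <- rep(NA_character_, length(d))
  out[!is.na(d) & d == 0] <- "immobile"
  out[!is.na(d) & d > 0] <- "upward"
  out[!is.na(d) & d < 0] <- "downward"
  factor(out, levels = c("immobile", "downward", "upward"))
}
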