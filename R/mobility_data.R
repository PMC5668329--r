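#' Eligibility filters for mobility records
#'
#' Applies, in order: the minimum-age rule (outcome measured validly only in
#' adults), exclusion of respondents still enrolled in education (destination
#' not yet final), and listwise deletion of records missing the origin,
#' destination, outcome, age, or any column named in \code{require_complete}.
#' Counts removed at each step are reconciled in the attached report.
#'
#' @param data Data frame of person-level records with columns
#'   \code{origin}, \code{destination}, \code{outcome}, \code{age}, and
#'   optionally \code{enrolled}.
#' @param min_age Minimum age in years (default 18).
#' @param exclude_enrolled Drop records with \code{enrolled == 1}.
#' @param require_complete Extra columns that must be non-missing
#'   (covariates, for listwise deletion).
#' @return List with \code{records} (the retained data frame) and
#'   \code{report}, a \code{filter_report} with fields \code{n_input},
#'   \code{n_removed_age}, \code{n_removed_enrolled},
#'   \code{n_removed_missing}, \code{n_retained}.
#' @export
apply_eligibility_filters <- function(data, min_age = 18,
                                      exclude_enrolled = TRUE,
                                      require_complete = character()) {
  stopifnot(is.data.frame(data))
  n_input <- nrow(data)
  keep <- rep(TRUE, n_input)

  age_ok <- !is.na(data$age) & data$age >= min_age
  n_removed_age <- sum(keep & !age_ok)
  keep <- keep & age_ok

  if (exclude_enrolled && !is.null(data$enrolled)) {
    enr <- !is.na(data$enrolled) & data$enrolled == 1
    n_removed_enrolled <- sum(keep & enr)
    keep <- keep & !enr
  } else {
    n_removed_enrolled <- 0L
  }

  need <- unique(c("origin", "destination", "outcome", "age", require_complete))
  need <- intersect(need, names(data))
  complete <- stats::complete.cases(data[need])
  n_removed_missing <- sum(keep & !complete)
  keep <- keep & complete

  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- structure(
    list(n_input = n_input,
         n_removed_age = as.integer(n_removed_age),
         n_removed_enrolled = as.integer(n_removed_enrolled),
         n_removed_missing = as.integer(n_removed_missing),
         n_retained = nrow(out)),
    class = "filter_report")
  if (nrow(out) == 0L) stop("no records remain after eligibility filtering")
  list(records = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Eligibility filter report\n")
  cat(sprintf("  input records:    %d\n", x$n_input))
  cat(sprintf("  removed (age):    %d\n", x$n_removed_age))
  cat(sprintf("  removed (enrolled): %d\n", x$n_removed_enrolled))
  cat(sprintf("  removed (missing):  %d\n", x$n_removed_missing))
  cat(sprintf("  retained:         %d\n", x$n_retained))
  invisible(x)
}

#' Cross-tabulate origin by destination
#'
#' Unweighted respondent counts in a square K x K mobility table with row,
#' column and grand totals. The diagonal holds the immobile; cells above the
#' diagonal the upwardly mobile; cells below it the downwardly mobile.
#'
#' @param origin,destination Education levels, or a data frame with columns
#'   \code{origin} and \code{destination} as the first argument.
#' @return A \code{mobility_table}: list with \code{counts} (K x K integer
#'   matrix, rows = origin), \code{row_totals}, \code{col_totals},
#'   \code{grand_total}.
#' @export
mobility_table <- function(origin, destination = NULL) {
  if (is.data.frame(origin)) {
    destination <- origin$destination
    origin <- origin$origin
  }
  origin <- as_education(origin)
  destination <- as_education(destination)
  if (length(origin) == 0L) stop("no records to tabulate")
  counts <- table(origin = origin, destination = destination)
  counts <- matrix(as.integer(counts), nrow = nlevels(origin),
                   dimnames = dimnames(counts))
  new_mobility_table(counts)
}

new_mobility_table <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts),
            all(counts >= 0))
  structure(
    list(counts = counts,
         row_totals = stats::setNames(as.integer(rowSums(counts)),
                                      rownames(counts)),
         col_totals = stats::setNames(as.integer(colSums(counts)),
                                      colnames(counts)),
         grand_total = as.integer(sum(counts))),
    class = "mobility_table")
}

#' @export
print.mobility_table <- function(x, ...) {
  m <- cbind(x$counts, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$grand_total))
  cat("Mobility table (origin rows x destination columns)\n")
  print(m)
  invisible(x)
}

#' Centre a covariate at its (weighted) mean
#'
#' @param values Numeric vector.
#' @param weights Optional positive case weights.
#' @return List with \code{centered} (values minus the mean) and \code{mean}.
#' @export
center_covariate <- function(values, weights = NULL) {
  stopifnot(is.numeric(values), length(values) > 0)
  m <- if (is.null(weights)) mean(values) else
    sum(values * weights) / sum(weights)
  list(centered = values - m, mean = m)
}

#' Read person-level mobility records from CSV
#'
#' Expects a header row. Column names can be remapped via \code{column_map}
#' (a named list, e.g. \code{list(origin = "par_edu")}). If \code{outcome}
#' is absent but \code{height_cm} and \code{weight_kg} are present, the
#' binary overweight/obesity indicator is computed as BMI = kg/m^2 >= 25.
#' If origin/destination columns hold ISCED digit codes they are collapsed
#' via [recode_isced()].
#'
#' @param path CSV file path.
#' @param column_map Optional named list mapping canonical names
#'   (\code{origin}, \code{destination}, \code{outcome}, \code{age}, ...) to
#'   the file's column names.
#' @return Data frame of mobility records.
#' @export
read_mobility_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) stop("mapped column not in file: ", src)
      names(df)[names(df) == src] <- canon
    }
  }
  if (!"outcome" %in% names(df) &&
      all(c("height_cm", "weight_kg") %in% names(df))) {
    bmi <- df$weight_kg / (df$height_cm / 100)^2
    df$outcome <- as.integer(bmi >= 25)
  }
  for (col in c("origin", "destination")) {
    if (col %in% names(df)) {
      v <- df[[col]]
      if (is.numeric(v) || all(grepl("^[0-8]$", v[!is.na(v)]))) {
        df[[col]] <- recode_isced(as.integer(v), quiet = TRUE)
      } else {
        df[[col]] <- as_education(v)
      }
    }
  }
  if ("marital_status" %in% names(df)) {
    df$marital_status <- factor(df$marital_status,
                                levels = marital_levels())
  }
  df
}

#' Write mobility records to CSV
#'
#' Plain-text round-trip companion of [read_mobility_csv()].
#'
#' @param data Data frame of mobility records.
#' @param path Output path.
#' @export
write_mobility_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Marital status categories
#'
#' Reference level first (\code{no_partner}), matching the layout of the
#' package's regression tables.
#' @return Character vector of levels.
#' @export
marital_levels <- function() {
  c("no_partner", "married_cohab", "unmarried_cohab", "no_cohabitation")
}

#' Packaged educational mobility counts, Dutch adults 18-45 (2009 survey)
#'
#' Published 3 x 3 origin-by-destination respondent counts for males
#' (grand total 1569) and females (grand total 1771), used as simulator
#' defaults and as a fixture for table-fidelity tests.
#'
#' @param sex \code{"male"} or \code{"female"}.
#' @return A [mobility_table()].
#' @export
nl2009_mobility_counts <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  path <- system.file("extdata",
                      paste0("mobility_counts_", sex, ".csv"),
                      package = "diagref", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  counts <- as.matrix(df[, -1])
  dimnames(counts) <- list(origin = df[[1]], destination = colnames(counts))
  storage.mode(counts) <- "integer"
  new_mobility_table(counts)
}
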