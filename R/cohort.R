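#' Patient cohort
#'
#' Validates and types a cohort table for relative-survival analysis: one row
#' per subject with follow-up time since diagnosis (years, positive), vital
#' status (0 censored / 1 dead of any cause -- no cause of death is recorded),
#' the demographic keys needed for life-table lookup (\code{age} at diagnosis,
#' \code{sex}, calendar \code{year} of diagnosis) and any number of covariate
#' columns.  \code{sex} may be given as \code{female}/\code{male} labels or
#' 0/1 and is stored as 0/1 (female = 0).
#'
#' A \code{latent_cause} column (\code{cancer}/\code{other}, only for dead
#' subjects) is allowed for simulated cohorts; it is never used by the
#' estimators, only by truth checks.
#'
#' @param data a data.frame with columns \code{id,time,status,age,sex,year},
#'   plus covariates.
#' @param covariates character vector naming the covariate columns used by
#'   default in regression models; defaults to all remaining numeric columns.
#' @return A data.frame of class \code{cohort} with a \code{covariates}
#'   attribute.
#' @export
as_cohort <- function(data, covariates = NULL) {
  data <- as.data.frame(data)
  need <- c("id", "time", "status", "age", "sex", "year")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) < 2L) stop("a cohort needs at least 2 subjects")
  if (anyDuplicated(data$id)) stop("'id' must be unique per subject")
  bad <- which(!is.finite(data$time) | data$time <= 0)
  if (length(bad))
    stop("'time' must be positive and finite; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(!data$status %in% c(0, 1))
  if (length(bad))
    stop("'status' must be 0 (censored) or 1 (dead); offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  data$time <- as.numeric(data$time)
  data$status <- as.numeric(data$status)
  if (any(!is.finite(data$age) | data$age < 0))
    stop("'age' must be non-negative and finite")
  if (is.character(data$sex) || is.factor(data$sex)) {
    s <- as.character(data$sex)
    if (!all(s %in% c("female", "male")))
      stop("'sex' labels must be 'female' or 'male'")
    data$sex <- as.numeric(s == "male")
  }
  if (!all(data$sex %in% c(0, 1))) stop("'sex' must be female/male or 0/1")
  if (!is.numeric(data$year)) stop("'year' must be numeric")
  if ("latent_cause" %in% names(data)) {
    lc <- data$latent_cause
    ok <- is.na(lc) | lc %in% c("cancer", "other")
    if (!all(ok)) stop("'latent_cause' must be 'cancer', 'other' or NA")
    if (any(!is.na(lc) & data$status == 0))
      stop("'latent_cause' may be set only for dead subjects")
  }
  if (is.null(covariates)) {
    covariates <- attr(data, "covariates")
  }
  if (is.null(covariates)) {
    skip <- c(need, "latent_cause", "cens_cause")
    covariates <- names(data)[!names(data) %in% skip &
                                vapply(data, is.numeric, logical(1))]
  }
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop("covariate column(s) not found: ", paste(miss, collapse = ", "))
  structure(data, covariates = covariates,
            class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d subjects, %d deaths (%.1f%%), follow-up %.3g-%.3g years\n",
              nrow(x), sum(x$status), 100 * mean(x$status),
              min(x$time), max(x$time)))
  cat("covariates:", paste(attr(x, "covariates"), collapse = ", "), "\n")
  NextMethod()
}

#' Read / write a cohort CSV
#'
#' Header \code{id,time,status,age,sex,year} plus covariate columns; see
#' [as_cohort()] for the column contracts.  Numeric fields are written with
#' 12 significant digits so a write/read round trip preserves them to
#' relative 1e-12.
#'
#' @param path file path.
#' @param covariates passed to [as_cohort()].
#' @return \code{read_cohort} returns a \code{cohort};
#'   \code{write_cohort} returns \code{path} invisibly.
#' @export
read_cohort <- function(path, covariates = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cohort(d, covariates = covariates)
}

#' @rdname read_cohort
#' @param cohort a [as_cohort()] object.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  out <- as.data.frame(cohort)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) as.numeric(sprintf("%.15g", v)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
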