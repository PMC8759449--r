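#' Model timepoints from the death-time distribution
#'
#' Default placement of the \code{m} pseudo-observation timepoints: empirical
#' quantiles of the observed death times at probabilities \eqn{k/(m+1)},
#' \eqn{k = 1..m} (inverse-ECDF quantiles, so each timepoint is an observed
#' death time), deduplicated.  \code{type = "even"} instead spreads the
#' timepoints evenly over \code{(0, max death time]}.
#'
#' @param cohort a [as_cohort()] object.
#' @param m number of timepoints (the usual range is 5 to 10; default 5).
#' @param type \code{"quantile"} (default) or \code{"even"}.
#' @return strictly increasing numeric vector of length at most \code{m}.
#' @export
select_timepoints <- function(cohort, m = 5L, type = c("quantile", "even")) {
  cohort <- as_cohort(cohort)
  type <- match.arg(type)
  dt <- cohort$time[cohort$status == 1]
  ndist <- length(unique(dt))
  if (m < 1L) stop("'m' must be at least 1")
  if (ndist < m)
    stop(sprintf("only %d distinct death times; choose m <= %d", ndist, ndist))
  if (type == "quantile") {
    tp <- stats::quantile(dt, probs = seq_len(m) / (m + 1), type = 1,
                          names = FALSE)
  } else {
    tp <- seq(0, max(dt), length.out = m + 1L)[-1L]
  }
  sort(unique(tp))
}

## shared internals -----------------------------------------------------------

.pseudo_check_range <- function(cohort, t, what) {
  tmax <- max(cohort$time)
  if (any(t > tmax))
    stop(sprintf("%s beyond the estimable range; maximal time is %.6g years",
                 what, tmax))
  if (any(t <= 0)) stop(sprintf("%s must be positive", what))
}

.pseudo_rows <- function(cohort, tp, cause, indicator, theta) {
  ## model covariates plus the demographic keys (sex doubles as a covariate
  ## in typical designs)
  covs <- union(attr(cohort, "covariates"), c("age", "sex", "year"))
  data.frame(id = rep(cohort$id, times = length(tp)),
             j = rep(seq_along(tp), each = nrow(cohort)),
             time = rep(tp, each = nrow(cohort)),
             cause = cause, indicator = indicator,
             pseudo = as.vector(theta),
             cohort[rep(seq_len(nrow(cohort)), times = length(tp)), covs,
                    drop = FALSE],
             row.names = NULL)
}

.as_pseudo_data <- function(rows, cohort, indicator, timepoints, tau, m) {
  structure(rows,
            covariates = attr(cohort, "covariates"),
            indicator = indicator, timepoints = timepoints, tau = tau,
            m = m, n = nrow(cohort),
            class = c("pseudo_data", "data.frame"))
}

## literal leave-one-out refit; authoritative reference for the fast path
.pseudo_direct <- function(cohort, rt, tp, tau, resolution) {
  n <- nrow(cohort)
  ## subsample estimates are evaluated on the full-cohort grid superset:
  ## the estimator itself is unchanged by extra grid points, and the step
  ## integrals then use one common refinement
  all_times <- cohort$time
  eval_one <- function(dat) {
    grid <- .rs_grid(dat$time, resolution,
                     extra = c(tp, tau, all_times[all_times <= max(dat$time)]))
    eng <- .rs_engine(dat, rt, grid)
    list(FC = step_eval(grid, eng$FC, tp), FP = step_eval(grid, eng$FP, tp),
         lC = if (!is.null(tau)) step_integral(c(0, grid), c(0, eng$FC), tau),
         lP = if (!is.null(tau)) step_integral(c(0, grid), c(0, eng$FP), tau))
  }
  full <- eval_one(cohort)
  ntp <- length(tp)
  FC <- matrix(NA_real_, n, ntp); FP <- matrix(NA_real_, n, ntp)
  lC <- numeric(n); lP <- numeric(n)
  for (i in seq_len(n)) {
    di <- eval_one(cohort[-i, , drop = FALSE])
    FC[i, ] <- di$FC; FP[i, ] <- di$FP
    if (!is.null(tau)) { lC[i] <- di$lC; lP[i] <- di$lP }
  }
  list(full = full, FC_loo = FC, FP_loo = FP, lylC_loo = lC, lylP_loo = lP)
}

.pseudo_fast <- function(cohort, rt, tp, tau, resolution) {
  grid <- .rs_grid(cohort$time, resolution, extra = c(tp, tau))
  eval_idx <- findInterval(tp, grid)
  eng <- .rs_engine(cohort, rt, grid, loo = TRUE, eval_idx = eval_idx,
                    tau = tau)
  full <- list(FC = step_eval(grid, eng$FC, tp),
               FP = step_eval(grid, eng$FP, tp),
               lC = if (!is.null(tau)) step_integral(c(0, grid), c(0, eng$FC), tau),
               lP = if (!is.null(tau)) step_integral(c(0, grid), c(0, eng$FP), tau))
  list(full = full, FC_loo = eng$FC_loo, FP_loo = eng$FP_loo,
       lylC_loo = eng$lylC_loo, lylP_loo = eng$lylP_loo)
}

.jackknife <- function(n, full, loo) {
  ## n * theta_hat - (n-1) * theta_hat^{-i}; full recycled across rows of loo
  sweep(-(n - 1) * loo, 2L, n * full, "+")
}

#' Pseudo-observations for the crude probability of death
#'
#' Leave-one-out pseudo-observations
#' \eqn{\tilde F_{it} = n\,\hat F(t) - (n-1)\,\hat F^{-i}(t)} of the crude
#' probability of death from cancer and/or other causes at each timepoint.
#' Values can lie outside \eqn{[0,1]} by construction.  The \code{"fast"}
#' method updates the risk set, death atoms and population increments of the
#' full-sample computation for each left-out subject on a shared grid and is
#' exactly equal (to floating tolerance) to the literal \code{"direct"}
#' refit, which recomputes the estimator on each subsample and is kept as
#' the authoritative reference.
#'
#' @param cohort a [as_cohort()] object (n >= 2).
#' @param ratetable a [pop_ratetable()].
#' @param timepoints timepoint vector; default [select_timepoints()] with
#'   \code{m}.
#' @param m number of default timepoints.
#' @param cause one or both of \code{"cancer"}, \code{"other"}.
#' @param resolution auxiliary grid spacing (years), see
#'   [crude_probabilities()].
#' @param method \code{"fast"} (default) or \code{"direct"}.
#' @return A long-format data.frame of class \code{pseudo_data} with columns
#'   \code{id, j, time, cause, indicator, pseudo} plus the cohort covariates.
#' @export
pseudo_cpr <- function(cohort, ratetable, timepoints = NULL, m = 5L,
                       cause = c("cancer", "other"),
                       resolution = 1 / 365.241,
                       method = c("fast", "direct")) {
  cohort <- as_cohort(cohort)
  method <- match.arg(method)
  cause <- match.arg(cause, several.ok = TRUE)
  tp <- timepoints %||% select_timepoints(cohort, m)
  .pseudo_check_range(cohort, tp, "timepoints")
  res <- if (method == "fast") .pseudo_fast(cohort, ratetable, tp, NULL, resolution)
         else .pseudo_direct(cohort, ratetable, tp, NULL, resolution)
  n <- nrow(cohort)
  rows <- list()
  if ("cancer" %in% cause)
    rows$cancer <- .pseudo_rows(cohort, tp, "cancer", "cpr",
                                .jackknife(n, res$full$FC, res$FC_loo))
  if ("other" %in% cause)
    rows$other <- .pseudo_rows(cohort, tp, "other", "cpr",
                               .jackknife(n, res$full$FP, res$FP_loo))
  .as_pseudo_data(do.call(rbind, rows), cohort, "cpr", tp, NULL, length(tp))
}

#' Pseudo-observations for life years lost
#'
#' One pseudo-observation per subject and cause at the horizon \code{tau}:
#' \eqn{\tilde L_i(0,\tau) = n\,\hat L(0,\tau) - (n-1)\,\hat L(0,\tau)^{-i}}
#' (years; possibly negative or exceeding \code{tau}).
#'
#' @inheritParams pseudo_cpr
#' @param tau horizon in years (within the observed follow-up).
#' @return A \code{pseudo_data} data.frame with one row per subject and
#'   cause (\code{indicator = "lyl"}).
#' @export
pseudo_lyl <- function(cohort, ratetable, tau, cause = c("cancer", "other"),
                       resolution = 1 / 365.241,
                       method = c("fast", "direct")) {
  cohort <- as_cohort(cohort)
  method <- match.arg(method)
  cause <- match.arg(cause, several.ok = TRUE)
  stop_if_not_scalar(tau, "tau")
  .pseudo_check_range(cohort, tau, "'tau'")
  res <- if (method == "fast") .pseudo_fast(cohort, ratetable, numeric(0), tau, resolution)
         else .pseudo_direct(cohort, ratetable, numeric(0), tau, resolution)
  n <- nrow(cohort)
  rows <- list()
  if ("cancer" %in% cause)
    rows$cancer <- .pseudo_rows(cohort, tau, "cancer", "lyl",
                                .jackknife(n, res$full$lC,
                                           matrix(res$lylC_loo, ncol = 1L)))
  if ("other" %in% cause)
    rows$other <- .pseudo_rows(cohort, tau, "other", "lyl",
                               .jackknife(n, res$full$lP,
                                          matrix(res$lylP_loo, ncol = 1L)))
  .as_pseudo_data(do.call(rbind, rows), cohort, "lyl", NULL, tau, 1L)
}

#' @export
print.pseudo_data <- function(x, ...) {
  cat(sprintf("Pseudo-observations (%s): %d rows, %d subjects, m = %d, cause(s): %s\n",
              attr(x, "indicator"), nrow(x), attr(x, "n"), attr(x, "m"),
              paste(unique(x$cause), collapse = ", ")))
  NextMethod()
}
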