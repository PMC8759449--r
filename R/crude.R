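#' Counting processes on a time grid
#'
#' Event and at-risk counts underlying the estimators: \code{dN[k]} is the
#' number of deaths at \code{grid[k]} and \code{Y[k]} the number of subjects
#' still at risk at \code{grid[k]}.  Tie rule: a subject whose follow-up
#' equals \code{grid[k]} is counted at risk at \code{grid[k]}, so deaths are
#' processed against the full risk set and censorings leave the risk set just
#' after their time (the usual Kaplan-Meier convention).
#'
#' @param cohort a [as_cohort()] object.
#' @param grid strictly increasing positive times; must contain every
#'   distinct observed time.  Defaults to exactly those times.
#' @return list with \code{time} (the grid), \code{dN}, \code{Y}.
#' @export
counting_processes <- function(cohort, grid = NULL) {
  cohort <- as_cohort(cohort)
  if (is.null(grid)) grid <- sort(unique(cohort$time))
  if (!all(cohort$time %in% grid))
    stop("'grid' must contain all distinct observed times")
  cnt <- .rs_counts(cohort$time, cohort$status, grid)
  list(time = grid, dN = cnt$d, Y = cnt$Y)
}

#' Crude probabilities of death without cause-of-death information
#'
#' Splits the observed mortality into a cancer (excess) part and a population
#' (expected) part using a life table, and returns the overall Kaplan-Meier
#' survival \eqn{\hat S} together with the two crude probabilities of death
#' \deqn{\hat F_C(t) = \int_0^t \hat S(u-)\,d\hat\Lambda_C(u), \qquad
#'       \hat F_P(t) = \int_0^t \hat S(u-)\,d\hat\Lambda_P(u),}
#' where \eqn{d\hat\Lambda_P(u) = \sum_i Y_i(u)\, d\Lambda_P(u; z_i) / Y(u)}
#' accumulates each at-risk subject's expected hazard and
#' \eqn{d\hat\Lambda_C(u) = dN(u)/Y(u) - d\hat\Lambda_P(u)} is the excess
#' increment.  The three curves satisfy
#' \eqn{\hat S + \hat F_C + \hat F_P = 1} exactly on the whole grid.
#'
#' The curves are right-continuous step functions on the union of all
#' observed times and a regular auxiliary grid; population increments are
#' integrated exactly (piecewise-constant rates), so the auxiliary resolution
#' only controls how finely the continuous accumulation between events is
#' resolved.  \eqn{\hat F_C} may decrease locally between death times
#' (negative excess increments); \eqn{\hat F_P} is non-decreasing.
#'
#' @param cohort a [as_cohort()] object.
#' @param ratetable a [pop_ratetable()].
#' @param resolution auxiliary grid spacing in years (default: one day).
#' @param max_time last time needed; estimates beyond the last observed time
#'   are frozen at their final value (with a warning at evaluation).
#' @return Object of class \code{crude_estimates}: a list with
#'   \code{estimates} (data.frame \code{time,S,F_C,F_P}, starting at the
#'   origin row \code{0,1,0,0}), \code{n}, \code{resolution}.
#' @export
crude_probabilities <- function(cohort, ratetable, resolution = 1 / 365.241,
                                max_time = NULL) {
  cohort <- as_cohort(cohort)
  stopifnot(inherits(ratetable, "pop_ratetable"))
  if (resolution <= 0) stop("'resolution' must be positive")
  grid <- .rs_grid(cohort$time, resolution, extra = max_time)
  eng <- .rs_engine(cohort, ratetable, grid)
  est <- data.frame(time = c(0, grid), S = c(1, eng$S),
                    F_C = c(0, eng$FC), F_P = c(0, eng$FP))
  structure(list(estimates = est, n = nrow(cohort), resolution = resolution,
                 max_observed = max(cohort$time)),
            class = "crude_estimates")
}

#' @export
print.crude_estimates <- function(x, ...) {
  e <- x$estimates
  last <- e[nrow(e), ]
  cat(sprintf("Crude probabilities of death (relative survival), n = %d\n", x$n))
  cat(sprintf("  grid: %d points on (0, %.4g] years\n", nrow(e) - 1L, last$time))
  cat(sprintf("  at t = %.4g:  S = %.4f,  F_C (cancer) = %.4f,  F_P (other) = %.4f\n",
              last$time, last$S, last$F_C, last$F_P))
  invisible(x)
}

#' @export
plot.crude_estimates <- function(x, ...) {
  e <- x$estimates
  graphics::plot(e$time, e$S, type = "s", ylim = c(0, 1), xlab = "years since diagnosis",
                 ylab = "probability", ...)
  graphics::lines(e$time, e$F_C, type = "s", lty = 2)
  graphics::lines(e$time, e$F_P, type = "s", lty = 3)
  graphics::legend("topright", c("S", "F_C (cancer)", "F_P (other)"),
                   lty = 1:3, bty = "n")
  invisible(x)
}

#' Evaluate crude estimates at arbitrary times
#'
#' Right-continuous step evaluation; times beyond the last observed time use
#' the frozen final value with a warning.
#'
#' @param crude a [crude_probabilities()] result.
#' @param t times (years, non-negative).
#' @return data.frame \code{time,S,F_C,F_P}.
#' @export
crude_at <- function(crude, t) {
  stopifnot(inherits(crude, "crude_estimates"))
  if (any(t < 0)) stop("'t' must be non-negative")
  if (any(t > crude$max_observed))
    warning(sprintf("times beyond the last observed time (%.4g) use frozen estimates",
                    crude$max_observed))
  e <- crude$estimates
  data.frame(time = t,
             S = step_eval(e$time, e$S, t, v0 = 1),
             F_C = step_eval(e$time, e$F_C, t),
             F_P = step_eval(e$time, e$F_P, t))
}

#' Life years lost per cause
#'
#' Number of life years lost before the horizon \code{tau}, decomposed by
#' cause: \eqn{\hat L_C(0,\tau) = \int_0^\tau \hat F_C(u)\,du} and
#' \eqn{\hat L_P(0,\tau) = \int_0^\tau \hat F_P(u)\,du}, computed as exact
#' integrals of the right-continuous step functions (value times interval
#' length).  By construction
#' \eqn{\hat L_C + \hat L_P = \tau - \int_0^\tau \hat S}.
#'
#' @param crude a [crude_probabilities()] result.
#' @param tau horizon in years, \code{0 < tau <=} last observed time.
#' @return named numeric vector \code{c(cancer=, other=, total=)} (years).
#' @export
lyl <- function(crude, tau) {
  stopifnot(inherits(crude, "crude_estimates"))
  stop_if_not_scalar(tau, "tau")
  if (tau <= 0) stop("'tau' must be positive")
  if (tau > crude$max_observed)
    stop(sprintf("'tau' beyond the estimable range; maximal tau is %.6g years",
                 crude$max_observed))
  e <- crude$estimates
  LC <- step_integral(e$time, e$F_C, tau)
  LP <- step_integral(e$time, e$F_P, tau)
  c(cancer = LC, other = LP, total = LC + LP)
}
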