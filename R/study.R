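#' Performance measures for a set of replicate estimates
#'
#' The five standard frequentist measures for one coefficient over
#' \code{n_reps} simulation replicates: bias (mean estimate minus the
#' reference value), empirical standard error (sample SD of the estimates,
#' divisor \code{n_reps - 1}), model standard error (root mean of the
#' estimated variances), root mean squared error (about the reference value)
#' and coverage (proportion of 95\% Wald intervals containing the reference).
#' The measures satisfy
#' \eqn{\mathrm{RMSE}^2 = \mathrm{bias}^2 +
#'   \mathrm{empSE}^2 (n_{\mathrm{reps}}-1)/n_{\mathrm{reps}}}.
#'
#' @param estimates numeric vector of replicate estimates.
#' @param ses matching vector of model (sandwich) standard errors.
#' @param beta0 reference value (true or least-false parameter).
#' @param level confidence level for coverage.
#' @return one-row data.frame \code{beta0, mean, bias, empSE, ModSE, RMSE,
#'   coverage, n_reps}.
#' @export
performance_measures <- function(estimates, ses, beta0, level = 0.95) {
  if (length(estimates) != length(ses))
    stop("'estimates' and 'ses' must have the same length")
  if (length(estimates) < 2L) stop("need at least 2 replicate estimates")
  z <- stats::qnorm(1 - (1 - level) / 2)
  nr <- length(estimates)
  mn <- mean(estimates)
  data.frame(beta0 = beta0,
             mean = mn,
             bias = mn - beta0,
             empSE = stats::sd(estimates),
             ModSE = sqrt(mean(ses^2)),
             RMSE = sqrt(mean((estimates - beta0)^2)),
             coverage = mean(abs(estimates - beta0) <= z * ses),
             n_reps = nr)
}

#' Acceptable coverage band
#'
#' Binomial band for the empirical coverage of nominal \code{p} intervals
#' over \code{n_reps} replicates:
#' \eqn{p \pm z_{0.975}\sqrt{p(1-p)/n_{\mathrm{reps}}}}.
#'
#' @param n_reps number of replicates.
#' @param p nominal coverage.
#' @return numeric vector \code{c(lower, upper)}.
#' @export
acceptable_coverage_range <- function(n_reps, p = 0.95) {
  z <- stats::qnorm(0.975)
  half <- z * sqrt(p * (1 - p) / n_reps)
  c(lower = p - half, upper = p + half)
}

#' Monte-Carlo study configuration
#'
#' @param sim a [sim_config()] (the generating design).
#' @param n_reps number of replicates (>= 2).
#' @param m pseudo-observation timepoints per cause for the crude
#'   probability models.
#' @param tau horizon (years) for the life-years-lost model.
#' @param cpr_links link functions to fit to the crude-probability
#'   pseudo-observations.
#' @param causes causes to model.
#' @param indicators \code{"cpr"} and/or \code{"lyl"} (LYL uses the identity
#'   link).
#' @param resolution auxiliary grid spacing for the estimators.
#' @param seed master seed; per-replicate seeds are drawn from it by
#'   replicate index.
#' @return list of class \code{study_config}.
#' @export
study_config <- function(sim = sim_config(), n_reps = 100L, m = 5L, tau = 10,
                         cpr_links = "cloglog", causes = "cancer",
                         indicators = c("cpr", "lyl"),
                         resolution = 1 / 365.241, seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), n_reps >= 2L)
  indicators <- match.arg(indicators, c("cpr", "lyl"), several.ok = TRUE)
  causes <- match.arg(causes, c("cancer", "other"), several.ok = TRUE)
  cpr_links <- match.arg(cpr_links, c("cloglog", "log", "identity"),
                         several.ok = TRUE)
  structure(list(sim = sim, n_reps = as.integer(n_reps), m = as.integer(m),
                 tau = tau, cpr_links = cpr_links, causes = causes,
                 indicators = indicators, resolution = resolution,
                 seed = as.integer(seed)),
            class = "study_config")
}

## one engine pass per cohort serving both indicators and causes
.pseudo_joint <- function(cohort, rt, tp, tau, resolution) {
  res <- .pseudo_fast(cohort, rt, tp, tau, resolution)
  n <- nrow(cohort)
  cpr <- .as_pseudo_data(
    rbind(.pseudo_rows(cohort, tp, "cancer", "cpr",
                       .jackknife(n, res$full$FC, res$FC_loo)),
          .pseudo_rows(cohort, tp, "other", "cpr",
                       .jackknife(n, res$full$FP, res$FP_loo))),
    cohort, "cpr", tp, NULL, length(tp))
  lylp <- if (!is.null(tau)) .as_pseudo_data(
    rbind(.pseudo_rows(cohort, tau, "cancer", "lyl",
                       .jackknife(n, res$full$lC, matrix(res$lylC_loo, ncol = 1L))),
          .pseudo_rows(cohort, tau, "other", "lyl",
                       .jackknife(n, res$full$lP, matrix(res$lylP_loo, ncol = 1L)))),
    cohort, "lyl", NULL, tau, 1L)
  list(cpr = cpr, lyl = lylp)
}

.fit_row <- function(fit, rep, seed, link, cause, indicator) {
  data.frame(rep = rep, seed = seed, link = link, cause = cause,
             indicator = indicator, term = names(fit$coefficients),
             estimate = unname(fit$coefficients), se = unname(fit$se),
             converged = fit$converged, row.names = NULL)
}

#' Run the Monte-Carlo evaluation
#'
#' Per replicate: simulate a cohort, choose the quantile timepoints, compute
#' pseudo-observations for both causes and both indicators in a single
#' leave-one-out pass, and fit the requested GEE models.  Replicate-level
#' failures are caught, counted and excluded.  Reproducible from the master
#' seed: the per-replicate seed is assigned by replicate index.
#'
#' @param config a [study_config()].
#' @param progress print a dot per replicate.
#' @return list of class \code{rs_study}: \code{estimates} (long data.frame
#'   \code{rep,seed,link,cause,indicator,term,estimate,se,converged}),
#'   \code{failures}, \code{seeds}, \code{config}.
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  seeds <- sample.int(2147483646L, config$n_reps)
  rows <- vector("list", config$n_reps)
  failures <- list()
  for (r in seq_len(config$n_reps)) {
    out <- tryCatch({
      cohort <- simulate_cohort(config$sim, seed = seeds[r])
      tp <- select_timepoints(cohort, config$m)
      tau <- if ("lyl" %in% config$indicators) config$tau else NULL
      ps <- .pseudo_joint(cohort, config$sim$ratetable, tp, tau,
                          config$resolution)
      reps <- list()
      if ("cpr" %in% config$indicators) {
        for (lk in config$cpr_links) for (cs in config$causes) {
          fit <- fit_pseudo_gee(ps$cpr, link = lk, cause = cs)
          reps[[paste("cpr", lk, cs)]] <-
            .fit_row(fit, r, seeds[r], lk, cs, "cpr")
        }
      }
      if ("lyl" %in% config$indicators) {
        for (cs in config$causes) {
          fit <- fit_pseudo_gee(ps$lyl, link = "identity", cause = cs)
          reps[[paste("lyl", cs)]] <-
            .fit_row(fit, r, seeds[r], "identity", cs, "lyl")
        }
      }
      do.call(rbind, reps)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(rep = r, seed = seeds[r], message = conditionMessage(out))
    } else rows[[r]] <- out
    if (progress) cat(".", if (r %% 50 == 0) "\n", sep = "")
  }
  if (progress) cat("\n")
  structure(list(estimates = do.call(rbind, rows),
                 failures = if (length(failures)) do.call(rbind, failures)
                            else data.frame(),
                 seeds = seeds, config = config),
            class = "rs_study")
}

#' @export
print.rs_study <- function(x, ...) {
  cat(sprintf("Monte-Carlo study: %d replicates (N = %d), %d failures\n",
              x$config$n_reps, x$config$sim$n, nrow(x$failures)))
  cat("models:", paste(unique(paste(x$estimates$indicator, x$estimates$link,
                                    x$estimates$cause)), collapse = "; "), "\n")
  invisible(x)
}

#' Performance table for a study
#'
#' Aggregates the replicate estimates into one [performance_measures()] row
#' per (link, cause, indicator, term) found in \code{reference}.
#'
#' @param study a [run_study()] result.
#' @param reference data.frame \code{link, cause, indicator, term, beta0}
#'   giving the true or least-false reference value per coefficient.
#' @return data.frame of performance rows with identifying columns and
#'   \code{N} (cohort size).
#' @export
study_performance <- function(study, reference) {
  stopifnot(inherits(study, "rs_study"))
  need <- c("link", "cause", "indicator", "term", "beta0")
  if (!all(need %in% names(reference)))
    stop("'reference' must have columns ", paste(need, collapse = ", "))
  est <- study$estimates
  out <- lapply(seq_len(nrow(reference)), function(k) {
    rf <- reference[k, ]
    sel <- est$link == rf$link & est$cause == rf$cause &
      est$indicator == rf$indicator & est$term == rf$term
    if (!any(sel)) stop("no estimates for reference row ", k)
    cbind(rf[c("link", "cause", "indicator", "term")],
          performance_measures(est$estimate[sel], est$se[sel], rf$beta0),
          N = study$config$sim$n)
  })
  do.call(rbind, out)
}

#' Least-false parameters on one large no-drop-out cohort
#'
#' Fits the requested pseudo-observation model to a single large cohort
#' generated under the study design with drop-out disabled (administrative
#' censoring retained).  The fitted coefficients serve as reference values
#' for models whose link does not match the generating subdistribution-hazard
#' scale.
#'
#' @param sim a [sim_config()]; \code{n} and \code{dropouts} are overridden.
#' @param n cohort size for the reference fit.
#' @param link,cause,indicator model to fit (\code{indicator} \code{"cpr"} or
#'   \code{"lyl"}).
#' @param m,tau,resolution as in [study_config()].
#' @param seed integer seed.
#' @return the \code{pseudo_gee} fit (coefficients are the LFP values).
#' @export
least_false_parameters <- function(sim = sim_config(), n = 100000L,
                                   link = "cloglog", cause = "cancer",
                                   indicator = c("cpr", "lyl"), m = 5L,
                                   tau = 10, resolution = 1 / 365.241,
                                   seed = 1L) {
  stopifnot(inherits(sim, "sim_config"))
  indicator <- match.arg(indicator)
  sim$n <- as.integer(n)
  sim$dropouts <- FALSE
  cohort <- simulate_cohort(sim, seed = seed)
  if (indicator == "cpr") {
    tp <- select_timepoints(cohort, m)
    ps <- pseudo_cpr(cohort, sim$ratetable, timepoints = tp, cause = cause,
                     resolution = resolution)
  } else {
    ps <- pseudo_lyl(cohort, sim$ratetable, tau = tau, cause = cause,
                     resolution = resolution)
  }
  fit_pseudo_gee(ps, link = link, cause = cause)
}
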