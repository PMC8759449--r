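test_that("links are mutually inverse with analytic derivatives", {
  for (nm in c("cloglog", "log", "identity")) {
    lk <- gee_link(nm)
    mu <- c(0.05, 0.25, 0.63, 0.9)
    expect_lt(max(abs(lk$linkinv(lk$linkfun(mu)) - mu)), 1e-12)
    eta <- lk$linkfun(mu)
    num <- (lk$linkinv(eta + 1e-6) - lk$linkinv(eta - 1e-6)) / 2e-6
    expect_equal(lk$mu.eta(eta), num, tolerance = 1e-8)
  }
  expect_equal(gee_link("cloglog")$linkfun(1 - exp(-1)), 0)
  expect_equal(gee_link("log")$linkinv(log(0.25)), 0.25)
  expect_equal(gee_link("identity")$linkfun(0.3), 0.3)
})

test_that("closed forms: intercept-only fits", {
  coh <- toy_cohort(60, seed = 21)
  ps <- pseudo_cpr(coh, synth_ratetable(),
                   timepoints = select_timepoints(coh, 1), cause = "cancer")
  n <- length(unique(ps$id))
  f <- fit_pseudo_gee(ps, covariates = character(0), link = "identity")
  expect_equal(unname(coef(f)), mean(ps$pseudo))
  expect_equal(unname(f$se),
               sqrt(sum((ps$pseudo - mean(ps$pseudo))^2)) / n)
  fl <- fit_pseudo_gee(ps, covariates = character(0), link = "log")
  expect_equal(unname(coef(fl)), log(mean(ps$pseudo)))
})

test_that("identity-link GEE equals least squares with cluster-robust variance", {
  coh <- toy_cohort(100, seed = 22)
  tp <- select_timepoints(coh, 5)
  ps <- pseudo_cpr(coh, synth_ratetable(), timepoints = tp, cause = "cancer")
  fit <- fit_pseudo_gee(ps, covariates = "x1", link = "identity")
  d <- ps[order(ps$id, ps$j), ]
  ols <- stats::lm(pseudo ~ factor(j) + x1, data = d)
  expect_lt(max(abs(unname(coef(fit)) - unname(coef(ols)))), 1e-8)
  V <- sandwich::vcovCL(ols, cluster = d$id, type = "HC0", cadjust = FALSE)
  expect_lt(max(abs(unname(fit$se) - unname(sqrt(diag(V))))), 1e-8)
  expect_lt(fit$score_norm, 1e-8)
})

test_that("cloglog and log fits solve the estimating equation", {
  coh <- toy_cohort(100, seed = 23)
  tp <- select_timepoints(coh, 5)
  ps <- pseudo_cpr(coh, synth_ratetable(), timepoints = tp, cause = "cancer")
  for (lk in c("cloglog", "log")) {
    fit <- fit_pseudo_gee(ps, covariates = "x1", link = lk)
    expect_true(fit$converged)
    expect_lt(fit$score_norm, 1e-8)
    ## independent oracle: minimiser of the stacked least-squares objective
    d <- ps[order(ps$id, ps$j), ]
    X <- cbind(1, outer(d$j, 2:5, "==") + 0, d$x1)
    inv <- gee_link(lk)$linkinv
    ssr <- function(b) sum((d$pseudo - inv(as.vector(X %*% b)))^2)
    o <- stats::optim(coef(fit) + 0.05, ssr, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
    expect_lt(max(abs(unname(coef(fit)) - o$par)), 1e-5)
    expect_lte(ssr(coef(fit)), ssr(o$par) + 1e-10)
  }
})

test_that("fit is invariant to row order and flags rank deficiency", {
  coh <- toy_cohort(50, seed = 24)
  ps <- pseudo_cpr(coh, synth_ratetable(),
                   timepoints = select_timepoints(coh, 3), cause = "cancer")
  f1 <- fit_pseudo_gee(ps, covariates = "x1", link = "cloglog")
  set.seed(1)
  f2 <- fit_pseudo_gee(ps[sample(nrow(ps)), ], covariates = "x1",
                       link = "cloglog")
  expect_equal(coef(f1), coef(f2))
  expect_equal(f1$se, f2$se)
  ps$x2 <- 2 * ps$x1
  expect_error(fit_pseudo_gee(ps, covariates = c("x1", "x2"),
                              link = "identity"), "collinear.*x2")
})

test_that("Wald intervals follow beta +/- z se", {
  coh <- toy_cohort(40, seed = 25)
  ps <- pseudo_cpr(coh, synth_ratetable(),
                   timepoints = select_timepoints(coh, 2), cause = "cancer")
  fit <- fit_pseudo_gee(ps, covariates = "x1", link = "identity")
  ci <- wald_ci(fit)
  z <- stats::qnorm(0.975)
  expect_equal(unname(ci[, "lower"]), unname(coef(fit) - z * fit$se))
  expect_equal(unname(ci[, "upper"]), unname(coef(fit) + z * fit$se))
  ## hand example: 0.3 +/- 1.96 * 0.1
  fake <- fit
  fake$coefficients <- c(b = 0.3)
  fake$se <- c(b = 0.1)
  expect_equal(unname(wald_ci(fake)[, "lower"]), 0.3 - z * 0.1)
  expect_equal(round(unname(wald_ci(fake)), 3),
               matrix(c(0.104, 0.496), 1))
  ## coverage indicator equivalence
  b0 <- 0.25
  contains <- wald_ci(fit)[, 1] <= b0 & b0 <= wald_ci(fit)[, 2]
  expect_equal(unname(contains),
               unname(abs(coef(fit) - b0) <= z * fit$se))
  ## degenerate interval when se = 0
  fake$se <- c(b = 0)
  expect_equal(unname(wald_ci(fake)), matrix(c(0.3, 0.3), 1))
})
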