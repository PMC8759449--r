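test_that("Generalized Weibull baseline follows its closed forms", {
  expect_equal(sdh_baseline(1, 2, 1.6, 0.05),
               2 * 1.6^2 / (1 + 1.6^2 / 0.05))
  expect_equal(sdh_cum_baseline(0), 0)
  expect_equal(sdh_cum_baseline(10, 2, 1.6, 0.05),
               0.05 * log(1 + 256 / 0.05))
  quad <- stats::integrate(sdh_baseline, 0, 10, rel.tol = 1e-10)$value
  expect_equal(sdh_cum_baseline(10), quad, tolerance = 1e-8)
})

test_that("covariate generator matches the stated mixture", {
  cv <- gen_covariates(2e5, seed = 31)
  expect_equal(mean(cv$age), 0.25 * 47.5 + 0.35 * 70 + 0.4 * 77.5,
               tolerance = 0.002)
  expect_equal(mean(cv$sex), 0.5, tolerance = 0.01)
  expect_gt(min(cv$year), 2000)
  expect_lt(max(cv$year), 2003)
  expect_equal(mean(cv$age >= 65 & cv$age < 75), 0.35, tolerance = 0.01)
  expect_true(all(cv$age >= 30 & cv$age < 80))
})

test_that("closed-form truth conserves probability and responds to covariates", {
  cfg <- sim_config(n = 10)
  tr <- sim_truth(cfg, age = 72, sex = 1, year = 2001.2)
  tt <- seq(0.25, 10, by = 0.25)
  expect_lt(max(abs(tr$S(tt) + tr$F_C(tt) + tr$F_P(tt) - 1)), 1e-8)
  expect_true(all(tr$F_P(tt) >= 0 & tr$F_P(tt) <= 1))
  ## F_C increases with the linear predictor at fixed t
  tr_lo <- sim_truth(cfg, age = 60, sex = 0, year = 2001.2)
  expect_true(all(tr$F_C(tt) > tr_lo$F_C(tt)))
  ## no competing mortality: S = exp(-Gamma_C), F_P = 0
  cfg0 <- sim_config(n = 10, ratetable = zero_ratetable())
  tr0 <- sim_truth(cfg0, age = 72, sex = 1, year = 2001.2)
  expect_equal(tr0$S(tt), exp(-tr0$Gamma_C(tt)), tolerance = 1e-10)
  expect_lt(max(abs(tr0$F_P(tt))), 1e-10)
})

test_that("all-cause survival truth solves the competing-risks ODE", {
  ## independent check via the integrating-factor solution with stats::integrate
  cfg <- sim_config(n = 10)
  tr <- sim_truth(cfg, age = 66.4, sex = 0, year = 2002.3)
  Lp <- function(t) pop_cumhaz(cfg$ratetable, 66.4, "female", 2002.3, t)
  for (tt in c(1.3, 4.7, 9.5)) {
    ## integrand is smooth between integer boundary crossings; integrate
    ## piecewise so adaptive quadrature never straddles a rate jump
    br <- sort(unique(c(0, tt, seq(0.6, tt, by = 1), seq(0.7, tt, by = 1))))
    br <- br[br <= tt]
    I <- sum(vapply(seq_len(length(br) - 1L), function(k)
      stats::integrate(function(u) tr$f_C(u) * exp(Lp(u)), br[k], br[k + 1L],
                       rel.tol = 1e-10)$value, numeric(1)))
    expect_equal(tr$S(tt), exp(-Lp(tt)) * (1 - I), tolerance = 1e-8)
  }
})

test_that("simulated event times match the closed-form subdistributions", {
  cfg <- sim_config(n = 20000, dropout_rate = 0)
  cv <- data.frame(age = rep(72, 20000), sex = 1, year = 2001.2)
  ch <- simulate_cohort(cfg, seed = 42, covariates = cv)
  tr <- sim_truth(cfg, 72, 1, 2001.2)
  for (t in c(1, 3, 7)) {
    emp_C <- mean(ch$status == 1 & ch$time <= t &
                    !is.na(ch$latent_cause) & ch$latent_cause == "cancer")
    emp_P <- mean(ch$status == 1 & ch$time <= t &
                    !is.na(ch$latent_cause) & ch$latent_cause == "other")
    expect_lt(abs(emp_C - tr$F_C(t)),
              4 * sqrt(tr$F_C(t) * (1 - tr$F_C(t)) / 20000))
    expect_lt(abs(emp_P - tr$F_P(t)),
              4 * sqrt(tr$F_P(t) * (1 - tr$F_P(t)) / 20000))
  }
})

test_that("with null effects and no population hazard times follow exp(-Gamma0)", {
  cfg0 <- sim_config(n = 10000, beta_age = 0, beta_sex = 0, beta_year = 0,
                     dropout_rate = 0, ratetable = zero_ratetable())
  F <- function(t) -expm1(-sdh_cum_baseline(t))
  pv <- vapply(1:5, function(s) {
    ch <- simulate_cohort(cfg0, seed = 400 + s)
    suppressWarnings(stats::ks.test(ch$time[ch$status == 1],
                                    function(t) F(t) / F(10))$p.value)
  }, numeric(1))
  expect_true(all(pv > 0.01))
})

test_that("drop-out and administrative censoring behave as configured", {
  cfg <- sim_config(n = 20000)
  ch <- simulate_cohort(cfg, seed = 33)
  ## subjects neither dead nor dropped by 10y are admin-censored at exactly 10
  admin <- ch$cens_cause == "admin"
  expect_true(all(ch$time[admin] == 10))
  expect_true(all(ch$time <= 10))
  ## disabling dropouts removes loss to follow-up entirely
  cfg_nd <- sim_config(n = 2000, dropouts = FALSE)
  ch_nd <- simulate_cohort(cfg_nd, seed = 34)
  expect_true(all(ch_nd$cens_cause != "dropout"))
  ## exponential drop-out tail: P(dropout draw < 10) = 1 - exp(-0.35);
  ## among subjects who would survive past 10, observed dropout frequency
  p <- 1 - exp(-0.35)
  ## cohort-level dropout fraction is bounded by the 10-year tail probability
  expect_lt(mean(ch$cens_cause == "dropout"), p)
  ## reproducibility
  a <- simulate_cohort(sim_config(n = 200), seed = 77)
  b <- simulate_cohort(sim_config(n = 200), seed = 77)
  expect_identical(a, b)
  ## latent cause only for deaths
  expect_true(all(is.na(ch$latent_cause[ch$status == 0])))
  expect_true(all(!is.na(ch$latent_cause[ch$status == 1])))
})
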