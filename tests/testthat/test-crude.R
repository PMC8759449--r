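test_that("counting processes follow the tie rule", {
  coh <- as_cohort(data.frame(id = 1:4, time = c(1, 2, 2, 3),
                              status = c(1, 1, 0, 1),
                              age = 60, sex = 0, year = 2001))
  cp <- counting_processes(coh)
  expect_equal(cp$time, c(1, 2, 3))
  expect_equal(sum(cp$dN), 3)
  expect_equal(cp$Y, c(4, 3, 1))  # censored-at-2 subject still at risk at 2
  all_cens <- as_cohort(data.frame(id = 1:3, time = 1:3, status = 0,
                                   age = 60, sex = 0, year = 2001))
  expect_equal(sum(counting_processes(all_cens)$dN), 0)
  expect_error(counting_processes(coh, grid = c(1, 3)), "observed times")
})

test_that("zero population hazard reduces F_C to 1 - Kaplan-Meier", {
  coh <- toy_cohort(60, seed = 2)
  cr <- crude_probabilities(coh, zero_ratetable())
  km <- survival::survfit(survival::Surv(time, status) ~ 1,
                          data = as.data.frame(coh))
  kmv <- summary(km, times = cr$estimates$time)$surv
  expect_lt(max(abs(cr$estimates$F_C - (1 - kmv))), 1e-10)
  expect_equal(max(cr$estimates$F_P), 0)
})

test_that("conservation S + F_C + F_P = 1 holds exactly on the whole grid", {
  rt <- synth_ratetable()
  for (seed in 1:3) {
    coh <- toy_cohort(50, seed = seed, p_death = 0.6)
    e <- crude_probabilities(coh, rt)$estimates
    expect_lt(max(abs(e$S + e$F_C + e$F_P - 1)), 1e-10)
    expect_true(all(diff(e$F_P) >= -1e-12))
    expect_true(all(diff(e$S) <= 1e-12))
    expect_true(all(e$F_C <= 1 - e$S + 1e-12))
  }
})

test_that("overall survival equals the Kaplan-Meier estimator", {
  coh <- toy_cohort(80, seed = 5)
  e <- crude_probabilities(coh, synth_ratetable())$estimates
  km <- survival::survfit(survival::Surv(time, status) ~ 1,
                          data = as.data.frame(coh))
  kmv <- summary(km, times = e$time)$surv
  expect_lt(max(abs(e$S - kmv)), 1e-12)
})

test_that("estimates agree with a brute-force discrete-time computation", {
  ## two subjects, both dying, constant population hazard 0.1/yr
  coh <- as_cohort(data.frame(id = 1:2, time = c(1, 2), status = 1,
                              age = 60, sex = 0, year = 2001))
  rt <- const_ratetable(0.1)
  cr <- crude_probabilities(coh, rt)

  ## oracle: explicit discrete-time accumulation on a very fine grid
  h <- 1e-4
  g <- seq(h, 2, by = h)
  Y <- ifelse(g <= 1, 2, 1)  # at-risk counts (ties: at risk at own time)
  Y[g > 1 & g <= 2] <- 1
  dN <- numeric(length(g))
  dN[which.min(abs(g - 1))] <- 1
  dN[which.min(abs(g - 2))] <- 1
  dLp <- Y * 0.1 * h / Y     # same constant hazard for both subjects
  S <- cumprod(1 - dN / Y)
  Sprev <- c(1, S[-length(S)])
  FP <- cumsum(Sprev * dLp)
  FC <- cumsum(Sprev * (dN / Y - dLp))
  at <- function(tt) which.min(abs(g - tt))
  got <- crude_at(cr, c(1, 1.5, 2))
  expect_lt(max(abs(got$F_C - FC[c(at(1), at(1.5), at(2))])), 5e-4)
  expect_lt(max(abs(got$F_P - FP[c(at(1), at(1.5), at(2))])), 5e-4)

  ## closed forms at the event times (hand calculation):
  ## F_P(1) = 0.1 (hazard 0.1 accumulated with S(u-) = 1);
  ## F_C(1) = S(1-) * dN/Y - 0.1 = 0.5 - 0.1; then S = 0.5 on (1,2]
  expect_equal(got$F_P[1], 0.1, tolerance = 1e-10)
  expect_equal(got$F_C[1], 0.4, tolerance = 1e-10)
  expect_equal(got$F_P[3], 0.15, tolerance = 1e-10)
  expect_equal(got$F_C[3], 0.85, tolerance = 1e-10)
})

test_that("refining the auxiliary grid leaves estimates at event times unchanged", {
  coh <- toy_cohort(50, seed = 7)
  rt <- synth_ratetable()
  a <- crude_at(crude_probabilities(coh, rt), c(1, 2, 3))
  b <- crude_at(crude_probabilities(coh, rt, resolution = 0.5 / 365.241),
                c(1, 2, 3))
  expect_lt(max(abs(a$F_C - b$F_C)), 1e-4)
  expect_lt(max(abs(a$F_P - b$F_P)), 1e-4)
})

test_that("life years lost integrates the step functions and conserves", {
  coh <- toy_cohort(50, seed = 3, p_death = 1)  # no censoring
  cr0 <- crude_probabilities(coh, zero_ratetable())
  tau <- 3
  L <- lyl(cr0, tau)
  ## with lambda_P = 0 and no censoring: L_C = tau - mean(min(T_i, tau))
  expect_equal(unname(L["cancer"]), tau - mean(pmin(coh$time, tau)),
               tolerance = 1e-10)
  expect_equal(unname(L["other"]), 0)

  rt <- synth_ratetable()
  cr <- crude_probabilities(coh, rt)
  L2 <- lyl(cr, tau)
  e <- cr$estimates
  Sint <- sum(e$S[e$time < tau] *
                diff(c(e$time[e$time < tau], tau)))
  expect_equal(unname(L2["total"]), tau - Sint, tolerance = 1e-10)
  expect_error(lyl(cr, 2 * max(coh$time)), "maximal tau")
  expect_error(lyl(cr, -1), "positive")
})

test_that("evaluation beyond the last observed time freezes with a warning", {
  coh <- toy_cohort(20, seed = 4)
  cr <- crude_probabilities(coh, synth_ratetable())
  expect_warning(out <- crude_at(cr, max(coh$time) + 5), "frozen")
  last <- cr$estimates[nrow(cr$estimates), ]
  expect_equal(out$F_C, last$F_C)
})
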