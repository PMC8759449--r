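# shared fixtures, built in code

zero_ratetable <- function()
  pop_ratetable(30:105, 2000:2015, array(0, c(76, 16, 2)))

const_ratetable <- function(rate = 0.02)
  pop_ratetable(30:105, 2000:2015, array(rate, c(76, 16, 2)))

## 0.01 at age 60, 0.03 at age 61, 0.05 elsewhere, no year/sex variation
two_cell_ratetable <- function() {
  r <- array(0.05, c(76, 16, 2))
  r[31, , ] <- 0.01
  r[32, , ] <- 0.03
  pop_ratetable(30:105, 2000:2015, r)
}

## small cohort with exponential-ish follow-up, independent of the simulator
toy_cohort <- function(n = 40, seed = 1, p_death = 0.7, round_digits = 3) {
  set.seed(seed)
  tm <- stats::rexp(n, 0.25) + 0.02
  if (!is.null(round_digits)) tm <- round(tm, round_digits)
  as_cohort(data.frame(
    id = seq_len(n), time = tm,
    status = stats::rbinom(n, 1, p_death),
    age = stats::runif(n, 50, 80),
    sex = stats::rbinom(n, 1, 0.5),
    year = stats::runif(n, 2000, 2003),
    x1 = stats::rnorm(n)))
}

## memoised expensive computations shared across acceptance tests
.acc_cache <- new.env(parent = emptyenv())

acc_study <- function() {
  if (is.null(.acc_cache$study)) {
    cfg <- study_config(sim = sim_config(n = 1000), n_reps = 100L, m = 5L,
                        tau = 10, cpr_links = "cloglog", causes = "cancer",
                        indicators = c("cpr", "lyl"), seed = 20260901L)
    .acc_cache$study <- run_study(cfg)
  }
  .acc_cache$study
}
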