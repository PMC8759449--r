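#' Population rate table
#'
#' A population (expected) all-cause mortality rate table: one hazard per
#' person-year for each 1-year cell of attained age x calendar year x sex.
#' Rates are treated as piecewise constant on these cells, the convention of
#' national life tables.  Lookups outside the declared grid clamp to the
#' nearest edge cell, so long follow-up beyond the last tabulated age or year
#' remains usable.
#'
#' @param ages integer vector of attained ages (years), consecutive 1-year
#'   cells.
#' @param years integer vector of calendar years, consecutive 1-year cells.
#' @param rates numeric array of dimension
#'   \code{c(length(ages), length(years), 2)} (third dimension: female, male),
#'   hazards per person-year, all finite and non-negative.
#' @param metadata free-text provenance string.
#' @return An object of class \code{pop_ratetable}.
#' @seealso [synth_ratetable()], [pop_hazard()], [pop_cumhaz()]
#' @export
pop_ratetable <- function(ages, years, rates, metadata = "") {
  ages <- as.integer(ages)
  years <- as.integer(years)
  sexes <- c("female", "male")
  if (length(ages) == 0L || length(years) == 0L)
    stop("'ages' and 'years' must be non-empty")
  if (any(diff(ages) != 1L) || any(diff(years) != 1L))
    stop("'ages' and 'years' must be consecutive 1-year grids")
  if (!is.array(rates) || !identical(dim(rates),
                                     c(length(ages), length(years), 2L)))
    stop("'rates' must be an array of dim c(length(ages), length(years), 2)")
  if (anyNA(rates) || any(!is.finite(rates)))
    stop("'rates' must be finite with no missing cells")
  if (any(rates < 0))
    stop("'rates' must be non-negative")
  dimnames(rates) <- list(ages, years, sexes)
  structure(list(ages = ages, years = years, sexes = sexes,
                 rates = rates, metadata = as.character(metadata)),
            class = "pop_ratetable")
}

#' @export
print.pop_ratetable <- function(x, ...) {
  cat("Population rate table (piecewise-constant hazards, per person-year)\n")
  cat(sprintf("  ages : %d-%d\n", min(x$ages), max(x$ages)))
  cat(sprintf("  years: %d-%d\n", min(x$years), max(x$years)))
  cat(sprintf("  rate range: [%.3g, %.3g]\n", min(x$rates), max(x$rates)))
  if (nzchar(x$metadata)) cat("  ", x$metadata, "\n", sep = "")
  invisible(x)
}

#' Synthetic Gompertz-like life table
#'
#' Builds a deterministic rate table with log-linear age progression
#' (Gompertz), a constant male/female hazard ratio and a geometric calendar
#' trend:
#' \deqn{\lambda(a, y, s) = \mathrm{base} \cdot e^{\mathrm{slope}(a-30)}
#'   \cdot r_s \cdot \mathrm{trend}^{(y - y_0)},}
#' capped at 1 per person-year.  Defaults give hazards close to a
#' contemporary UK national life table (about 0.001/yr at age 30, doubling
#' every ~7.7 years of age, men ~50\% above women, ~2\% annual improvement).
#'
#' @param base_rate hazard per person-year at age 30, female, first year.
#' @param log_slope log-hazard increase per year of age.
#' @param sex_ratio male/female hazard ratio.
#' @param year_trend multiplicative change per calendar year (<1 means
#'   improving mortality).
#' @param ages,years integer grids (1-year cells).
#' @return A [pop_ratetable()].
#' @export
synth_ratetable <- function(base_rate = 0.001, log_slope = 0.09,
                            sex_ratio = 1.5, year_trend = 0.98,
                            ages = 30:105, years = 2000:2015) {
  if (base_rate <= 0 || sex_ratio <= 0 || year_trend <= 0)
    stop("'base_rate', 'sex_ratio' and 'year_trend' must be positive")
  if (length(ages) == 0L || length(years) == 0L)
    stop("'ages' and 'years' must be non-empty")
  a <- base_rate * exp(log_slope * (ages - 30))
  y <- year_trend^(years - years[1L])
  r <- outer(a, y)
  rates <- array(c(r, r * sex_ratio), dim = c(length(ages), length(years), 2L))
  rates <- pmin(rates, 1)
  pop_ratetable(ages, years, rates,
                metadata = sprintf(
                  "synthetic Gompertz table (base %g, slope %g, sex ratio %g, year trend %g)",
                  base_rate, log_slope, sex_ratio, year_trend))
}

## clamp + lookup indices for attained age / calendar year
.rt_cell <- function(rt, age, year) {
  ia <- pmin(pmax(floor(age), min(rt$ages)), max(rt$ages)) - min(rt$ages) + 1L
  iy <- pmin(pmax(floor(year), min(rt$years)), max(rt$years)) - min(rt$years) + 1L
  cbind(ia, iy)
}

.rt_sex_index <- function(rt, sex) {
  s <- as.character(sex)
  s[s %in% c("0", "F", "f")] <- "female"
  s[s %in% c("1", "M", "m")] <- "male"
  idx <- match(s, rt$sexes)
  if (anyNA(idx))
    stop("unknown sex label(s): ",
         paste(unique(s[is.na(idx)]), collapse = ", "),
         " (expected female/male or 0/1)")
  idx
}

#' Population hazard at a follow-up time
#'
#' Hazard per person-year that a subject with the given demographics is
#' exposed to at time \code{t} since diagnosis.  Attained age and calendar
#' time advance continuously with follow-up; the cell rate is right-continuous
#' in \code{t} and clamps at the grid edges.
#'
#' @param rt a [pop_ratetable()].
#' @param age age at diagnosis in years (fractional allowed).
#' @param sex \code{"female"}/\code{"male"} (or 0/1).
#' @param year calendar year of diagnosis (fractional allowed).
#' @param t time since diagnosis, years, non-negative.  Arguments are
#'   recycled to a common length.
#' @return numeric vector of hazards per person-year.
#' @export
pop_hazard <- function(rt, age, sex, year, t) {
  stopifnot(inherits(rt, "pop_ratetable"))
  n <- max(length(age), length(sex), length(year), length(t))
  age <- rep_len(age, n); year <- rep_len(year, n); t <- rep_len(t, n)
  isx <- rep_len(.rt_sex_index(rt, sex), n)
  if (any(t < 0)) stop("'t' must be non-negative")
  if (any(age < 0)) stop("'age' must be non-negative")
  cell <- .rt_cell(rt, age + t, year + t)
  rt$rates[cbind(cell, isx)]
}

## per-subject piecewise-constant hazard segments along follow-up
## returns list(bounds = c(0, ..., t_max), rates per segment,
##              cum = cumulative hazard at bounds)
.rt_segments <- function(rt, age, sex, year, t_max) {
  isx <- .rt_sex_index(rt, sex)
  crossings <- function(x0) {
    first <- ceiling(x0 + 1e-12) - x0
    if (first >= t_max) numeric(0) else seq(first, t_max, by = 1)
  }
  ba <- crossings(age)
  by <- crossings(year)
  bounds <- sort(unique(c(0, ba[ba > 0 & ba < t_max],
                          by[by > 0 & by < t_max], t_max)))
  mid <- (bounds[-length(bounds)] + bounds[-1L]) / 2
  cell <- .rt_cell(rt, age + mid, year + mid)
  rates <- rt$rates[cbind(cell, isx)]
  cum <- c(0, cumsum(rates * diff(bounds)))
  list(bounds = bounds, rates = rates, cum = cum)
}

## evaluate cumulative hazard for one subject's segments at times t (vector)
.rt_cumhaz_seg <- function(seg, t) {
  j <- findInterval(t, seg$bounds, rightmost.closed = FALSE)
  j <- pmin(pmax(j, 1L), length(seg$rates))
  seg$cum[j] + seg$rates[j] * (t - seg$bounds[j])
}

#' Cumulative population hazard along a subject's follow-up
#'
#' Exact integral \eqn{\Lambda_P(t; z) = \int_0^t \lambda_P(u; z)\,du} of the
#' piecewise-constant population hazard, with attained age and calendar year
#' advancing continuously from the (possibly fractional) values at diagnosis.
#' The result is continuous, non-decreasing and piecewise linear in \code{t}.
#'
#' @inheritParams pop_hazard
#' @return numeric vector of cumulative hazards (dimensionless).
#' @export
pop_cumhaz <- function(rt, age, sex, year, t) {
  stopifnot(inherits(rt, "pop_ratetable"))
  n <- max(length(age), length(sex), length(year), length(t))
  age <- rep_len(age, n); year <- rep_len(year, n); t <- rep_len(t, n)
  sex <- rep_len(sex, n)
  if (any(t < 0)) stop("'t' must be non-negative")
  if (any(age < 0)) stop("'age' must be non-negative")
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (t[i] == 0) next
    seg <- .rt_segments(rt, age[i], sex[i], year[i], t[i])
    out[i] <- seg$cum[length(seg$cum)]
  }
  out
}

## n x length(grid) matrix of Lambda_P,i(min(grid, cap_i)); cap defaults to
## no capping.  Used by the estimation engine (cap at each subject's
## follow-up gives at-risk-masked increments directly).
.rt_cumhaz_matrix <- function(rt, age, sex, year, grid, cap = NULL) {
  n <- length(age)
  tmax <- max(grid)
  out <- matrix(0, n, length(grid))
  for (i in seq_len(n)) {
    seg <- .rt_segments(rt, age[i], sex[i], year[i], tmax)
    tt <- if (is.null(cap)) grid else pmin(grid, cap[i])
    out[i, ] <- .rt_cumhaz_seg(seg, tt)
  }
  out
}

#' Read / write a rate table as long CSV
#'
#' Plain-text dialect: header \code{age,year,sex,rate}, one row per cell,
#' integer age and year, sex in \code{female}/\code{male}.
#'
#' @param path file path.
#' @return \code{read_ratetable} returns a [pop_ratetable()];
#'   \code{write_ratetable} returns \code{path} invisibly.
#' @export
read_ratetable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "year", "sex", "rate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("rate-table file is missing column(s): ", paste(miss, collapse = ", "))
  ages <- sort(unique(d$age)); years <- sort(unique(d$year))
  rates <- array(NA_real_, c(length(ages), length(years), 2L))
  ia <- match(d$age, ages); iy <- match(d$year, years)
  isx <- match(d$sex, c("female", "male"))
  if (anyNA(isx)) stop("sex must be 'female' or 'male'")
  rates[cbind(ia, iy, isx)] <- d$rate
  if (anyNA(rates)) stop("rate table has missing cells inside its grid")
  pop_ratetable(ages, years, rates, metadata = paste("read from", path))
}

#' @rdname read_ratetable
#' @param rt a [pop_ratetable()].
#' @export
write_ratetable <- function(rt, path) {
  stopifnot(inherits(rt, "pop_ratetable"))
  g <- expand.grid(age = rt$ages, year = rt$years, sex = rt$sexes,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$rate <- as.vector(rt$rates)
  g$rate <- as.numeric(sprintf("%.15g", g$rate))
  utils::write.csv(g, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
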