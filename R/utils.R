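`%||%` <- function(x, y) if (is.null(x)) y else x

## row-wise cumulative ops that keep matrix shape for 1-row inputs
row_cumsum <- function(m) {
  if (nrow(m) == 1L) return(matrix(cumsum(m[1L, ]), nrow = 1L))
  t(apply(m, 1L, cumsum))
}

row_cumprod <- function(m) {
  if (nrow(m) == 1L) return(matrix(cumprod(m[1L, ]), nrow = 1L))
  t(apply(m, 1L, cumprod))
}

## Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch), cached per order
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  if (n == 1L) {
    out <- list(nodes = 0, weights = 2)
  } else {
    i <- seq_len(n - 1L)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- b
    J[cbind(i + 1L, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    out <- list(nodes = e$values, weights = 2 * e$vectors[1L, ]^2)
  }
  .gl_cache[[key]] <- out
  out
}

## value of a right-continuous step function (value[k] on [grid[k], grid[k+1]))
## with value `v0` on [0, grid[1])
step_eval <- function(grid, values, t, v0 = 0) {
  idx <- findInterval(t, grid)
  out <- rep_len(v0, length(t))
  out[idx > 0L] <- values[idx[idx > 0L]]
  out[t < 0] <- NA_real_
  out
}

## integral over [0, tau] of the right-continuous step function above (v0 = 0)
step_integral <- function(grid, values, tau) {
  if (tau <= grid[1L]) return(0)
  G <- length(grid)
  upper <- pmin(c(grid[-1L], Inf), tau)
  len <- pmax(upper - pmin(grid, tau), 0)
  sum(values * len)
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
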