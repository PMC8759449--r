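## Core relative-survival estimation engine.
##
## All estimators live on a common time grid that contains every observed
## time (deaths and censorings), so the at-risk set is constant within each
## grid interval (t_{k-1}, t_k] and the piecewise-constant population-hazard
## increments are accumulated exactly via differences of Lambda_P.  On such a
## grid the estimates at observed times do not depend on how fine the
## auxiliary grid is; the auxiliary resolution only refines the step
## functions between events (relevant for the life-years-lost integrals).

.rs_grid <- function(time, resolution, extra = NULL) {
  tmax <- max(time)
  aux <- if (is.finite(resolution) && resolution > 0)
    seq(resolution, tmax, by = resolution) else numeric(0)
  g <- sort(unique(c(time, aux, extra[extra > 0 & extra <= tmax])))
  g[g > 0]
}

.rs_counts <- function(time, status, grid) {
  idx <- match(time, grid)  # exact: grid contains every observed time
  d <- tabulate(idx[status == 1], nbins = length(grid))
  st <- sort(time)
  Y <- length(time) - findInterval(grid, st, left.open = TRUE)
  list(d = d, Y = Y)
}

## Kaplan-Meier + crude probability curves from the interval summaries
## d (deaths per grid atom), Y (at risk), P (at-risk-summed population-hazard
## increments per interval).  Vector version, used for the full sample.
.rs_curves <- function(d, Y, P) {
  pos <- Y > 0
  h <- ifelse(pos, d / Y, 0)
  S <- cumprod(1 - h)
  Sprev <- c(1, S[-length(S)])
  dFP <- ifelse(pos, Sprev * P / Y, 0)
  dTot <- ifelse(pos, Sprev * d / Y, 0)
  list(S = S, FC = cumsum(dTot - dFP), FP = cumsum(dFP))
}

## Full-sample curves and, optionally, exact leave-one-out curves reduced to
## what the pseudo-observation layer needs: values of F_C / F_P at
## grid[eval_idx] and (if tau is given) step integrals over [0, tau].
##
## Leaving out subject i removes one unit from the risk set up to T_i, the
## subject's own death atom, and the subject's own population-hazard
## increments; the remaining computation is identical to the full-sample
## estimator on the same (super)grid, so leave-one-out values match a literal
## refit exactly.
.rs_engine <- function(cohort, rt, grid, loo = FALSE,
                       eval_idx = integer(0), tau = NULL,
                       chunk_elems = 2e6) {
  n <- nrow(cohort)
  G <- length(grid)
  time <- cohort$time; status <- cohort$status
  cnt <- .rs_counts(time, status, grid)
  d <- cnt$d; Y <- cnt$Y

  chunk <- max(1L, min(n, floor(chunk_elems / G)))
  starts <- seq(1L, n, by = chunk)

  ## pass 1: accumulate at-risk-masked population increments
  ## (increment matrices are kept for pass 2 when they fit in memory)
  keep_w <- loo && (as.double(n) * G) <= 8e6
  w_cache <- if (keep_w) vector("list", length(starts))
  P <- numeric(G)
  for (s in seq_along(starts)) {
    idx <- starts[s]:min(starts[s] + chunk - 1L, n)
    Lcap <- .rt_cumhaz_matrix(rt, cohort$age[idx], cohort$sex[idx],
                              cohort$year[idx], grid, cap = time[idx])
    w <- Lcap - cbind(0, Lcap[, -G, drop = FALSE])
    if (keep_w) w_cache[[s]] <- w
    P <- P + colSums(w)
  }

  full <- .rs_curves(d, Y, P)
  out <- list(grid = grid, d = d, Y = Y, P = P,
              S = full$S, FC = full$FC, FP = full$FP)
  if (!loo) return(out)

  ne <- length(eval_idx)
  FC_loo <- matrix(NA_real_, n, ne)
  FP_loo <- matrix(NA_real_, n, ne)
  lylC <- if (!is.null(tau)) numeric(n) else NULL
  lylP <- if (!is.null(tau)) numeric(n) else NULL
  if (!is.null(tau)) {
    upper <- pmin(c(grid[-1L], Inf), tau)
    wts <- pmax(upper - pmin(grid, tau), 0)
  }

  for (s in seq_along(starts)) {
    idx <- starts[s]:min(starts[s] + chunk - 1L, n)
    m <- length(idx)
    Ti <- time[idx]; di <- status[idx]
    w <- if (keep_w) w_cache[[s]] else {
      Lcap <- .rt_cumhaz_matrix(rt, cohort$age[idx], cohort$sex[idx],
                                cohort$year[idx], grid, cap = Ti)
      Lcap - cbind(0, Lcap[, -G, drop = FALSE])
    }
    Rm <- outer(Ti, grid, ">=")
    Ym <- matrix(Y, m, G, byrow = TRUE) - Rm
    Dm <- matrix(d, m, G, byrow = TRUE)
    dcol <- match(Ti, grid)
    dead <- which(di == 1)
    if (length(dead))
      Dm[cbind(dead, dcol[dead])] <- Dm[cbind(dead, dcol[dead])] - 1
    Pm <- matrix(P, m, G, byrow = TRUE) - w
    pos <- Ym > 0
    hm <- matrix(0, m, G); hm[pos] <- Dm[pos] / Ym[pos]
    Sm <- row_cumprod(1 - hm)
    Sprev <- cbind(1, Sm[, -G, drop = FALSE])
    dFP <- matrix(0, m, G); dFP[pos] <- (Sprev * Pm)[pos] / Ym[pos]
    dTot <- matrix(0, m, G); dTot[pos] <- (Sprev * Dm)[pos] / Ym[pos]
    FCm <- row_cumsum(dTot - dFP)
    FPm <- row_cumsum(dFP)
    if (ne) {
      FC_loo[idx, ] <- FCm[, eval_idx, drop = FALSE]
      FP_loo[idx, ] <- FPm[, eval_idx, drop = FALSE]
    }
    if (!is.null(tau)) {
      lylC[idx] <- as.vector(FCm %*% wts)
      lylP[idx] <- as.vector(FPm %*% wts)
    }
  }
  out$FC_loo <- FC_loo; out$FP_loo <- FP_loo
  out$lylC_loo <- lylC; out$lylP_loo <- lylP
  out
}
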