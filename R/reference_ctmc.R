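# Exact brute-force oracle for the regulatory-unit chain.
#
# Full CTMC over a chain of n_ru four-state RUs (tropomyosin N/P x troponin
# U/B), 4^n_ru states.  Used at small n_ru to validate the triplet closures;
# the crossbridge side is validated separately through the PDE/ODE moment
# equivalence.  Per-unit encoding u in 0..3: tropomyosin = u mod 2
# (0 = N, 1 = P), troponin = u div 2 (0 = U, 1 = B); chain state index
# 1 + sum_k u_k 4^(k-1).

#' Encode/decode regulatory-unit chain configurations
#'
#' Bijection between flat state indices \code{1 .. 4^n_ru} and per-unit
#' (tropomyosin, troponin) configurations.
#'
#' @param idx flat indices (vectorised).
#' @param n_ru chain length.
#' @return \code{ctmc_decode}: matrix \code{length(idx) x n_ru} of per-unit
#'   codes 0..3; \code{ctmc_encode}: flat indices.
#' @export
ctmc_decode <- function(idx, n_ru) {
  sapply(seq_len(n_ru), function(k) ((idx - 1) %/% 4^(k - 1)) %% 4)
}

#' @rdname ctmc_decode
#' @param conf matrix of per-unit codes 0..3.
#' @export
ctmc_encode <- function(conf, n_ru) {
  conf <- matrix(conf, ncol = n_ru)
  as.integer(1 + conf %*% 4^(seq_len(n_ru) - 1))
}

#' Generator matrix of the regulatory-unit chain
#'
#' Builds the sparse infinitesimal generator of the full chain CTMC: each
#' unit can flip its troponin state (calcium binding/unbinding, rate
#' depending on its own tropomyosin) or its tropomyosin state (rate depending
#' on both neighbours' tropomyosin -- missing neighbours at the filament ends
#' count as non-permissive -- its own troponin, and, when \code{SL} is given,
#' the single-filament weight of its position).
#'
#' @param n_ru chain length (guarded at <= 10; the state space is
#'   \code{4^n_ru}).
#' @param table a \code{\link{ru_rate_table}} (SE family).
#' @param SL sarcomere length (um) modulating the permissive-direction rates
#'   through \code{chi_SF}, or \code{NULL} for an unmodulated chain.
#' @param geom a \code{\link{sarcomere_geometry}} with matching \code{n_ru}.
#' @return sparse \code{dgCMatrix} of size \code{4^n_ru}; rows sum to zero.
#' @export
ctmc_generator <- function(n_ru, table, SL = NULL,
                           geom = sarcomere_geometry(n_ru = max(n_ru, 3L))) {
  if (n_ru > 10L) stop("n_ru > 10: state space 4^n_ru too large for the ",
                       "exact oracle")
  ns <- 4L^n_ru
  idx <- seq_len(ns)
  xSF <- if (is.null(SL)) rep(1, n_ru) else chi_SF(SL, seq_len(n_ru), geom)
  tm_of <- function(k) ((idx - 1) %/% 4^(k - 1)) %% 2          # 0=N, 1=P
  tn_of <- function(k) ((idx - 1) %/% (2 * 4^(k - 1))) %% 2    # 0=U, 1=B
  ii <- jj <- integer(0); vv <- numeric(0)
  for (k in seq_len(n_ru)) {
    tm <- tm_of(k); tn <- tn_of(k)
    nl <- if (k > 1L) tm_of(k - 1L) else 0
    nr <- if (k < n_ru) tm_of(k + 1L) else 0
    n <- nl + nr
    # troponin flip
    rate_tn <- ifelse(tn == 0, table$kC_UB,
                      ifelse(tm == 0, table$kC_BU_N, table$kC_BU_P))
    tgt_tn <- idx + ifelse(tn == 0, 1L, -1L) * 2L * 4L^(k - 1L)
    # tropomyosin flip
    np <- ifelse(tn == 0, table$kT_NP_U[n + 1], table$kT_NP_B[n + 1])
    rate_tm <- ifelse(tm == 0, xSF[k] * np, table$kT_PN[n + 1])
    tgt_tm <- idx + ifelse(tm == 0, 1L, -1L) * 4L^(k - 1L)
    ii <- c(ii, idx, idx); jj <- c(jj, tgt_tn, tgt_tm)
    vv <- c(vv, rate_tn, rate_tm)
  }
  keep <- vv > 0
  G <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = vv[keep],
                            dims = c(ns, ns))
  Matrix::Diagonal(ns, x = -Matrix::rowSums(G)) + G
}

#' Stationary distribution of the master equation
#'
#' Solves \code{t(G) p = 0}, \code{sum(p) = 1} by replacing one balance
#' equation with the normalisation constraint (sparse LU).
#'
#' @param G generator from \code{\link{ctmc_generator}}.
#' @param tol residual tolerance for the verification
#'   \code{max |t(G) p| <= tol}.
#' @return probability vector.
#' @export
master_steady_state <- function(G, tol = 1e-10) {
  ns <- nrow(G)
  A <- Matrix::t(G)
  A[ns, ] <- 1
  b <- c(rep(0, ns - 1L), 1)
  p <- as.vector(Matrix::solve(A, b))
  p[p < 0 & p > -1e-12] <- 0
  p <- p / sum(p)
  res <- max(abs(as.vector(Matrix::t(G) %*% p)))
  if (res > tol * max(1, max(abs(G)))) {
    warning(sprintf("master-equation residual %.3g above tolerance", res))
  }
  p
}

#' Transient solution of the master equation
#'
#' Integrates \code{dp/dt = t(G) p} with a sparse stiff solver.
#'
#' @param G generator matrix.
#' @param p0 initial distribution.
#' @param times output times (s).
#' @return matrix \code{length(times) x ns} of distributions.
#' @export
master_transient <- function(G, p0, times) {
  Gt <- Matrix::t(G)
  f <- function(t, p, parms) list(as.vector(Gt %*% p))
  out <- deSolve::ode(p0, times, f, parms = NULL, method = "lsodes",
                      rtol = 1e-8, atol = 1e-12)
  unname(out[, -1, drop = FALSE])
}

# marginal permissivity profile from a full-chain distribution
master_permissivity <- function(p, n_ru) {
  idx <- seq_along(p)
  vapply(seq_len(n_ru), function(k) {
    tm <- ((idx - 1) %/% 4^(k - 1)) %% 2
    sum(p[tm == 1])
  }, numeric(1))
}

# exact triplet distribution (64-vector in the SE state encoding) for the
# triplet centred at interior unit i
master_triplet <- function(p, n_ru, i) {
  stopifnot(i >= 2L, i <= n_ru - 1L)
  idx <- seq_along(p)
  u <- function(k) ((idx - 1) %/% 4^(k - 1)) %% 4
  ul <- u(i - 1L); uc <- u(i); ur <- u(i + 1L)
  key <- 1 + (ul %% 2) + 2 * (uc %% 2) + 4 * (ur %% 2) +
    8 * (ul %/% 2) + 16 * (uc %/% 2) + 32 * (ur %/% 2)
  as.vector(rowsum(p, key))
}

#' Gillespie sampling of the regulatory-unit chain
#'
#' Stochastic simulation of the exact chain CTMC (used only as a
#' cross-validation oracle; the reduced models are deterministic).  All
#' randomness flows from \code{seed}.
#'
#' @param n_ru chain length.
#' @param table a \code{\link{ru_rate_table}}.
#' @param T_end simulated time per trajectory (s).
#' @param n_traj number of trajectories.
#' @param seed RNG seed (required, recorded in the result).
#' @param SL optional sarcomere length for positional modulation.
#' @param geom geometry with matching \code{n_ru}.
#' @return list with \code{P_hat} (empirical per-unit permissivity at
#'   \code{T_end}), \code{se} (binomial standard errors), \code{final}
#'   (matrix of final per-unit codes), \code{events} (event log of the first
#'   trajectory: time, unit, type), and \code{seed}.
#' @export
gillespie_trajectories <- function(n_ru, table, T_end, n_traj, seed,
                                   SL = NULL,
                                   geom = sarcomere_geometry(
                                     n_ru = max(n_ru, 3L))) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  set.seed(seed)
  xSF <- if (is.null(SL)) rep(1, n_ru) else chi_SF(SL, seq_len(n_ru), geom)
  final <- matrix(0L, n_traj, n_ru)
  ev_t <- numeric(0); ev_u <- integer(0); ev_type <- character(0)
  for (tr in seq_len(n_traj)) {
    tm <- integer(n_ru)   # 0 = N, 1 = P
    tn <- integer(n_ru)   # 0 = U, 1 = B
    t <- 0
    repeat {
      nl <- c(0L, tm[-n_ru]); nr <- c(tm[-1L], 0L)
      n <- nl + nr
      r_tm <- ifelse(tm == 0L,
                     xSF * ifelse(tn == 0L, table$kT_NP_U[n + 1],
                                  table$kT_NP_B[n + 1]),
                     table$kT_PN[n + 1])
      r_tn <- ifelse(tn == 0L, table$kC_UB,
                     ifelse(tm == 0L, table$kC_BU_N, table$kC_BU_P))
      rates <- c(r_tm, r_tn)
      rtot <- sum(rates)
      if (rtot <= 0) break
      t <- t + stats::rexp(1, rtot)
      if (t > T_end) break
      j <- sample.int(2L * n_ru, 1L, prob = rates)
      if (j <= n_ru) {
        tm[j] <- 1L - tm[j]
        if (tr == 1L) {
          ev_t <- c(ev_t, t); ev_u <- c(ev_u, j)
          ev_type <- c(ev_type, "Tm")
        }
      } else {
        u <- j - n_ru
        tn[u] <- 1L - tn[u]
        if (tr == 1L) {
          ev_t <- c(ev_t, t); ev_u <- c(ev_u, u)
          ev_type <- c(ev_type, "Tn")
        }
      }
    }
    final[tr, ] <- tm + 2L * tn
  }
  P_hat <- colMeans(final %% 2L == 1L)
  list(P_hat = P_hat,
       se = sqrt(pmax(P_hat * (1 - P_hat), 1 / n_traj) / n_traj),
       final = final,
       events = data.frame(time = ev_t, unit = ev_u, type = ev_type),
       seed = seed)
}

#' Closure-error report for the spatially explicit reduction
#'
#' Quantifies what the triplet closure (conditional independence of distant
#' units given the intermediate ones) loses: for each calcium level, the
#' steady per-unit permissivity of the reduced model is compared against the
#' exact master-equation marginals, together with the total-variation
#' distance between the stored triplet distributions and the exact ones.
#' The closure is exact when the cooperativity \code{gamma} equals one.
#'
#' Because the constructed rate table satisfies detailed balance, the
#' stationary law of the chain is a nearest-neighbour Gibbs field with the
#' spatial Markov property, and the closure is exact at stationarity for any
#' \code{gamma}; the approximation error of the closure lives in the
#' transients.  With \code{t_eval = NULL} the report compares steady states
#' (errors at solver tolerance); with a numeric \code{t_eval} it compares
#' the distributions at that time after a calcium step from the all-N,
#' all-unbound state, where the \code{gamma > 1} closure error is finite.
#'
#' @param n_ru chain length (small; the exact side is \code{4^n_ru}).
#' @param ru a \code{\link{ru_parameters}} object (SE family).
#' @param Ca_grid calcium levels (uM).
#' @param SL sarcomere length or \code{NULL} for an unmodulated chain.
#' @param geom geometry with \code{n_ru} matching.
#' @param t_end integration horizon used to reach the reduced model's steady
#'   state (s).
#' @param t_eval optional transient comparison time (s).
#' @return data.frame with columns \code{Ca}, \code{unit}, \code{P_exact},
#'   \code{P_reduced}, \code{abs_err}, \code{triplet_tv} (total-variation
#'   distance between stored and exact triplet distributions, NA at the
#'   boundary units).
#' @export
closure_error_report <- function(n_ru, ru, Ca_grid, SL = NULL,
                                 geom = sarcomere_geometry(n_ru = n_ru),
                                 t_end = 5, t_eval = NULL) {
  stopifnot(geom$n_ru == n_ru)
  M <- n_ru - 2L
  cache <- se_cache()
  out <- list()
  for (Ca in Ca_grid) {
    table <- ru_rate_table(ru, Ca, if (is.null(SL)) ru$SL_kd else SL, "SE")
    G <- ctmc_generator(n_ru, table, SL, geom)
    if (is.null(t_eval)) {
      p <- master_steady_state(G)
      pi_red <- se_ru_steady(ru, Ca, SL, geom, t_end = t_end)
    } else {
      p0 <- numeric(4^n_ru); p0[1] <- 1
      p <- master_transient(G, p0, c(0, t_eval))[2, ]
      chiSF <- if (is.null(SL)) rep(1, n_ru) else {
        chi_SF(SL, seq_len(n_ru), geom)
      }
      wts <- se_weights(table, cache)
      f <- function(t, y, parms) {
        list(as.vector(se_ru_rhs_core(matrix(y, 64L, M), table, chiSF,
                                      cache, wts)))
      }
      y0 <- numeric(64L * M); y0[64L * (seq_len(M) - 1L) + 1L] <- 1
      o <- deSolve::ode(y0, c(0, t_eval), f, parms = NULL,
                        method = "lsodes", rtol = 1e-8, atol = 1e-11)
      pi_red <- matrix(unname(o[2, -1]), 64L, M)
    }
    P_ex <- master_permissivity(p, n_ru)
    P_red <- se_permissivity(pi_red)
    tv <- rep(NA_real_, n_ru)
    for (i in 2:(n_ru - 1L)) {
      tv[i] <- 0.5 * sum(abs(master_triplet(p, n_ru, i) - pi_red[, i - 1L]))
    }
    out[[length(out) + 1L]] <- data.frame(
      Ca = Ca, unit = seq_len(n_ru), P_exact = P_ex, P_reduced = P_red,
      abs_err = abs(P_ex - P_red), triplet_tv = tv)
  }
  do.call(rbind, out)
}
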