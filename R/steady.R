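# Steady-state solvers.  Because crossbridges do not feed back on the
# regulatory units, the RU block can be equilibrated on its own and the
# moment equations then solved in closed form (they are linear given the
# permissivity and coupling rates).

#' Steady state of the mean-field triplet distribution
#'
#' Self-consistent-field iteration: the aggregated edge rates are frozen at
#' the current iterate, the resulting linear 16-state master equation is
#' solved exactly for its stationary distribution, and the edge rates are
#' updated; iterates therefore stay probability vectors.  Mild damping is
#' applied if the iteration oscillates; a time-integration fallback covers
#' pathological parameter corners.
#'
#' @param ru a \code{\link{ru_parameters}} object.
#' @param Ca calcium (uM).
#' @param SL sarcomere length (um).
#' @param tol convergence tolerance on the iterate (max-norm).
#' @param eps_den denominator guard.
#' @return 16-vector of steady triplet probabilities.
#' @export
mf_ru_steady <- function(ru, Ca, SL, tol = 1e-12, eps_den = 1e-12) {
  cache <- mf_cache()
  table <- ru_rate_table(ru, Ca, SL, "MF")
  w <- mf_edge_weights(table, cache)
  buB <- table$kC_BU_P + cache$bNn * (table$kC_BU_N - table$kC_BU_P)
  rE <- buB + cache$eU * (table$kC_UB - buB)
  s <- 1:16
  iL <- cbind(cache$flipA, s); iC <- cbind(cache$flipB, s)
  iR <- cbind(cache$flipD, s); iE <- cbind(cache$flipE, s)
  An <- matrix(0, 17, 16)
  An[17, ] <- 1
  b <- c(rep(0, 16), 1)
  lin_steady <- function(pi) {
    wpi <- w * pi
    denL <- as.vector(cache$AggBD %*% pi)
    ktL <- as.vector(cache$AggBD %*% wpi) / denL
    ktL[denL <= eps_den] <- 0
    denR <- as.vector(cache$AggBA %*% pi)
    ktR <- as.vector(cache$AggBA %*% wpi) / denR
    ktR[denR <= eps_den] <- 0
    rL <- ktL[cache$mapL]; rR <- ktR[cache$mapR]
    A <- An
    A[iL] <- rL; A[iC] <- w; A[iR] <- rR; A[iE] <- rE
    A[cbind(s, s)] <- -(rL + w + rR + rE)
    p <- stats::lsfit(A, b, intercept = FALSE)$coefficients
    p <- pmax(p, 0)
    p / sum(p)
  }
  pi <- rep(1 / 16, 16)
  ok <- FALSE
  damp <- 1
  for (it in 1:200) {
    pin <- lin_steady(pi)
    dlt <- max(abs(pin - pi))
    pi <- damp * pin + (1 - damp) * pi
    if (dlt < tol) { ok <- TRUE; break }
    if (it == 40) damp <- 0.5   # slow oscillatory cases
  }
  if (!ok && max(abs(mf_ru_rhs_core(pi, table, cache, eps_den))) > 1e-6) {
    f <- function(t, y, p) list(mf_ru_rhs_core(y, table, cache, eps_den))
    y0 <- numeric(16); y0[1] <- 1
    out <- deSolve::lsoda(y0, c(0, 5), f, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    pi <- pmax(unname(out[nrow(out), -1]), 0)
  }
  pi / sum(pi)
}

#' Steady state of the spatially explicit RU block
#'
#' Integrates the triplet subsystem (crossbridges do not feed back on it)
#' with a sparse stiff solver until the residual is below tolerance.
#'
#' @param ru a \code{\link{ru_parameters}} object.
#' @param Ca calcium (uM).
#' @param SL sarcomere length (um) or \code{NULL} for an unmodulated chain.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @param t_end integration horizon (s), extended once if the residual test
#'   fails.
#' @param tol max-norm residual tolerance (1/s).
#' @param eps_den denominator guard.
#' @return 64 x (n_ru - 2) matrix of steady triplet probabilities.
#' @export
se_ru_steady <- function(ru, Ca, SL = NULL, geom = sarcomere_geometry(),
                         t_end = 5, tol = 1e-6, eps_den = 1e-12) {
  M <- geom$n_ru - 2L
  table <- ru_rate_table(ru, Ca, if (is.null(SL)) ru$SL_kd else SL, "SE")
  chiSF <- if (is.null(SL)) rep(1, geom$n_ru) else {
    chi_SF(SL, seq_len(geom$n_ru), geom)
  }
  cache <- se_cache()
  wts <- se_weights(table)
  f <- function(t, y, p) {
    list(as.vector(se_ru_rhs_core(matrix(y, 64L, M), table, chiSF, cache,
                                  wts, eps_den)))
  }
  y0 <- numeric(64L * M); y0[64L * (seq_len(M) - 1L) + 1L] <- 1
  for (Tend in c(t_end, 4 * t_end)) {
    out <- deSolve::ode(y0, c(0, Tend), f, parms = NULL, method = "lsodes",
                        rtol = 1e-8, atol = 1e-11, maxsteps = 100000)
    y <- unname(out[nrow(out), -1])
    if (max(abs(f(0, y, NULL)[[1]])) < tol) break
    y0 <- y
  }
  pi <- matrix(pmax(y, 0), 64L, M)
  sweep(pi, 2, colSums(pi), "/")
}

# closed-form steady crossbridge moments given frozen RU quantities
# (vectorised over units); returns the four moment vectors
xb_moment_steady <- function(P, ktNP, ktPN, r, s0, s1, v = 0) {
  p <- r + ktPN; m <- r + ktNP
  det <- p * m - ktNP * ktPN
  muP0 <- (m * (P * s0)) / det
  muN0 <- (ktPN * (P * s0)) / det
  b1P <- P * s1 - v * muP0
  b1N <- -v * muN0
  muP1 <- (m * b1P + ktNP * b1N) / det
  muN1 <- (ktPN * b1P + p * b1N) / det
  list(muP0 = muP0, muN0 = muN0, muP1 = muP1, muN1 = muN1)
}

#' Steady isometric active tension
#'
#' Fast path for steady-state protocols: equilibrates the RU block, then
#' solves the (linear) moment equations in closed form at zero velocity.
#' Works for both moments-model families; the PDE variants share their
#' steady tension with the matched moments model by construction.
#'
#' @param model a \code{\link{sarcomere_model}}.
#' @param Ca calcium (uM).
#' @param SL sarcomere length (um).
#' @return list with \code{Ta} (MPa), \code{P} (scalar or profile),
#'   \code{mu0}, \code{mu1}, and the frozen coupling rates.
#' @export
steady_tension <- function(model, Ca, SL) {
  ru <- model$ru; xb <- model$xb; geom <- model$geom
  r <- xb_total_rate(xb, 0)
  if (model$family == "MF") {
    pi <- mf_ru_steady(ru, Ca, SL, eps_den = model$solver$eps_den)
    table <- ru_rate_table(ru, Ca, SL, "MF")
    kt <- mf_xb_coupling_rates(pi, table, model$solver$eps_den)
    P <- mf_permissivity(pi)
    ms <- xb_moment_steady(P, kt[["kt_NP"]], kt[["kt_PN"]], r,
                           xb$mu_fP0, xb$mu_fP1)
    xs <- chi_so(SL, geom)
    list(Ta = xb$a_XB * xs * (ms$muP1 + ms$muN1),
         P = P, mu0 = xs * (ms$muP0 + ms$muN0),
         mu1 = xs * (ms$muP1 + ms$muN1),
         kt_NP = kt[["kt_NP"]], kt_PN = kt[["kt_PN"]], pi = pi)
  } else {
    pi <- se_ru_steady(ru, Ca, SL, geom, eps_den = model$solver$eps_den)
    table <- ru_rate_table(ru, Ca, SL, "SE")
    chiSF <- chi_SF(SL, seq_len(geom$n_ru), geom)
    kt <- se_xb_coupling_core(pi, chiSF, se_weights(table),
                              model$solver$eps_den)
    wM <- chi_M(SL, seq_len(geom$n_ru), geom) * chiSF
    ms <- xb_moment_steady(kt$P, kt$kt_NP, kt$kt_PN, r,
                           xb$mu_fP0 * wM, xb$mu_fP1 * wM)
    list(Ta = xb$a_XB * mean(ms$muP1 + ms$muN1),
         P = kt$P, mu0 = mean(ms$muP0 + ms$muN0),
         mu1 = mean(ms$muP1 + ms$muN1),
         kt_NP = kt$kt_NP, kt_PN = kt$kt_PN, pi = pi)
  }
}
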