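# Mean-field triplet models.
#
# State of the MF-ODE model: 16 triplet probabilities pi^{alpha beta delta,
# eta} -- tropomyosin states (alpha, beta, delta) of three consecutive RUs
# plus the troponin state eta of the central one -- and the four
# distribution moments (muP0, muN0, muP1, muN1) of the attached-crossbridge
# strain density.  The MF-PDE variant replaces the moments by two transported
# densities nP(x), nN(x) on an x grid.
#
# Encoding: states are enumerated with bits (alpha, beta, delta, eta), value
# 1 = N/U, 2 = P/B, packed little-endian:
#   s = 1 + (alpha-1) + 2 (beta-1) + 4 (delta-1) + 8 (eta-1).

mf_cache_build <- function() {
  a <- rep(rep(1:2, times = 8))
  b <- rep(rep(1:2, each = 2), times = 4)
  d <- rep(rep(1:2, each = 4), times = 2)
  e <- rep(1:2, each = 8)
  s <- seq_len(16L)
  flip <- function(bit, stride) s + ifelse(bit == 1L, stride, -stride)
  kBD <- (b - 1L) + 2L * (d - 1L) + 1L     # key (f = beta, beta_t = delta)
  kBA <- (b - 1L) + 2L * (a - 1L) + 1L     # key (f = beta, beta_t = alpha)
  AggBD <- matrix(0, 4, 16); AggBD[cbind(kBD, s)] <- 1
  AggBA <- matrix(0, 4, 16); AggBA[cbind(kBA, s)] <- 1
  list(a = a, b = b, d = d, e = e,
       flipA = flip(a, 1L), flipB = flip(b, 2L),
       flipD = flip(d, 4L), flipE = flip(e, 8L),
       n_ad = (a == 2L) + (d == 2L),
       AggBD = AggBD, AggBA = AggBA,
       mapL = (a - 1L) + 2L * (b - 1L) + 1L,
       mapR = (d - 1L) + 2L * (b - 1L) + 1L,
       bP = b == 2L, bN = b == 1L,
       eU = as.numeric(e == 1L), bNn = as.numeric(b == 1L))
}

.mf_cache <- NULL
mf_cache <- function() {
  if (is.null(.mf_cache)) {
    # assigned in the package namespace on first use
    utils::assignInMyNamespace(".mf_cache", mf_cache_build())
  }
  .mf_cache
}

# tropomyosin transition weight of each triplet state: the rate at which the
# CENTRAL unit flips, given its neighbours (alpha, delta) and troponin eta.
# The same vector serves as (i) the central-flip rate and (ii) the weight in
# the edge-rate conditional expectations of the shifted triplet.
mf_edge_weights <- function(table, cache = mf_cache()) {
  npB <- table$kT_NP_B[cache$n_ad + 1L]
  np <- npB + cache$eU * (table$kT_NP_U[cache$n_ad + 1L] - npB)
  pn <- table$kT_PN[cache$n_ad + 1L]
  pn + cache$bNn * (np - pn)
}

#' Aggregated edge transition rates of the mean-field triplet model
#'
#' The tropomyosin units at the two edges of the representative triplet have
#' one neighbour outside the triplet; their transition rates are closed as
#' conditional expectations over the (translation-invariant) triplet
#' distribution itself.  The left-edge rate for a unit currently in state
#' \code{f} next to a centre in state \code{beta} averages the bare rate over
#' the unobserved outer neighbour and troponin state, weighting by the triplet
#' probabilities shifted one unit left; the right edge is symmetric.  When a
#' conditioning probability falls below \code{eps_den} the rate is returned
#' as zero (the flux it multiplies is of the same vanishing order).
#'
#' @param pi numeric vector of 16 triplet probabilities.
#' @param table a \code{\link{ru_rate_table}}.
#' @param eps_den denominator guard.
#' @return list with 2 x 2 matrices \code{left} and \code{right}; rows are
#'   the current state \code{f} of the edge unit (N, P), columns the centre
#'   state (N, P).  Entry [f, beta] is the rate of the f -> not-f flip.
#' @export
mf_edge_rates <- function(pi, table, eps_den = 1e-12) {
  cache <- mf_cache()
  w <- mf_edge_weights(table, cache)
  ktL <- as.vector(cache$AggBD %*% (w * pi)) /
    pmax(as.vector(cache$AggBD %*% pi), eps_den)
  ktL[as.vector(cache$AggBD %*% pi) <= eps_den] <- 0
  ktR <- as.vector(cache$AggBA %*% (w * pi)) /
    pmax(as.vector(cache$AggBA %*% pi), eps_den)
  ktR[as.vector(cache$AggBA %*% pi) <= eps_den] <- 0
  dn <- list(c("N", "P"), c("N", "P"))
  list(left = matrix(ktL, 2, 2, dimnames = dn),
       right = matrix(ktR, 2, 2, dimnames = dn))
}

# time derivative of the 16 triplet probabilities (four forward/backward
# transition groups: left edge, centre, right edge, central troponin)
mf_ru_rhs_core <- function(pi, table, cache, eps_den = 1e-12) {
  w <- mf_edge_weights(table, cache)
  wpi <- w * pi
  denL <- as.vector(cache$AggBD %*% pi)
  ktL <- as.vector(cache$AggBD %*% wpi) / denL
  ktL[denL <= eps_den] <- 0
  denR <- as.vector(cache$AggBA %*% pi)
  ktR <- as.vector(cache$AggBA %*% wpi) / denR
  ktR[denR <= eps_den] <- 0
  rL <- ktL[cache$mapL]
  rR <- ktR[cache$mapR]
  buB <- table$kC_BU_P + cache$bNn * (table$kC_BU_N - table$kC_BU_P)
  rE <- buB + cache$eU * (table$kC_UB - buB)
  fA <- cache$flipA; fB <- cache$flipB; fD <- cache$flipD; fE <- cache$flipE
  rL[fA] * pi[fA] - rL * pi +
    w[fB] * pi[fB] - w * pi +
    rR[fD] * pi[fD] - rR * pi +
    rE[fE] * pi[fE] - rE * pi
}

#' Time derivative of the mean-field RU triplet distribution
#'
#' @param pi numeric vector of 16 triplet probabilities.
#' @param Ca calcium concentration (uM).
#' @param SL sarcomere length (um).
#' @param ru a \code{\link{ru_parameters}} object.
#' @param eps_den denominator guard for the aggregated edge rates.
#' @return numeric vector of 16 derivatives (sums to zero).
#' @export
mf_ru_rhs <- function(pi, Ca, SL, ru, eps_den = 1e-12) {
  if (any(!is.finite(pi))) stop("non-finite triplet probabilities")
  table <- ru_rate_table(ru, Ca, SL, "MF")
  mf_ru_rhs_core(pi, table, mf_cache(), eps_den)
}

#' Permissivity of the mean-field model
#'
#' Probability that a regulatory unit in the single-overlap zone is
#' permissive: the marginal of the central tropomyosin state.
#'
#' @param pi numeric vector of 16 triplet probabilities.
#' @return scalar in [0, 1].
#' @export
mf_permissivity <- function(pi) sum(pi[mf_cache()$bP])

#' Crossbridge-coupling transition rates of the mean-field model
#'
#' Tropomyosin flip rates conditioned on the current permissivity state,
#' which drive the exchange between the permissive- and non-permissive-
#' associated crossbridge populations.  At a degenerate permissivity (0 or 1)
#' the undefined rate is returned as zero; the flux it multiplies vanishes.
#'
#' @param pi numeric vector of 16 triplet probabilities.
#' @param table a \code{\link{ru_rate_table}}.
#' @param eps_den denominator guard.
#' @return named numeric vector \code{c(kt_NP, kt_PN)} (1/s).
#' @export
mf_xb_coupling_rates <- function(pi, table, eps_den = 1e-12) {
  cache <- mf_cache()
  w <- mf_edge_weights(table, cache)
  P <- sum(pi[cache$bP])
  numNP <- sum(w[cache$bN] * pi[cache$bN])
  numPN <- sum(w[cache$bP] * pi[cache$bP])
  c(kt_NP = if (1 - P > eps_den) numNP / (1 - P) else 0,
    kt_PN = if (P > eps_den) numPN / P else 0)
}

# moments block shared by MF and (per unit) SE:
#   mu = (muP0, muN0, muP1, muN1), src = (s0, s1) permissive sources
xb_moments_rhs <- function(muP0, muN0, muP1, muN1, r, ktNP, ktPN, P, s0, s1,
                           v) {
  list(dP0 = -(r + ktPN) * muP0 + ktNP * muN0 + P * s0,
       dN0 = -(r + ktNP) * muN0 + ktPN * muP0,
       dP1 = -v * muP0 - (r + ktPN) * muP1 + ktNP * muN1 + P * s1,
       dN1 = -v * muN0 - (r + ktNP) * muN1 + ktPN * muP1)
}

#' Full right-hand side of the MF-ODE model
#'
#' Concatenates the triplet-distribution derivative with the four
#' distribution-moments equations.  State layout:
#' \code{c(pi[1:16], muP0, muN0, muP1, muN1)} (20 components).
#'
#' @param y numeric state vector of length 20.
#' @param Ca calcium concentration (uM).
#' @param SL sarcomere length (um).
#' @param v normalised shortening velocity (1/s).
#' @param ru,xb parameter objects.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @param eps_den denominator guard.
#' @return numeric vector of 20 derivatives.
#' @export
mf_ode_rhs <- function(y, Ca, SL, v, ru, xb, geom = sarcomere_geometry(),
                       eps_den = 1e-12) {
  if (any(!is.finite(y))) stop("non-finite model state")
  cache <- mf_cache()
  pi <- y[1:16]
  table <- ru_rate_table(ru, Ca, SL, "MF")
  dpi <- mf_ru_rhs_core(pi, table, cache, eps_den)
  P <- sum(pi[cache$bP])
  kt <- mf_xb_coupling_rates(pi, table, eps_den)
  r <- xb_total_rate(xb, v)
  mom <- xb_attachment_moments(xb, SL, NULL, geom)
  dm <- xb_moments_rhs(y[17], y[18], y[19], y[20], r, kt[["kt_NP"]],
                       kt[["kt_PN"]], P, mom$mu_f0, mom$mu_f1, v)
  c(dpi, dm$dP0, dm$dN0, dm$dP1, dm$dN1)
}

#' Active tension of the mean-field moments model
#'
#' \code{T_a = a_XB * chi_so(SL) * (muP1 + muN1)}; filament overlap enters
#' multiplicatively through the single-overlap ratio.  If \code{k_XB} is set,
#' the dimensional half-filament force
#' \code{F_hf = k_XB (SL0/2) n_ru chi_so (muP1 + muN1)} is attached as
#' attribute \code{"F_hf"}.
#'
#' @param y MF-ODE state vector (length 20).
#' @param SL sarcomere length (um).
#' @param xb an \code{\link{xb_parameters}} object.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @return active tension (MPa).
#' @export
mf_active_tension <- function(y, SL, xb, geom = sarcomere_geometry()) {
  mu1 <- chi_so(SL, geom) * (y[19] + y[20])
  Ta <- xb$a_XB * mu1
  if (!is.null(xb$k_XB)) {
    attr(Ta, "F_hf") <- xb$k_XB * (geom$SL0 / 2) * geom$n_ru * mu1
  }
  Ta
}

# ---- MF-PDE ----------------------------------------------------------------

# first-order upwind transport term for d n/d t = v_hs * d n/d x + reactions
# (characteristics move towards -x when v_hs > 0); zero inflow at the
# upstream boundary, outflow at the other.
upwind_transport <- function(n, v_hs, dx) {
  if (v_hs == 0) return(0 * n)
  if (is.matrix(n)) {
    K <- nrow(n)
    if (v_hs > 0) {
      v_hs * (rbind(n[-1, , drop = FALSE], 0) - n) / dx
    } else {
      v_hs * (n - rbind(0, n[-K, , drop = FALSE])) / dx
    }
  } else {
    K <- length(n)
    if (v_hs > 0) {
      v_hs * (c(n[-1], 0) - n) / dx
    } else {
      v_hs * (n - c(0, n[-K])) / dx
    }
  }
}

#' Right-hand side of the MF-PDE model
#'
#' Method-of-lines discretisation of the transported strain densities
#' \code{nP(x)}, \code{nN(x)} coupled to the triplet distribution.  State
#' layout \code{c(pi[1:16], nP[1:nx], nN[1:nx])}.  Transport uses first-order
#' upwinding with zero inflow.
#'
#' @param y state vector.
#' @param Ca calcium (uM).
#' @param SL sarcomere length (um).
#' @param v_hs half-sarcomere shortening velocity (um/s),
#'   \code{v_hs = v * SL0 / 2}.
#' @param ru,xb parameter objects.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @param grid list with \code{x} (nodes, um) and \code{dx}.
#' @param fPx attachment-rate profile evaluated on \code{grid$x} (1/s).
#' @param eps_den denominator guard.
#' @return derivative vector.
#' @export
mf_pde_rhs <- function(y, Ca, SL, v_hs, ru, xb, geom, grid, fPx,
                       eps_den = 1e-12) {
  if (any(!is.finite(y))) stop("non-finite model state")
  cache <- mf_cache()
  nx <- length(grid$x)
  pi <- y[1:16]
  nP <- y[16 + seq_len(nx)]
  nN <- y[16 + nx + seq_len(nx)]
  table <- ru_rate_table(ru, Ca, SL, "MF")
  dpi <- mf_ru_rhs_core(pi, table, cache, eps_den)
  P <- sum(pi[cache$bP])
  kt <- mf_xb_coupling_rates(pi, table, eps_den)
  v <- 2 * v_hs / geom$SL0
  r <- xb_total_rate(xb, v)
  gP <- r - fPx
  dnP <- upwind_transport(nP, v_hs, grid$dx) +
    (P / geom$DM - nP) * fPx - gP * nP -
    kt[["kt_PN"]] * nP + kt[["kt_NP"]] * nN
  dnN <- upwind_transport(nN, v_hs, grid$dx) -
    r * nN - kt[["kt_NP"]] * nN + kt[["kt_PN"]] * nP
  c(dpi, dnP, dnN)
}

#' Force and tension of the strain-density models
#'
#' Integrates the attached-crossbridge strain densities:
#' \code{mu^p = chi_so(SL) * sum_x (x/(SL0/2))^p (nP + nN) dx}, active
#' tension \code{T_a = a_XB mu^1} and, when \code{k_XB} is set, the
#' half-filament force \code{F_hf = n_ru chi_so integral k_XB x (nP+nN) dx}.
#'
#' @param y MF-PDE state vector.
#' @param SL sarcomere length (um).
#' @param xb an \code{\link{xb_parameters}} object.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @param grid list with \code{x} and \code{dx}.
#' @return list with \code{Ta} (MPa), \code{mu0}, \code{mu1} and (if
#'   \code{k_XB} set) \code{F_hf}.
#' @export
mf_pde_force <- function(y, SL, xb, geom, grid) {
  nx <- length(grid$x)
  nP <- y[16 + seq_len(nx)]
  nN <- y[16 + nx + seq_len(nx)]
  ntot <- nP + nN
  xs <- chi_so(SL, geom)
  mu0 <- xs * sum(ntot) * grid$dx
  mu1 <- xs * sum((grid$x / (geom$SL0 / 2)) * ntot) * grid$dx
  out <- list(Ta = xb$a_XB * mu1, mu0 = mu0, mu1 = mu1)
  if (!is.null(xb$k_XB)) {
    out$F_hf <- geom$n_ru * xs * sum(xb$k_XB * grid$x * ntot) * grid$dx
  }
  out
}
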