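# Spatially explicit per-unit models.
#
# RU block: joint probabilities pi_i^{alpha beta delta, th eta la} of the
# tropomyosin triple (alpha, beta, delta) AND troponin triple (th, eta, la)
# of units (i-1, i, i+1), stored for the interior units i = 2 .. n_ru-1 as a
# 64 x (n_ru - 2) matrix.  Columns are triplets (triplet-major), rows are
# the 64 states with bits packed little-endian:
#   s = 1 + (alpha-1) + 2(beta-1) + 4(delta-1) + 8(th-1) + 16(eta-1)
#       + 32(la-1),   1 = N/U, 2 = P/B.
# XB block: per-RU moment quadruples (SE-ODE) or per-RU strain densities
# (SE-PDE) for all units i = 1 .. n_ru.

se_cache_build <- function() {
  s <- seq_len(64L)
  bit <- function(k) ((s - 1L) %/% 2L^(k - 1L)) %% 2L + 1L
  a <- bit(1); b <- bit(2); d <- bit(3)
  t1 <- bit(4); t2 <- bit(5); t3 <- bit(6)
  flip <- function(x, stride) s + ifelse(x == 1L, stride, -stride)
  # 32-row marginals: rows of B32 are the states with the summed-out bit = U,
  # in increasing s order, so row r of B32 carries the remaining five bits in
  # the same little-endian order.
  iT1U <- which(t1 == 1L); iT1B <- which(t1 == 2L)
  iT3U <- which(t3 == 1L); iT3B <- which(t3 == 2L)
  sub5 <- function(rows) list(a = a[rows], b = b[rows], d = d[rows],
                              t1 = t1[rows], t2 = t2[rows], t3 = t3[rows])
  mL <- sub5(iT1U)   # roles (xi, f, beta_t | ., th_t, eta_t)
  mR <- sub5(iT3U)   # roles (beta_t, f, xi | eta_t, la_t, .)
  keyL32 <- (mL$b - 1L) + 2L * (mL$d - 1L) + 4L * (mL$t2 - 1L) +
    8L * (mL$t3 - 1L) + 1L
  keyR32 <- (mR$b - 1L) + 2L * (mR$a - 1L) + 4L * (mR$t2 - 1L) +
    8L * (mR$t1 - 1L) + 1L
  AggL <- matrix(0, 16, 32); AggL[cbind(keyL32, seq_len(32L))] <- 1
  AggR <- matrix(0, 16, 32); AggR[cbind(keyR32, seq_len(32L))] <- 1
  key16 <- expand.grid(f = 1:2, bt = 1:2, tn = 1:2, eta = 1:2)
  list(a = a, b = b, d = d, t1 = t1, t2 = t2, t3 = t3,
       flipA = flip(a, 1L), flipB = flip(b, 2L), flipD = flip(d, 4L),
       flipT1 = flip(t1, 8L), flipT2 = flip(t2, 16L), flipT3 = flip(t3, 32L),
       iT1U = iT1U, iT1B = iT1B, iT3U = iT3U, iT3B = iT3B,
       mL = mL, mR = mR, AggL = AggL, AggR = AggR,
       key16 = key16,
       fNkeys16 = which(key16$f == 1L),
       mapL64 = (a - 1L) + 2L * (b - 1L) + 4L * (t1 - 1L) +
         8L * (t2 - 1L) + 1L,
       mapR64 = (d - 1L) + 2L * (b - 1L) + 4L * (t3 - 1L) +
         8L * (t2 - 1L) + 1L,
       aN = a == 1L, aP = a == 2L, bN = b == 1L, bP = b == 2L,
       dN = d == 1L, dP = d == 2L,
       n_ad = (a == 2L) + (d == 2L))
}

.se_cache <- NULL
se_cache <- function() {
  if (is.null(.se_cache)) {
    utils::assignInMyNamespace(".se_cache", se_cache_build())
  }
  .se_cache
}

# parameter-dependent weight vectors used by the SE right-hand side; all
# exclude the chi_SF modulation, which is applied per unit afterwards
se_weights <- function(table, cache = se_cache()) {
  kNP <- function(n, tn) ifelse(tn == 1L, table$kT_NP_U[n + 1L],
                                table$kT_NP_B[n + 1L])
  kPN <- function(n) table$kT_PN[n + 1L]
  w_of <- function(m) {
    n <- (m$a == 2L) + (m$d == 2L)
    ifelse(m$b == 1L, kNP(n, m$t2), kPN(n))
  }
  # central-flip weight per 64-state (tropomyosin of the centre unit)
  wC64 <- ifelse(cache$b == 1L, kNP(cache$n_ad, cache$t2), kPN(cache$n_ad))
  # boundary 16-key tables (missing outer neighbour in state N => n = [bt==P])
  nb <- (cache$key16$bt == 2L) + 0L
  bL <- ifelse(cache$key16$f == 1L, kNP(nb, cache$key16$tn), kPN(nb))
  # XB-coupling weights for the boundary RUs (units 1 and n_ru)
  nb1 <- (cache$b == 2L) + 0L
  list(wL32 = w_of(cache$mL), wR32 = w_of(cache$mR), wC64 = wC64,
       kt_boundary16 = bL,
       wNPL64 = ifelse(cache$aN, kNP(nb1, cache$t1), 0),
       wPNL64 = ifelse(cache$aP, kPN(nb1), 0),
       wNPR64 = ifelse(cache$dN, kNP(nb1, cache$t3), 0),
       wPNR64 = ifelse(cache$dP, kPN(nb1), 0))
}

#' Aggregated edge rates of a spatially explicit triplet
#'
#' Transition rates of the two edge tropomyosin units of the triplet stored
#' at interior unit \code{i}, closed as conditional expectations over the
#' neighbouring stored triplet (the triplet centred at the transitioning
#' unit).  For \code{i = 1} and \code{i = n_ru} the missing outer neighbour
#' is taken to be non-permissive and the bare rate is returned.
#'
#' @param pi 64 x (n_ru - 2) matrix of triplet probabilities.
#' @param i index of the transitioning unit (1 .. n_ru).
#' @param table a \code{\link{ru_rate_table}}.
#' @param SL sarcomere length (um); modulates the permissive-direction rate
#'   through \code{chi_SF}.  Use \code{NULL} for an unmodulated chain.
#' @param geom a \code{\link{sarcomere_geometry}} with \code{n_ru} matching
#'   \code{pi}.
#' @param eps_den denominator guard.
#' @return 16-vector of rates indexed by (current state f, inner neighbour
#'   state, troponin of the transitioning unit, inner troponin), little-
#'   endian, each 1 = N/U first.
#' @export
se_edge_rates <- function(pi, i, table, SL = NULL,
                          geom = sarcomere_geometry(), eps_den = 1e-12) {
  cache <- se_cache()
  check_ru_index(i, geom)
  n_ru <- ncol(pi) + 2L
  w <- se_weights(table, cache)
  xSF <- if (is.null(SL)) rep(1, n_ru) else chi_SF(SL, seq_len(n_ru), geom)
  if (i == 1L || i == n_ru) {
    out <- w$kt_boundary16
    out[cache$fNkeys16] <- out[cache$fNkeys16] * xSF[i]
    return(out)
  }
  co <- pi[, i - 1L]
  B <- co[cache$iT1U] + co[cache$iT1B]
  den <- as.vector(cache$AggL %*% B)
  num <- as.vector(cache$AggL %*% (w$wL32 * B))
  out <- ifelse(den > eps_den, num / den, 0)
  out[cache$fNkeys16] <- out[cache$fNkeys16] * xSF[i]
  out
}

# time derivative of the full 64 x (n_ru-2) triplet block; chiSF is the
# per-unit single-filament weight (length n_ru, all 1 for an unmodulated
# chain)
se_ru_rhs_core <- function(pi, table, chiSF, cache, wts, eps_den = 1e-12) {
  M <- ncol(pi)
  # left-edge aggregated tables from each stored triplet (source column c
  # describes the flip of its centre unit c + 1)
  B32L <- pi[cache$iT1U, , drop = FALSE] + pi[cache$iT1B, , drop = FALSE]
  denL <- cache$AggL %*% B32L
  numL <- cache$AggL %*% (wts$wL32 * B32L)
  tabL <- ifelse(denL > eps_den, numL / denL, 0)
  tabL[cache$fNkeys16, ] <- tabL[cache$fNkeys16, ] *
    rep(chiSF[2:(M + 1L)], each = 8L)
  bL <- wts$kt_boundary16
  bL[cache$fNkeys16] <- bL[cache$fNkeys16] * chiSF[1L]
  KL <- cbind(bL, tabL[, -M, drop = FALSE])
  # right-edge tables
  B32R <- pi[cache$iT3U, , drop = FALSE] + pi[cache$iT3B, , drop = FALSE]
  denR <- cache$AggR %*% B32R
  numR <- cache$AggR %*% (wts$wR32 * B32R)
  tabR <- ifelse(denR > eps_den, numR / denR, 0)
  tabR[cache$fNkeys16, ] <- tabR[cache$fNkeys16, ] *
    rep(chiSF[2:(M + 1L)], each = 8L)
  bR <- wts$kt_boundary16
  bR[cache$fNkeys16] <- bR[cache$fNkeys16] * chiSF[M + 2L]
  KR <- cbind(tabR[, -1L, drop = FALSE], bR)
  RL <- KL[cache$mapL64, , drop = FALSE]
  RR <- KR[cache$mapR64, , drop = FALSE]
  RC <- matrix(wts$wC64, 64L, M)
  RC[cache$bN, ] <- RC[cache$bN, ] * rep(chiSF[2:(M + 1L)], each = 32L)
  # troponin flip rates (calcium binding/unbinding of the three units)
  buN <- table$kC_BU_N; buP <- table$kC_BU_P; ub <- table$kC_UB
  r4 <- ifelse(cache$t1 == 1L, ub, ifelse(cache$a == 1L, buN, buP))
  r5 <- ifelse(cache$t2 == 1L, ub, ifelse(cache$b == 1L, buN, buP))
  r6 <- ifelse(cache$t3 == 1L, ub, ifelse(cache$d == 1L, buN, buP))
  fA <- cache$flipA; fB <- cache$flipB; fD <- cache$flipD
  f1 <- cache$flipT1; f2 <- cache$flipT2; f3 <- cache$flipT3
  RL[fA, , drop = FALSE] * pi[fA, , drop = FALSE] - RL * pi +
    RC[fB, , drop = FALSE] * pi[fB, , drop = FALSE] - RC * pi +
    RR[fD, , drop = FALSE] * pi[fD, , drop = FALSE] - RR * pi +
    r4[f1] * pi[f1, , drop = FALSE] - r4 * pi +
    r5[f2] * pi[f2, , drop = FALSE] - r5 * pi +
    r6[f3] * pi[f3, , drop = FALSE] - r6 * pi
}

#' Time derivative of the spatially explicit RU block
#'
#' @param pi 64 x (n_ru - 2) matrix of triplet probabilities (interior units
#'   2 .. n_ru - 1).
#' @param Ca calcium (uM).
#' @param SL sarcomere length (um), or \code{NULL} for an unmodulated chain
#'   (all single-filament weights equal to one).
#' @param ru a \code{\link{ru_parameters}} object.
#' @param geom a \code{\link{sarcomere_geometry}}; \code{geom$n_ru} must
#'   equal \code{ncol(pi) + 2}.
#' @param eps_den denominator guard.
#' @return matrix of derivatives, same shape as \code{pi}; each column sums
#'   to zero.
#' @export
se_ru_rhs <- function(pi, Ca, SL, ru, geom = sarcomere_geometry(),
                      eps_den = 1e-12) {
  if (any(!is.finite(pi))) stop("non-finite triplet probabilities")
  if (ncol(pi) + 2L != geom$n_ru) {
    stop("pi must have n_ru - 2 columns")
  }
  table <- ru_rate_table(ru, Ca, if (is.null(SL)) ru$SL_kd else SL, "SE")
  chiSF <- if (is.null(SL)) rep(1, geom$n_ru) else {
    chi_SF(SL, seq_len(geom$n_ru), geom)
  }
  se_ru_rhs_core(pi, table, chiSF, se_cache(), se_weights(table), eps_den)
}

#' Per-unit permissivity profile
#'
#' Probability that each RU along the thin filament is permissive.  The
#' interior units read the central slot of their own triplet; the first and
#' last unit read the corresponding edge slot of triplets 2 and
#' \code{n_ru - 1}.
#'
#' @param pi 64 x (n_ru - 2) matrix.
#' @return numeric vector of length \code{n_ru}.
#' @export
se_permissivity <- function(pi) {
  cache <- se_cache()
  M <- ncol(pi)
  c(sum(pi[cache$aP, 1L]),
    colSums(pi[cache$bP, , drop = FALSE]),
    sum(pi[cache$dP, M]))
}

# XB-coupling tropomyosin rates for every RU (length n_ru vectors);
# boundary units use the adjacent stored triplet with the missing neighbour
# taken non-permissive
se_xb_coupling_core <- function(pi, chiSF, wts, eps_den = 1e-12) {
  cache <- se_cache()
  M <- ncol(pi)
  P <- se_permissivity(pi)
  numNP_int <- chiSF[2:(M + 1L)] * colSums(wts$wC64 * pi * cache$bN)
  numPN_int <- colSums(wts$wC64 * pi * cache$bP)
  numNP <- c(chiSF[1L] * sum(wts$wNPL64 * pi[, 1L]), numNP_int,
             chiSF[M + 2L] * sum(wts$wNPR64 * pi[, M]))
  numPN <- c(sum(wts$wPNL64 * pi[, 1L]), numPN_int,
             sum(wts$wPNR64 * pi[, M]))
  ktNP <- ifelse(1 - P > eps_den, numNP / (1 - P), 0)
  ktPN <- ifelse(P > eps_den, numPN / P, 0)
  list(kt_NP = ktNP, kt_PN = ktPN, P = P)
}

#' Crossbridge-coupling rates for each regulatory unit
#'
#' @param pi 64 x (n_ru - 2) matrix of triplet probabilities.
#' @param table a \code{\link{ru_rate_table}}.
#' @param SL sarcomere length (um) or \code{NULL} for an unmodulated chain.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @param eps_den denominator guard.
#' @return list with vectors \code{kt_NP}, \code{kt_PN} (length n_ru) and
#'   the permissivity profile \code{P}.
#' @export
se_xb_coupling_rates <- function(pi, table, SL = NULL,
                                 geom = sarcomere_geometry(),
                                 eps_den = 1e-12) {
  chiSF <- if (is.null(SL)) rep(1, geom$n_ru) else {
    chi_SF(SL, seq_len(geom$n_ru), geom)
  }
  se_xb_coupling_core(pi, chiSF, se_weights(table), eps_den)
}

# state layout helpers for SE-ODE: c(pi (64*(n-2)), muP0, muN0, muP1, muN1)
se_unpack <- function(y, n_ru) {
  M <- n_ru - 2L
  npi <- 64L * M
  list(pi = matrix(y[seq_len(npi)], 64L, M),
       muP0 = y[npi + seq_len(n_ru)],
       muN0 = y[npi + n_ru + seq_len(n_ru)],
       muP1 = y[npi + 2L * n_ru + seq_len(n_ru)],
       muN1 = y[npi + 3L * n_ru + seq_len(n_ru)])
}

#' Full right-hand side of the SE-ODE model
#'
#' Triplet block plus per-RU distribution-moments equations with spatially
#' modulated attachment sources.  State layout
#' \code{c(pi, muP0[1:n], muN0[1:n], muP1[1:n], muN1[1:n])} with
#' \code{pi} column-major, \code{(n_ru - 2) * 64 + 4 n_ru} components in
#' total (2048 at the default 32 RUs).
#'
#' @param y state vector.
#' @param Ca calcium (uM).
#' @param SL sarcomere length (um).
#' @param v normalised shortening velocity (1/s).
#' @param ru,xb parameter objects.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @param eps_den denominator guard.
#' @return derivative vector.
#' @export
se_ode_rhs <- function(y, Ca, SL, v, ru, xb, geom = sarcomere_geometry(),
                       eps_den = 1e-12) {
  if (any(!is.finite(y))) stop("non-finite model state")
  n_ru <- geom$n_ru
  st <- se_unpack(y, n_ru)
  table <- ru_rate_table(ru, Ca, SL, "SE")
  idx <- seq_len(n_ru)
  chiSF <- chi_SF(SL, idx, geom)
  wts <- se_weights(table)
  dpi <- se_ru_rhs_core(st$pi, table, chiSF, se_cache(), wts, eps_den)
  kt <- se_xb_coupling_core(st$pi, chiSF, wts, eps_den)
  r <- xb_total_rate(xb, v)
  wM <- chi_M(SL, idx, geom) * chiSF
  dm <- xb_moments_rhs(st$muP0, st$muN0, st$muP1, st$muN1, r,
                       kt$kt_NP, kt$kt_PN, kt$P,
                       xb$mu_fP0 * wM, xb$mu_fP1 * wM, v)
  c(as.vector(dpi), dm$dP0, dm$dN0, dm$dP1, dm$dN1)
}

#' Active tension of the spatially explicit moments model
#'
#' \code{T_a = a_XB * (1/n_ru) * sum_i (muP1_i + muN1_i)}; filament overlap
#' is already encoded in the per-unit attachment sources, so no
#' single-overlap factor appears.
#'
#' @param y SE-ODE state vector.
#' @param xb an \code{\link{xb_parameters}} object.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @return active tension (MPa); attribute \code{"F_hf"} when \code{k_XB}
#'   is set.
#' @export
se_active_tension <- function(y, xb, geom = sarcomere_geometry()) {
  st <- se_unpack(y, geom$n_ru)
  mu1 <- mean(st$muP1 + st$muN1)
  Ta <- xb$a_XB * mu1
  if (!is.null(xb$k_XB)) {
    attr(Ta, "F_hf") <- xb$k_XB * (geom$SL0 / 2) * geom$n_ru * mu1
  }
  Ta
}

# ---- SE-PDE ----------------------------------------------------------------

se_pde_unpack <- function(y, n_ru, nx) {
  M <- n_ru - 2L
  npi <- 64L * M
  list(pi = matrix(y[seq_len(npi)], 64L, M),
       nP = matrix(y[npi + seq_len(nx * n_ru)], nx, n_ru),
       nN = matrix(y[npi + nx * n_ru + seq_len(nx * n_ru)], nx, n_ru))
}

#' Right-hand side of the SE-PDE model
#'
#' Per-RU copy of the strain-density equations with spatially modulated
#' attachment profile \code{fP_i(x) = fP(x) chi_M(SL, i) chi_SF(SL, i)} and
#' detachment \code{gP_i = r(v) - fP_i}, \code{gN = r(v)}.  State layout
#' \code{c(pi, nP[(x, i)], nN[(x, i)])}, densities column-major by unit.
#'
#' @param y state vector.
#' @param Ca calcium (uM).
#' @param SL sarcomere length (um).
#' @param v_hs half-sarcomere shortening velocity (um/s).
#' @param ru,xb parameter objects.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @param grid list with \code{x}, \code{dx}.
#' @param fPx attachment profile on the grid (1/s).
#' @param eps_den denominator guard.
#' @return derivative vector.
#' @export
se_pde_rhs <- function(y, Ca, SL, v_hs, ru, xb, geom, grid, fPx,
                       eps_den = 1e-12) {
  if (any(!is.finite(y))) stop("non-finite model state")
  n_ru <- geom$n_ru
  nx <- length(grid$x)
  st <- se_pde_unpack(y, n_ru, nx)
  table <- ru_rate_table(ru, Ca, SL, "SE")
  idx <- seq_len(n_ru)
  chiSF <- chi_SF(SL, idx, geom)
  wts <- se_weights(table)
  dpi <- se_ru_rhs_core(st$pi, table, chiSF, se_cache(), wts, eps_den)
  kt <- se_xb_coupling_core(st$pi, chiSF, wts, eps_den)
  v <- 2 * v_hs / geom$SL0
  r <- xb_total_rate(xb, v)
  wM <- chi_M(SL, idx, geom) * chiSF
  fPi <- outer(fPx, wM)                       # nx x n_ru
  gPi <- r - fPi
  ktNP <- rep(kt$kt_NP, each = nx)
  ktPN <- rep(kt$kt_PN, each = nx)
  Pi <- rep(kt$P, each = nx)
  dnP <- upwind_transport(st$nP, v_hs, grid$dx) +
    (Pi / geom$DM - st$nP) * fPi - gPi * st$nP -
    ktPN * st$nP + ktNP * st$nN
  dnN <- upwind_transport(st$nN, v_hs, grid$dx) -
    r * st$nN - ktNP * st$nN + ktPN * st$nP
  c(as.vector(dpi), as.vector(dnP), as.vector(dnN))
}

#' Force and tension of the SE-PDE model
#'
#' Sums the strain integrals over all regulatory units:
#' \code{mu^1 = (1/n_ru) sum_i integral (x/(SL0/2)) (n_iP + n_iN) dx},
#' \code{T_a = a_XB mu^1}, and when \code{k_XB} is set the half-filament
#' force \code{F_hf = sum_i integral k_XB x (n_iP + n_iN) dx}.
#'
#' @param y SE-PDE state vector.
#' @param xb an \code{\link{xb_parameters}} object.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @param grid list with \code{x}, \code{dx}.
#' @return list with \code{Ta}, \code{mu0}, \code{mu1}, optionally
#'   \code{F_hf}.
#' @export
se_pde_force <- function(y, xb, geom, grid) {
  nx <- length(grid$x)
  st <- se_pde_unpack(y, geom$n_ru, nx)
  ntot <- st$nP + st$nN
  mu0 <- mean(colSums(ntot)) * grid$dx
  mu1 <- mean(colSums((grid$x / (geom$SL0 / 2)) * ntot)) * grid$dx
  out <- list(Ta = xb$a_XB * mu1, mu0 = mu0, mu1 = mu1)
  if (!is.null(xb$k_XB)) {
    out$F_hf <- xb$k_XB * sum(grid$x * ntot) * grid$dx
  }
  out
}
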