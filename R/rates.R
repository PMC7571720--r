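#' Number of permissive neighbours
#'
#' Counts the permissive states among the two tropomyosin neighbours of a
#' regulatory unit; the cooperative transition rates depend on the neighbour
#' states only through this count.
#'
#' @param alpha,delta neighbour tropomyosin states, \code{"N"} or \code{"P"}
#'   (vectorised).
#' @return integer in \{0, 1, 2\}.
#' @export
neighbor_count <- function(alpha, delta) {
  chk <- function(s) {
    if (!all(s %in% c("N", "P"))) stop("tropomyosin state must be 'N' or 'P'")
  }
  chk(alpha); chk(delta)
  as.integer(alpha == "P") + as.integer(delta == "P")
}

# effective calcium dissociation constant; linear in SL for the MF family,
# clamped below to keep the unguarded linear law positive
kd_eff <- function(ru, SL, family) {
  if (family == "MF") {
    kd <- ru$kd_bar + ru$alpha_kd * (SL - ru$SL_kd)
    kd <- max(kd, ru$kd_floor_frac * ru$kd_bar)
  } else {
    kd <- ru$kd_bar
  }
  if (kd <= 0) stop("effective calcium dissociation constant is nonpositive")
  kd
}

#' Regulatory-unit transition-rate table
#'
#' Generates the eight transition rates of the four-state RU cycle from the
#' named constants (the table is constructed, never hand-entered, so the
#' detailed-balance structure of the cycle holds for every neighbour count
#' \code{n}):
#' \itemize{
#'   \item calcium binding \code{kC_UB} (identical for permissive and
#'     non-permissive tropomyosin): \code{(koff / kd) * Ca};
#'   \item calcium unbinding \code{kC_BU_N = koff},
#'     \code{kC_BU_P = koff / mu};
#'   \item tropomyosin N to P, indexed by the neighbour permissive count
#'     \code{n = 0, 1, 2}: \code{kT_NP_U(n) = (Q/mu) kbasic gamma^n} (calcium
#'     unbound) and \code{kT_NP_B(n) = Q kbasic gamma^n} (bound);
#'   \item tropomyosin P to N, independent of the troponin state:
#'     \code{kT_PN(n) = kbasic gamma^(2 - n)}.
#' }
#' For the mean-field family the dissociation constant is evaluated at the
#' given sarcomere length, \code{kd(SL) = kd_bar + alpha_kd (SL - SL_kd)},
#' clamped below at \code{kd_floor_frac * kd_bar}; the spatially explicit
#' family uses the constant \code{kd_bar}.
#'
#' @param ru a \code{\link{ru_parameters}} object.
#' @param Ca intracellular calcium concentration (uM, >= 0).
#' @param SL sarcomere length (um); only used by the MF family.
#' @param family \code{"SE"} or \code{"MF"}.
#' @return object of class \code{"ru_rate_table"}: list with scalar rates
#'   \code{kC_UB}, \code{kC_BU_N}, \code{kC_BU_P}, length-3 vectors
#'   \code{kT_NP_U}, \code{kT_NP_B}, \code{kT_PN} (indexed by \code{n + 1}),
#'   and the effective \code{kd}.
#' @export
ru_rate_table <- function(ru, Ca, SL = ru$SL_kd, family = c("SE", "MF")) {
  family <- match.arg(family)
  if (!is.finite(Ca) || Ca < 0) stop("Ca must be nonnegative")
  kd <- kd_eff(ru, SL, family)
  n <- 0:2
  structure(list(
    kC_UB   = (ru$koff / kd) * Ca,
    kC_BU_N = ru$koff,
    kC_BU_P = ru$koff / ru$mu,
    kT_NP_U = (ru$Q / ru$mu) * ru$kbasic * ru$gamma^n,
    kT_NP_B = ru$Q * ru$kbasic * ru$gamma^n,
    kT_PN   = ru$kbasic * ru$gamma^(2 - n),
    kd = kd, Ca = Ca, SL = SL, family = family, mu = ru$mu
  ), class = "ru_rate_table")
}

#' @export
print.ru_rate_table <- function(x, ...) {
  cat(sprintf("RU rate table (%s family, Ca = %g uM, kd = %g uM)\n",
              x$family, x$Ca, x$kd))
  cat(sprintf("  kC_UB = %.4g, kC_BU_N = %.4g, kC_BU_P = %.4g  [1/s]\n",
              x$kC_UB, x$kC_BU_N, x$kC_BU_P))
  cat("  n:        0          1          2\n")
  cat(sprintf("  kT_NP_U  %-10.4g %-10.4g %-10.4g\n",
              x$kT_NP_U[1], x$kT_NP_U[2], x$kT_NP_U[3]))
  cat(sprintf("  kT_NP_B  %-10.4g %-10.4g %-10.4g\n",
              x$kT_NP_B[1], x$kT_NP_B[2], x$kT_NP_B[3]))
  cat(sprintf("  kT_PN    %-10.4g %-10.4g %-10.4g\n",
              x$kT_PN[1], x$kT_PN[2], x$kT_PN[3]))
  invisible(x)
}

#' Position-modulated permissive transition rate
#'
#' In the spatially explicit models the N-to-P tropomyosin transition of RU
#' \code{i} is suppressed outside the single-filament region (the central
#' zone of the sarcomere where the two thin filaments meet):
#' \code{kT_NP_i = chi_SF(SL, i) * kT_NP}.  The reverse (P to N) rate is not
#' modulated.
#'
#' @param table a \code{\link{ru_rate_table}}.
#' @param i RU index (vectorised).
#' @param SL sarcomere length (um).
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @return list with matrices \code{kT_NP_U}, \code{kT_NP_B} of dimension
#'   \code{length(i) x 3} (columns n = 0, 1, 2) and the unmodulated vector
#'   \code{kT_PN}.
#' @export
se_np_rate <- function(table, i, SL, geom = sarcomere_geometry()) {
  w <- chi_SF(SL, i, geom)
  list(kT_NP_U = outer(w, table$kT_NP_U),
       kT_NP_B = outer(w, table$kT_NP_B),
       kT_PN = table$kT_PN)
}

#' Total crossbridge turnover rate
#'
#' The strain-independent total attachment + detachment rate
#' \code{r(v) = r0 + alpha * |v|}, an even function of the normalised
#' shortening velocity \code{v = -(dSL/dt)/SL0} (units 1/s).
#'
#' @param xb an \code{\link{xb_parameters}} object.
#' @param v normalised shortening velocity (1/s), vectorised.
#' @return rate in 1/s.
#' @export
xb_total_rate <- function(xb, v) xb$r0 + xb$alpha * abs(v)

#' Position-modulated attachment-rate moments
#'
#' Attachment is possible only where the RU faces the thick filament and lies
#' in the single-filament region, so in the spatially explicit family the
#' attachment-rate moments of RU \code{i} are
#' \code{mu_fP^p * chi_M(SL, i) * chi_SF(SL, i)}.  In the mean-field family
#' (\code{i = NULL}) the moments are unmodulated; filament overlap enters the
#' force through the single-overlap ratio instead.  Attachment onto
#' non-permissive RUs never occurs, so the corresponding moments are zero.
#'
#' @param xb an \code{\link{xb_parameters}} object.
#' @param SL sarcomere length (um).
#' @param i RU index (vectorised) for the SE family, or \code{NULL} for MF.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @return list with components \code{mu_f0}, \code{mu_f1} (permissive
#'   attachment moments, 1/s) and \code{mu_fN0 = mu_fN1 = 0}.
#' @export
xb_attachment_moments <- function(xb, SL, i = NULL,
                                  geom = sarcomere_geometry()) {
  if (is.null(i)) {
    w <- 1
  } else {
    w <- chi_M(SL, i, geom) * chi_SF(SL, i, geom)
  }
  list(mu_f0 = xb$mu_fP0 * w, mu_f1 = xb$mu_fP1 * w,
       mu_fN0 = 0 * w, mu_fN1 = 0 * w)
}

#' Strain profile of the attachment rate
#'
#' The strain-density (PDE) models need an explicit attachment-rate profile
#' \code{f_P(x)} over the XB strain \code{x}; the moments models only fix its
#' zeroth and first moments.  This constructs a compactly supported profile
#' whose moments reproduce \code{(mu_fP0, mu_fP1)} exactly:
#' \code{integral f_P dx / DM = mu_fP0} and
#' \code{integral (x / (SL0/2)) f_P dx / DM = mu_fP1}.  The paired detachment
#' rates are \code{g_P(x, v) = r(v) - f_P(x)} (nonnegative provided
#' \code{max f_P <= r0}) and \code{g_N(x, v) = r(v)}.
#'
#' For the rectangular shape the height is \code{height_frac * r0} and the
#' width and centre solve the two moment constraints; for the triangular
#' shape an isoceles triangle of peak \code{height_frac * r0} is used.
#'
#' @param xb an \code{\link{xb_parameters}} object.
#' @param geom a \code{\link{sarcomere_geometry}} (supplies \code{DM} and
#'   \code{SL0}).
#' @param shape \code{"rectangular"} (default) or \code{"triangular"}.
#' @param height_frac peak of the profile as a fraction of \code{r0}
#'   (0 < height_frac <= 1).
#' @return object of class \code{"fP_profile"}: list of functions
#'   \code{fP(x)}, \code{gP(x, v)}, \code{gN(x, v)} plus support metadata
#'   (\code{x_center}, \code{half_width}, um).
#' @export
build_fP_profile <- function(xb, geom = sarcomere_geometry(),
                             shape = c("rectangular", "triangular"),
                             height_frac = 1) {
  shape <- match.arg(shape)
  stopifnot(height_frac > 0, height_frac <= 1)
  h <- height_frac * xb$r0
  area <- xb$mu_fP0 * geom$DM            # um / s
  xc <- (xb$mu_fP1 / xb$mu_fP0) * geom$SL0 / 2
  if (shape == "rectangular") {
    wdt <- area / h
    hw <- wdt / 2
    fP <- function(x) ifelse(abs(x - xc) <= hw, h, 0)
  } else {
    # isoceles triangle: area = h * hw, centroid at the peak
    hw <- area / h
    fP <- function(x) pmax(0, h * (1 - abs(x - xc) / hw))
  }
  if (h > xb$r0 + 1e-12) {
    stop("profile height exceeds r0; detachment rate would be negative")
  }
  structure(list(
    fP = fP,
    gP = function(x, v) xb_total_rate(xb, v) - fP(x),
    gN = function(x, v) rep_len(xb_total_rate(xb, v), length(x)),
    x_center = xc, half_width = hw, height = h, shape = shape,
    mu_fP0 = xb$mu_fP0, mu_fP1 = xb$mu_fP1
  ), class = "fP_profile")
}

#' Cell-averaged attachment profile on a grid
#'
#' Evaluates the attachment-rate profile as averages over the finite-volume
#' cells \code{[x_k - dx/2, x_k + dx/2]}, so that the discrete zeroth moment
#' \code{sum(fP) dx} equals the continuous one exactly (pointwise sampling
#' of the discontinuous profile would alias its support against the grid).
#' Rectangular profiles are averaged analytically; other shapes by Simpson
#' subsampling.
#'
#' @param profile an object from \code{\link{build_fP_profile}}.
#' @param x cell centres (um).
#' @param dx cell width (um).
#' @return vector of cell-averaged rates (1/s).
#' @export
fP_profile_grid <- function(profile, x, dx) {
  if (profile$shape == "rectangular") {
    a <- profile$x_center - profile$half_width
    b <- profile$x_center + profile$half_width
    frac <- (pmin(x + dx / 2, b) - pmax(x - dx / 2, a)) / dx
    profile$height * pmax(frac, 0)
  } else {
    xs <- seq(-0.5, 0.5, length.out = 9) * dx
    w <- c(1, 4, 2, 4, 2, 4, 2, 4, 1) / 24
    vals <- vapply(seq_along(xs),
                   function(j) profile$fP(x + xs[j]), numeric(length(x)))
    as.vector(vals %*% w)
  }
}
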