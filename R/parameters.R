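#' Regulatory-unit kinetic parameters
#'
#' The six constants governing the four-state tropomyosin/troponin (RU)
#' Markov model, plus the phenomenological length dependence of the calcium
#' sensitivity used by the mean-field family.
#'
#' The forward/backward rate pairs of the RU cycle are generated from these
#' constants (see \code{\link{ru_rate_table}}): \code{Q} biases the
#' permissive-direction tropomyosin transitions, \code{mu} differentiates
#' calcium unbinding (and tropomyosin kinetics) between permissive and
#' non-permissive tropomyosin, and \code{gamma} sets the strength of the
#' nearest-neighbour end-to-end cooperativity (its thermodynamic reading is
#' \code{gamma = exp(2 dE / kB T)} with \code{dE} the energetic gain of
#' equal-state neighbours).  \code{kd_bar} is the calcium dissociation
#' constant at the reference length \code{SL_kd}; in the mean-field family it
#' varies linearly with sarcomere length with slope \code{alpha_kd}
#' (negative for the shipped presets: longer sarcomeres are more calcium
#' sensitive), while the spatially explicit family keeps it constant
#' (\code{alpha_kd = 0}; the length dependence there is emergent).
#'
#' @param Q dimensionless tropomyosin bias (> 0).
#' @param mu dimensionless permissive/non-permissive asymmetry (> 0).
#' @param gamma dimensionless cooperativity (>= 1).
#' @param kd_bar calcium dissociation constant at \code{SL_kd} (uM).
#' @param alpha_kd slope of the dissociation constant in SL (uM/um; <= 0 for
#'   the shipped mean-field presets, 0 for the spatially explicit ones).
#' @param SL_kd reference sarcomere length for \code{kd_bar} (um).
#' @param koff calcium unbinding rate from non-permissive RUs (1/s).
#' @param kbasic basic tropomyosin transition rate (1/s).
#' @param kd_floor_frac lower clamp on the length-modulated dissociation
#'   constant, as a fraction of \code{kd_bar} (the linear law is unguarded).
#' @return object of class \code{"ru_parameters"}.
#' @export
ru_parameters <- function(Q, mu, gamma, kd_bar, alpha_kd = 0, SL_kd = 2.15,
                          koff, kbasic, kd_floor_frac = 0.05) {
  stopifnot(Q > 0, mu > 0, gamma >= 1, kd_bar > 0, koff > 0, kbasic > 0,
            SL_kd > 0, kd_floor_frac > 0, kd_floor_frac < 1)
  structure(list(Q = Q, mu = mu, gamma = gamma, kd_bar = kd_bar,
                 alpha_kd = alpha_kd, SL_kd = SL_kd, koff = koff,
                 kbasic = kbasic, kd_floor_frac = kd_floor_frac),
            class = "ru_parameters")
}

#' Crossbridge cycling parameters
#'
#' Scalar constants of the two-state crossbridge (XB) attachment-detachment
#' model in its distribution-moments form.  \code{mu_fP0} and \code{mu_fP1}
#' are the zeroth and first moments of the attachment-rate profile over XB
#' strain (strain normalised by \code{SL0/2}); \code{r0 + alpha * |v|} is the
#' strain-independent total attachment + detachment rate at normalised
#' shortening velocity \code{v}; \code{a_XB} maps the first strain moment to
#' macroscopic active tension.  \code{k_XB} (optional) is the single-XB
#' spring stiffness used only for the dimensional half-filament force.
#'
#' @param mu_fP0 zeroth attachment-rate moment (1/s, > 0).
#' @param mu_fP1 first attachment-rate moment (1/s).
#' @param r0 total attachment-detachment rate at v = 0 (1/s, > 0).
#' @param alpha velocity sensitivity of the detachment rate (dimensionless,
#'   for v expressed in 1/s).
#' @param a_XB tension per unit first moment (MPa, > 0).
#' @param k_XB optional XB spring stiffness for dimensional forces; unset by
#'   default.
#' @return object of class \code{"xb_parameters"}.
#' @export
xb_parameters <- function(mu_fP0, mu_fP1, r0, alpha, a_XB, k_XB = NULL) {
  stopifnot(mu_fP0 > 0, r0 > 0, alpha >= 0, a_XB > 0)
  structure(list(mu_fP0 = mu_fP0, mu_fP1 = mu_fP1, r0 = r0, alpha = alpha,
                 a_XB = a_XB, k_XB = k_XB),
            class = "xb_parameters")
}

.sarco_presets <- list(
  rat_room = list(
    SE = list(ru = list(Q = 3, mu = 10, gamma = 20, kd_bar = 1.622,
                        alpha_kd = 0, koff = 120, kbasic = 28),
              xb = list(mu_fP0 = 57.416, mu_fP1 = 1.368, r0 = 134.31,
                        alpha = 25.184, a_XB = 22.894)),
    MF = list(ru = list(Q = 2, mu = 10, gamma = 12, kd_bar = 0.835,
                        alpha_kd = -1.258, koff = 120, kbasic = 24),
              xb = list(mu_fP0 = 32.708, mu_fP1 = 0.779, r0 = 134.31,
                        alpha = 25.184, a_XB = 22.894))
  ),
  human_body = list(
    SE = list(ru = list(Q = 3, mu = 10, gamma = 20, kd_bar = 0.74,
                        alpha_kd = 0, koff = 100, kbasic = 13),
              xb = list(mu_fP0 = 57.157, mu_fP1 = 1.362, r0 = 134.31,
                        alpha = 25.184, a_XB = 22.894)),
    MF = list(ru = list(Q = 2, mu = 10, gamma = 12, kd_bar = 0.381,
                        alpha_kd = -0.571, koff = 100, kbasic = 13),
              xb = list(mu_fP0 = 32.653, mu_fP1 = 0.778, r0 = 134.31,
                        alpha = 25.184, a_XB = 22.894))
  )
)

#' Calibrated parameter presets
#'
#' Returns the calibrated RU and XB parameter sets for room-temperature rat
#' (\code{"rat_room"}) or body-temperature human (\code{"human_body"})
#' cardiomyocytes, for either model family.  The spatially explicit family
#' (\code{"SE"}) has \code{alpha_kd = 0} (length-dependent activation is
#' emergent); the mean-field family (\code{"MF"}) carries the phenomenological
#' length-dependent calcium sensitivity.
#'
#' @param name \code{"rat_room"} or \code{"human_body"}.
#' @param family \code{"SE"} or \code{"MF"}.
#' @return list with components \code{ru} (\code{\link{ru_parameters}}) and
#'   \code{xb} (\code{\link{xb_parameters}}).
#' @examples
#' sarcomere_preset("rat_room", "MF")$ru$kd_bar  # 0.835 uM
#' @export
sarcomere_preset <- function(name = c("rat_room", "human_body"),
                             family = c("SE", "MF")) {
  name <- match.arg(name)
  family <- match.arg(family)
  p <- .sarco_presets[[name]][[family]]
  list(ru = do.call(ru_parameters, p$ru),
       xb = do.call(xb_parameters, p$xb))
}

#' @export
print.ru_parameters <- function(x, ...) {
  cat("Regulatory-unit parameters\n")
  cat(sprintf("  Q = %g, mu = %g, gamma = %g\n", x$Q, x$mu, x$gamma))
  cat(sprintf("  kd_bar = %g uM (alpha_kd = %g uM/um at SL_kd = %g um)\n",
              x$kd_bar, x$alpha_kd, x$SL_kd))
  cat(sprintf("  koff = %g 1/s, kbasic = %g 1/s\n", x$koff, x$kbasic))
  invisible(x)
}

#' @export
print.xb_parameters <- function(x, ...) {
  cat("Crossbridge parameters\n")
  cat(sprintf("  mu_fP0 = %g 1/s, mu_fP1 = %g 1/s\n", x$mu_fP0, x$mu_fP1))
  cat(sprintf("  r0 = %g 1/s, alpha = %g, a_XB = %g MPa\n",
              x$r0, x$alpha, x$a_XB))
  if (!is.null(x$k_XB)) cat(sprintf("  k_XB = %g\n", x$k_XB))
  invisible(x)
}
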