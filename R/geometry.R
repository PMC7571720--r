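#' Sarcomere filament geometry
#'
#' Bundles the geometric constants of the half-sarcomere: filament lengths,
#' regulatory-unit (RU) and myosin-head (MH) counts, and the smoothing width
#' used by the overlap weight functions.  Defaults are the standard values for
#' cardiac sarcomeres (lengths in micrometres).
#'
#' @param SL0 reference sarcomere length (um).
#' @param LA actin (thin) filament length (um).
#' @param LM myosin (thick) filament length (um).
#' @param LH bare-zone length at the centre of the thick filament (um);
#'   must be smaller than \code{LM}.
#' @param eps smoothing width of the tanh overlap transitions (um).
#' @param n_ru number of regulatory units per actin filament (>= 3).
#' @param n_mh number of myosin heads per half thick filament (>= 1).
#' @param DM inter-head spacing along the crown-bearing half filament (um).
#'   Defaults to \code{(LM - LH) / (2 * n_mh)}, i.e. heads evenly spaced along
#'   one half of the head-bearing region.  Only the strain-density (PDE)
#'   models use \code{DM} explicitly; the moments models absorb it into the
#'   attachment-rate moments.
#'
#' @return An object of class \code{"sarcomere_geometry"}.
#' @examples
#' geom <- sarcomere_geometry()
#' chi_so(2.2, geom)
#' @export
sarcomere_geometry <- function(SL0 = 2.2, LA = 1.25, LM = 1.65, LH = 0.18,
                               eps = 0.05, n_ru = 32L, n_mh = 18L,
                               DM = NULL) {
  stopifnot(SL0 > 0, LA > 0, LM > 0, LH > 0, eps > 0)
  if (LH >= LM) stop("bare-zone length LH must be smaller than LM")
  n_ru <- as.integer(n_ru); n_mh <- as.integer(n_mh)
  if (n_ru < 3L) stop("n_ru must be at least 3")
  if (n_mh < 1L) stop("n_mh must be at least 1")
  if (is.null(DM)) DM <- (LM - LH) / (2 * n_mh)
  stopifnot(DM > 0)
  structure(list(SL0 = SL0, LA = LA, LM = LM, LH = LH, eps = eps,
                 n_ru = n_ru, n_mh = n_mh, DM = DM),
            class = "sarcomere_geometry")
}

#' @export
print.sarcomere_geometry <- function(x, ...) {
  cat("Sarcomere geometry\n")
  cat(sprintf("  SL0 = %.3g um, LA = %.3g um, LM = %.3g um, LH = %.3g um\n",
              x$SL0, x$LA, x$LM, x$LH))
  cat(sprintf("  %d RUs per thin filament, %d heads per half thick filament\n",
              x$n_ru, x$n_mh))
  cat(sprintf("  head spacing DM = %.4g um, smoothing eps = %.3g um\n",
              x$DM, x$eps))
  invisible(x)
}

#' Single-overlap ratio
#'
#' Fraction of the thin filament lying in the single-overlap zone (the region
#' where the thick filament overlaps exactly one thin filament) as a function
#' of sarcomere length.  Piecewise linear and continuous: zero for
#' \code{SL <= LA} and for \code{SL > 2 LA + LM}, and exactly one on the
#' plateau \code{(2 LA - LH, 2 LA + LH]}.
#'
#' @param SL sarcomere length (um), vectorised.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @return numeric vector in [0, 1].
#' @export
chi_so <- function(SL, geom = sarcomere_geometry()) {
  if (any(!is.finite(SL)) || any(SL <= 0)) {
    stop("SL must be positive and finite")
  }
  LA <- geom$LA; LM <- geom$LM; LH <- geom$LH
  out <- numeric(length(SL))
  b2 <- SL > LA & SL <= LM
  b3 <- SL > LM & SL <= 2 * LA - LH
  b4 <- SL > 2 * LA - LH & SL <= 2 * LA + LH
  b5 <- SL > 2 * LA + LH & SL <= 2 * LA + LM
  out[b2] <- 2 * (SL[b2] - LA) / (LM - LH)
  out[b3] <- (SL[b3] + LM - 2 * LA) / (LM - LH)
  out[b4] <- 1
  out[b5] <- (LM + 2 * LA - SL[b5]) / (LM - LH)
  out
}

# RU coordinates measured from the thin-filament end nearest the sarcomere
# centre; i = 1 is the innermost RU.
ru_coord <- function(i, geom) (geom$LA / geom$n_ru) * (i - 0.5)

check_ru_index <- function(i, geom) {
  if (any(i < 1L) || any(i > geom$n_ru) || any(i != round(i))) {
    stop("RU index out of range 1..", geom$n_ru)
  }
}

#' Thick-filament facing weight
#'
#' Smooth indicator (tanh transitions of width \code{eps}) that RU \code{i}
#' faces the half thick filament at sarcomere length \code{SL}: approximately
#' one between the projected left and right ends of the thick filament and
#' approximately zero outside, always strictly inside (0, 1).
#'
#' @param SL sarcomere length (um), scalar.
#' @param i RU index (1-based, vectorised), 1 = nearest the sarcomere centre.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @return numeric vector in (0, 1).
#' @export
chi_M <- function(SL, i, geom = sarcomere_geometry()) {
  check_ru_index(i, geom)
  yi <- ru_coord(i, geom)
  yLM <- (2 * geom$LA - SL + geom$LH) / 2
  yRM <- (2 * geom$LA - SL + geom$LM) / 2
  0.5 * tanh((yi - yLM) / geom$eps) + 0.5 * tanh(-(yi - yRM) / geom$eps)
}

#' Single-filament weight
#'
#' Smooth indicator that RU \code{i} lies in the single-filament region (no
#' overlap with the thin filament from the opposite half-sarcomere):
#' \code{0.5 * (1 + tanh((y_i - y_SF)/eps))} with \code{y_SF = 2 LA - SL}.
#' Permissive-direction tropomyosin transitions and crossbridge attachment are
#' suppressed where this weight vanishes.
#'
#' @inheritParams chi_M
#' @return numeric vector in (0, 1).
#' @export
chi_SF <- function(SL, i, geom = sarcomere_geometry()) {
  check_ru_index(i, geom)
  yi <- ru_coord(i, geom)
  ySF <- 2 * geom$LA - SL
  0.5 * (1 + tanh((yi - ySF) / geom$eps))
}
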