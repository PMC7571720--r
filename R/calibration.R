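# Three-stage sequential calibration pipeline.
#
# The experimental setups decouple: force-velocity and fast-step features
# probe crossbridge cycling with the thin filament in steady state (stage 1);
# steady force-calcium curves depend only on the ratios of opposite
# regulatory-unit rates (stage 2: Q, mu, gamma, kd, alpha_kd); twitch
# kinetics finally pin the absolute rates kbasic and koff (stage 3).

# normalised force-velocity closed form.  Summing the permissive and
# non-permissive moment equations cancels the coupling fluxes, giving
#   mu0 = P s0 / r(v),  mu1 = (P s1 - v mu0) / r(v)
# so the curve is T(v)/T(0) = (1 - v rho / r(v)) r0 / r(v), with
# rho = mu_fP0 / mu_fP1.  It is invariant under a common rescaling of
# (r0, alpha, rho): the normalised curve fixes only two of the three.
fv_Tnorm <- function(v, r0, alpha, rho) {
  r <- r0 + alpha * abs(v)
  (1 - v * rho / r) * r0 / r
}

#' Stage 1: calibrate the crossbridge parameters
#'
#' Fits the crossbridge constants from steady tension, the shape of the
#' force-velocity relationship, and the slope of the instantaneous
#' tension-elongation curve, using the frozen-activation closed forms:
#' \itemize{
#'   \item the stiffness ratio (tension-elongation slope divided by the
#'     isometric tension, 1/um) fixes
#'     \code{rho = mu_fP0 / mu_fP1 = (SL0/2) * stiffness_ratio};
#'   \item \code{(r0, alpha)} are then least-squares fitted to the
#'     normalised force-velocity curve
#'     \code{T(v)/T(0) = (1 - v rho / r(v)) r0 / r(v)} (which is invariant
#'     under a common rescaling of \code{(r0, alpha, rho)}, so it cannot fix
#'     all three on its own);
#'   \item the attached-fraction (duty-ratio) target \code{mu0_iso} sets
#'     \code{mu_fP0}, and the isometric tension sets \code{a_XB}.
#' }
#' Without \code{mu0_iso} the split of \code{(mu_fP0, mu_fP1)} against
#' \code{a_XB} is underdetermined: the function warns and keeps
#' \code{mu_fP1} at \code{mu_fP1_prior}.
#'
#' @param targets list with components \code{fv} (data.frame \code{v},
#'   \code{T_norm}), \code{Ta_iso} (MPa), \code{SL_ref} (um),
#'   \code{stiffness_ratio} (1/um), optionally \code{mu0_iso}
#'   (overlap-weighted attached fraction at the reference state) and
#'   \code{mu_fP1_prior}.
#' @param fixed_ru frozen regulatory steady state at the reference
#'   activation: list with \code{P}, \code{kt_NP}, \code{kt_PN} (output of
#'   \code{\link{steady_tension}}); enters the absolute-scale step.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @param start starting values \code{c(r0, alpha)}.
#' @return an \code{\link{xb_parameters}} object; the force-velocity fit is
#'   attached as attribute \code{"fit"}.
#' @export
calibrate_xb <- function(targets, fixed_ru, geom = sarcomere_geometry(),
                         start = c(r0 = 100, alpha = 10)) {
  stopifnot(is.data.frame(targets$fv), !is.null(targets$Ta_iso),
            !is.null(targets$SL_ref))
  if (is.null(targets$stiffness_ratio)) {
    stop("a stiffness_ratio target (tension-elongation slope / isometric ",
         "tension) is required: the normalised force-velocity curve alone ",
         "leaves the scale of (r0, alpha, mu_fP0/mu_fP1) free")
  }
  rho <- (geom$SL0 / 2) * targets$stiffness_ratio
  dat <- targets$fv
  fit <- minpack.lm::nlsLM(
    T_norm ~ fv_Tnorm(v, exp(lr0), exp(la), rho),
    data = dat,
    start = list(lr0 = log(start[["r0"]]), la = log(start[["alpha"]])),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- exp(stats::coef(fit))
  r0 <- unname(cf["lr0"]); alpha <- unname(cf["la"])
  if (rho <= alpha) {
    stop("infeasible targets: mu_fP0/mu_fP1 <= alpha implies no finite ",
         "maximum shortening velocity")
  }
  P <- fixed_ru$P; ktNP <- fixed_ru$kt_NP; ktPN <- fixed_ru$kt_PN
  xs <- chi_so(targets$SL_ref, geom)
  c0 <- {
    ms <- xb_moment_steady(P, ktNP, ktPN, r0, 1, 1)
    ms$muP0 + ms$muN0
  }
  if (!is.null(targets$mu0_iso)) {
    mu_fP0 <- targets$mu0_iso / (xs * c0)
    mu_fP1 <- mu_fP0 / rho
  } else {
    warning("no attached-fraction target: the scale of (mu_fP0, mu_fP1) vs ",
            "a_XB is underdetermined; keeping mu_fP1 at its prior")
    mu_fP1 <- if (!is.null(targets$mu_fP1_prior)) targets$mu_fP1_prior else 1
    mu_fP0 <- rho * mu_fP1
  }
  a_XB <- targets$Ta_iso / (xs * c0 * mu_fP1)
  out <- xb_parameters(mu_fP0 = mu_fP0, mu_fP1 = mu_fP1, r0 = r0,
                       alpha = alpha, a_XB = a_XB)
  attr(out, "fit") <- fit
  out
}

# Hill features of the model force-calcium curve at one SL
model_hill_features <- function(ru, xb, SL, family, geom, Ca_grid) {
  mdl <- sarcomere_model(if (family == "MF") "MF-ODE" else "SE-ODE",
                         ru = ru, xb = xb, geom = geom)
  fc <- force_calcium_curve(mdl, Ca_grid, SL)
  c(log(fc$hill$EC50), log(fc$hill$nH), log(fc$hill$Ta_max))
}

#' Stage 2: calibrate the regulatory-unit steady-state parameters
#'
#' Bound-constrained least squares of \code{(Q, mu, gamma, kd_bar,
#' alpha_kd)} against steady force-calcium targets at two or more sarcomere
#' lengths.  Targets are either raw curve samples (columns \code{SL},
#' \code{Ca}, \code{Ta}; the recommended form -- the asymmetry of the curve
#' around half activation is what carries information on \code{Q} and
#' \code{mu}) or Hill triples (columns \code{SL}, \code{Ta_max},
#' \code{EC50}, \code{nH}; the curve is then summarised before comparison,
#' which discards the asymmetry, leaving \code{kd_bar} identified only
#' jointly with \code{(Q, mu)} since \code{EC50 = kd_bar h(Q, mu, gamma)}).
#' For the spatially explicit family \code{alpha_kd} is fixed at zero (the
#' length dependence is emergent).  The plateau scale requires the stage-1
#' crossbridge parameters, passed fixed.
#'
#' @param targets data.frame in one of the two forms above (>= 2 distinct
#'   SLs).
#' @param xb fixed stage-1 \code{\link{xb_parameters}}.
#' @param family \code{"MF"} or \code{"SE"}.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @param init starting \code{\link{ru_parameters}}.
#' @param n_Ca points of the internal calcium grid per SL (Hill-triple
#'   targets only).
#' @param maxit optimizer iteration cap.
#' @param profile if \code{TRUE}, 1-D misfit slices over \code{Q} and
#'   \code{mu} around the optimum are attached as attribute
#'   \code{"profiles"} (the pair is weakly identified).
#' @return an \code{\link{ru_parameters}} object with attributes
#'   \code{"misfit"}, \code{"convergence"} and optionally \code{"profiles"}.
#' @export
calibrate_ru_steady <- function(targets, xb, family = c("MF", "SE"),
                                geom = sarcomere_geometry(),
                                init = NULL, n_Ca = 12, maxit = 150,
                                profile = TRUE) {
  family <- match.arg(family)
  stopifnot(is.data.frame(targets))
  samples <- all(c("SL", "Ca", "Ta") %in% names(targets))
  if (!samples &&
      !all(c("SL", "Ta_max", "EC50", "nH") %in% names(targets))) {
    stop("targets must have columns (SL, Ca, Ta) or (SL, Ta_max, EC50, nH)")
  }
  SLs <- sort(unique(targets$SL))
  stopifnot(length(SLs) >= 2)
  ec50_guess <- if (samples) {
    stats::median(targets$Ca)
  } else mean(targets$EC50)
  if (is.null(init)) {
    init <- if (family == "MF") {
      ru_parameters(Q = 2, mu = 10, gamma = 12, kd_bar = ec50_guess,
                    alpha_kd = -1, koff = 120, kbasic = 24)
    } else {
      ru_parameters(Q = 3, mu = 10, gamma = 20, kd_bar = ec50_guess,
                    alpha_kd = 0, koff = 120, kbasic = 28)
    }
  }
  make_ru <- function(th) {
    ru_parameters(Q = exp(th[1]), mu = exp(th[2]), gamma = exp(th[3]),
                  kd_bar = exp(th[4]),
                  alpha_kd = if (family == "MF") th[5] else 0,
                  koff = init$koff, kbasic = init$kbasic)
  }
  objective <- if (samples) {
    scl <- stats::ave(targets$Ta, targets$SL, FUN = max)
    function(th) {
      ru <- make_ru(th)
      mdl <- tryCatch(
        sarcomere_model(if (family == "MF") "MF-ODE" else "SE-ODE",
                        ru = ru, xb = xb, geom = geom),
        error = function(e) NULL)
      if (is.null(mdl)) return(1e6)
      Ta_hat <- tryCatch(
        vapply(seq_len(nrow(targets)), function(j) {
          steady_tension(mdl, targets$Ca[j], targets$SL[j])$Ta
        }, numeric(1)),
        error = function(e) NULL)
      if (is.null(Ta_hat)) return(1e6)
      sum(((Ta_hat - targets$Ta) / scl)^2)
    }
  } else {
    grids <- lapply(seq_len(nrow(targets)), function(k) {
      exp(seq(log(targets$EC50[k] / 6), log(targets$EC50[k] * 6),
              length.out = n_Ca))
    })
    tgt <- cbind(log(targets$EC50), log(targets$nH), log(targets$Ta_max))
    function(th) {
      ru <- make_ru(th)
      err <- 0
      for (k in seq_len(nrow(targets))) {
        f <- tryCatch(model_hill_features(ru, xb, targets$SL[k], family,
                                          geom, grids[[k]]),
                      error = function(e) rep(10, 3))
        err <- err + sum((f - tgt[k, ])^2)
      }
      err
    }
  }
  th0 <- c(log(init$Q), log(init$mu), log(init$gamma), log(init$kd_bar),
           if (family == "MF") init$alpha_kd)
  lower <- c(log(0.1), log(1.01), log(1), log(0.01),
             if (family == "MF") -10)
  upper <- c(log(50), log(200), log(200), log(50),
             if (family == "MF") 0)
  if (family == "SE") { th0 <- th0[1:4] }
  opt <- stats::optim(th0, objective, method = "L-BFGS-B",
                      lower = lower[seq_along(th0)],
                      upper = upper[seq_along(th0)],
                      control = list(maxit = maxit, factr = 1e7))
  ru_hat <- make_ru(if (family == "MF") opt$par else c(opt$par, 0))
  attr(ru_hat, "misfit") <- opt$value
  attr(ru_hat, "convergence") <- opt$convergence
  if (profile) {
    slice <- function(j) {
      g <- opt$par[j] + log(seq(0.5, 2, length.out = 7))
      vals <- vapply(g, function(x) {
        th <- opt$par; th[j] <- x; objective(th)
      }, numeric(1))
      data.frame(value = exp(g), misfit = vals)
    }
    attr(ru_hat, "profiles") <- list(Q = slice(1), mu = slice(2))
  }
  ru_hat
}

#' Stage 3: calibrate the regulatory-unit kinetic parameters
#'
#' Seeded Monte-Carlo sampling of \code{(kbasic, koff)} within prescribed
#' ranges (log-uniform); for each sample an isometric twitch is simulated
#' and scored by the L2 misfit of the normalised tension trace against the
#' target.  The two rates are poorly identified jointly (a ridge of
#' near-optimal pairs), so the full sample table is part of the result, not
#' just the best pair.
#'
#' @param targets list with \code{time}, \code{Ta} (target twitch trace),
#'   \code{transient} (calcium input) and \code{SL}.
#' @param ru,xb parameters with all constants except \code{kbasic},
#'   \code{koff} fixed (stage-1/2 output).
#' @param ranges list with \code{kbasic = c(lo, hi)},
#'   \code{koff = c(lo, hi)} (1/s).
#' @param n_samples number of Monte-Carlo samples (>= 1).
#' @param seed RNG seed (required).
#' @param family model family used for the simulations.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @param dt output step for the simulated twitches (s).
#' @return list with \code{best} (named vector kbasic, koff),
#'   \code{best_misfit}, and \code{samples} (data.frame kbasic, koff,
#'   misfit).
#' @export
calibrate_ru_kinetics <- function(targets, ru, xb, ranges, n_samples, seed,
                                  family = "MF",
                                  geom = sarcomere_geometry(), dt = 2e-3) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  stopifnot(n_samples >= 1)
  for (nm in c("kbasic", "koff")) {
    rg <- ranges[[nm]]
    if (is.null(rg) || length(rg) != 2 || rg[1] <= 0 || rg[2] < rg[1]) {
      stop("invalid range for ", nm)
    }
  }
  set.seed(seed)
  kb <- exp(stats::runif(n_samples, log(ranges$kbasic[1]),
                         log(ranges$kbasic[2])))
  ko <- exp(stats::runif(n_samples, log(ranges$koff[1]),
                         log(ranges$koff[2])))
  t_tgt <- targets$time
  y_tgt <- targets$Ta / max(targets$Ta)
  t_end <- max(t_tgt)
  misfit <- vapply(seq_len(n_samples), function(s) {
    ru_s <- ru_parameters(Q = ru$Q, mu = ru$mu, gamma = ru$gamma,
                          kd_bar = ru$kd_bar, alpha_kd = ru$alpha_kd,
                          SL_kd = ru$SL_kd, koff = ko[s], kbasic = kb[s])
    mdl <- sarcomere_model(if (family == "MF") "MF-ODE" else "SE-ODE",
                           ru = ru_s, xb = xb, geom = geom)
    tw <- tryCatch(
      isometric_twitch(mdl, targets$transient, targets$SL,
                       t_end = t_end, dt = dt),
      error = function(e) NULL)
    if (is.null(tw)) return(Inf)
    y <- stats::approx(tw$trace$time, tw$trace$Ta / max(tw$trace$Ta),
                       xout = t_tgt, rule = 2)$y
    mean((y - y_tgt)^2)
  }, numeric(1))
  k <- which.min(misfit)
  list(best = c(kbasic = kb[k], koff = ko[k]), best_misfit = misfit[k],
       samples = data.frame(kbasic = kb, koff = ko, misfit = misfit),
       seed = seed)
}
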