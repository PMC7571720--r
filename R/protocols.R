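# Virtual-experiment protocols, runnable on any of the four models.

# assemble the full steady model state at constant (Ca, SL, v = 0) from the
# equilibrated RU block plus the closed-form crossbridge steady state
assemble_steady_state <- function(model, Ca, SL) {
  ru <- model$ru; xb <- model$xb; geom <- model$geom
  r <- xb_total_rate(xb, 0)
  if (model$family == "MF") {
    pi <- mf_ru_steady(ru, Ca, SL, eps_den = model$solver$eps_den)
    table <- ru_rate_table(ru, Ca, SL, "MF")
    kt <- mf_xb_coupling_rates(pi, table, model$solver$eps_den)
    P <- mf_permissivity(pi)
    ktNP <- kt[["kt_NP"]]; ktPN <- kt[["kt_PN"]]
    if (model$form == "ODE") {
      ms <- xb_moment_steady(P, ktNP, ktPN, r, xb$mu_fP0, xb$mu_fP1)
      return(c(pi, ms$muP0, ms$muN0, ms$muP1, ms$muN1))
    }
    fPx <- model$fPx
    det <- (r + ktPN) * (r + ktNP) - ktNP * ktPN
    bP <- (P / geom$DM) * fPx
    nP <- (r + ktNP) * bP / det
    nN <- ktPN * bP / det
    return(c(pi, nP, nN))
  }
  pi <- se_ru_steady(ru, Ca, SL, geom, eps_den = model$solver$eps_den)
  table <- ru_rate_table(ru, Ca, SL, "SE")
  idx <- seq_len(geom$n_ru)
  chiSF <- chi_SF(SL, idx, geom)
  kt <- se_xb_coupling_core(pi, chiSF, se_weights(table),
                            model$solver$eps_den)
  wM <- chi_M(SL, idx, geom) * chiSF
  if (model$form == "ODE") {
    ms <- xb_moment_steady(kt$P, kt$kt_NP, kt$kt_PN, r,
                           xb$mu_fP0 * wM, xb$mu_fP1 * wM)
    return(c(as.vector(pi), ms$muP0, ms$muN0, ms$muP1, ms$muN1))
  }
  fPi <- outer(model$fPx, wM)
  ktNP <- rep(kt$kt_NP, each = length(model$grid$x))
  ktPN <- rep(kt$kt_PN, each = length(model$grid$x))
  Pm <- rep(kt$P, each = length(model$grid$x))
  det <- (r + ktPN) * (r + ktNP) - ktNP * ktPN
  bP <- (Pm / geom$DM) * as.vector(fPi)
  nP <- (r + ktNP) * bP / det
  nN <- ktPN * bP / det
  c(as.vector(pi), nP, nN)
}

#' Run a model to its isometric steady state
#'
#' Holds calcium, sarcomere length and velocity fixed and equilibrates the
#' model.  The default method equilibrates the regulatory-unit block and
#' assembles the crossbridge steady state in closed form, then verifies the
#' full residual; \code{method = "integrate"} integrates the full system in
#' chunks until the state-derivative norm falls below \code{tol_ss} or
#' \code{t_max} is reached (the result is then flagged, not an error).
#'
#' @param model a \code{\link{sarcomere_model}}.
#' @param Ca calcium (uM).
#' @param SL sarcomere length (um).
#' @param method \code{"fast"} or \code{"integrate"}.
#' @param t_chunk,t_max chunk length and horizon for the integration path (s).
#' @param tol_ss steady-state tolerance on \code{max |dy/dt|} (1/s).
#' @return list with \code{state}, \code{Ta_iso} (MPa), \code{converged},
#'   \code{residual}, \code{t_used}.
#' @export
run_to_steady_state <- function(model, Ca, SL, method = c("fast",
                                                          "integrate"),
                                t_chunk = 2, t_max = 20, tol_ss = 1e-4) {
  method <- match.arg(method)
  if (method == "fast") {
    y <- assemble_steady_state(model, Ca, SL)
    res <- max(abs(model_rhs(model, y, Ca, SL, 0)))
    return(list(state = y, Ta_iso = model_tension(model, y, SL),
                converged = res < max(tol_ss, 1e-3), residual = res,
                t_used = NA_real_))
  }
  y <- initial_state(model)
  t_used <- 0
  converged <- FALSE
  res <- Inf
  while (t_used < t_max) {
    out <- sarco_integrate(model, y, c(0, t_chunk), Ca, SL, 0)
    y <- out[nrow(out), -1]
    t_used <- t_used + t_chunk
    res <- max(abs(model_rhs(model, y, Ca, SL, 0)))
    if (res < tol_ss) { converged <- TRUE; break }
  }
  list(state = y, Ta_iso = model_tension(model, y, SL),
       converged = converged, residual = res, t_used = t_used)
}

#' Hill fit of a force-calcium curve
#'
#' Least-squares fit of \code{Ta = Ta_max / (1 + (EC50 / Ca)^nH)}.
#'
#' @param Ca calcium levels (uM).
#' @param Ta tensions (MPa).
#' @return object of class \code{"hill_fit"}: list with \code{Ta_max},
#'   \code{EC50}, \code{nH} and the fitted values.
#' @export
hill_fit <- function(Ca, Ta) {
  stopifnot(length(Ca) == length(Ta), length(Ca) >= 4)
  ok <- Ca > 0
  Ca <- Ca[ok]; Ta <- Ta[ok]
  Tmax0 <- max(Ta)
  half <- Tmax0 / 2
  EC0 <- tryCatch(stats::approx(Ta, Ca, xout = half, ties = "ordered")$y,
                  error = function(e) NA_real_)
  if (!is.finite(EC0)) EC0 <- stats::median(Ca)
  fit <- minpack.lm::nlsLM(
    Ta ~ Tmax / (1 + (EC50 / Ca)^nH),
    start = list(Tmax = Tmax0 * 1.02, EC50 = EC0, nH = 2),
    lower = c(Tmax0 * 0.2, min(Ca) / 10, 0.2),
    upper = c(Tmax0 * 10, max(Ca) * 10, 30),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(Ta_max = unname(cf["Tmax"]), EC50 = unname(cf["EC50"]),
                 nH = unname(cf["nH"]), fitted = stats::fitted(fit),
                 Ca = Ca, Ta = Ta),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: Ta_max = %.4g MPa, EC50 = %.4g uM, nH = %.3g\n",
              x$Ta_max, x$EC50, x$nH))
  invisible(x)
}

#' Steady-state force-calcium curve with Hill fit
#'
#' @param model a \code{\link{sarcomere_model}}.
#' @param Ca_grid calcium levels (uM).
#' @param SL sarcomere length (um).
#' @param method steady-state method, see \code{\link{run_to_steady_state}}.
#' @return list with \code{curve} (data.frame Ca, Ta) and \code{hill}
#'   (\code{\link{hill_fit}}).
#' @export
force_calcium_curve <- function(model, Ca_grid, SL, method = "fast") {
  Ta <- vapply(Ca_grid, function(Ca) {
    if (method == "fast") steady_tension(model, Ca, SL)$Ta
    else run_to_steady_state(model, Ca, SL, method = "integrate")$Ta_iso
  }, numeric(1))
  list(curve = data.frame(Ca = Ca_grid, Ta = Ta),
       hill = hill_fit(Ca_grid, Ta))
}

#' Steady-state force-length curve
#'
#' @param model a \code{\link{sarcomere_model}}.
#' @param SL_grid sarcomere lengths (um).
#' @param Ca calcium (uM).
#' @return data.frame with \code{SL}, \code{Ta}.
#' @export
force_length_curve <- function(model, SL_grid, Ca) {
  Ta <- vapply(SL_grid, function(SL) steady_tension(model, Ca, SL)$Ta,
               numeric(1))
  data.frame(SL = SL_grid, Ta = Ta)
}

#' Synthetic intracellular calcium transient
#'
#' Double-exponential pulse \code{c_dia + (c_peak - c_dia) w(t - t_start)}
#' with \code{w} a rise/decay difference of exponentials normalised to peak
#' value one; constant at \code{c_dia} before \code{t_start}.  The defaults
#' give a plausible room-temperature rat transient.
#'
#' @param c_dia diastolic calcium (uM).
#' @param c_peak peak calcium (uM), > \code{c_dia}.
#' @param tau_rise,tau_decay rise and decay time constants (s).
#' @param t_start stimulus onset (s).
#' @return function \code{t -> Ca(t)} (vectorised) of class
#'   \code{"ca_transient"}, with the parameters attached as attribute
#'   \code{"params"}.
#' @export
synthetic_calcium_transient <- function(c_dia = 0.1, c_peak = 1.0,
                                        tau_rise = 0.02, tau_decay = 0.11,
                                        t_start = 0) {
  stopifnot(c_peak > c_dia, c_dia >= 0, tau_rise > 0, tau_decay > 0)
  if (abs(tau_decay - tau_rise) < 1e-12) {
    w <- function(s) (s / tau_rise) * exp(1 - s / tau_rise)
  } else {
    s_pk <- tau_rise * tau_decay / (tau_decay - tau_rise) *
      log(tau_decay / tau_rise)
    w_pk <- exp(-s_pk / tau_decay) - exp(-s_pk / tau_rise)
    w <- function(s) (exp(-s / tau_decay) - exp(-s / tau_rise)) / w_pk
  }
  f <- function(t) {
    s <- t - t_start
    ifelse(s <= 0, c_dia, c_dia + (c_peak - c_dia) * w(pmax(s, 0)))
  }
  structure(f, params = list(c_dia = c_dia, c_peak = c_peak,
                             tau_rise = tau_rise, tau_decay = tau_decay,
                             t_start = t_start),
            class = c("ca_transient", "function"))
}

#' Twitch kinetics metrics
#'
#' Peak tension, time to peak from stimulus onset, and times from the peak
#' to 50\% and 90\% relaxation towards the pre-twitch baseline.  The peak is
#' refined by a local parabola; relaxation crossings are linearly
#' interpolated.  Metrics are \code{NA} when the trace is flat.
#'
#' @param time time grid (s).
#' @param Ta tension trace (MPa).
#' @param t_start stimulus onset (s).
#' @param baseline pre-twitch tension; defaults to the first sample.
#' @return list of class \code{"twitch_metrics"} with \code{Ta_peak},
#'   \code{TTP}, \code{RT50}, \code{RT90}.
#' @export
twitch_metrics <- function(time, Ta, t_start = 0, baseline = NULL) {
  if (is.null(baseline)) baseline <- Ta[1]
  k <- which.max(Ta)
  amp <- Ta[k] - baseline
  if (!is.finite(amp) || amp <= 1e-9 * max(abs(Ta), 1e-300)) {
    return(structure(list(Ta_peak = NA_real_, TTP = NA_real_,
                          RT50 = NA_real_, RT90 = NA_real_),
                     class = "twitch_metrics"))
  }
  # parabolic refinement of the peak
  if (k > 1 && k < length(Ta)) {
    y1 <- Ta[k - 1]; y2 <- Ta[k]; y3 <- Ta[k + 1]
    den <- y1 - 2 * y2 + y3
    off <- if (abs(den) > 0) 0.5 * (y1 - y3) / den else 0
    off <- max(min(off, 0.5), -0.5)
    t_pk <- time[k] + off * (time[min(k + 1, length(time))] - time[k])
    Ta_pk <- y2 - 0.25 * (y1 - y3) * off
  } else {
    t_pk <- time[k]; Ta_pk <- Ta[k]
  }
  cross <- function(frac) {
    level <- Ta_pk - frac * (Ta_pk - baseline)
    post <- which(time > t_pk)
    below <- post[which(Ta[post] <= level)]
    if (!length(below)) return(NA_real_)
    j <- below[1]
    if (j == 1) return(time[j] - t_pk)
    t0 <- time[j - 1]; t1 <- time[j]
    f <- (Ta[j - 1] - level) / (Ta[j - 1] - Ta[j])
    (t0 + f * (t1 - t0)) - t_pk
  }
  structure(list(Ta_peak = Ta_pk, TTP = t_pk - t_start,
                 RT50 = cross(0.5), RT90 = cross(0.9)),
            class = "twitch_metrics")
}

#' @export
print.twitch_metrics <- function(x, ...) {
  cat(sprintf(
    "Twitch: Ta_peak = %.4g MPa, TTP = %.4g s, RT50 = %.4g s, RT90 = %.4g s\n",
    x$Ta_peak, x$TTP, x$RT50, x$RT90))
  invisible(x)
}

#' Isometric twitch
#'
#' Applies a calcium transient at fixed sarcomere length, starting from the
#' diastolic steady state, and extracts the twitch kinetics metrics.
#'
#' @param model a \code{\link{sarcomere_model}}.
#' @param transient a \code{\link{synthetic_calcium_transient}} (or any
#'   function of time returning calcium in uM; metrics then use
#'   \code{t_start = 0} unless given).
#' @param SL sarcomere length (um).
#' @param t_end end of the simulation (s); default covers the transient.
#' @param dt output sampling step (s).
#' @return list with \code{trace} (data.frame time, Ca, Ta) and
#'   \code{metrics} (\code{\link{twitch_metrics}}).
#' @export
isometric_twitch <- function(model, transient, SL, t_end = NULL, dt = 1e-3) {
  p <- attr(transient, "params")
  if (is.null(p)) p <- list(c_dia = transient(0), t_start = 0,
                            tau_decay = 0.2)
  if (is.null(t_end)) t_end <- p$t_start + max(1, 10 * p$tau_decay)
  y0 <- assemble_steady_state(model, p$c_dia, SL)
  times <- seq(0, t_end, by = dt)
  out <- sarco_integrate(model, y0, times, transient, SL, 0)
  tt <- out[, 1]
  Ta <- vapply(seq_along(tt),
               function(k) model_tension(model, out[k, -1], SL), numeric(1))
  trace <- data.frame(time = tt, Ca = transient(tt), Ta = Ta)
  list(trace = trace,
       metrics = twitch_metrics(tt, Ta, t_start = p$t_start,
                                baseline = Ta[1]))
}

#' Closed-form maximum shortening velocity
#'
#' Zero crossing of the steady first strain moment when the activation state
#' is frozen fully permissive and the tropomyosin coupling fluxes are off:
#' \code{v_max = mu_fP1 r0 / (mu_fP0 - alpha mu_fP1)} (1/s).
#'
#' @param xb an \code{\link{xb_parameters}} object.
#' @return v_max (1/s).
#' @export
xb_vmax_closed_form <- function(xb) {
  den <- xb$mu_fP0 - xb$alpha * xb$mu_fP1
  if (den <= 0) stop("infeasible parameters: mu_fP0 <= alpha * mu_fP1 ",
                     "gives no finite maximum shortening velocity")
  xb$mu_fP1 * xb$r0 / den
}

#' Force-velocity curve
#'
#' Starting from the isometric steady state at (Ca, SL), applies a constant
#' normalised shortening velocity and records the steady tension plateau,
#' normalised by the isometric value.  In the default \code{"frozen"} mode
#' the regulatory state (permissivity and coupling rates) and the overlap
#' are frozen at their isometric values and the linear moment equations are
#' solved at each velocity -- this mirrors measuring the plateau before
#' appreciable length drift; \code{"free"} integrates the full model over a
#' short window with drifting length.
#'
#' @param model a \code{\link{sarcomere_model}}.
#' @param Ca calcium (uM).
#' @param SL sarcomere length (um).
#' @param v_grid shortening velocities (1/s, >= 0).
#' @param mode \code{"frozen"} or \code{"free"}.
#' @param window measurement window for the free mode (s).
#' @return list with \code{curve} (data.frame v, T_norm), \code{v_max}
#'   (root-bracketed zero crossing, frozen mode) and \code{Ta_iso}.
#' @export
force_velocity_curve <- function(model, Ca, SL, v_grid = seq(0, 8, by = 0.5),
                                 mode = c("frozen", "free"), window = 0.02) {
  mode <- match.arg(mode)
  st <- steady_tension(model, Ca, SL)
  xb <- model$xb; geom <- model$geom
  if (mode == "frozen") {
    if (model$family == "MF") {
      s0 <- xb$mu_fP0; s1 <- xb$mu_fP1
    } else {
      idx <- seq_len(geom$n_ru)
      wM <- chi_M(SL, idx, geom) * chi_SF(SL, idx, geom)
      s0 <- xb$mu_fP0 * wM; s1 <- xb$mu_fP1 * wM
    }
    mu1_of <- function(v) {
      ms <- xb_moment_steady(st$P, st$kt_NP, st$kt_PN,
                             xb_total_rate(xb, v), s0, s1, v)
      if (model$family == "MF") ms$muP1 + ms$muN1 else mean(ms$muP1 + ms$muN1)
    }
    mu1_iso <- mu1_of(0)
    T_norm <- vapply(v_grid, function(v) mu1_of(v) / mu1_iso, numeric(1))
    # bracket the zero crossing
    v_hi <- max(v_grid[1] + 1, max(v_grid))
    while (mu1_of(v_hi) > 0 && v_hi < 1000) v_hi <- 2 * v_hi
    v_max <- if (mu1_of(v_hi) <= 0) {
      stats::uniroot(mu1_of, c(0, v_hi), tol = 1e-10)$root
    } else NA_real_
  } else {
    y0 <- assemble_steady_state(model, Ca, SL)
    T_norm <- vapply(v_grid, function(v) {
      SL_f <- function(t) SL - v * geom$SL0 * t
      out <- sarco_integrate(model, y0, c(0, window), Ca, SL_f, v)
      model_tension(model, out[nrow(out), -1], SL_f(window)) / st$Ta
    }, numeric(1))
    v_max <- NA_real_
  }
  list(curve = data.frame(v = v_grid, T_norm = T_norm), v_max = v_max,
       Ta_iso = st$Ta)
}

#' Tension response to fast length steps
#'
#' From the isometric steady state, applies a length step \code{dL} (per
#' half-sarcomere, um; positive = stretch) as a constant velocity over a
#' short interval \code{dt_step}, and records the tension at the end of the
#' step normalised by the pre-step tension (a T2-type curve for the moments
#' models, which carry no instantaneous elasticity).
#'
#' @param model a \code{\link{sarcomere_model}}.
#' @param dL_grid half-sarcomere length steps (um).
#' @param dt_step step duration (s).
#' @param Ca calcium (uM).
#' @param SL initial sarcomere length (um).
#' @return data.frame with \code{dL}, \code{T_rel}.
#' @export
fast_step_response <- function(model, dL_grid, dt_step = 2e-4, Ca = 1.2,
                               SL = 2.2) {
  y0 <- assemble_steady_state(model, Ca, SL)
  T0 <- model_tension(model, y0, SL)
  geom <- model$geom
  T_rel <- vapply(dL_grid, function(dL) {
    if (dL == 0) return(1)
    v_step <- -dL / (dt_step * geom$SL0 / 2)
    SL_f <- function(t) SL + 2 * dL * t / dt_step
    out <- sarco_integrate(model, y0, c(0, dt_step), Ca, SL_f, v_step)
    model_tension(model, out[nrow(out), -1], SL_f(dt_step)) / T0
  }, numeric(1))
  data.frame(dL = dL_grid, T_rel = T_rel)
}
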