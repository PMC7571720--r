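#' Construct a sarcomere force-generation model
#'
#' Builds one of the four model reductions:
#' \describe{
#'   \item{\code{"MF-ODE"}}{mean-field triplet + distribution moments;
#'     16 + 4 = 20 states.}
#'   \item{\code{"MF-PDE"}}{mean-field triplet + transported strain
#'     densities on an x grid.}
#'   \item{\code{"SE-ODE"}}{spatially explicit triplets + per-RU moments;
#'     \code{(n_ru - 2) * 64 + 4 n_ru} states (2048 at the default 32 RUs).}
#'   \item{\code{"SE-PDE"}}{spatially explicit triplets + per-RU strain
#'     densities.}
#' }
#'
#' @param model one of \code{"MF-ODE"}, \code{"MF-PDE"}, \code{"SE-ODE"},
#'   \code{"SE-PDE"}.
#' @param preset preset name passed to \code{\link{sarcomere_preset}}
#'   (\code{"rat_room"} or \code{"human_body"}); ignored when both \code{ru}
#'   and \code{xb} are supplied.
#' @param ru,xb optional \code{\link{ru_parameters}} /
#'   \code{\link{xb_parameters}} overriding the preset.
#' @param geom a \code{\link{sarcomere_geometry}}.
#' @param grid for the PDE variants: list with \code{x_min}, \code{x_max}
#'   (um) and \code{nx} nodes.  The default covers the attachment-profile
#'   support with margin for convective displacement.
#' @param profile_shape attachment-profile shape for the PDE variants, see
#'   \code{\link{build_fP_profile}}.
#' @param rtol,atol integrator tolerances (adaptive stiff solvers).  The
#'   defaults are \code{1e-6} / \code{1e-9} for the moments (ODE) variants
#'   and \code{1e-9} / \code{1e-12} for the strain-density (PDE) variants,
#'   where the sparse solver needs the tighter setting to hold probability
#'   conservation at the 1e-8 level over long trajectories.
#' @param eps_den denominator guard for the aggregated (closure) rates.
#' @return object of class \code{"sarcomere_model"}.
#' @examples
#' m <- sarcomere_model("MF-ODE", "rat_room")
#' print(m)
#' @export
sarcomere_model <- function(model = c("MF-ODE", "MF-PDE", "SE-ODE", "SE-PDE"),
                            preset = c("rat_room", "human_body"),
                            ru = NULL, xb = NULL,
                            geom = sarcomere_geometry(),
                            grid = list(x_min = -0.05, x_max = 0.06,
                                        nx = 401L),
                            profile_shape = "rectangular",
                            rtol = NULL, atol = NULL, eps_den = 1e-12) {
  model <- match.arg(model)
  family <- if (startsWith(model, "MF")) "MF" else "SE"
  form <- if (endsWith(model, "ODE")) "ODE" else "PDE"
  if (is.null(rtol)) rtol <- if (form == "ODE") 1e-6 else 1e-9
  if (is.null(atol)) atol <- if (form == "ODE") 1e-9 else 1e-12
  preset_name <- NULL
  if (is.null(ru) || is.null(xb)) {
    preset_name <- match.arg(preset)
    p <- sarcomere_preset(preset_name, family)
    if (is.null(ru)) ru <- p$ru
    if (is.null(xb)) xb <- p$xb
  }
  stopifnot(inherits(ru, "ru_parameters"), inherits(xb, "xb_parameters"),
            inherits(geom, "sarcomere_geometry"))
  obj <- list(model = model, family = family, form = form,
              preset = preset_name, ru = ru, xb = xb, geom = geom,
              solver = list(rtol = rtol, atol = atol, eps_den = eps_den))
  if (form == "PDE") {
    x <- seq(grid$x_min, grid$x_max, length.out = as.integer(grid$nx))
    obj$grid <- list(x = x, dx = x[2] - x[1])
    obj$profile <- build_fP_profile(xb, geom, profile_shape)
    obj$fPx <- fP_profile_grid(obj$profile, x, obj$grid$dx)
    if (obj$profile$x_center - obj$profile$half_width < grid$x_min ||
        obj$profile$x_center + obj$profile$half_width > grid$x_max) {
      stop("grid does not cover the attachment-profile support")
    }
  }
  class(obj) <- "sarcomere_model"
  obj
}

#' Number of state variables of a model
#' @param model a \code{\link{sarcomere_model}}.
#' @return integer state count.
#' @export
n_states <- function(model) {
  n <- model$geom$n_ru
  switch(model$model,
         "MF-ODE" = 20L,
         "MF-PDE" = 16L + 2L * length(model$grid$x),
         "SE-ODE" = (n - 2L) * 64L + 4L * n,
         "SE-PDE" = (n - 2L) * 64L + 2L * n * length(model$grid$x))
}

#' Default initial state
#'
#' All regulatory units start non-permissive with troponin unbound, and no
#' attached crossbridges (zero moments / densities).
#'
#' @param model a \code{\link{sarcomere_model}}.
#' @return numeric state vector.
#' @export
initial_state <- function(model) {
  y <- numeric(n_states(model))
  if (model$family == "MF") {
    y[1] <- 1
  } else {
    M <- model$geom$n_ru - 2L
    y[64L * (seq_len(M) - 1L) + 1L] <- 1
  }
  y
}

#' @export
print.sarcomere_model <- function(x, ...) {
  cat(sprintf("Sarcomere force-generation model: %s\n", x$model))
  cat(sprintf("  %s family, %s crossbridge description, %d state variables\n",
              if (x$family == "MF") "mean-field" else "spatially explicit",
              if (x$form == "ODE") "distribution-moments" else
                "strain-density", n_states(x)))
  if (!is.null(x$preset)) cat(sprintf("  preset: %s\n", x$preset))
  cat(sprintf("  %d RUs, gamma = %g, kd_bar = %g uM, a_XB = %g MPa\n",
              x$geom$n_ru, x$ru$gamma, x$ru$kd_bar, x$xb$a_XB))
  invisible(x)
}

#' @export
coef.sarcomere_model <- function(object, ...) {
  ru <- object$ru; xb <- object$xb
  c(Q = ru$Q, mu = ru$mu, gamma = ru$gamma, kd_bar = ru$kd_bar,
    alpha_kd = ru$alpha_kd, koff = ru$koff, kbasic = ru$kbasic,
    mu_fP0 = xb$mu_fP0, mu_fP1 = xb$mu_fP1, r0 = xb$r0, alpha = xb$alpha,
    a_XB = xb$a_XB)
}

# evaluate the model right-hand side at given inputs
model_rhs <- function(model, y, Ca, SL, v) {
  eps <- model$solver$eps_den
  switch(model$model,
    "MF-ODE" = mf_ode_rhs(y, Ca, SL, v, model$ru, model$xb, model$geom, eps),
    "SE-ODE" = se_ode_rhs(y, Ca, SL, v, model$ru, model$xb, model$geom, eps),
    "MF-PDE" = mf_pde_rhs(y, Ca, SL, v * model$geom$SL0 / 2, model$ru,
                          model$xb, model$geom, model$grid, model$fPx, eps),
    "SE-PDE" = se_pde_rhs(y, Ca, SL, v * model$geom$SL0 / 2, model$ru,
                          model$xb, model$geom, model$grid, model$fPx, eps))
}

# active tension from a state vector
model_tension <- function(model, y, SL) {
  switch(model$model,
    "MF-ODE" = as.numeric(mf_active_tension(y, SL, model$xb, model$geom)),
    "SE-ODE" = as.numeric(se_active_tension(y, model$xb, model$geom)),
    "MF-PDE" = mf_pde_force(y, SL, model$xb, model$geom, model$grid)$Ta,
    "SE-PDE" = se_pde_force(y, model$xb, model$geom, model$grid)$Ta)
}

as_time_fun <- function(f) {
  if (is.function(f)) f else function(t) rep_len(f, length(t))
}

# integrate the model over `times` with inputs Ca(t), SL(t), v(t) (scalars
# or functions of time).  Small systems use lsoda; the large spatially
# explicit systems use lsodes with internally detected Jacobian sparsity.
sarco_integrate <- function(model, y0, times, Ca, SL, v = 0,
                            method = NULL, ...) {
  Ca_f <- as_time_fun(Ca); SL_f <- as_time_fun(SL); v_f <- as_time_fun(v)
  f <- function(t, y, p) list(model_rhs(model, y, Ca_f(t), SL_f(t), v_f(t)))
  if (is.null(method)) {
    method <- if (length(y0) <= 200L) "lsoda" else "lsodes"
  }
  if (method == "cfl_explicit") {
    # explicit fixed-step path for the PDE variants; enforces the CFL bound
    dt <- diff(times)
    vmax <- max(abs(v_f(times)))
    v_hs_max <- vmax * model$geom$SL0 / 2
    if (model$form == "PDE" &&
        any(dt * v_hs_max / model$grid$dx > 1)) {
      stop("step-size error: CFL condition dt * |v_hs| / dx <= 1 violated")
    }
    out <- deSolve::rk4(y0, times, f, parms = NULL)
  } else {
    out <- deSolve::ode(y0, times, f, parms = NULL, method = method,
                        rtol = model$solver$rtol, atol = model$solver$atol,
                        maxsteps = 100000, ...)
  }
  unname(out)
}

#' Simulate a trajectory of a sarcomere model
#'
#' Integrates the model over \code{times} with prescribed calcium, sarcomere
#' length and normalised shortening velocity (each a scalar or a function of
#' time) and returns the tension trace together with summary state variables.
#'
#' @param object a \code{\link{sarcomere_model}}.
#' @param nsim,seed unused (the models are deterministic); present for
#'   compatibility with the generic.
#' @param times output time grid (s).
#' @param Ca calcium (uM): scalar or function of time.
#' @param SL sarcomere length (um): scalar or function of time.
#' @param v normalised shortening velocity (1/s): scalar or function.
#' @param y0 initial state; defaults to \code{\link{initial_state}}.
#' @param keep_state if \code{TRUE} the full state matrix is attached as
#'   attribute \code{"state"}.
#' @param ... passed to the integrator.
#' @return data.frame with columns \code{time}, \code{Ca}, \code{SL},
#'   \code{v}, \code{P} (permissivity), \code{mu0}, \code{mu1}, \code{Ta}.
#' @export
simulate.sarcomere_model <- function(object, nsim = 1, seed = NULL,
                                     times = seq(0, 1, by = 1e-3),
                                     Ca = 1, SL = object$geom$SL0, v = 0,
                                     y0 = NULL, keep_state = FALSE, ...) {
  if (is.null(y0)) y0 <- initial_state(object)
  Ca_f <- as_time_fun(Ca); SL_f <- as_time_fun(SL); v_f <- as_time_fun(v)
  out <- sarco_integrate(object, y0, times, Ca_f, SL_f, v_f, ...)
  tt <- out[, 1]
  states <- out[, -1, drop = FALSE]
  perm <- apply(states, 1, function(y) model_permissivity(object, y))
  summ <- t(apply(states, 1, function(y) model_moments(object, y)))
  SLt <- SL_f(tt)
  Ta <- vapply(seq_along(tt),
               function(k) model_tension(object, states[k, ], SLt[k]),
               numeric(1))
  res <- data.frame(time = tt, Ca = Ca_f(tt), SL = SLt, v = v_f(tt),
                    P = perm, mu0 = summ[, 1], mu1 = summ[, 2], Ta = Ta)
  if (keep_state) attr(res, "state") <- states
  res
}

# scalar permissivity (mean over units for the SE family)
model_permissivity <- function(model, y) {
  if (model$family == "MF") {
    mf_permissivity(y[1:16])
  } else {
    mean(se_permissivity(matrix(y[seq_len(64L * (model$geom$n_ru - 2L))],
                                64L)))
  }
}

# overall attached fraction mu0 and first moment mu1 (overlap-weighted)
model_moments <- function(model, y) {
  geom <- model$geom
  switch(model$model,
    "MF-ODE" = c(y[17] + y[18], y[19] + y[20]),
    "SE-ODE" = {
      st <- se_unpack(y, geom$n_ru)
      c(mean(st$muP0 + st$muN0), mean(st$muP1 + st$muN1))
    },
    "MF-PDE" = {
      nx <- length(model$grid$x)
      ntot <- y[16 + seq_len(nx)] + y[16 + nx + seq_len(nx)]
      c(sum(ntot), sum(model$grid$x / (geom$SL0 / 2) * ntot)) * model$grid$dx
    },
    "SE-PDE" = {
      f <- se_pde_force(y, model$xb, geom, model$grid)
      c(f$mu0, f$mu1)
    })
}
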