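test_that("isometric steady state: limits and method agreement", {
  m <- sarcomere_model("MF-ODE", "rat_room")
  st_sat <- run_to_steady_state(m, Ca = 100, SL = 2.2)
  st_0 <- run_to_steady_state(m, Ca = 0, SL = 2.2)
  # without calcium only the basal tropomyosin flicker (order Q/(mu gamma^2)
  # of full permissivity) remains: tension a few 1e-3 of saturating
  expect_lt(st_0$Ta_iso, 5e-3 * st_sat$Ta_iso)
  expect_identical(run_to_steady_state(m, 1, SL = 1.0)$Ta_iso, 0)  # no overlap
  sti <- run_to_steady_state(m, 1.0, 2.2, method = "integrate",
                             t_chunk = 1, t_max = 10)
  stf <- run_to_steady_state(m, 1.0, 2.2)
  expect_true(sti$converged)
  expect_true(stf$converged)
  expect_equal(sti$Ta_iso, stf$Ta_iso, tolerance = 1e-4)
})

test_that("Hill fit recovers exact generative parameters", {
  Ca <- exp(seq(log(0.05), log(20), length.out = 15))
  Ta <- 0.1 / (1 + (1.0 / Ca)^3)
  h <- hill_fit(Ca, Ta)
  expect_equal(h$Ta_max, 0.1, tolerance = 1e-6)
  expect_equal(h$EC50, 1.0, tolerance = 1e-6)
  expect_equal(h$nH, 3, tolerance = 1e-6)
})

test_that("force-calcium curve: monotone, cooperative, consistent plateau", {
  m <- sarcomere_model("MF-ODE", "rat_room")
  grid <- exp(seq(log(0.1), log(10), length.out = 12))
  fc <- force_calcium_curve(m, grid, 2.15)
  expect_true(all(diff(fc$curve$Ta) > 0))
  expect_gt(fc$hill$nH, 1)
  Ta_sat <- steady_tension(m, 1000, 2.15)$Ta
  expect_lt(abs(fc$hill$Ta_max - Ta_sat) / Ta_sat, 0.02)
})

test_that("force-length curve factorises through the overlap ratio", {
  m <- sarcomere_model("MF-ODE", "rat_room")
  SLs <- seq(1.45, 2.55, by = 0.1)
  fl <- force_length_curve(m, SLs, Ca = 100)
  xs <- chi_so(SLs, m$geom)
  # at saturating calcium the MF curve is chi_so times a constant, up to
  # the mild SL dependence of the calcium sensitivity
  expect_lt(max(abs(fl$Ta / max(fl$Ta) - xs / max(xs))), 0.01)
  fl0 <- force_length_curve(m, c(1.8, 2.2), Ca = 1e-6)
  expect_lt(max(fl0$Ta), 5e-3 * max(fl$Ta))   # basal flicker only
  # slope change across SL = LM (the ascending-limb kink of the overlap)
  s_lo <- (fl$Ta[2] - fl$Ta[1]) / 0.1     # 1.45 -> 1.55, below LM
  s_hi <- (fl$Ta[4] - fl$Ta[3]) / 0.1     # 1.65 -> 1.75, above LM
  expect_gt(s_lo / s_hi, 1.5)             # factor ~2 slope drop at LM
})

test_that("synthetic calcium transient is normalised and well-behaved", {
  tr <- synthetic_calcium_transient(c_dia = 0.1, c_peak = 1, t_start = 0.05)
  expect_identical(tr(c(-1, 0, 0.05)), rep(0.1, 3))
  tt <- seq(0, 2, by = 1e-4)
  expect_equal(max(tr(tt)), 1.0, tolerance = 1e-6)
  tr_inf <- synthetic_calcium_transient(tau_decay = 1e6)
  expect_equal(tr_inf(5), 1.0, tolerance = 1e-4)       # plateau limit
  expect_error(synthetic_calcium_transient(c_peak = 0.05), "c_peak")
})

test_that("twitch metrics are exact on a prescribed triangular pulse", {
  tt <- seq(0, 1, by = 1e-3)
  base <- 0.01; pk <- 0.11; t_pk <- 0.2
  Ta <- ifelse(tt <= t_pk, base + (pk - base) * tt / t_pk,
               pmax(base, pk - (pk - base) * (tt - t_pk) / 0.4))
  mtr <- twitch_metrics(tt, Ta, t_start = 0)
  expect_equal(mtr$Ta_peak, pk, tolerance = 1e-3)
  expect_equal(mtr$TTP, t_pk, tolerance = 2e-3)
  expect_equal(mtr$RT50, 0.2, tolerance = 2e-3)        # 50% of 0.4 s ramp
  expect_equal(mtr$RT90, 0.36, tolerance = 2e-3)
  # flat trace: metrics reported as absent
  flat <- twitch_metrics(tt, rep(base, length(tt)))
  expect_true(is.na(flat$Ta_peak) && is.na(flat$RT90))
})

test_that("twitch simulation: metrics stable under sampling refinement", {
  m <- sarcomere_model("MF-ODE", "rat_room")
  tr <- synthetic_calcium_transient()
  tw1 <- isometric_twitch(m, tr, 2.2, t_end = 1.1, dt = 2e-3)
  tw2 <- isometric_twitch(m, tr, 2.2, t_end = 1.1, dt = 1e-3)
  expect_equal(tw1$metrics$TTP, tw2$metrics$TTP, tolerance = 2e-3)
  expect_equal(tw1$metrics$RT50, tw2$metrics$RT50, tolerance = 2e-3)
  expect_equal(tw1$metrics$Ta_peak, tw2$metrics$Ta_peak, tolerance = 1e-3)
  # constant calcium: flat tension, metrics absent
  flat_tr <- function(t) rep_len(0.1, length(t))
  twf <- isometric_twitch(m, flat_tr, 2.2, t_end = 0.3)
  expect_true(is.na(twf$metrics$Ta_peak))
})

test_that("force-velocity: normalisation, monotonicity, closed-form zero", {
  m <- sarcomere_model("MF-ODE", "rat_room")
  fv <- force_velocity_curve(m, 1.2, 2.2, v_grid = seq(0, 7, by = 0.5))
  expect_equal(fv$curve$T_norm[1], 1)
  expect_true(all(diff(fv$curve$T_norm) < 0))
  expect_true(all(diff(fv$curve$T_norm, differences = 2) > 0))  # convex
  expect_equal(fv$v_max, xb_vmax_closed_form(m$xb), tolerance = 1e-6)
  # activation invariance of the normalised curve
  fv2 <- force_velocity_curve(m, 0.6, 2.0, v_grid = seq(0, 7, by = 0.5))
  expect_equal(fv$curve$T_norm, fv2$curve$T_norm, tolerance = 1e-10)
  # free-running mode agrees near the isometric point
  fvf <- force_velocity_curve(m, 1.2, 2.2, v_grid = c(0, 1), mode = "free")
  expect_equal(fvf$curve$T_norm[2], fv$curve$T_norm[fv$curve$v == 1],
               tolerance = 0.05)
})

test_that("fast length steps: sign convention and frozen-rate prediction", {
  m <- sarcomere_model("MF-ODE", "rat_room")
  dL <- c(-0.006, -0.003, 0, 0.003)
  fs <- fast_step_response(m, dL, Ca = 1.2, SL = 2.2)
  expect_identical(fs$T_rel[dL == 0], 1)
  expect_true(all(diff(fs$T_rel) > 0))   # shortening drops tension
  # independent short-time oracle: integrate the four-moment linear system
  # with regulatory rates frozen at the pre-step state
  st <- steady_tension(m, 1.2, 2.2)
  xb <- m$xb
  dt <- 2e-4
  pred <- vapply(dL[dL != 0], function(d) {
    v <- -d / (dt * m$geom$SL0 / 2)
    r <- xb_total_rate(xb, v)
    f <- function(t, y, p) {
      list(c(-(r + st$kt_PN) * y[1] + st$kt_NP * y[2] + st$P * xb$mu_fP0,
             -(r + st$kt_NP) * y[2] + st$kt_PN * y[1],
             -v * y[1] - (r + st$kt_PN) * y[3] + st$kt_NP * y[4] +
               st$P * xb$mu_fP1,
             -v * y[2] - (r + st$kt_NP) * y[4] + st$kt_PN * y[3]))
    }
    ms <- sarcodyn:::xb_moment_steady(st$P, st$kt_NP, st$kt_PN, xb$r0,
                                      xb$mu_fP0, xb$mu_fP1)
    y0 <- c(ms$muP0, ms$muN0, ms$muP1, ms$muN1)
    out <- deSolve::lsoda(y0, c(0, dt), f, parms = NULL,
                          rtol = 1e-10, atol = 1e-13)
    (out[2, 4] + out[2, 5]) / (y0[3] + y0[4])
  }, numeric(1))
  # overlap ratio shifts slightly with the step; compare within 1%
  expect_equal(fs$T_rel[dL != 0], pred, tolerance = 0.01)
})
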