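test_that("MF-ODE has exactly 20 scalar states", {
  m <- sarcomere_model("MF-ODE", "rat_room")
  expect_identical(n_states(m), 20L)
  expect_identical(length(initial_state(m)), 20L)
})

test_that("triplet derivative conserves probability on arbitrary states", {
  ru <- rat_mf()$ru
  set.seed(7)
  for (k in 1:8) {
    p <- stats::runif(16); p <- p / sum(p)
    expect_lt(abs(sum(mf_ru_rhs(p, Ca = 2^stats::runif(1, -3, 3),
                                SL = stats::runif(1, 1.8, 2.4), ru))),
              1e-10)
  }
  expect_error(mf_ru_rhs(c(NA, rep(1, 15)), 1, 2.2, ru), "non-finite")
})

test_that("steady permissivity at gamma = 1 equals the single-RU law", {
  ru1 <- ru_parameters(Q = 2, mu = 10, gamma = 1, kd_bar = 0.835,
                       alpha_kd = 0, koff = 120, kbasic = 24)
  for (Ca in c(0.2, 0.8, 3)) {
    expect_equal(mf_permissivity(mf_ru_steady(ru1, Ca, 2.15)),
                 single_ru_P(ru1, Ca, n = 0), tolerance = 1e-8)
  }
})

test_that("aggregated edge rates are conditional expectations", {
  ru <- rat_mf()$ru
  tb <- ru_rate_table(ru, 1, 2.15, "MF")
  # degenerate distribution: rate conditioned on that single state
  p <- numeric(16); p[1] <- 1          # all (N,N,N,U)
  er <- mf_edge_rates(p, tb)
  expect_equal(er$left["N", "N"], tb$kT_NP_U[1], tolerance = 1e-12)
  # gamma = 1: the P -> N edge rate is neighbour-independent = kbasic
  ru1 <- ru_parameters(Q = 2, mu = 10, gamma = 1, kd_bar = 0.835,
                       alpha_kd = 0, koff = 120, kbasic = 24)
  tb1 <- ru_rate_table(ru1, 1, 2.15, "MF")
  set.seed(3)
  p <- stats::runif(16); p <- p / sum(p)
  er1 <- mf_edge_rates(p, tb1)
  expect_equal(unname(er1$left["P", ]), c(24, 24), tolerance = 1e-12)
  # uniform distribution: plain 4-term average, recomputed by hand
  pu <- rep(1 / 16, 16)
  eru <- mf_edge_rates(pu, tb)
  hand <- mean(c(tb$kT_NP_U[c(1, 2)], tb$kT_NP_B[c(1, 2)]))
  expect_equal(eru$left["N", "N"], hand, tolerance = 1e-12)
})

test_that("permissivity and coupling-rate marginals", {
  expect_equal(mf_permissivity(rep(1 / 16, 16)), 0.5)
  cache_bP <- sarcodyn:::mf_cache()$bP
  p <- numeric(16); p[which(cache_bP)] <- 1 / 8
  expect_equal(mf_permissivity(p), 1)
  ru <- rat_mf()$ru
  tb <- ru_rate_table(ru, 1, 2.15, "MF")
  kt <- mf_xb_coupling_rates(p, tb)
  expect_identical(kt[["kt_NP"]], 0)  # P = 1: undefined rate suppressed
  expect_gt(kt[["kt_PN"]], 0)
  # degenerate distribution: conditioned rate
  p2 <- numeric(16); p2[1] <- 1
  kt2 <- mf_xb_coupling_rates(p2, tb)
  expect_equal(kt2[["kt_NP"]], tb$kT_NP_U[1], tolerance = 1e-12)
})

test_that("moment equations have the frozen-activation closed forms", {
  xb <- rat_mf()$xb
  # independent route: integrate the linear moment system directly
  mom_run <- function(v, T_end = 2) {
    f <- function(t, y, p) {
      r <- xb$r0 + xb$alpha * abs(v)
      list(c(-r * y[1] + xb$mu_fP0,
             -v * y[1] - r * y[2] + xb$mu_fP1))
    }
    out <- deSolve::lsoda(c(0, 0), c(0, T_end), f, parms = NULL,
                          rtol = 1e-11, atol = 1e-14)
    unname(out[nrow(out), -1])
  }
  expect_equal(mom_run(0)[1], xb$mu_fP0 / xb$r0, tolerance = 1e-9)
  expect_equal(xb$mu_fP0 / xb$r0, 0.2435, tolerance = 1e-3)
  vmax <- xb_vmax_closed_form(xb)
  expect_lt(abs(mom_run(vmax)[2]) / (xb$mu_fP1 / xb$r0), 1e-3)
  # moments with no source stay zero
  m <- sarcomere_model("MF-ODE", "rat_room")
  y <- initial_state(m)                       # all non-permissive, P = 0
  dy <- mf_ode_rhs(y, Ca = 0, SL = 2.2, v = 0, m$ru, m$xb, m$geom)
  expect_identical(unname(dy[17:20]), rep(0, 4))
})

test_that("active tension composes overlap and first moments", {
  xb <- rat_mf()$xb
  geom <- sarcomere_geometry()
  y <- numeric(20); y[1] <- 1
  expect_identical(as.numeric(mf_active_tension(y, 2.2, xb, geom)), 0)
  y[19] <- 0.1; y[20] <- 0.02
  expect_identical(as.numeric(mf_active_tension(y, 1.0, xb, geom)), 0)
  expect_equal(as.numeric(mf_active_tension(y, 2.2, xb, geom)),
               xb$a_XB * chi_so(2.2, geom) * 0.12, tolerance = 1e-12)
  xbk <- xb_parameters(xb$mu_fP0, xb$mu_fP1, xb$r0, xb$alpha, xb$a_XB,
                       k_XB = 2)
  Ta <- mf_active_tension(y, 2.2, xbk, geom)
  expect_equal(attr(Ta, "F_hf"),
               2 * 1.1 * 32 * chi_so(2.2, geom) * 0.12, tolerance = 1e-12)
})

test_that("strain-density model relaxes to the pointwise fixed point", {
  m <- sarcomere_model("MF-PDE", "rat_room",
                       grid = list(x_min = -0.05, x_max = 0.06, nx = 151L))
  nx <- 151L
  # long-time integration of the PDE at rest...
  out <- sarcodyn:::sarco_integrate(m, initial_state(m), c(0, 3),
                                    Ca = 60, SL = 2.2, v = 0)
  y <- out[nrow(out), -1]
  nP <- y[16 + seq_len(nx)]
  nN <- y[16 + nx + seq_len(nx)]
  # ...against the per-node 2x2 balance solved independently here
  pi_ss <- mf_ru_steady(m$ru, 60, 2.2)
  tb <- ru_rate_table(m$ru, 60, 2.2, "MF")
  kt <- mf_xb_coupling_rates(pi_ss, tb)
  P <- mf_permissivity(pi_ss)
  r <- m$xb$r0
  pred <- t(vapply(seq_len(nx), function(k) {
    A <- matrix(c(r + kt[["kt_PN"]], -kt[["kt_PN"]],
                  -kt[["kt_NP"]], r + kt[["kt_NP"]]), 2, 2)
    solve(A, c((P / m$geom$DM) * m$fPx[k], 0))
  }, numeric(2)))
  expect_equal(nP, pred[, 1], tolerance = 1e-4)
  expect_equal(nN, pred[, 2], tolerance = 1e-4)
  # summing the two balance equations cancels the coupling: the total
  # attached density equals DM^-1 P fP / (fP + gP) pointwise
  pred0 <- (P / m$geom$DM) * m$fPx / r
  expect_equal(pred[, 1] + pred[, 2], pred0, tolerance = 1e-10)
  expect_equal(nP + nN, pred0, tolerance = 1e-4)
  # zero densities with no permissive units give a zero derivative
  y0 <- initial_state(m)
  dy <- sarcodyn:::model_rhs(m, y0, Ca = 0, SL = 2.2, v = 0)
  expect_lt(max(abs(dy[17:length(dy)])), 1e-12)
})

test_that("strain-density force integrals match the moment route", {
  m <- sarcomere_model("MF-PDE", "rat_room")
  nx <- length(m$grid$x)
  xb <- xb_parameters(m$xb$mu_fP0, m$xb$mu_fP1, m$xb$r0, m$xb$alpha,
                      m$xb$a_XB, k_XB = 1)
  y <- numeric(16 + 2 * nx); y[1] <- 1
  expect_identical(mf_pde_force(y, 2.2, xb, m$geom, m$grid)$Ta, 0)
  # a density symmetric about x = 0 exerts no net force
  g <- exp(-(m$grid$x / 0.01)^2)
  ys <- c(numeric(16), g, g); ys[1] <- 1
  f <- mf_pde_force(ys, 2.2, xb, m$geom, m$grid)
  expect_lt(abs(f$F_hf), 1e-10 * sum(g))
  # moment bookkeeping equals quadrature
  expect_equal(f$Ta, xb$a_XB * f$mu1, tolerance = 1e-12)
})

test_that("upwind transport respects the CFL guard on the explicit path", {
  m <- sarcomere_model("MF-PDE", "rat_room",
                       grid = list(x_min = -0.05, x_max = 0.06, nx = 101L))
  y0 <- sarcodyn:::assemble_steady_state(m, 1, 2.2)
  expect_error(
    sarcodyn:::sarco_integrate(m, y0, seq(0, 0.01, by = 5e-3), 1, 2.2,
                               v = 8, method = "cfl_explicit"),
    "CFL")
  ok <- sarcodyn:::sarco_integrate(m, y0, seq(0, 1e-4, by = 5e-5), 1, 2.2,
                                   v = 8, method = "cfl_explicit")
  expect_true(all(is.finite(ok)))
})
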