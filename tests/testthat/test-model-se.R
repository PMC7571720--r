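test_that("state counts match the closed-form sizes", {
  m <- sarcomere_model("SE-ODE", "rat_room")
  expect_identical(n_states(m), 2048L)                 # (32-2)*64 + 4*32
  m6 <- sarcomere_model("SE-ODE", "rat_room", geom = geom_n(6))
  expect_identical(n_states(m6), (6L - 2L) * 64L + 4L * 6L)
})

test_that("per-triplet probability conservation is exact", {
  ru <- rat_se()$ru
  geom <- geom_n(8)
  set.seed(11)
  pi <- matrix(stats::runif(64 * 6), 64)
  pi <- sweep(pi, 2, colSums(pi), "/")
  d <- se_ru_rhs(pi, Ca = 1.2, SL = 2.1, ru, geom)
  expect_lt(max(abs(colSums(d))), 1e-10)
  d2 <- se_ru_rhs(pi, Ca = 1.2, SL = NULL, ru, geom)
  expect_lt(max(abs(colSums(d2))), 1e-10)
})

test_that("unmodulated chain at gamma = 1 relaxes to the single-RU law", {
  ru1 <- ru_parameters(Q = 3, mu = 10, gamma = 1, kd_bar = 1.622,
                       alpha_kd = 0, koff = 120, kbasic = 28)
  geom <- geom_n(6)
  pi <- se_ru_steady(ru1, 1.0, NULL, geom)
  expect_equal(se_permissivity(pi), rep(single_ru_P(ru1, 1.0, 0), 6),
               tolerance = 1e-6)
})

test_that("edge rates handle boundaries and degenerate distributions", {
  ru <- rat_se()$ru
  geom <- geom_n(6)
  tb <- ru_rate_table(ru, 1, family = "SE")
  pi <- matrix(0, 64, 4); pi[1, ] <- 1      # all (NNN, UUU)
  # unit 1 is a boundary: bare rate with the missing neighbour at N
  e1 <- se_edge_rates(pi, 1L, tb, SL = NULL, geom)
  # key (f=N, inner=N, troponin=U, eta=U) is index 1
  expect_equal(e1[1], tb$kT_NP_U[1], tolerance = 1e-12)
  # interior unit with concentrated distribution: conditioned rate
  e3 <- se_edge_rates(pi, 3L, tb, SL = NULL, geom)
  expect_equal(e3[1], tb$kT_NP_U[1], tolerance = 1e-12)
  # gamma = 1: the P-direction rate is the bare kbasic everywhere
  ru1 <- ru_parameters(Q = 3, mu = 10, gamma = 1, kd_bar = 1.622,
                       alpha_kd = 0, koff = 120, kbasic = 28)
  tb1 <- ru_rate_table(ru1, 1, family = "SE")
  set.seed(5)
  pr <- matrix(stats::runif(64 * 4), 64); pr <- sweep(pr, 2, colSums(pr), "/")
  e <- se_edge_rates(pr, 3L, tb1, SL = NULL, geom)
  # keys with f = P (even positions of the first bit) must equal kbasic
  fP_keys <- which(sarcodyn:::se_cache()$key16$f == 2L)
  expect_equal(unname(e[fP_keys]), rep(28, 8), tolerance = 1e-10)
})

test_that("permissivity profile marginals", {
  pi <- matrix(1 / 64, 64, 4)
  expect_equal(se_permissivity(pi), rep(0.5, 6))
  cache <- sarcodyn:::se_cache()
  pc <- matrix(0, 64, 4)
  pc[which(cache$bP)[1], ] <- 1
  expect_equal(se_permissivity(pc)[2:5], rep(1, 4))
})

test_that("reduced chain matches the exact master equation at n = 6", {
  ruSE <- rat_se()$ru
  geom <- geom_n(6)
  tb <- ru_rate_table(ruSE, 1.0, family = "SE")
  G <- ctmc_generator(6, tb, NULL, geom)
  P_ex <- sarcodyn:::master_permissivity(master_steady_state(G), 6)
  P_red <- se_permissivity(se_ru_steady(ruSE, 1.0, NULL, geom))
  # detailed balance makes the stationary law a spatial Markov field, so
  # the triplet closure is exact at stationarity even at gamma = 20
  expect_equal(P_red, P_ex, tolerance = 1e-7)
})

test_that("length-dependent suppression shapes the permissivity profile", {
  ruSE <- rat_se()$ru
  geom <- sarcomere_geometry()
  pi <- se_ru_steady(ruSE, 3, 2.2, geom)
  P <- se_permissivity(pi)
  # units facing the opposite half-sarcomere are switched off ...
  expect_lt(max(P[1:4]), 0.01)
  # ... and the free end of the filament is depressed relative to the core
  expect_lt(P[32], 0.8 * max(P))
  expect_gt(max(P), 0.9)
})

test_that("moment block: zero-overlap units keep zero moments", {
  m <- sarcomere_model("SE-ODE", "rat_room")
  y <- sarcodyn:::assemble_steady_state(m, 3, 2.2)
  dy <- sarcodyn:::model_rhs(m, y, 3, 2.2, 0)
  st <- sarcodyn:::se_unpack(y, 32L)
  w <- chi_M(2.2, 1:32, m$geom) * chi_SF(2.2, 1:32, m$geom)
  expect_lt(max(st$muP0[w < 1e-8]), 1e-10)
  # assembled steady state is an actual fixed point of the full rhs
  expect_lt(max(abs(dy)), 1e-4)
})

test_that("SE-PDE moments track the SE-ODE moments", {
  geom <- geom_n(8)
  mo <- sarcomere_model("SE-ODE", "rat_room", geom = geom)
  mp <- sarcomere_model("SE-PDE", "rat_room", geom = geom,
                        grid = list(x_min = -0.05, x_max = 0.06, nx = 151L))
  tt <- seq(0, 0.3, by = 0.05)
  so <- simulate(mo, times = tt, Ca = 2, SL = 2.2)
  sp <- simulate(mp, times = tt, Ca = 2, SL = 2.2)
  expect_lt(max(abs(so$mu1 - sp$mu1)) / max(abs(so$mu1)), 0.02)
  expect_lt(max(abs(so$P - sp$P)), 1e-6)   # identical RU subsystem
})

test_that("SE-PDE force integrals behave like the MF ones", {
  geom <- geom_n(5)
  m <- sarcomere_model("SE-PDE", "rat_room", geom = geom,
                       grid = list(x_min = -0.05, x_max = 0.06, nx = 111L))
  nx <- 111L
  xb <- xb_parameters(m$xb$mu_fP0, m$xb$mu_fP1, m$xb$r0, m$xb$alpha,
                      m$xb$a_XB, k_XB = 1.5)
  y <- initial_state(m)
  expect_identical(se_pde_force(y, xb, geom, m$grid)$Ta, 0)
  g <- exp(-(m$grid$x / 0.008)^2)
  y2 <- c(y[seq_len(64 * 3)], rep(g, 5), rep(g, 5))
  f <- se_pde_force(y2, xb, geom, m$grid)
  expect_lt(abs(f$F_hf), 1e-9 * sum(g))    # symmetric density, odd integrand
  expect_equal(f$Ta, xb$a_XB * f$mu1, tolerance = 1e-12)
})
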