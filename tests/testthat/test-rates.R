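test_that("neighbour counting and state validation", {
  expect_identical(neighbor_count("P", "P"), 2L)
  expect_identical(neighbor_count("N", "N"), 0L)
  expect_identical(neighbor_count("N", "P"), 1L)
  expect_error(neighbor_count("X", "P"), "'N' or 'P'")
})

test_that("rate table reproduces the generated rates for the presets", {
  ru <- rat_mf()$ru
  tb <- ru_rate_table(ru, Ca = 1, SL = 2.15, family = "MF")
  expect_equal(tb$kd, 0.835, tolerance = 1e-12)          # at SL_kd
  expect_equal(tb$kC_UB, 120 / 0.835, tolerance = 1e-12)
  ruSE <- rat_se()$ru
  tbSE <- ru_rate_table(ruSE, Ca = 1, family = "SE")
  expect_equal(tbSE$kT_PN[1], 28 * 400, tolerance = 1e-12)  # kbasic gamma^2
  tb0 <- ru_rate_table(ru, Ca = 0, SL = 2.15, family = "MF")
  expect_identical(tb0$kC_UB, 0)
  expect_error(ru_rate_table(ru, Ca = -1, family = "MF"), "nonnegative")
})

test_that("detailed-balance loop consistency holds for every n", {
  for (preset in list(rat_mf()$ru, rat_se()$ru, human_mf()$ru)) {
    tb <- ru_rate_table(preset, Ca = 0.7, SL = 2.1,
                        family = if (preset$alpha_kd == 0) "SE" else "MF")
    for (n in 0:2) {
      loop <- (tb$kT_NP_B[n + 1] / tb$kT_PN[n + 1]) *
        (tb$kC_BU_P / tb$kC_BU_N) *
        (tb$kT_PN[n + 1] / tb$kT_NP_U[n + 1])
      expect_equal(loop, 1, tolerance = 1e-12)
      # the ratios the steady state depends on
      expect_equal(tb$kT_NP_B[n + 1] / tb$kT_PN[n + 1],
                   preset$Q * preset$gamma^(2 * n - 2), tolerance = 1e-12)
      expect_equal(tb$kT_NP_U[n + 1] / tb$kT_PN[n + 1],
                   preset$Q / preset$mu * preset$gamma^(2 * n - 2),
                   tolerance = 1e-12)
    }
  }
})

test_that("length-modulated dissociation constant is clamped below", {
  ru <- rat_mf()$ru
  # at SL = 1.0 the linear law would be 0.835 - 1.258 * (1 - 2.15) < 0? no:
  # 0.835 + 1.4467 > 0; drive it negative with a long stretch instead
  tb <- ru_rate_table(ru, Ca = 1, SL = 3.5, family = "MF")
  expect_equal(tb$kd, 0.05 * 0.835, tolerance = 1e-12)
  tb2 <- ru_rate_table(ru, Ca = 1, SL = 2.0, family = "MF")
  expect_equal(tb2$kd, 0.835 - 1.258 * (2.0 - 2.15), tolerance = 1e-12)
})

test_that("positional modulation of the permissive transition", {
  geom <- sarcomere_geometry()
  ru <- rat_se()$ru
  tb <- ru_rate_table(ru, Ca = 1, family = "SE")
  deep <- se_np_rate(tb, 30L, 2.2, geom)   # RU far into single-filament zone
  expect_equal(deep$kT_NP_B[1, ], tb$kT_NP_B, tolerance = 1e-6)
  i <- 12L
  yi <- (geom$LA / geom$n_ru) * (i - 0.5)
  half <- se_np_rate(tb, i, 2 * geom$LA - yi, geom)  # y_i = y_SF
  expect_equal(half$kT_NP_U[1, ], tb$kT_NP_U / 2, tolerance = 1e-12)
  expect_identical(half$kT_PN, tb$kT_PN)   # reverse rate unmodulated
  expect_error(se_np_rate(tb, 40L, 2.2, geom), "out of range")
})

test_that("crossbridge total rate and attachment moments", {
  xb <- rat_mf()$xb
  expect_equal(xb_total_rate(xb, 0), 134.31, tolerance = 1e-12)
  expect_identical(xb_total_rate(xb, 1), xb_total_rate(xb, -1))
  expect_equal(xb_total_rate(xb, 2), 134.31 + 2 * 25.184, tolerance = 1e-12)
  mom <- xb_attachment_moments(xb, 2.2, i = NULL)
  expect_equal(c(mom$mu_f0, mom$mu_f1), c(32.708, 0.779), tolerance = 1e-12)
  expect_identical(mom$mu_fN0, 0)
  geom <- sarcomere_geometry()
  xbSE <- rat_se()$xb
  # units in the central zone have vanishing overlap weight -> zero source
  low <- xb_attachment_moments(xbSE, 2.2, i = 1L, geom)
  expect_lt(low$mu_f0, 1e-6 * xbSE$mu_fP0)
  mid <- xb_attachment_moments(xbSE, 2.2, i = 15L, geom)
  expect_equal(mid$mu_f0,
               xbSE$mu_fP0 * chi_M(2.2, 15L, geom) * chi_SF(2.2, 15L, geom),
               tolerance = 1e-12)
})

test_that("attachment profile matches its prescribed moments", {
  geom <- sarcomere_geometry()
  xb <- rat_mf()$xb
  for (shape in c("rectangular", "triangular")) {
    pf <- build_fP_profile(xb, geom, shape)
    m0 <- stats::integrate(pf$fP, -0.2, 0.2, subdivisions = 2000,
                           rel.tol = 1e-12)$value / geom$DM
    m1 <- stats::integrate(function(x) x / (geom$SL0 / 2) * pf$fP(x),
                           -0.2, 0.2, subdivisions = 2000,
                           rel.tol = 1e-12)$value / geom$DM
    expect_equal(m0, xb$mu_fP0, tolerance = 1e-8)
    expect_equal(m1, xb$mu_fP1, tolerance = 1e-8)
    expect_lte(pf$height, xb$r0 + 1e-9)
    expect_gte(min(pf$gP(seq(-0.05, 0.05, by = 1e-3), 0)), -1e-9)
  }
  # symmetric moments centre the profile at zero
  xb0 <- xb_parameters(mu_fP0 = 30, mu_fP1 = 0, r0 = 134.31, alpha = 25,
                       a_XB = 22)
  expect_equal(build_fP_profile(xb0, geom)$x_center, 0)
  # cell averages preserve the zeroth moment exactly on any grid
  pf <- build_fP_profile(xb, geom)
  x <- seq(-0.05, 0.06, length.out = 173)
  fx <- fP_profile_grid(pf, x, x[2] - x[1])
  expect_equal(sum(fx) * (x[2] - x[1]) / geom$DM, xb$mu_fP0,
               tolerance = 1e-10)
})
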