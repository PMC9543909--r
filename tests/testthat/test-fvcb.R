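test_that("limitation-state assimilation matches hand-evaluated forms", {
  # effective Michaelis term Kc*(1+O/Ko) = 350*(1+300/300) = 700
  k700 <- kinetic_constants(Kc = 350, Ko = 300, O = 300)
  p <- fvcb_params(Vcmax = 100, Jmax = 150, TPU = 9, Rd = 1, gm = Inf,
                   Gammastar = 40)
  expect_equal(assimilation_rubisco(260, p, k700), 100 * 220 / 960 - 1)
  expect_equal(assimilation_rubp(300, 150, p), 150 * 260 / 1520 - 1)
  expect_equal(assimilation_rubp(1e9, 150, p), 150 / 4 - 1, tolerance = 1e-6)

  # compensation point and saturation limits
  pdef <- fvcb_params(Vcmax = 100, Jmax = 150, TPU = 9)
  expect_equal(assimilation_rubisco(pdef$Gammastar, pdef), -0.73)
  expect_equal(assimilation_rubp(pdef$Gammastar, 150, pdef), -0.73)
  expect_equal(assimilation_rubisco(1e9, pdef), 100 - 0.73, tolerance = 1e-6)

  # TPU plateau
  expect_equal(assimilation_tpu(fvcb_params(100, 150, 9, Rd = 0.73)), 26.27)
  expect_equal(assimilation_tpu(fvcb_params(100, 150, 10, Rd = 0)), 30)
  expect_equal(assimilation_tpu(fvcb_params(100, 150, 0.73 / 3, Rd = 0.73)), 0)

  expect_error(assimilation_rubisco(-1, pdef), "non-negative")
  expect_error(assimilation_rubp(300, -5, pdef), "non-negative")
})

test_that("minimum rule selects the smallest branch with ordered ties", {
  k <- kinetic_constants()
  set.seed(11)
  for (i in 1:25) {
    p <- fvcb_params(Vcmax = runif(1, 40, 140), Jmax = runif(1, 60, 220),
                     TPU = runif(1, 4, 14), Rd = runif(1, 0.2, 1.5),
                     gm = Inf, Gammastar = runif(1, 30, 45))
    Cc <- sort(runif(8, 5, 1500))
    m <- model_assimilation(Cc, p, k)
    expect_true(all(m$An <= assimilation_rubisco(Cc, p, k) + 1e-12))
    expect_true(all(m$An <= assimilation_rubp(Cc, p$Jmax, p) + 1e-12))
    expect_true(all(m$An <= assimilation_tpu(p) + 1e-12))
    # non-decreasing in Cc
    expect_true(all(diff(m$An) >= -1e-9))
  }
})

test_that("operating point satisfies the coupled system and matches bisection", {
  k <- kinetic_constants()
  p <- walnut_truth()
  # gm = Inf: no drawdown
  pinf <- fvcb_params(p$Vcmax, p$Jmax, p$TPU, p$Rd, Inf, p$Gammastar)
  op <- solve_operating_point(c(100, 300, 900), pinf, k)
  expect_equal(op$Cc, c(100, 300, 900))

  # fixed-point residual < 1e-9 relative on a grid and random params
  set.seed(21)
  for (i in 1:20) {
    pr <- fvcb_params(Vcmax = runif(1, 40, 140), Jmax = runif(1, 80, 220),
                      TPU = runif(1, 5, 14), Rd = runif(1, 0.2, 1.5),
                      gm = runif(1, 0.05, 0.6), Gammastar = runif(1, 30, 45))
    Ci <- sort(runif(6, 60, 1400))
    op <- solve_operating_point(Ci, pr, k)
    model_an <- model_assimilation(op$Cc, pr, k)$An
    expect_true(all(abs(model_an - op$An) < 1e-9 * pmax(1, abs(op$An))))
  }

  # independent bisection oracle at the spec'd configuration
  an_oracle <- bisection_operating_point(300, p, k)
  expect_equal(solve_operating_point(300, p, k)$An, an_oracle,
               tolerance = 1e-9)
})

test_that("noiseless self-generated curves are recovered to 0.1 percent", {
  p <- walnut_truth()
  cv <- simulate_gas_exchange(sim_spec(p, gs = 0.3, noise_sd = 0, seed = 5))
  ft <- fit_aci(cv)
  expect_lt(abs(ft$params$Vcmax - p$Vcmax) / p$Vcmax, 1e-3)
  expect_lt(abs(ft$params$Jmax - p$Jmax) / p$Jmax, 1e-3)
  expect_lt(abs(ft$params$TPU - p$TPU) / p$TPU, 1e-3)
  expect_lt(abs(ft$params$gm - p$gm) / p$gm, 1e-3)
  expect_lt(ft$diagnostics$sse, 1e-12)
  # labels are non-decreasing in the rubisco -> rubp -> tpu order
  lv <- c(rubisco = 1, rubp_regeneration = 2, tpu = 3)[ft$assignment$labels]
  expect_true(all(diff(lv) >= 0))
})

test_that("fitted gm agrees with the fluorescence-method gm on shared data", {
  p <- walnut_truth()
  cv <- simulate_gas_exchange(sim_spec(p, gs = 0.3, noise_sd = 0, seed = 9))
  ft <- fit_aci(cv)
  ok <- !is.na(cv$PhiPSII) & cv$An > 0
  jf <- electron_transport(cv$PhiPSII[ok], cv$PPFD[ok])
  gm_flu <- gm_variable_j(cv$An[ok], cv$Ci[ok], jf)
  expect_true(all(abs(gm_flu - ft$params$gm) / ft$params$gm < 0.02))
})

test_that("underdetermined and degenerate fit inputs error cleanly", {
  p <- walnut_truth()
  cv <- simulate_gas_exchange(sim_spec(p, gs = 0.3, noise_sd = 0, seed = 2))
  expect_error(fit_aci(cv[1:3, ]), "insufficient data")
  expect_error(aci_curve(data.frame(Ca = 400, Ci = -5, An = 10)), "positive")
})

test_that("Amax is the TPU plateau, shuffle-invariant, and flagged without one", {
  expect_equal(as.numeric(amax(fvcb_params(100, 150, 9.08, Rd = 0.73))), 26.51)

  p <- walnut_truth()
  cv <- simulate_gas_exchange(sim_spec(p, gs = 0.3, noise_sd = 0, seed = 4))
  ft1 <- fit_aci(cv)
  shuffled <- cv[c(7, 2, 11, 4, 12, 6, 1, 8, 3, 10, 5, 9), ]
  ft2 <- fit_aci(shuffled)
  expect_equal(as.numeric(amax(ft1)), as.numeric(amax(ft2)), tolerance = 1e-9)
  expect_equal(as.numeric(amax(ft1)), 3 * 9.08 - 0.73, tolerance = 1e-4)

  # TPU so high that the plateau is never reached -> flagged estimate
  phi <- fvcb_params(100, 150, 20, Rd = 0.73, gm = 0.2)
  cvhi <- simulate_gas_exchange(sim_spec(phi, gs = 0.3, noise_sd = 0, seed = 3))
  fthi <- fit_aci(cvhi)
  expect_warning(a <- amax(fthi), "extrapolation")
  expect_true(attr(a, "flagged"))
})

test_that("reference-Ca interpolation converts pressure and refuses extrapolation", {
  expect_equal(40.4 / 101325 * 1e6, 398.7171, tolerance = 1e-4)
  cv <- data.frame(Ca = c(390, 410), Ci = c(300, 320), An = c(14, 16))
  expect_equal(an_at_reference_ca(cv, 400, units = "umol/mol"), 15)
  # a knot point is returned unchanged
  cv2 <- data.frame(Ca = c(380, 398.7171, 420), Ci = c(1, 2, 3),
                    An = c(10, 12.5, 14))
  expect_equal(an_at_reference_ca(cv2, 40.4), 12.5, tolerance = 1e-3)
  expect_error(an_at_reference_ca(data.frame(Ca = c(500, 700), An = c(1, 2)),
                                  40.4), "outside")
})

test_that("leak correction is additive in the CO2 gradient", {
  cv <- data.frame(Ca = c(400, 1500), Ci = c(300, 1200), An = c(15, 25))
  expect_equal(leak_correct(cv, 0)$An, cv$An)                 # identity
  expect_equal(leak_correct(cv, 1e-4)$An[1], 15)              # no gradient
  expect_equal(leak_correct(cv, 1e-4)$An[2], 25 + 0.11)       # 1e-4 * 1100
  # coefficient recovered from an empty-chamber calibration
  ca <- seq(100, 1500, by = 200)
  flux <- -2e-4 * (ca - 400)
  expect_equal(estimate_leak(ca, flux), 2e-4)
})
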