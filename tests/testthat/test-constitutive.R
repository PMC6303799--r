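test_that("wave speed follows the wall-stiffness law", {
  blood <- blood_properties()
  ## hand evaluations of c_d = sqrt((2/3rho) [k1 exp(k2 r) + k3])
  expect_equal(wave_speed(1.0, wall_law("systemic"), blood), 460.63, tolerance = 1e-4)
  expect_equal(wave_speed(0.2, wall_law("coronary"), blood), 826.90, tolerance = 1e-4)
  ## k1 = 0 limit: radius-independent speed sqrt(2 k3 / (3 rho))
  lw <- wall_law("systemic", k1 = 0)
  expect_equal(wave_speed(0.3, lw, blood), wave_speed(1.7, lw, blood))
  expect_equal(wave_speed(0.5, lw, blood), sqrt(2 * lw$k3 / (3 * blood$rho)))
  expect_error(wave_speed(-1, wall_law("systemic"), blood), "positive")
  ## independent closed-form oracle agrees
  for (r in c(0.1, 0.5, 1.2))
    expect_equal(wave_speed(r, wall_law("systemic"), blood),
                 oracle_linear_wave_speed(r, wall_law("systemic"), blood))
})

test_that("tube law inverts exactly and is consistent with the wave speed", {
  blood <- blood_properties()
  law <- wall_law("systemic")
  set.seed(1)
  for (i in 1:100) {
    r <- runif(1, 0.05, 1.5)
    Ad <- pi * r^2
    beta <- tube_beta(r, law)
    Pd <- mmHg_to_dyn(runif(1, 60, 100))
    A <- Ad * runif(1, 0.7, 1.5)
    P <- tube_law(A, Ad, beta, Pd)
    expect_equal(tube_law_area(P, Ad, beta, Pd), A, tolerance = 1e-12)
    ## rho c_d^2 = A_d dP/dA at the diastolic state (finite difference)
    h <- 1e-6 * Ad
    dPdA <- (tube_law(Ad + h, Ad, beta, Pd) - tube_law(Ad - h, Ad, beta, Pd)) / (2 * h)
    expect_equal(blood$rho * wave_speed(r, law, blood)^2, Ad * dPdA,
                 tolerance = 1e-6)
  }
  expect_equal(tube_law(0.5, 0.5, 1e5, 1000), 1000)  # reference state
  expect_error(tube_law(-0.1, 0.5, 1e5, 1000), "positive")
  expect_error(tube_law_area(-1e9, 0.5, 1e5, 1000), "collapse")
})

test_that("viscous resistance matches the Poiseuille-type closed form", {
  blood <- blood_properties()
  A <- 0.5; l <- 10; r <- sqrt(A / pi)
  seg <- arterial_segment("a", l, r, r, "x", "y")
  Rv <- segment_viscous_resistance(seg, blood)
  expect_equal(Rv, 22 * pi * blood$mu * l / A^2, tolerance = 1e-12)
  expect_equal(Rv * 5, oracle_poiseuille_drop(5, l, A, blood))  # dP at Q = 5
  ## degenerate length
  seg0 <- arterial_segment("b", 1e-9, r, r, "x", "y")
  expect_lt(segment_viscous_resistance(seg0, blood), 1e-6)
  ## tapered vessel vs dense-trapezoid oracle at 10x resolution
  segt <- arterial_segment("c", 8, 0.9, 0.45, "x", "y")
  dense <- segment_viscous_resistance(segt, blood, n = 640)
  ## composite trapezoid: O(h^2), ~3e-4 relative at 64 intervals on this taper
  expect_equal(segment_viscous_resistance(segt, blood, n = 64), dense,
               tolerance = 1e-3)
})

test_that("volume compliance matches closed forms and is additive", {
  blood <- blood_properties()
  A <- 0.5; l <- 10; r <- sqrt(A / pi)
  cd <- 460.6328
  beta <- 2 * blood$rho * sqrt(A) * cd^2   # beta chosen so c_d = 460.63
  seg <- arterial_segment("a", l, r, r, "x", "y", beta = beta)
  expect_equal(segment_volume_compliance(seg, blood), A * l / (blood$rho * cd^2),
               tolerance = 1e-10)
  expect_equal(segment_volume_compliance(seg, blood), 2.223e-5, tolerance = 1e-3)
  ## split-and-sum additivity on a tapered vessel
  segt <- arterial_segment("t", 6, 1.0, 0.5, "x", "y")
  h1 <- arterial_segment("t1", 3, 1.0, 0.75, "x", "m")
  h2 <- arterial_segment("t2", 3, 0.75, 0.5, "m", "y")
  expect_equal(segment_volume_compliance(segt, blood, n = 128),
               segment_volume_compliance(h1, blood, n = 64) +
                 segment_volume_compliance(h2, blood, n = 64),
               tolerance = 1e-6)
})

test_that("stenosis descriptors enforce geometry and evaluate the loss law", {
  expect_error(stenosis_descriptor("s", 1, 1, A0 = 0.5, As = 0.6), "As < A0")
  st <- stenosis_descriptor("s", 1, 1, A0 = 0.5, As = 0.125,
                            K_visc = 100, K_exp = 10)
  expect_equal(stenosis_pressure_loss(0, st), 0)
  expect_equal(stenosis_pressure_loss(5, st), 750)  # 100*5 + 10*25
  ## antisymmetry of the quadratic law: loss opposes the flow direction
  Q <- seq(-10, 10, by = 0.5)
  dp <- stenosis_pressure_loss(Q, st)
  expect_equal(dp, -rev(dp))
  expect_true(all(sign(dp[Q != 0]) == sign(Q[Q != 0])))
  ## geometric coefficient rule produces positive coefficients
  k <- stenosis_coefficients(A0 = 0.5, As = 0.125, length_s = 1)
  expect_gt(k$K_visc, 0); expect_gt(k$K_exp, 0)
})
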