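test_that("WK3 pressure response reproduces closed-form limits", {
  T_per <- 0.8; n <- 1000
  t <- (0:(n - 1)) * T_per / n
  ## constant flow: P = P_out + (R1+R2) Q0
  Qc <- periodic_waveform(t, rep(4, n), T_per)
  P <- wk3_pressure_response(Qc, 150, 8e-4, 1400, mmHg_to_dyn(5))
  expect_equal(P$values, rep(mmHg_to_dyn(5) + 1550 * 4, n), tolerance = 1e-10)
  ## C -> infinity: pulsatile part passes through R1 only
  Qp <- periodic_waveform(t, 10 + 3 * sin(2 * pi * t / T_per), T_per)
  Pinf <- wk3_pressure_response(Qp, 150, 1e3, 1400, mmHg_to_dyn(5))
  expect_lt(max(abs((Pinf$values - mean(Pinf$values)) - 150 * (Qp$values - 10))),
            1)
  ## zero inflow from a displaced state: exact exponential decay
  Q0 <- periodic_waveform(t, rep(0, n), T_per)
  P0 <- mmHg_to_dyn(100); Pout <- mmHg_to_dyn(5)
  Pd <- wk3_pressure_response(Q0, 150, 8e-4, 1400, Pout,
                              Pc0 = P0, max_cycles = 1)
  expect_equal(Pd$values, oracle_wk_decay(t, P0, Pout, 1400, 8e-4),
               tolerance = 1e-10)
})

test_that("ODE response matches the closed-form WK3 impedance", {
  T_per <- 0.8; n <- 1000
  t <- (0:(n - 1)) * T_per / n
  set.seed(7)
  for (rep in 1:20) {
    R1 <- runif(1, 50, 500); R2 <- runif(1, 500, 4000)
    C <- 10^runif(1, -4, -2.5)
    for (k in 1:5) {
      w <- 2 * pi * k / T_per
      Q <- periodic_waveform(t, 10 + 2 * sin(w * t), T_per)
      P <- wk3_pressure_response(Q, R1, C, R2, mmHg_to_dyn(5))
      zs <- input_impedance(P, Q, n_harmonics = 6)
      Zth <- oracle_wk3_impedance(w, R1, C, R2)
      row <- which.min(abs(zs$frequency - k / T_per))
      expect_lt(abs(zs$modulus[row] - Mod(Zth)) / Mod(Zth), 1e-3)
      expect_lt(abs(zs$phase[row] - Arg(Zth)) * 180 / pi, 0.5)
    }
  }
})

test_that("fitting recovers known WK3 parameters from noiseless data", {
  T_per <- 0.8; n <- 1000
  t <- (0:(n - 1)) * T_per / n
  Q <- periodic_waveform(t, 60 + 40 * sin(2 * pi * t / T_per) +
                           15 * sin(4 * pi * t / T_per + 1) +
                           5 * sin(6 * pi * t / T_per + 2), T_per)
  Rt <- 1200; ratio_true <- 0.12; C_true <- 9e-4
  R1t <- Rt * ratio_true / (1 + ratio_true)
  Pb <- wk3_pressure_response(Q, R1t, C_true, Rt - R1t, mmHg_to_dyn(5))
  fit <- fit_wk3(Q, Pb, mmHg_to_dyn(5), init = list(R1 = 300, C = 3e-4))
  expect_lt(abs(fit$theta[1] - ratio_true) / ratio_true, 0.01)
  expect_lt(abs(fit$theta[2] - C_true) / C_true, 0.01)
  expect_lt(fit$objective, 1e-6)
  ## total-resistance constraint holds exactly (the fixed total comes from
  ## the baseline time averages, which match Rt to the ODE drift tolerance)
  expect_equal(fit$R1 + fit$R2, fit$R_tot, tolerance = 1e-12)
  expect_equal(fit$R_tot, Rt, tolerance = 1e-6)
  ## objective never increases relative to the initial guess
  expect_lte(fit$objective, fit$objective_initial)
  ## fixed point: starting at the truth leaves the objective at its optimum
  fit2 <- fit_wk3(Q, Pb, mmHg_to_dyn(5), init = list(R1 = R1t, C = C_true))
  expect_lt(fit2$objective, 1e-8)
  expect_lte(fit2$objective, fit2$objective_initial)
  ## nested-model inequality: C-only fit cannot beat the full subset
  fitC <- fit_wk3(Q, Pb, mmHg_to_dyn(5), init = list(R1 = 300, C = 3e-4),
                  subset = "C")
  expect_equal(fitC$R1 / fitC$R2, 300 / (fitC$R_tot - 300), tolerance = 1e-9)
  expect_gte(fitC$objective + 1e-12, fit$objective)
})

test_that("Method 2 reduction fits the cut faces and beats Method 1", {
  net <- make_fixture("binary_tree", 3)
  ss <- solve_steady(net)
  cfg <- solver_config(max_cycles = 15)
  keep <- c("s1", "s2", "s3")
  sites <- list(list(seg = "s1", pos = 0), list(seg = "s2", pos = 1))
  rb <- run_simulation(net, cfg, sites = sites)
  ## retain-all is the identity
  expect_equal(reduce_with_method2(net, rb, names(net$segments), ss = ss), net)
  red1 <- truncate_network(net, ss, keep)
  red2 <- reduce_with_method2(net, rb, keep, ss = ss, config = cfg)
  fits <- attr(red2, "fits")
  expect_length(fits, 2)
  for (f in fits) expect_lte(f$objective, f$objective_initial)
  ## fitted R1 at systemic cut faces stays below Z_c on this fixture
  zc <- characteristic_impedance(net, ss, "s2", 1)
  expect_lt(fits[[1]]$R1, zc)
  ## distal-site error ordering between the methods
  rr1 <- run_simulation(red1, cfg, sites = sites)
  rr2 <- run_simulation(red2, cfg, sites = sites)
  Pb <- sim_wave(rb, "s2", 1, "P")
  e1 <- eps_avg(Pb, sim_wave(rr1, "s2", 1, "P"))
  e2 <- eps_avg(Pb, sim_wave(rr2, "s2", 1, "P"))
  expect_lte(e2, e1)
})
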