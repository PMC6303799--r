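test_that("constant inflow settles to the series-resistance steady state", {
  net <- const_flow_vessel(Q0 = 5)
  res <- run_simulation(net, solver_config(max_cycles = 20),
                        sites = list(list(seg = "v", pos = 0)))
  expect_true(res$converged)
  P_in <- wave_mean(sim_wave(res, "v", 0, "P"))
  Rv <- segment_viscous_resistance(net$segments$v, net$blood)
  p <- net$boundaries[[2]]$params
  P_expect <- p$P_out + (p$R1 + p$R2 + Rv) * 5
  expect_equal(P_in, P_expect, tolerance = 0.01)
})

test_that("zero inflow at the reference pressure is an exact equilibrium", {
  blood <- blood_properties()
  t <- (0:199) / 200
  zero <- periodic_waveform(t, rep(0, 200), 1)
  seg <- arterial_segment("v", 10, 1, 0.8, "a", "b", p_dia = mmHg_to_dyn(80))
  net <- vascular_network(
    list(seg),
    list(boundary_condition("a", "inflow_Q", wave = zero),
         boundary_condition("b", "wk3", R1 = 100, C = 1e-3, R2 = 1500,
                            P_out = mmHg_to_dyn(80))),
    blood = blood)
  res <- run_simulation(net, solver_config(max_cycles = 2),
                        sites = list(list(seg = "v", pos = 0.5)))
  expect_equal(max(abs(sim_wave(res, "v", 0.5, "P")$values - mmHg_to_dyn(80))), 0)
  expect_equal(max(abs(sim_wave(res, "v", 0.5, "Q")$values)), 0)
})

test_that("a small pulse travels at the linear diastolic wave speed", {
  pv <- pulse_vessel()
  res <- run_simulation(pv$net, solver_config(max_cycles = 1, n_out = 4000),
                        sites = list(list(seg = "v", pos = 0.125),
                                     list(seg = "v", pos = 0.875)))
  dt_ff <- foot_time(sim_wave(res, "v", 0.875, "P")) -
    foot_time(sim_wave(res, "v", 0.125, "P"))
  expect_equal(dt_ff, 30 / pv$cd, tolerance = 0.03)
})

test_that("a matched (R1 = Z_c) outlet absorbs the incident pulse", {
  pv <- pulse_vessel()
  res <- run_simulation(pv$net, solver_config(max_cycles = 1, n_out = 4000),
                        sites = list(list(seg = "v", pos = 0.5)))
  Pm <- sim_wave(res, "v", 0.5, "P")
  v <- Pm$values - Pm$values[1]
  a_i <- max(v)
  t_r <- pv$t0 + 60 / pv$cd       # outlet echo revisits the midpoint
  win <- Pm$t > t_r - 0.03 & Pm$t < t_r + 0.06
  expect_lt(max(abs(v[win])) / a_i, 0.02)
})

test_that("junctions conserve mass and respect symmetry", {
  net <- make_fixture("binary_tree", 2)
  res <- run_simulation(net, solver_config(max_cycles = 12),
                        sites = list(list(seg = "s2", pos = 0.5),
                                     list(seg = "s3", pos = 0.5)))
  expect_true(res$converged)
  expect_lt(res$diagnostics$mass_defect, 1e-8 * res$diagnostics$maxQ)
  Q2 <- sim_wave(res, "s2", 0.5, "Q")$values
  Q3 <- sim_wave(res, "s3", 0.5, "Q")$values
  expect_lt(max(abs(Q2 - Q3)) / max(abs(Q2)), 1e-10)
})

test_that("a cycle of the converged solution balances volumes", {
  net <- make_fixture("binary_tree", 3)
  res <- run_simulation(net, solver_config(max_cycles = 15))
  expect_true(res$converged)
  v_in <- wave_integral(sim_wave(res, "s1", 0, "Q"))
  v_out <- sum(vapply(4:7, function(k)
    wave_integral(sim_wave(res, paste0("s", k), 1, "Q")), 0))
  SV <- wave_integral(inflow_boundary(net)$params$wave)
  expect_lt(abs(v_in - v_out), 0.005 * SV)
  ## all output sites wrap periodically within tolerance x pulse pressure
  for (j in seq_along(res$P)) {
    pp <- diff(range(res$P[[j]]$values))
    expect_lt(res$diagnostics$wrap_gap[j], 5 * res$periodicity_residual * pp +
                1e-3 * pp)
  }
})

test_that("halving the grid spacing changes waveforms marginally", {
  net <- make_fixture("binary_tree", 2)
  s <- list(list(seg = "s1", pos = 0))
  r1 <- run_simulation(net, solver_config(dx_target = 0.25, max_cycles = 15), sites = s)
  r2 <- run_simulation(net, solver_config(dx_target = 0.125, max_cycles = 15), sites = s)
  P1 <- sim_wave(r1, "s1", 0, "P")$values
  P2 <- sim_wave(r2, "s1", 0, "P")$values
  expect_lt(max(abs(P1 - P2)) / diff(range(P1)), 0.005)
})

test_that("stenosis junctions impose the quadratic pressure loss", {
  net <- insert_coarctation(const_flow_vessel(Q0 = 20), "v", 1, 0.3)
  st <- net$stenoses[[1]]
  res <- run_simulation(net, solver_config(max_cycles = 20),
                        sites = list(list(seg = "v", pos = 0.35),
                                     list(seg = "v", pos = 0.65)))
  expect_true(res$converged)
  drop <- wave_mean(sim_wave(res, "v", 0.35, "P")) -
    wave_mean(sim_wave(res, "v", 0.65, "P"))
  ## the empirical loss dominates the small viscous drop between the sites
  dp_sten <- stenosis_pressure_loss(20, st)
  dp_visc <- oracle_poiseuille_drop(20, 3 - st$length_s, pi, net$blood)
  expect_equal(drop, dp_sten + dp_visc, tolerance = 0.1)
})

test_that("coronary outlets impede systolic flow via the LV pressure source", {
  net <- make_fixture("toy_coronary")
  share_sys <- function(g) {
    n2 <- net
    for (i in 2:3) n2$boundaries[[i]]$params$gamma_im <- g
    res <- run_simulation(n2, solver_config(max_cycles = 10),
                          sites = list(list(seg = "cor_side", pos = 1)))
    Q <- sim_wave(res, "cor_side", 1, "Q")
    sys <- Q$t < 0.35 * Q$period
    mean(Q$values[sys]) / mean(Q$values)
  }
  s0 <- share_sys(0); s1 <- share_sys(1); s2 <- share_sys(2)
  ## with the LV source the systolic mean drops below the cycle mean even
  ## though the driving pressure peaks in systole; without it, it exceeds it
  expect_lt(s1, 1)
  expect_gt(s0, 1)
  ## doubling gamma_im monotonically decreases the systolic share
  expect_gt(s0, s1)
  expect_gt(s1, s2)
})

test_that("hyperaemia lowers FFR across a coronary stenosis", {
  net <- make_fixture("toy_coronary")
  sites <- list(list(seg = "cor_root", pos = 0), list(seg = "cor_sten", pos = 1))
  cfg <- solver_config(max_cycles = 12)
  rest <- run_simulation(net, cfg, sites = sites)
  hyp <- run_simulation(set_hyperaemia(net, diseased_outlets = "nS"), cfg,
                        sites = sites)
  ffr_rest <- ffr(sim_wave(rest, "cor_root", 0, "P"),
                  sim_wave(rest, "cor_sten", 1, "P"))
  ffr_hyp <- ffr(sim_wave(hyp, "cor_root", 0, "P"),
                 sim_wave(hyp, "cor_sten", 1, "P"))
  ## higher hyperaemic flow drives a larger quadratic stenosis loss
  expect_lt(ffr_hyp, ffr_rest)
  expect_gt(ffr_hyp, 0.5); expect_lt(ffr_rest, 1)
})

test_that("CFL and collapse guards abort with diagnostics", {
  net <- const_flow_vessel()
  expect_error(run_simulation(net, solver_config(dt_override = 5e-3)), "CFL")
})
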