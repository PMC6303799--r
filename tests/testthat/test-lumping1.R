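test_that("steady solve reproduces series-resistance closed forms", {
  net <- const_flow_vessel(Q0 = 5)
  ss <- solve_steady(net)
  p <- net$boundaries[[2]]$params
  Rv <- pulsetrim:::steady_seg_RvCv(net, ss, "v")$Rv
  P_in <- steady_state_at(net, ss, "v", 0)$P
  expect_equal(P_in, p$P_out + (Rv + p$R1 + p$R2) * 5, tolerance = 1e-10)
  ## lumped resistance at the inlet equals the full series chain
  expect_equal(lumped_resistance(net, ss, "v", 0, p$P_out), Rv + p$R1 + p$R2,
               tolerance = 1e-10)
  expect_equal(lumped_resistance(net, ss, "v", 1, p$P_out), p$R1 + p$R2,
               tolerance = 1e-8)
})

test_that("steady solve matches the independent nodal-analysis oracle", {
  check_net <- function(net) {
    ss <- solve_steady(net, areas = "frozen", include_dynamic = FALSE)
    edges <- do.call(rbind, lapply(net$segments, function(s)
      data.frame(from = s$from_node, to = s$to_node,
                 R = segment_viscous_resistance(s, net$blood), id = s$id)))
    outs <- do.call(rbind, lapply(
      Filter(function(b) b$variant == "wk3", net$boundaries), function(b)
        data.frame(node = b$node, R = b$params$R1 + b$params$R2,
                   P_out = b$params$P_out)))
    orc <- oracle_nodal_analysis(edges, outs, inflow_boundary(net)$node,
                                 wave_mean(inflow_boundary(net)$params$wave))
    Qss <- vapply(edges$id, function(id) ss$segments[[id]]$Q, 0)
    max(abs(Qss - orc$Q_edges) / max(abs(orc$Q_edges)))
  }
  for (s in 1:20) expect_lt(check_net(random_tree_fixture(s)), 1e-8)
  ## a looped network (flow can route around the ring)
  expect_lt(check_net(make_fixture("ring_with_outlets")), 1e-8)
})

test_that("symmetric trees carry equal sibling flows", {
  net <- make_fixture("binary_tree", 3)
  ss <- solve_steady(net)
  expect_equal(ss$segments$s2$Q, ss$segments$s3$Q, tolerance = 1e-10)
  expect_equal(ss$segments$s4$Q, ss$segments$s7$Q, tolerance = 1e-10)
  ## junction mass conservation
  expect_equal(ss$segments$s1$Q, ss$segments$s2$Q + ss$segments$s3$Q,
               tolerance = 1e-10)
  ## parallel-resistance bookkeeping at the bifurcation inlet (without the
  ## dynamic-pressure junction terms, static series/parallel algebra is exact)
  ssl <- solve_steady(net, include_dynamic = FALSE)
  p <- net$boundaries[[2]]$params
  Rv1 <- pulsetrim:::steady_seg_RvCv(net, ssl, "s1")$Rv
  Rv2 <- pulsetrim:::steady_seg_RvCv(net, ssl, "s2")$Rv
  Rv4 <- pulsetrim:::steady_seg_RvCv(net, ssl, "s4")$Rv
  path <- Rv2 + (Rv4 + p$R1 + p$R2) / 2
  expect_equal(lumped_resistance(net, ssl, "s1", 0, p$P_out),
               Rv1 + path / 2, tolerance = 1e-6)
})

test_that("terminal equivalent compliance follows the printed combination", {
  ## hand evaluation: C_v=0.1, C=1, R1=0.1, R2=1, R_v=0.05 -> 1.115/1.15
  expect_equal(terminal_compliance_wk3(0.1, 0.05, 0.1, 1.0, 1.0),
               1.115 / 1.15, tolerance = 1e-12)
  ## limiting case C_v = 0, R_v = 0: C R2/(R1+R2)
  expect_equal(terminal_compliance_wk3(0, 0, 0.1, 1.0, 1.0), 1.0 / 1.1,
               tolerance = 1e-12)
  ## coronary terminal: plain sum of compliances
  netc <- make_fixture("toy_coronary")
  ssc <- solve_steady(netc)
  rc <- pulsetrim:::steady_seg_RvCv(netc, ssc, "cor_side")
  p <- netc$boundaries[[3]]$params
  expect_equal(pulsetrim:::terminal_contribution(netc, ssc, "cor_side"),
               rc$Cv + p$C_a + p$C_m, tolerance = 1e-12)
})

test_that("characteristic impedance scales as rho c / A", {
  ## direct evaluation at a known mean state
  expect_equal(1.06 * 460.6 / 0.5, 976.5, tolerance = 1e-3)
  net <- make_fixture("single_vessel")
  ss <- solve_steady(net)
  st <- steady_state_at(net, ss, "s1", 1)
  expect_equal(characteristic_impedance(net, ss, "s1", 1),
               net$blood$rho * st$c / st$A, tolerance = 1e-12)
  ## diastolic vs mean state differ by less than 10% on the fixture
  Zc_dia <- net$blood$rho * wave_speed(1, wall_law("systemic"), net$blood) / pi
  expect_lt(abs(characteristic_impedance(net, ss, "s1", 1) - Zc_dia) / Zc_dia,
            0.10)
})

test_that("truncation preserves steady inlet pressure and total compliance", {
  net <- make_fixture("binary_tree", 3)
  ss <- solve_steady(net)
  ## retain everything: identity
  expect_equal(truncate_network(net, ss, names(net$segments)), net)
  for (keep in list("s1", c("s1", "s2", "s3"),
                    c("s1", "s2", "s3", "s4", "s5"))) {
    red <- truncate_network(net, ss, keep)
    ssr <- solve_steady(red)
    expect_equal(steady_state_at(red, ssr, "s1", 0)$P,
                 steady_state_at(net, ss, "s1", 0)$P, tolerance = 1e-6)
    ## compliance bookkeeping oracle: reduced total = baseline total minus,
    ## per removed segment, the difference between its naive contribution
    ## (diastolic C_v plus outlet C) and its lumped contribution (terminal
    ## combination rule or mean-state C_v)
    removed <- setdiff(names(net$segments), keep)
    deficit <- sum(vapply(removed, function(id) {
      rc <- pulsetrim:::steady_seg_RvCv(net, ss, id)
      cv_dia <- segment_volume_compliance(net$segments[[id]], net$blood)
      ct <- pulsetrim:::terminal_contribution(net, ss, id)
      if (is.null(ct)) return(cv_dia - rc$Cv)
      bc <- Filter(function(b) b$node == net$segments[[id]]$to_node,
                   net$boundaries)[[1]]
      cv_dia + bc$params$C - ct
    }, 0))
    expect_equal(total_compliance(red), total_compliance(net) - deficit,
                 tolerance = 1e-6)
  }
  ## cutting where lumped resistance does not exceed Z_c is rejected
  blood <- blood_properties()
  t <- (0:199) / 200
  wave <- periodic_waveform(t, rep(5, 200), 1)
  chain <- vascular_network(
    list(arterial_segment("a", 5, 1, 1, "n0", "n1"),
         arterial_segment("b", 5, 1, 1, "n1", "n2")),
    list(boundary_condition("n0", "inflow_Q", wave = wave),
         boundary_condition("n2", "wk3", R1 = 50, C = 1e-3, R2 = 40,
                            P_out = mmHg_to_dyn(80))),
    blood = blood)
  ss2 <- solve_steady(chain)
  expect_error(truncate_network(chain, ss2, "a"), "retain more vessels")
})

test_that("reducing a symmetric tree keeps the pulsatile root waveform close", {
  net <- make_fixture("binary_tree", 3)
  ss <- solve_steady(net)
  cfg <- solver_config(max_cycles = 15)
  sites <- list(list(seg = "s1", pos = 0))
  rb <- run_simulation(net, cfg, sites = sites)
  red <- truncate_network(net, ss, c("s1", "s2", "s3"))
  rr <- run_simulation(red, cfg, sites = sites)
  Pb <- sim_wave(rb, "s1", 0, "P"); Pr <- sim_wave(rr, "s1", 0, "P")
  ## mean root pressure reproduced almost exactly (resistance preserved)
  expect_equal(wave_mean(Pr), wave_mean(Pb), tolerance = 2e-3)
  ## pulse pressure within 10%
  pp_b <- diff(range(Pb$values)); pp_r <- diff(range(Pr$values))
  expect_lt(abs(pp_r - pp_b) / pp_b, 0.10)
})
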