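test_that("ageing rescales stiffness, resistance and compliance by construction", {
  net <- make_fixture("binary_tree", 3)
  net$meta$proximal_ids <- "s1"
  aged <- apply_ageing(net)
  ## enforced ratios
  expect_equal(total_compliance(aged) / total_compliance(net), 0.5,
               tolerance = 1e-6)
  expect_equal(pulsetrim:::total_outlet_resistance(aged) /
                 pulsetrim:::total_outlet_resistance(net), 1.1,
               tolerance = 1e-6)
  ## declared proximal segments stiffen 2.5x, the rest 1.5x
  expect_equal(aged$segments$s1$beta_scale, 2.5)
  expect_equal(aged$segments$s5$beta_scale, 1.5)
  expect_equal(pulsetrim:::segment_beta(aged$segments$s1, 0.5),
               2.5 * pulsetrim:::segment_beta(net$segments$s1, 0.5))
  ## purity: the input network is untouched
  expect_equal(net$segments$s1$beta_scale, 1)
  expect_error(apply_ageing(make_fixture("toy_coronary")), "WK3")
})

test_that("coarctation insertion follows the geometric rule", {
  net <- make_fixture("single_vessel")
  net2 <- insert_coarctation(net, "s1", 1, 0.5)
  st <- net2$stenoses[[1]]
  expect_equal(st$As / st$A0, 0.25)               # (d/D)^2
  expect_equal(st$x_start + st$length_s / 2, net$segments$s1$length / 2)
  expect_gt(st$K_visc, 0); expect_gt(st$K_exp, 0)
  ## no constriction -> no stenosis element
  expect_length(insert_coarctation(net, "s1", 1, 1.0)$stenoses, 0)
  expect_error(insert_coarctation(net, "s1", 20, 0.5), "fit")
  expect_length(net$stenoses, 0)                  # purity
})

test_that("inflow rescaling hits HR/ET/SV targets and round-trips", {
  w <- synthetic_inflow(60, 0.3, 70)
  ## the two reported physiological extremes
  for (par in list(c(56, 0.315, 106), c(120, 0.2, 44))) {
    w2 <- rescale_inflow(w, par[1], par[2], par[3])
    expect_equal(wave_integral(w2), par[3], tolerance = 1e-9)
    expect_equal(w2$period, 60 / par[1])
    ## zero flow outside ejection
    expect_equal(max(w2$values[w2$t > 0.02 + par[2]]), 0)
  }
  ## identity parameters reproduce the input within interpolation tolerance
  wi <- rescale_inflow(w, 60, 0.3, 70)
  expect_lt(max(abs(wi$values - w$values)) / max(w$values), 0.02)
  expect_error(rescale_inflow(w, 60, 1.2, 70), "shorter")
})

test_that("hyperaemia divides coronary outlet resistance preserving ratios", {
  net <- make_fixture("toy_coronary")
  p0 <- net$boundaries[[2]]$params
  ## alpha = 1 everywhere: identity
  same <- set_hyperaemia(net, 1, 1)
  expect_equal(same$boundaries[[2]]$params$R_a, p0$R_a)
  ## defaults: 3 healthy, 1.25 distal of the stenosis
  hyp <- set_hyperaemia(net, diseased_outlets = "nS")
  ps <- hyp$boundaries[[2]]$params   # nS outlet (diseased)
  ph <- hyp$boundaries[[3]]$params   # nH outlet (healthy)
  tot <- function(p) p$R_a + p$R_m + p$R_v_out
  expect_equal(tot(ps), tot(p0) / 1.25, tolerance = 1e-12)
  expect_equal(tot(ph), tot(net$boundaries[[3]]$params) / 3, tolerance = 1e-12)
  expect_equal(ps$R_a / ps$R_m, p0$R_a / p0$R_m, tolerance = 1e-12)
  ## total R halves then thirds as alpha goes 2 -> 3
  h2 <- set_hyperaemia(net, 2, 2)
  h3 <- set_hyperaemia(net, 3, 3)
  expect_equal(tot(h2$boundaries[[3]]$params), tot(net$boundaries[[3]]$params) / 2)
  expect_equal(tot(h3$boundaries[[3]]$params), tot(net$boundaries[[3]]$params) / 3)
  expect_error(set_hyperaemia(net, diseased_outlets = "nope"), "not found")
  expect_error(set_hyperaemia(make_fixture("single_vessel")), "coronary")
})

test_that("coronary outlet parameters distribute by Murray's law", {
  CO <- 90; Pp <- mmHg_to_dyn(93); Po <- mmHg_to_dyn(5)
  ## two equal radii: equal split, each outlet R = 2x the total
  d <- distribute_coronary_outlet_params(CO, Pp, Po, c(0.2, 0.2))
  expect_equal(d$Q[1], d$Q[2])
  R_tot <- (Pp - Po) / (0.045 * CO)
  expect_equal(d$R_total[1], 2 * R_tot, tolerance = 1e-12)
  ## radii 2:1 -> flows 8:1 (Murray exponent 3)
  d2 <- distribute_coronary_outlet_params(CO, Pp, Po, c(0.4, 0.2))
  expect_equal(d2$Q[1] / d2$Q[2], 8, tolerance = 1e-12)
  expect_equal(d2$C_total[1] / d2$C_total[2], 8, tolerance = 1e-12)
  expect_equal(sum(d2$Q), 0.045 * CO, tolerance = 1e-12)
  expect_error(distribute_coronary_outlet_params(CO, Pp, Po, c(0, 0.2)),
               "positive")
})
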