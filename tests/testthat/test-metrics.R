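test_that("average relative errors match hand computations", {
  expect_equal(eps_avg(c(100, 80), c(100, 80)), 0)
  expect_equal(eps_avg(c(100, 80), c(101, 79)), 0.01125)        # (1% + 1.25%)/2
  expect_equal(eps_avg(c(0, 10), c(1, 10), kind = "flow"), 0.05) # max-normalized
  expect_error(eps_avg(c(1, 0, 2), c(1, 1, 2)), "zero")
  expect_error(eps_avg(c(-3, -1), c(1, 1), kind = "flow"), "positive")
})

test_that("extrema errors match hand computations and offset behaviour", {
  b <- c(80, 95, 120, 100)
  r <- c(81, 96, 118, 99)
  e <- eps_extrema(b, r)
  expect_equal(unname(e["eps_P_sys"]), 2 / 120)
  expect_equal(unname(e["eps_P_dia"]), 1 / 80)
  expect_equal(unname(e["eps_PP"]), 3 / 40)
  ## a pure offset leaves PP untouched but shifts the systolic error
  e2 <- eps_extrema(b, b + 5)
  expect_equal(unname(e2["eps_PP"]), 0)
  expect_equal(unname(e2["eps_P_sys"]), 5 / 120)
  expect_error(eps_extrema(c(1, 1), c(1, 1)), "pulse pressure")
})

test_that("inflection detection matches an analytic two-Gaussian oracle", {
  T_per <- 1; n <- 1000
  t <- (0:(n - 1)) * T_per / n
  ## main systolic peak with an earlier shoulder bump
  p <- mmHg_to_dyn(80 + 40 * (exp(-(t - 0.30)^2 / (2 * 0.06^2)) +
                              0.35 * exp(-(t - 0.16)^2 / (2 * 0.03^2))))
  ## oracle: root of the analytic second derivative closest to the peak
  d2 <- function(tt) {
    g <- function(tt, mu, s, a) a * exp(-(tt - mu)^2 / (2 * s^2)) *
      (((tt - mu) / s^2)^2 - 1 / s^2)
    g(tt, 0.30, 0.06, 40) + g(tt, 0.16, 0.03, 14)
  }
  root <- stats::uniroot(d2, c(0.2, 0.28))$root
  w <- periodic_waveform(t, p, T_per)
  infl <- find_inflection(w)
  expect_true(infl$found)
  expect_lt(abs(t[infl$index] - root), 2 * T_per / n)
  ## identical waveforms and pure offsets give zero augmentation error
  expect_equal(eps_aug(w, w), 0)
  expect_equal(eps_aug(w, periodic_waveform(t, p + mmHg_to_dyn(7), T_per)), 0)
  ## featureless waveform: undefined, flagged, not zero
  flat <- periodic_waveform(t, mmHg_to_dyn(80 + 0.01 * sin(2 * pi * t)), T_per)
  a <- eps_aug(w, flat)
  expect_true(is.na(a) || a > 0)
})

test_that("iFR and FFR follow their windowed-mean definitions", {
  T_per <- 1; n <- 1000
  t <- (0:(n - 1)) * T_per / n
  Pp <- periodic_waveform(t, rep(mmHg_to_dyn(80), n), T_per)
  Pd <- periodic_waveform(t, rep(mmHg_to_dyn(60), n), T_per)
  expect_equal(ifr(Pp, Pp), 1)
  expect_equal(ifr(Pp, Pd), 0.75)
  expect_equal(ffr(Pp, Pd), 0.75)
  ## constant drop: 1 - d/mean(Pp)
  Pd2 <- periodic_waveform(t, Pp$values - mmHg_to_dyn(10), T_per)
  expect_equal(ffr(Pp, Pd2), 1 - 10 / 80, tolerance = 1e-12)
  ## iFR uses only the last 30% of the cycle by default
  v <- rep(mmHg_to_dyn(80), n)
  v[t < 0.7] <- mmHg_to_dyn(200)      # distorted outside the window
  expect_equal(ifr(periodic_waveform(t, v, T_per), Pd,
                   wave_free_fraction = 0.30), 0.75)
})

test_that("impedance spectra reduce to expected limits", {
  T_per <- 0.8; n <- 1000
  t <- (0:(n - 1)) * T_per / n
  ## constant P and Q: single DC point
  zs <- input_impedance(rep(100, n), rep(4, n), period = T_per)
  expect_equal(zs$modulus[1], 25)
  expect_equal(zs$phase[1], 0)
  expect_equal(nrow(zs), 1)     # flat signals carry no harmonic content
  ## DC phase is zero for any passive pair
  Q <- periodic_waveform(t, 10 + 2 * sin(2 * pi * t / T_per), T_per)
  P <- wk3_pressure_response(Q, 150, 8e-4, 1400, mmHg_to_dyn(5))
  zs2 <- input_impedance(P, Q)
  expect_equal(zs2$phase[zs2$frequency == 0], 0)
})

test_that("metrics are invariant under a common time shift", {
  T_per <- 1; n <- 1000
  t <- (0:(n - 1)) * T_per / n
  pb <- mmHg_to_dyn(90 + 20 * sin(2 * pi * t) + 5 * sin(4 * pi * t + 1))
  pr <- mmHg_to_dyn(90 + 19 * sin(2 * pi * t) + 6 * sin(4 * pi * t + 1.1))
  shift <- 137
  rot <- function(v) c(v[-(1:shift)], v[1:shift])
  expect_equal(eps_avg(pb, pr), eps_avg(rot(pb), rot(pr)))
  expect_equal(eps_extrema(pb, pr), eps_extrema(rot(pb), rot(pr)))
  wb <- periodic_waveform(t, pb, T_per); wr <- periodic_waveform(t, pr, T_per)
  wbs <- periodic_waveform(t, rot(pb), T_per)
  wrs <- periodic_waveform(t, rot(pr), T_per)
  expect_equal(eps_aug(wb, wr), eps_aug(wbs, wrs), tolerance = 1e-6)
  ## self-comparison is exactly zero for every metric
  expect_equal(eps_avg(wb, wb), 0)
  expect_equal(unname(eps_extrema(wb, wb)), c(0, 0, 0))
  expect_equal(eps_aug(wb, wb), 0)
  expect_equal(abs(ifr(wb, wb) - 1), 0)
  ## full report on identical waveforms
  rep0 <- compare_waveforms(wb, wb, wb, wb)
  expect_equal(rep0$eps_P_avg, 0)
  expect_equal(rep0$eps_Q_avg, 0)
})
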