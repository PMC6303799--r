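## Metrics accept either periodic_waveform objects or plain numeric vectors;
## the reduced series is resampled onto the baseline grid when needed.
metric_series <- function(x) {
  if (inherits(x, "periodic_waveform")) x$values else as.numeric(x)
}

metric_pair <- function(baseline, reduced) {
  b <- metric_series(baseline)
  if (inherits(reduced, "periodic_waveform") && length(reduced$values) != length(b))
    reduced <- wave_resample(reduced, length(b))
  r <- metric_series(reduced)
  if (length(r) != length(b))
    stop("baseline and reduced series must share a grid length")
  list(b = b, r = r)
}

#' Average relative waveform error
#'
#' Pressure: mean over the cycle of \eqn{|P^R_i - P^B_i| / |P^B_i|}.
#' Flow: mean of \eqn{|Q^R_i - Q^B_i| / \max_j Q^B_j} (normalized by the
#' baseline cycle maximum to avoid division near zero-crossings).
#'
#' @param baseline,reduced waveforms (\code{periodic_waveform} or numeric
#'   vectors on a common uniform grid); the reduced waveform is resampled to
#'   the baseline grid if needed.
#' @param kind \code{"pressure"} or \code{"flow"}.
#' @return the error as a dimensionless fraction.
#' @export
eps_avg <- function(baseline, reduced, kind = c("pressure", "flow")) {
  kind <- match.arg(kind)
  p <- metric_pair(baseline, reduced)
  if (kind == "pressure") {
    if (any(p$b == 0)) stop("relative pressure error undefined: baseline crosses zero")
    mean(abs(p$r - p$b) / abs(p$b))
  } else {
    qmax <- max(p$b)
    if (qmax <= 0) stop("flow error undefined: baseline cycle maximum is not positive")
    mean(abs(p$r - p$b) / qmax)
  }
}

#' Systolic, diastolic and pulse-pressure errors
#'
#' \eqn{\epsilon_{P,sys} = |P^B_{sys}-P^R_{sys}|/P^B_{sys}}, likewise for the
#' diastolic minimum, and \eqn{\epsilon_{PP} = |PP^B - PP^R| / PP^B} with
#' PP = P_sys - P_dia.
#'
#' @inheritParams eps_avg
#' @return named vector \code{c(eps_P_sys, eps_P_dia, eps_PP)} (fractions).
#' @export
eps_extrema <- function(baseline, reduced) {
  p <- metric_pair(baseline, reduced)
  sys_b <- max(p$b); dia_b <- min(p$b)
  sys_r <- max(p$r); dia_r <- min(p$r)
  pp_b <- sys_b - dia_b
  if (pp_b <= 0) stop("baseline pulse pressure is zero; eps_PP undefined")
  c(eps_P_sys = abs(sys_b - sys_r) / sys_b,
    eps_P_dia = abs(dia_b - dia_r) / dia_b,
    eps_PP = abs(pp_b - (sys_r - dia_r)) / pp_b)
}

#' Locate the early-systolic inflection point of a pressure waveform
#'
#' The cycle is rotated to start at the diastolic minimum; the waveform is
#' smoothed with a Savitzky-Golay filter (2nd-order polynomial,
#' \code{window}-point window) and the inflection is the last zero crossing
#' of the smoothed second derivative between the upstroke foot and the
#' systolic peak.
#'
#' @param w pressure waveform (\code{periodic_waveform} or numeric vector).
#' @param window Savitzky-Golay window length (odd).
#' @return list with \code{index} (into the original grid), \code{P_infl},
#'   and \code{found}; when no inflection exists \code{found} is FALSE and
#'   the values are NA (the metric is then undefined, not zero).
#' @export
find_inflection <- function(w, window = 7) {
  v <- metric_series(w)
  n <- length(v)
  i_min <- which.min(v)
  rot <- c(v[i_min:n], v[seq_len(i_min - 1)])
  i_pk <- which.max(rot)
  if (i_pk < 5) return(list(index = NA, P_infl = NA_real_, found = FALSE))
  sm <- signal::sgolayfilt(rot, p = 2, n = window)
  d2 <- c(NA, diff(diff(sm)), NA)
  lo <- 3; hi <- i_pk - 1
  if (hi <= lo) return(list(index = NA, P_infl = NA_real_, found = FALSE))
  sgn <- sign(d2[lo:hi])
  cross <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  if (!length(cross)) return(list(index = NA, P_infl = NA_real_, found = FALSE))
  i_rot <- lo + cross[length(cross)]     # last crossing before the peak
  idx <- ((i_rot + i_min - 2) %% n) + 1  # back to the original grid
  list(index = idx, P_infl = v[idx], found = TRUE)
}

#' Augmentation-pressure error
#'
#' The augmentation pressure of each waveform is P_sys minus the pressure at
#' the early-systolic inflection point; the error is the absolute difference
#' of augmentation pressures normalized by the baseline pulse pressure.
#'
#' @inheritParams eps_avg
#' @param window Savitzky-Golay window for inflection detection.
#' @return the error fraction, or NA (with attribute \code{undefined = TRUE})
#'   when an inflection cannot be located.
#' @export
eps_aug <- function(baseline, reduced, window = 7) {
  p <- metric_pair(baseline, reduced)
  ib <- find_inflection(p$b, window)
  ir <- find_inflection(p$r, window)
  if (!ib$found || !ir$found)
    return(structure(NA_real_, undefined = TRUE))
  pp_b <- max(p$b) - min(p$b)
  aug_b <- max(p$b) - ib$P_infl
  aug_r <- max(p$r) - ir$P_infl
  abs(aug_b - aug_r) / pp_b
}

#' Instantaneous wave-free ratio (iFR)
#'
#' Mean distal over mean proximal pressure across the diastolic wave-free
#' window, taken as the last \code{wave_free_fraction} of the cycle.
#'
#' @param P_proximal,P_distal synchronized pressure waveforms over one cycle.
#' @param wave_free_fraction fraction of the cycle forming the window
#'   (default 0.30, i.e. the last 30\%).
#' @return iFR (dimensionless).
#' @export
ifr <- function(P_proximal, P_distal, wave_free_fraction = 0.30) {
  p <- metric_pair(P_proximal, P_distal)
  n <- length(p$b)
  win <- seq.int(from = floor((1 - wave_free_fraction) * n) + 1, to = n)
  mp <- mean(p$b[win])
  if (mp <= 0) stop("mean proximal pressure in the wave-free window is not positive")
  mean(p$r[win]) / mp
}

#' Fractional flow reserve (FFR)
#'
#' Cycle-averaged distal over proximal pressure; meaningful under simulated
#' hyperaemia (see \code{\link{set_hyperaemia}}).
#'
#' @inheritParams ifr
#' @return FFR (dimensionless).
#' @export
ffr <- function(P_proximal, P_distal) {
  p <- metric_pair(P_proximal, P_distal)
  mp <- mean(p$b)
  if (mp <= 0) stop("mean proximal pressure is not positive")
  mean(p$r) / mp
}

#' Input impedance spectrum from one periodic cycle
#'
#' Harmonic-wise ratio of the discrete Fourier coefficients of pressure and
#' flow at multiples of 1/T; the DC point is mean(P)/mean(Q). Harmonics with
#' negligible flow content (|Q_k| below 1e-12 of the fundamental) are
#' omitted.
#'
#' @param P,Q synchronized \code{periodic_waveform}s (or numeric vectors
#'   sharing a grid, in which case \code{period} must be given).
#' @param period cycle duration (s) when plain vectors are passed.
#' @param n_harmonics number of harmonics to report.
#' @return data.frame with \code{frequency} (Hz), \code{modulus}
#'   (dyn s cm^-5) and \code{phase} (radians).
#' @export
input_impedance <- function(P, Q, period = NULL, n_harmonics = 10) {
  if (inherits(P, "periodic_waveform")) period <- P$period
  if (is.null(period)) stop("period required when passing plain vectors")
  p <- metric_pair(P, Q)
  n <- length(p$b)
  Pf <- stats::fft(p$b) / n
  Qf <- stats::fft(p$r) / n
  kmax <- min(n_harmonics, floor((n - 1) / 2))
  freq <- (0:kmax) / period
  keep <- c(TRUE, Mod(Qf[2:(kmax + 1)]) > 1e-12 * max(Mod(Qf)))
  Z <- c(Re(Pf[1]) / Re(Qf[1]), (Pf / Qf)[2:(kmax + 1)])
  data.frame(frequency = freq[keep], modulus = Mod(Z)[keep],
             phase = Arg(Z)[keep])[order(freq[keep]), ]
}

#' Full waveform comparison report
#'
#' Convenience wrapper computing every error metric between baseline and
#' reduced pressure (and optionally flow) waveforms.
#'
#' @param P_baseline,P_reduced pressure waveforms.
#' @param Q_baseline,Q_reduced optional flow waveforms.
#' @return an object of class \code{metric_report} (fractions internally;
#'   printed as percentages and mmHg).
#' @export
compare_waveforms <- function(P_baseline, P_reduced,
                              Q_baseline = NULL, Q_reduced = NULL) {
  ext <- eps_extrema(P_baseline, P_reduced)
  out <- list(eps_P_avg = eps_avg(P_baseline, P_reduced, "pressure"),
              eps_P_sys = unname(ext["eps_P_sys"]),
              eps_P_dia = unname(ext["eps_P_dia"]),
              eps_PP = unname(ext["eps_PP"]),
              eps_P_aug = eps_aug(P_baseline, P_reduced))
  if (!is.null(Q_baseline) && !is.null(Q_reduced))
    out$eps_Q_avg <- eps_avg(Q_baseline, Q_reduced, "flow")
  b <- metric_series(P_baseline)
  out$P_sys_mmHg <- dyn_to_mmHg(max(b))
  out$P_dia_mmHg <- dyn_to_mmHg(min(b))
  out$PP_mmHg <- dyn_to_mmHg(max(b) - min(b))
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  for (nm in names(x)) {
    if (startsWith(nm, "eps_"))
      cat(sprintf("  %-10s %s\n", nm,
                  if (is.na(x[[nm]])) "undefined" else sprintf("%.3f%%", 100 * x[[nm]])))
    else cat(sprintf("  %-10s %.2f\n", nm, x[[nm]]))
  }
  invisible(x)
}
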