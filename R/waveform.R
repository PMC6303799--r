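#' Periodic waveform
#'
#' A uniformly sampled periodic signal over one period (flow, pressure, ...).
#' Samples are stored on the open grid t = 0, T/n, ..., (n-1)T/n; a closed
#' input grid (last sample at t = T) is accepted when its endpoint value is
#' consistent with the periodic wrap.
#'
#' @param t sample times (s), uniform, starting at 0.
#' @param values sample values (cm^3 s^-1 for flow, dyn cm^-2 for pressure).
#' @param period period T (s); inferred from the grid when omitted.
#' @return an object of class \code{periodic_waveform}.
#' @export
periodic_waveform <- function(t, values, period = NULL) {
  n <- length(t)
  if (n < 4) stop("periodic_waveform needs at least 4 samples")
  if (length(values) != n) stop("t and values must have equal length")
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1] + 1e-15))
    stop("periodic_waveform requires a uniform time grid")
  if (abs(t[1]) > 1e-12) stop("waveform grid must start at t = 0")
  dt <- dt[1]
  if (is.null(period)) period <- t[n] + dt
  ## closed grid: endpoint duplicates t = 0 sample
  if (abs(t[n] - period) < 1e-9 * period) {
    vr <- diff(range(values))
    if (abs(values[n] - values[1]) > 1e-6 * max(vr, abs(values[1]), 1))
      stop("waveform endpoint inconsistent with periodic wrap")
    t <- t[-n]; values <- values[-n]; n <- n - 1
  }
  if (abs(n * dt - period) > 1e-8 * period)
    stop("waveform grid does not span one period")
  structure(list(t = t, values = values, period = period),
            class = "periodic_waveform")
}

#' Periodic linear interpolation of a waveform
#' @param w a \code{periodic_waveform}.
#' @param tq query times (s); wrapped into [0, T).
#' @return interpolated values.
#' @export
wave_interp <- function(w, tq) {
  n <- length(w$t)
  dt <- w$period / n
  tq <- tq %% w$period
  i0 <- floor(tq / dt)
  frac <- tq / dt - i0
  i0 <- (i0 %% n) + 1
  i1 <- (i0 %% n) + 1
  (1 - frac) * w$values[i0] + frac * w$values[i1]
}

#' Resample a waveform to n uniform points per period
#' @inheritParams wave_interp
#' @param n number of samples.
#' @export
wave_resample <- function(w, n) {
  tq <- (0:(n - 1)) * w$period / n
  periodic_waveform(tq, wave_interp(w, tq), w$period)
}

#' Period mean of a waveform
#' @inheritParams wave_interp
#' @export
wave_mean <- function(w) mean(w$values)

#' Integral of a waveform over one period (e.g. stroke volume of a flow wave)
#' @inheritParams wave_interp
#' @export
wave_integral <- function(w) sum(w$values) * w$period / length(w$values)

#' @export
print.periodic_waveform <- function(x, ...) {
  cat(sprintf("<periodic_waveform: %d samples, T=%.4g s, range [%.4g, %.4g]>\n",
              length(x$t), x$period, min(x$values), max(x$values)))
  invisible(x)
}
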