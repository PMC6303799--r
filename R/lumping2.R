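#' Periodic pressure response of a WK3 driven by a flow waveform
#'
#' Integrates the WK3 ODE \eqn{C\,dP_c/dt = Q - (P_c - P_{out})/R_2},
#' \eqn{P = P_c + R_1 Q}, with an exact exponential step for the
#' piecewise-linear flow between samples, marching repeated cycles until the
#' start-of-cycle state drifts by less than \code{drift_tol} (relative).
#'
#' @param Q a \code{periodic_waveform} of flow (cm^3 s^-1).
#' @param R1,C,R2 WK3 parameters (CGS).
#' @param P_out reference pressure (dyn cm^-2).
#' @param drift_tol relative start-of-cycle drift accepted as periodic.
#' @param max_cycles maximum cycles to march.
#' @param Pc0 initial compliance-chamber pressure; defaults to the periodic
#'   mean estimate P_out + R2 * mean(Q). Set together with
#'   \code{max_cycles = 1} to inspect the transient response.
#' @return a \code{periodic_waveform} of pressure over one period.
#' @export
wk3_pressure_response <- function(Q, R1, C, R2, P_out,
                                  drift_tol = 1e-8, max_cycles = 50,
                                  Pc0 = NULL) {
  n <- length(Q$t)
  h <- Q$period / n
  q <- c(Q$values, Q$values[1])     # closed cycle for stepping
  tau <- R2 * C
  E <- exp(-h / tau)
  I1 <- tau * (1 - E)
  I2 <- tau * h - tau^2 * (1 - E)   # int_0^h tau' * exp(-(h-t)/tau) dt
  Pc <- if (is.null(Pc0)) P_out + R2 * mean(Q$values) else Pc0
  trace <- numeric(n)
  for (cycle in seq_len(max_cycles)) {
    P0 <- Pc
    for (i in seq_len(n)) {
      trace[i] <- Pc
      dQ <- q[i + 1] - q[i]
      Pc <- P_out + (Pc - P_out) * E + (q[i] * I1 + (dQ / h) * I2) / C
    }
    if (abs(Pc - P0) <= drift_tol * max(abs(P0), 1)) break
  }
  periodic_waveform(Q$t, trace + R1 * Q$values, Q$period)
}

#' Fit WK3 parameters to baseline waveforms at a truncation site (Method 2)
#'
#' Drives the WK3 ODE with the baseline flow waveform and minimizes the
#' average relative pressure error against the baseline pressure waveform.
#' The total resistance is held fixed at
#' \eqn{R_1 + R_2 = (P_{avg} - P_{out}) / Q_{avg}}; the optimized subset is
#' \eqn{(\theta_1, \theta_2) = (R_1/R_2, C)} by default, using a
#' derivative-free simplex on log-transformed parameters (which also keeps
#' all proposals positive).
#'
#' @param Q_baseline,P_baseline \code{periodic_waveform}s from the converged
#'   baseline 1D solution at the site.
#' @param P_out reference pressure of the outlet (dyn cm^-2).
#' @param init list with initial guesses \code{R1} and \code{C} (typically
#'   Z_c and the lumped compliance from Method 1).
#' @param subset \code{"ratio_C"} (optimize R1/R2 and C) or \code{"C"}
#'   (optimize C only, R1/R2 frozen at the initial ratio).
#' @param reltol objective convergence tolerance of the simplex.
#' @return an object of class \code{wk3_fit}: fitted \code{R1}, \code{C},
#'   \code{R2}, the objective (average relative pressure error), the initial
#'   objective, iteration count and a convergence flag.
#' @export
fit_wk3 <- function(Q_baseline, P_baseline, P_out, init,
                    subset = c("ratio_C", "C"), reltol = 1e-10) {
  subset <- match.arg(subset)
  if (length(P_baseline$values) != length(Q_baseline$values))
    P_baseline <- wave_resample(P_baseline, length(Q_baseline$values))
  P_avg <- wave_mean(P_baseline)
  Q_avg <- wave_mean(Q_baseline)
  if (Q_avg <= 0) stop("fit_wk3 requires positive mean flow at the site")
  R_tot <- (P_avg - P_out) / Q_avg
  if (R_tot <= 0) stop("fit_wk3: mean pressure at the site is below P_out")
  R1_0 <- min(init$R1, 0.9 * R_tot)  # keep the initial guess feasible
  theta0 <- c(ratio = R1_0 / (R_tot - R1_0), C = init$C)

  objective <- function(theta) {
    R1 <- R_tot * theta[1] / (1 + theta[1])
    R2 <- R_tot / (1 + theta[1])
    P <- wk3_pressure_response(Q_baseline, R1, theta[2], R2, P_out)
    mean(abs(P$values - P_baseline$values) / abs(P_baseline$values))
  }
  f0 <- objective(theta0)
  if (subset == "C") {
    opt <- stats::optim(log(theta0["C"]),
                        function(lc) objective(c(theta0["ratio"], exp(lc))),
                        method = "Brent",
                        lower = log(theta0["C"]) - 8, upper = log(theta0["C"]) + 8)
    theta <- c(theta0["ratio"], exp(opt$par))
    iters <- NA_integer_
  } else {
    opt <- stats::optim(log(theta0), function(lt) objective(exp(lt)),
                        method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = 2000))
    theta <- exp(opt$par)
    iters <- opt$counts[["function"]]
  }
  fbest <- opt$value
  warn <- FALSE
  if (fbest > f0) { theta <- theta0; fbest <- f0; warn <- TRUE }
  R1 <- R_tot * theta[1] / (1 + theta[1])
  structure(list(R1 = unname(R1), C = unname(theta[2]),
                 R2 = unname(R_tot - R1), R_tot = R_tot,
                 theta = unname(theta), objective = fbest,
                 objective_initial = f0, iterations = iters,
                 subset = subset, warning = warn),
            class = "wk3_fit")
}

#' @export
print.wk3_fit <- function(x, ...) {
  cat(sprintf("<wk3_fit: R1=%.4g, C=%.4g, R2=%.4g; eps_P_avg %.3e (init %.3e)>\n",
              x$R1, x$C, x$R2, x$objective, x$objective_initial))
  invisible(x)
}

#' Reduce a network with per-site WK3 optimization (Method 2)
#'
#' Builds the Method 1 reduced topology, then replaces every new systemic
#' WK3 outlet's parameters with values fitted to the baseline 1D waveforms at
#' the cut face (\code{\link{fit_wk3}}), using the Method 1 values (Z_c and
#' the lumped compliance, with R1 + R2 fixed by Ohm's law on the baseline
#' time averages) as the initial guess. Coronary cuts keep their Method 1
#' parameters.
#'
#' @param net the baseline network.
#' @param baseline_result a converged \code{\link{run_simulation}} of
#'   \code{net} containing waveforms at every cut face (automatically re-run
#'   with those sites when missing).
#' @param retained_ids segment ids to keep.
#' @param ss optional precomputed steady solution of \code{net}.
#' @param config solver configuration used when the baseline must be re-run.
#' @return the reduced \code{vascular_network} with fitted outlets, with the
#'   per-cut fits attached as attribute \code{"fits"}.
#' @export
reduce_with_method2 <- function(net, baseline_result = NULL, retained_ids,
                                ss = NULL, config = solver_config()) {
  if (is.null(ss)) ss <- solve_steady(net)
  red <- truncate_network(net, ss, retained_ids)
  removed <- setdiff(names(net$segments), retained_ids)
  if (!length(removed)) return(red)
  ## cut faces: nodes of `red` carrying boundaries absent from `net`
  base_bc_nodes <- vapply(net$boundaries, `[[`, "", "node")
  cut_bcs <- Filter(function(b) !(b$node %in% base_bc_nodes), red$boundaries)
  inc <- node_incidence(red)
  cut_sites <- lapply(cut_bcs, function(b) {
    ref <- NULL
    for (e in inc[[b$node]]) if (e[2] == "dist") ref <- e[1]
    list(node = b$node, seg = ref, pos = 1)
  })
  need <- Filter(function(cs) {
    is.null(baseline_result) ||
      !any(vapply(baseline_result$sites, function(st)
        st$seg == cs$seg && abs(st$pos - cs$pos) < 1e-9, TRUE))
  }, cut_sites)
  if (length(need)) {
    sites <- c(lapply(cut_sites, function(cs) list(seg = cs$seg, pos = cs$pos)))
    baseline_result <- run_simulation(net, config, sites = sites)
  }
  fits <- list()
  for (i in seq_along(cut_bcs)) {
    b <- cut_bcs[[i]]
    if (b$variant != "wk3") next   # coronary cuts keep Method 1 parameters
    cs <- cut_sites[[i]]
    Qb <- sim_wave(baseline_result, cs$seg, cs$pos, "Q")
    Pb <- sim_wave(baseline_result, cs$seg, cs$pos, "P")
    fit <- fit_wk3(Qb, Pb, b$params$P_out,
                   init = list(R1 = b$params$R1, C = b$params$C))
    fits[[cs$node]] <- fit
    j <- which(vapply(red$boundaries, function(x) x$node == b$node, TRUE))
    red$boundaries[[j]]$params$R1 <- fit$R1
    red$boundaries[[j]]$params$R2 <- fit$R2
    red$boundaries[[j]]$params$C <- fit$C
  }
  validate_network(red)
  attr(red, "fits") <- fits
  red
}
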