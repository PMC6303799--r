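#' Synthetic aortic inflow waveform
#'
#' Half-sine ejection lobe of duration ET scaled to integrate to the stroke
#' volume, zero flow in diastole. Peak flow is pi*SV/(2*ET).
#'
#' @param HR heart rate (bpm).
#' @param ET ejection time (s), must be shorter than the period 60/HR.
#' @param SV stroke volume (cm^3).
#' @param n samples per period.
#' @return a \code{periodic_waveform} of flow (cm^3 s^-1).
#' @export
synthetic_inflow <- function(HR = 60, ET = 0.3, SV = 70, n = 1000) {
  T_per <- 60 / HR
  if (ET >= T_per) stop("ET must be shorter than the period")
  t <- (0:(n - 1)) * T_per / n
  q <- ifelse(t < ET, pi * SV / (2 * ET) * sin(pi * t / ET), 0)
  q <- q * SV / (sum(q) * T_per / n)   # discrete integral exactly SV
  periodic_waveform(t, q, T_per)
}

#' Synthetic left-ventricular pressure waveform
#'
#' Smooth squared-sine systolic bump (duration \code{systole_fraction} of the
#' cycle) rising to \code{peak}; zero during diastole. Non-negative
#' everywhere.
#'
#' @param HR heart rate (bpm).
#' @param peak peak LV pressure (mmHg).
#' @param systole_fraction fraction of the cycle in systole.
#' @param n samples per period.
#' @return a \code{periodic_waveform} of pressure (dyn cm^-2).
#' @export
synthetic_lv_pressure <- function(HR = 60, peak = 120, systole_fraction = 0.35,
                                  n = 1000) {
  T_per <- 60 / HR
  Ts <- systole_fraction * T_per
  t <- (0:(n - 1)) * T_per / n
  p <- ifelse(t < Ts, mmHg_to_dyn(peak) * sin(pi * t / Ts)^2, 0)
  periodic_waveform(t, p, T_per)
}

#' Synthetic aortic-root pressure waveform
#'
#' Diastolic plateau with a squared-sine systolic bump between \code{dia} and
#' \code{sys}; used to drive pressure-inflow (coronary) fixtures.
#'
#' @param HR heart rate (bpm).
#' @param sys,dia systolic/diastolic pressure (mmHg).
#' @param systole_fraction fraction of the cycle in systole.
#' @param n samples per period.
#' @return a \code{periodic_waveform} of pressure (dyn cm^-2).
#' @export
synthetic_aortic_pressure <- function(HR = 60, sys = 120, dia = 80,
                                      systole_fraction = 0.35, n = 1000) {
  T_per <- 60 / HR
  Ts <- systole_fraction * T_per
  t <- (0:(n - 1)) * T_per / n
  p <- mmHg_to_dyn(dia) +
    ifelse(t < Ts, mmHg_to_dyn(sys - dia) * sin(pi * t / Ts)^2, 0)
  periodic_waveform(t, p, T_per)
}

#' Deterministic toy-network fixtures
#'
#' Families:
#' \describe{
#'   \item{single_vessel}{one aorta-like uniform vessel (r = 1 cm,
#'     l = 10 cm) with a half-sine inflow and a WK3 outlet.}
#'   \item{binary_tree}{symmetric tree of \code{generations} generations;
#'     daughter radius = parent * 2^(-1/3) (Murray-consistent), lengths
#'     halving per generation; WK3 outlets at the leaves.}
#'   \item{ring_with_outlets}{a root vessel feeding a 4-segment ring
#'     (a circle-of-Willis-like loop) with WK3 outlets on two ring nodes.}
#'   \item{toy_coronary}{pressure-driven coronary bifurcation with one
#'     stenosis of area ratio \code{area_ratio} on one branch and coronary
#'     Windkessel outlets.}
#' }
#' Outlet resistances are set so the network carries a target mean pressure
#' at the nominal mean inflow; compliances are split equally from a total
#' arterial compliance. All fixtures are deterministic.
#'
#' @param family fixture family.
#' @param generations tree depth (binary_tree).
#' @param area_ratio stenotic As/A0 (toy_coronary).
#' @param base_radius,base_length root vessel geometry (cm).
#' @param HR,ET,SV inflow parameters (see \code{\link{synthetic_inflow}}).
#' @param p_target target mean pressure (mmHg).
#' @param p_out outflow reference pressure (mmHg).
#' @param C_total total peripheral (WK) compliance (cm^5 dyn^-1).
#' @return a validated \code{\link{vascular_network}}.
#' @export
make_fixture <- function(family = c("single_vessel", "binary_tree",
                                    "ring_with_outlets", "toy_coronary"),
                         generations = 3, area_ratio = 0.25,
                         base_radius = 1, base_length = 10,
                         HR = 60, ET = 0.3, SV = 70,
                         p_target = 93, p_out = 5, C_total = 9e-4) {
  family <- match.arg(family)
  blood <- blood_properties()
  wl <- wall_law("systemic")
  inflow <- synthetic_inflow(HR, ET, SV)
  Qm <- wave_mean(inflow)
  R_net <- (mmHg_to_dyn(p_target) - mmHg_to_dyn(p_out)) / Qm
  P_out <- mmHg_to_dyn(p_out)
  wk3_for <- function(r_leaf, n_outlets) {
    Zc <- blood$rho * wave_speed(r_leaf, wl, blood) / (pi * r_leaf^2)
    Ri <- n_outlets * R_net
    list(R1 = Zc, R2 = Ri - Zc, C = C_total / n_outlets, P_out = P_out)
  }
  if (family == "single_vessel") {
    seg <- arterial_segment("s1", base_length, base_radius, base_radius,
                            "n_in", "n_out", wall = wl)
    p <- wk3_for(base_radius, 1)
    return(vascular_network(
      list(seg),
      list(boundary_condition("n_in", "inflow_Q", wave = inflow),
           boundary_condition("n_out", "wk3", R1 = p$R1, C = p$C, R2 = p$R2,
                              P_out = p$P_out)),
      blood = blood))
  }
  if (family == "binary_tree") {
    segs <- list(); bcs <- list()
    ## breadth-first construction: segment k has children 2k, 2k+1
    n_seg <- 2^generations - 1
    for (k in seq_len(n_seg)) {
      gen <- floor(log2(k))
      r <- base_radius * 2^(-gen / 3)
      l <- base_length / 2^gen
      from <- if (k == 1) "n_in" else paste0("n", k %/% 2)
      segs[[k]] <- arterial_segment(paste0("s", k), l, r, r,
                                    from, paste0("n", k), wall = wl)
    }
    leaves <- seq.int(2^(generations - 1), n_seg)
    p <- wk3_for(base_radius * 2^(-(generations - 1) / 3), length(leaves))
    bcs <- c(list(boundary_condition("n_in", "inflow_Q", wave = inflow)),
             lapply(leaves, function(k)
               boundary_condition(paste0("n", k), "wk3", R1 = p$R1, C = p$C,
                                  R2 = p$R2, P_out = p$P_out)))
    return(vascular_network(segs, bcs, blood = blood))
  }
  if (family == "ring_with_outlets") {
    rr <- 0.7 * base_radius
    segs <- list(
      arterial_segment("root", base_length, base_radius, base_radius,
                       "n_in", "nA", wall = wl),
      arterial_segment("ring_ab", 6, rr, rr, "nA", "nB", wall = wl),
      arterial_segment("ring_bc", 6, rr, rr, "nB", "nC", wall = wl),
      arterial_segment("ring_ad", 6, rr, rr, "nA", "nD", wall = wl),
      arterial_segment("ring_dc", 6, rr, rr, "nD", "nC", wall = wl))
    p <- wk3_for(rr, 2)
    bcs <- list(
      boundary_condition("n_in", "inflow_Q", wave = inflow),
      boundary_condition("nB", "wk3", R1 = p$R1, C = p$C, R2 = p$R2,
                         P_out = p$P_out),
      boundary_condition("nC", "wk3", R1 = p$R1, C = p$C, R2 = p$R2,
                         P_out = p$P_out))
    return(vascular_network(segs, bcs, blood = blood))
  }
  ## toy_coronary
  cwl <- wall_law("coronary")
  CO <- 90
  segs <- list(
    arterial_segment("cor_root", 3, 0.2, 0.2, "n_in", "nJ", wall = cwl),
    arterial_segment("cor_sten", 3, 0.16, 0.16, "nJ", "nS", wall = cwl),
    arterial_segment("cor_side", 3, 0.16, 0.16, "nJ", "nH", wall = cwl))
  pp <- synthetic_aortic_pressure(HR)
  lv <- synthetic_lv_pressure(HR)
  dist <- distribute_coronary_outlet_params(
    CO, wave_mean(pp), P_out, c(sten = 0.16, side = 0.16))
  cor_bc <- function(node, row) {
    boundary_condition(node, "wk_cor",
      R_a = 0.32 * dist$R_total[row], R_m = 0.52 * dist$R_total[row],
      R_v_out = 0.16 * dist$R_total[row],
      C_a = 0.11 * dist$C_total[row], C_m = 0.89 * dist$C_total[row],
      gamma_im = 1, alpha = 1, P_out = P_out, lv_pressure = lv)
  }
  net <- vascular_network(
    segs,
    list(boundary_condition("n_in", "inflow_P", wave = pp),
         cor_bc("nS", 1), cor_bc("nH", 2)),
    blood = blood)
  A0 <- segment_Ad(net$segments$cor_sten, 0.5)
  sten <- stenosis_descriptor("cor_sten", x_start = 1.25, length_s = 0.5,
                              A0 = A0, As = area_ratio * A0, blood = blood)
  net$stenoses <- list(sten)
  validate_network(net)
  net
}

#' Random tree fixture for property tests
#'
#' Draws a small asymmetric tree (random depth, radii and lengths) from an
#' explicitly seeded generator; the caller's RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param max_children maximum children per junction.
#' @return a validated \code{\link{vascular_network}}.
#' @export
random_tree_fixture <- function(seed, max_children = 3) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  blood <- blood_properties()
  wl <- wall_law("systemic")
  segs <- list()
  leaves <- character()
  add_seg <- function(parent_node, r, l, id) {
    segs[[id]] <<- arterial_segment(id, l, r, r * stats::runif(1, 0.85, 1),
                                    parent_node, paste0("n_", id), wall = wl)
  }
  add_seg("n_in", stats::runif(1, 0.8, 1.2), stats::runif(1, 6, 12), "s1")
  frontier <- "s1"
  for (depth in 1:2) {
    nxt <- character()
    for (pid in frontier) {
      nk <- sample(0:max_children, 1, prob = c(0.2, 0.1, 0.5, 0.2))
      if (nk < 2) { leaves <- c(leaves, pid); next }
      for (j in seq_len(nk)) {
        id <- paste0(pid, "_", j)
        pr <- segs[[pid]]$r_dist
        add_seg(segs[[pid]]$to_node, pr * stats::runif(1, 0.55, 0.8),
                stats::runif(1, 3, 8), id)
        nxt <- c(nxt, id)
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  leaves <- c(leaves, frontier)
  inflow <- synthetic_inflow()
  Qm <- wave_mean(inflow)
  R_net <- (mmHg_to_dyn(93) - mmHg_to_dyn(5)) / Qm
  bcs <- list(boundary_condition("n_in", "inflow_Q", wave = inflow))
  for (id in leaves) {
    r <- segs[[id]]$r_dist
    Zc <- blood$rho * wave_speed(r, wl, blood) / (pi * r^2)
    Ri <- length(leaves) * R_net * stats::runif(1, 0.8, 1.25)
    bcs[[length(bcs) + 1]] <-
      boundary_condition(segs[[id]]$to_node, "wk3", R1 = Zc, C = 9e-4 / length(leaves),
                         R2 = Ri - Zc, P_out = mmHg_to_dyn(5))
  }
  vascular_network(segs, bcs, blood = blood)
}

#' Closed-form reference oracles
#'
#' Independent closed-form references used by the test-suite and acceptance
#' checks: Poiseuille-type pressure drop, Windkessel decay, WK3 input
#' impedance, diastolic wave speed, and a dense nodal-analysis solve of a
#' linear resistive network.
#'
#' @name oracles
NULL

#' @rdname oracles
#' @param Q flow (cm^3 s^-1); \code{l} length (cm); \code{A} area (cm^2).
#' @param l,A see above.
#' @param blood \code{blood_properties}.
#' @export
oracle_poiseuille_drop <- function(Q, l, A, blood = blood_properties()) {
  friction_coefficient(blood) * l * Q / A^2
}

#' @rdname oracles
#' @param t time (s); \code{P0} initial pressure; \code{P_out} reference.
#' @param P0,P_out,R2,C Windkessel decay parameters.
#' @export
oracle_wk_decay <- function(t, P0, P_out, R2, C) {
  P_out + (P0 - P_out) * exp(-t / (R2 * C))
}

#' @rdname oracles
#' @param omega angular frequency (rad s^-1); vectorised.
#' @param R1 WK3 proximal resistance.
#' @export
oracle_wk3_impedance <- function(omega, R1, C, R2) {
  R1 + R2 / (1 + 1i * omega * R2 * C)
}

#' @rdname oracles
#' @param r_d diastolic radius (cm).
#' @param law a \code{wall_law}.
#' @export
oracle_linear_wave_speed <- function(r_d, law, blood = blood_properties()) {
  sqrt((2 / (3 * blood$rho)) * (law$k1 * exp(law$k2 * r_d) + law$k3))
}

#' @rdname oracles
#' @param edges data.frame with columns \code{from}, \code{to}, \code{R}
#'   (internal resistive edges).
#' @param outlets data.frame with columns \code{node}, \code{R},
#'   \code{P_out} (edges to ground).
#' @param inflow_node node receiving the injected flow.
#' @param Q_in injected flow (cm^3 s^-1).
#' @export
oracle_nodal_analysis <- function(edges, outlets, inflow_node, Q_in) {
  nodes <- unique(c(edges$from, edges$to, outlets$node, inflow_node))
  id <- stats::setNames(seq_along(nodes), nodes)
  n <- length(nodes)
  G <- matrix(0, n, n); b <- numeric(n)
  for (i in seq_len(nrow(edges))) {
    a <- id[[edges$from[i]]]; z <- id[[edges$to[i]]]; g <- 1 / edges$R[i]
    G[a, a] <- G[a, a] + g; G[z, z] <- G[z, z] + g
    G[a, z] <- G[a, z] - g; G[z, a] <- G[z, a] - g
  }
  for (i in seq_len(nrow(outlets))) {
    a <- id[[outlets$node[i]]]; g <- 1 / outlets$R[i]
    G[a, a] <- G[a, a] + g
    b[a] <- b[a] + g * outlets$P_out[i]
  }
  b[id[[inflow_node]]] <- b[id[[inflow_node]]] + Q_in
  P <- drop(solve(G, b))
  names(P) <- nodes
  Qe <- (P[edges$from] - P[edges$to]) / edges$R
  list(P = P, Q_edges = unname(Qe))
}
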