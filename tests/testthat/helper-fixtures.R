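## Shared helpers for the test-suite. Fixtures themselves come from the
## package's own generators (make_fixture etc.); helpers here only wrap
## common test constructions.

## Uniform single vessel with explicit parameters and a constant inflow.
const_flow_vessel <- function(Q0 = 5, r = 1, l = 10, R1 = 200, R2 = 1500,
                              C = 1e-3, p_out = 80, p_dia = 80, n = 200) {
  blood <- blood_properties()
  t <- (0:(n - 1)) / n
  wave <- periodic_waveform(t, rep(Q0, n), 1)
  seg <- arterial_segment("v", l, r, r, "nin", "nout",
                          wall = wall_law("systemic"),
                          p_dia = mmHg_to_dyn(p_dia))
  vascular_network(
    list(seg),
    list(boundary_condition("nin", "inflow_Q", wave = wave),
         boundary_condition("nout", "wk3", R1 = R1, C = C, R2 = R2,
                            P_out = mmHg_to_dyn(p_out))),
    blood = blood)
}

## Gaussian flow-pulse network on a long uniform vessel with a matched
## (R1 = Z_c) outlet; used for wave-speed and reflection checks.
pulse_vessel <- function(l = 40, r = 1, amp = 5, t0 = 0.05, sigma = 0.005,
                         C = 5e-3, R2 = 1500, n = 4000) {
  blood <- blood_properties()
  wl <- wall_law("systemic")
  cd <- wave_speed(r, wl, blood)
  Zc <- blood$rho * cd / (pi * r^2)
  t <- (0:(n - 1)) / n
  wave <- periodic_waveform(t, amp * exp(-(t - t0)^2 / (2 * sigma^2)), 1)
  seg <- arterial_segment("v", l, r, r, "nin", "nout", wall = wl,
                          p_dia = mmHg_to_dyn(80))
  net <- vascular_network(
    list(seg),
    list(boundary_condition("nin", "inflow_Q", wave = wave),
         boundary_condition("nout", "wk3", R1 = Zc, C = C, R2 = R2,
                            P_out = mmHg_to_dyn(80))),
    blood = blood)
  list(net = net, cd = cd, Zc = Zc, t0 = t0)
}

## Sub-sample foot arrival time: first crossing of 10% of the peak rise.
foot_time <- function(w) {
  v <- w$values - w$values[1]
  thr <- 0.1 * max(v)
  i <- which(v > thr)[1]
  w$t[i - 1] + (thr - v[i - 1]) / (v[i] - v[i - 1]) * (w$t[i] - w$t[i - 1])
}

## Total compliance bookkeeping: integrated 1D + WK outlet compliances.
total_compliance <- function(net) {
  cwk <- sum(vapply(net$boundaries, function(b) {
    if (b$variant == "wk3") b$params$C
    else if (b$variant == "wk_cor") b$params$C_a + b$params$C_m
    else 0
  }, 0))
  pulsetrim:::total_1d_compliance(net) + cwk
}

## Brute-force enumeration of the truncation candidate family on a tree:
## retained subsets that contain the root and protected ids, are closed
## towards the root, and keep all or none of every junction's children.
brute_force_candidates <- function(net, protected = character()) {
  ids <- names(net$segments)
  root <- node_incidence_root(net)
  children <- lapply(net$segments, function(s)
    names(Filter(function(x) x$from_node == s$to_node, net$segments)))
  ok <- function(keep) {
    if (!(root %in% keep)) return(FALSE)
    if (!all(protected %in% keep)) return(FALSE)
    for (id in keep) {
      s <- net$segments[[id]]
      if (id != root) {
        parent <- names(Filter(function(x) x$to_node == s$from_node, net$segments))
        if (length(parent) && !all(parent %in% keep)) return(FALSE)
      }
      kids <- children[[id]]
      if (length(kids) && !(all(kids %in% keep) || !any(kids %in% keep)))
        return(FALSE)
    }
    ## removed side: a removed segment's children must be removed
    for (id in setdiff(ids, keep)) {
      kids <- children[[id]]
      if (any(kids %in% keep)) return(FALSE)
    }
    TRUE
  }
  n <- length(ids)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    keep <- ids[bitwAnd(mask, bitwShiftL(1, seq_len(n) - 1)) != 0]
    if (ok(keep)) out[[length(out) + 1]] <- sort(keep)
  }
  out
}

node_incidence_root <- function(net) {
  infl <- inflow_boundary(net)
  for (s in net$segments) if (s$from_node == infl$node) return(s$id)
  stop("no root segment")
}
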