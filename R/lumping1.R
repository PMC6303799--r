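#' Lumped resistance distal of a site (Ohm's law on the steady solution)
#'
#' \deqn{R = (\bar P - P_{out,WK}) / \bar Q} evaluated at the site with the
#' steady static pressure and mean flow.
#'
#' @param net a \code{vascular_network}.
#' @param ss a \code{\link{solve_steady}} solution on \code{net}.
#' @param seg_id segment id of the site.
#' @param pos relative position in [0, 1] (default 1, the distal face).
#' @param P_out outflow reference pressure (dyn cm^-2).
#' @return lumped resistance (dyn s cm^-5).
#' @export
lumped_resistance <- function(net, ss, seg_id, pos = 1, P_out) {
  st <- steady_state_at(net, ss, seg_id, pos)
  if (abs(st$Q) < 1e-12)
    stop("cannot lump at ", seg_id, "@", pos, ": mean flow is (numerically) zero")
  (st$P - P_out) / st$Q
}

#' Characteristic impedance at a site from the steady mean state
#'
#' \deqn{Z_c = \rho \bar c / \bar A.}
#'
#' @inheritParams lumped_resistance
#' @return Z_c (dyn s cm^-5).
#' @export
characteristic_impedance <- function(net, ss, seg_id, pos = 1) {
  st <- steady_state_at(net, ss, seg_id, pos)
  net$blood$rho * st$c / st$A
}

## Mean-state R_v and C_v of one segment from the steady solution.
steady_seg_RvCv <- function(net, ss, seg_id) {
  seg <- net$segments[[seg_id]]
  s <- ss$segments[[seg_id]]
  Af <- function(sq) stats::approx(ss$sgrid, s$Abar, xout = sq)$y
  cf <- function(sq) local_wave_speed(Af(sq), segment_Ad(seg, sq),
                                      segment_beta(seg, sq), net$blood$rho)
  list(Rv = segment_viscous_resistance(seg, net$blood, n = length(ss$sgrid) - 1,
                                       Abar = Af),
       Cv = segment_volume_compliance(seg, net$blood, n = length(ss$sgrid) - 1,
                                      Abar = Af, cbar = cf))
}

#' Equivalent compliance of a terminal vessel coupled to a WK3 outlet
#'
#' \deqn{C_t = \frac{C_v R_2 + C_v R_1 + C R_2 + C_v R_v}{R_2 + R_1 + R_v}}
#' for a vessel of volume compliance C_v and viscous resistance R_v feeding a
#' WK3 (R1, C, R2).
#'
#' @param C_v vessel volume compliance (cm^5 dyn^-1).
#' @param R_v vessel viscous resistance (dyn s cm^-5).
#' @param R1,C,R2 WK3 parameters.
#' @return C_t (cm^5 dyn^-1).
#' @export
terminal_compliance_wk3 <- function(C_v, R_v, R1, C, R2) {
  (C_v * R2 + C_v * R1 + C * R2 + C_v * R_v) / (R2 + R1 + R_v)
}

#' Lumped compliance of all vessels distal of a cut face
#'
#' Every non-terminal distal segment contributes its volume compliance C_v;
#' terminal segments contribute the equivalent compliance of the
#' vessel+outlet pair (\code{\link{terminal_compliance_wk3}} for WK3 outlets,
#' C_v + C_a + C_m for coronary outlets). Contributions combine by parallel
#' addition (all arterial compliances reference a common external pressure);
#' the combiner can be swapped via \code{combine}.
#'
#' @inheritParams lumped_resistance
#' @param combine function reducing the vector of contributions (default
#'   \code{sum}, i.e. parallel addition).
#' @return lumped compliance (cm^5 dyn^-1).
#' @export
lumped_compliance <- function(net, ss, seg_id, combine = sum) {
  distal <- distal_segments(net, seg_id)
  if (!length(distal)) {
    ## cut at the face of a terminal vessel: its own terminal C_t
    contrib <- terminal_contribution(net, ss, seg_id)
    if (is.null(contrib)) stop("segment ", seg_id,
                               " has no distal subtree and no terminal outlet")
    return(contrib)
  }
  bc_by_node <- list()
  for (b in net$boundaries) bc_by_node[[b$node]] <- b
  deg <- vapply(node_incidence(net), length, 0L)
  contribs <- vapply(distal, function(id) {
    ct <- terminal_contribution(net, ss, id)
    if (!is.null(ct)) return(ct)
    rc <- steady_seg_RvCv(net, ss, id)
    rc$Cv
  }, 0)
  ## WK models attached at interior (junction) nodes of the distal set
  distal_nodes <- unique(unlist(lapply(net$segments[distal], function(s)
    c(s$from_node, s$to_node))))
  extra <- 0
  for (b in net$boundaries) {
    if (!(b$node %in% distal_nodes) || deg[b$node] == 1) next
    if (b$variant == "wk3") extra <- extra + b$params$C
    if (b$variant == "wk_cor") extra <- extra + b$params$C_a + b$params$C_m
  }
  combine(c(contribs, extra))
}

## Terminal C_t of a segment whose distal node carries an outlet; NULL if the
## segment is not terminal.
terminal_contribution <- function(net, ss, seg_id) {
  seg <- net$segments[[seg_id]]
  inc <- node_incidence(net)
  if (length(inc[[seg$to_node]]) != 1) return(NULL)
  bc <- NULL
  for (b in net$boundaries) if (b$node == seg$to_node) bc <- b
  if (is.null(bc) || !(bc$variant %in% c("wk3", "wk_cor"))) return(NULL)
  rc <- steady_seg_RvCv(net, ss, seg_id)
  if (bc$variant == "wk3") {
    p <- bc$params
    terminal_compliance_wk3(rc$Cv, rc$Rv, p$R1, p$C, p$R2)
  } else {
    rc$Cv + bc$params$C_a + bc$params$C_m
  }
}

#' Truncate a network, replacing removed distal beds by lumped outlets
#' (Method 1)
#'
#' Every connected component of removed segments must hang from a single
#' retained node; at each such cut the component is replaced by a Windkessel
#' outlet whose total resistance is the steady lumped resistance at the cut
#' (\code{\link{lumped_resistance}}), whose compliance is the lumped distal
#' compliance, and whose proximal resistance is the characteristic impedance
#' Z_c of the cut face. Coronary beds are replaced by coronary Windkessel
#' outlets with the lumped totals divided among the elements by fixed
#' configurable ratios.
#'
#' @param net the baseline \code{vascular_network}.
#' @param ss a steady solution of \code{net} (\code{\link{solve_steady}}).
#' @param retained_ids segment ids to keep; must form a connected subnetwork
#'   containing the inflow.
#' @param cor_r_split,cor_c_split ratios dividing lumped coronary resistance
#'   among (R_a, R_m, R_v_out) and compliance among (C_a, C_m).
#' @return the reduced \code{vascular_network}.
#' @export
truncate_network <- function(net, ss, retained_ids,
                             cor_r_split = c(0.32, 0.52, 0.16),
                             cor_c_split = c(0.11, 0.89)) {
  retained_ids <- as.character(retained_ids)
  unknown <- setdiff(retained_ids, names(net$segments))
  if (length(unknown)) stop("unknown retained ids: ", paste(unknown, collapse = ", "))
  removed <- setdiff(names(net$segments), retained_ids)
  if (!length(removed)) return(net)
  infl <- inflow_boundary(net)
  inc <- node_incidence(net)
  root <- inc[[infl$node]][[1]][1]
  if (!(root %in% retained_ids)) stop("retained set must contain the root segment")

  ## connectivity of the retained subnetwork
  ret_nodes <- unique(unlist(lapply(net$segments[retained_ids], function(s)
    c(s$from_node, s$to_node))))
  comp <- component_of(net, retained_ids, net$segments[[root]]$from_node)
  if (!setequal(comp$segs, retained_ids))
    stop("retained segments do not form a connected subnetwork containing the inflow")

  ## group removed segments into hanging components
  comps <- list()
  left <- removed
  while (length(left)) {
    cc <- component_of(net, left, net$segments[[left[1]]]$from_node,
                       seed_seg = left[1])
    comps[[length(comps) + 1]] <- cc$segs
    left <- setdiff(left, cc$segs)
  }
  new_bcs <- list()
  for (cs in comps) {
    cnodes <- unique(unlist(lapply(net$segments[cs], function(s)
      c(s$from_node, s$to_node))))
    attach_nodes <- intersect(cnodes, ret_nodes)
    if (length(attach_nodes) != 1)
      stop("removed component {", paste(cs, collapse = ","),
           "} must hang from exactly one retained node (found ",
           length(attach_nodes), ")")
    nd <- attach_nodes
    new_bcs[[length(new_bcs) + 1]] <-
      lump_component(net, ss, nd, cs, retained_ids, cor_r_split, cor_c_split)
  }
  keep_bc <- Filter(function(b) {
    b$node %in% ret_nodes &&
      !any(vapply(new_bcs, function(nb) nb$node == b$node, TRUE))
  }, net$boundaries)
  keep_sten <- Filter(function(st) st$segment_id %in% retained_ids, net$stenoses)
  vascular_network(net$segments[retained_ids], c(keep_bc, new_bcs), keep_sten,
                   net$blood, meta = net$meta)
}

## Connected component of `ids` (a subset of segments) reachable from `node`.
component_of <- function(net, ids, node, seed_seg = NULL) {
  segs <- net$segments[ids]
  seen_nodes <- character()
  seen_segs <- character()
  queue <- node
  if (!is.null(seed_seg)) queue <- unique(c(net$segments[[seed_seg]]$from_node,
                                            net$segments[[seed_seg]]$to_node))
  while (length(queue)) {
    nd <- queue[1]; queue <- queue[-1]
    if (nd %in% seen_nodes) next
    seen_nodes <- c(seen_nodes, nd)
    for (s in segs) {
      if (s$id %in% seen_segs) next
      if (s$from_node == nd || s$to_node == nd) {
        seen_segs <- c(seen_segs, s$id)
        queue <- c(queue, setdiff(c(s$from_node, s$to_node), seen_nodes))
      }
    }
  }
  list(segs = seen_segs, nodes = seen_nodes)
}

## Build the lumped outlet replacing component `cs` hanging from node `nd`.
lump_component <- function(net, ss, nd, cs, retained_ids,
                           cor_r_split, cor_c_split) {
  inc <- node_incidence(net)
  rho <- net$blood$rho
  ## reference retained face at the cut (a retained segment's distal end)
  ref <- NULL
  for (e in inc[[nd]]) if (e[1] %in% retained_ids && e[2] == "dist") ref <- e[1]
  if (is.null(ref))
    stop("cut at node ", nd, " has no retained distal face; reorient the network")
  ## flow into the component
  Qcut <- 0
  for (e in inc[[nd]]) {
    if (!(e[1] %in% cs)) next
    Q <- ss$segments[[e[1]]]$Q
    Qcut <- Qcut + if (e[2] == "prox") Q else -Q
  }
  if (Qcut <= 1e-12)
    stop("cut at node ", nd, " carries no distal mean flow; cannot lump")
  Pcut <- steady_state_at(net, ss, ref, 1)$P

  ## outlets inside the component determine the kind and P_out
  bcs <- Filter(function(b) b$variant %in% c("wk3", "wk_cor") &&
                  b$node %in% unlist(lapply(net$segments[cs], function(s)
                    c(s$from_node, s$to_node))), net$boundaries)
  if (!length(bcs)) stop("removed component at node ", nd, " has no outlets")
  kinds <- unique(vapply(bcs, `[[`, "", "variant"))
  if (length(kinds) != 1)
    stop("removed component at node ", nd, " mixes WK3 and coronary outlets")
  P_out <- bcs[[1]]$params$P_out
  R_lump <- (Pcut - P_out) / Qcut
  C_lump <- lumped_compliance_of_set(net, ss, cs)

  ## characteristic impedance of the cut: component root faces in parallel
  zc_g <- 0
  for (e in inc[[nd]]) {
    if (!(e[1] %in% cs)) next
    pos <- if (e[2] == "prox") 0 else 1
    zc_g <- zc_g + 1 / characteristic_impedance(net, ss, e[1], pos)
  }
  Zc <- 1 / zc_g

  if (kinds == "wk3") {
    if (R_lump <= Zc)
      stop("lumping invalid at node ", nd, ": lumped resistance (",
           format(R_lump), ") does not exceed Z_c (", format(Zc),
           "); retain more vessels")
    boundary_condition(nd, "wk3", R1 = Zc, C = C_lump, R2 = R_lump - Zc,
                       P_out = P_out)
  } else {
    p0 <- bcs[[1]]$params
    boundary_condition(nd, "wk_cor",
      R_a = cor_r_split[1] * R_lump, R_m = cor_r_split[2] * R_lump,
      R_v_out = cor_r_split[3] * R_lump,
      C_a = cor_c_split[1] * C_lump, C_m = cor_c_split[2] * C_lump,
      gamma_im = if (is.null(p0$gamma_im)) 1 else p0$gamma_im,
      alpha = if (is.null(p0$alpha)) 1 else p0$alpha,
      P_out = P_out, lv_pressure = p0$lv_pressure)
  }
}

## Lumped compliance of an explicit segment set (used by truncate_network).
lumped_compliance_of_set <- function(net, ss, ids) {
  deg <- vapply(node_incidence(net), length, 0L)
  nodes <- unique(unlist(lapply(net$segments[ids], function(s)
    c(s$from_node, s$to_node))))
  total <- 0
  for (id in ids) {
    ct <- terminal_contribution(net, ss, id)
    total <- total + if (!is.null(ct)) ct else steady_seg_RvCv(net, ss, id)$Cv
  }
  for (b in net$boundaries) {
    if (!(b$node %in% nodes) || deg[b$node] == 1) next
    if (b$variant == "wk3") total <- total + b$params$C
    if (b$variant == "wk_cor") total <- total + b$params$C_a + b$params$C_m
  }
  total
}
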