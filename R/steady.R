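#' Steady-state linearized network solve (Picard iteration)
#'
#' Solves the steady, linearized 1D equations on the whole network: flow
#' conservation at junctions, viscous segment pressure drops
#' \eqn{\Delta \bar P = R_v(\bar A)\,\bar Q}, total-pressure continuity with
#' mean velocities at junctions, and the tube law linking mean area to mean
#' pressure. Vessel areas are frozen, the resulting linear resistive network
#' is solved by nodal analysis, areas are updated from the new pressures, and
#' the cycle repeats until the node pressures settle.
#'
#' Stenoses enter through their Newton linearization: tangent resistance
#' \eqn{K_{visc} + 2K_{exp}|\bar Q|} plus the matching lagged source, so the
#' converged solution satisfies the exact quadratic loss law.
#'
#' @param net a \code{vascular_network}.
#' @param mean_inflow mean inflow (cm^3 s^-1); defaults to the time average
#'   of the prescribed inflow waveform.
#' @param areas \code{"picard"} (update areas from pressures) or
#'   \code{"frozen"} (keep diastolic areas; a single linear solve).
#' @param include_dynamic include the dynamic pressure (rho U^2 / 2) terms in
#'   the junction coupling.
#' @param tol relative change in node pressures accepted as converged.
#' @param max_iter maximum Picard sweeps.
#' @param nq quadrature intervals per segment for R_v / C_v integrals.
#' @return an object of class \code{steady_solution}: node total pressures,
#'   per-segment mean flow, end static pressures and mean area/wave-speed
#'   profiles, iteration count and residual.
#' @export
solve_steady <- function(net, mean_inflow = NULL,
                         areas = c("picard", "frozen"),
                         include_dynamic = TRUE,
                         tol = 1e-8, max_iter = 200, nq = 64) {
  areas <- match.arg(areas)
  validate_network(net)
  infl <- inflow_boundary(net)
  inflow_P <- infl$variant == "inflow_P"
  if (!inflow_P) {
    if (is.null(mean_inflow)) mean_inflow <- wave_mean(infl$params$wave)
    if (mean_inflow <= 0) stop("mean inflow must be positive")
  }

  nodes <- names(node_incidence(net))
  nid <- stats::setNames(seq_along(nodes), nodes)
  nn <- length(nodes)
  segs <- net$segments
  sten_by_seg <- list()
  for (st in net$stenoses) sten_by_seg[[st$segment_id]] <- st
  bc_by_node <- list()
  for (b in net$boundaries) bc_by_node[[b$node]] <- b
  rho <- net$blood$rho
  inc <- node_incidence(net)

  sgrid <- seq(0, 1, length.out = nq + 1)
  ## per-segment linearization state
  st8 <- lapply(segs, function(seg) {
    list(Abar = segment_Ad(seg, sgrid), Q = 0,
         P_prox = seg$p_dia, P_dist = seg$p_dia)
  })

  seg_Rv <- function(seg, Abar) {
    sten <- sten_by_seg[[seg$id]]
    kf <- friction_coefficient(net$blood)
    if (is.null(sten)) return(trapz_uniform(kf / Abar^2, seg$length / nq))
    x <- sgrid * seg$length
    inside <- x > sten$x_start & x < sten$x_start + sten$length_s
    w <- ifelse(inside, 0, 1)       # stenotic span removed from the 1D domain
    y <- w * kf / Abar^2
    trapz_uniform(y, seg$length / nq)
  }

  pt <- stats::setNames(rep(segs[[1]]$p_dia, nn), nodes)
  iter <- 0; resid <- Inf
  for (iter in seq_len(max_iter)) {
    G <- matrix(0, nn, nn)
    rhs <- numeric(nn)
    stamp_edge <- function(a, b, R, S) {
      g <- 1 / R
      G[a, a] <<- G[a, a] + g; G[a, b] <<- G[a, b] - g
      G[b, b] <<- G[b, b] + g; G[b, a] <<- G[b, a] - g
      rhs[a] <<- rhs[a] + g * S
      rhs[b] <<- rhs[b] - g * S
    }
    for (seg in segs) {
      s <- st8[[seg$id]]
      Rv <- seg_Rv(seg, s$Abar)
      Sdyn <- 0
      if (include_dynamic) {
        Ua <- s$Q / s$Abar[1]; Ub <- s$Q / s$Abar[nq + 1]
        Sdyn <- rho * (Ua^2 - Ub^2) / 2
      }
      sten <- sten_by_seg[[seg$id]]
      if (!is.null(sten)) {
        Rv <- Rv + sten$K_visc + 2 * sten$K_exp * abs(s$Q)
        Sdyn <- Sdyn - sten$K_exp * s$Q * abs(s$Q)
      }
      stamp_edge(nid[seg$from_node], nid[seg$to_node], Rv, Sdyn)
    }
    for (b in net$boundaries) {
      a <- nid[b$node]
      if (b$variant == "inflow_Q") {
        rhs[a] <- rhs[a] + mean_inflow
      } else if (b$variant == "inflow_P") {
        ## Dirichlet node at the mean prescribed pressure
        G[a, ] <- 0; G[a, a] <- 1
        rhs[a] <- wave_mean(b$params$wave)
      } else if (b$variant %in% c("wk3", "wk_cor")) {
        p <- b$params
        Rout <- if (b$variant == "wk3") p$R1 + p$R2 else p$R_a + p$R_m + p$R_v_out
        Sout <- 0
        if (include_dynamic) {
          ## the WK sees static pressure; remove the node's dynamic head,
          ## estimated from the adjacent segment face (lagged)
          e <- inc[[b$node]][[1]]
          seg <- segs[[e[1]]]
          s <- st8[[seg$id]]
          A <- if (e[2] == "prox") s$Abar[1] else s$Abar[nq + 1]
          Sout <- rho * (s$Q / A)^2 / 2
        }
        g <- 1 / Rout
        G[a, a] <- G[a, a] + g
        rhs[a] <- rhs[a] + g * (p$P_out + Sout)
      }
    }
    pt_new <- stats::setNames(drop(solve(G, rhs)), nodes)
    ## recover segment flows and end static pressures; update areas
    for (seg in segs) {
      s <- st8[[seg$id]]
      Rv <- seg_Rv(seg, s$Abar)
      Sdyn <- 0
      if (include_dynamic) {
        Ua <- s$Q / s$Abar[1]; Ub <- s$Q / s$Abar[nq + 1]
        Sdyn <- rho * (Ua^2 - Ub^2) / 2
      }
      sten <- sten_by_seg[[seg$id]]
      if (!is.null(sten)) {
        Rv <- Rv + sten$K_visc + 2 * sten$K_exp * abs(s$Q)
        Sdyn <- Sdyn - sten$K_exp * s$Q * abs(s$Q)
      }
      Q <- (pt_new[seg$from_node] - pt_new[seg$to_node] - Sdyn) / Rv
      st8[[seg$id]]$Q <- unname(Q)
      Pa <- pt_new[seg$from_node]; Pb <- pt_new[seg$to_node]
      if (include_dynamic) {
        Pa <- Pa - rho * (Q / s$Abar[1])^2 / 2
        Pb <- Pb - rho * (Q / s$Abar[nq + 1])^2 / 2
      }
      st8[[seg$id]]$P_prox <- unname(Pa)
      st8[[seg$id]]$P_dist <- unname(Pb)
      if (areas == "picard") {
        Px <- Pa + sgrid * (Pb - Pa)
        st8[[seg$id]]$Abar <- tube_law_area(Px, segment_Ad(seg, sgrid),
                                            segment_beta(seg, sgrid), seg$p_dia)
      }
    }
    resid <- max(abs(pt_new - pt)) / max(abs(pt_new))
    pt <- pt_new
    if (resid <= tol && iter > 1) break
  }
  if (resid > tol)
    stop("solve_steady did not converge in ", max_iter,
         " Picard sweeps (residual ", format(resid), ")")
  if (inflow_P) {
    root <- inc[[infl$node]][[1]][1]
    mean_inflow <- st8[[root]]$Q
  }
  structure(list(node_pt = pt, segments = st8, sgrid = sgrid,
                 mean_inflow = mean_inflow, iterations = iter,
                 residual = resid, include_dynamic = include_dynamic),
            class = "steady_solution")
}

#' Mean state of the steady solution at a site
#'
#' @param net the network the solution was computed on.
#' @param ss a \code{steady_solution}.
#' @param seg_id segment id.
#' @param pos relative position in [0, 1].
#' @return list with static pressure \code{P}, flow \code{Q}, area \code{A}
#'   and wave speed \code{c} at the site.
#' @export
steady_state_at <- function(net, ss, seg_id, pos = 1) {
  seg <- net$segments[[seg_id]]
  if (is.null(seg)) stop("unknown segment ", seg_id)
  s <- ss$segments[[seg_id]]
  P <- s$P_prox + pos * (s$P_dist - s$P_prox)
  A <- stats::approx(ss$sgrid, s$Abar, xout = pos)$y
  cc <- local_wave_speed(A, segment_Ad(seg, pos), segment_beta(seg, pos),
                         net$blood$rho)
  list(P = unname(P), Q = s$Q, A = A, c = cc)
}

#' @export
print.steady_solution <- function(x, ...) {
  cat(sprintf("<steady_solution: %d nodes, %d iterations, residual %.2e>\n",
              length(x$node_pt), x$iterations, x$residual))
  invisible(x)
}
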