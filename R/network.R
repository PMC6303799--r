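#' Boundary condition
#'
#' Attaches an inflow or outflow model to a network node. Variants:
#' \describe{
#'   \item{inflow_Q}{prescribed periodic flow waveform (\code{wave}).}
#'   \item{inflow_P}{prescribed periodic pressure waveform (\code{wave}).}
#'   \item{wk3}{three-element Windkessel: proximal resistance \code{R1},
#'     compliance \code{C}, peripheral resistance \code{R2}, reference
#'     pressure \code{P_out} (all CGS).}
#'   \item{wk_cor}{coronary Windkessel chain
#'     R_a -> C_a -> R_m -> C_m -> R_v_out with the intramyocardial
#'     compliance C_m referenced to \code{gamma_im} times a left-ventricular
#'     pressure waveform \code{lv_pressure}; \code{alpha} records the
#'     hyperaemic resistance divisor already applied.}
#' }
#'
#' @param node node name the condition attaches to.
#' @param variant one of \code{"inflow_Q"}, \code{"inflow_P"}, \code{"wk3"},
#'   \code{"wk_cor"}.
#' @param ... variant parameters (see Details).
#' @return an object of class \code{boundary_condition}.
#' @export
boundary_condition <- function(node, variant = c("inflow_Q", "inflow_P", "wk3", "wk_cor"),
                               ...) {
  variant <- match.arg(variant)
  params <- list(...)
  bc <- structure(list(node = as.character(node), variant = variant,
                       params = params), class = "boundary_condition")
  validate_boundary(bc)
  bc
}

validate_boundary <- function(bc) {
  p <- bc$params
  switch(bc$variant,
    inflow_Q = ,
    inflow_P = {
      if (!inherits(p$wave, "periodic_waveform"))
        stop("boundary at node ", bc$node, ": inflow needs a periodic_waveform 'wave'")
    },
    wk3 = {
      need <- c("R1", "C", "R2", "P_out")
      miss <- setdiff(need, names(p))
      if (length(miss)) stop("wk3 boundary at node ", bc$node,
                             ": missing ", paste(miss, collapse = ", "))
      if (p$R1 <= 0 || p$R2 <= 0) stop("wk3 boundary at node ", bc$node,
                                       ": resistances must be positive")
      if (p$C <= 0) stop("wk3 boundary at node ", bc$node, ": compliance must be positive")
    },
    wk_cor = {
      need <- c("R_a", "C_a", "R_m", "C_m", "R_v_out", "lv_pressure")
      miss <- setdiff(need, names(p))
      if (length(miss)) stop("wk_cor boundary at node ", bc$node,
                             ": missing ", paste(miss, collapse = ", "))
      if (any(c(p$R_a, p$R_m, p$R_v_out) <= 0))
        stop("wk_cor boundary at node ", bc$node, ": resistances must be positive")
      if (any(c(p$C_a, p$C_m) <= 0))
        stop("wk_cor boundary at node ", bc$node, ": compliances must be positive")
      if (!inherits(p$lv_pressure, "periodic_waveform"))
        stop("wk_cor boundary at node ", bc$node, ": lv_pressure must be a periodic_waveform")
      if (is.null(p$gamma_im)) bc$params$gamma_im <- 1
      if (!is.null(p$alpha) && p$alpha < 1)
        stop("wk_cor boundary at node ", bc$node, ": alpha must be >= 1")
    })
  invisible(bc)
}

#' Stenosis descriptor
#'
#' A focal narrowing inside a segment. In the pulse-wave solver the stenotic
#' span is removed from the 1D grid and replaced by an internal two-way
#' junction carrying the empirical pressure loss
#' \deqn{\Delta P = K_{visc} Q + K_{exp} Q |Q|.}
#'
#' @param segment_id id of the host segment.
#' @param x_start axial start of the stenotic span (cm from proximal face).
#' @param length_s span length (cm).
#' @param A0 unobstructed reference area (cm^2).
#' @param As minimal stenotic area (cm^2), 0 < As < A0.
#' @param K_visc viscous loss coefficient (dyn s cm^-5); computed from
#'   geometry when NULL.
#' @param K_exp expansion loss coefficient (dyn s^2 cm^-8); computed from
#'   geometry when NULL.
#' @param blood \code{blood_properties} used when computing default
#'   coefficients.
#' @return an object of class \code{stenosis_descriptor}.
#' @export
stenosis_descriptor <- function(segment_id, x_start, length_s, A0, As,
                                K_visc = NULL, K_exp = NULL,
                                blood = blood_properties()) {
  if (!(As > 0 && As < A0)) stop("stenosis on segment ", segment_id,
                                 ": require 0 < As < A0")
  if (length_s <= 0) stop("stenosis length must be positive")
  if (is.null(K_visc) || is.null(K_exp)) {
    k <- stenosis_coefficients(A0, As, length_s, blood)
    if (is.null(K_visc)) K_visc <- k$K_visc
    if (is.null(K_exp)) K_exp <- k$K_exp
  }
  if (K_visc < 0 || K_exp < 0) stop("stenosis coefficients must be non-negative")
  structure(list(segment_id = as.character(segment_id), x_start = x_start,
                 length_s = length_s, A0 = A0, As = As,
                 K_visc = K_visc, K_exp = K_exp),
            class = "stenosis_descriptor")
}

#' Empirical stenosis loss coefficients from geometry
#'
#' Young-Tsai-type rule: \eqn{K_{visc} = K_v \mu L_s / (A_0 D_0^2)} with
#' \eqn{K_v = 32 (0.83 L_s + 1.64 D_s)(A_0/A_s)^2 / D_0} and
#' \eqn{K_{exp} = \frac{K_t \rho}{2 A_0^2}(A_0/A_s - 1)^2}, K_t = 1.52.
#' Used as default when explicit coefficients are not stored with the
#' network; stored coefficients always take precedence.
#'
#' @param A0 unobstructed area (cm^2).
#' @param As minimal area (cm^2).
#' @param length_s stenosis length (cm).
#' @param blood \code{blood_properties}.
#' @return list with \code{K_visc}, \code{K_exp}.
#' @export
stenosis_coefficients <- function(A0, As, length_s, blood = blood_properties()) {
  D0 <- 2 * sqrt(A0 / pi)
  Ds <- 2 * sqrt(As / pi)
  Kv <- 32 * (0.83 * length_s + 1.64 * Ds) * (A0 / As)^2 / D0
  Kt <- 1.52
  list(K_visc = Kv * blood$mu / (A0 * D0^2),
       K_exp = Kt * blood$rho / (2 * A0^2) * (A0 / As - 1)^2)
}

#' Stenosis pressure loss
#'
#' \deqn{\Delta P = K_{visc} Q + K_{exp} Q |Q|} for the (signed)
#' trans-stenotic flow Q.
#'
#' @param Q flow (cm^3 s^-1); vectorised.
#' @param sten a \code{stenosis_descriptor}.
#' @return pressure loss (dyn cm^-2).
#' @export
stenosis_pressure_loss <- function(Q, sten) {
  sten$K_visc * Q + sten$K_exp * Q * abs(Q)
}

#' Vascular network
#'
#' Directed graph of arterial segments joined at named nodes, with stenoses,
#' boundary conditions and blood properties. Segment orientation (proximal ->
#' distal) must point away from the inflow node along every branch.
#'
#' @param segments list of \code{\link{arterial_segment}}.
#' @param boundaries list of \code{\link{boundary_condition}}.
#' @param stenoses list of \code{\link{stenosis_descriptor}}.
#' @param blood a \code{\link{blood_properties}}.
#' @param meta optional named list of metadata (e.g. \code{proximal_ids}
#'   declaring the proximal aorta / major branch segments used by the ageing
#'   scenario).
#' @param validate run \code{\link{validate_network}}.
#' @return an object of class \code{vascular_network}.
#' @export
vascular_network <- function(segments, boundaries, stenoses = list(),
                             blood = blood_properties(), meta = list(),
                             validate = TRUE) {
  names(segments) <- vapply(segments, `[[`, "", "id")
  net <- structure(list(segments = segments, boundaries = boundaries,
                        stenoses = stenoses, blood = blood, meta = meta),
                   class = "vascular_network")
  if (validate) validate_network(net)
  net
}

## node -> list of c(segment id, end "prox"/"dist")
node_incidence <- function(net) {
  inc <- list()
  for (seg in net$segments) {
    inc[[seg$from_node]] <- c(inc[[seg$from_node]], list(c(seg$id, "prox")))
    inc[[seg$to_node]] <- c(inc[[seg$to_node]], list(c(seg$id, "dist")))
  }
  inc
}

#' The unique inflow boundary condition of a network
#' @param net a \code{vascular_network}.
#' @return the inflow \code{boundary_condition}.
#' @export
inflow_boundary <- function(net) {
  infl <- Filter(function(b) b$variant %in% c("inflow_Q", "inflow_P"), net$boundaries)
  if (length(infl) != 1) stop("network must have exactly one inflow boundary, found ",
                              length(infl))
  infl[[1]]
}

#' Validate a vascular network
#'
#' Checks connectivity, boundary placement (every terminal face carries
#' exactly one boundary condition, exactly one inflow), orientation, stenosis
#' geometry and positivity invariants. Loops (e.g. a circle of Willis) are
#' permitted.
#'
#' @param net a \code{vascular_network}.
#' @return the network, invisibly; errors describe the offending element.
#' @export
validate_network <- function(net) {
  ids <- vapply(net$segments, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate segment ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  if (!length(net$segments)) stop("network has no segments")
  inc <- node_incidence(net)
  ## connectivity by BFS over nodes
  nodes <- names(inc)
  seen <- structure(rep(FALSE, length(nodes)), names = nodes)
  queue <- nodes[1]; seen[queue] <- TRUE
  while (length(queue)) {
    nd <- queue[1]; queue <- queue[-1]
    for (e in inc[[nd]]) {
      seg <- net$segments[[e[1]]]
      other <- if (e[2] == "prox") seg$to_node else seg$from_node
      if (!seen[other]) { seen[other] <- TRUE; queue <- c(queue, other) }
    }
  }
  if (!all(seen)) stop("network is not connected; unreachable nodes: ",
                       paste(nodes[!seen], collapse = ", "))
  bnodes <- vapply(net$boundaries, `[[`, "", "node")
  if (anyDuplicated(bnodes)) stop("multiple boundary conditions at node(s): ",
                                  paste(unique(bnodes[duplicated(bnodes)]), collapse = ", "))
  infl <- inflow_boundary(net)
  deg <- vapply(inc, length, 0L)
  term <- names(deg)[deg == 1]
  missing_bc <- setdiff(term, bnodes)
  if (length(missing_bc)) stop("terminal node(s) without boundary condition: ",
                               paste(missing_bc, collapse = ", "))
  orphan_bc <- setdiff(bnodes, nodes)
  if (length(orphan_bc)) stop("boundary condition at unknown node(s): ",
                              paste(orphan_bc, collapse = ", "))
  ## orientation: inflow node must be a proximal face; terminal outlets distal
  ie <- inc[[infl$node]]
  if (deg[infl$node] != 1 || ie[[1]][2] != "prox")
    stop("inflow node must be the proximal face of a single root segment")
  for (b in net$boundaries) {
    if (b$variant %in% c("wk3", "wk_cor") && deg[b$node] == 1) {
      e <- inc[[b$node]][[1]]
      if (e[2] != "dist")
        stop("outlet boundary at node ", b$node,
             " must attach to a distal segment face (reorient segment ", e[1], ")")
    }
    validate_boundary(b)
  }
  for (st in net$stenoses) {
    seg <- net$segments[[st$segment_id]]
    if (is.null(seg)) stop("stenosis references unknown segment ", st$segment_id)
    if (st$x_start < 0 || st$x_start + st$length_s >= seg$length)
      stop("stenosis span outside segment ", st$segment_id)
    if (!(st$As > 0 && st$As < st$A0))
      stop("stenosis on segment ", st$segment_id, ": require 0 < As < A0")
  }
  ## wall law must be physical over every segment's radius range
  for (seg in net$segments) {
    if (is.null(seg$beta)) invisible(wall_Eh(c(seg$r_prox, seg$r_dist), seg$wall))
    else if (seg$beta <= 0) stop("segment ", seg$id, ": beta override must be positive")
  }
  invisible(net)
}

#' Segments disconnected from the inflow by removing one segment
#'
#' The "distal set" of a cut at the distal face of \code{seg_id}: every
#' segment whose connection to the inflow passes through \code{seg_id}. On a
#' tree this is the subtree hanging from the segment's distal node; inside a
#' loop it is empty (flow can route around).
#'
#' @param net a \code{vascular_network}.
#' @param seg_id id of the cut segment (retained; its distal face is the cut).
#' @return character vector of removed segment ids (possibly empty).
#' @export
distal_segments <- function(net, seg_id) {
  if (is.null(net$segments[[seg_id]])) stop("unknown segment ", seg_id)
  infl <- inflow_boundary(net)
  inc <- node_incidence(net)
  seen <- structure(rep(FALSE, length(inc)), names = names(inc))
  queue <- infl$node; seen[queue] <- TRUE
  while (length(queue)) {
    nd <- queue[1]; queue <- queue[-1]
    for (e in inc[[nd]]) {
      if (e[1] == seg_id) next
      seg <- net$segments[[e[1]]]
      other <- if (e[2] == "prox") seg$to_node else seg$from_node
      if (!seen[other]) { seen[other] <- TRUE; queue <- c(queue, other) }
    }
  }
  reach <- names(seen)[seen]
  removed <- vapply(net$segments, function(s)
    !(s$from_node %in% reach) || !(s$to_node %in% reach), TRUE)
  setdiff(names(net$segments)[removed], seg_id)
}

#' @export
print.vascular_network <- function(x, ...) {
  nb <- vapply(x$boundaries, `[[`, "", "variant")
  cat(sprintf("<vascular_network: %d segments, %d stenoses, boundaries: %s>\n",
              length(x$segments), length(x$stenoses),
              paste(sprintf("%s x%d", names(table(nb)), table(nb)), collapse = ", ")))
  invisible(x)
}
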