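#' Arterial segment
#'
#' One 1D model segment: a straight compliant tube with linearly tapering
#' diastolic radius between its proximal and distal faces. Wall stiffness is
#' taken from a \code{\link{wall_law}} evaluated at the local diastolic radius,
#' unless an explicit constant \code{beta} override is given.
#'
#' @param id segment identifier (character).
#' @param length segment length (cm).
#' @param r_prox,r_dist diastolic radii at the proximal/distal face (cm).
#' @param from_node,to_node node names of the proximal/distal face.
#' @param wall a \code{\link{wall_law}} object.
#' @param beta optional explicit tube-law stiffness override
#'   (g s^-2 cm^-1), constant along the segment.
#' @param beta_scale multiplier on the wall stiffness (used by scenario
#'   re-parametrizations such as ageing).
#' @param p_dia diastolic reference pressure (dyn cm^-2).
#' @param name optional human-readable label.
#' @return an object of class \code{arterial_segment}.
#' @export
arterial_segment <- function(id, length, r_prox, r_dist, from_node, to_node,
                             wall = wall_law("systemic"), beta = NULL,
                             beta_scale = 1, p_dia = mmHg_to_dyn(80), name = id) {
  if (length <= 0) stop("segment ", id, ": length must be positive")
  if (r_prox <= 0 || r_dist <= 0) stop("segment ", id, ": radii must be positive")
  if (beta_scale <= 0) stop("segment ", id, ": beta_scale must be positive")
  structure(list(id = as.character(id), name = name, length = length,
                 r_prox = r_prox, r_dist = r_dist,
                 from_node = as.character(from_node),
                 to_node = as.character(to_node),
                 wall = wall, beta = beta, beta_scale = beta_scale,
                 p_dia = p_dia),
            class = "arterial_segment")
}

## Local diastolic geometry along the taper; s is relative position in [0, 1].
segment_radius <- function(seg, s) seg$r_prox + s * (seg$r_dist - seg$r_prox)
segment_Ad <- function(seg, s) pi * segment_radius(seg, s)^2

segment_beta <- function(seg, s) {
  sc <- if (is.null(seg$beta_scale)) 1 else seg$beta_scale
  sc * (if (!is.null(seg$beta)) rep(seg$beta, length(s))
        else tube_beta(segment_radius(seg, s), seg$wall))
}

## Diastolic wave speed along the segment (from beta if overridden).
segment_cd <- function(seg, s, blood) {
  b <- segment_beta(seg, s)
  Ad <- segment_Ad(seg, s)
  sqrt(b / (2 * blood$rho * sqrt(Ad)))
}

#' Viscous (Poiseuille-type) resistance of a segment
#'
#' \deqn{R_v = \int_0^l \frac{2(\zeta+2)\pi\mu}{\bar A(x)^2}\,dx,} evaluated by
#' composite trapezoid along the taper. By default the diastolic area profile
#' is used as linearization state; an explicit mean-area profile may be
#' supplied (as from the steady network solve).
#'
#' @param seg an \code{arterial_segment}.
#' @param blood a \code{blood_properties}.
#' @param n number of quadrature intervals.
#' @param Abar optional function of relative position s in [0,1] returning the
#'   linearization area (cm^2); defaults to the diastolic area profile.
#' @return R_v (dyn s cm^-5).
#' @export
segment_viscous_resistance <- function(seg, blood, n = 64, Abar = NULL) {
  s <- seq(0, 1, length.out = n + 1)
  A <- if (is.null(Abar)) segment_Ad(seg, s) else Abar(s)
  integrand <- friction_coefficient(blood) / A^2
  trapz_uniform(integrand, seg$length / n)
}

#' Volume compliance of a segment
#'
#' \deqn{C_v = \frac{1}{\rho}\int_0^l \frac{\bar A(x)}{\bar c(x)^2}\,dx,}
#' by composite trapezoid. Defaults to the diastolic state; mean-state
#' profiles from a steady solve may be supplied.
#'
#' @inheritParams segment_viscous_resistance
#' @param cbar optional function of s returning the linearization wave speed.
#' @return C_v (cm^5 dyn^-1).
#' @export
segment_volume_compliance <- function(seg, blood, n = 64, Abar = NULL, cbar = NULL) {
  s <- seq(0, 1, length.out = n + 1)
  A <- if (is.null(Abar)) segment_Ad(seg, s) else Abar(s)
  cc <- if (is.null(cbar)) segment_cd(seg, s, blood) else cbar(s)
  trapz_uniform(A / cc^2, seg$length / n) / blood$rho
}

trapz_uniform <- function(y, h) {
  n <- length(y)
  h * (sum(y) - 0.5 * (y[1] + y[n]))
}

#' @export
print.arterial_segment <- function(x, ...) {
  cat(sprintf("<arterial_segment %s: l=%.3g cm, r=%.3g->%.3g cm, %s -> %s>\n",
              x$id, x$length, x$r_prox, x$r_dist, x$from_node, x$to_node))
  invisible(x)
}
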