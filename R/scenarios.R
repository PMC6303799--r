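#' Re-parametrize a network to represent normal ageing
#'
#' Ageing stiffens the arterial wall and raises peripheral resistance. The
#' tube-law stiffness beta is multiplied by \code{beta_proximal} (default 2.5)
#' on a declared list of proximal aorta / major branch segments and by
#' \code{beta_other} (default 1.5) elsewhere. Every WK3 outlet's total
#' resistance is scaled by \code{resistance_factor} (default 1.1) through its
#' peripheral resistance R2, so the parallel total arterial resistance scales
#' by exactly that factor. WK3 compliances are then rescaled so that the
#' total arterial compliance (sum of outlet compliances plus integrated 1D
#' compliance after stiffening) equals \code{compliance_factor} (default 1/2)
#' times its baseline value.
#'
#' @param net a \code{vascular_network} with WK3 outlets.
#' @param proximal_ids character vector of segment ids forming the "proximal
#'   aorta and major branches" list; defaults to
#'   \code{net$meta$proximal_ids}.
#' @param resistance_factor total-resistance multiplier.
#' @param compliance_factor total-compliance multiplier.
#' @param beta_proximal,beta_other stiffness multipliers.
#' @return a new \code{vascular_network}; the input is not modified.
#' @export
apply_ageing <- function(net, proximal_ids = net$meta$proximal_ids,
                         resistance_factor = 1.1, compliance_factor = 0.5,
                         beta_proximal = 2.5, beta_other = 1.5) {
  wk3_idx <- which(vapply(net$boundaries, function(b) b$variant == "wk3", TRUE))
  if (!length(wk3_idx)) stop("apply_ageing requires a network with WK3 outlets")
  if (is.null(proximal_ids)) proximal_ids <- character()
  unknown <- setdiff(proximal_ids, names(net$segments))
  if (length(unknown)) stop("proximal_ids not in network: ",
                            paste(unknown, collapse = ", "))
  c1d_base <- total_1d_compliance(net)
  cwk_base <- sum(vapply(net$boundaries[wk3_idx], function(b) b$params$C, 0))
  out <- net
  for (id in names(out$segments)) {
    f <- if (id %in% proximal_ids) beta_proximal else beta_other
    sc <- out$segments[[id]]$beta_scale
    out$segments[[id]]$beta_scale <- (if (is.null(sc)) 1 else sc) * f
  }
  c1d_aged <- total_1d_compliance(out)
  c_target <- compliance_factor * (c1d_base + cwk_base)
  s_c <- (c_target - c1d_aged) / cwk_base
  if (s_c <= 0) stop("ageing compliance target unattainable: stiffened 1D ",
                     "compliance already exceeds the target total")
  for (i in wk3_idx) {
    p <- out$boundaries[[i]]$params
    rtot_new <- resistance_factor * (p$R1 + p$R2)
    if (rtot_new <= p$R1) stop("ageing resistance target below R1 at node ",
                               out$boundaries[[i]]$node)
    out$boundaries[[i]]$params$R2 <- rtot_new - p$R1
    out$boundaries[[i]]$params$C <- p$C * s_c
  }
  validate_network(out)
  out
}

## Integrated compliance of all 1D segments at the diastolic state.
total_1d_compliance <- function(net) {
  sum(vapply(net$segments, segment_volume_compliance, 0, blood = net$blood))
}

## Parallel total of outlet resistances (1/sum of conductances).
total_outlet_resistance <- function(net) {
  g <- 0
  for (b in net$boundaries) {
    if (b$variant == "wk3") g <- g + 1 / (b$params$R1 + b$params$R2)
    if (b$variant == "wk_cor")
      g <- g + 1 / (b$params$R_a + b$params$R_m + b$params$R_v_out)
  }
  if (g == 0) stop("network has no outlet boundaries")
  1 / g
}

#' Insert an aortic-coarctation-type stenosis
#'
#' Adds a \code{\link{stenosis_descriptor}} centred at the midpoint of a
#' segment, with minimal area \code{diameter_fraction^2} times the local
#' unobstructed area and loss coefficients from the geometric rule
#' (\code{\link{stenosis_coefficients}}).
#'
#' @param net a \code{vascular_network}.
#' @param segment_id host segment.
#' @param length_s stenosis length (cm), default 1.
#' @param diameter_fraction residual diameter as a fraction of the
#'   unobstructed diameter (0.5 = a 50\% diameter stenosis).
#' @return a new \code{vascular_network} with the stenosis added.
#' @export
insert_coarctation <- function(net, segment_id, length_s = 1,
                               diameter_fraction = 0.5) {
  seg <- net$segments[[segment_id]]
  if (is.null(seg)) stop("unknown segment ", segment_id)
  if (length_s >= seg$length)
    stop("stenosis length ", length_s, " cm does not fit in segment ",
         segment_id, " (", seg$length, " cm)")
  if (diameter_fraction <= 0 || diameter_fraction > 1)
    stop("diameter_fraction must be in (0, 1]")
  A0 <- segment_Ad(seg, 0.5)
  if (diameter_fraction == 1) return(net)  # no constriction
  sten <- stenosis_descriptor(segment_id,
                              x_start = seg$length / 2 - length_s / 2,
                              length_s = length_s,
                              A0 = A0, As = diameter_fraction^2 * A0,
                              blood = net$blood)
  out <- net
  out$stenoses <- c(out$stenoses, list(sten))
  validate_network(out)
  out
}

#' Rescale an inflow waveform to a new heart rate, ejection time and stroke
#' volume
#'
#' The contiguous support of positive flow (the ejection interval) is
#' time-scaled to the new ejection time \code{ET}, the amplitude is scaled so
#' the waveform integrates to \code{SV} over the new period 60/HR, and flow
#' is zero outside ejection.
#'
#' @param wave a \code{periodic_waveform} of flow with an identifiable
#'   ejection interval.
#' @param HR heart rate (beats per minute).
#' @param ET ejection time (s), must be shorter than the period.
#' @param SV stroke volume (cm^3).
#' @param n number of samples of the output waveform.
#' @return a \code{periodic_waveform}.
#' @export
rescale_inflow <- function(wave, HR, ET, SV, n = 1000) {
  T_new <- 60 / HR
  if (ET >= T_new) stop("ejection time ET must be shorter than the period 60/HR")
  v <- wave$values
  thr <- 1e-6 * max(v)
  pos <- v > thr
  if (!any(pos)) stop("inflow waveform has no positive ejection interval")
  ## contiguous run containing the maximum (rotate so it does not wrap)
  imax <- which.max(v)
  nsmp <- length(v)
  i0 <- imax; while (pos[((i0 - 2) %% nsmp) + 1] && i0 != imax + 1) {
    i0 <- ((i0 - 2) %% nsmp) + 1
    if (i0 == imax) break
  }
  i1 <- imax; while (pos[(i1 %% nsmp) + 1] && i1 != imax - 1) {
    i1 <- (i1 %% nsmp) + 1
    if (i1 == imax) break
  }
  dt0 <- wave$period / nsmp
  t_start <- (i0 - 1) * dt0
  et0 <- (((i1 - i0) %% nsmp) + 1) * dt0
  ## sample the ejection lobe on its own relative coordinate
  s_rel <- function(s) wave_interp(wave, t_start + s * et0)
  t_new_start <- min(t_start, T_new - ET)
  t_out <- (0:(n - 1)) * T_new / n
  q <- numeric(n)
  inside <- (t_out - t_new_start) >= 0 & (t_out - t_new_start) <= ET
  q[inside] <- s_rel((t_out[inside] - t_new_start) / ET)
  q[q < 0] <- 0
  integ <- sum(q) * T_new / n
  if (integ <= 0) stop("rescaled waveform has nonpositive volume")
  periodic_waveform(t_out, q * SV / integ, T_new)
}

#' Apply coronary hyperaemia
#'
#' Divides the total resistance of every coronary (wk_cor) outlet by a factor
#' alpha, preserving the internal resistance ratios:
#' \code{alpha_healthy} (default 3) for healthy outlets and
#' \code{alpha_diseased} (default 1.25) for outlets distal of a stenosis.
#'
#' @param net a \code{vascular_network} with coronary outlets.
#' @param alpha_healthy resistance divisor for healthy outlets (>= 1).
#' @param alpha_diseased resistance divisor for diseased outlets (>= 1).
#' @param diseased_outlets node names of outlets distal of the stenosis.
#' @return a new \code{vascular_network}.
#' @export
set_hyperaemia <- function(net, alpha_healthy = 3, alpha_diseased = 1.25,
                           diseased_outlets = character()) {
  cor_idx <- which(vapply(net$boundaries, function(b) b$variant == "wk_cor", TRUE))
  if (!length(cor_idx)) stop("set_hyperaemia requires coronary outlets")
  if (alpha_healthy < 1 || alpha_diseased < 1) stop("alpha must be >= 1")
  cor_nodes <- vapply(net$boundaries[cor_idx], `[[`, "", "node")
  unknown <- setdiff(diseased_outlets, cor_nodes)
  if (length(unknown)) stop("diseased outlet(s) not found among coronary outlets: ",
                            paste(unknown, collapse = ", "))
  out <- net
  for (i in cor_idx) {
    nd <- out$boundaries[[i]]$node
    a <- if (nd %in% diseased_outlets) alpha_diseased else alpha_healthy
    p <- out$boundaries[[i]]$params
    out$boundaries[[i]]$params$R_a <- p$R_a / a
    out$boundaries[[i]]$params$R_m <- p$R_m / a
    out$boundaries[[i]]$params$R_v_out <- p$R_v_out / a
    prev <- if (is.null(p$alpha)) 1 else p$alpha
    out$boundaries[[i]]$params$alpha <- prev * a
  }
  out
}

#' Distribute total coronary resistance and compliance among outlets
#'
#' The total coronary resistance is set from the mean driving pressure and
#' the coronary share of cardiac output (Ohm's law); it is then apportioned
#' so that outlet flows follow Murray's law (flow proportional to radius to
#' the power \code{murray_exponent}, so outlet resistance proportional to
#' r^-murray_exponent). Compliance is distributed proportional to
#' r^murray_exponent.
#'
#' @param CO cardiac output (cm^3 s^-1).
#' @param mean_Pp mean perfusion (proximal) pressure (dyn cm^-2).
#' @param P_out outflow reference pressure (dyn cm^-2).
#' @param outlet_radii vector of outlet radii (cm), optionally named.
#' @param coronary_fraction fraction of CO perfusing the coronaries
#'   (default 0.045).
#' @param C_total total coronary compliance to distribute (cm^5 dyn^-1).
#' @param murray_exponent exponent of Murray's law (default 3).
#' @return data.frame with one row per outlet: radius, Q (mean flow),
#'   R_total and C_total.
#' @export
distribute_coronary_outlet_params <- function(CO, mean_Pp, P_out, outlet_radii,
                                              coronary_fraction = 0.045,
                                              C_total = 3.6e-5,
                                              murray_exponent = 3) {
  if (any(outlet_radii <= 0)) stop("outlet radii must be positive")
  if (mean_Pp <= P_out) stop("mean perfusion pressure must exceed P_out")
  Q_cor <- coronary_fraction * CO
  w <- outlet_radii^murray_exponent
  w <- w / sum(w)
  Q_i <- Q_cor * w
  R_i <- (mean_Pp - P_out) / Q_i
  data.frame(outlet = if (is.null(names(outlet_radii)))
               paste0("outlet", seq_along(outlet_radii)) else names(outlet_radii),
             radius = outlet_radii, Q = Q_i, R_total = R_i,
             C_total = C_total * w, stringsAsFactors = FALSE)
}
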