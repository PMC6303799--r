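#' Read and write vascular networks as JSON
#'
#' The on-disk schema uses clinical units (mm radii, mmHg pressures); all
#' values are converted to internal CGS on load. The document carries
#' \code{blood}, \code{segments} (id, name, length_cm, r_prox_mm, r_dist_mm,
#' wall_law, p_dia_mmHg, from_node, to_node, optional beta), \code{stenoses},
#' \code{boundaries} and a derived \code{connections} map (junction node ->
#' list of [segment_id, end]).
#'
#' @param path file path of the network JSON document.
#' @return \code{load_network}: a validated \code{\link{vascular_network}}.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (fld in c("segments", "boundaries"))
    if (is.null(doc[[fld]])) stop("network file missing field '", fld, "'")
  blood <- if (is.null(doc$blood)) blood_properties() else
    blood_properties(doc$blood$rho, doc$blood$mu, doc$blood$zeta)
  segments <- lapply(doc$segments, function(s) {
    for (fld in c("id", "length_cm", "r_prox_mm", "r_dist_mm", "from_node", "to_node"))
      if (is.null(s[[fld]])) stop("segment entry missing field '", fld, "'")
    wl <- parse_wall_law(s$wall_law)
    arterial_segment(
      id = s$id, name = if (is.null(s$name)) s$id else s$name,
      length = s$length_cm,
      r_prox = mm_to_cm(s$r_prox_mm), r_dist = mm_to_cm(s$r_dist_mm),
      from_node = s$from_node, to_node = s$to_node,
      wall = wl, beta = s$beta,
      beta_scale = if (is.null(s$beta_scale)) 1 else s$beta_scale,
      p_dia = mmHg_to_dyn(if (is.null(s$p_dia_mmHg)) 80 else s$p_dia_mmHg))
  })
  stenoses <- lapply(null_to_list(doc$stenoses), function(st) {
    stenosis_descriptor(st$segment_id, st$x_start_cm, st$length_cm,
                        st$A0_cm2, st$As_cm2,
                        K_visc = st$K_visc, K_exp = st$K_exp, blood = blood)
  })
  boundaries <- lapply(doc$boundaries, function(b) parse_boundary(b))
  vascular_network(segments, boundaries, stenoses, blood,
                   meta = null_to_list(doc$meta))
}

null_to_list <- function(x) if (is.null(x)) list() else x

parse_wall_law <- function(wl) {
  if (is.null(wl)) return(wall_law("systemic"))
  if (is.character(wl)) return(wall_law(wl))
  wall_law(if (is.null(wl$kind)) "systemic" else wl$kind,
           k1 = wl$k1, k2 = wl$k2, k3 = wl$k3)
}

parse_wave_json <- function(w) {
  if (is.null(w)) stop("boundary waveform missing")
  t <- unlist(w$t_s)
  if (!is.null(w$q_mls)) return(periodic_waveform(t, unlist(w$q_mls), w$period_s))
  if (!is.null(w$p_mmhg)) return(periodic_waveform(t, mmHg_to_dyn(unlist(w$p_mmhg)),
                                                   w$period_s))
  stop("waveform must carry 'q_mls' or 'p_mmhg' values")
}

parse_boundary <- function(b) {
  if (is.null(b$node) || is.null(b$variant)) stop("boundary entry missing node/variant")
  p <- null_to_list(b$params)
  switch(b$variant,
    inflow_Q = boundary_condition(b$node, "inflow_Q", wave = parse_wave_json(p$wave)),
    inflow_P = boundary_condition(b$node, "inflow_P", wave = parse_wave_json(p$wave)),
    wk3 = boundary_condition(b$node, "wk3", R1 = p$R1, C = p$C, R2 = p$R2,
                             P_out = mmHg_to_dyn(p$p_out_mmHg)),
    wk_cor = boundary_condition(b$node, "wk_cor",
      R_a = p$R_a, C_a = p$C_a, R_m = p$R_m, C_m = p$C_m, R_v_out = p$R_v_out,
      gamma_im = if (is.null(p$gamma_im)) 1 else p$gamma_im,
      alpha = if (is.null(p$alpha)) 1 else p$alpha,
      P_out = mmHg_to_dyn(p$p_out_mmHg),
      lv_pressure = parse_wave_json(p$lv_pressure)),
    stop("unknown boundary variant '", b$variant, "' at node ", b$node))
}

#' @rdname load_network
#' @param net a \code{vascular_network} to serialise.
#' @export
save_network <- function(net, path) {
  segs <- lapply(net$segments, function(s) {
    out <- list(id = s$id, name = s$name, length_cm = s$length,
                r_prox_mm = cm_to_mm(s$r_prox), r_dist_mm = cm_to_mm(s$r_dist),
                from_node = s$from_node, to_node = s$to_node,
                wall_law = list(kind = s$wall$kind, k1 = s$wall$k1,
                                k2 = s$wall$k2, k3 = s$wall$k3),
                p_dia_mmHg = dyn_to_mmHg(s$p_dia))
    if (!is.null(s$beta)) out$beta <- s$beta
    if (!is.null(s$beta_scale) && s$beta_scale != 1) out$beta_scale <- s$beta_scale
    out
  })
  stens <- lapply(net$stenoses, function(st)
    list(segment_id = st$segment_id, x_start_cm = st$x_start,
         length_cm = st$length_s, A0_cm2 = st$A0, As_cm2 = st$As,
         K_visc = st$K_visc, K_exp = st$K_exp))
  bnds <- lapply(net$boundaries, serialise_boundary)
  conns <- list()
  for (s in net$segments) {
    conns[[s$from_node]] <- c(conns[[s$from_node]], list(list(s$id, "prox")))
    conns[[s$to_node]] <- c(conns[[s$to_node]], list(list(s$id, "dist")))
  }
  doc <- list(blood = net$blood[c("rho", "mu", "zeta")],
              segments = unname(segs), stenoses = unname(stens),
              boundaries = unname(bnds), connections = conns,
              meta = net$meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

serialise_wave <- function(w, kind = c("flow", "pressure")) {
  kind <- match.arg(kind)
  if (kind == "flow") list(t_s = w$t, q_mls = w$values, period_s = w$period)
  else list(t_s = w$t, p_mmhg = dyn_to_mmHg(w$values), period_s = w$period)
}

serialise_boundary <- function(b) {
  p <- b$params
  params <- switch(b$variant,
    inflow_Q = list(wave = serialise_wave(p$wave, "flow")),
    inflow_P = list(wave = serialise_wave(p$wave, "pressure")),
    wk3 = list(R1 = p$R1, C = p$C, R2 = p$R2, p_out_mmHg = dyn_to_mmHg(p$P_out)),
    wk_cor = list(R_a = p$R_a, C_a = p$C_a, R_m = p$R_m, C_m = p$C_m,
                  R_v_out = p$R_v_out,
                  gamma_im = if (is.null(p$gamma_im)) 1 else p$gamma_im,
                  alpha = if (is.null(p$alpha)) 1 else p$alpha,
                  p_out_mmHg = dyn_to_mmHg(p$P_out),
                  lv_pressure = serialise_wave(p$lv_pressure, "pressure")))
  list(node = b$node, variant = b$variant, params = params)
}

#' Read/write a waveform as 2-column delimited text
#'
#' The header names the units: \code{t_s,q_mls} for flow (cm^3/s) or
#' \code{t_s,p_mmhg} for pressure; values are converted to CGS on read.
#'
#' @param path file path.
#' @param period optional period override (s).
#' @return a \code{\link{periodic_waveform}} (pressure in dyn cm^-2).
#' @export
read_waveform <- function(path, period = NULL) {
  df <- utils::read.csv(path)
  if (!"t_s" %in% names(df)) stop("waveform file must have a 't_s' column")
  if ("q_mls" %in% names(df)) periodic_waveform(df$t_s, df$q_mls, period)
  else if ("p_mmhg" %in% names(df))
    periodic_waveform(df$t_s, mmHg_to_dyn(df$p_mmhg), period)
  else stop("waveform file must have a 'q_mls' or 'p_mmhg' column")
}

#' @rdname read_waveform
#' @param w a \code{periodic_waveform}.
#' @param kind \code{"flow"} or \code{"pressure"} (sets the unit column).
#' @export
write_waveform <- function(w, path, kind = c("flow", "pressure")) {
  kind <- match.arg(kind)
  df <- if (kind == "flow") data.frame(t_s = w$t, q_mls = w$values)
  else data.frame(t_s = w$t, p_mmhg = dyn_to_mmHg(w$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read arterial segments from a CSV table
#'
#' Column layout mirrors the JSON segment schema: id, name, length_cm,
#' r_prox_mm, r_dist_mm, wall_law (kind name), p_dia_mmHg, from_node,
#' to_node.
#'
#' @param path CSV file path.
#' @return list of \code{\link{arterial_segment}}.
#' @export
read_segments_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    arterial_segment(r$id, r$length_cm, mm_to_cm(r$r_prox_mm), mm_to_cm(r$r_dist_mm),
                     r$from_node, r$to_node,
                     wall = wall_law(if (is.null(r$wall_law)) "systemic" else r$wall_law),
                     p_dia = mmHg_to_dyn(if (is.null(r$p_dia_mmHg)) 80 else r$p_dia_mmHg),
                     name = if (is.null(r$name)) r$id else r$name)
  })
}
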