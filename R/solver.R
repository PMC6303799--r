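#' Solver configuration
#'
#' @param dx_target target grid spacing (cm).
#' @param cfl Courant number in (0, 1] used to set the time step
#'   dt = cfl * min(dx / (|U| + c)), recomputed at each cycle start.
#' @param max_cycles maximum number of cardiac cycles to run.
#' @param periodicity_tol relative cycle-to-cycle L2 change of site pressures
#'   below which the solution is accepted as periodic.
#' @param n_out number of uniform output samples per cycle.
#' @param dt_override fixed time step (s), bypassing the CFL estimate.
#' @return an object of class \code{solver_config}.
#' @export
solver_config <- function(dx_target = 0.25, cfl = 0.9, max_cycles = 20,
                          periodicity_tol = 1e-3, n_out = 1000,
                          dt_override = NULL) {
  if (cfl <= 0 || cfl > 1) stop("cfl must be in (0, 1]")
  if (dx_target <= 0) stop("dx_target must be positive")
  if (periodicity_tol <= 0) stop("periodicity_tol must be positive")
  structure(list(dx_target = dx_target, cfl = cfl, max_cycles = max_cycles,
                 periodicity_tol = periodicity_tol, n_out = n_out,
                 dt_override = dt_override), class = "solver_config")
}

## Discretize a network into solver segments (stenotic spans removed and
## replaced by loss junctions) plus coupling descriptors for the C++ core.
discretize_network <- function(net, dx_target) {
  sten_by_seg <- list()
  for (st in net$stenoses) {
    if (!is.null(sten_by_seg[[st$segment_id]]))
      stop("segment ", st$segment_id, " hosts more than one stenosis")
    sten_by_seg[[st$segment_id]] <- st
  }
  ssegs <- list()
  ends_at_node <- list()   # node -> list of c(sseg index, end 0/1)
  sten_coups <- list()
  add_end <- function(node, idx, end) {
    ends_at_node[[node]] <<- c(ends_at_node[[node]], list(c(idx, end)))
  }
  make_sseg <- function(seg, x0, x1) {
    len <- x1 - x0
    nint <- max(4, ceiling(len / dx_target))
    x <- x0 + (0:nint) * (len / nint)
    s <- x / seg$length
    list(net_id = seg$id, x0 = x0, len = len, dx = len / nint,
         Ad = segment_Ad(seg, s), beta = segment_beta(seg, s),
         Pdia = rep(seg$p_dia, nint + 1))
  }
  for (seg in net$segments) {
    st <- sten_by_seg[[seg$id]]
    if (is.null(st)) {
      ssegs[[length(ssegs) + 1]] <- make_sseg(seg, 0, seg$length)
      i <- length(ssegs)
      add_end(seg$from_node, i, 0)
      add_end(seg$to_node, i, 1)
    } else {
      if (st$x_start <= 0 || st$x_start + st$length_s >= seg$length)
        stop("stenotic span must be interior to segment ", seg$id)
      ssegs[[length(ssegs) + 1]] <- make_sseg(seg, 0, st$x_start)
      i1 <- length(ssegs)
      ssegs[[length(ssegs) + 1]] <- make_sseg(seg, st$x_start + st$length_s,
                                              seg$length)
      i2 <- length(ssegs)
      add_end(seg$from_node, i1, 0)
      add_end(seg$to_node, i2, 1)
      sten_coups[[length(sten_coups) + 1]] <-
        list(type = 0L,
             ends = rbind(c(i1, 1L), c(i2, 0L)),
             kv = c(0, st$K_visc), ke = c(0, st$K_exp),
             inflow = NULL, wk = NULL,
             label = paste0("stenosis:", seg$id))
    }
  }
  bc_by_node <- list()
  for (b in net$boundaries) bc_by_node[[b$node]] <- b
  coups <- list()
  for (node in names(ends_at_node)) {
    ends <- ends_at_node[[node]]
    bc <- bc_by_node[[node]]
    ## distal faces first: end 0 is the pressure/WK reference end
    ord <- order(vapply(ends, function(e) -e[2], 0))
    ends <- ends[ord]
    emat <- do.call(rbind, ends)
    storage.mode(emat) <- "integer"
    n <- nrow(emat)
    if (!is.null(bc) && bc$variant %in% c("inflow_Q", "inflow_P")) {
      coups[[length(coups) + 1]] <-
        list(type = if (bc$variant == "inflow_Q") 1L else 2L,
             ends = emat, kv = numeric(n), ke = numeric(n),
             inflow = bc, wk = NULL, label = node)
    } else {
      wk <- NULL
      if (!is.null(bc)) wk <- list(bc)
      if (is.null(bc) && n == 1)
        stop("terminal node ", node, " has no boundary condition")
      coups[[length(coups) + 1]] <-
        list(type = 0L, ends = emat, kv = numeric(n), ke = numeric(n),
             inflow = NULL, wk = wk, label = node)
    }
  }
  coups <- c(coups, sten_coups)
  list(ssegs = ssegs, coups = coups)
}

## Map a (segment_id, relative position) site onto a solver segment node.
site_to_node <- function(disc, net, seg_id, pos) {
  seg <- net$segments[[seg_id]]
  if (is.null(seg)) stop("output site on unknown segment ", seg_id)
  if (pos < 0 || pos > 1) stop("site position must be in [0, 1]")
  x <- pos * seg$length
  cand <- which(vapply(disc$ssegs, function(s) s$net_id == seg_id, TRUE))
  best <- NULL; bestd <- Inf
  for (i in cand) {
    s <- disc$ssegs[[i]]
    xl <- max(s$x0, min(s$x0 + s$len, x))
    if (abs(xl - x) < bestd) {
      bestd <- abs(xl - x)
      node <- round((xl - s$x0) / s$dx) + 1
      node <- max(1, min(length(s$Ad), node))
      best <- c(i, node)
    }
  }
  best
}

## Default output sites: inflow face of the root plus every terminal outlet.
default_sites <- function(net) {
  infl <- inflow_boundary(net)
  inc <- node_incidence(net)
  sites <- list()
  root <- inc[[infl$node]][[1]][1]
  sites[[1]] <- list(seg = root, pos = 0)
  deg <- vapply(inc, length, 0L)
  for (b in net$boundaries) {
    if (b$variant %in% c("wk3", "wk_cor") && deg[b$node] == 1) {
      e <- inc[[b$node]][[1]]
      sites[[length(sites) + 1]] <- list(seg = e[1], pos = 1)
    }
  }
  sites
}

wk_descriptor <- function(bc, seg_pdia) {
  p <- bc$params
  if (bc$variant == "wk3")
    list(type = 0L, par = c(p$R1, p$C, p$R2, p$P_out),
         state = c(seg_pdia, 0), plv = NULL, wave = NULL)
  else
    list(type = 1L,
         par = c(p$R_a, p$C_a, p$R_m, p$C_m, p$R_v_out,
                 if (is.null(p$gamma_im)) 1 else p$gamma_im, p$P_out),
         state = c(seg_pdia, seg_pdia, 0), plv = NULL, wave = p$lv_pressure)
}

#' Run a pulse-wave simulation to periodic convergence
#'
#' Advances the 1D equations with the MacCormack predictor-corrector scheme,
#' cycle by cycle, until the relative cycle-to-cycle L2 change of pressure at
#' all output sites drops below \code{config$periodicity_tol}. The final
#' cycle is returned, resampled to \code{config$n_out} uniform points.
#'
#' @param net a validated \code{\link{vascular_network}} with a periodic
#'   inflow boundary.
#' @param config a \code{\link{solver_config}}.
#' @param sites list of output sites, each \code{list(seg =, pos =)} with
#'   \code{pos} the relative position in [0, 1]; defaults to the inflow face
#'   plus every terminal outlet.
#' @return an object of class \code{simulation_result} with per-site
#'   \code{P}, \code{Q}, \code{A} waveforms (\code{\link{periodic_waveform}}),
#'   convergence information and solver diagnostics.
#' @export
run_simulation <- function(net, config = solver_config(), sites = NULL) {
  validate_network(net)
  if (is.null(sites)) sites <- default_sites(net)
  disc <- discretize_network(net, config$dx_target)
  infl <- inflow_boundary(net)
  T_per <- infl$params$wave$period
  rho <- net$blood$rho
  kf <- friction_coefficient(net$blood)

  ## solver state
  state <- lapply(disc$ssegs, function(s)
    list(P = s$Pdia, Q = numeric(length(s$Pdia))))
  wk_state <- lapply(disc$coups, function(cp) {
    if (is.null(cp$wk)) return(list())
    lapply(cp$wk, function(bc) {
      e <- cp$ends[1, ]
      wk_descriptor(bc, disc$ssegs[[e[1]]]$Pdia[1])
    })
  })

  site_nodes <- do.call(rbind, lapply(sites, function(st)
    site_to_node(disc, net, st$seg, st$pos)))
  storage.mode(site_nodes) <- "integer"
  nsites <- nrow(site_nodes)
  tout <- (0:(config$n_out - 1)) * T_per / config$n_out

  prev <- NULL
  residual <- Inf
  converged <- FALSE
  diag <- list(mass_defect = 0, maxQ = 0, max_cfl = 0)
  cycles <- 0
  traces <- NULL
  last <- NULL

  for (cycle in seq_len(config$max_cycles)) {
    ## CFL time step from the current state
    dtmin <- Inf
    for (k in seq_along(disc$ssegs)) {
      s <- disc$ssegs[[k]]
      A <- (sqrt(s$Ad) + (state[[k]]$P - s$Pdia) * s$Ad / s$beta)^2
      cc <- local_wave_speed(A, s$Ad, s$beta, rho)
      ## 25% speed headroom: wave speed stiffens as pressure rises within
      ## the cycle, while dt stays fixed until the next cycle start
      dtmin <- min(dtmin, s$dx / (1.25 * max(abs(state[[k]]$Q / A) + cc)))
    }
    dt <- if (is.null(config$dt_override)) config$cfl * dtmin else config$dt_override
    nsteps <- max(2L, as.integer(ceiling(T_per / dt)))
    dt <- T_per / nsteps
    tsteps <- (0:nsteps) * dt

    coups_c <- lapply(seq_along(disc$coups), function(k) {
      cp <- disc$coups[[k]]
      out <- list(type = cp$type, ends = cp$ends, kv = cp$kv, ke = cp$ke,
                  label = cp$label, inflow = NULL, wk = NULL)
      if (!is.null(cp$inflow))
        out$inflow <- wave_interp(cp$inflow$params$wave, tsteps)
      if (length(wk_state[[k]])) {
        out$wk <- lapply(wk_state[[k]], function(w) {
          if (w$type == 1L) w$plv <- wave_interp(w$wave, tsteps)
          w[c("type", "par", "state", "plv")]
        })
      }
      out
    })
    segs_c <- lapply(seq_along(disc$ssegs), function(k)
      c(state[[k]], disc$ssegs[[k]][c("Ad", "beta", "Pdia", "dx")]))

    res <- .mac_cycle(segs_c, coups_c, rho, kf, dt, nsteps, site_nodes)

    for (k in seq_along(state)) state[[k]] <- res$segs[[k]]
    for (k in seq_along(wk_state))
      for (j in seq_along(wk_state[[k]]))
        wk_state[[k]][[j]]$state <- res$wk[[k]][[j]]
    diag$mass_defect <- max(diag$mass_defect, res$mass_defect)
    diag$maxQ <- max(diag$maxQ, res$maxQ)
    diag$max_cfl <- max(diag$max_cfl, res$max_cfl)
    cycles <- cycle

    traces <- list(
      P = vapply(seq_len(nsites), function(j)
        stats::approx(tsteps, res$siteP[, j], xout = tout)$y, numeric(length(tout))),
      Q = vapply(seq_len(nsites), function(j)
        stats::approx(tsteps, res$siteQ[, j], xout = tout)$y, numeric(length(tout))),
      A = vapply(seq_len(nsites), function(j)
        stats::approx(tsteps, res$siteA[, j], xout = tout)$y, numeric(length(tout))))
    last <- res

    if (!is.null(prev)) {
      residual <- max(vapply(seq_len(nsites), function(j) {
        num <- sqrt(sum((traces$P[, j] - prev[, j])^2))
        den <- sqrt(sum(traces$P[, j]^2))
        num / den
      }, 0))
      if (residual <= config$periodicity_tol) { converged <- TRUE; break }
    }
    prev <- traces$P
  }

  diag$wrap_gap <- vapply(seq_len(nsites), function(j)
    abs(last$siteP[1, j] - last$siteP[nrow(last$siteP), j]), 0)

  site_names <- vapply(sites, function(st) paste0(st$seg, "@", st$pos), "")
  mk_waves <- function(M) {
    w <- lapply(seq_len(nsites), function(j) periodic_waveform(tout, M[, j], T_per))
    names(w) <- site_names
    w
  }
  structure(list(sites = sites, site_names = site_names,
                 t = tout, period = T_per,
                 P = mk_waves(traces$P), Q = mk_waves(traces$Q),
                 A = mk_waves(traces$A),
                 cycles_run = cycles, converged = converged,
                 periodicity_residual = residual,
                 diagnostics = diag),
            class = "simulation_result")
}

#' Extract a site waveform from a simulation result
#'
#' @param res a \code{simulation_result}.
#' @param seg segment id of the site.
#' @param pos relative position of the site.
#' @param what \code{"P"}, \code{"Q"} or \code{"A"}.
#' @return the site's \code{periodic_waveform}.
#' @export
sim_wave <- function(res, seg, pos, what = c("P", "Q", "A")) {
  what <- match.arg(what)
  hit <- which(vapply(res$sites, function(st)
    st$seg == seg && abs(st$pos - pos) < 1e-9, TRUE))
  if (!length(hit)) stop("site ", seg, "@", pos, " not among recorded sites")
  res[[what]][[hit[1]]]
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result: %d sites, %d cycles, %s (residual %.2e)>\n",
              length(x$sites), x$cycles_run,
              if (x$converged) "periodic" else "NOT converged",
              x$periodicity_residual))
  invisible(x)
}
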