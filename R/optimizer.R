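#' Quantity-of-interest specification for topology optimization
#'
#' Defines where and how the reduced network is compared with the baseline.
#' Supported metrics: \code{"eps_P_avg"}, \code{"eps_Q_avg"},
#' \code{"eps_P_sys+eps_P_dia"}, \code{"eps_PP+eps_P_aug"} (evaluated per
#' site and averaged over sites) and \code{"eps_iFR"} (requires exactly two
#' sites: proximal then distal).
#'
#' @param sites list of sites, each \code{list(seg =, pos =)}.
#' @param metric metric name (see Details).
#' @param threshold acceptable error (fraction; absolute for eps_iFR).
#' @return an object of class \code{quantity_spec}.
#' @export
quantity_spec <- function(sites, metric = c("eps_P_avg", "eps_Q_avg",
                                            "eps_P_sys+eps_P_dia",
                                            "eps_PP+eps_P_aug", "eps_iFR"),
                          threshold) {
  metric <- match.arg(metric)
  if (threshold <= 0) stop("threshold must be positive")
  if (metric == "eps_iFR" && length(sites) != 2)
    stop("eps_iFR requires exactly two sites (proximal, distal)")
  structure(list(sites = sites, metric = metric, threshold = threshold),
            class = "quantity_spec")
}

## Evaluate a quantity_spec between two simulation results.
evaluate_qspec <- function(qspec, base_res, red_res) {
  get_w <- function(res, st, what) sim_wave(res, st$seg, st$pos, what)
  if (qspec$metric == "eps_iFR") {
    ib <- ifr(get_w(base_res, qspec$sites[[1]], "P"),
              get_w(base_res, qspec$sites[[2]], "P"))
    ir <- ifr(get_w(red_res, qspec$sites[[1]], "P"),
              get_w(red_res, qspec$sites[[2]], "P"))
    return(abs(ib - ir))
  }
  per_site <- vapply(qspec$sites, function(st) {
    switch(qspec$metric,
      "eps_P_avg" = eps_avg(get_w(base_res, st, "P"), get_w(red_res, st, "P"),
                            "pressure"),
      "eps_Q_avg" = eps_avg(get_w(base_res, st, "Q"), get_w(red_res, st, "Q"),
                            "flow"),
      "eps_P_sys+eps_P_dia" = {
        e <- eps_extrema(get_w(base_res, st, "P"), get_w(red_res, st, "P"))
        unname(e["eps_P_sys"] + e["eps_P_dia"])
      },
      "eps_PP+eps_P_aug" = {
        e <- eps_extrema(get_w(base_res, st, "P"), get_w(red_res, st, "P"))
        a <- eps_aug(get_w(base_res, st, "P"), get_w(red_res, st, "P"))
        if (is.na(a)) stop("augmentation undefined at site ", st$seg, "@", st$pos)
        unname(e["eps_PP"]) + a
      })
  }, 0)
  mean(per_site)
}

#' Enumerate candidate reduced topologies
#'
#' The candidate family consists of truncations at segment distal faces:
#' cutting at a face removes every segment whose connection to the inflow
#' passes through it, and cuts compose. Candidates never remove protected
#' segments and are returned in ascending order of retained artery count.
#'
#' @param net a \code{vascular_network}.
#' @param protected_ids segment ids that must remain in every candidate
#'   (quantity-of-interest sites and the inflow path).
#' @return list of candidates, each \code{list(retained, cuts, n_arteries)},
#'   smallest first; the identity (no cut) candidate is included.
#' @export
enumerate_candidates <- function(net, protected_ids = character()) {
  ids <- names(net$segments)
  unknown <- setdiff(protected_ids, ids)
  if (length(unknown)) stop("protected segment(s) not in network: ",
                            paste(unknown, collapse = ", "))
  infl <- inflow_boundary(net)
  root <- node_incidence(net)[[infl$node]][[1]][1]
  Dset <- lapply(stats::setNames(ids, ids), function(s) distal_segments(net, s))
  cuts <- names(Filter(function(d) length(d) > 0 &&
                         !any(protected_ids %in% d), Dset))
  if (length(cuts) > 20)
    stop("candidate family too large for exhaustive enumeration (",
         length(cuts), " cut faces)")
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (mask in 0:(2^length(cuts) - 1)) {
    sel <- cuts[bitwAnd(mask, bitwShiftL(1, seq_along(cuts) - 1)) != 0]
    removed <- unique(unlist(Dset[sel], use.names = FALSE))
    sel <- setdiff(sel, removed)            # drop cuts inside removed regions
    retained <- setdiff(ids, removed)
    key <- paste(sort(retained), collapse = "|")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    out[[length(out) + 1]] <- list(retained = retained, cuts = sel,
                                   n_arteries = length(retained))
  }
  ord <- order(vapply(out, `[[`, 0L, "n_arteries"),
               vapply(out, function(cd) paste(sort(cd$retained), collapse = "|"), ""))
  out[ord]
}

#' Find the smallest network meeting a waveform-error threshold
#'
#' Simulates the baseline once, then walks the candidate reduced topologies
#' in ascending artery count, reducing each with Method 1
#' (\code{\link{truncate_network}}) or Method 2
#' (\code{\link{reduce_with_method2}}), simulating it and evaluating the
#' quantity-of-interest error. Returns the first candidate meeting the
#' threshold; in exhaustive mode all candidates are evaluated and minimality
#' is certified.
#'
#' @param net the baseline network.
#' @param qspec a \code{\link{quantity_spec}}.
#' @param method 1 (algebraic) or 2 (optimized WK3 parameters).
#' @param config a \code{\link{solver_config}}.
#' @param exhaustive evaluate every candidate and certify minimality.
#' @param protected_ids additional segment ids to protect (the
#'   quantity-of-interest site segments are always protected).
#' @return an object of class \code{topo_outcome}: the best retained set,
#'   its size and error, the full candidate table, and an
#'   \code{infeasible} flag when no candidate meets the threshold.
#' @export
optimize_topology <- function(net, qspec, method = 2,
                              config = solver_config(), exhaustive = FALSE,
                              protected_ids = character()) {
  stopifnot(method %in% c(1, 2))
  protected <- unique(c(protected_ids,
                        vapply(qspec$sites, function(st) st$seg, "")))
  unknown <- setdiff(protected, names(net$segments))
  if (length(unknown)) stop("protected/site segment(s) not in network: ",
                            paste(unknown, collapse = ", "))
  cands <- enumerate_candidates(net, protected)
  all_cuts <- unique(unlist(lapply(cands, `[[`, "cuts")))
  base_sites <- c(qspec$sites,
                  lapply(all_cuts, function(s) list(seg = s, pos = 1)))
  ## drop duplicate sites
  keys <- vapply(base_sites, function(st) paste0(st$seg, "@", st$pos), "")
  base_sites <- base_sites[!duplicated(keys)]
  base_res <- run_simulation(net, config, sites = base_sites)
  if (!base_res$converged)
    warning("baseline simulation did not reach periodicity tolerance")
  ss <- solve_steady(net)

  rows <- list()
  best <- NULL
  for (i in seq_along(cands)) {
    cd <- cands[[i]]
    err <- if (length(cd$cuts) == 0) 0 else {
      red <- if (method == 1) truncate_network(net, ss, cd$retained)
             else reduce_with_method2(net, base_res, cd$retained, ss = ss,
                                      config = config)
      red_res <- run_simulation(red, config, sites = qspec$sites)
      evaluate_qspec(qspec, base_res, red_res)
    }
    feasible <- err <= qspec$threshold
    rows[[length(rows) + 1]] <- data.frame(
      candidate = paste(sort(cd$retained), collapse = "+"),
      n_arteries = cd$n_arteries, error = err, feasible = feasible,
      stringsAsFactors = FALSE)
    if (feasible && is.null(best)) {
      best <- list(cd = cd, error = err)
      if (!exhaustive) break
    }
    if (feasible && exhaustive &&
        (cd$n_arteries < best$cd$n_arteries ||
         (cd$n_arteries == best$cd$n_arteries && err < best$error)))
      best <- list(cd = cd, error = err)
  }
  tab <- do.call(rbind, rows)
  infeasible <- is.null(best)
  structure(list(
    best_retained_ids = if (infeasible) character() else sort(best$cd$retained),
    n_arteries = if (infeasible) NA_integer_ else best$cd$n_arteries,
    achieved_error = if (infeasible) NA_real_ else best$error,
    candidate_table = tab, method = method, threshold = qspec$threshold,
    metric = qspec$metric, exhaustive = exhaustive, infeasible = infeasible),
    class = "topo_outcome")
}

#' @export
print.topo_outcome <- function(x, ...) {
  if (x$infeasible) {
    cat("<topo_outcome: no candidate met the threshold>\n")
  } else {
    cat(sprintf("<topo_outcome: %d arteries, %s = %.4g (threshold %.4g), method %d>\n",
                x$n_arteries, x$metric, x$achieved_error, x$threshold, x$method))
  }
  print(utils::head(x$candidate_table, 10))
  invisible(x)
}
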