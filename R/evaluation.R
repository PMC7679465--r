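#' Procrustean alignment of inferred angles
#'
#' The S1 likelihood is invariant under global rotation and reflection of
#' all angles, so inferred coordinates are aligned to the truth before any
#' error is measured: the global rotation (searched over both orientations)
#' minimizing the summed squared circular distance is found by a dense grid
#' (default step 1e-3 rad) followed by local refinement.
#'
#' @param theta_inferred,theta_real equal-length angle vectors (radians).
#' @param grid_step rotation grid step in radians.
#' @return List with `aligned` (rotated/reflected inferred angles),
#'   `rotation` (in `[0, 2*pi)`), `reflected` (logical), `ss` (residual sum
#'   of squared circular distances).
#' @export
procrustes_align <- function(theta_inferred, theta_real, grid_step = 1e-3) {
  if (length(theta_inferred) != length(theta_real) ||
      length(theta_real) < 2L)
    stop_invalid("need two equal-length angle vectors (length >= 2)")
  tr <- theta_real %% (2 * pi)
  phis <- seq(0, 2 * pi, by = grid_step)
  best <- NULL
  for (reflected in c(FALSE, TRUE)) {
    ti <- if (reflected) (-theta_inferred) %% (2 * pi)
          else theta_inferred %% (2 * pi)
    d0 <- tr - ti
    cost <- function(phi) {
      dd <- pi - abs(pi - abs(outer(phi, d0, "-")) %% (2 * pi))
      rowSums(dd^2)
    }
    cg <- cost(phis)
    k <- which.min(cg)
    opt <- optimize(function(p) cost(p), phis[k] + c(-1, 1) * grid_step)
    cand <- list(rotation = opt$minimum %% (2 * pi), ss = opt$objective,
                 reflected = reflected,
                 aligned = (ti + opt$minimum) %% (2 * pi))
    if (is.null(best) || cand$ss < best$ss) best <- cand
  }
  best
}

#' Coordinate-recovery error metrics
#'
#' `d_kappa` is the mean absolute difference between inferred and real
#' latent degrees; `d_theta` is the mean circular distance between inferred
#' and real angles after Procrustean alignment (rotation + reflection), and
#' is therefore gauge-invariant.
#'
#' @param kappa_inferred,kappa_real latent-degree vectors (same length).
#' @param theta_inferred,theta_real angle vectors (same length).
#' @param align align before measuring (default TRUE).
#' @return Nonnegative scalar error (radians for `d_theta`, <= pi).
#' @export
d_kappa <- function(kappa_inferred, kappa_real) {
  if (length(kappa_inferred) != length(kappa_real))
    stop_invalid("length mismatch")
  mean(abs(kappa_inferred - kappa_real))
}

#' @rdname d_kappa
#' @export
d_theta <- function(theta_inferred, theta_real, align = TRUE) {
  if (length(theta_inferred) != length(theta_real))
    stop_invalid("length mismatch")
  ti <- if (align) procrustes_align(theta_inferred, theta_real)$aligned
        else theta_inferred
  mean(circ_dist(ti, theta_real %% (2 * pi)))
}

#' Empirical connection-probability curve
#'
#' Bins per-pair distances into logarithmically spaced bins and reports the
#' connected fraction per bin with a binomial standard error; the standard
#' check that an embedding (or a generated graph) follows its theoretical
#' connection-probability curve.
#'
#' @param g an `aggregated_graph` (or any graph whose edges label the pairs).
#' @param chi per-pair distances aligned with `pairs`.
#' @param pairs two-column matrix of node pairs; default all unordered pairs.
#' @param n_bins number of logarithmic bins.
#' @return Data frame with `mid`, `n`, `n_connected`, `freq`, `se` per
#'   retained (nonempty) bin.
#' @export
empirical_connection_curve <- function(g, chi, pairs = pair_indices(g$n_nodes),
                                       n_bins = 20L) {
  if (length(chi) != nrow(pairs)) stop_invalid("`chi`/`pairs` length mismatch")
  key <- pair_key(g$edges[, 1L], g$edges[, 2L], g$n_nodes)
  connected <- pair_key(pairs[, 1L], pairs[, 2L], g$n_nodes) %in% key
  ok <- is.finite(chi) & chi > 0
  chi <- chi[ok]; connected <- connected[ok]
  brk <- exp(seq(log(min(chi)), log(max(chi)), length.out = n_bins + 1L))
  brk[1L] <- brk[1L] * (1 - 1e-12); brk[n_bins + 1L] <- brk[n_bins + 1L] * (1 + 1e-12)
  b <- cut(chi, brk, labels = FALSE)
  n <- tabulate(b, n_bins)
  nc <- vapply(seq_len(n_bins), function(k) sum(connected[b == k]), 0L)
  keep <- n > 0L
  freq <- nc[keep] / n[keep]
  data.frame(mid = sqrt(brk[-(n_bins + 1L)] * brk[-1L])[keep],
             n = n[keep], n_connected = nc[keep], freq = freq,
             se = sqrt(pmax(freq * (1 - freq), 1e-12) / n[keep]))
}

#' Inference accuracy versus aggregation interval
#'
#' Generates one dynamic-S1 temporal network at the largest interval,
#' then, for each tau in `tau_grid`, aggregates slots `1..tau`, embeds the
#' aggregate, and reports the recovery errors D_kappa (inferred aggregated
#' degrees divided by alpha at the generating temperature, against the true
#' per-slot kappas) and D_theta (after Procrustean alignment), together
#' with the aggregate density.  Embedding failures at extreme tau are
#' recorded as missing rows, not raised.
#'
#' @param coords generating `latent_coords` (the ground truth).
#' @param mean_degrees per-slot mean degrees, length >= `max(tau_grid)`.
#' @param temperature generating temperature.
#' @param tau_grid increasing aggregation intervals.
#' @param seed integer seed for generation and embedding.
#' @param temperature_known embed with the generating temperature instead of
#'   estimating it (faster sweeps; default FALSE).
#' @param max_sweeps refinement sweep cap passed to [embed_graph()].
#' @return Data frame with `tau`, `d_kappa`, `d_theta`, `density`.
#' @export
aggregation_sweep <- function(coords, mean_degrees, temperature, tau_grid,
                              seed = NULL, temperature_known = FALSE,
                              max_sweeps = 10L) {
  if (is.unsorted(tau_grid, strictly = TRUE))
    stop_invalid("`tau_grid` must be increasing")
  if (length(mean_degrees) < max(tau_grid))
    stop_invalid("`mean_degrees` shorter than max(tau_grid)")
  tn <- generate_dynamic_s1(coords, mean_degrees[seq_len(max(tau_grid))],
                            temperature, seed = seed)
  rows <- lapply(tau_grid, function(tau) {
    g <- aggregate_network(tn, seq_len(tau))
    dens <- graph_density(g)
    emb <- tryCatch(
      embed_graph(g, temperature = if (temperature_known) temperature,
                  seed = seed, max_sweeps = max_sweeps),
      error = function(e) NULL)
    if (is.null(emb))
      return(data.frame(tau = tau, d_kappa = NA_real_, d_theta = NA_real_,
                        density = dens))
    ids <- emb$node_ids
    ki <- per_slot_kappa(emb$kappa_agg, tau, temperature)
    data.frame(tau = tau,
               d_kappa = d_kappa(ki, coords$kappa[ids]),
               d_theta = d_theta(emb$theta, coords$theta[ids]),
               density = dens)
  })
  do.call(rbind, rows)
}
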