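## Connection-probability factory shared by inference, refinement and
## model-ensemble generation.  In "fermi_dirac" mode distances are plain
## effective distances; in "aggregated" mode they are rescaled distances
## chi_tilde and the probability is the exact tau-slot aggregation
## 1 - (1 - p(alpha * chi_tilde))^tau.
conn_prob_fn <- function(temperature, mode = c("fermi_dirac", "aggregated"),
                         tau = NULL) {
  mode <- match.arg(mode)
  if (mode == "fermi_dirac")
    return(function(chi) connection_probability(chi, temperature))
  if (is.null(tau) || tau < 1)
    stop_invalid("aggregated mode requires `tau` >= 1")
  a <- alpha_factor(tau, temperature)
  function(chi)
    aggregated_probability_exact(chi * a, temperature, tau)
}

## (1/pi) * integral over dtheta in [0, pi] of P(R*dtheta/(mu*q)), evaluated
## for a vector of kappa products q by Gauss-Legendre quadrature in
## log(dtheta): the integrand's transition scale mu*q/R spans many orders of
## magnitude across kappa pairs, so a flat grid cannot resolve it.  The
## missed head [0, exp(lo)], where P = 1, is added back in closed form.
expected_pair_prob <- function(q, mu, radius, probfn, quad_n = 96L,
                               lo = log(1e-12)) {
  gl <- gl_quadrature(quad_n, lo, log(pi))
  acc <- numeric(length(q))
  for (k in seq_along(gl$x)) {
    dth <- exp(gl$x[k])
    chi <- chi_from_parts(rep(dth, length(q)), q, mu, radius)
    acc <- acc + gl$w[k] * dth * probfn(chi)
  }
  (acc + exp(lo)) / pi
}

#' Infer latent degrees from an aggregated graph
#'
#' Finds hidden degrees kappa_tilde such that each node's model-expected
#' degree (with angles integrated out uniformly) matches its observed
#' degree.  The expected degree depends on a node only through its kappa and
#' the multiset of all kappas, so the fixed point is solved on the unique
#' observed degree values and mapped back.  Zero-degree nodes are not
#' allowed (pass a connected component).
#'
#' @param g an `aggregated_graph` (a connected component, all degrees >= 1).
#' @param temperature temperature T in (0, 1).
#' @param mode `"fermi_dirac"` (plain S1 likelihood) or `"aggregated"`
#'   (exact finite-tau aggregated probability).
#' @param tau number of slots (aggregated mode only).
#' @param tol relative tolerance on expected-vs-observed degrees.
#' @param max_iter iteration cap; non-convergence raises an error carrying
#'   the worst relative mismatch.
#' @return Numeric vector of inferred kappa_tilde, one per node.
#' @export
infer_latent_degrees <- function(g, temperature,
                                 mode = c("fermi_dirac", "aggregated"),
                                 tau = NULL, tol = 1e-3, max_iter = 1000L) {
  mode <- match.arg(mode)
  check_temperature(temperature)
  deg <- aggregated_degrees(g)
  if (any(deg == 0L))
    stop_invalid("zero-degree nodes cannot be embedded; pass a component")
  probfn <- conn_prob_fn(temperature, mode, tau)
  n <- g$n_nodes
  radius <- n / (2 * pi)
  kbar <- mean(deg)
  mu <- compute_mu(kbar, kbar, temperature)

  ud <- sort(unique(deg))
  nd <- tabulate(match(deg, ud), length(ud))
  ku <- as.numeric(ud)
  rate <- 1; prev <- Inf
  for (it in seq_len(max_iter)) {
    q <- outer(ku, ku)
    f <- matrix(expected_pair_prob(as.vector(q), mu, radius, probfn),
                length(ku))
    ek <- as.vector(f %*% nd) - diag(f)
    err <- max(abs(ek - ud) / ud)
    if (err < tol) break
    ## adaptive damping: back off when the multiplicative update overshoots
    rate <- if (err > prev) max(rate * 0.5, 0.05) else min(rate * 1.05, 1)
    prev <- err
    ku <- ku * (ud / ek)^rate
  }
  if (err >= tol)
    stop("latent-degree inference did not converge: worst relative ",
         sprintf("mismatch %.3g after %d iterations", err, max_iter),
         call. = FALSE)
  ku[match(deg, ud)]
}

#' Infer the temperature of an aggregated graph
#'
#' Estimates T by matching the observed mean local clustering coefficient
#' with the model expectation, computed from small synthetic ensembles
#' generated at candidate temperatures with the kappas inferred at that
#' temperature.  Candidates are a grid of step 0.05 on `[0.05, 0.95]` with
#' one local refinement around the best grid point.  Degenerate observed
#' clustering (0 or 1) returns the corresponding boundary with a warning.
#'
#' @inheritParams infer_latent_degrees
#' @param n_rep synthetic graphs per candidate temperature.
#' @param seed optional integer seed (local to this call).
#' @return Estimated temperature in `[0.05, 0.95]`.
#' @export
infer_temperature <- function(g, mode = c("fermi_dirac", "aggregated"),
                              tau = NULL, n_rep = 3L, seed = NULL) {
  mode <- match.arg(mode)
  ig <- as_igraph(g)
  c_obs <- igraph::transitivity(ig, type = "localaverage")
  if (!is.finite(c_obs)) stop_invalid("graph carries no triangles/clustering signal")
  if (c_obs <= 0 || c_obs >= 1) {
    warning("degenerate observed clustering; returning boundary temperature")
    return(if (c_obs >= 1) 0.05 else 0.95)
  }
  model_clust <- function(T) {
    kap <- infer_latent_degrees(g, T, mode, tau)
    probfn <- conn_prob_fn(T, mode, tau)
    n <- g$n_nodes
    mu <- compute_mu(mean(aggregated_degrees(g)), mean(aggregated_degrees(g)), T)
    pairs <- pair_indices(n)
    cc <- replicate(n_rep, {
      th <- runif(n, 0, 2 * pi)
      dth <- circ_dist(th[pairs[, 1L]], th[pairs[, 2L]])
      chi <- chi_from_parts(dth, kap[pairs[, 1L]] * kap[pairs[, 2L]], mu,
                            n / (2 * pi))
      p <- probfn(chi)
      e <- pairs[runif(length(p)) < p, , drop = FALSE]
      igraph::transitivity(as_igraph(aggregated_graph(e, n)),
                           type = "localaverage")
    })
    mean(cc, na.rm = TRUE)
  }
  with_local_seed(seed, {
    grid <- seq(0.05, 0.95, by = 0.05)
    gap <- vapply(grid, function(T) abs(model_clust(T) - c_obs), 0)
    best <- grid[which.min(gap)]
    local <- c(best - 0.025, best, best + 0.025)
    local <- local[local >= 0.05 & local <= 0.95]
    gap2 <- vapply(local, function(T) abs(model_clust(T) - c_obs), 0)
    That <- local[which.min(gap2)]
    if (min(gap2) > 0.05)
      warning(sprintf(paste0("clustering matched only to %.3f; temperature ",
                             "estimate %.2f may be unreliable"),
                      min(gap2), That))
    That
  })
}

#' Laplacian-Eigenmaps initial angles
#'
#' Initial angular coordinates from the two leading non-trivial eigenvectors
#' of the symmetric normalized Laplacian of the edge-weighted graph, with
#' weights `1/sqrt(kappa_i * kappa_j)` so that hubs carry less angular
#' information: `theta_i = atan2(v2_i, v1_i)` mapped to `[0, 2*pi)`.
#'
#' @param g a connected `aggregated_graph` with at least 3 nodes.
#' @param kappa inferred latent degrees (weights).
#' @param jitter magnitude of the tie-breaking jitter applied to zero
#'   eigenvector entries.
#' @return Numeric vector of initial angles.
#' @export
initial_angles_le <- function(g, kappa, jitter = 1e-6) {
  n <- g$n_nodes
  if (n < 3L) stop_invalid("need at least 3 nodes")
  if (igraph::components(as_igraph(g))$no != 1L)
    stop_invalid("Laplacian Eigenmaps initialization needs a connected graph")
  w <- 1 / sqrt(kappa[g$edges[, 1L]] * kappa[g$edges[, 2L]])
  W <- matrix(0, n, n)
  W[g$edges] <- w
  W[g$edges[, c(2L, 1L), drop = FALSE]] <- w
  d <- rowSums(W)
  S <- W / sqrt(outer(d, d))
  L <- diag(n) - S
  ev <- eigen(L, symmetric = TRUE)
  v1 <- ev$vectors[, n - 1L] / sqrt(d)
  v2 <- ev$vectors[, n - 2L] / sqrt(d)
  zero <- abs(v1) < .Machine$double.eps & abs(v2) < .Machine$double.eps
  if (any(zero)) {
    v1[zero] <- v1[zero] + runif(sum(zero), -jitter, jitter)
    v2[zero] <- v2[zero] + runif(sum(zero), -jitter, jitter)
  }
  atan2(v2, v1) %% (2 * pi)
}

## Bernoulli log-likelihood of the graph given angles; P clamped away from
## {0,1} so missing far edges keep a finite penalty
loglik_total <- function(adj, theta, cmat, probfn) {
  dth <- circ_dist_outer(theta)
  P <- probfn(cmat * dth)
  P <- pmin(pmax(P, 1e-15), 1 - 1e-15)
  ll <- ifelse(adj, log(P), log1p(-P))
  sum(ll[upper.tri(ll)])
}

circ_dist_outer <- function(theta) {
  d <- abs(outer(theta, theta, "-")) %% (2 * pi)
  pi - abs(pi - d)
}

#' Refine angles by likelihood maximization
#'
#' Coordinate-ascent sweeps over nodes in decreasing degree order.  For each
#' node the candidate set is its current angle, the circular mean of its
#' neighbors' angles, wrapped-Gaussian proposals around the current angle
#' (scale shrinking across sweeps), and a uniform coarse grid; the candidate
#' maximizing the node's conditional Bernoulli log-likelihood is kept, so
#' the total log-likelihood is non-decreasing.  Stops when a full sweep
#' improves the total log-likelihood by less than `tol`.
#'
#' @inheritParams infer_latent_degrees
#' @param kappa inferred latent degrees.
#' @param theta_init initial angles (e.g. from [initial_angles_le()]).
#' @param mu degree-calibration constant consistent with `kappa` (default:
#'   recomputed from the observed mean degree).
#' @param max_sweeps sweep cap.
#' @param n_prop wrapped-Gaussian proposals per node per sweep.
#' @param n_grid coarse-grid candidates per node per sweep.
#' @param seed optional integer seed for the proposals.
#' @return List with `theta` (refined angles), `log_likelihood`, and
#'   `trace` (total log-likelihood after each sweep).
#' @export
refine_angles_mle <- function(g, kappa, theta_init, temperature,
                              mode = c("fermi_dirac", "aggregated"),
                              tau = NULL, mu = NULL, max_sweeps = 10L,
                              tol = 1e-3, n_prop = 8L, n_grid = 16L,
                              seed = NULL) {
  mode <- match.arg(mode)
  probfn <- conn_prob_fn(temperature, mode, tau)
  n <- g$n_nodes
  deg <- aggregated_degrees(g)
  if (is.null(mu)) mu <- compute_mu(mean(deg), mean(deg), temperature)
  radius <- n / (2 * pi)
  adj <- adjacency_logical(g)
  cmat <- radius / (mu * outer(kappa, kappa))
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ]))
  theta <- theta_init %% (2 * pi)
  grid <- seq(0, 2 * pi, length.out = n_grid + 1L)[-(n_grid + 1L)]
  order_nodes <- order(deg, decreasing = TRUE)

  node_ll <- function(i, phi) {
    dth <- circ_dist(phi, theta[-i])
    P <- probfn(cmat[i, -i] * dth)
    P <- pmin(pmax(P, 1e-15), 1 - 1e-15)
    sum(ifelse(adj[i, -i], log(P), log1p(-P)))
  }

  ## constant, wide proposal scale: narrowing the proposals across sweeps
  ## lets the ascent accumulate micro-moves into a high-likelihood but
  ## globally warped (non-uniform angular density) configuration, which
  ## degrades coordinate recovery without improving the map's uses
  sd_prop <- pi / 2
  with_local_seed(seed, {
    ll <- loglik_total(adj, theta, cmat, probfn)
    trace <- ll
    for (sweep in seq_len(max_sweeps)) {
      for (i in order_nodes) {
        cand <- c(theta[i], circular_mean(theta[nbrs[[i]]]),
                  (theta[i] + rnorm(n_prop, 0, sd_prop)) %% (2 * pi),
                  grid)
        lls <- vapply(cand, function(phi) node_ll(i, phi), 0)
        best <- which.max(lls)
        theta[i] <- cand[best]
      }
      ll_new <- loglik_total(adj, theta, cmat, probfn)
      trace <- c(trace, ll_new)
      improved <- ll_new - ll
      ll <- ll_new
      if (improved < tol) break
    }
    list(theta = theta, log_likelihood = ll, trace = trace)
  })
}

#' Embed an aggregated graph into the hyperbolic plane
#'
#' Full embedding pipeline on the largest connected component: temperature
#' estimation (clustering matching), latent-degree inference (expected
#' degree fixed point), Laplacian-Eigenmaps angular initialization, and
#' likelihood-maximization refinement; hidden degrees are then converted to
#' hyperbolic radial coordinates.  Zero-degree nodes and smaller components
#' carry no likelihood signal and are excluded (reported in `excluded`).
#'
#' @param g an `aggregated_graph`.
#' @param mode `"fermi_dirac"` uses the plain S1 connection probability;
#'   `"aggregated"` uses the exact finite-tau aggregated probability (needs
#'   `tau`).  With `tau = 1` the two coincide.
#' @param tau number of slots behind the aggregate (aggregated mode).
#' @param temperature optional known temperature; skips estimation.
#' @param seed integer seed making the embedding reproducible.
#' @param max_sweeps refinement sweep cap.
#' @return An object of class `embedding`: `node_ids` (indices into the
#'   original graph), `kappa_agg`, `theta`, `temperature_hat`, `mu_tilde`,
#'   `mode`, `tau`, `log_likelihood`, `radial` (a `hyperbolic_coords`),
#'   `radius` (= component size / 2 pi), `excluded`, `labels`.
#' @export
embed_graph <- function(g, mode = c("fermi_dirac", "aggregated"), tau = NULL,
                        temperature = NULL, seed = NULL, max_sweeps = 10L) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "aggregated_graph"))
  comp <- igraph::components(as_igraph(g))
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) < 3L)
    stop_invalid("largest component has fewer than 3 nodes; cannot embed")
  remap <- match(seq_len(g$n_nodes), keep)
  esub <- g$edges[g$edges[, 1L] %in% keep & g$edges[, 2L] %in% keep, ,
                  drop = FALSE]
  gsub <- aggregated_graph(cbind(remap[esub[, 1L]], remap[esub[, 2L]]),
                           length(keep))

  with_local_seed(seed, {
    That <- temperature %||% infer_temperature(gsub, mode, tau)
    kap <- infer_latent_degrees(gsub, That, mode, tau)
    deg <- aggregated_degrees(gsub)
    mu_tilde <- compute_mu(mean(deg), mean(deg), That)
    th0 <- initial_angles_le(gsub, kap)
    ref <- refine_angles_mle(gsub, kap, th0, That, mode, tau, mu = mu_tilde,
                             max_sweeps = max_sweeps)
    ncomp <- length(keep)
    radial <- to_hyperbolic(list(kappa = kap, mu = mu_tilde, n_nodes = ncomp))
    structure(list(node_ids = keep, kappa_agg = kap, theta = ref$theta,
                   temperature_hat = That, mu_tilde = mu_tilde, mode = mode,
                   tau = tau, log_likelihood = ref$log_likelihood,
                   radial = radial, radius = ncomp / (2 * pi),
                   n_nodes = g$n_nodes,
                   excluded = setdiff(seq_len(g$n_nodes), keep),
                   labels = if (!is.null(g$node_labels))
                     g$node_labels[keep] else NULL),
              class = "embedding")
  })
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf(paste0("embedding: %d/%d nodes, mode %s, T_hat = %.2f, ",
                     "logL = %.1f\n"),
              length(x$node_ids), x$n_nodes, x$mode, x$temperature_hat,
              x$log_likelihood))
  invisible(x)
}

#' Build the reference embedding from ground-truth coordinates
#'
#' Maps true per-slot latent coordinates to the time-aggregated scale
#' (kappa_tilde = alpha * kappa, mu_tilde = mu / alpha), giving the
#' embedding a routing/prediction/epidemic analysis would use if inference
#' were perfect.  Zero-kappa nodes are excluded.
#'
#' @param coords a `latent_coords` object (the generating truth).
#' @param tau number of slots of the aggregation window.
#' @param temperature generating temperature; default from `coords`.
#' @return An `embedding` object.
#' @export
embedding_from_truth <- function(coords, tau, temperature = NULL) {
  temperature <- temperature %||% coords$temperature
  a <- alpha_factor(tau, temperature)
  keep <- which(coords$kappa > 0)
  kap <- coords$kappa[keep] * a
  mu_tilde <- coords$mu / a
  ncomp <- length(keep)
  radial <- to_hyperbolic(list(kappa = kap, mu = mu_tilde, n_nodes = ncomp))
  structure(list(node_ids = keep, kappa_agg = kap, theta = coords$theta[keep],
                 temperature_hat = temperature, mu_tilde = mu_tilde,
                 mode = "truth", tau = tau, log_likelihood = NA_real_,
                 radial = radial, radius = ncomp / (2 * pi),
                 n_nodes = coords$n_nodes,
                 excluded = setdiff(seq_len(coords$n_nodes), keep),
                 labels = NULL),
            class = "embedding")
}

## position of original node ids inside the embedding, NA when not embedded
embedding_pos <- function(emb, ids) match(ids, emb$node_ids)

#' Effective and hyperbolic distances in an embedding
#'
#' `embedding_chi` returns the effective distance
#' `chi_tilde = R * dtheta / (mu_tilde * kappa_i * kappa_j)`;
#' `hyperbolic_distance` returns `x = r_i + r_j + 2*log(dtheta/2)`
#' (approximately the hyperbolic distance; clamped below at `|r_i - r_j|`,
#' the exact distance of coincident angles).
#'
#' @param emb an `embedding`.
#' @param i,j node ids in the original graph (vectors allowed); must be
#'   embedded.
#' @return Numeric vector of distances.
#' @export
embedding_chi <- function(emb, i, j) {
  pi_ <- embedding_pos(emb, i); pj <- embedding_pos(emb, j)
  if (anyNA(pi_) || anyNA(pj)) stop_invalid("node without coordinates")
  chi_from_parts(circ_dist(emb$theta[pi_], emb$theta[pj]),
                 emb$kappa_agg[pi_] * emb$kappa_agg[pj],
                 emb$mu_tilde, emb$radius)
}

#' @rdname embedding_chi
#' @export
hyperbolic_distance <- function(emb, i, j) {
  pi_ <- embedding_pos(emb, i); pj <- embedding_pos(emb, j)
  if (anyNA(pi_) || anyNA(pj)) stop_invalid("node without coordinates")
  r <- emb$radial$r
  dth <- circ_dist(emb$theta[pi_], emb$theta[pj])
  x <- r[pi_] + r[pj] + 2 * log(dth / 2)
  pmax(x, abs(r[pi_] - r[pj]))
}

#' Per-slot latent degrees from aggregated ones
#'
#' Divides inferred aggregated hidden degrees by
#' `alpha = tau^T / Gamma(1+T)`, recovering per-slot latent degrees.
#'
#' @param x an `embedding` or a numeric vector of aggregated degrees.
#' @param tau number of slots, >= 1.
#' @param temperature temperature; defaults to the embedding's estimate.
#' @return Numeric vector of per-slot latent degrees.
#' @examples
#' per_slot_kappa(56.6, 2584, 0.72)
#' @export
per_slot_kappa <- function(x, tau, temperature = NULL) {
  if (inherits(x, "embedding")) {
    temperature <- temperature %||% x$temperature_hat
    x <- x$kappa_agg
  }
  if (is.null(temperature)) stop_invalid("`temperature` is required")
  x / alpha_factor(tau, temperature)
}
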