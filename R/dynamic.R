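#' Temporal network container
#'
#' A temporal contact network: an ordered sequence of per-slot undirected
#' edge sets over `n_nodes` fixed nodes.  Edges are two-column integer
#' matrices with i < j, no self-loops, no duplicates within a slot.
#'
#' @param edges_by_slot list of edge matrices (may contain empty slots).
#' @param n_nodes number of nodes.
#' @param slot_seconds optional slot duration metadata, seconds.
#' @param mean_degrees optional prescribed per-slot mean degrees.
#' @param node_labels optional character labels (I/O round-tripping).
#' @return An object of class `temporal_network`.
#' @export
temporal_network <- function(edges_by_slot, n_nodes, slot_seconds = NULL,
                             mean_degrees = NULL, node_labels = NULL) {
  edges_by_slot <- lapply(edges_by_slot, canonical_edges, n_nodes = n_nodes)
  structure(list(n_nodes = as.integer(n_nodes),
                 n_slots = length(edges_by_slot),
                 edges_by_slot = edges_by_slot,
                 slot_seconds = slot_seconds,
                 mean_degrees = mean_degrees,
                 node_labels = node_labels),
            class = "temporal_network")
}

canonical_edges <- function(e, n_nodes) {
  if (is.null(e) || nrow(e) == 0L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  e <- cbind(i = as.integer(pmin(e[, 1L], e[, 2L])),
             j = as.integer(pmax(e[, 1L], e[, 2L])))
  if (any(e[, 1L] == e[, 2L])) stop_invalid("self-loops are not allowed")
  if (any(e < 1L) || any(e > n_nodes)) stop_invalid("node id out of range")
  e[!duplicated(pair_key(e[, 1L], e[, 2L], n_nodes)), , drop = FALSE]
}

#' @export
print.temporal_network <- function(x, ...) {
  cat(sprintf("temporal_network: %d nodes, %d slots, %d contacts total\n",
              x$n_nodes, x$n_slots,
              sum(vapply(x$edges_by_slot, nrow, 0L))))
  invisible(x)
}

#' Generate a dynamic-S1 temporal network
#'
#' Every slot t is an independent S1 snapshot over the same fixed
#' coordinates, with per-slot mean degree `mean_degrees[t]` (edges do not
#' persist between slots).  With a constant mean degree the slot occupancy
#' of each pair is i.i.d. Bernoulli, so the generator draws each pair's
#' occupied-slot count Binomial(tau, p) and places the occupied slots
#' uniformly at random, which is distributionally identical to slot-by-slot
#' sampling and much faster; heterogeneous `mean_degrees` fall back to the
#' slot-by-slot path.
#'
#' @param coords a `latent_coords` object (fixed for all slots).
#' @param mean_degrees per-slot mean degrees, length tau >= 1.
#' @param temperature temperature; default: the one in `coords`.
#' @param seed optional integer seed (local to this call).
#' @param slot_seconds optional slot duration metadata.
#' @return A [temporal_network()].
#' @export
generate_dynamic_s1 <- function(coords, mean_degrees, temperature = NULL,
                                seed = NULL, slot_seconds = NULL) {
  stopifnot(inherits(coords, "latent_coords"))
  if (length(mean_degrees) < 1L) stop_invalid("`mean_degrees` must be nonempty")
  if (any(mean_degrees < 0)) stop_invalid("`mean_degrees` must be nonnegative")
  temperature <- temperature %||% coords$temperature
  tau <- length(mean_degrees)
  n <- coords$n_nodes
  pairs <- pair_indices(n)

  with_local_seed(seed, {
    if (length(unique(mean_degrees)) == 1L) {
      mu <- compute_mu(mean_degrees[1L], coords$kappa_bar, temperature)
      p <- s1_edge_probs(coords, mu, temperature, pairs)
      counts <- rbinom(length(p), tau, p)
      active <- which(counts > 0L)
      slots <- unlist(lapply(active, function(k)
        sort.int(sample.int(tau, counts[k]))), use.names = FALSE)
      ii <- rep.int(pairs[active, 1L], counts[active])
      jj <- rep.int(pairs[active, 2L], counts[active])
      idx_by_slot <- split(seq_along(slots),
                           factor(slots, levels = seq_len(tau)))
      ebs <- lapply(idx_by_slot, function(ix)
        cbind(i = ii[ix], j = jj[ix]))
    } else {
      ## chi scales as 1/mu, so cache chi^(1/T) at a reference mu
      kref <- mean_degrees[which(mean_degrees > 0)[1L]]
      if (is.na(kref)) stop_invalid("all-zero `mean_degrees`")
      mu_ref <- compute_mu(kref, coords$kappa_bar, temperature)
      dth <- circ_dist(coords$theta[pairs[, 1L]], coords$theta[pairs[, 2L]])
      kprod <- coords$kappa[pairs[, 1L]] * coords$kappa[pairs[, 2L]]
      chi_ref_pow <- chi_from_parts(dth, kprod, mu_ref,
                                    coords$radius)^(1 / temperature)
      ebs <- lapply(seq_len(tau), function(t) {
        kt <- mean_degrees[t]
        if (kt == 0) return(NULL)
        scal <- (mu_ref / compute_mu(kt, coords$kappa_bar,
                                     temperature))^(1 / temperature)
        p <- 1 / (1 + chi_ref_pow * scal)
        pairs[runif(length(p)) < p, , drop = FALSE]
      })
    }
    temporal_network(ebs, n, slot_seconds = slot_seconds,
                     mean_degrees = mean_degrees)
  })
}

#' Time-aggregate a temporal network
#'
#' Builds the simple undirected graph in which two nodes are connected iff
#' they co-occur in at least one slot of the window.
#'
#' @param tn a [temporal_network()].
#' @param window integer vector of slot indices; default: all slots.
#' @return An object of class `aggregated_graph` with fields `n_nodes`,
#'   `edges` (two-column matrix, i < j), `window`.
#' @export
aggregate_network <- function(tn, window = NULL) {
  stopifnot(inherits(tn, "temporal_network"))
  window <- window %||% seq_len(tn$n_slots)
  if (length(window) == 0L) stop_invalid("empty aggregation window")
  if (any(window < 1L) || any(window > tn$n_slots))
    stop_invalid("window outside [1, n_slots]")
  em <- do.call(rbind, tn$edges_by_slot[window])
  aggregated_graph(em, tn$n_nodes, window = range(window),
                   node_labels = tn$node_labels)
}

#' @rdname aggregate_network
#' @param edges edge matrix (deduplicated on construction).
#' @param n_nodes number of nodes.
#' @param node_labels optional labels.
#' @export
aggregated_graph <- function(edges, n_nodes, window = NULL,
                             node_labels = NULL) {
  edges <- canonical_edges(edges, n_nodes)
  structure(list(n_nodes = as.integer(n_nodes), edges = edges,
                 window = window, node_labels = node_labels),
            class = "aggregated_graph")
}

#' @export
print.aggregated_graph <- function(x, ...) {
  cat(sprintf("aggregated_graph: %d nodes, %d edges, density %.4f\n",
              x$n_nodes, nrow(x$edges), graph_density(x)))
  invisible(x)
}

#' Node degrees of an aggregated graph
#' @param g an `aggregated_graph`.
#' @return Integer degree vector of length `n_nodes`.
#' @export
aggregated_degrees <- function(g) {
  tabulate(c(g$edges[, 1L], g$edges[, 2L]), g$n_nodes)
}

as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g$n_nodes, directed = FALSE)
  if (nrow(g$edges) > 0L) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}

## logical adjacency matrix
adjacency_logical <- function(g) {
  a <- matrix(FALSE, g$n_nodes, g$n_nodes)
  a[g$edges] <- TRUE
  a[g$edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  a
}

#' Density of an aggregated graph
#'
#' `d = 2L / (N (N - 1))` where L is the number of links.
#'
#' @param g an `aggregated_graph`.
#' @return Density in `[0, 1]`.
#' @export
graph_density <- function(g) {
  if (g$n_nodes < 2L) stop_invalid("density needs at least 2 nodes")
  2 * nrow(g$edges) / (g$n_nodes * (g$n_nodes - 1))
}

#' Exact aggregated connection probability
#'
#' Probability that a pair at per-slot effective distance chi is connected
#' in at least one of tau independent slots:
#' `P(chi) = 1 - (1 - p(chi))^tau` with p the Fermi-Dirac probability.
#'
#' @param chi nonnegative effective distance(s).
#' @param temperature temperature T in (0, 1).
#' @param tau number of slots, integer >= 1.
#' @return Probabilities in `[0, 1]`.
#' @export
aggregated_probability_exact <- function(chi, temperature, tau) {
  if (length(tau) != 1L || tau < 1) stop_invalid("`tau` must be >= 1")
  1 - (1 - connection_probability(chi, temperature))^tau
}

#' Limiting aggregated connection probability
#'
#' The tau-free curve in the rescaled distance `chi_tilde = chi / alpha`:
#' `P(chi_tilde) = 1 - exp(-(Gamma(1+T)/chi_tilde)^(1/T))`, valid for large
#' tau.  Approaches 1 as chi_tilde -> 0 and `C / chi_tilde^(1/T)` with
#' `C = Gamma(1+T)^(1/T)` at large distances.
#'
#' @param chi_tilde positive rescaled effective distance(s).
#' @param temperature temperature T in (0, 1).
#' @return Probabilities in `[0, 1]`.
#' @export
aggregated_probability_theory <- function(chi_tilde, temperature) {
  if (any(chi_tilde <= 0)) stop_invalid("`chi_tilde` must be positive")
  check_temperature(temperature)
  1 - exp(-(gamma(1 + temperature) / chi_tilde)^(1 / temperature))
}

#' Aggregation factor alpha
#'
#' `alpha = tau^T / Gamma(1+T)`: the ratio between a node's expected
#' time-aggregated degree and its per-slot hidden degree, for tau >> 1.
#'
#' @param tau number of slots, >= 1.
#' @param temperature temperature T in (0, 1).
#' @return The positive scalar alpha, strictly increasing in tau.
#' @examples
#' alpha_factor(10000, 0.5) # 100 / Gamma(1.5)
#' @export
alpha_factor <- function(tau, temperature) {
  if (any(tau < 1)) stop_invalid("`tau` must be >= 1")
  check_temperature(temperature)
  tau^temperature / gamma(1 + temperature)
}

#' Directly sample the time-aggregated graph of a dynamic-S1 network
#'
#' Samples each pair once with the exact aggregated probability
#' [aggregated_probability_exact()]; distributionally identical to
#' generating tau snapshots and aggregating, without materializing the
#' temporal network.
#'
#' @inheritParams generate_dynamic_s1
#' @param mean_degree constant per-slot mean degree.
#' @param tau number of slots.
#' @return An `aggregated_graph`.
#' @export
sample_aggregated_s1 <- function(coords, mean_degree, temperature, tau,
                                 seed = NULL) {
  stopifnot(inherits(coords, "latent_coords"))
  mu <- compute_mu(mean_degree, coords$kappa_bar, temperature)
  pairs <- pair_indices(coords$n_nodes)
  p <- s1_edge_probs(coords, mu, temperature, pairs)
  bigp <- 1 - (1 - p)^tau
  with_local_seed(seed,
    aggregated_graph(pairs[runif(length(bigp)) < bigp, , drop = FALSE],
                     coords$n_nodes, window = c(1L, as.integer(tau))))
}

## long table of per-pair occupied slots, ordered by (pair, slot)
pair_slot_long <- function(tn) {
  tau <- tn$n_slots
  counts <- vapply(tn$edges_by_slot, nrow, 0L)
  slot <- rep.int(seq_len(tau), counts)
  em <- do.call(rbind, tn$edges_by_slot)
  if (is.null(em) || nrow(em) == 0L)
    return(list(key = numeric(0), slot = integer(0)))
  key <- pair_key(em[, 1L], em[, 2L], tn$n_nodes)
  o <- order(key, slot)
  list(key = key[o], slot = slot[o])
}

#' Contact and intercontact durations
#'
#' For every pair of nodes, a contact is a maximal run of consecutive slots
#' in which the pair is connected; an intercontact is a maximal gap between
#' two contacts of the same pair (gaps before the first or after the last
#' contact are censored and excluded).  Durations are in slots.  In the
#' dynamic-S1 model the two distributions are power laws with exponents
#' `2 + T` and `2 - T`.
#'
#' @param tn a [temporal_network()].
#' @return Integer vector of durations (a multiset).
#' @export
contact_durations <- function(tn) {
  ps <- pair_slot_long(tn)
  if (length(ps$key) == 0L) return(integer(0))
  n <- length(ps$key)
  newrun <- c(TRUE, ps$key[-1L] != ps$key[-n] | ps$slot[-1L] != ps$slot[-n] + 1L)
  tabulate(cumsum(newrun))
}

#' @rdname contact_durations
#' @export
intercontact_durations <- function(tn) {
  ps <- pair_slot_long(tn)
  n <- length(ps$key)
  if (n < 2L) return(integer(0))
  same <- ps$key[-1L] == ps$key[-n]
  gap <- ps$slot[-1L] - ps$slot[-n] - 1L
  gap[same & gap > 0L]
}

#' Discrete power-law exponent by maximum likelihood
#'
#' Fits `P(x) ~ x^-a` for integer x >= `xmin` by maximizing the zeta-based
#' discrete likelihood; the normalizer is the Hurwitz zeta
#' `zeta(a) - sum_(k<xmin) k^-a`.
#'
#' @param x positive integer observations.
#' @param xmin lower cutoff (default 1).
#' @return Fitted exponent `a`.
#' @export
fit_powerlaw_discrete <- function(x, xmin = 1L) {
  x <- x[x >= xmin]
  if (length(x) < 10L) stop_invalid("too few observations for a power-law fit")
  n <- length(x); slx <- sum(log(x))
  hz <- function(a) {
    z <- pracma::zeta(a)
    if (xmin > 1L) z <- z - sum(seq_len(xmin - 1L)^(-a))
    z
  }
  nll <- function(a) n * log(hz(a)) + a * slx
  optimize(nll, c(1.05, 6))$minimum
}

#' Counterpart specification of an observed temporal network
#'
#' Extracts the inputs needed to generate a synthetic dynamic-S1 counterpart
#' of an observed network: each node's hidden degree kappa_i is its average
#' degree per slot, and the per-slot mean degrees reproduce the observed
#' activity profile.  Zero-activity nodes are retained (kappa = 0, they
#' generate no edges) and flagged.
#'
#' @param tn a [temporal_network()].
#' @return An object of class `counterpart_spec` with fields `kappa`,
#'   `mean_degrees`, `n_nodes`, `n_slots`, `zero_activity` (indices).
#' @export
build_counterpart <- function(tn) {
  stopifnot(inherits(tn, "temporal_network"))
  if (tn$n_slots < 1L) stop_invalid("empty temporal network")
  em <- do.call(rbind, tn$edges_by_slot)
  inc <- tabulate(c(em[, 1L], em[, 2L]), tn$n_nodes)
  kappa <- inc / tn$n_slots
  kt <- vapply(tn$edges_by_slot, nrow, 0L) * 2 / tn$n_nodes
  structure(list(kappa = kappa, mean_degrees = kt, n_nodes = tn$n_nodes,
                 n_slots = tn$n_slots, zero_activity = which(kappa == 0)),
            class = "counterpart_spec")
}

#' Generate a counterpart temporal network
#'
#' @param spec a [build_counterpart()] result (or compatible list).
#' @param temperature temperature for the counterpart, e.g. from
#'   [calibrate_temperature()].
#' @param seed optional integer seed.
#' @return A [temporal_network()].
#' @export
generate_counterpart <- function(spec, temperature, seed = NULL) {
  check_temperature(temperature)
  n <- spec$n_nodes
  with_local_seed(seed, {
    coords <- latent_coords(spec$kappa, runif(n, 0, 2 * pi),
                            mean_degree = max(mean(spec$mean_degrees), 1e-12),
                            temperature = temperature)
    generate_dynamic_s1(coords, spec$mean_degrees, temperature)
  })
}

## deterministic expected aggregated mean degree, averaging the exact
## finite-tau probability 1 - (1 - p)^tau over kappa pairs and uniform angles
expected_aggregated_degree <- function(kappa, mean_degree, temperature, tau,
                                       max_pairs = 20000L) {
  n <- length(kappa)
  mu <- compute_mu(mean_degree, mean(kappa), temperature)
  radius <- n / (2 * pi)
  pairs <- pair_indices(n)
  if (nrow(pairs) > max_pairs) {
    idx <- unique(round(seq(1L, nrow(pairs), length.out = max_pairs)))
    pairs <- pairs[idx, , drop = FALSE]
  }
  kprod <- kappa[pairs[, 1L]] * kappa[pairs[, 2L]]
  probfn <- function(chi)
    aggregated_probability_exact(chi, temperature, tau)
  (n - 1) * mean(expected_pair_prob(kprod, mu, radius, probfn))
}

#' Calibrate the counterpart temperature
#'
#' Finds T in `[0.05, 0.95]` such that the predicted mean time-aggregated
#' degree of the counterpart matches a target.  The prediction averages the
#' exact aggregated connection probability over the empirical kappa pairs
#' and uniform angles (deterministic; the per-slot mean degree is taken as
#' the mean of `mean_degrees`), and the monotone equation is solved by
#' bisection.  A warning is issued when the thermodynamic-limit prediction
#' `alpha * kappa_bar` exceeds half the network size, where degree-cutoff
#' saturation degrades the scaling.
#'
#' @param spec a `counterpart_spec`.
#' @param target_aggregated_degree target mean aggregated degree,
#'   `< n_nodes - 1`.
#' @param tol absolute tolerance on the matched degree.
#' @return Calibrated temperature in (0, 1).
#' @export
calibrate_temperature <- function(spec, target_aggregated_degree,
                                  tol = 0.05) {
  if (target_aggregated_degree <= 0 ||
      target_aggregated_degree >= spec$n_nodes - 1)
    stop_invalid("target aggregated degree must lie in (0, N-1)")
  kbar_slot <- mean(spec$mean_degrees)
  f <- function(T) expected_aggregated_degree(spec$kappa, kbar_slot, T,
                                              spec$n_slots) -
    target_aggregated_degree
  lo <- 0.05; hi <- 0.95
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0)
    stop_invalid("calibration target unattainable within T in [0.05, 0.95]")
  for (it in 1:60) {
    mid <- (lo + hi) / 2; fm <- f(mid)
    if (abs(fm) < tol) break
    if (fm > 0) hi <- mid else lo <- mid
  }
  Tcal <- (lo + hi) / 2
  if (alpha_factor(spec$n_slots, Tcal) * mean(spec$kappa) >
      0.5 * (spec$n_nodes - 1))
    warning("predicted aggregated degree in the saturation regime; ",
            "thermodynamic-limit scaling kappa_tilde = alpha*kappa degrades")
  Tcal
}
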