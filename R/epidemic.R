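#' Simulate a discrete-time SI process on a temporal network
#'
#' Susceptible-infected dynamics: in each slot, a susceptible node in
#' contact with m infected neighbors becomes infected with probability
#' `1 - (1 - beta)^m` (independent Bernoulli attempts per contact).  State
#' updates take effect at the end of the slot (synchronous update, no
#' same-slot transmission chains); infection is absorbing.
#'
#' @param tn a [temporal_network()].
#' @param source initially infected node (arrival slot 0).
#' @param beta per-slot per-contact infection probability, in (0, 1].
#' @param window slot indices to simulate; default all slots.
#' @param seed optional integer seed (local to this call).
#' @return An object of class `epidemic_run`: `source`, `beta`,
#'   `arrival_slot` (per node; `NA` = never infected, 0 = source).
#' @export
simulate_si <- function(tn, source, beta, window = seq_len(tn$n_slots),
                        seed = NULL) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1)
    stop_invalid("`beta` must lie in (0, 1]")
  n <- tn$n_nodes
  with_local_seed(seed, {
    infected <- logical(n)
    infected[source] <- TRUE
    arrival <- rep(NA_integer_, n)
    arrival[source] <- 0L
    for (t in window) {
      e <- tn$edges_by_slot[[t]]
      if (nrow(e) == 0L) next
      ia <- infected[e[, 1L]]; ib <- infected[e[, 2L]]
      sus <- c(e[ia & !ib, 2L], e[ib & !ia, 1L])
      if (length(sus) == 0L) next
      m <- tabulate(sus, n)
      at_risk <- which(m > 0L)
      newly <- at_risk[runif(length(at_risk)) < 1 - (1 - beta)^m[at_risk]]
      if (length(newly)) {
        infected[newly] <- TRUE    # takes effect at end of slot
        arrival[newly] <- t
      }
      if (all(infected)) break
    }
    structure(list(source = source, beta = beta, arrival_slot = arrival),
              class = "epidemic_run")
  })
}

#' Epidemic arrival time versus hyperbolic distance from the source
#'
#' Pairs every infected node (excluding the source and nodes without
#' coordinates) with its hyperbolic distance
#' `x = r_s + r_i + 2*log(dtheta/2)` from the source, and bins the distance
#' axis into bins of width `delta`; bins with fewer than `min_count`
#' samples are dropped.
#'
#' @param run an `epidemic_run`.
#' @param emb an `embedding` covering the run's nodes.
#' @param delta bin width (hyperbolic distance units), default 1.
#' @param min_count minimum samples per retained bin, default 5.
#' @return List with `samples` (data frame: node, distance, arrival) and
#'   `bins` (data frame: mid, n, mean_arrival, sd_arrival).
#' @export
arrival_vs_distance <- function(run, emb, delta = 1, min_count = 5L) {
  if (is.na(embedding_pos(emb, run$source)))
    stop_invalid("source has no coordinates")
  nodes <- setdiff(emb$node_ids, run$source)
  nodes <- nodes[!is.na(run$arrival_slot[nodes])]
  x <- hyperbolic_distance(emb, rep(run$source, length(nodes)), nodes)
  samples <- data.frame(node = nodes, distance = x,
                        arrival = run$arrival_slot[nodes])
  b <- floor(samples$distance / delta)
  keep <- stats::ave(b, b, FUN = length) >= min_count
  bs <- samples[keep, , drop = FALSE]
  bb <- floor(bs$distance / delta)
  bins <- data.frame(
    mid = (sort(unique(bb)) + 0.5) * delta,
    n = as.vector(table(bb)),
    mean_arrival = as.vector(tapply(bs$arrival, bb, mean)),
    sd_arrival = as.vector(tapply(bs$arrival, bb, stats::sd)))
  list(samples = samples, bins = bins)
}

#' Spearman rank correlation
#'
#' Pearson correlation of the rank variables (ties receive average ranks):
#' `rho = cov(rg_X, rg_Y) / (sigma_rg_X * sigma_rg_Y)`.
#'
#' @param x,y numeric vectors, length >= 3, non-constant.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_invalid("need two equal-length vectors of length >= 3")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop_invalid("constant input: rank correlation undefined")
  cor(x, y, method = "spearman")
}

#' Mean arrival/distance correlation across SI runs
#'
#' Runs `n_sources` SI processes from random embedded source nodes and
#' reports, per run, the Spearman correlation between each node's infection
#' slot and its hyperbolic distance from that run's source, plus the mean
#' across runs.  Runs infecting fewer than 3 nodes are excluded with a
#' warning.
#'
#' @inheritParams simulate_si
#' @param emb an `embedding` used for the distances (by default the map of
#'   the full observation window).
#' @param n_sources number of independent runs (distinct random sources).
#' @return List with `rho` (per retained run), `mean_rho`, `sources`.
#' @export
epidemic_experiment <- function(tn, emb, beta = 0.05, n_sources = 10L,
                                window = seq_len(tn$n_slots), seed = NULL) {
  with_local_seed(seed, {
    sources <- sample(emb$node_ids, n_sources)
    rhos <- rep(NA_real_, n_sources)
    for (k in seq_len(n_sources)) {
      run <- simulate_si(tn, sources[k], beta, window)
      avd <- arrival_vs_distance(run, emb, min_count = 1L)
      if (nrow(avd$samples) < 3L) next
      rhos[k] <- spearman_rho(avd$samples$distance, avd$samples$arrival)
    }
    if (anyNA(rhos))
      warning(sum(is.na(rhos)), " run(s) infected fewer than 3 nodes; excluded")
    list(rho = rhos[!is.na(rhos)], mean_rho = mean(rhos, na.rm = TRUE),
         sources = sources)
  })
}
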