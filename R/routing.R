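## neighbors of node x in one slot's edge matrix
slot_neighbors <- function(e, x) {
  if (nrow(e) == 0L) return(integer(0))
  unname(c(e[e[, 1L] == x, 2L], e[e[, 2L] == x, 1L]))
}

## vector of distances-to-destination for every node; Inf for nodes without
## coordinates so they are never admissible targets
dist_to_destination <- function(tn, emb, destination,
                                distance = c("effective", "similarity")) {
  distance <- match.arg(distance)
  d <- rep(Inf, tn$n_nodes)
  pd <- embedding_pos(emb, destination)
  if (is.na(pd)) stop_invalid("destination has no coordinates")
  pos <- seq_along(emb$node_ids)
  dth <- circ_dist(emb$theta, emb$theta[pd])
  d[emb$node_ids] <- if (distance == "effective")
    chi_from_parts(dth, emb$kappa_agg * emb$kappa_agg[pd], emb$mu_tilde,
                   emb$radius)
  else dth
  d
}

routing_outcome <- function(source, destination, success, hops,
                            delivery_slot, path, visited) {
  structure(list(source = source, destination = destination,
                 success = success, hops = hops,
                 delivery_slot = delivery_slot, path = path,
                 visited = visited),
            class = "routing_outcome")
}

#' Greedy routing on the temporal network (H2H-GR)
#'
#' A packet starts at `source` in the first slot of the window.  In each
#' slot the carrier delivers immediately if the destination is a current
#' neighbor; otherwise it forwards to the neighbor with the smallest
#' effective distance to the destination, but only if that distance is
#' strictly smaller than its own (ties broken by smallest node id), and
#' keeps the packet when no admissible neighbor exists.  Forwarding repeats
#' within a slot until the packet cannot move, then the next slot begins.
#' Distances strictly decrease along the path, so no node receives the
#' packet twice.  Undelivered at window end counts as failure.
#'
#' @param tn a [temporal_network()].
#' @param emb an `embedding` providing coordinates (nodes without
#'   coordinates are never forwarded to).
#' @param source,destination node ids (distinct; both with coordinates).
#' @param window slot indices; default all slots.
#' @param distance `"effective"` (chi) or `"similarity"` (angular only).
#' @return A `routing_outcome`: `success`, `hops`, `delivery_slot`, `path`,
#'   `visited`.
#' @export
greedy_route <- function(tn, emb, source, destination,
                         window = seq_len(tn$n_slots),
                         distance = c("effective", "similarity")) {
  if (source == destination) stop_invalid("source equals destination")
  d <- dist_to_destination(tn, emb, destination, distance)
  if (!is.finite(d[source])) stop_invalid("source has no coordinates")
  carrier <- source
  path <- source
  hops <- 0L
  for (t in window) {
    e <- tn$edges_by_slot[[t]]
    repeat {
      nbs <- slot_neighbors(e, carrier)
      if (length(nbs) == 0L) break
      if (destination %in% nbs)
        return(routing_outcome(source, destination, TRUE, hops + 1L, t,
                               c(path, destination), c(path, destination)))
      cand <- nbs[d[nbs] < d[carrier]]
      if (length(cand) == 0L) break
      nxt <- cand[order(d[cand], cand)][1L]
      carrier <- nxt
      path <- c(path, nxt)
      hops <- hops + 1L
    }
  }
  routing_outcome(source, destination, FALSE, hops, NA_integer_, path, path)
}

#' Random routing baseline (H2H-RR)
#'
#' As [greedy_route()] but coordinate-free: if the destination is a current
#' neighbor the carrier delivers; otherwise it forwards uniformly at random
#' among neighbors that have never received the packet, and keeps the packet
#' when there are none.  No node receives the packet twice.
#'
#' @inheritParams greedy_route
#' @param seed optional integer seed (local to this call).
#' @return A `routing_outcome`.
#' @export
random_route <- function(tn, source, destination,
                         window = seq_len(tn$n_slots), seed = NULL) {
  if (source == destination) stop_invalid("source equals destination")
  with_local_seed(seed, {
    visited <- logical(tn$n_nodes)
    visited[source] <- TRUE
    carrier <- source
    path <- source
    hops <- 0L
    for (t in window) {
      e <- tn$edges_by_slot[[t]]
      repeat {
        nbs <- slot_neighbors(e, carrier)
        if (length(nbs) == 0L) break
        if (destination %in% nbs) {
          visited[destination] <- TRUE
          return(routing_outcome(source, destination, TRUE, hops + 1L, t,
                                 c(path, destination), which(visited)))
        }
        cand <- nbs[!visited[nbs]]
        if (length(cand) == 0L) break
        nxt <- cand[sample.int(length(cand), 1L)]
        visited[nxt] <- TRUE
        carrier <- nxt
        path <- c(path, nxt)
        hops <- hops + 1L
      }
    }
    routing_outcome(source, destination, FALSE, hops, NA_integer_, path,
                    which(visited))
  })
}

## doubled (directed) temporal edge table restricted to a window
temporal_edge_table <- function(tn, window) {
  counts <- vapply(tn$edges_by_slot[window], nrow, 0L)
  em <- do.call(rbind, tn$edges_by_slot[window])
  if (is.null(em) || nrow(em) == 0L)
    return(list(t = integer(0), u = integer(0), v = integer(0)))
  tt <- rep.int(window, counts)
  list(t = c(tt, tt), u = c(em[, 1L], em[, 2L]), v = c(em[, 2L], em[, 1L]))
}

strp_hops <- function(ed, n_nodes, source, destination, w_start, max_hops) {
  ea <- rep(Inf, n_nodes)
  ea[source] <- w_start
  for (h in seq_len(max_hops)) {
    ok <- ea[ed$u] <= ed$t
    if (!any(ok)) return(NA_integer_)
    best <- tapply(ed$t[ok], ed$v[ok], min)
    idx <- as.integer(names(best))
    newea <- ea
    newea[idx] <- pmin(ea[idx], best)
    if (is.finite(newea[destination])) return(h)
    if (identical(newea, ea)) return(NA_integer_)
    ea <- newea
  }
  NA_integer_
}

#' Shortest time-respecting path length
#'
#' Minimum hop count over paths whose successive edges occur in
#' non-decreasing slot order within the window (multiple hops within one
#' slot allowed).  `NA` when the destination is unreachable.
#'
#' @inheritParams greedy_route
#' @return Integer hop count or `NA`.
#' @export
shortest_time_respecting_path <- function(tn, source, destination,
                                          window = seq_len(tn$n_slots)) {
  if (source == destination) return(0L)
  ed <- temporal_edge_table(tn, window)
  strp_hops(ed, tn$n_nodes, source, destination, min(window), tn$n_nodes)
}

#' Evaluate a routing strategy over many source-destination pairs
#'
#' Runs the chosen strategy for every ordered pair, and reports the success
#' ratio `p_s` (successes / attempted pairs) and the mean stretch `s_bar`
#' over successful pairs, where the stretch of a pair is the delivered hop
#' count divided by its shortest time-respecting path length.
#'
#' @inheritParams greedy_route
#' @param pairs two-column matrix of ordered (source, destination) pairs.
#' @param strategy `"greedy"` or `"random"`.
#' @param emb required for `"greedy"`; ignored for `"random"`.
#' @param seed integer seed driving the random strategy.
#' @return List with `p_s`, `mean_stretch`, and `per_pair` (a data frame
#'   with source, destination, success, hops, delivery_slot, spt, stretch).
#' @export
evaluate_routing <- function(tn, emb = NULL, pairs,
                             window = seq_len(tn$n_slots),
                             strategy = c("greedy", "random"),
                             distance = c("effective", "similarity"),
                             seed = NULL) {
  strategy <- match.arg(strategy)
  distance <- match.arg(distance)
  if (is.null(dim(pairs)) || nrow(pairs) == 0L)
    stop_invalid("`pairs` must be a nonempty two-column matrix")
  if (strategy == "greedy" && is.null(emb))
    stop_invalid("greedy routing needs an embedding")
  ed <- temporal_edge_table(tn, window)
  with_local_seed(seed, {
    res <- lapply(seq_len(nrow(pairs)), function(k) {
      s <- pairs[k, 1L]; d <- pairs[k, 2L]
      out <- if (strategy == "greedy")
        greedy_route(tn, emb, s, d, window, distance)
      else random_route(tn, s, d, window)
      spt <- if (out$success)
        strp_hops(ed, tn$n_nodes, s, d, min(window), tn$n_nodes)
      else NA_integer_
      data.frame(source = s, destination = d, success = out$success,
                 hops = out$hops, delivery_slot = out$delivery_slot,
                 spt = spt, stretch = if (isTRUE(out$success) && !is.na(spt))
                   out$hops / spt else NA_real_)
    })
    per_pair <- do.call(rbind, res)
    list(p_s = mean(per_pair$success),
         mean_stretch = mean(per_pair$stretch, na.rm = TRUE),
         per_pair = per_pair)
  })
}

#' Nodes active (non-zero degree) in a window
#'
#' Helper for day-based routing experiments: the pair universe is formed
#' from nodes present in both the routing day and the coordinate-source day.
#'
#' @param tn a [temporal_network()].
#' @param window slot indices.
#' @return Integer vector of active node ids.
#' @export
active_nodes <- function(tn, window = seq_len(tn$n_slots)) {
  em <- do.call(rbind, tn$edges_by_slot[window])
  if (is.null(em)) return(integer(0))
  sort(unique(as.vector(em)))
}
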