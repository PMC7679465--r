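#' Read and write slot-stamped temporal edge lists
#'
#' The interchange format is the SocioPatterns-style text edge list: one
#' whitespace-separated `t i j` triple per line, `t` a nonnegative integer
#' timestamp in seconds, `i`, `j` arbitrary node labels; `#` lines are
#' comments.  Timestamps are quantized to slots by integer division by
#' `slot_seconds`; duplicate same-slot edges are deduplicated and self-loop
#' lines dropped with a warning count.  Labels are mapped to dense 1-based
#' ids (mapping kept in `node_labels`); writing emits `t = (slot-1) *
#' slot_seconds`, so a write/read round trip is the identity on the slot
#' representation.
#'
#' @param path file path.
#' @param slot_seconds slot duration in seconds (default 20, the standard
#'   face-to-face observation interval).
#' @param tn a [temporal_network()] to write.
#' @return `read_temporal`: a [temporal_network()].
#' @export
read_temporal <- function(path, slot_seconds = 20) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  df <- tryCatch(
    read.table(path, header = FALSE, comment.char = "#",
               colClasses = c("numeric", "character", "character")),
    error = function(e) stop_invalid("cannot parse ", path, ": ",
                                     conditionMessage(e)))
  if (ncol(df) < 3L) stop_invalid("expected `t i j` lines in ", path)
  self <- df[[2L]] == df[[3L]]
  if (any(self)) {
    warning(sum(self), " self-loop line(s) dropped")
    df <- df[!self, , drop = FALSE]
  }
  labels <- sort(unique(c(df[[2L]], df[[3L]])))
  i <- match(df[[2L]], labels)
  j <- match(df[[3L]], labels)
  slot <- df[[1L]] %/% slot_seconds + 1L
  n_slots <- max(slot)
  by_slot <- split(seq_along(slot), factor(slot, levels = seq_len(n_slots)))
  ebs <- lapply(by_slot, function(ix) cbind(i = i[ix], j = j[ix]))
  temporal_network(ebs, length(labels), slot_seconds = slot_seconds,
                   node_labels = labels)
}

#' @rdname read_temporal
#' @export
write_temporal <- function(tn, path, slot_seconds = NULL) {
  slot_seconds <- slot_seconds %||% tn$slot_seconds %||% 1
  labels <- tn$node_labels %||% as.character(seq_len(tn$n_nodes))
  counts <- vapply(tn$edges_by_slot, nrow, 0L)
  em <- do.call(rbind, tn$edges_by_slot)
  t <- (rep.int(seq_len(tn$n_slots), counts) - 1L) * slot_seconds
  lines <- if (is.null(em) || nrow(em) == 0L) character(0)
  else paste(t, labels[em[, 1L]], labels[em[, 2L]])
  writeLines(lines, path)
  invisible(path)
}

#' Read and write coordinate tables
#'
#' Coordinates are exchanged as TSV with columns `node`, `kappa`, `theta`,
#' `r` and `# key=value` header comments carrying the scalars needed to
#' recompute any pairwise effective distance (`mu`, `temperature`,
#' `radius`, `disk_radius`, `mode`, `tau`).
#'
#' @param emb an `embedding` (or truth embedding from
#'   [embedding_from_truth()]).
#' @param path file path.
#' @param labels optional full label vector indexed by node id.
#' @return `read_coordinates`: an `embedding` whose `node_ids` are row
#'   numbers unless `match_labels` is given.
#' @param match_labels optional label vector of the host network (e.g.
#'   `tn$node_labels`); when given, `node_ids` are matched into it.
#' @export
write_coordinates <- function(emb, path, labels = NULL) {
  labels <- labels %||% emb$labels %||% as.character(emb$node_ids)
  if (length(labels) > length(emb$node_ids)) labels <- labels[emb$node_ids]
  hdr <- c(
    sprintf("# n_nodes=%d", emb$n_nodes),
    sprintf("# temperature=%.10g", emb$temperature_hat),
    sprintf("# mu=%.15g", emb$mu_tilde),
    sprintf("# radius=%.15g", emb$radius),
    sprintf("# disk_radius=%.15g", emb$radial$disk_radius),
    sprintf("# mode=%s", emb$mode),
    sprintf("# tau=%s", emb$tau %||% "NA"))
  body <- sprintf("%s\t%.15g\t%.15g\t%.15g", labels, emb$kappa_agg,
                  emb$theta, emb$radial$r)
  writeLines(c(hdr, "node\tkappa\ttheta\tr", body), path)
  invisible(path)
}

#' @rdname write_coordinates
#' @export
read_coordinates <- function(path, match_labels = NULL) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  raw <- readLines(path)
  hdr <- grep("^#", raw, value = TRUE)
  kv <- do.call(rbind, regmatches(hdr, regexec("^# *([a-z_]+)=(.*)$", hdr)))
  meta <- stats::setNames(as.list(kv[, 3L]), kv[, 2L])
  df <- read.table(text = raw[!grepl("^#", raw)], header = TRUE,
                   sep = "\t", colClasses = c("character", rep("numeric", 3)))
  node_ids <- if (is.null(match_labels)) seq_len(nrow(df))
  else {
    ids <- match(df$node, match_labels)
    if (anyNA(ids)) stop_invalid("coordinate labels absent from network")
    ids
  }
  n_nodes <- as.integer(meta$n_nodes %||% nrow(df))
  tau <- suppressWarnings(as.numeric(meta$tau %||% NA))
  structure(list(node_ids = node_ids, kappa_agg = df$kappa,
                 theta = df$theta %% (2 * pi),
                 temperature_hat = as.numeric(meta$temperature),
                 mu_tilde = as.numeric(meta$mu), mode = meta$mode %||% "file",
                 tau = if (is.na(tau)) NULL else tau,
                 log_likelihood = NA_real_,
                 radial = structure(list(r = df$r,
                                         disk_radius = as.numeric(meta$disk_radius)),
                                    class = "hyperbolic_coords"),
                 radius = as.numeric(meta$radius),
                 n_nodes = n_nodes,
                 excluded = integer(0), labels = df$node),
            class = "embedding")
}

#' Read a node-metadata table
#'
#' Two-column TSV mapping node label to group label (class, department,
#' role, ...), as distributed alongside proximity datasets.
#'
#' @param path file path.
#' @return Data frame with columns `node`, `group`.
#' @export
read_metadata <- function(path) {
  df <- read.table(path, header = FALSE, comment.char = "#", sep = "\t",
                   colClasses = "character")
  if (anyDuplicated(df[[1L]])) stop_invalid("duplicate node labels")
  stats::setNames(df[, 1:2], c("node", "group"))
}

#' Generate a synthetic fixture on disk
#'
#' Samples a dynamic-S1 temporal network from a configuration (counterpart
#' construction) and writes the temporal edge list together with a
#' ground-truth coordinate file.  Deterministic under `seed`.
#'
#' @param config list with `n_nodes`, `n_slots`, `temperature`,
#'   `mean_degree` (scalar, or length-`n_slots` vector of per-slot mean
#'   degrees), and optionally `kappa_law` (default: delta at the mean
#'   per-slot degree) and `slot_seconds` (default 20).
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @return Invisibly, a list with `tn`, `coords`, `temporal_path`,
#'   `truth_path`.
#' @export
make_fixture <- function(config, dir, seed) {
  needed <- c("n_nodes", "n_slots", "temperature", "mean_degree")
  missing <- setdiff(needed, names(config))
  if (length(missing))
    stop_invalid("fixture config lacks: ", paste(missing, collapse = ", "))
  kd <- config$mean_degree
  mean_degrees <- if (length(kd) == 1L) rep(kd, config$n_slots)
  else if (length(kd) == config$n_slots) kd
  else stop_invalid("`mean_degree` must be scalar or length n_slots")
  law <- config$kappa_law %||% kappa_delta(mean(mean_degrees))
  params <- s1_params(config$n_nodes, mean(mean_degrees),
                      config$temperature, kappa_law = law, seed = seed)
  coords <- sample_latent(params)
  tn <- generate_dynamic_s1(coords, mean_degrees, config$temperature,
                            seed = seed + 1L,
                            slot_seconds = config$slot_seconds %||% 20)
  tn$node_labels <- as.character(seq_len(config$n_nodes))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  temporal_path <- file.path(dir, "temporal.tsv")
  truth_path <- file.path(dir, "coordinates_truth.tsv")
  write_temporal(tn, temporal_path)
  truth <- embedding_from_truth(coords, tau = config$n_slots,
                                temperature = config$temperature)
  write_coordinates(truth, truth_path, labels = tn$node_labels)
  invisible(list(tn = tn, coords = coords, temporal_path = temporal_path,
                 truth_path = truth_path))
}
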