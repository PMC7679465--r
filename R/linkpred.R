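#' Geometric link-prediction scores
#'
#' Score `s_ij = 1 / chi_tilde_ij` from previous-window coordinates: the
#' smaller the effective distance, the more likely a future link.
#' Coincident coordinates (chi = 0) score `Inf` and rank first.
#'
#' @param emb_prev `embedding` inferred from the previous window.
#' @param pairs two-column matrix of node ids (all embedded).
#' @return Numeric score vector.
#' @export
geometric_scores <- function(emb_prev, pairs) {
  1 / embedding_chi(emb_prev, pairs[, 1L], pairs[, 2L])
}

#' Common-neighbor link-prediction scores
#'
#' Number of common neighbors of each pair in the previous window's
#' time-aggregated graph.
#'
#' @param g_prev previous-window `aggregated_graph`.
#' @param pairs two-column matrix of node ids.
#' @return Integer count vector.
#' @export
common_neighbor_scores <- function(g_prev, pairs) {
  a <- adjacency_logical(g_prev)
  rowSums(a[pairs[, 1L], , drop = FALSE] & a[pairs[, 2L], , drop = FALSE])
}

check_scored <- function(scores, labels, need_negative = TRUE) {
  if (length(scores) != length(labels)) stop_invalid("length mismatch")
  if (!any(labels)) stop_invalid("no positive labels: metric undefined")
  if (need_negative && all(labels))
    stop_invalid("no negative labels: metric undefined")
}

#' Area under the ROC curve
#'
#' Probability that a random positive outranks a random negative, ties
#' counted one half (the Mann-Whitney convention).
#'
#' @param scores numeric scores (higher = more likely positive); `Inf` allowed.
#' @param labels logical (or 0/1) labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  check_scored(scores, labels)
  r <- rank(scores)        # average ranks handle ties
  npos <- sum(labels); nneg <- sum(!labels)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve by threshold sweep
#'
#' Sweeps thresholds over descending scores (tied scores form one step) and
#' reports, per threshold, the fraction of positives above it (TPR) and of
#' negatives above it (FPR).
#'
#' @inheritParams auroc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  check_scored(scores, labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  step_end <- which(c(s[-1L] != s[-length(s)], TRUE))
  tp <- cumsum(y)[step_end]; fp <- cumsum(!y)[step_end]
  data.frame(threshold = s[step_end], fpr = fp / sum(!labels),
             tpr = tp / sum(labels))
}

## AUROC via trapezoid on the sweep curve -- used as the internal
## cross-check route against the rank computation
auroc_from_curve <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  fpr <- c(0, rc$fpr); tpr <- c(0, rc$tpr)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Precision-recall curve and average precision
#'
#' The PR sweep orders pairs by descending score (tied scores form one
#' threshold step); AUPR is computed as average precision,
#' `sum_k Precision(k) * dRecall(k)` over the sweep (step interpolation,
#' not trapezoidal).  The chance level equals the label prevalence.
#'
#' @inheritParams auroc
#' @return `pr_curve`: data frame with `threshold`, `recall`, `precision`;
#'   `aupr`: scalar average precision in (0, 1].
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  check_scored(scores, labels, need_negative = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  step_end <- which(c(s[-1L] != s[-length(s)], TRUE))
  tp <- cumsum(y)[step_end]
  k <- step_end
  data.frame(threshold = s[step_end], recall = tp / sum(labels),
             precision = tp / k)
}

#' @rdname pr_curve
#' @export
aupr <- function(scores, labels) {
  pc <- pr_curve(scores, labels)
  sum(pc$precision * diff(c(0, pc$recall)))
}

#' Scored pairs for next-window link prediction
#'
#' Builds the pair universe (all unordered pairs of nodes present in both
#' the previous and the target window, and embedded when the geometric
#' method is used), labels each pair by connectivity in the target window's
#' aggregate, scores it by the chosen method, and attaches AUROC/AUPR.
#'
#' @param g_target target-window `aggregated_graph` (labels).
#' @param emb_prev previous-window `embedding` (geometric method).
#' @param g_prev previous-window `aggregated_graph` (CN method and presence
#'   filter).
#' @param method `"geometric"` or `"cn"`.
#' @param exclude_known drop pairs already connected in the previous window
#'   (default keeps all co-present pairs).
#' @return An object of class `scored_pairs`: `pairs`, `scores`, `labels`,
#'   `auroc`, `aupr`, `chance` (label prevalence).
#' @export
predict_links <- function(g_target, emb_prev = NULL, g_prev = NULL,
                          method = c("geometric", "cn"),
                          exclude_known = FALSE) {
  method <- match.arg(method)
  present_target <- which(aggregated_degrees(g_target) > 0L)
  present_prev <- if (!is.null(g_prev))
    which(aggregated_degrees(g_prev) > 0L)
  else if (!is.null(emb_prev)) emb_prev$node_ids
  else stop_invalid("need `g_prev` or `emb_prev` for the previous window")
  shared <- intersect(present_prev, present_target)
  if (method == "geometric") {
    if (is.null(emb_prev)) stop_invalid("geometric method needs `emb_prev`")
    shared <- intersect(shared, emb_prev$node_ids)
  }
  if (length(shared) < 2L) stop_invalid("windows share fewer than 2 nodes")
  idx <- pair_indices(length(shared))
  pairs <- cbind(shared[idx[, 1L]], shared[idx[, 2L]])
  if (exclude_known && !is.null(g_prev)) {
    known <- pair_key(g_prev$edges[, 1L], g_prev$edges[, 2L], g_prev$n_nodes)
    pairs <- pairs[!(pair_key(pairs[, 1L], pairs[, 2L], g_prev$n_nodes)
                     %in% known), , drop = FALSE]
  }
  tkey <- pair_key(g_target$edges[, 1L], g_target$edges[, 2L],
                   g_target$n_nodes)
  labels <- pair_key(pairs[, 1L], pairs[, 2L], g_target$n_nodes) %in% tkey
  scores <- if (method == "geometric") geometric_scores(emb_prev, pairs)
  else common_neighbor_scores(g_prev, pairs)
  structure(list(pairs = pairs, scores = scores, labels = labels,
                 auroc = auroc(scores, labels),
                 aupr = aupr(scores, labels),
                 chance = mean(labels), method = method),
            class = "scored_pairs")
}

#' @export
print.scored_pairs <- function(x, ...) {
  cat(sprintf("scored_pairs (%s): %d pairs, prevalence %.3f, AUROC %.3f, AUPR %.3f\n",
              x$method, length(x$scores), x$chance, x$auroc, x$aupr))
  invisible(x)
}
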