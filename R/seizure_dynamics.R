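#' Node sequence: each node's highest-similarity partner
#'
#' From a symmetric similarity matrix (diagonal excluded), assigns every
#' node the index of its most similar partner: `partner(i) = argmax_{j != i}
#' S_ij`, ties broken toward the smallest node index. A length-N integer
#' vector results; repeats are allowed and typical. Rows with no positive
#' score have no informative partner; they default to the smallest index
#' other than `i` and are reported in the `"degenerate"` attribute.
#'
#' The assignment depends only on within-row score order, so it is
#' invariant to any strictly increasing transformation of the scores.
#'
#' An alternative reading of "the k highest-similarity nodes" is provided
#' behind `mode = "global_top_k"`: rank all unordered pairs by score
#' (ties toward smaller indices), walk the top pairs in order, and emit
#' their member nodes until `k` entries are collected. The per-node argmax
#' remains the default because observed sequences are length-N vectors
#' with repeats, which per-row selection produces naturally.
#'
#' @param sim N x N symmetric similarity matrix (e.g. from
#'   [similarity_matrix()]).
#' @param mode `"per_node"` (default) or `"global_top_k"`.
#' @param k sequence length for global mode (default N).
#' @return integer vector of length N (or `k`), class `node_sequence`.
#' @export
node_sequence <- function(sim, mode = c("per_node", "global_top_k"), k = NULL) {
  mode <- match.arg(mode)
  s <- unname(as.matrix(sim))
  n <- nrow(s)
  if (n < 2) stop_config("need at least 2 nodes")
  if (mode == "global_top_k") {
    if (is.null(k)) k <- n
    ut <- which(upper.tri(s), arr.ind = TRUE)
    ord <- order(-s[upper.tri(s)], ut[, 1], ut[, 2])
    nodes <- as.integer(t(ut[ord, , drop = FALSE]))  # i then j, pair by pair
    return(structure(nodes[seq_len(min(k, length(nodes)))],
                     class = "node_sequence"))
  }
  diag(s) <- -Inf
  partner <- apply(s, 1, which.max)  # which.max takes the first (smallest) max
  degenerate <- apply(s, 1, function(r) all(r[is.finite(r)] <= 0))
  if (any(degenerate)) {
    partner[degenerate] <- ifelse(which(degenerate) == 1L, 2L, 1L)
    structure(as.integer(partner), degenerate = which(degenerate),
              class = "node_sequence")
  } else {
    structure(as.integer(partner), class = "node_sequence")
  }
}

#' Cosine similarity and Euclidean distance between node sequences
#'
#' Sequences are compared as raw positive integer vectors in fixed node
#' order. Cosine similarity `a.b / (|a||b|)` lies in (0, 1] for positive
#' vectors and equals 1 for identical (or parallel -- a documented caveat)
#' sequences; Euclidean distance `sqrt(sum((a-b)^2))` is 0 iff the
#' sequences are identical.
#'
#' @param a,b equal-length numeric vectors (node sequences).
#' @return a single number.
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b), length(a) > 0)
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' @rdname cosine_similarity
#' @export
euclidean_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  sqrt(sum((a - b)^2))
}

#' Node sequences for every window of a network series
#'
#' Runs the chosen similarity index on each window's network (binarizing
#' weighted adjacencies at `threshold` first, since the indices are
#' defined on neighbour sets) and extracts the per-window node sequence.
#'
#' @param series a `plv_network_series` or `binary_network_series`.
#' @param index similarity index for ranking (default `"RA"`, the index
#'   used for the sequence analysis).
#' @param threshold binarization threshold applied to weighted series.
#' @return windows x N integer matrix of sequences, with the window table
#'   attached as attribute `"windows"`.
#' @export
window_node_sequences <- function(series, index = "RA", threshold = 0.3) {
  stopifnot(inherits(series, "plv_network_series"))
  adj <- series$adjacency
  if (!inherits(series, "binary_network_series"))
    adj <- lapply(adj, binarize, threshold = threshold)
  seqs <- t(vapply(adj, function(a) {
    g <- graph_from_binary_adjacency(a)
    as.integer(node_sequence(similarity_matrix(g, index)))
  }, integer(length(series$node_labels))))
  attr(seqs, "windows") <- series$windows
  seqs
}

#' Variation of node sequences across windows
#'
#' Quantifies reorganization of the network over time. In `consecutive`
#' mode each window's sequence is compared with its predecessor's; in
#' `cross_condition` mode every window of `cond_a` is compared with every
#' window of `cond_b`, returning the full pairwise distribution.
#'
#' @param seqs windows x N sequence matrix from [window_node_sequences()]
#'   (or any integer matrix with one sequence per row).
#' @param conditions character vector of per-window condition labels;
#'   taken from the `"windows"` attribute when absent.
#' @param mode `"consecutive"` or `"cross_condition"`.
#' @param cond_a,cond_b conditions compared in `cross_condition` mode.
#' @return data.frame: consecutive mode has one row per window from the
#'   second onward (`window`, `condition`, `cosine_prev`, `euclid_prev`);
#'   cross-condition mode one row per window pair (`window_a`, `window_b`,
#'   `cosine`, `euclid`).
#' @export
variation_series <- function(seqs, conditions = NULL,
                             mode = c("consecutive", "cross_condition"),
                             cond_a = "preictal", cond_b = "ictal") {
  mode <- match.arg(mode)
  seqs <- as.matrix(seqs)
  if (is.null(conditions)) {
    w <- attr(seqs, "windows")
    conditions <- if (!is.null(w)) w$condition else rep("unlabeled", nrow(seqs))
  }
  stopifnot(length(conditions) == nrow(seqs))
  if (mode == "consecutive") {
    if (nrow(seqs) < 2) stop_config("need >= 2 windows for consecutive variation")
    i <- 2:nrow(seqs)
    data.frame(
      window = i,
      condition = conditions[i],
      cosine_prev = vapply(i, function(j)
        cosine_similarity(seqs[j - 1, ], seqs[j, ]), 0),
      euclid_prev = vapply(i, function(j)
        euclidean_distance(seqs[j - 1, ], seqs[j, ]), 0))
  } else {
    ia <- which(conditions == cond_a)
    ib <- which(conditions == cond_b)
    if (!length(ia) || !length(ib))
      stop_config("no windows labeled %s or %s", cond_a, cond_b)
    grid <- expand.grid(window_a = ia, window_b = ib)
    grid$cosine <- mapply(function(a, b) cosine_similarity(seqs[a, ], seqs[b, ]),
                          grid$window_a, grid$window_b)
    grid$euclid <- mapply(function(a, b) euclidean_distance(seqs[a, ], seqs[b, ]),
                          grid$window_a, grid$window_b)
    grid
  }
}

#' Node index summation
#'
#' Sums each window's node sequence. Because intrafocus sites carry the
#' lowest node indices (1..3 of 6 by default), lower sums mean the
#' network's strongest similarity partners concentrate on intrafocus
#' sites, higher sums mean more extrafocus involvement. Returns per-window
#' sums plus a per-condition mean/sd summary.
#'
#' @inheritParams variation_series
#' @return list with `per_window` (data.frame `window`, `condition`,
#'   `index_sum`) and `per_condition` (data.frame `condition`, `mean`,
#'   `sd`, `n_windows`).
#' @export
node_index_summation <- function(seqs, conditions = NULL) {
  seqs <- as.matrix(seqs)
  if (is.null(conditions)) {
    w <- attr(seqs, "windows")
    conditions <- if (!is.null(w)) w$condition else rep("unlabeled", nrow(seqs))
  }
  stopifnot(length(conditions) == nrow(seqs))
  per_window <- data.frame(window = seq_len(nrow(seqs)),
                           condition = conditions,
                           index_sum = rowSums(seqs))
  agg <- lapply(split(per_window$index_sum, per_window$condition), function(v)
    c(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
      n_windows = length(v)))
  per_condition <- data.frame(condition = names(agg),
                              do.call(rbind, agg), row.names = NULL)
  list(per_window = per_window, per_condition = per_condition)
}
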