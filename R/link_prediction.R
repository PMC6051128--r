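#' Common-neighbour similarity indices
#'
#' Node-pair similarity scores on a simple undirected graph, all built
#' from the common-neighbour set `N(x) intersect N(y)` and the node
#' degrees `k`:
#' \describe{
#'   \item{CN}{`|N(x) intersect N(y)|` -- the raw count.}
#'   \item{RA (resource allocation)}{`sum_z 1/k(z)` over common
#'     neighbours: each shared neighbour forwards a unit of resource split
#'     equally among its links.}
#'   \item{AA (Adamic-Adar)}{`sum_z 1/ln k(z)` -- like RA but with a
#'     logarithmic degree penalty (natural logarithm).}
#'   \item{Sorenson}{`2 |N(x) intersect N(y)| / (k(x) + k(y))` -- the
#'     count normalized by the endpoint degree sum, in `[0, 1]`.}
#' }
#' Every common neighbour of a pair on a simple graph touches both
#' endpoints and so has degree at least 2, keeping RA and AA finite.
#'
#' @param g an [igraph::graph], simple and undirected.
#' @param x,y distinct vertex names or ids.
#' @return a single numeric score (integer-valued for `common_neighbors`).
#' @export
#' @examples
#' g <- make_toy_network()
#' common_neighbors(g, 2, 5)   # 2
#' resource_allocation(g, 2, 5) # 1
#' adamic_adar(g, 2, 5)        # 2.8854
#' sorenson(g, 2, 5)           # 2/3
common_neighbors <- function(g, x, y) {
  length(common_nbr_set(g, x, y))
}

#' @rdname common_neighbors
#' @export
resource_allocation <- function(g, x, y) {
  z <- common_nbr_set(g, x, y)
  if (!length(z)) return(0)
  sum(1 / igraph::degree(g, z))
}

#' @rdname common_neighbors
#' @export
adamic_adar <- function(g, x, y) {
  z <- common_nbr_set(g, x, y)
  if (!length(z)) return(0)
  kz <- igraph::degree(g, z)
  if (any(kz < 2)) stop("common neighbour with degree < 2: graph is not simple")
  sum(1 / log(kz))
}

#' @rdname common_neighbors
#' @export
sorenson <- function(g, x, y) {
  ks <- igraph::degree(g, c(as.character(x), as.character(y)))
  if (sum(ks) == 0) {
    out <- 0
    attr(out, "undefined") <- TRUE
    return(out)
  }
  2 * common_neighbors(g, x, y) / sum(ks)
}

common_nbr_set <- function(g, x, y) {
  x <- as.character(x); y <- as.character(y)
  if (identical(x, y)) stop_config("x and y must be distinct nodes")
  nx <- igraph::neighbors(g, x)$name
  ny <- igraph::neighbors(g, y)$name
  intersect(nx, ny)
}

#' Full similarity matrix for one index
#'
#' Scores every unordered node pair of the graph under one of the four
#' indices, by dense adjacency algebra. The result is symmetric and
#' nonnegative with a zero diagonal (self-similarity is excluded).
#'
#' @param g an [igraph::graph], simple and undirected. When scoring a
#'   train/probe split, pass the train graph (see [train_graph()]).
#' @param index one of `"CN"`, `"RA"`, `"AA"`, `"Sorenson"`.
#' @return N x N numeric matrix with dimnames = vertex names, class
#'   `similarity_matrix`, attribute `index`.
#' @export
similarity_matrix <- function(g, index = c("CN", "RA", "AA", "Sorenson")) {
  index <- match.arg(index)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A <- (A != 0) * 1
  k <- rowSums(A)
  S <- switch(index,
    CN = A %*% A,
    RA = {
      inv <- ifelse(k >= 2, 1 / k, 0)  # degree<2 nodes are never common nbrs
      A %*% (A * inv)
    },
    AA = {
      inv <- ifelse(k >= 2, 1 / log(k), 0)
      A %*% (A * inv)
    },
    Sorenson = {
      cn <- A %*% A
      ksum <- outer(k, k, "+")
      out <- ifelse(ksum > 0, 2 * cn / ksum, 0)
      out
    })
  diag(S) <- 0
  dimnames(S) <- list(igraph::V(g)$name, igraph::V(g)$name)
  structure(S, index = index, class = c("similarity_matrix", "matrix", "array"))
}

#' Weighted resource-allocation variant
#'
#' Generalizes the resource-allocation index to a weighted adjacency:
#' `S_xy = sum_z w_xz w_zy / strength(z)`, with `strength(z) = sum_j w_zj`.
#' The four standard indices are defined on neighbour sets and degrees, so
#' weighted networks are normally binarized first; this variant is the
#' opt-in alternative that uses the weights directly.
#'
#' @param adjacency symmetric nonnegative weight matrix, zero diagonal.
#' @return N x N symmetric score matrix, zero diagonal, class
#'   `similarity_matrix`.
#' @export
weighted_resource_allocation <- function(adjacency) {
  w <- unname(as.matrix(adjacency))
  stopifnot(isSymmetric(w), all(w >= 0), all(diag(w) == 0))
  s <- rowSums(w)
  inv <- ifelse(s > 0, 1 / s, 0)
  S <- w %*% (w * inv)
  diag(S) <- 0
  structure(S, index = "RA_weighted",
            class = c("similarity_matrix", "matrix", "array"))
}

#' Randomized train/probe edge split
#'
#' Partitions the edge set uniformly at random into a train set holding
#' `round(train_ratio * |E|)` edges and a probe (test) set holding the
#' rest. Scores must then be computed on the train graph only.
#'
#' @param g an [igraph::graph] with at least 2 edges.
#' @param train_ratio fraction of edges in the train set, in (0, 1);
#'   ratios above 0.95 are rejected (the protocol caps the train share at
#'   95 percent).
#' @param seed integer seed, or NULL to draw from the current stream.
#' @return list with integer edge-id vectors `train`, `probe`, plus
#'   `train_ratio`; class `edge_split`.
#' @export
split_edges <- function(g, train_ratio, seed = NULL) {
  m <- igraph::ecount(g)
  if (m < 2) stop_config("graph needs >= 2 edges to split")
  if (!(train_ratio > 0 && train_ratio < 1))
    stop_config("train_ratio must lie in (0, 1)")
  if (train_ratio > 0.95)
    stop_config("train_ratio must not exceed 0.95")
  maybe_set_seed(seed)
  n_train <- round(train_ratio * m)
  n_train <- min(max(n_train, 1L), m - 1L)  # keep both sets nonempty
  train <- sort(sample.int(m, n_train))
  structure(list(train = train, probe = setdiff(seq_len(m), train),
                 train_ratio = train_ratio),
            class = "edge_split")
}

#' @rdname split_edges
#' @param split an `edge_split`.
#' @return `train_graph`: the graph restricted to the train edges (same
#'   vertex set).
#' @export
train_graph <- function(g, split) {
  igraph::subgraph_from_edges(g, split$train, delete.vertices = FALSE)
}

#' Sampled AUC of a similarity index under an edge split
#'
#' Draws `n_comparisons` random (probe edge, non-edge) pairs, scores both
#' ends with the index computed on the train graph only, and returns
#' `(n' + 0.5 n'') / n` where `n'` counts comparisons in which the probe
#' edge scores strictly higher and `n''` counts exact ties. Non-edges are
#' node pairs absent from the full edge set (train and probe alike).
#'
#' @param g the full graph.
#' @param split an [split_edges()] result on `g`.
#' @param index index name, or a function `(train_graph) -> N x N score
#'   matrix` for custom scorers.
#' @param n_comparisons number of sampled comparisons; default
#'   `min(10000, n_probe * n_nonedge)`.
#' @param seed integer seed, or NULL.
#' @return numeric AUC in `[0, 1]`, with attribute `n` (comparisons used).
#' @export
auc_score <- function(g, split, index, n_comparisons = NULL, seed = NULL) {
  maybe_set_seed(seed)
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) != 0
  nonedge_idx <- which(upper.tri(A) & !A)
  if (!length(nonedge_idx))
    stop_config("graph is complete: no non-edges to compare against")
  if (!length(split$probe)) stop_config("probe set is empty")
  gt <- train_graph(g, split)
  S <- if (is.function(index)) index(gt) else similarity_matrix(gt, index)
  el <- igraph::as_edgelist(g, names = FALSE)[split$probe, , drop = FALSE]
  probe_idx <- (pmax(el[, 1], el[, 2]) - 1) * n + pmin(el[, 1], el[, 2])
  probe_scores <- S[probe_idx]
  nonedge_scores <- S[nonedge_idx]
  if (is.null(n_comparisons))
    n_comparisons <- min(10000L, length(probe_scores) * length(nonedge_scores))
  sp <- probe_scores[sample.int(length(probe_scores), n_comparisons, replace = TRUE)]
  sn <- nonedge_scores[sample.int(length(nonedge_scores), n_comparisons, replace = TRUE)]
  auc <- (sum(sp > sn) + 0.5 * sum(sp == sn)) / n_comparisons
  attr(auc, "n") <- n_comparisons
  auc
}

#' Benchmark similarity indices by repeated sampled AUC
#'
#' For every (graph, train ratio) cell, draws `n_repetitions` fresh edge
#' splits from a deterministic per-repetition seed stream and scores each
#' index on the same splits (paired comparison). Results for repetition
#' `r` do not depend on the total number of repetitions.
#'
#' @param graphs named list of [igraph::graph]s.
#' @param indices character vector of index names.
#' @param ratios train ratios to sweep.
#' @param n_repetitions splits per cell (default 100).
#' @param n_comparisons per-repetition AUC comparisons (NULL = default
#'   rule of [auc_score()]).
#' @param seed master integer seed.
#' @return data.frame with columns `network`, `index`, `train_ratio`,
#'   `mean_auc`, `sd_auc`, `n_reps`, `seed`.
#' @export
benchmark <- function(graphs, indices = c("CN", "RA", "AA", "Sorenson"),
                      ratios = seq(0.70, 0.95, by = 0.05),
                      n_repetitions = 100, n_comparisons = NULL, seed = 1) {
  if (is.null(names(graphs)))
    names(graphs) <- paste0("graph", seq_along(graphs))
  rows <- list()
  for (gname in names(graphs)) {
    g <- graphs[[gname]]
    for (ratio in ratios) {
      aucs <- matrix(NA_real_, n_repetitions, length(indices),
                     dimnames = list(NULL, indices))
      for (r in seq_len(n_repetitions)) {
        set.seed((seed + 7919L * r) %% .Machine$integer.max)
        sp <- split_edges(g, ratio)
        for (idx in indices)
          aucs[r, idx] <- auc_score(g, sp, idx, n_comparisons)
      }
      for (idx in indices)
        rows[[length(rows) + 1L]] <- data.frame(
          network = gname, index = idx, train_ratio = ratio,
          mean_auc = mean(aucs[, idx]), sd_auc = sd(aucs[, idx]),
          n_reps = n_repetitions, seed = seed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
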