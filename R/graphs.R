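#' The six-node worked-example network
#'
#' Builds the small undirected graph used for the worked examples of the
#' common-neighbour similarity indices: nodes 1..6 with edge set
#' (1,2), (1,5), (2,4), (4,5), (2,3), (2,6). On this graph nodes 2 and 5
#' share the two common neighbours {1, 4}, node 2 has degree 4, and node 2
#' is the single common neighbour of the pair (3, 6) -- the configuration
#' that yields CN(2,5) = 2, RA(2,5) = 1, RA(3,6) = 1/4, AA(2,5) = 2.8854
#' and Sorenson(2,5) = 2/3.
#'
#' @return an [igraph::graph] with 6 vertices named "1".."6".
#' @export
#' @examples
#' g <- make_toy_network()
#' igraph::degree(g)
make_toy_network <- function() {
  el <- matrix(c(1, 2, 1, 5, 2, 4, 4, 5, 2, 3, 2, 6),
               ncol = 2, byrow = TRUE)
  g <- igraph::graph_from_edgelist(apply(el, 2, as.character), directed = FALSE)
  igraph::permute(g, match(igraph::V(g)$name, as.character(1:6)))
}

#' Seeded random benchmark graphs
#'
#' Connected simple undirected graphs for link-prediction benchmarking:
#' Barabasi-Albert preferential attachment (`scale_free`), Watts-Strogatz
#' rewired ring (`small_world`, rewiring probability `p_rewire`), or a
#' uniform random graph with fixed edge count (`erdos_renyi`). The realized
#' mean degree must land within 20% of `target_mean_degree`, otherwise the
#' request is rejected as unreachable for that model. Generation retries
#' (up to 100 draws from the seeded stream) until the graph is connected.
#'
#' @param model one of `"scale_free"`, `"small_world"`, `"erdos_renyi"`.
#' @param n_nodes number of vertices (>= 4).
#' @param target_mean_degree desired mean degree (at most `n_nodes - 1`,
#'   the complete graph).
#' @param seed integer RNG seed, or NULL to use the current stream.
#' @param p_rewire Watts-Strogatz rewiring probability.
#' @return a connected [igraph::graph] with vertices named "1".."n_nodes".
#' @export
generate_random_graph <- function(model = c("scale_free", "small_world", "erdos_renyi"),
                                  n_nodes, target_mean_degree, seed = NULL,
                                  p_rewire = 0.1) {
  model <- match.arg(model)
  if (n_nodes < 4) stop_config("n_nodes must be >= 4")
  if (target_mean_degree > n_nodes - 1)
    stop_config("target_mean_degree must be <= n_nodes - 1 (complete graph)")
  if (target_mean_degree <= 0) stop_config("target_mean_degree must be positive")
  maybe_set_seed(seed)

  draw <- switch(model,
    scale_free = {
      m <- max(1L, round(target_mean_degree / 2))
      function() igraph::sample_pa(n_nodes, m = m, directed = FALSE)
    },
    small_world = {
      nei <- round(target_mean_degree / 2)
      if (nei < 1 || abs(2 * nei - target_mean_degree) / target_mean_degree > 0.2)
        stop_config("small_world cannot realize mean degree %g on a ring lattice",
                    target_mean_degree)
      function() igraph::sample_smallworld(1, n_nodes, nei, p_rewire,
                                           loops = FALSE, multiple = FALSE)
    },
    erdos_renyi = {
      m_edges <- round(n_nodes * target_mean_degree / 2)
      if (m_edges > choose(n_nodes, 2))
        stop_config("erdos_renyi: requested mean degree exceeds the complete graph")
      function() igraph::sample_gnm(n_nodes, m_edges)
    })

  g <- NULL
  for (i in 1:100) {
    cand <- igraph::simplify(draw())
    if (igraph::is_connected(cand)) { g <- cand; break }
  }
  if (is.null(g))
    stop_config("could not draw a connected %s graph in 100 attempts", model)
  realized <- mean(igraph::degree(g))
  if (abs(realized - target_mean_degree) / target_mean_degree > 0.2)
    stop_config("%s: realized mean degree %.2f not within 20%% of target %g",
                model, realized, target_mean_degree)
  igraph::V(g)$name <- as.character(seq_len(n_nodes))
  g
}

#' Edge-list text I/O
#'
#' Graphs are exchanged as whitespace-delimited text with one edge per line:
#' `node_u node_v [weight]`, 1-based node labels. This reader also ingests
#' published benchmark edge lists supplied by the user.
#'
#' @param g an [igraph::graph].
#' @param path file path.
#' @return `read_edgelist_txt` returns an igraph graph (with an edge
#'   attribute `weight` when a third column is present); `write_edgelist_txt`
#'   returns `path` invisibly.
#' @export
write_edgelist_txt <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  df <- data.frame(u = el[, 1], v = el[, 2])
  if ("weight" %in% igraph::edge_attr_names(g))
    df$w <- igraph::E(g)$weight
  write.table(df, path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edgelist_txt
#' @export
read_edgelist_txt <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  g <- igraph::graph_from_edgelist(
    cbind(as.character(df[[1]]), as.character(df[[2]])), directed = FALSE)
  if (ncol(df) >= 3) igraph::E(g)$weight <- as.numeric(df[[3]])
  g
}

# Adjacency (binary, symmetric, zero-diagonal) -> igraph on nodes "1".."N".
# Used to hand connectivity-module networks to the link-prediction module.
graph_from_binary_adjacency <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                           diag = FALSE)
  igraph::V(g)$name <- as.character(seq_len(nrow(adj)))
  g
}
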