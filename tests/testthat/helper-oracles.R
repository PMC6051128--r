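# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: graphs are handled as raw edge-list matrices
# and scores computed by direct set enumeration.

# Neighbour set of `v` in a 2-column edge matrix (character labels).
bf_neighbors <- function(el, v) {
  v <- as.character(v)
  unique(c(el[el[, 1] == v, 2], el[el[, 2] == v, 1]))
}

bf_degree <- function(el, v) length(bf_neighbors(el, v))

# Brute-force similarity index by set enumeration.
bf_index <- function(el, x, y, index) {
  cn <- intersect(bf_neighbors(el, x), bf_neighbors(el, y))
  switch(index,
    CN = length(cn),
    RA = if (!length(cn)) 0 else sum(1 / vapply(cn, function(z) bf_degree(el, z), 0)),
    AA = if (!length(cn)) 0 else sum(1 / log(vapply(cn, function(z) bf_degree(el, z), 0))),
    Sorenson = {
      ks <- bf_degree(el, x) + bf_degree(el, y)
      if (ks == 0) 0 else 2 * length(cn) / ks
    })
}

# Edge matrix (character) of an igraph graph, for feeding the oracles.
edge_matrix <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  matrix(as.character(el), ncol = 2)
}

# Exact rank AUC by full enumeration over probe x non-edge score pairs.
exact_auc <- function(probe_scores, nonedge_scores) {
  gt <- outer(probe_scores, nonedge_scores, ">")
  eq <- outer(probe_scores, nonedge_scores, "==")
  (sum(gt) + 0.5 * sum(eq)) / length(gt)
}

# PLV by a direct elementwise complex-sum loop (window <= 64 samples).
plv_loop <- function(phases) {
  n <- nrow(phases)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    acc <- 0 + 0i
    for (t in seq_len(ncol(phases)))
      acc <- acc + exp(1i * (phases[i, t] - phases[j, t]))
    out[i, j] <- Mod(acc) / ncol(phases)
  }
  out
}

# Probe/non-edge scores of a split under the package's score matrix,
# indexed independently of auc_score()'s internals.
split_scores <- function(g, split, S) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) != 0
  el <- igraph::as_edgelist(g, names = FALSE)[split$probe, , drop = FALSE]
  probe <- vapply(seq_len(nrow(el)), function(r) S[el[r, 1], el[r, 2]], 0)
  ne <- which(upper.tri(A) & !A, arr.ind = TRUE)
  nonedge <- vapply(seq_len(nrow(ne)), function(r) S[ne[r, 1], ne[r, 2]], 0)
  list(probe = probe, nonedge = nonedge)
}

# Short synthetic recording shared by preprocessing tests.
make_test_recording <- function(freqs = c(10), n_s = 4, fs = 256,
                                amp = 50, seizure = NULL) {
  t <- seq(0, n_s - 1 / fs, by = 1 / fs)
  x <- do.call(rbind, lapply(seq_len(3), function(i)
    Reduce(`+`, lapply(freqs, function(f) amp * sin(2 * pi * f * t + i)))))
  eeg_recording(x, fs = fs, seizures = seizure)
}
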