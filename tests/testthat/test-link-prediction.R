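test_that("similarity indices reproduce the worked-example values", {
  g <- make_toy_network()
  expect_identical(common_neighbors(g, 2, 5), 2L)
  expect_equal(resource_allocation(g, 2, 5), 1)
  expect_equal(resource_allocation(g, 3, 6), 0.25)
  expect_equal(adamic_adar(g, 2, 5), 2.8854, tolerance = 1e-4)
  expect_equal(adamic_adar(g, 2, 5), 2 / log(2), tolerance = 1e-12)
  expect_equal(sorenson(g, 2, 5), 2 / 3, ignore_attr = TRUE)
  expect_identical(common_neighbors(g, 1, 3), 1L)   # shared neighbour: node 2
})

test_that("indices handle stars, triangles and disjoint pairs", {
  star <- igraph::make_star(7, mode = "undirected", center = 1)
  igraph::V(star)$name <- as.character(1:7)
  expect_equal(resource_allocation(star, 2, 3), 1 / 6)  # hub degree n-1
  expect_equal(adamic_adar(star, 2, 3), 1 / log(6))

  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- as.character(1:3)
  expect_equal(sorenson(k3, 1, 2), 0.5, ignore_attr = TRUE)

  disjoint <- igraph::make_graph(~ 1 - 2, 3 - 4)
  expect_identical(common_neighbors(disjoint, 1, 3), 0L)
  expect_equal(resource_allocation(disjoint, 1, 3), 0)
  expect_equal(sorenson(disjoint, 1, 3), 0, ignore_attr = TRUE)
})

test_that("similarity matrix agrees with per-pair ops and brute force", {
  set.seed(10)
  for (rep in 1:20) {
    g <- generate_random_graph("erdos_renyi", sample(5:12, 1), 3, seed = rep)
    el <- edge_matrix(g)
    nms <- igraph::V(g)$name
    for (idx in c("CN", "RA", "AA", "Sorenson")) {
      S <- similarity_matrix(g, idx)
      fun <- switch(idx, CN = common_neighbors, RA = resource_allocation,
                    AA = adamic_adar, Sorenson = sorenson)
      for (pair in list(c(1, 2), c(2, 4), c(3, 5))) {
        x <- nms[pair[1]]; y <- nms[pair[2]]
        expect_equal(unname(S[x, y]), as.numeric(fun(g, x, y)),
                     tolerance = 1e-12, ignore_attr = TRUE)
        expect_equal(unname(S[x, y]), bf_index(el, x, y, idx),
                     tolerance = 1e-12)
      }
      expect_true(isSymmetric(unclass(S)))
      expect_true(all(S >= 0))
    }
  }
})

test_that("indices are symmetric, zero without shared neighbours, dominated", {
  set.seed(3)
  for (rep in 1:10) {
    g <- generate_random_graph("scale_free", 15, 4, seed = rep + 50)
    cn <- similarity_matrix(g, "CN")
    ra <- similarity_matrix(g, "RA")
    aa <- similarity_matrix(g, "AA")
    so <- similarity_matrix(g, "Sorenson")
    expect_true(all((cn == 0) == (ra == 0)))
    expect_true(all((cn == 0) == (so == 0)))
    # every common neighbour has degree >= 2, so RA <= CN/2, AA <= CN/ln 2
    expect_true(all(ra <= cn / 2 + 1e-12))
    expect_true(all(aa <= cn / log(2) + 1e-12))
  }
})

test_that("relabeling nodes permutes the similarity matrix consistently", {
  g <- generate_random_graph("erdos_renyi", 8, 3, seed = 1)
  p <- sample(8)
  gp <- igraph::permute(g, p)
  S <- similarity_matrix(g, "RA")
  Sp <- similarity_matrix(gp, "RA")
  # vertex "k" must score identically against vertex "l" in both graphs
  nms <- igraph::V(g)$name
  expect_equal(Sp[nms, nms], S[nms, nms], tolerance = 1e-12)
})

test_that("edge splits partition E with the requested ratio", {
  g <- generate_random_graph("erdos_renyi", 25, 8, seed = 2)
  m <- igraph::ecount(g)
  expect_equal(m, 100)
  sp <- split_edges(g, 0.9, seed = 1)
  expect_length(sp$train, 90)
  expect_length(sp$probe, 10)
  expect_setequal(c(sp$train, sp$probe), seq_len(m))
  sp2 <- split_edges(g, 0.9, seed = 1)
  expect_identical(sp, sp2)
  expect_error(split_edges(g, 0.97), "0.95")
  expect_error(split_edges(g, 0), "0, 1")
})

test_that("probe edges are hidden from the scorer", {
  g <- make_toy_network()
  sp <- split_edges(g, 0.7, seed = 3)
  gt <- train_graph(g, sp)
  expect_equal(igraph::vcount(gt), 6)
  expect_equal(igraph::ecount(gt), length(sp$train))
})

test_that("AUC follows the half-credit tie rule exactly", {
  g <- generate_random_graph("erdos_renyi", 12, 4, seed = 5)
  sp <- split_edges(g, 0.8, seed = 5)
  n <- igraph::vcount(g)
  constant <- function(gt) matrix(1, n, n)
  expect_equal(as.numeric(auc_score(g, sp, constant, 500, seed = 1)), 0.5)

  # an oracle scorer that knows the probe edges earns AUC exactly 1
  el <- igraph::as_edgelist(g, names = FALSE)[sp$probe, , drop = FALSE]
  oracle <- function(gt) {
    S <- matrix(0, n, n)
    S[el] <- 1; S[el[, 2:1]] <- 1
    S
  }
  expect_equal(as.numeric(auc_score(g, sp, oracle, 500, seed = 1)), 1)

  expect_error(
    auc_score(igraph::make_full_graph(5),
              list(train = 1:8, probe = 9:10), "RA"), "complete")
})

test_that("reversing scores maps AUC to its complement", {
  for (s in 1:5) {
    g <- generate_random_graph("scale_free", 20, 4, seed = s)
    sp <- split_edges(g, 0.8, seed = s)
    fwd <- function(gt) similarity_matrix(gt, "RA")
    rev_ <- function(gt) -similarity_matrix(gt, "RA")
    a1 <- as.numeric(auc_score(g, sp, fwd, 2000, seed = 99))
    a2 <- as.numeric(auc_score(g, sp, rev_, 2000, seed = 99))
    expect_equal(a1 + a2, 1, tolerance = 1e-12)
  }
})

test_that("benchmark is deterministic and repetition-stable", {
  g <- generate_random_graph("scale_free", 20, 4, seed = 1)
  b1 <- benchmark(list(g = g), indices = "RA", ratios = 0.9,
                  n_repetitions = 3, seed = 42)
  b2 <- benchmark(list(g = g), indices = "RA", ratios = 0.9,
                  n_repetitions = 3, seed = 42)
  expect_identical(b1, b2)

  # repetition r does not depend on the total repetition count
  one <- benchmark(list(g = g), indices = "RA", ratios = 0.9,
                   n_repetitions = 1, seed = 42)
  expect_equal(one$mean_auc, {
    aucs <- numeric(1)
    set.seed((42 + 7919) %% .Machine$integer.max)
    sp <- split_edges(g, 0.9)
    as.numeric(auc_score(g, sp, "RA"))
  })

  sweep <- benchmark(list(g = g), indices = "RA",
                     ratios = seq(0.7, 0.95, 0.05), n_repetitions = 2, seed = 1)
  expect_equal(nrow(sweep), 6)
})

test_that("weighted RA reduces to plain RA on binary adjacencies", {
  for (s in 1:5) {
    g <- generate_random_graph("erdos_renyi", 10, 4, seed = s)
    A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    # on a 0/1 matrix, strength = degree, so the variants coincide
    expect_equal(unname(unclass(weighted_resource_allocation(A))),
                 unname(unclass(similarity_matrix(g, "RA"))),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # weights reweight the allocation: heavier two-step paths score higher
  w <- matrix(0, 3, 3)
  w[1, 3] <- w[3, 1] <- 0.9
  w[2, 3] <- w[3, 2] <- 0.3
  S <- weighted_resource_allocation(w)
  expect_equal(S[1, 2], 0.9 * 0.3 / 1.2, tolerance = 1e-12)
})
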