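complete_graph <- function(n, w = 1) {
  A <- matrix(w, n, n)
  diag(A) <- 0
  dimnames(A) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  graph_from_adj(A)
}

test_that("density and APL hit their closed forms", {
  g6 <- complete_graph(6)
  expect_equal(graph_density(g6), 1)
  expect_equal(as.numeric(average_path_length(g6)), 1)

  empty <- graph_from_adj(matrix(0, 4, 4,
                                 dimnames = list(paste0("n", 1:4),
                                                 paste0("n", 1:4))))
  expect_equal(graph_density(empty), 0)
  expect_true(is.na(average_path_length(empty)))

  # 3-node path: distances 1, 1, 2
  A <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  A["a", "b"] <- A["b", "a"] <- A["b", "c"] <- A["c", "b"] <- 1
  expect_equal(as.numeric(average_path_length(graph_from_adj(A))), 4 / 3)

  # 28 nodes, 94 edges -> 94 / C(28,2)
  set.seed(14)
  repeat {
    A28 <- random_adjacency(28, p = 94 / 378, weighted = FALSE)
    if (sum(A28[upper.tri(A28)] > 0) == 94) break
  }
  expect_equal(graph_density(graph_from_adj(A28)), 94 / 378)
})

test_that("APL excludes unreachable pairs and reports their fraction", {
  # two disconnected 3-cliques: all finite distances are 1
  A <- matrix(0, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1
  diag(A) <- 0
  apl <- average_path_length(graph_from_adj(A))
  expect_equal(as.numeric(apl), 1)
  expect_equal(attr(apl, "unreachable_frac"), 9 / 15)
  expect_equal(
    as.numeric(average_path_length(graph_from_adj(A),
                                   mode = "largest_component")), 1)
})

test_that("Barrat clustering hits closed forms and brute-force enumeration", {
  # uniform triangle: c_i = 1 for each node
  tri <- complete_graph(3, w = 0.7)
  expect_equal(unname(weighted_clustering(tri)), rep(1, 3))
  # star center has no neighbour-neighbour links
  A <- matrix(0, 5, 5, dimnames = list(paste0("n", 1:5), paste0("n", 1:5)))
  A[1, 2:5] <- A[2:5, 1] <- runif(4, 0.2, 1)
  star <- graph_from_adj(A)
  expect_equal(unname(weighted_clustering(star, "n1")), 0)
  expect_equal(average_clustering(star), 0)

  # random weighted 7-node graphs vs triple enumeration
  set.seed(21)
  for (rep in 1:5) {
    A <- random_adjacency(7, p = 0.5)
    g <- graph_from_adj(A)
    ci <- weighted_clustering(g)
    oracle <- vapply(seq_len(7), function(i) oracle_barrat(A, i), numeric(1))
    expect_equal(unname(ci), oracle, tolerance = 1e-12)
    expect_equal(average_clustering(g), mean(oracle), tolerance = 1e-12)
  }

  # with equal weights the Barrat coefficient reduces to unweighted clustering
  set.seed(22)
  A <- random_adjacency(8, p = 0.5, weighted = FALSE)
  g <- graph_from_adj(A)
  unweighted <- igraph::transitivity(g, type = "local", isolates = "zero")
  expect_equal(unname(weighted_clustering(g)), unname(unweighted),
               tolerance = 1e-12)

  expect_equal(average_clustering(complete_graph(5, 0.4)), 1)
  expect_equal(average_clustering(graph_from_adj(matrix(0, 3, 3,
    dimnames = list(letters[1:3], letters[1:3])))), 0)
})

test_that("modularity matches the direct Q formula", {
  # two disconnected equal cliques with the matching partition: Q = 0.5
  A <- matrix(0, 8, 8, dimnames = list(paste0("n", 1:8), paste0("n", 1:8)))
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  g <- graph_from_adj(A)
  p <- setNames(rep(1:2, each = 4), paste0("n", 1:8))
  expect_equal(modularity_score(g, p), 0.5, tolerance = 1e-12)

  # all nodes in one community: e_11 = 1, a_1 = 1 -> Q = 0
  p1 <- setNames(rep(1, 8), paste0("n", 1:8))
  expect_equal(modularity_score(g, p1), 0, tolerance = 1e-12)

  # random graph + random partition vs direct-formula oracle
  set.seed(31)
  for (rep in 1:5) {
    A <- random_adjacency(9, p = 0.45, weighted = FALSE)
    if (sum(A) == 0) next
    memb <- sample(1:3, 9, replace = TRUE)
    names(memb) <- rownames(A)
    expect_equal(modularity_score(graph_from_adj(A), memb),
                 oracle_modularity(A, memb), tolerance = 1e-12)
  }

  expect_warning(q <- modularity_score(
    graph_from_adj(matrix(0, 3, 3, dimnames = list(letters[1:3],
                                                   letters[1:3]))),
    setNames(1:3, letters[1:3])), "edgeless")
  expect_true(is.na(q))
})

test_that("community detection recovers planted structure", {
  # two disconnected cliques: unambiguous split, NMI = 1
  A <- matrix(0, 8, 8, dimnames = list(paste0("n", 1:8), paste0("n", 1:8)))
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  ref <- setNames(rep(1:2, each = 4), paste0("n", 1:8))
  det <- detect_communities(graph_from_adj(A), reference = ref)
  expect_equal(det$n_communities, 2)
  expect_equal(det$nmi, 1)

  # complete graph: detected Q can be no worse than the anatomical split
  gK <- complete_graph(8)
  ref2 <- setNames(rep(1:2, each = 4), paste0("n", 1:8))
  detK <- detect_communities(gK, reference = ref2)
  expect_gte(detK$Q, modularity_score(gK, ref2) - 1e-9)

  # planted 4-module graphs: dense intra, sparse inter
  set.seed(41)
  nmis <- vapply(1:20, function(rep) {
    n_per <- 5
    A <- matrix(0, 20, 20)
    memb <- rep(1:4, each = n_per)
    for (i in 1:19) for (j in (i + 1):20) {
      p <- if (memb[i] == memb[j]) 0.95 else 0.05
      if (runif(1) < p) A[i, j] <- A[j, i] <- 1
    }
    dimnames(A) <- list(paste0("n", 1:20), paste0("n", 1:20))
    det <- detect_communities(graph_from_adj(A),
                              reference = setNames(memb, rownames(A)))
    det$nmi
  }, numeric(1))
  expect_gte(mean(nmis >= 0.9), 0.9)

  expect_warning(d0 <- detect_communities(graph_from_adj(
    matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])))),
    "edgeless")
  expect_true(d0$degenerate)
  expect_equal(d0$n_communities, 3)
})

test_that("detected partition Q dominates the anatomical Q (exhaustive check)", {
  # on graphs small enough to enumerate all partitions into <= 4 blocks,
  # greedy Q must be within tolerance of the true optimum, and the
  # anatomical Q can never exceed the detected Q
  set.seed(51)
  all_partitions <- function(n, k) {
    grid <- expand.grid(rep(list(seq_len(k)), n))
    as.matrix(grid)
  }
  for (rep in 1:3) {
    A <- random_adjacency(6, p = 0.5, weighted = FALSE)
    if (sum(A) == 0) next
    g <- graph_from_adj(A)
    det <- detect_communities(g)
    parts <- all_partitions(6, 3)
    qs <- apply(parts, 1L, function(m) {
      names(m) <- rownames(A)
      oracle_modularity(A, m)
    })
    q_best <- max(qs)
    expect_lte(det$Q, q_best + 1e-9)
    anat <- setNames(rep(1:2, each = 3), rownames(A))
    expect_lte(modularity_score(g, anat), det$Q + 1e-9)
  }
})

test_that("graph-measure monotonicity under edge addition", {
  set.seed(61)
  A <- random_adjacency(10, p = 0.3, weighted = FALSE)
  g <- graph_from_adj(A)
  missing_pairs <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
  pick <- missing_pairs[sample(nrow(missing_pairs), 1), ]
  A2 <- A
  A2[pick[1], pick[2]] <- A2[pick[2], pick[1]] <- 1
  g2 <- graph_from_adj(A2)
  expect_gt(graph_density(g2), graph_density(g))
  # APL restricted to the pairs reachable in BOTH graphs cannot increase
  d1 <- igraph::distances(g, weights = NA)
  d2 <- igraph::distances(g2, weights = NA)
  both <- is.finite(d1) & is.finite(d2) & upper.tri(d1)
  expect_lte(mean(d2[both]), mean(d1[both]))
})

test_that("density, APL, clustering and Q agree with oracles on random graphs", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    A <- random_adjacency(n, p = runif(1, 0.2, 0.8))
    g <- graph_from_adj(A)
    expect_equal(graph_density(g), oracle_density(A), tolerance = 1e-9)
    expect_equal(as.numeric(average_path_length(g)), oracle_apl(A),
                 tolerance = 1e-9)
    ci <- weighted_clustering(g)
    oracle_ci <- vapply(seq_len(n), function(i) oracle_barrat(A, i),
                        numeric(1))
    expect_equal(unname(ci), oracle_ci, tolerance = 1e-9)
    if (sum(A) > 0) {
      memb <- setNames(sample(1:4, n, replace = TRUE), rownames(A))
      expect_equal(modularity_score(g, memb), oracle_modularity(A, memb),
                   tolerance = 1e-9)
    }
  }
})

test_that("measure_all produces complete traces with expected bookkeeping", {
  gen <- generate_recording(synth_config(seed = 8, duration_s = 150,
                                         onset_s = 75))
  ws <- segment_windows(gen$recording)
  tr <- measure_all(ws)
  expect_s3_class(tr, "tbl_df")
  expect_equal(max(tr$window), 30)
  # Mod only for the global scope
  expect_setequal(unique(tr$scope[tr$measure == "Mod"]), "global")
  # every scope x measure x window combination present
  per <- dplyr::count(tr, .data$scope, .data$measure)
  expect_true(all(per$n == 30))
  expect_equal(nrow(per), 3 * 5 + 1)  # DoL/APL/ACC/SE/excit_count x 3 + Mod
  # bounded measures within range
  expect_true(all(tr$value[tr$measure == "DoL"] >= 0 &
                    tr$value[tr$measure == "DoL"] <= 1))
  expect_true(all(tr$value[tr$measure == "ACC"] >= 0 &
                    tr$value[tr$measure == "ACC"] <= 1 + 1e-12))
  expect_true(all(tr$value[tr$measure == "APL"] >= 1, na.rm = TRUE))
})

test_that("measure_all recovers the generator's coupling orderings", {
  gen <- ictal_fixture(seed = 12)
  ws <- segment_windows(gen$recording)
  tr <- measure_all(ws, measures = "DoL")
  glob <- dplyr::filter(tr, .data$scope == "global")
  expect_gt(mean(glob$value[glob$rel_onset_s >= 0]),
            mean(glob$value[glob$rel_onset_s < 0]))
  # lateralized deficit: ipsilateral (left) below contralateral in both stages
  ml <- dplyr::filter(tr, .data$scope == "mesial_left")
  mr <- dplyr::filter(tr, .data$scope == "mesial_right")
  for (stage in list(c(-Inf, 0), c(0, Inf))) {
    sel <- function(t) t$rel_onset_s >= stage[1] & t$rel_onset_s < stage[2]
    expect_lt(mean(ml$value[sel(ml)]), mean(mr$value[sel(mr)]))
  }
})
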