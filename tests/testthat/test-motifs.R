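test_that("canonical ids match hand-derived values for reference patterns", {
  # 4-node single-input module: the canonical labeling puts the three
  # leaves first, so only the last row (1110) is nonzero -> id 14
  star <- matrix(0L, 4, 4); star[1, 2:4] <- 1L
  expect_equal(canonical_id(star), 14)
  # feed-forward loop (regulator -> middleman -> target, regulator ->
  # target): minimal labeling (target, middleman, regulator) gives rows
  # 000 100 110 -> id 38
  ffl <- matrix(0L, 3, 3); ffl[1, 2] <- ffl[1, 3] <- ffl[2, 3] <- 1L
  expect_equal(canonical_id(ffl), 38)
  # 3-cycle: both labelings of a directed triangle are cycles; the smaller
  # code is rows 001 100 010 -> id 98
  cyc <- matrix(0L, 3, 3); cyc[1, 2] <- cyc[2, 3] <- cyc[3, 1] <- 1L
  expect_equal(canonical_id(cyc), 98)
  # decoding a canonical id reproduces an isomorphic matrix
  expect_equal(canonical_id(decode_motif_id(14, 4)), 14)
  expect_equal(canonical_id(decode_motif_id(38, 3)), 38)
  expect_error(decode_motif_id(2^9, 3), "out of range")
  # ids with a diagonal bit set are rejected (node self-loop)
  expect_error(decode_motif_id(256, 3), "diagonal")
})

test_that("the canonical id is invariant under node relabeling", {
  set.seed(40)
  for (i in 1:100) {
    k <- sample(3:5, 1)
    adj <- matrix(rbinom(k * k, 1, 0.4), k, k); diag(adj) <- 0L
    perm <- sample(k)
    expect_identical(canonical_id(adj), canonical_id(adj[perm, perm]))
  }
})

test_that("canonical ids induce exactly the isomorphism classes of all
           4-node digraphs", {
  # complete check over all 2^12 off-diagonal bit patterns: two graphs get
  # the same id exactly when igraph finds them isomorphic
  off <- which(diag(4) == 0)
  ids <- character(4096)
  canon <- character(4096)
  for (code in 0:4095) {
    adj <- matrix(0L, 4, 4)
    adj[off] <- as.integer(intToBits(code)[1:12])
    ids[code + 1] <- format(canonical_id(adj), scientific = FALSE)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
    cp <- igraph::canonical_permutation(g)$labeling
    cg <- igraph::permute(g, cp)
    canon[code + 1] <- paste(t(as.matrix(
      igraph::as_adjacency_matrix(cg))), collapse = "")
  }
  # same partition: the two labelings agree on every pair via a bijection
  expect_equal(length(unique(ids)), length(unique(canon)))
  expect_true(all(tapply(canon, ids, function(v) length(unique(v)) == 1)))
})

test_that("exact enumeration matches a brute-force census on random graphs", {
  for (seed in c(1, 2, 3)) {
    g <- random_digraph(n = 11, p = 0.18, seed = seed)
    for (k in c(3, 4)) {
      got <- enumerate_subgraphs(g, k)
      want <- brute_census(g, k)
      expect_equal(got$motif_id, want$motif_id)
      expect_equal(got$count, want$count)
    }
  }
  # two disjoint 3-cycles pool into one class with count 2
  cyc2 <- igraph::make_graph(c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4),
                             directed = TRUE)
  cen <- enumerate_subgraphs(cyc2, 3)
  expect_equal(cen$motif_id, 98)
  expect_equal(cen$count, 2)
  expect_equal(nrow(enumerate_subgraphs(igraph::make_graph(c(1, 2),
                                                           directed = TRUE),
                                        3)), 0)
})

test_that("sampled concentrations converge to the exact census shares", {
  g <- random_digraph(n = 30, p = 0.12, seed = 9)
  exact <- enumerate_subgraphs(g, 3)
  conc <- exact$count / sum(exact$count)
  est <- sample_subgraphs(g, 3, n_samples = 20000, seed = 5)
  expect_equal(sum(est$concentration), 1, tolerance = 1e-12)
  hit <- match(est$motif_id, exact$motif_id)
  expect_false(anyNA(hit))
  big <- conc >= 0.05
  m <- match(exact$motif_id[big], est$motif_id)
  expect_lt(max(abs(est$concentration[m] - conc[big])), 0.05)
  # deterministic under a seed
  est2 <- sample_subgraphs(g, 3, n_samples = 500, seed = 77)
  est3 <- sample_subgraphs(g, 3, n_samples = 500, seed = 77)
  expect_identical(est2, est3)
})

test_that("randomization preserves every in- and out-degree and moves the
           edge set", {
  g <- random_digraph(n = 40, p = 0.08, seed = 13)
  r <- randomize_graph(g, switches_per_edge = 5, seed = 3)
  expect_equal(igraph::degree(r, mode = "in"),
               igraph::degree(g, mode = "in"))
  expect_equal(igraph::degree(r, mode = "out"),
               igraph::degree(g, mode = "out"))
  expect_equal(igraph::ecount(r), igraph::ecount(g))
  eid <- function(x) paste(igraph::as_edgelist(x)[, 1],
                           igraph::as_edgelist(x)[, 2])
  expect_lt(length(intersect(eid(g), eid(r))), igraph::ecount(g))
  expect_false(any(igraph::which_loop(r)))
  expect_false(any(igraph::which_multiple(r)))
  # graphs too small to switch are returned unchanged
  tiny <- igraph::make_graph(c(1, 2), directed = TRUE)
  expect_equal(eid(randomize_graph(tiny, seed = 1)), eid(tiny))
})

test_that("planted bi-fans are reported significant and sparse patterns are
           filtered by the minimum count", {
  g <- planted_bifan_graph(copies = 25, extra_edges = 15, seed = 8)
  ms <- motif_significance(g, 4, n_random = 100, seed = 2)
  bif <- ms[ms$motif_id == canonical_id(bifan_adj()), ]
  expect_equal(nrow(bif), 1)
  expect_gte(bif$count, 25)
  expect_true(bif$significant)
  expect_gte(bif$z, 2)
  expect_lte(bif$p, 0.05)
  # p is floored by the add-one estimator
  expect_gte(min(ms$p), 1 / 101)
  # a motif observed fewer than min_count times is never significant
  strict <- motif_significance(g, 4, n_random = 50, seed = 2,
                               min_count = 1e9)
  expect_false(any(strict$significant))
})

test_that("motif composition glues two 4-node motifs on a shared pair", {
  star4 <- matrix(0L, 4, 4); star4[1, 2:4] <- 1L
  id4 <- canonical_id(star4)
  comps <- compose_motifs(id4, id4)
  expect_gt(length(comps), 0)
  for (key in names(comps)) {
    adj <- comps[[key]]
    expect_equal(dim(adj), c(6, 6))
    expect_equal(format(canonical_id(adj), scientific = FALSE), key)
    gu <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
    expect_true(igraph::is_connected(gu, mode = "weak"))
  }
  # the double star (two hubs sharing two leaves) is among the compositions
  dbl <- matrix(0L, 6, 6)
  dbl[1, c(2, 3, 4)] <- 1L   # hub 1 -> leaves 2, 3, 4
  dbl[5, c(2, 3, 6)] <- 1L   # hub 5 -> shared leaves 2, 3 and own leaf 6
  expect_true(format(canonical_id(dbl), scientific = FALSE) %in%
                names(comps))
  # composing with the empty motif yields nothing connected
  expect_error(compose_motifs(id4, id4, k = 5), "k = 6")
  expect_length(compose_motifs(0, 0), 0)
})
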