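# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# naive double-centered distance correlation, written with explicit loops
naive_dcor <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    a[i, j] <- abs(x[i] - x[j])
    b[i, j] <- abs(y[i] - y[j])
  }
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  vxy <- 0; vx <- 0; vy <- 0
  for (i in 1:n) for (j in 1:n) {
    vxy <- vxy + A[i, j] * B[i, j]
    vx <- vx + A[i, j]^2
    vy <- vy + B[i, j]^2
  }
  sqrt((vxy / n^2) / sqrt((vx / n^2) * (vy / n^2)))
}

# exhaustive triple join over all (miRNA, TF, gene) combinations
brute_loops <- function(mirna_targets, tf_targets) {
  m2t <- mirna_targets[mirna_targets$target_kind == "TF", ]
  m2g <- mirna_targets[mirna_targets$target_kind == "gene", ]
  mis <- unique(m2t$regulator_id)
  tfs <- unique(c(m2t$target_id, tf_targets$regulator_id))
  gs <- unique(c(m2g$target_id, tf_targets$target_id))
  out <- list()
  for (mi in mis) for (tf in tfs) for (g in gs) {
    if (any(m2t$regulator_id == mi & m2t$target_id == tf) &&
        any(m2g$regulator_id == mi & m2g$target_id == g) &&
        any(tf_targets$regulator_id == tf & tf_targets$target_id == g) &&
        mi != tf && mi != g && tf != g)
      out[[length(out) + 1]] <- data.frame(mirna_id = mi, tf_id = tf,
                                           gene_id = g,
                                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(mirna_id = character(0), tf_id = character(0),
                      gene_id = character(0)))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$mirna_id, res$tf_id, res$gene_id), ]
  rownames(res) <- NULL
  res
}

# brute-force census of connected induced k-subgraphs over all C(n, k)
# subsets; classes keyed by canonical_id (whose correctness is established
# separately against igraph isomorphism)
brute_census <- function(g, k) {
  n <- igraph::vcount(g)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  storage.mode(adj) <- "integer"
  und <- (adj + t(adj)) > 0
  tally <- list()
  for (sub in utils::combn(n, k, simplify = FALSE)) {
    a <- adj[sub, sub]
    # weak connectivity check by reachability on the undirected version
    u <- und[sub, sub]
    seen <- c(TRUE, rep(FALSE, k - 1))
    repeat {
      reach <- seen | (colSums(u[seen, , drop = FALSE]) > 0)
      if (all(reach == seen)) break
      seen <- reach
    }
    if (!all(seen)) next
    id <- format(canonical_id(a), scientific = FALSE)
    tally[[id]] <- (if (is.null(tally[[id]])) 0 else tally[[id]]) + 1
  }
  if (!length(tally))
    return(data.frame(motif_id = numeric(0), count = numeric(0)))
  out <- data.frame(motif_id = as.numeric(names(tally)),
                    count = as.numeric(unlist(tally)))
  out <- out[order(out$motif_id), ]
  rownames(out) <- NULL
  out
}

# noiseless-in-outcome triad whose mediator disturbance is exactly
# orthogonal to the treatment, so OLS recovers a, b, c' without error
make_exact_triad <- function(n = 20, a = 2, b = 3, c_prime = 1,
                             beta2 = 0.5, beta3 = -0.25) {
  x <- seq(-2, 2, length.out = n)
  e <- stats::rnorm(n)
  e2 <- stats::lm.fit(cbind(1, x), e)$residuals   # orthogonal to (1, x)
  m <- beta2 + a * x + e2
  y <- beta3 + c_prime * x + b * m
  data.frame(x = x, m = m, y = y)
}

# random directed simple graph on n nodes
random_digraph <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  adj <- matrix(stats::runif(n * n) < p, n, n)
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj * 1, mode = "directed")
}

# graph made of `copies` disjoint bi-fans (2 sources -> same 2 targets)
# plus a few random cross edges
planted_bifan_graph <- function(copies = 30, extra_edges = 20,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  edges <- NULL
  for (i in seq_len(copies)) {
    o <- (i - 1) * 4
    edges <- rbind(edges, cbind(o + c(1, 1, 2, 2), o + c(3, 4, 3, 4)))
  }
  n <- copies * 4
  have <- paste(edges[, 1], edges[, 2])
  added <- 0
  while (added < extra_edges) {
    e <- sample.int(n, 2)
    key <- paste(e[1], e[2])
    if (key %in% have) next
    edges <- rbind(edges, e)
    have <- c(have, key)
    added <- added + 1
  }
  igraph::make_graph(t(edges), n = n, directed = TRUE)
}

bifan_adj <- function() {
  adj <- matrix(0L, 4, 4)
  adj[1, 3] <- adj[1, 4] <- adj[2, 3] <- adj[2, 4] <- 1L
  adj
}
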