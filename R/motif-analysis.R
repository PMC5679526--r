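graph_edge_index <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  list(from = as.integer(el[, 1]), to = as.integer(el[, 2]),
       n = igraph::vcount(g))
}

#' Canonical integer id of a directed k-node subgraph
#'
#' The id is the minimum, over all k! node relabelings, of the integer whose
#' k^2-bit binary representation is the row-major concatenation of the
#' adjacency matrix (first row most significant).  This is the id scheme
#' used by FANMOD-style motif reports; e.g. the 4-node single-input module
#' (one regulator targeting the other three nodes) has id 14.
#'
#' @param adjacency k x k binary matrix with zero diagonal (k <= 7).
#' @return the canonical id as a numeric scalar (exact up to 2^49).
#' @export
canonical_id <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  cpp_canonical_id(adjacency)
}

#' Decode a motif id back into an adjacency matrix
#'
#' Row-major bit unpacking, the inverse of [canonical_id()] for canonical
#' ids.
#'
#' @param motif_id non-negative integer-valued id, < 2^(k^2).
#' @param k subgraph size.
#' @return k x k binary adjacency matrix.
#' @export
decode_motif_id <- function(motif_id, k) {
  if (motif_id < 0 || motif_id >= 2^(k * k)) stop("motif_id out of range")
  adj <- matrix(0L, k, k)
  for (r in seq_len(k)) for (c in seq_len(k)) {
    p <- k * k - 1 - (k * (r - 1) + (c - 1))
    adj[r, c] <- as.integer((motif_id %/% 2^p) %% 2)
  }
  if (any(diag(adj) != 0))
    stop("not a simple-graph id: diagonal bit set")
  adj
}

#' Exact census of connected induced k-node subgraphs
#'
#' Enumerates every connected (ignoring edge direction) induced k-node
#' subgraph exactly once with the ESU algorithm and pools counts by
#' canonical motif id.
#'
#' @param g a directed igraph graph.
#' @param k subgraph size (3, 4 or 5).
#' @return data.frame with columns `motif_id` and `count`, sorted by id;
#'   zero rows when the graph has fewer than k nodes.
#' @export
enumerate_subgraphs <- function(g, k) {
  if (!k %in% 3:5) stop("k must be 3, 4 or 5")
  if (igraph::vcount(g) < k)
    return(data.frame(motif_id = numeric(0), count = numeric(0)))
  ei <- graph_edge_index(g)
  cpp_enumerate(ei$from, ei$to, ei$n, as.integer(k))
}

#' Estimate motif concentrations by sampling the enumeration tree
#'
#' Draws `n_samples` random root-to-leaf descents of the ESU enumeration
#' tree; each completed leaf (one connected k-subgraph) is weighted by the
#' inverse of its sampling probability, so the weighted concentrations
#' converge to the exact ones as `n_samples` grows.
#'
#' @param g a directed igraph graph.
#' @param k subgraph size (>= 3).
#' @param n_samples number of descents.
#' @param seed optional integer seed.
#' @return data.frame with columns `motif_id` and `concentration`
#'   (concentrations sum to 1).
#' @export
sample_subgraphs <- function(g, k, n_samples, seed = NULL) {
  if (k < 3) stop("k must be >= 3")
  if (n_samples <= 0) stop("n_samples must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ei <- graph_edge_index(g)
  df <- cpp_sample(ei$from, ei$to, ei$n, as.integer(k),
                   as.integer(n_samples))
  if (!nrow(df))
    return(data.frame(motif_id = numeric(0), concentration = numeric(0)))
  data.frame(motif_id = df$motif_id,
             concentration = df$count / sum(df$count))
}

#' Degree-preserving randomization of a directed graph
#'
#' Applies repeated two-edge switches (u->v, x->y) => (u->y, x->v),
#' rejecting switches that would create self-loops or parallel edges, so
#' both the in- and out-degree of every node are preserved exactly.  Node
#' attributes are untouched.
#'
#' @param g a directed igraph graph.
#' @param switches_per_edge switch attempts per edge (default 3).
#' @param seed optional integer seed.
#' @return the randomized graph.
#' @export
randomize_graph <- function(g, switches_per_edge = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  ne <- igraph::ecount(g)
  if (ne < 2) return(g)
  igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                           niter = switches_per_edge * ne))
}

#' Motif significance against a degree-preserving null ensemble
#'
#' Counts k-node subgraph classes exactly, builds a null ensemble of
#' `n_random` degree-preserving randomizations, and flags a motif
#' significant when z >= `z_min`, p <= `p_max` and its observed count is at
#' least `min_count` (the FANMOD-style thresholds z >= 2, p <= 0.05,
#' frequency >= 5).  p uses the add-one estimator
#' (1 + #{null >= observed}) / (1 + n_random); a zero null standard
#' deviation leaves z undefined and the motif non-significant.
#'
#' @param g a directed igraph graph.
#' @param k subgraph size (3, 4 or 5).
#' @param n_random null-ensemble size (default 1000).
#' @param seed optional integer seed.
#' @param z_min,p_max,min_count significance thresholds.
#' @param switches_per_edge switch attempts per edge for each null graph.
#' @return data.frame with one row per motif id: `motif_id`, `k`, `count`,
#'   `concentration`, `null_mean`, `null_sd`, `z`, `p`, `significant`.
#' @export
motif_significance <- function(g, k, n_random = 1000, seed = NULL,
                               z_min = 2, p_max = 0.05, min_count = 5,
                               switches_per_edge = 3) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  real <- enumerate_subgraphs(g, k)
  null_counts <- matrix(0, n_random, nrow(real))
  extra <- list()
  for (i in seq_len(n_random)) {
    rg <- randomize_graph(g, switches_per_edge)
    nc <- enumerate_subgraphs(rg, k)
    hit <- match(real$motif_id, nc$motif_id)
    null_counts[i, ] <- ifelse(is.na(hit), 0, nc$count[hit])
    novel <- setdiff(nc$motif_id, real$motif_id)
    for (id in novel) {
      key <- format(id, scientific = FALSE)
      if (is.null(extra[[key]])) extra[[key]] <- numeric(n_random)
      extra[[key]][i] <- nc$count[nc$motif_id == id]
    }
  }
  ids <- real$motif_id
  counts <- real$count
  nulls <- null_counts
  if (length(extra)) {
    ids <- c(ids, as.numeric(names(extra)))
    counts <- c(counts, rep(0, length(extra)))
    nulls <- cbind(nulls, do.call(cbind, extra))
  }
  null_mean <- colMeans(nulls)
  null_sd <- apply(nulls, 2, stats::sd)
  z <- ifelse(null_sd > 0, (counts - null_mean) / null_sd, NA_real_)
  p <- vapply(seq_along(ids), function(j)
    (1 + sum(nulls[, j] >= counts[j])) / (1 + n_random), numeric(1))
  sig <- !is.na(z) & z >= z_min & p <= p_max & counts >= min_count
  if (any(is.na(z)))
    message(sum(is.na(z)), " motif(s) with zero null sd: z undefined, ",
            "treated as not significant")
  out <- data.frame(motif_id = ids, k = k, count = counts,
                    concentration = counts / max(sum(counts), 1),
                    null_mean = null_mean, null_sd = null_sd,
                    z = z, p = p, significant = sig)
  out <- out[order(out$motif_id), ]
  rownames(out) <- NULL
  out
}

#' Compose two 4-node motifs into candidate 6-node motifs
#'
#' Overlaps the two motifs on exactly two shared nodes (4 + 4 - 2 = 6), in
#' every way in which the edges between the shared pair agree in both
#' motifs, and returns the non-isomorphic weakly connected results.
#'
#' @param m1,m2 canonical 4-node motif ids.
#' @param k output size; must be 6.
#' @return named list of 6 x 6 adjacency matrices, names = canonical ids;
#'   empty when no consistent overlap exists.
#' @export
compose_motifs <- function(m1, m2, k = 6) {
  if (k != 6) stop("composition of two 4-node motifs yields k = 6")
  A <- decode_motif_id(m1, 4)
  B <- decode_motif_id(m2, 4)
  out <- list()
  seen <- character(0)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    for (p in 1:4) for (q in 1:4) {
      if (p == q) next
      # identify A's (i, j) with B's (p, q); edges inside the shared pair
      # must agree
      if (A[i, j] != B[p, q] || A[j, i] != B[q, p]) next
      mapB <- integer(4)
      mapB[p] <- i; mapB[q] <- j
      restB <- setdiff(1:4, c(p, q))
      mapB[restB] <- c(5, 6)
      adj <- matrix(0L, 6, 6)
      adj[1:4, 1:4] <- A
      for (r in 1:4) for (s in 1:4)
        if (B[r, s] == 1) adj[mapB[r], mapB[s]] <- 1L
      gu <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
      if (!igraph::is_connected(gu, mode = "weak")) next
      id <- canonical_id(adj)
      key <- format(id, scientific = FALSE)
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[key]] <- decode_motif_id(id, 6)
    }
  }
  out
}
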