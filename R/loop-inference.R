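#' De-duplicate a regulator->target table
#'
#' Rows for the same (regulator, target) pair coming from different source
#' databases are merged: sources are concatenated and the best (lowest,
#' mirSVR-like) score is kept.  Self-regulation rows are dropped.
#'
#' @param table data.frame with columns `regulator_id`, `target_id` and
#'   optionally `regulator_kind`, `target_kind`, `source`, `score`.
#' @return the de-duplicated table.
#' @export
dedupe_targets <- function(table) {
  table <- table[table$regulator_id != table$target_id, , drop = FALSE]
  if (!nrow(table)) return(table)
  key <- paste(table$regulator_id, table$target_id, sep = "\r")
  if (!anyDuplicated(key)) return(table)
  sp <- split(seq_len(nrow(table)), key)
  rows <- lapply(sp, function(idx) {
    r <- table[idx[1], , drop = FALSE]
    if ("source" %in% names(table))
      r$source <- paste(unique(table$source[idx]), collapse = ";")
    if ("score" %in% names(table)) {
      s <- table$score[idx]
      r$score <- if (all(is.na(s))) NA_real_ else min(s, na.rm = TRUE)
    }
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Infer closed miRNA -> TF -> gene regulatory loops
#'
#' A closed loop is an ordered triad (miRNA, TF, gene) such that the miRNA
#' targets both the TF and the gene and the TF targets the same gene.  The
#' result is exactly the triple join of the two target tables restricted to
#' the supplied entity universes.
#'
#' @param mirna_targets data.frame of miRNA->TF and miRNA->gene rows
#'   (columns `regulator_id`, `target_id`, `target_kind` in
#'   `c("TF","gene")`).
#' @param tf_targets data.frame of TF->gene rows.
#' @param universe optional list with character vectors `mirna`, `tf`,
#'   `gene` restricting the triads (e.g. to differentially expressed
#'   entities); `NULL` leaves a dimension unrestricted.
#' @return data.frame with columns `mirna_id`, `tf_id`, `gene_id`, sorted
#'   lexicographically, no duplicates.
#' @export
infer_closed_loops <- function(mirna_targets, tf_targets, universe = NULL) {
  mirna_targets <- dedupe_targets(mirna_targets)
  tf_targets <- dedupe_targets(tf_targets)
  m2t <- mirna_targets[mirna_targets$target_kind == "TF",
                       c("regulator_id", "target_id")]
  m2g <- mirna_targets[mirna_targets$target_kind == "gene",
                       c("regulator_id", "target_id")]
  t2g <- tf_targets[, c("regulator_id", "target_id")]
  mirnas <- unique(c(m2t$regulator_id, m2g$regulator_id))
  genes <- unique(c(m2g$target_id, t2g$target_id))
  amb <- intersect(mirnas, genes)
  if (length(amb))
    stop("identifier(s) appear as both miRNA and gene: ",
         paste(amb, collapse = ", "))
  if (!is.null(universe)) {
    if (!is.null(universe$mirna)) {
      m2t <- m2t[m2t$regulator_id %in% universe$mirna, ]
      m2g <- m2g[m2g$regulator_id %in% universe$mirna, ]
    }
    if (!is.null(universe$tf)) {
      m2t <- m2t[m2t$target_id %in% universe$tf, ]
      t2g <- t2g[t2g$regulator_id %in% universe$tf, ]
    }
    if (!is.null(universe$gene)) {
      m2g <- m2g[m2g$target_id %in% universe$gene, ]
      t2g <- t2g[t2g$target_id %in% universe$gene, ]
    }
  }
  names(m2t) <- c("mirna_id", "tf_id")
  names(m2g) <- c("mirna_id", "gene_id")
  names(t2g) <- c("tf_id", "gene_id")
  loops <- merge(m2t, t2g, by = "tf_id")
  loops <- merge(loops, m2g, by = c("mirna_id", "gene_id"))
  loops <- unique(loops[, c("mirna_id", "tf_id", "gene_id")])
  loops <- loops[loops$mirna_id != loops$tf_id &
                   loops$mirna_id != loops$gene_id &
                   loops$tf_id != loops$gene_id, , drop = FALSE]
  loops <- loops[order(loops$mirna_id, loops$tf_id, loops$gene_id), ,
                 drop = FALSE]
  rownames(loops) <- NULL
  loops
}

#' Map a set of loops to a directed regulatory graph
#'
#' Nodes carry a `kind` attribute (miRNA, TF or gene); the edge set is the
#' union of the loops' edges with duplicates merged.
#'
#' @param loops data.frame as returned by [infer_closed_loops()].
#' @return an igraph directed graph with vertex attribute `kind` and edge
#'   attribute `edge_type`.
#' @export
loops_to_graph <- function(loops) {
  nodes <- rbind(
    data.frame(name = unique(loops$mirna_id), kind = "miRNA",
               stringsAsFactors = FALSE),
    data.frame(name = unique(loops$tf_id), kind = "TF",
               stringsAsFactors = FALSE),
    data.frame(name = unique(loops$gene_id), kind = "gene",
               stringsAsFactors = FALSE))
  if (anyDuplicated(nodes$name))
    stop("a node appears with more than one kind")
  edges <- unique(rbind(
    data.frame(from = loops$mirna_id, to = loops$tf_id,
               edge_type = "miRNA_TF", stringsAsFactors = FALSE),
    data.frame(from = loops$mirna_id, to = loops$gene_id,
               edge_type = "miRNA_gene", stringsAsFactors = FALSE),
    data.frame(from = loops$tf_id, to = loops$gene_id,
               edge_type = "TF_gene", stringsAsFactors = FALSE)))
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

#' Write a regulatory graph as an edge-list TSV (and optionally GraphML)
#' @param g igraph graph from [loops_to_graph()].
#' @param path TSV output path.
#' @param graphml optional GraphML output path.
#' @return invisibly, `path`.
#' @export
write_graph_tsv <- function(g, path, graphml = NULL) {
  el <- igraph::as_data_frame(g, what = "edges")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(g, graphml, format = "graphml")
  invisible(path)
}
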