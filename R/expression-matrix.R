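#' Expression matrix with sample metadata
#'
#' A light container for an entities x samples abundance table together with
#' the per-column metadata the pipeline needs: time point, condition
#' (injured vs sham) and replicate number.
#'
#' @param values numeric matrix, rows = entities (rownames required),
#'   columns = samples.
#' @param sample_meta data.frame with one row per column of `values` and
#'   columns `time_point` (character), `condition` (`"injured"` or `"sham"`)
#'   and `replicate` (integer).
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `meta`.
#' @export
expression_matrix <- function(values, sample_meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have entity rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate entity ids in expression matrix")
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  need <- c("time_point", "condition", "replicate")
  miss <- setdiff(need, names(sample_meta))
  if (length(miss)) stop("sample_meta missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(sample_meta) != ncol(values))
    stop("sample_meta rows (", nrow(sample_meta),
         ") != matrix columns (", ncol(values), ")")
  bad <- setdiff(unique(sample_meta$condition), c("injured", "sham"))
  if (length(bad)) stop("unknown condition label(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(colnames(values)))
    colnames(values) <- paste(sample_meta$time_point, sample_meta$condition,
                              sample_meta$replicate, sep = "_")
  structure(list(values = values, meta = sample_meta), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "entities x", ncol(x$values),
      "samples\n")
  cat("time points:", paste(unique(x$meta$time_point), collapse = ", "), "\n")
  tb <- table(x$meta$condition)
  cat("conditions: ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix to a set of sample columns
#' @param x an `expr_matrix`.
#' @param cols logical or integer index over samples.
#' @return an `expr_matrix` with the selected columns.
#' @export
subset_samples <- function(x, cols) {
  expression_matrix(x$values[, cols, drop = FALSE],
                    x$meta[cols, , drop = FALSE])
}

#' Write an expression matrix as TSV (values + sample metadata)
#' @param x an `expr_matrix`.
#' @param path file path for the values table; the metadata is written next
#'   to it with suffix `.samples.tsv` replacing `.tsv`.
#' @return invisibly, the two paths written.
#' @export
write_expr_matrix <- function(x, path) {
  df <- data.frame(entity_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mpath <- sub("\\.tsv$", ".samples.tsv", path)
  if (mpath == path) mpath <- paste0(path, ".samples.tsv")
  meta <- cbind(sample_id = colnames(x$values), x$meta)
  utils::write.table(meta, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, mpath))
}

#' Read an expression matrix written by [write_expr_matrix()]
#' @param path path of the values TSV.
#' @return an `expr_matrix`.
#' @export
read_expr_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$entity_id
  mpath <- sub("\\.tsv$", ".samples.tsv", path)
  if (mpath == path) mpath <- paste0(path, ".samples.tsv")
  meta <- utils::read.table(mpath, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
  colnames(vals) <- meta$sample_id
  expression_matrix(vals, meta[, c("time_point", "condition", "replicate")])
}
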