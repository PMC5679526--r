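#' Per-chip 75th-percentile then per-gene median normalization
#'
#' Each sample column is divided by its own 75th percentile (chip scaling),
#' then each entity row is divided by its median across samples, the
#' two-step scheme standard for single-color arrays.
#'
#' @param matrix an `expr_matrix` with positive values.
#' @return the normalized `expr_matrix`; every row has median 1.
#' @export
normalize <- function(matrix) {
  v <- matrix$values
  q75 <- apply(v, 2, stats::quantile, probs = 0.75, names = FALSE)
  bad <- which(q75 <= 0)
  if (length(bad))
    stop("non-positive 75th percentile in column(s): ",
         paste(colnames(v)[bad], collapse = ", "))
  v <- sweep(v, 2, q75, "/")
  med <- apply(v, 1, stats::median)
  if (any(med == 0)) stop("zero row median after chip scaling")
  v <- sweep(v, 1, med, "/")
  expression_matrix(v, matrix$meta)
}

#' Two-group differential expression with fold-change and BH filters
#'
#' For one time point, computes per entity the injured/sham fold change on
#' the linear scale (down-regulation reported as the negative reciprocal, so
#' the magnitude filter is symmetric), a Welch t-test p-value, and
#' Benjamini-Hochberg adjusted p-values across all entities.  An entity
#' passes when |fc| >= fc_threshold and bh_p <= p_threshold.
#'
#' @param matrix an `expr_matrix`.
#' @param time_point time-point label selecting the columns to compare.
#' @param fc_threshold fold-change magnitude cutoff (default 2).
#' @param p_threshold adjusted p-value cutoff (default 0.05).
#' @return data.frame with columns `entity_id`, `fc`, `raw_p`, `bh_p`,
#'   `passes`.
#' @export
differential_expression <- function(matrix, time_point,
                                    fc_threshold = 2, p_threshold = 0.05) {
  sel <- matrix$meta$time_point == time_point
  if (!any(sel)) stop("no samples at time point ", time_point)
  inj <- sel & matrix$meta$condition == "injured"
  sham <- sel & matrix$meta$condition == "sham"
  if (sum(inj) < 2 || sum(sham) < 2)
    stop("need >= 2 replicates per group at time point ", time_point)
  vi <- matrix$values[, inj, drop = FALSE]
  vs <- matrix$values[, sham, drop = FALSE]
  mi <- rowMeans(vi)
  ms <- rowMeans(vs)
  ratio <- mi / ms
  fc <- ifelse(ratio >= 1, ratio, -1 / ratio)
  raw_p <- vapply(seq_len(nrow(vi)), function(i) {
    if (stats::sd(vi[i, ]) == 0 && stats::sd(vs[i, ]) == 0) {
      if (all(vi[i, ] == vs[i, 1])) 1 else 0
    } else stats::t.test(vi[i, ], vs[i, ])$p.value
  }, numeric(1))
  bh_p <- stats::p.adjust(raw_p, method = "BH")
  data.frame(entity_id = rownames(matrix$values), fc = fc,
             raw_p = raw_p, bh_p = bh_p,
             passes = abs(fc) >= fc_threshold & bh_p <= p_threshold,
             stringsAsFactors = FALSE)
}

#' Impute expression at unobserved time points by a per-entity least-squares
#' line
#'
#' Fits, for each entity and condition, an ordinary least-squares line of
#' expression on numeric time over the observed time points, and appends one
#' fitted column per (target time, condition).  Observed columns are
#' unchanged.
#'
#' @param matrix an `expr_matrix` whose `time_point` labels parse as numbers.
#' @param observed_times numeric time labels to fit on.
#' @param target_times numeric time labels to impute.
#' @return an `expr_matrix` with the imputed columns appended (replicate 1,
#'   per condition present in the data).
#' @export
impute_timepoints <- function(matrix, observed_times, target_times) {
  tnum <- suppressWarnings(as.numeric(matrix$meta$time_point))
  if (anyNA(tnum)) stop("time_point labels must be numeric for imputation")
  if (length(unique(observed_times)) < 2)
    stop("need >= 2 observed time points to fit a line")
  conds <- unique(matrix$meta$condition)
  new_vals <- list(); new_meta <- list()
  for (cond in conds) {
    sel <- matrix$meta$condition == cond & tnum %in% observed_times
    if (sum(sel) < 2) stop("fewer than 2 observed columns for condition ",
                           cond)
    tt <- tnum[sel]
    if (length(unique(tt)) < 2)
      stop("need >= 2 distinct observed time points for condition ", cond)
    v <- matrix$values[, sel, drop = FALSE]
    X <- cbind(1, tt)
    # one least-squares solve for all entities: coef is 2 x n_entities
    coefs <- solve(crossprod(X), crossprod(X, t(v)))
    for (t0 in target_times) {
      pred <- drop(c(1, t0) %*% coefs)
      new_vals[[length(new_vals) + 1]] <- pred
      new_meta[[length(new_meta) + 1]] <-
        data.frame(time_point = as.character(t0), condition = cond,
                   replicate = 1L, stringsAsFactors = FALSE)
    }
  }
  add <- do.call(cbind, new_vals)
  colnames(add) <- paste0("imputed_",
                          unlist(lapply(new_meta, function(m)
                            paste(m$time_point, m$condition, sep = "_"))))
  vals <- cbind(matrix$values, add)
  meta <- rbind(matrix$meta, do.call(rbind, new_meta))
  expression_matrix(vals, meta)
}

#' Collapse multi-probe genes to their first listed probe
#'
#' @param matrix an `expr_matrix` whose rows are probes.
#' @param probe_order named list: for each gene, the ordered character
#'   vector of its probe ids; the gene's expression is the row of the first
#'   listed probe.
#' @return an `expr_matrix` with one row per gene, in `probe_order` order.
#' @export
collapse_probes <- function(matrix, probe_order) {
  all_probes <- unlist(probe_order, use.names = FALSE)
  if (anyDuplicated(all_probes))
    stop("a probe maps to more than one gene")
  missing <- setdiff(all_probes, rownames(matrix$values))
  if (length(missing))
    stop("probe(s) absent from matrix: ", paste(missing, collapse = ", "))
  first <- vapply(probe_order, `[`, character(1), 1)
  v <- matrix$values[first, , drop = FALSE]
  rownames(v) <- names(probe_order)
  expression_matrix(v, matrix$meta)
}
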