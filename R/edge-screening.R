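#' Pearson correlation of one loop edge
#'
#' @param x,y equal-length numeric vectors (n >= 3), non-constant.
#' @return list with `pearson_r` and the two-sided `pearson_p` from the t
#'   statistic r * sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom.
#' @export
pearson_edge <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Pearson correlation undefined")
  ct <- stats::cor.test(x, y)
  list(pearson_r = unname(ct$estimate), pearson_p = ct$p.value)
}

dist_matrix <- function(x) {
  x <- as.numeric(x)
  abs(outer(x, x, "-"))
}

#' Sample distance correlation
#'
#' Computes the sample distance correlation from pairwise distance matrices
#' via double centering: dcor^2 = V^2(x,y) / sqrt(V^2(x) V^2(y)) with
#' V^2(x,y) = mean(A * B), A and B the double-centered distance matrices.
#' Zero population dcor characterizes independence; the sample value lies in
#' [0, 1] and is sensitive to nonlinear dependence.
#'
#' @param x,y equal-length numeric vectors (n >= 4).
#' @return the sample distance correlation in [0, 1].
#' @export
distance_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: distance correlation defined as 0")
    return(0)
  }
  dc <- function(d) {
    d - outer(rowMeans(d), rep(1, n)) - outer(rep(1, n), colMeans(d)) +
      mean(d)
  }
  A <- dc(dist_matrix(x))
  B <- dc(dist_matrix(y))
  vxy <- mean(A * B)
  vx <- mean(A * A)
  vy <- mean(B * B)
  if (vx <= 0 || vy <= 0) return(0)
  sqrt(max(0, vxy) / sqrt(vx * vy))
}

# modified (bias-corrected) double centering for the dcor t-test
astar <- function(d) {
  n <- nrow(d)
  m <- rowMeans(d)
  M <- mean(d)
  A <- d - outer(m, rep(1, n)) - outer(rep(1, n), m) + M
  A <- A - d / n
  diag(A) <- m - M
  (n / (n - 1)) * A
}

#' Bias-corrected distance correlation
#'
#' The modified statistic underlying the distance-correlation t-test; unlike
#' the plain sample statistic it can be negative and is centered near zero
#' under independence.
#'
#' @param x,y equal-length numeric vectors (n >= 4).
#' @return the bias-corrected distance correlation.
#' @export
bcdcor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need n >= 4")
  A <- astar(dist_matrix(x))
  B <- astar(dist_matrix(y))
  xy <- sum(A * B) - (n / (n - 2)) * sum(diag(A) * diag(B))
  xx <- sum(A * A) - (n / (n - 2)) * sum(diag(A)^2)
  yy <- sum(B * B) - (n / (n - 2)) * sum(diag(B)^2)
  if (xx <= 0 || yy <= 0) return(0)
  xy / sqrt(xx * yy)
}

#' Distance-correlation t-test of independence
#'
#' One-sided test of multivariate independence based on the bias-corrected
#' distance correlation R*: T = sqrt(v - 1) * R* / sqrt(1 - R*^2) with
#' v = n(n-3)/2, approximately Student t with n(n-3)/2 - 1 degrees of
#' freedom (and approximately standard normal for n >= 10).
#'
#' @param x,y equal-length numeric vectors.
#' @return list with `dcor_stat` (T), `dcor_df` (n(n-3)/2 - 1), `dcor_p`
#'   (upper-tail p) and `bcR` (the bias-corrected statistic).  For n < 10 a
#'   warning is attached: the t approximation is unreliable.
#' @export
dcor_ttest <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need n >= 4")
  warn <- NULL
  if (n < 10) {
    warn <- "n < 10: the t approximation of the dcor test is unreliable"
    warning(warn)
  }
  r <- bcdcor(x, y)
  v <- n * (n - 3) / 2
  df <- v - 1
  r <- max(min(r, 1), -1)
  stat <- if (abs(r) >= 1) sign(r) * Inf else sqrt(df) * r / sqrt(1 - r^2)
  p <- stats::pt(stat, df = df, lower.tail = FALSE)
  out <- list(dcor_stat = stat, dcor_df = df, dcor_p = p, bcR = r)
  if (!is.null(warn)) attr(out, "warning") <- warn
  out
}

edge_stats <- function(x, y) {
  pe <- pearson_edge(x, y)
  tt <- dcor_ttest(x, y)
  list(n = length(x), pearson_r = pe$pearson_r, pearson_p = pe$pearson_p,
       dcor = distance_correlation(x, y), dcor_stat = tt$dcor_stat,
       dcor_df = tt$dcor_df, dcor_p = tt$dcor_p)
}

#' Screen candidate loops by edge-wise dependence
#'
#' Scores the three edges of each loop (miRNA-TF, miRNA-gene, TF-gene) with
#' Pearson and distance correlation and keeps loops whose three edges are
#' all significant under the distance-correlation t-test at `alpha`.  The
#' Pearson p-value only labels each edge `linear` (TRUE/FALSE), which
#' downstream mediation uses to route between linear and spline models.
#'
#' @param loops data.frame with `mirna_id`, `tf_id`, `gene_id`.
#' @param mirna_expr,tf_expr,gene_expr `expr_matrix` objects sharing sample
#'   columns; screening uses the injured columns (where the co-variation
#'   structure lives) if both conditions are present.
#' @param alpha edge significance level (default 0.05).
#' @param adjust `"none"` (default, the plain per-edge filter) or `"BH"`
#'   to Benjamini-Hochberg-adjust the dcor p-values across all edges first.
#' @param time_point optional time-point label to restrict columns.
#' @return data.frame of retained loops with per-edge statistics columns
#'   (`*_mt`, `*_mg`, `*_tg` suffixes for the three edges).  Loops whose
#'   members lack an expression row are skipped and listed in the
#'   `"skipped"` attribute.
#' @export
screen_loops <- function(loops, mirna_expr, tf_expr, gene_expr,
                         alpha = 0.05, adjust = c("none", "BH"),
                         time_point = NULL) {
  adjust <- match.arg(adjust)
  pick <- function(em) {
    sel <- rep(TRUE, ncol(em$values))
    if (!is.null(time_point)) sel <- sel & em$meta$time_point == time_point
    if (any(em$meta$condition == "injured"))
      sel <- sel & em$meta$condition == "injured"
    em$values[, sel, drop = FALSE]
  }
  vm <- pick(mirna_expr); vt <- pick(tf_expr); vg <- pick(gene_expr)
  if (ncol(vm) != ncol(vt) || ncol(vm) != ncol(vg))
    stop("expression matrices must share sample columns")
  skipped <- character(0)
  rows <- vector("list", nrow(loops))
  for (i in seq_len(nrow(loops))) {
    mi <- loops$mirna_id[i]; tf <- loops$tf_id[i]; g <- loops$gene_id[i]
    if (!(mi %in% rownames(vm)) || !(tf %in% rownames(vt)) ||
        !(g %in% rownames(vg))) {
      skipped <- c(skipped, paste(mi, tf, g, sep = "|"))
      next
    }
    x <- vm[mi, ]; m <- vt[tf, ]; y <- vg[g, ]
    s_mt <- edge_stats(x, m)
    s_mg <- edge_stats(x, y)
    s_tg <- edge_stats(m, y)
    rows[[i]] <- data.frame(
      mirna_id = mi, tf_id = tf, gene_id = g, n = s_mt$n,
      r_mt = s_mt$pearson_r, pr_mt = s_mt$pearson_p,
      dcor_mt = s_mt$dcor, pd_mt = s_mt$dcor_p,
      r_mg = s_mg$pearson_r, pr_mg = s_mg$pearson_p,
      dcor_mg = s_mg$dcor, pd_mg = s_mg$dcor_p,
      r_tg = s_tg$pearson_r, pr_tg = s_tg$pearson_p,
      dcor_tg = s_tg$dcor, pd_tg = s_tg$dcor_p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (length(skipped))
    message(length(skipped), " loop(s) skipped for missing expression rows")
  if (is.null(out)) {
    out <- data.frame()
    attr(out, "skipped") <- skipped
    return(out)
  }
  pd <- cbind(out$pd_mt, out$pd_mg, out$pd_tg)
  if (adjust == "BH")
    pd <- matrix(stats::p.adjust(pd, method = "BH"), ncol = 3)
  keep <- rowSums(pd <= alpha) == 3
  out$linear_mt <- out$pr_mt <= alpha
  out$linear_mg <- out$pr_mg <= alpha
  out$linear_tg <- out$pr_tg <= alpha
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
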