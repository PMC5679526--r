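#' Specify one planted miRNA -> TF -> gene triad
#'
#' A triad spec records the structural coefficients of the single-mediator
#' model: the treatment effect on the mediator (`a`, miRNA on TF), the
#' mediator effect on the outcome given treatment (`b`, TF on gene) and the
#' direct effect (`c_prime`, miRNA on gene given TF), together with the
#' noise levels and the loop class the coefficients encode.
#'
#' Class coding: `M_T` (mediated by the TF only: a != 0, b != 0, c' = 0),
#' `M_M` (direct miRNA effect only: c' != 0, a*b = 0), `M_TM` (both
#' channels: a != 0, b != 0, c' != 0), `NULL` (no effects at all).
#'
#' @param mirna_id,tf_id,gene_id entity identifiers (distinct).
#' @param a,b,c_prime structural coefficients.
#' @param noise_sd_m,noise_sd_y non-negative noise standard deviations for
#'   the mediator and outcome equations.
#' @param intended_class one of `"M_T"`, `"M_M"`, `"M_TM"`, `"NULL"`.
#' @return a one-row data.frame of class `triad_spec`.
#' @export
triad_spec <- function(mirna_id, tf_id, gene_id, a, b, c_prime,
                       noise_sd_m = 0.5, noise_sd_y = 0.5,
                       intended_class = NULL) {
  ids <- c(mirna_id, tf_id, gene_id)
  if (anyDuplicated(ids)) stop("triad node ids must be distinct")
  if (noise_sd_m < 0 || noise_sd_y < 0) stop("noise sd must be >= 0")
  if (is.null(intended_class)) {
    intended_class <-
      if (a == 0 && b == 0 && c_prime == 0) "NULL"
      else if (a != 0 && b != 0 && c_prime == 0) "M_T"
      else if (c_prime != 0 && a * b == 0) "M_M"
      else if (a != 0 && b != 0 && c_prime != 0) "M_TM"
      else stop("coefficients match no loop class")
  }
  ok <- switch(intended_class,
    M_T  = a != 0 && b != 0 && c_prime == 0,
    M_M  = c_prime != 0 && a * b == 0,
    M_TM = a != 0 && b != 0 && c_prime != 0,
    "NULL" = a == 0 && b == 0 && c_prime == 0,
    stop("unknown intended_class: ", intended_class))
  if (!ok) stop("coefficients inconsistent with intended_class ",
                intended_class)
  out <- data.frame(mirna_id = mirna_id, tf_id = tf_id, gene_id = gene_id,
                    a = a, b = b, c_prime = c_prime,
                    noise_sd_m = noise_sd_m, noise_sd_y = noise_sd_y,
                    intended_class = intended_class,
                    stringsAsFactors = FALSE)
  class(out) <- c("triad_spec", class(out))
  out
}

#' Simulate one triad's structural sample vectors
#'
#' Draws X i.i.d. standard normal, M = beta2 + a X + e2 and
#' Y = beta3 + c' X + b M + e3 with independent Gaussian errors.
#'
#' @param n sample count.
#' @param a,b,c_prime structural coefficients.
#' @param noise_sd_m,noise_sd_y error standard deviations.
#' @param beta2,beta3 intercepts of the mediator and outcome equations.
#' @return data.frame with columns `x`, `m`, `y`.
#' @export
simulate_triad <- function(n, a, b, c_prime, noise_sd_m = 0.5,
                           noise_sd_y = 0.5, beta2 = 0, beta3 = 0) {
  if (n < 1) stop("n must be positive")
  x <- stats::rnorm(n)
  m <- beta2 + a * x + stats::rnorm(n, sd = noise_sd_m)
  y <- beta3 + c_prime * x + b * m + stats::rnorm(n, sd = noise_sd_y)
  data.frame(x = x, m = m, y = y)
}

default_coeff_ranges <- function() {
  list(a = c(0.5, 1.5), b = c(0.5, 1.5), c_prime = c(0.3, 1.0))
}

draw_coeff <- function(range, sign = NULL) {
  if (any(range <= 0)) stop("coefficient ranges must exclude 0")
  v <- stats::runif(1, range[1], range[2])
  s <- if (is.null(sign)) sample(c(-1, 1), 1) else sign
  s * v
}

#' Generate a synthetic dataset with planted closed regulatory loops
#'
#' Builds miRNA, TF and gene expression matrices plus regulator->target
#' tables in which a known set of closed loops (miRNA targets a TF and a
#' gene; the TF targets the same gene) is planted alongside decoy edges
#' that never complete an unplanned loop, so loop-inference precision and
#' recall are exactly computable.
#'
#' Each matrix carries `n_samples` injured and `n_samples` sham replicate
#' columns at one time point.  The injured columns of a triad's members
#' follow the structural equations around an injured baseline; sham columns
#' are independent noise around the sham baseline, so the injured/sham
#' baseline ratio plants the fold change.  Decoy entities sit at the sham
#' baseline in both conditions (fold change ~ 1).
#'
#' @param n_triads named integer vector of triad counts per class, names in
#'   `c("M_T","M_M","M_TM","NULL")`.
#' @param n_decoy_edges number of decoy regulator->target edges to add.
#' @param n_samples replicates per condition (>= 10; the distance
#'   correlation t-test approximation needs n >= 10).
#' @param coeff_ranges list with positive ranges `a`, `b`, `c_prime` for the
#'   coefficient magnitudes; signs are drawn at random.
#' @param noise_sd Gaussian noise sd used for both structural equations and
#'   measurement noise on sham/decoy values.
#' @param fc_magnitude planted injured/sham fold-change magnitude (>= 2).
#' @param baseline sham-condition expression baseline (linear scale).
#' @param time_point time-point label for all columns.
#' @param seed integer seed; regeneration with the same arguments and seed
#'   is byte-identical.
#' @return an object of class `synthetic_dataset`: list with elements
#'   `mirna_expr`, `tf_expr`, `gene_expr` (expr_matrix), `mirna_targets`,
#'   `tf_targets` (data.frame), `truth` (triad_spec rows plus planted fold
#'   changes) and `seed`.
#' @export
generate_dataset <- function(n_triads = c(M_T = 5, M_M = 5, M_TM = 5),
                             n_decoy_edges = 20, n_samples = 50,
                             coeff_ranges = default_coeff_ranges(),
                             noise_sd = 0.5, fc_magnitude = 4,
                             baseline = 20, time_point = "24h",
                             seed = 1L) {
  if (n_samples < 1) stop("zero samples requested")
  if (n_samples < 10)
    stop("n_samples must be >= 10 (distance correlation t-test requirement)")
  if (fc_magnitude < 2) stop("fc_magnitude must be >= 2")
  classes <- c("M_T", "M_M", "M_TM", "NULL")
  n_triads <- n_triads[!is.na(n_triads)]
  if (!length(n_triads) || sum(n_triads) == 0)
    stop("all triad class counts are zero")
  bad <- setdiff(names(n_triads), classes)
  if (length(bad)) stop("unknown triad class(es): ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))

  specs <- list()
  k <- 0
  for (cls in names(n_triads)) {
    for (i in seq_len(n_triads[[cls]])) {
      k <- k + 1
      id <- sprintf("%03d", k)
      a <- b <- cp <- 0
      if (cls %in% c("M_T", "M_TM")) {
        a <- draw_coeff(coeff_ranges$a)
        b <- draw_coeff(coeff_ranges$b)
      }
      if (cls == "M_M") {
        # direct channel only: a carries the miRNA->TF edge, b is zero so
        # the TF does not mediate, and c' is the direct miRNA->gene effect
        a <- draw_coeff(coeff_ranges$a)
        cp <- draw_coeff(coeff_ranges$c_prime)
      }
      if (cls == "M_TM") cp <- draw_coeff(coeff_ranges$c_prime)
      specs[[k]] <- triad_spec(paste0("miR_", id), paste0("TF_", id),
                               paste0("G_", id), a = a, b = b, c_prime = cp,
                               noise_sd_m = noise_sd, noise_sd_y = noise_sd,
                               intended_class = cls)
    }
  }
  truth <- do.call(rbind, specs)

  n_tri <- nrow(truth)
  meta <- data.frame(
    time_point = time_point,
    condition = rep(c("injured", "sham"), each = n_samples),
    replicate = rep(seq_len(n_samples), 2),
    stringsAsFactors = FALSE)

  # planted fold-change direction per entity (up or down at random)
  fc_sign <- function(n) sample(c(1, -1), n, replace = TRUE)
  dir_m <- fc_sign(n_tri); dir_t <- fc_sign(n_tri); dir_g <- fc_sign(n_tri)
  base_of <- function(dir) ifelse(dir > 0, baseline * fc_magnitude,
                                  baseline / fc_magnitude)

  mk_row <- function(inj_base, dev) {
    c(inj_base + dev, baseline + stats::rnorm(n_samples, sd = noise_sd))
  }

  vm <- matrix(0, n_tri, 2 * n_samples)
  vt <- matrix(0, n_tri, 2 * n_samples)
  vg <- matrix(0, n_tri, 2 * n_samples)
  for (i in seq_len(n_tri)) {
    tr <- truth[i, ]
    d <- simulate_triad(n_samples, tr$a, tr$b, tr$c_prime,
                        tr$noise_sd_m, tr$noise_sd_y)
    vm[i, ] <- mk_row(base_of(dir_m[i]), d$x)
    vt[i, ] <- mk_row(base_of(dir_t[i]), d$m)
    vg[i, ] <- mk_row(base_of(dir_g[i]), d$y)
  }
  rownames(vm) <- truth$mirna_id
  rownames(vt) <- truth$tf_id
  rownames(vg) <- truth$gene_id

  truth$fc_mirna <- ifelse(dir_m > 0, fc_magnitude, -fc_magnitude)
  truth$fc_tf    <- ifelse(dir_t > 0, fc_magnitude, -fc_magnitude)
  truth$fc_gene  <- ifelse(dir_g > 0, fc_magnitude, -fc_magnitude)

  # planted edges
  mirna_targets <- rbind(
    data.frame(regulator_id = truth$mirna_id, regulator_kind = "miRNA",
               target_id = truth$tf_id, target_kind = "TF",
               source = "planted", score = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(regulator_id = truth$mirna_id, regulator_kind = "miRNA",
               target_id = truth$gene_id, target_kind = "gene",
               source = "planted", score = NA_real_,
               stringsAsFactors = FALSE))
  tf_targets <- data.frame(regulator_id = truth$tf_id, regulator_kind = "TF",
                           target_id = truth$gene_id, target_kind = "gene",
                           source = "planted", score = NA_real_,
                           stringsAsFactors = FALSE)

  # decoy entities: noise-only rows with fold change ~ 1
  n_dec <- max(2L, ceiling(n_decoy_edges / 4))
  dec_m <- sprintf("miR_dec%03d", seq_len(n_dec))
  dec_t <- sprintf("TF_dec%03d",  seq_len(n_dec))
  dec_g <- sprintf("G_dec%03d",   seq_len(n_dec))
  noise_rows <- function(ids) {
    v <- matrix(baseline + stats::rnorm(length(ids) * 2 * n_samples,
                                        sd = noise_sd),
                length(ids), 2 * n_samples)
    rownames(v) <- ids
    v
  }
  vm <- rbind(vm, noise_rows(dec_m))
  vt <- rbind(vt, noise_rows(dec_t))
  vg <- rbind(vg, noise_rows(dec_g))

  all_m <- rownames(vm); all_t <- rownames(vt); all_g <- rownames(vg)
  has_edge <- function(tab, r, t) any(tab$regulator_id == r & tab$target_id == t)
  closes_loop <- function(kind, r, t) {
    if (kind == "m2t") {
      g <- mirna_targets$target_id[mirna_targets$regulator_id == r &
                                     mirna_targets$target_kind == "gene"]
      any(g %in% tf_targets$target_id[tf_targets$regulator_id == t])
    } else if (kind == "m2g") {
      tfs <- mirna_targets$target_id[mirna_targets$regulator_id == r &
                                       mirna_targets$target_kind == "TF"]
      any(tfs %in% tf_targets$regulator_id[tf_targets$target_id == t])
    } else {
      ms <- mirna_targets$regulator_id[mirna_targets$target_id == r &
                                         mirna_targets$target_kind == "TF"]
      mg <- mirna_targets$regulator_id[mirna_targets$target_id == t &
                                         mirna_targets$target_kind == "gene"]
      any(ms %in% mg)
    }
  }
  added <- 0; attempts <- 0
  while (added < n_decoy_edges && attempts < 200 * n_decoy_edges) {
    attempts <- attempts + 1
    kind <- sample(c("m2t", "m2g", "t2g"), 1)
    if (kind == "m2t") {
      r <- sample(all_m, 1); t <- sample(all_t, 1)
      if (has_edge(mirna_targets, r, t) || closes_loop(kind, r, t)) next
      mirna_targets <- rbind(mirna_targets,
        data.frame(regulator_id = r, regulator_kind = "miRNA", target_id = t,
                   target_kind = "TF", source = "decoy", score = NA_real_,
                   stringsAsFactors = FALSE))
    } else if (kind == "m2g") {
      r <- sample(all_m, 1); t <- sample(all_g, 1)
      if (has_edge(mirna_targets, r, t) || closes_loop(kind, r, t)) next
      mirna_targets <- rbind(mirna_targets,
        data.frame(regulator_id = r, regulator_kind = "miRNA", target_id = t,
                   target_kind = "gene", source = "decoy", score = NA_real_,
                   stringsAsFactors = FALSE))
    } else {
      r <- sample(all_t, 1); t <- sample(all_g, 1)
      if (has_edge(tf_targets, r, t) || closes_loop(kind, r, t)) next
      tf_targets <- rbind(tf_targets,
        data.frame(regulator_id = r, regulator_kind = "TF", target_id = t,
                   target_kind = "gene", source = "decoy", score = NA_real_,
                   stringsAsFactors = FALSE))
    }
    added <- added + 1
  }
  if (added < n_decoy_edges)
    warning("only ", added, " of ", n_decoy_edges,
            " decoy edges could be placed without closing a loop")

  out <- list(
    mirna_expr = expression_matrix(vm, meta),
    tf_expr = expression_matrix(vt, meta),
    gene_expr = expression_matrix(vg, meta),
    mirna_targets = mirna_targets,
    tf_targets = tf_targets,
    truth = truth,
    seed = as.integer(seed))
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$truth), "planted triads (",
      paste(names(table(x$truth$intended_class)),
            table(x$truth$intended_class), sep = "=", collapse = ", "),
      "), seed", x$seed, "\n")
  cat("edges:", nrow(x$mirna_targets), "miRNA->target,",
      nrow(x$tf_targets), "TF->gene\n")
  invisible(x)
}

#' Write a synthetic dataset to a directory of TSV files plus a manifest
#'
#' @param ds a `synthetic_dataset`.
#' @param directory output directory (created if absent).
#' @return invisibly, the directory path.
#' @export
write_dataset <- function(ds, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  wt <- function(df, f) utils::write.table(
    df, file.path(directory, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_expr_matrix(ds$mirna_expr, file.path(directory, "mirna_expr.tsv"))
  write_expr_matrix(ds$tf_expr, file.path(directory, "tf_expr.tsv"))
  write_expr_matrix(ds$gene_expr, file.path(directory, "gene_expr.tsv"))
  wt(ds$mirna_targets, "mirna_targets.tsv")
  wt(ds$tf_targets, "tf_targets.tsv")
  wt(ds$truth, "truth.tsv")
  yaml::write_yaml(list(seed = ds$seed, n_triads = nrow(ds$truth),
                        files = c("mirna_expr.tsv", "tf_expr.tsv",
                                  "gene_expr.tsv", "mirna_targets.tsv",
                                  "tf_targets.tsv", "truth.tsv")),
                   file.path(directory, "manifest.yaml"))
  invisible(directory)
}

#' Read a synthetic dataset written by [write_dataset()]
#' @param directory directory containing the TSV files and manifest.
#' @return a `synthetic_dataset`.
#' @export
read_dataset <- function(directory) {
  man <- yaml::read_yaml(file.path(directory, "manifest.yaml"))
  rt <- function(f) {
    x <- utils::read.table(file.path(directory, f), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
    # an all-NA score column reads back as logical
    if ("score" %in% names(x)) x$score <- as.numeric(x$score)
    x
  }
  out <- list(
    mirna_expr = read_expr_matrix(file.path(directory, "mirna_expr.tsv")),
    tf_expr = read_expr_matrix(file.path(directory, "tf_expr.tsv")),
    gene_expr = read_expr_matrix(file.path(directory, "gene_expr.tsv")),
    mirna_targets = rt("mirna_targets.tsv"),
    tf_targets = rt("tf_targets.tsv"),
    truth = rt("truth.tsv"),
    seed = as.integer(man$seed))
  class(out) <- "synthetic_dataset"
  out
}
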