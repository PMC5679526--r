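pipeline_defaults <- function() {
  list(
    paths = NULL,
    synthetic = NULL,
    alpha = 0.05,
    fc_threshold = 2,
    n_boot = 1000,
    n_random_graphs = 1000,
    motif_sizes = c(3, 4),
    seed = 1L,
    orientation = "miRNA_treats_TF_mediates",
    time_point = "24h")
}

# small deterministic string hash (FNV-1a, 32-bit) for the manifest
config_hash <- function(config) {
  s <- utf8ToInt(paste(yaml::as.yaml(config), collapse = ""))
  h <- 2166136261
  for (ch in s) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, rejects unknown keys
#' and reports all range violations at once.  The defaults are the study's
#' stated operating points: edge/effect significance 0.05, absolute
#' fold-change threshold 2, 1000 bootstrap simulations, 1000 random graphs.
#'
#' @param raw path to a YAML config file, or a named list (possibly empty).
#' @return the completed config list, classed `pipeline_config`.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw)) raw <- yaml::read_yaml(raw)
  if (is.null(raw)) raw <- list()
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  problems <- character(0)
  if (length(unknown))
    problems <- c(problems, paste("unknown key(s):",
                                  paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, raw[intersect(names(raw),
                                                   names(defaults))])
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(is.numeric(cfg$alpha) && cfg$alpha >= 0 && cfg$alpha <= 1,
      "alpha must be in [0, 1]")
  chk(is.numeric(cfg$fc_threshold) && cfg$fc_threshold > 0,
      "fc_threshold must be positive")
  chk(is.numeric(cfg$n_boot) && cfg$n_boot >= 100,
      "n_boot must be >= 100")
  chk(is.numeric(cfg$n_random_graphs) && cfg$n_random_graphs >= 1,
      "n_random_graphs must be >= 1")
  chk(all(cfg$motif_sizes %in% 3:5), "motif_sizes must be within 3..5")
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
      "seed must be an integer")
  chk(cfg$orientation %in% c("miRNA_treats_TF_mediates",
                             "TF_treats_miRNA_mediates"),
      "orientation must name which variable is treatment")
  if (length(problems))
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run causal mediation on every screened loop
#'
#' Model kinds are routed per loop from the edge linearity flags set by
#' [screen_loops()]: the mediator model is linear when the miRNA-TF edge is
#' Pearson-significant, the outcome model when both gene edges are;
#' otherwise cubic regression splines are used.
#'
#' @param screened data.frame from [screen_loops()].
#' @param mirna_expr,tf_expr,gene_expr `expr_matrix` objects.
#' @param n_boot bootstrap replicates per loop.
#' @param seed base seed; loop i uses seed + i.
#' @param orientation treatment/mediator orientation; the reversed
#'   orientation swaps the miRNA and TF roles.
#' @param time_point optional time-point restriction.
#' @return list of `loop_mediation` objects, one per screened loop.
#' @export
mediate_screened <- function(screened, mirna_expr, tf_expr, gene_expr,
                             n_boot = 1000, seed = 1L,
                             orientation = "miRNA_treats_TF_mediates",
                             time_point = NULL) {
  pick <- function(em) {
    sel <- rep(TRUE, ncol(em$values))
    if (!is.null(time_point)) sel <- sel & em$meta$time_point == time_point
    if (any(em$meta$condition == "injured"))
      sel <- sel & em$meta$condition == "injured"
    em$values[, sel, drop = FALSE]
  }
  vm <- pick(mirna_expr); vt <- pick(tf_expr); vg <- pick(gene_expr)
  lapply(seq_len(nrow(screened)), function(i) {
    r <- screened[i, ]
    x <- vm[r$mirna_id, ]; m <- vt[r$tf_id, ]; y <- vg[r$gene_id, ]
    if (orientation == "TF_treats_miRNA_mediates") { tmp <- x; x <- m; m <- tmp }
    kind_m <- if (isTRUE(r$linear_mt)) "linear" else "spline"
    kind_y <- if (isTRUE(r$linear_mg) && isTRUE(r$linear_tg)) "linear"
              else "spline"
    mediate_loop(x, m, y, kind_m = kind_m, kind_y = kind_y, n_boot = n_boot,
                 seed = (seed + i) %% 2147483647,
                 orientation = orientation,
                 loop = c(r$mirna_id, r$tf_id, r$gene_id))
  })
}

mediation_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) data.frame(
    mirna_id = f$loop[1], tf_id = f$loop[2], gene_id = f$loop[3],
    orientation = f$orientation, a = f$a, b = f$b, c = f$c,
    c_prime = f$c_prime, acme = f$acme, ade = f$ade, te = f$te,
    acme_lo = f$acme_ci[1], acme_hi = f$acme_ci[2],
    ade_lo = f$ade_ci[1], ade_hi = f$ade_ci[2],
    acme_p = f$acme_p, ade_p = f$ade_p, te_p = f$te_p,
    model_m_kind = f$model_m_kind, model_y_kind = f$model_y_kind,
    n_boot = f$n_boot, seed = f$seed, stringsAsFactors = FALSE)))
}

#' Run the full loop-mediation pipeline
#'
#' Executes the four stages in order — preprocessing and differential
#' expression, closed-loop inference, edge screening plus per-loop causal
#' mediation with classification, and network-motif significance on the
#' mediated-loop graph — writing per-stage TSVs, a YAML summary with the
#' class and direction counts, and a reproducibility manifest.
#'
#' @param config a `pipeline_config` (see [validate_config()]); must carry
#'   either a `synthetic` block of [generate_dataset()] arguments or a
#'   `paths` block naming the input TSVs.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results (`de`,
#'   `loops`, `screened`, `mediation`, `classified`, `summary`, `motifs`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  wt <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  ds <- stage("input", {
    if (!is.null(config$synthetic)) {
      args <- config$synthetic
      if (is.null(args$seed)) args$seed <- config$seed
      if (!is.null(args$n_triads)) args$n_triads <- unlist(args$n_triads)
      do.call(generate_dataset, args)
    } else if (!is.null(config$paths)) {
      p <- config$paths
      list(mirna_expr = read_expr_matrix(p$mirna_expr),
           tf_expr = read_expr_matrix(p$tf_expr),
           gene_expr = read_expr_matrix(p$gene_expr),
           mirna_targets = utils::read.table(p$mirna_targets, sep = "\t",
                                             header = TRUE,
                                             stringsAsFactors = FALSE),
           tf_targets = utils::read.table(p$tf_targets, sep = "\t",
                                          header = TRUE,
                                          stringsAsFactors = FALSE))
    } else stop("config must provide a 'synthetic' or 'paths' block")
  })

  de <- stage("preprocess", {
    out <- lapply(list(mirna = ds$mirna_expr, tf = ds$tf_expr,
                       gene = ds$gene_expr),
                  differential_expression, time_point = config$time_point,
                  fc_threshold = config$fc_threshold)
    wt(out$mirna, "de_mirna.tsv"); wt(out$tf, "de_tf.tsv")
    wt(out$gene, "de_gene.tsv")
    out
  })
  universe <- list(mirna = de$mirna$entity_id[de$mirna$passes],
                   tf = de$tf$entity_id[de$tf$passes],
                   gene = de$gene$entity_id[de$gene$passes])

  loops <- stage("loop_inference", {
    l <- infer_closed_loops(ds$mirna_targets, ds$tf_targets, universe)
    wt(l, "loops.tsv")
    l
  })

  screened <- stage("edge_screening", {
    s <- screen_loops(loops, ds$mirna_expr, ds$tf_expr, ds$gene_expr,
                      alpha = config$alpha, time_point = config$time_point)
    if (nrow(s)) wt(s, "screened.tsv") else
      wt(data.frame(mirna_id = character(0), tf_id = character(0),
                    gene_id = character(0)), "screened.tsv")
    s
  })

  fits <- list(); med <- NULL; classified <- NULL
  summary_counts <- list(n_loops = nrow(loops), n_screened = nrow(screened))
  if (nrow(screened)) {
    fits <- stage("mediation", {
      mediate_screened(screened, ds$mirna_expr, ds$tf_expr,
                       ds$gene_expr, n_boot = config$n_boot,
                       seed = config$seed,
                       orientation = config$orientation,
                       time_point = config$time_point)
    })
    med <- stage("mediation", {
      tab <- mediation_table(fits)
      wt(tab, "mediation.tsv")
      tab
    })
    classified <- stage("classification", {
      fc_of <- function(tab, id) {
        v <- tab$fc[match(id, tab$entity_id)]
        if (is.na(v)) NA_real_ else v
      }
      rows <- lapply(fits, function(f) {
        cl <- classify(f, alpha = config$alpha,
                       fc = c(mirna = fc_of(de$mirna, f$loop[1]),
                              tf = fc_of(de$tf, f$loop[2]),
                              gene = fc_of(de$gene, f$loop[3])))
        if (cl$cls == "M_TM") cl <- subclassify_mtm(cl)
        cl
      })
      cls <- do.call(rbind, rows)
      wt(cls, "classification.tsv")
      cls
    })
    summary_counts$class_counts <- as.list(table(classified$cls))
    summary_counts$explained_fraction <-
      sum(classified$cls != "UNEXPLAINED") / nrow(classified)
    summary_counts$mtm_agreement <-
      as.list(table(classified$agreement[classified$cls == "M_TM"]))
    dt <- direction_tables(classified)
    summary_counts$direction_M_T <- as.list(dt$M_T)
    summary_counts$direction_M_M <- as.list(dt$M_M)
    wt(top_effects(classified), "top_effects.tsv")
  }

  motifs <- list()
  mediated <- if (!is.null(classified))
    classified[classified$cls != "UNEXPLAINED", , drop = FALSE]
  else NULL
  if (!is.null(mediated) && nrow(mediated)) {
    motifs <- stage("motif_analysis", {
      g <- loops_to_graph(mediated[, c("mirna_id", "tf_id", "gene_id")])
      write_graph_tsv(g, file.path(out_dir, "mediated_graph.tsv"))
      out <- list()
      for (k in config$motif_sizes) {
        mk <- motif_significance(g, k, n_random = config$n_random_graphs,
                                 seed = config$seed + k)
        wt(mk, sprintf("motifs_k%d.tsv", k))
        out[[as.character(k)]] <- mk
      }
      out
    })
  }

  yaml::write_yaml(summary_counts, file.path(out_dir, "summary.yaml"))
  manifest <- list(config = unclass(config), config_hash = config_hash(config),
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("loopmed")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(de = de, loops = loops, screened = screened,
                 mediation = med, classified = classified,
                 summary = summary_counts, motifs = motifs))
}
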