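sign_chr <- function(v) ifelse(v > 0, "+", ifelse(v < 0, "-", "0"))

#' Classify a mediated loop by which effect is significant
#'
#' `M_T` when only the ACME is significant (the TF carries the effect),
#' `M_M` when only the ADE is (the miRNA acts directly), `M_TM` when both
#' are, `UNEXPLAINED` when neither is.  The three named classes are
#' mutually exclusive, so together with UNEXPLAINED they partition the
#' screened loops.
#'
#' @param result a `loop_mediation` object.
#' @param alpha significance level (default 0.05).
#' @param fc optional named numeric vector `c(mirna=, tf=, gene=)` of
#'   signed fold changes, carried through for the direction sub-tables.
#' @return one-row data.frame of class `loop_classification` with columns
#'   `mirna_id`, `tf_id`, `gene_id`, `cls`, `acme`, `ade`, `acme_p`,
#'   `ade_p`, `acme_sign`, `ade_sign`, `agreement`, `tg_follows`,
#'   `fc_mirna`, `fc_tf`, `fc_gene`.
#' @export
classify <- function(result, alpha = 0.05, fc = NULL) {
  stopifnot(inherits(result, "loop_mediation"))
  acme_sig <- result$acme_p <= alpha
  ade_sig <- result$ade_p <= alpha
  cls <- if (acme_sig && ade_sig) "M_TM"
         else if (acme_sig) "M_T"
         else if (ade_sig) "M_M"
         else "UNEXPLAINED"
  ids <- if (is.null(result$loop)) c(NA, NA, NA) else result$loop
  out <- data.frame(
    mirna_id = ids[1], tf_id = ids[2], gene_id = ids[3],
    cls = cls, acme = result$acme, ade = result$ade,
    acme_p = result$acme_p, ade_p = result$ade_p,
    acme_sign = sign_chr(result$acme), ade_sign = sign_chr(result$ade),
    agreement = "n/a", tg_follows = "n/a",
    fc_mirna = if (is.null(fc)) NA_real_ else unname(fc["mirna"]),
    fc_tf = if (is.null(fc)) NA_real_ else unname(fc["tf"]),
    fc_gene = if (is.null(fc)) NA_real_ else unname(fc["gene"]),
    stringsAsFactors = FALSE)
  class(out) <- c("loop_classification", class(out))
  out
}

#' Sub-classify an M_TM loop by agreement of ACME and ADE and by which
#' regulator the target gene follows
#'
#' Agreement is `supporting` when ACME and ADE share a sign (the mediator
#' reinforces the direct effect) and `opposing` otherwise.  For opposing
#' loops the target gene follows the miRNA when its fold-change sign
#' matches the miRNA's, else the TF; for supporting loops it follows both
#' when all three fold-change signs agree, else neither.
#'
#' @param c a one-row `loop_classification` with `cls == "M_TM"` and
#'   fold changes present.
#' @return the classification with `agreement` and `tg_follows` filled in.
#' @export
subclassify_mtm <- function(c) {
  stopifnot(inherits(c, "loop_classification"))
  if (c$cls != "M_TM") stop("subclassify_mtm applies to M_TM loops only")
  if (c$acme == 0 || c$ade == 0) {
    warning("zero effect: agreement undefined")
    c$agreement <- "n/a"
    return(c)
  }
  supporting <- sign(c$acme) == sign(c$ade)
  c$agreement <- if (supporting) "supporting" else "opposing"
  if (is.na(c$fc_mirna) || is.na(c$fc_tf) || is.na(c$fc_gene)) {
    c$tg_follows <- "n/a"
    return(c)
  }
  if (!supporting) {
    c$tg_follows <- if (sign(c$fc_gene) == sign(c$fc_mirna)) "miRNA" else "TF"
  } else {
    c$tg_follows <- if (sign(c$fc_gene) == sign(c$fc_mirna) &&
                        sign(c$fc_gene) == sign(c$fc_tf)) "both" else "neither"
  }
  c
}

#' Direction count tables for classified loops
#'
#' For the M_T class, counts loops whose TF and target gene fold changes
#' share a direction (up/up vs down/down); for the M_M class, loops whose
#' miRNA and target gene move oppositely (down-miRNA/up-gene vs
#' up-miRNA/down-gene).  Loops matching neither pattern are counted under
#' `other`, so the listed cells can sum to less than the class total.
#'
#' @param classified data.frame of stacked `loop_classification` rows.
#' @return list with components `M_T` and `M_M`, each a named count vector.
#' @export
direction_tables <- function(classified) {
  mt <- classified[classified$cls == "M_T", , drop = FALSE]
  mm <- classified[classified$cls == "M_M", , drop = FALSE]
  mt_up <- sum(mt$fc_tf > 0 & mt$fc_gene > 0, na.rm = TRUE)
  mt_dn <- sum(mt$fc_tf < 0 & mt$fc_gene < 0, na.rm = TRUE)
  mm_du <- sum(mm$fc_mirna < 0 & mm$fc_gene > 0, na.rm = TRUE)
  mm_ud <- sum(mm$fc_mirna > 0 & mm$fc_gene < 0, na.rm = TRUE)
  list(
    M_T = c(up_tf_up_tg = mt_up, down_tf_down_tg = mt_dn,
            other = nrow(mt) - mt_up - mt_dn, total = nrow(mt)),
    M_M = c(down_mirna_up_tg = mm_du, up_mirna_down_tg = mm_ud,
            other = nrow(mm) - mm_du - mm_ud, total = nrow(mm)))
}

#' Extract the k highest and k lowest ACME and ADE per loop class
#'
#' @param results data.frame with columns `mirna_id`, `tf_id`, `gene_id`,
#'   `cls`, `acme`, `ade` (stacked classifications).
#' @param k how many loops per extreme (default 5); classes smaller than k
#'   return all their loops, flagged `short = TRUE`.
#' @return data.frame with columns `cls`, `effect`, `extreme`, `rank`,
#'   the loop ids, `value` and `short`.
#' @export
top_effects <- function(results, k = 5) {
  out <- list()
  loop_key <- paste(results$mirna_id, results$tf_id, results$gene_id)
  for (cls in sort(unique(results$cls))) {
    sub <- results[results$cls == cls, , drop = FALSE]
    key <- loop_key[results$cls == cls]
    short <- nrow(sub) < k
    kk <- min(k, nrow(sub))
    for (effect in c("acme", "ade")) {
      v <- sub[[effect]]
      for (extreme in c("highest", "lowest")) {
        ord <- if (extreme == "highest") order(-v, key) else order(v, key)
        sel <- ord[seq_len(kk)]
        out[[length(out) + 1]] <- data.frame(
          cls = cls, effect = effect, extreme = extreme, rank = seq_len(kk),
          mirna_id = sub$mirna_id[sel], tf_id = sub$tf_id[sel],
          gene_id = sub$gene_id[sel], value = v[sel], short = short,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
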