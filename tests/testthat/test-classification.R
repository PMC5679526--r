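# builds a loop_mediation-shaped stub with prescribed effects and p-values
stub_result <- function(acme, ade, acme_p, ade_p,
                        loop = c("m1", "t1", "g1")) {
  structure(list(loop = loop, acme = acme, ade = ade,
                 acme_p = acme_p, ade_p = ade_p),
            class = "loop_mediation")
}

test_that("classification follows the two-significance rule exactly", {
  expect_equal(classify(stub_result(1, 1, 0.01, 0.50))$cls, "M_T")
  expect_equal(classify(stub_result(1, 1, 0.50, 0.01))$cls, "M_M")
  expect_equal(classify(stub_result(1, 1, 0.01, 0.01))$cls, "M_TM")
  expect_equal(classify(stub_result(1, 1, 0.50, 0.50))$cls, "UNEXPLAINED")
  # boundary: p exactly at alpha counts as significant
  expect_equal(classify(stub_result(1, 1, 0.05, 1))$cls, "M_T")
  # alpha is respected
  expect_equal(classify(stub_result(1, 1, 0.04, 0.5), alpha = 0.01)$cls,
               "UNEXPLAINED")
  cl <- classify(stub_result(-2, 0.5, 0.01, 0.01),
                 fc = c(mirna = 4, tf = -4, gene = -4))
  expect_equal(cl$acme_sign, "-")
  expect_equal(cl$ade_sign, "+")
  expect_equal(cl$fc_tf, -4)
})

test_that("every p-value pair lands in exactly one class", {
  set.seed(10)
  for (i in 1:50) {
    cl <- classify(stub_result(rnorm(1), rnorm(1), runif(1), runif(1)))
    expect_true(cl$cls %in% c("M_T", "M_M", "M_TM", "UNEXPLAINED"))
    expect_equal(nrow(cl), 1)
  }
})

test_that("M_TM subclassification separates supporting from opposing loops
           and assigns which regulator the gene follows", {
  mk <- function(acme, ade, fc) {
    cl <- classify(stub_result(acme, ade, 0.01, 0.01), fc = fc)
    subclassify_mtm(cl)
  }
  # opposing, gene follows the miRNA (shared fold-change sign)
  s1 <- mk(2, -1, c(mirna = 4, tf = -4, gene = 4))
  expect_equal(s1$agreement, "opposing")
  expect_equal(s1$tg_follows, "miRNA")
  # opposing, gene follows the TF
  s2 <- mk(-2, 1, c(mirna = 4, tf = -4, gene = -4))
  expect_equal(s2$agreement, "opposing")
  expect_equal(s2$tg_follows, "TF")
  # supporting, all three move together
  s3 <- mk(1.5, 0.5, c(mirna = 4, tf = 4, gene = 4))
  expect_equal(s3$agreement, "supporting")
  expect_equal(s3$tg_follows, "both")
  # supporting, signs split
  s4 <- mk(-1.5, -0.5, c(mirna = 4, tf = -4, gene = 4))
  expect_equal(s4$agreement, "supporting")
  expect_equal(s4$tg_follows, "neither")
  # guards
  expect_error(subclassify_mtm(classify(stub_result(1, 1, 0.5, 0.5))),
               "M_TM")
  expect_warning(mk(0, 1, c(mirna = 4, tf = 4, gene = 4)), "zero effect")
  s5 <- mk(1, 1, c(mirna = NA, tf = 4, gene = 4))
  expect_equal(s5$tg_follows, "n/a")
})

test_that("direction tables match a hand count and sum to the class totals", {
  rows <- rbind(
    classify(stub_result(1, 1, .01, .5, c("m1", "t1", "g1")),
             fc = c(mirna = -4, tf = 4, gene = 4)),     # M_T up/up
    classify(stub_result(1, 1, .01, .5, c("m2", "t2", "g2")),
             fc = c(mirna = 4, tf = -4, gene = -4)),    # M_T down/down
    classify(stub_result(1, 1, .01, .5, c("m3", "t3", "g3")),
             fc = c(mirna = 4, tf = -4, gene = 4)),     # M_T other
    classify(stub_result(1, 1, .5, .01, c("m4", "t4", "g4")),
             fc = c(mirna = -4, tf = 4, gene = 4)),     # M_M down-mi/up-g
    classify(stub_result(1, 1, .5, .01, c("m5", "t5", "g5")),
             fc = c(mirna = 4, tf = 4, gene = -4)))     # M_M up-mi/down-g
  dt <- direction_tables(rows)
  expect_equal(dt$M_T,
               c(up_tf_up_tg = 1, down_tf_down_tg = 1, other = 1, total = 3))
  expect_equal(dt$M_M,
               c(down_mirna_up_tg = 1, up_mirna_down_tg = 1, other = 0,
                 total = 2))
  # random property: listed cells never exceed the class total
  set.seed(20)
  rnd <- do.call(rbind, lapply(1:40, function(i)
    classify(stub_result(rnorm(1), rnorm(1), runif(1), runif(1),
                         paste0(c("m", "t", "g"), i)),
             fc = sample(c(-4, 4), 3, replace = TRUE) |>
               (\(s) c(mirna = s[1], tf = s[2], gene = s[3]))())))
  dtr <- direction_tables(rnd)
  for (tab in dtr) {
    expect_gte(tab[["other"]], 0)
    expect_equal(sum(tab[1:3]), tab[["total"]])
  }
})

test_that("top effects agree with a sort-based oracle and flag short
           classes", {
  set.seed(30)
  res <- data.frame(mirna_id = paste0("m", 1:20), tf_id = paste0("t", 1:20),
                    gene_id = paste0("g", 1:20),
                    cls = rep(c("M_T", "M_M"), each = 10),
                    acme = rnorm(20), ade = rnorm(20),
                    stringsAsFactors = FALSE)
  top <- top_effects(res, k = 5)
  sub <- res[res$cls == "M_T", ]
  want <- sub$acme[order(-sub$acme)][1:5]
  got <- top$value[top$cls == "M_T" & top$effect == "acme" &
                     top$extreme == "highest"]
  expect_equal(got, want)
  want_lo <- sub$ade[order(sub$ade)][1:5]
  got_lo <- top$value[top$cls == "M_T" & top$effect == "ade" &
                        top$extreme == "lowest"]
  expect_equal(got_lo, want_lo)
  expect_false(any(top$short))
  # a class smaller than k returns all rows, flagged short
  small <- res[c(1:2, 11:20), ]
  tops <- top_effects(small, k = 5)
  expect_true(all(tops$short[tops$cls == "M_T"]))
  expect_equal(sum(tops$cls == "M_T" & tops$effect == "acme" &
                     tops$extreme == "highest"), 2)
  # ties broken lexicographically by loop id
  tie <- data.frame(mirna_id = c("mB", "mA"), tf_id = c("t", "t"),
                    gene_id = c("g", "g"), cls = "M_T",
                    acme = c(1, 1), ade = c(0, 0))
  tt <- top_effects(tie, k = 1)
  expect_equal(tt$mirna_id[tt$effect == "acme" & tt$extreme == "highest"],
               "mA")
})

test_that("end-to-end classification recovers planted loop classes", {
  ds <- generate_dataset(n_triads = c(M_T = 3, M_M = 3, M_TM = 3,
                                      `NULL` = 3),
                         n_samples = 60, noise_sd = 0.4, seed = 33)
  inj <- ds$mirna_expr$meta$condition == "injured"
  hits <- 0
  for (i in seq_len(nrow(ds$truth))) {
    tr <- ds$truth[i, ]
    x <- ds$mirna_expr$values[tr$mirna_id, inj]
    m <- ds$tf_expr$values[tr$tf_id, inj]
    y <- ds$gene_expr$values[tr$gene_id, inj]
    res <- mediate_loop(x, m, y, n_boot = 300, seed = 100 + i,
                        loop = c(tr$mirna_id, tr$tf_id, tr$gene_id))
    cl <- classify(res)
    want <- if (tr$intended_class == "NULL") "UNEXPLAINED"
            else tr$intended_class
    if (cl$cls == want) hits <- hits + 1
  }
  expect_gte(hits, 10)   # at least 10 of the 12 planted classes recovered
})
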