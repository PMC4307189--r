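test_that("condition means average replicate samples per (condition, dose)", {
  vals <- matrix(c(10, 20, 30, 5, 7, 100), 1, 6)
  em <- make_expr(rbind(vals, vals * 2),
                  condition = rep(c("parental", "resistant"), each = 3),
                  dose = c(0, 0, 1, 0, 1, 1))
  prof <- condition_means(em)
  expect_equal(prof$means[1, "parental_0"], 15)  # mean(10, 20)
  expect_equal(prof$means[1, "parental_1"], 30)  # singleton passes through
  expect_equal(prof$means[1, "resistant_1"], mean(c(7, 100)))
  expect_equal(prof$conditions$condition, c("parental", "parental",
                                            "resistant", "resistant"))

  set.seed(61)
  em2 <- make_expr(matrix(rnorm(5 * 12), 5, 12),
                   condition = rep(c("parental", "resistant"), each = 6),
                   dose = rep(c(0, 0.1, 1), 4))
  prof2 <- condition_means(em2)
  grp <- paste(sample_info(em2)$condition, sample_info(em2)$dose, sep = "_")
  for (cn in colnames(prof2$means))
    expect_equal(prof2$means[, cn],
                 rowMeans(unclass(em2)[, grp == cn, drop = FALSE]))
})

test_that("heatmap normalization z-scores then scales to unit max-abs", {
  em <- make_expr(rbind(c(1, 2, 3), c(5, 5, 5), c(0, 10, 20)),
                  condition = c("parental", "parental", "resistant"),
                  dose = c(0, 1, 1))
  # one sample per condition group: means == values
  prof <- normalize_profile(condition_means(em))
  expect_equal(unname(prof$normalized[1, ]), c(-1, 0, 1))
  expect_equal(unname(prof$normalized[2, ]), c(0, 0, 0))  # constant guard
  expect_equal(unname(prof$normalized[3, ]), c(-1, 0, 1))
  expect_true(all(apply(abs(prof$normalized[c(1, 3), ]), 1, max) == 1))
  # invariance to per-gene positive affine rescaling of the means
  em2 <- make_expr(rbind(c(1, 2, 3) * 7 + 100, c(5, 5, 5), c(0, 10, 20)),
                   condition = c("parental", "parental", "resistant"),
                   dose = c(0, 1, 1))
  prof2 <- normalize_profile(condition_means(em2))
  expect_equal(prof2$normalized, prof$normalized, tolerance = 1e-12)
})

test_that("up-regulated pair selection requires both genes to increase", {
  em <- make_expr(rbind(c(87.71, 96.84), c(76.59, 78.6), c(100, 90)),
                  genes = c("AKT2", "MAML2", "DOWN"),
                  condition = c("parental", "resistant"), dose = c(0, 0))
  prof <- condition_means(em)
  tb <- data.frame(gene_i = c("AKT2", "AKT2"), gene_j = c("MAML2", "DOWN"),
                   pathway_j = c("Notch", "Wnt"), odds = c(16.67, 20),
                   stringsAsFactors = FALSE)
  got <- select_upregulated_pairs(tb, prof)
  expect_equal(nrow(got$table), 1L)
  expect_equal(got$table$gene_j, "MAML2")  # both genes up: 87.71->96.84, 76.59->78.6
  expect_setequal(got$genes, c("AKT2", "MAML2"))
  # subset of the input and idempotent
  again <- select_upregulated_pairs(got$table, prof)
  expect_equal(again$table, got$table)
  empty <- select_upregulated_pairs(tb[0, ], prof)
  expect_equal(nrow(empty$table), 0L)
})

test_that("fold-change reversal selects sign-flipped treatment responses", {
  # gene1: parental 1uM doubles (lfc +1), resistant 1uM halves vs parental
  # basal (lfc -1) -> selected. gene2: same sign -> not selected.
  # gene3: parental lfc exactly 0 -> no dysregulation -> not selected.
  par <- rbind(g1 = c(10, 20), g2 = c(10, 20), g3 = c(10, 10))
  res <- rbind(g1 = c(12, 5), g2 = c(11, 15), g3 = c(4, 5))
  cond <- make_paired_conditions(par, res, doses = c(0, 1), replicates = c(1, 1))
  got <- fold_change_reversal(cond$parental, cond$resistant)
  expect_identical(got$genes, "g1")
  expect_equal(got$details$replicate, 1L)
  # down-in-parental / up-in-resistant direction also counts
  par2 <- rbind(g1 = c(10, 5))
  res2 <- rbind(g1 = c(10, 21))
  cond2 <- make_paired_conditions(par2, res2, doses = c(0, 1),
                                  replicates = c(1, 1))
  expect_identical(fold_change_reversal(cond2$parental, cond2$resistant)$genes,
                   "g1")
})

test_that("reversal needs consistency across all doses within one replicate", {
  # two treatment doses: parental up at both, resistant down at both -> hit
  par <- rbind(g1 = c(10, 20, 40, 10, 11, 9), g2 = c(10, 20, 5, 10, 20, 40))
  res <- rbind(g1 = c(10, 5, 2, 10, 12, 13), g2 = c(10, 5, 2, 10, 20, 40))
  cond <- make_paired_conditions(par, res,
                                 doses = rep(c(0, 0.1, 1), 2),
                                 replicates = rep(c(1, 2), each = 3))
  got <- fold_change_reversal(cond$parental, cond$resistant)
  # g1 replicate 1 qualifies; g2's parental doses disagree in sign in rep 1
  # and resistant matches parental sign in rep 2
  expect_identical(got$genes, "g1")
  # nonpositive values make the record undefined, with a warning
  par_bad <- rbind(g1 = c(10, -20))
  res_bad <- rbind(g1 = c(10, 5))
  cond_bad <- make_paired_conditions(par_bad, res_bad, doses = c(0, 1),
                                     replicates = c(1, 1))
  expect_warning(out <- fold_change_reversal(cond_bad$parental,
                                             cond_bad$resistant),
                 "skipped")
  expect_length(out$genes, 0L)
})

test_that("reversal screen direction flips when condition labels swap", {
  par <- rbind(g1 = c(10, 20))
  res <- rbind(g1 = c(10, 5))
  cond <- make_paired_conditions(par, res, doses = c(0, 1), replicates = c(1, 1))
  fwd <- fold_change_reversal(cond$parental, cond$resistant)
  # swapping roles keeps g1 selected (signs strictly opposite either way)
  swapped <- make_paired_conditions(res, par, doses = c(0, 1),
                                    replicates = c(1, 1))
  bwd <- fold_change_reversal(swapped$parental, swapped$resistant)
  expect_identical(fwd$genes, bwd$genes)
})
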