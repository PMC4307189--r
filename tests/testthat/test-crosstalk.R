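test_that("odds ratios reproduce the worked table rows and edge cases", {
  expect_equal(round(odds_ratio(0.5, 0.03), 2), 16.67)
  expect_equal(odds_ratio(0.5, 0.04), 12.5)
  expect_equal(odds_ratio(0.37, 0.37), 1.0)
  expect_identical(odds_ratio(0.2, 0), Inf)
  expect_warning(z <- odds_ratio(0, 0), "defined as 0")
  expect_equal(z, 0)
  expect_error(odds_ratio(1.2, 0.5), "\\[0, 1\\]")
  expect_error(odds_ratio(0.5, -0.1), "\\[0, 1\\]")
  # scale consistency: common rescaling cancels
  set.seed(51)
  p <- runif(20, 0.01, 0.5); q <- runif(20, 0.01, 0.5)
  expect_equal(odds_ratio(0.9 * p, 0.9 * q), odds_ratio(p, q))
})

test_that("resistant-pair filtering applies both inclusive thresholds", {
  genes <- c("A", "B", "C")
  mk <- function(ab, ac, bc) {
    m <- matrix(0, 3, 3, dimnames = list(genes, genes))
    m[1, 2] <- m[2, 1] <- ab; m[1, 3] <- m[3, 1] <- ac
    m[2, 3] <- m[3, 2] <- bc
    m
  }
  er <- mk(0.5, 0.4, 0.5)
  ep <- mk(0.03, 0.01, 0.05)
  got <- filter_resistant_pairs(er, ep)
  # A-B passes (odds 16.67, pr 0.5 at the boundary is inclusive);
  # A-C fails pr_R despite odds 40; B-C fails the odds cutoff (10 exactly passes)
  keys <- unordered_keys(got$gene_i, got$gene_j)
  expect_setequal(keys, c("A::B", "B::C"))
  expect_equal(got$odds[got$gene_i == "B"], 10)

  # brute-force double-loop oracle on random matrices
  set.seed(52)
  n <- 15
  ids <- sprintf("g%02d", 1:n)
  r <- matrix(runif(n * n), n, n); r <- (r + t(r)) / 2; diag(r) <- 0
  p <- matrix(runif(n * n), n, n); p <- (p + t(p)) / 2; diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(ids, ids)
  got2 <- filter_resistant_pairs(r, p, odds_min = 2, pr_min = 0.4)
  manual <- character()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (r[i, j] / p[i, j] >= 2 && r[i, j] >= 0.4)
      manual <- c(manual, paste(ids[i], ids[j], sep = "::"))
  expect_setequal(unordered_keys(got2$gene_i, got2$gene_j), manual)
  # monotone in both thresholds
  expect_lte(nrow(filter_resistant_pairs(r, p, odds_min = 3, pr_min = 0.4)),
             nrow(got2))
  expect_lte(nrow(filter_resistant_pairs(r, p, odds_min = 2, pr_min = 0.6)),
             nrow(got2))
})

test_that("cross-talk enumeration applies the same-pathway exclusions", {
  coll <- pathway_collection(list(EGFR = c("A", "B"), Notch = c("B", "C")),
                             "EGFR")
  got <- enumerate_crosstalk_pairs(coll, c("A", "B", "C"))
  expect_equal(nrow(got), 1L)
  expect_equal(got$gene_i, "A")
  expect_equal(got$gene_j, "C")
  expect_equal(got$pathway_j, "Notch")

  # same unordered pair counted once per other pathway
  coll2 <- pathway_collection(list(EGFR = "A", Q1 = "X", Q2 = "X"), "EGFR")
  got2 <- enumerate_crosstalk_pairs(coll2, c("A", "X"))
  expect_equal(nrow(got2), 2L)
  expect_equal(length(unique(unordered_keys(got2$gene_i, got2$gene_j))), 1L)

  coll3 <- pathway_collection(list(EGFR = "A", Q = "X"), "EGFR")
  got3 <- enumerate_crosstalk_pairs(coll3, c("A", "X"))
  expect_equal(got3$gene_i, "A"); expect_equal(got3$gene_j, "X")

  # the universe restricts both endpoints
  got4 <- enumerate_crosstalk_pairs(coll, c("A", "B"))
  expect_equal(nrow(got4), 0L)
  expect_error(enumerate_crosstalk_pairs(coll, c("Z")), "no genes")
  # per-record contract: gene_i in the pathway of interest, gene_j in pathway_j,
  # never both in one pathway
  set.seed(53)
  genes <- sprintf("g%02d", 1:20)
  coll5 <- make_toy_pathways(genes, n_pathways = 4, sizes = 5, overlap = 2,
                             seed = 3)
  got5 <- enumerate_crosstalk_pairs(coll5, genes)
  poi <- coll5$pathways[[coll5$pathway_of_interest]]
  for (k in seq_len(nrow(got5))) {
    expect_true(got5$gene_i[k] %in% poi)
    q <- coll5$pathways[[got5$pathway_j[k]]]
    expect_true(got5$gene_j[k] %in% q)
    expect_false(got5$gene_i[k] %in% q && got5$gene_j[k] %in% q)
    expect_false(got5$gene_i[k] %in% poi && got5$gene_j[k] %in% poi)
  }
})

test_that("intersection joins on unordered pairs and sorts by odds", {
  cand <- data.frame(gene_i = c("A", "D"), gene_j = c("C", "A"),
                     pr_R = c(0.6, 0.9), pr_P = c(0.05, 0.03),
                     odds = c(12, 30), stringsAsFactors = FALSE)
  xt <- data.frame(gene_i = c("A", "A", "A"), gene_j = c("C", "D", "E"),
                   pathway_j = c("Notch", "Wnt", "Wnt"),
                   stringsAsFactors = FALSE)
  got <- intersect_crosstalks(cand, xt)
  expect_equal(nrow(got), 2L)
  expect_equal(got$gene_j, c("D", "C"))  # descending odds
  expect_equal(got$odds, c(30, 12))
  expect_equal(nrow(intersect_crosstalks(cand[0, ], xt)), 0L)

  # randomized set-join oracle
  set.seed(54)
  ids <- sprintf("g%02d", 1:12)
  cand2 <- data.frame(gene_i = sample(ids, 25, TRUE),
                      gene_j = sample(ids, 25, TRUE),
                      stringsAsFactors = FALSE)
  cand2 <- cand2[cand2$gene_i != cand2$gene_j, ]
  cand2 <- cand2[!duplicated(unordered_keys(cand2$gene_i, cand2$gene_j)), ]
  cand2$pr_R <- runif(nrow(cand2)); cand2$pr_P <- runif(nrow(cand2))
  cand2$odds <- cand2$pr_R / cand2$pr_P
  xt2 <- data.frame(gene_i = sample(ids, 30, TRUE),
                    gene_j = sample(ids, 30, TRUE),
                    pathway_j = sample(c("P1", "P2"), 30, TRUE),
                    stringsAsFactors = FALSE)
  xt2 <- xt2[xt2$gene_i != xt2$gene_j, ]
  got2 <- intersect_crosstalks(cand2, xt2)
  in_cand <- unordered_keys(xt2$gene_i, xt2$gene_j) %in%
    unordered_keys(cand2$gene_i, cand2$gene_j)
  expect_equal(nrow(got2), sum(in_cand))
  expect_setequal(paste(got2$gene_i, got2$gene_j, got2$pathway_j),
                  paste(xt2$gene_i, xt2$gene_j, xt2$pathway_j)[in_cand])
})

test_that("summaries count totals, distinct pairs, pathways and shared pairs", {
  tb <- data.frame(gene_i = c("A", "A"), gene_j = c("C", "C"),
                   pathway_j = c("Notch", "Wnt"),
                   odds = c(12, 12), stringsAsFactors = FALSE)
  s <- summarize_crosstalks(tb)
  expect_equal(s$n_crosstalks, 2L)
  expect_equal(s$n_distinct_pairs, 1L)
  expect_equal(s$n_other_pathways, 2L)
  s0 <- summarize_crosstalks(tb[0, ])
  expect_equal(unlist(s0[c("n_crosstalks", "n_distinct_pairs",
                           "n_other_pathways")]),
               c(n_crosstalks = 0L, n_distinct_pairs = 0L,
                 n_other_pathways = 0L))
  expect_gte(s$n_crosstalks, s$n_distinct_pairs)

  # multi-source overlap equals a brute-force multiset intersection
  t1 <- data.frame(gene_i = c("A", "A"), gene_j = c("B", "C"),
                   pathway_j = "P", stringsAsFactors = FALSE)
  t2 <- data.frame(gene_i = c("B", "A"), gene_j = c("A", "D"),
                   pathway_j = "Q", stringsAsFactors = FALSE)
  t3 <- data.frame(gene_i = "A", gene_j = "D", pathway_j = "R",
                   stringsAsFactors = FALSE)
  ms <- summarize_crosstalks(list(r = t1, k = t2, w = t3))
  expect_equal(ms$pairs_in_2plus_sources, 2L)  # A::B (t1,t2) and A::D (t2,t3)
  expect_equal(ms$n_distinct_pairs, 3L)
})

test_that("GMT and per-file pathway encodings round-trip", {
  coll <- pathway_collection(list(EGFR = c("A", "B"), Notch = c("C", "D")),
                             "EGFR", name = "demo")
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, gmt)
  back <- read_gmt(gmt, "EGFR")
  expect_equal(back$pathways, coll$pathways)

  d <- withr::local_tempdir()
  writeLines("A\tB", file.path(d, "EGFR.txt"))
  writeLines(c("C", "D"), file.path(d, "Notch.txt"))
  got <- read_pathway_files(list.files(d, full.names = TRUE), "EGFR")
  expect_setequal(got$pathways$EGFR, c("A", "B"))
  expect_setequal(got$pathways$Notch, c("C", "D"))
  expect_error(pathway_collection(list(A = character(), B = "x"), "B"),
               "non-empty")
  expect_error(pathway_collection(list(B = "x"), "A"), "not among")
})
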