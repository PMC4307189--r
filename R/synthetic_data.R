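#' Draw coupled propensity pairs from the hierarchical prior
#'
#' g independent bivariate-normal draws with mean zero and covariance `Sigma`,
#' the generative form of the prior coupling each gene's (resistant, parental)
#' propensity pair.
#'
#' @param g number of genes.
#' @param Sigma 2x2 symmetric positive-definite covariance.
#' @param seed integer seed.
#' @return g x 2 matrix, columns `R` and `P`.
#' @export
simulate_alpha_pairs <- function(g, Sigma, seed) {
  check_spd2(Sigma, "Sigma")
  set.seed(seed)
  z <- matrix(rnorm(g * 2L), g, 2L)
  out <- z %*% chol(Sigma)
  colnames(out) <- c("R", "P")
  out
}

#' Simulate a network from the undirected p1-model
#'
#' Each dyad i < j is independently present with probability
#' `edge_probability(theta, alpha[i], alpha[j])`.
#'
#' @param theta global density parameter.
#' @param alpha numeric vector of per-gene propensities.
#' @param seed integer seed.
#' @param condition provenance label for the resulting network.
#' @param gene_ids optional gene symbols (defaults to `g1..gn`).
#' @return a `RelationshipNetwork`.
#' @export
simulate_p1_network <- function(theta, alpha, seed,
                                condition = c("resistant", "parental"),
                                gene_ids = NULL) {
  condition <- match.arg(condition)
  g <- length(alpha)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%02d", seq_len(g))
  set.seed(seed)
  p <- edge_probability(theta, outer(alpha, rep(0, g), "+"),
                        outer(rep(0, g), alpha, "+"))
  adj <- matrix(0L, g, g)
  ut <- upper.tri(adj)
  adj[ut] <- rbinom(sum(ut), 1L, p[ut])
  adj <- adj + t(adj)
  relationship_network(gene_ids, adj, NA_real_, condition)
}

#' Default generation settings of the synthetic two-condition experiment
#'
#' The emulated study: two conditions (parental / resistant), three lapatinib
#' doses (0, 0.1, 1 uM) with 2 replicates each (6 samples per condition),
#' g = 60 genes of which 3 blocks of 6 share a latent factor in *both*
#' conditions, 10 planted cross-talk pairs (20 genes) share one latent
#' "compensatory module" factor only in the resistant condition (plus a
#' positive resistant mean shift so the up-regulation screen can find them),
#' 8 background genes respond to dose with opposite slopes in the two
#' conditions (food for the fold-change-reversal screen), and the rest are
#' independent noise.
#'
#' @param g total genes.
#' @param n_blocks,block_size blocks sharing a factor in both conditions.
#' @param n_planted_pairs resistant-only cross-talk pairs.
#' @param doses treatment doses; 0 is basal.
#' @param n_replicates replicates per dose per condition.
#' @param baseline mean expression level (platform units).
#' @param factor_sd latent-factor standard deviation (units of expression).
#' @param noise_sd independent per-gene noise standard deviation.
#' @param planted_shift additive up-shift of planted genes in resistant
#'   samples.
#' @param n_responders dose-responding background genes.
#' @param responder_slope expression change per unit dose (sign flips between
#'   conditions).
#' @param correlate,shift flags disabling the planted correlation or the
#'   planted mean shift.
#' @return list of settings for [simulate_expression_pair()].
#' @export
synthetic_defaults <- function(g = 60L, n_blocks = 3L, block_size = 6L,
                               n_planted_pairs = 10L,
                               doses = c(0, 0.1, 1), n_replicates = 2L,
                               baseline = 100, factor_sd = 10, noise_sd = 1,
                               planted_shift = 15, n_responders = 8L,
                               responder_slope = 30,
                               correlate = TRUE, shift = TRUE) {
  n_block_genes <- n_blocks * block_size
  n_planted_genes <- 2L * n_planted_pairs
  if (n_block_genes + n_planted_genes + n_responders > g)
    stop("g too small for the requested blocks, planted pairs and responders")
  list(g = g, n_blocks = n_blocks, block_size = block_size,
       n_planted_pairs = n_planted_pairs, doses = doses,
       n_replicates = n_replicates, baseline = baseline,
       factor_sd = factor_sd, noise_sd = noise_sd,
       planted_shift = planted_shift, n_responders = n_responders,
       responder_slope = responder_slope, correlate = correlate,
       shift = shift)
}

#' Simulate a two-condition expression experiment with planted structure
#'
#' Generates parental and resistant expression matrices under the latent
#' factor scheme of [synthetic_defaults()] together with the ground truth
#' needed by recovery tests.
#'
#' @param settings list from [synthetic_defaults()].
#' @param seed integer seed.
#' @return list with `parental` and `resistant` (`ExpressionMatrix`) and
#'   `truth` (class `SyntheticTruth`): gene roles, `planted_pairs` (two-column
#'   character matrix), `block_assignments`, responder genes, settings, seed.
#' @export
simulate_expression_pair <- function(settings = synthetic_defaults(), seed) {
  set.seed(seed)
  g <- settings$g
  genes <- sprintf("G%03d", seq_len(g))
  n_block_genes <- settings$n_blocks * settings$block_size
  block_of <- rep(NA_integer_, g)
  block_of[seq_len(n_block_genes)] <-
    rep(seq_len(settings$n_blocks), each = settings$block_size)
  planted_idx <- n_block_genes + seq_len(2L * settings$n_planted_pairs)
  first_idx <- planted_idx[seq_len(settings$n_planted_pairs)]
  second_idx <- planted_idx[-seq_len(settings$n_planted_pairs)]
  bg_idx <- setdiff(seq_len(g), c(which(!is.na(block_of)), planted_idx))
  responder_idx <- bg_idx[seq_len(settings$n_responders)]
  dose_per_sample <- rep(settings$doses, each = settings$n_replicates)
  repl <- rep(seq_len(settings$n_replicates), times = length(settings$doses))
  n_s <- length(dose_per_sample)

  gen_condition <- function(cond) {
    vals <- settings$baseline +
      matrix(rnorm(g * n_s, sd = settings$noise_sd), g, n_s)
    for (b in seq_len(settings$n_blocks)) {
      f <- rnorm(n_s, sd = settings$factor_sd)
      vals[which(block_of == b), ] <-
        vals[which(block_of == b), , drop = FALSE] +
        matrix(f, settings$block_size, n_s, byrow = TRUE)
    }
    if (cond == "resistant") {
      if (settings$correlate) {
        f <- rnorm(n_s, sd = settings$factor_sd)
        vals[planted_idx, ] <- vals[planted_idx, , drop = FALSE] +
          matrix(f, length(planted_idx), n_s, byrow = TRUE)
      }
      if (settings$shift)
        vals[planted_idx, ] <- vals[planted_idx, ] + settings$planted_shift
    }
    slope <- if (cond == "parental") settings$responder_slope
    else -settings$responder_slope
    vals[responder_idx, ] <- vals[responder_idx, , drop = FALSE] +
      outer(rep(slope, length(responder_idx)), dose_per_sample)
    dimnames(vals) <- list(genes,
                           sprintf("%s_d%g_r%d", substr(cond, 1, 3),
                                   dose_per_sample, repl))
    expression_matrix(vals, condition = rep(cond, n_s),
                      dose = dose_per_sample, replicate = repl)
  }

  parental <- gen_condition("parental")
  resistant <- gen_condition("resistant")
  truth <- structure(list(
    planted_pairs = cbind(gene_i = genes[first_idx],
                          gene_j = genes[second_idx]),
    planted_genes = genes[planted_idx],
    first_genes = genes[first_idx],
    second_genes = genes[second_idx],
    block_assignments = setNames(block_of, genes),
    responder_genes = genes[responder_idx],
    background_genes = genes[setdiff(bg_idx, responder_idx)],
    settings = settings, seed = seed), class = "SyntheticTruth")
  list(parental = parental, resistant = resistant, truth = truth)
}

#' Build a toy pathway collection
#'
#' Without planted pairs: `n_pathways` other pathways of the requested sizes
#' drawn from `genes`, sharing `overlap` members with the pathway of interest
#' chain-wise (overlap 0 gives pairwise-disjoint pathways). With a
#' `SyntheticTruth`, the collection mirrors the overlapping-membership
#' structure of curated pathway databases in the way that matters for
#' cross-talk enumeration: the pathway of interest holds the first gene of
#' every planted pair, and the k-th other pathway holds the k-th pair's second
#' gene together with the *other* pairs' first genes (shared upstream
#' members), so the same-pathway exclusion rule leaves exactly the planted
#' pairs as candidate cross-talks among planted genes. A few unstructured
#' background genes are mixed into every partner pathway (none into the
#' pathway of interest, where a single filler gene would anchor a candidate
#' pair with every partner pathway).
#'
#' @param genes gene symbols to draw from.
#' @param n_pathways number of pathways beside the pathway of interest.
#' @param sizes integer vector (recycled) of other-pathway sizes.
#' @param overlap shared members between consecutive pathways (no-truth mode).
#' @param seed integer seed.
#' @param truth optional `SyntheticTruth` from [simulate_expression_pair()].
#' @param n_background_per_pathway background genes mixed into each pathway
#'   (truth mode).
#' @param poi_name name given to the pathway of interest.
#' @return a [pathway_collection()].
#' @export
make_toy_pathways <- function(genes, n_pathways = 5L, sizes = 6L, overlap = 0L,
                              seed = 1L, truth = NULL,
                              n_background_per_pathway = 2L,
                              poi_name = "pathway_of_interest") {
  set.seed(seed)
  if (!is.null(truth)) {
    np <- nrow(truth$planted_pairs)
    # filler members come from the unstructured background only: block and
    # dose-responder genes are deliberately (co-)regulated, and a propensity-
    # smoothing model cannot tell such hubs from planted ones -- membership
    # is the screen, so the toy membership must not offer them as partners
    pool <- truth$background_genes
    # the pathway of interest carries no filler: a filler gene there would
    # pair with every partner pathway, so one chance-correlated noise gene
    # (probability a few percent per gene at 6 samples) would dominate the
    # candidate set; filler in a partner pathway anchors O(1) pairs instead
    poi <- truth$first_genes
    paths <- setNames(vector("list", np), sprintf("pathway_%02d", seq_len(np)))
    for (k in seq_len(np)) {
      bg <- sample(pool, n_background_per_pathway)
      paths[[k]] <- c(truth$second_genes[k], truth$first_genes[-k], bg)
    }
    return(pathway_collection(c(setNames(list(poi), poi_name), paths),
                              poi_name, name = "toy"))
  }
  sizes <- rep_len(sizes, n_pathways + 1L)
  if (sum(sizes) - overlap * n_pathways > length(genes))
    stop("not enough genes for the requested pathway sizes")
  paths <- vector("list", n_pathways + 1L)
  pos <- 1L
  prev <- character()
  for (k in seq_len(n_pathways + 1L)) {
    n_new <- sizes[k] - if (k == 1L) 0L else min(overlap, length(prev))
    fresh <- genes[seq.int(pos, length.out = n_new)]
    pos <- pos + n_new
    shared <- if (k == 1L) character() else utils::head(prev, min(overlap, length(prev)))
    paths[[k]] <- c(shared, fresh)
    prev <- paths[[k]]
  }
  names(paths) <- c(poi_name, sprintf("pathway_%02d", seq_len(n_pathways)))
  pathway_collection(paths, poi_name, name = "toy")
}

#' Write synthetic inputs in the pipeline's on-disk formats
#'
#' Emits one combined probe-level-style expression TSV (gene level, identity
#' annotation), a sample map, a seed gene list (all genes), and the pathway
#' collection as GMT, plus the ground truth as JSON — everything
#' [run_pipeline()] reads.
#'
#' @param sim list from [simulate_expression_pair()].
#' @param dir output directory (created if needed).
#' @param pathways optional `PathwayCollection` (defaults to the truth-derived
#'   toy collection with seed `sim$truth$seed`).
#' @return named list of file paths.
#' @export
write_synthetic_inputs <- function(sim, dir, pathways = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comb <- cbind(unclass(sim$parental), unclass(sim$resistant))
  ip <- sample_info(sim$parental); ir <- sample_info(sim$resistant)
  sm <- rbind(ip, ir)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                sample_map = file.path(dir, "sample_map.tsv"),
                seeds = file.path(dir, "seed_genes.txt"),
                pathways = file.path(dir, "pathways.gmt"),
                truth = file.path(dir, "truth.json"))
  write_expression_table(
    expression_matrix(comb, condition = sm$condition, dose = sm$dose,
                      replicate = sm$replicate),
    paths$expression, feature_col = "gene_symbol")
  write.table(sm, paths$sample_map, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(rownames(comb), paths$seeds)
  if (is.null(pathways))
    pathways <- make_toy_pathways(rownames(comb), seed = sim$truth$seed,
                                  truth = sim$truth)
  write_gmt(pathways, paths$pathways)
  tr <- sim$truth
  jsonlite::write_json(
    list(planted_pairs = as.data.frame(tr$planted_pairs),
         planted_genes = tr$planted_genes,
         responder_genes = tr$responder_genes,
         seed = tr$seed),
    paths$truth, auto_unbox = TRUE, digits = NA)
  paths
}
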