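#' Odds ratio of resistant versus parental posterior edge probabilities
#'
#' The resistance score of a gene pair: the ratio of its posterior edge
#' probability in the resistant network to that in the parental network.
#' `pr_P = 0` with `pr_R > 0` gives `Inf` (sorts above any finite odds);
#' `pr_R = pr_P = 0` is defined as 0 with a warning.
#'
#' @param pr_R,pr_P posterior edge probabilities in `[0, 1]` (vectorized).
#' @return numeric vector of odds ratios (positive, possibly `Inf`).
#' @export
odds_ratio <- function(pr_R, pr_P) {
  if (any(pr_R < 0 | pr_R > 1, na.rm = FALSE) ||
      any(pr_P < 0 | pr_P > 1) || any(!is.finite(pr_R)) || any(!is.finite(pr_P)))
    stop("posterior probabilities must lie in [0, 1]")
  out <- pr_R / pr_P
  both_zero <- pr_R == 0 & pr_P == 0
  if (any(both_zero)) {
    warning("pr_R = pr_P = 0 for ", sum(both_zero),
            " pair(s); odds defined as 0")
    out[both_zero] <- 0
  }
  out
}

#' Select gene pairs with resistant-specific high edge probability
#'
#' Keeps unordered gene pairs whose odds ratio and resistant posterior edge
#' probability both meet their (inclusive) thresholds. The defaults are the
#' conservative cutoffs of the primary analysis (odds >= 10, pr_R >= 0.5);
#' `pr_min` is configurable because the validation analysis relaxed it to
#' 0.15.
#'
#' @param edge_prob_R,edge_prob_P symmetric posterior edge probability
#'   matrices with gene ids as dimnames (as produced by [gibbs_fit()]).
#' @param odds_min minimum odds ratio (inclusive), default 10.
#' @param pr_min minimum resistant probability (inclusive), default 0.5.
#' @return data.frame with columns `gene_i`, `gene_j` (each unordered pair
#'   once, i before j in matrix order), `pr_R`, `pr_P`, `odds`.
#' @export
filter_resistant_pairs <- function(edge_prob_R, edge_prob_P,
                                   odds_min = 10.0, pr_min = 0.5) {
  stopifnot(identical(dim(edge_prob_R), dim(edge_prob_P)),
            identical(rownames(edge_prob_R), rownames(edge_prob_P)))
  genes <- rownames(edge_prob_R)
  if (is.null(genes)) stop("edge probability matrices need gene dimnames")
  ut <- which(upper.tri(edge_prob_R), arr.ind = TRUE)
  pr_R <- edge_prob_R[ut]
  pr_P <- edge_prob_P[ut]
  odds <- suppressWarnings(odds_ratio(pr_R, pr_P))
  keep <- odds >= odds_min & pr_R >= pr_min
  data.frame(gene_i = genes[ut[keep, 1L]],
             gene_j = genes[ut[keep, 2L]],
             pr_R = pr_R[keep], pr_P = pr_P[keep], odds = odds[keep],
             stringsAsFactors = FALSE)
}

#' Assemble a pathway collection
#'
#' @param pathways named list of character vectors (pathway name -> gene
#'   symbols); every set must be non-empty.
#' @param pathway_of_interest name of the pathway whose cross-talks are sought
#'   (e.g. the EGFR/ErbB pathway); must be an element of `pathways`.
#' @param name source label (e.g. "Reactome").
#' @return object of class `PathwayCollection`.
#' @export
pathway_collection <- function(pathways, pathway_of_interest, name = "pathways") {
  if (!length(pathways) || is.null(names(pathways)) ||
      any(!nzchar(names(pathways))))
    stop("'pathways' must be a non-empty named list")
  if (any(vapply(pathways, length, 0L) == 0L))
    stop("every pathway gene set must be non-empty")
  if (!pathway_of_interest %in% names(pathways))
    stop("pathway_of_interest '", pathway_of_interest,
         "' is not among the pathways")
  pathways <- lapply(pathways, function(x) unique(as.character(x)))
  structure(list(name = name, pathways = pathways,
                 pathway_of_interest = pathway_of_interest),
            class = "PathwayCollection")
}

#' @export
print.PathwayCollection <- function(x, ...) {
  cat(sprintf("PathwayCollection '%s': %d pathways (pathway of interest: %s)\n",
              x$name, length(x$pathways), x$pathway_of_interest))
  invisible(x)
}

#' Read pathways from a GMT file
#'
#' One gene set per line: name, description, then member symbols,
#' tab-delimited.
#'
#' @param path GMT file path.
#' @param pathway_of_interest name of the pathway of interest in the file.
#' @param name source label (defaults to the file name).
#' @return a [pathway_collection()].
#' @export
read_gmt <- function(path, pathway_of_interest, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  pathway_collection(sets, pathway_of_interest, name)
}

#' Write a pathway collection as a GMT file
#' @param collection a `PathwayCollection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$pathways), function(nm) {
    paste(c(nm, "na", collection$pathways[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read one-pathway-per-file tab-delimited gene lists
#'
#' The alternative pathway encoding: each file holds the gene symbols of one
#' pathway (tab- or newline-delimited); the file name (without extension) is
#' the pathway name.
#'
#' @param paths character vector of file paths.
#' @param pathway_of_interest pathway (file) name of interest.
#' @param name source label.
#' @return a [pathway_collection()].
#' @export
read_pathway_files <- function(paths, pathway_of_interest, name = "pathways") {
  sets <- lapply(paths, function(p) {
    toks <- unlist(strsplit(readLines(p, warn = FALSE), "\t", fixed = TRUE))
    unique(trimws(toks[nzchar(trimws(toks))]))
  })
  names(sets) <- sub("\\.[^.]*$", "", basename(paths))
  pathway_collection(sets, pathway_of_interest, name)
}

#' Enumerate candidate cross-talk gene pairs
#'
#' A cross-talk candidate is a pair (gene_i, gene_j) with gene_i in the
#' pathway of interest and gene_j in some other pathway Q, both restricted to
#' `universe`; pairs whose two genes co-occur in the pathway of interest or
#' co-occur in Q are excluded (the same-pathway rule, applied per pathway).
#' The same unordered gene pair may appear under several `pathway_j` values,
#' which is why total and distinct cross-talk counts differ.
#'
#' @param collection a `PathwayCollection`.
#' @param universe character vector of genes under consideration (typically
#'   the network gene list).
#' @return data.frame with columns `gene_i`, `gene_j`, `pathway_j`.
#' @export
enumerate_crosstalk_pairs <- function(collection, universe) {
  universe <- unique(as.character(universe))
  poi_name <- collection$pathway_of_interest
  poi <- intersect(collection$pathways[[poi_name]], universe)
  if (!length(poi))
    stop("pathway of interest has no genes in the universe")
  others <- setdiff(names(collection$pathways), poi_name)
  res <- vector("list", length(others))
  for (k in seq_along(others)) {
    q <- intersect(collection$pathways[[others[k]]], universe)
    if (!length(q)) next
    grid <- expand.grid(gene_i = poi, gene_j = q, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[grid$gene_i != grid$gene_j, , drop = FALSE]
    # same-pathway exclusions: both in the pathway of interest, or both in Q
    both_poi <- grid$gene_j %in% poi
    both_q <- grid$gene_i %in% q
    grid <- grid[!both_poi & !both_q, , drop = FALSE]
    if (nrow(grid)) {
      grid$pathway_j <- others[k]
      res[[k]] <- grid
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene_i = character(), gene_j = character(),
                      pathway_j = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "::")
}

#' Intersect resistant pairs with cross-talk candidates
#'
#' One record per (pair, pathway_j) candidate whose unordered gene pair
#' passed [filter_resistant_pairs()]; attaches the posterior probabilities,
#' odds ratio and (optionally) condition-averaged expression of both genes.
#' Sorted by descending odds, then gene_i, gene_j (stable).
#'
#' @param candidates data.frame from [filter_resistant_pairs()].
#' @param crosstalks data.frame from [enumerate_crosstalk_pairs()].
#' @param profile optional `ConditionProfile` (see [condition_means()])
#'   supplying average expression columns `avg_ge_i_P`, `avg_ge_i_R`,
#'   `avg_ge_j_P`, `avg_ge_j_R`.
#' @return data.frame of cross-talk records with columns `gene_i`, `gene_j`,
#'   `pathway_j`, `pr_R`, `pr_P`, `odds` and, with a profile, the four
#'   average-expression columns.
#' @export
intersect_crosstalks <- function(candidates, crosstalks, profile = NULL) {
  key_c <- pair_key(candidates$gene_i, candidates$gene_j)
  key_x <- pair_key(crosstalks$gene_i, crosstalks$gene_j)
  hit <- match(key_x, key_c)
  out <- crosstalks[!is.na(hit), , drop = FALSE]
  idx <- hit[!is.na(hit)]
  out$pr_R <- candidates$pr_R[idx]
  out$pr_P <- candidates$pr_P[idx]
  out$odds <- candidates$odds[idx]
  if (!is.null(profile) && nrow(out)) {
    avg <- condition_average_ge(profile)
    out$avg_ge_i_P <- avg[out$gene_i, "parental"]
    out$avg_ge_i_R <- avg[out$gene_i, "resistant"]
    out$avg_ge_j_P <- avg[out$gene_j, "parental"]
    out$avg_ge_j_R <- avg[out$gene_j, "resistant"]
  }
  ord <- order(-out$odds, out$gene_i, out$gene_j, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a cross-talk table (or several, one per pathway source)
#'
#' @param tables a single cross-talk data.frame from [intersect_crosstalks()],
#'   or a named list of them (one per pathway collection).
#' @return list with `n_crosstalks`, `n_distinct_pairs`, `n_other_pathways`
#'   and, for multiple tables, `per_source` counts and `pairs_in_2plus_sources`
#'   (distinct unordered pairs present in at least two sources' tables).
#' @export
summarize_crosstalks <- function(tables) {
  single <- is.data.frame(tables)
  if (single) tables <- list(tables)
  counts <- lapply(tables, function(tb) {
    list(n_crosstalks = nrow(tb),
         n_distinct_pairs = length(unique(pair_key(tb$gene_i, tb$gene_j))),
         n_other_pathways = length(unique(tb$pathway_j)))
  })
  if (single) return(counts[[1L]])
  keysets <- lapply(tables, function(tb) unique(pair_key(tb$gene_i, tb$gene_j)))
  all_keys <- unlist(keysets)
  multi <- sum(table(all_keys) >= 2L)
  list(per_source = counts,
       n_crosstalks = sum(vapply(counts, `[[`, 0L, "n_crosstalks")),
       n_distinct_pairs = length(unique(all_keys)),
       pairs_in_2plus_sources = multi)
}
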