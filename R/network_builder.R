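#' Absolute Pearson correlation matrix over genes
#'
#' Entry (i, j) is the absolute sample Pearson correlation of gene rows i and j
#' across the matrix's samples. Pairs involving a zero-variance gene are
#' undefined (NA) and can never become edges; the diagonal is NA.
#'
#' @param expr gene-level `ExpressionMatrix` for one condition.
#' @return object of class `PccMatrix`: a symmetric numeric matrix in `[0, 1]`
#'   with NA for undefined pairs and the diagonal.
#' @export
abs_pcc_matrix <- function(expr) {
  if (ncol(expr) < 2L) stop("need at least 2 samples to compute correlations")
  if (ncol(expr) < 3L)
    stop("PCC over 2 samples is degenerate (always +/-1); need >= 3")
  if (ncol(expr) == 3L)
    warning("only 3 samples: correlation estimates will be very noisy")
  vals <- unclass(expr)
  sds <- apply(vals, 1L, sd)
  zerovar <- sds == 0
  if (any(zerovar))
    message(sum(zerovar), " zero-variance gene(s): their pairs are undefined ",
            "and will never be edges")
  r <- suppressWarnings(abs(cor(t(vals))))
  r[zerovar, ] <- NA_real_
  r[, zerovar] <- NA_real_
  diag(r) <- NA_real_
  structure(r, class = c("PccMatrix", "matrix"))
}

#' Quantile-based relationship threshold
#'
#' Returns the `(1 - top_fraction)` empirical quantile (linear interpolation of
#' order statistics, R type 7) of the defined upper-triangle absolute PCC
#' values, so that approximately `top_fraction` of gene pairs lie strictly
#' above it.
#'
#' @param pcc a `PccMatrix`.
#' @param top_fraction fraction of pairs to call relationships, in (0, 1).
#' @return scalar threshold in `[0, 1]`.
#' @export
select_threshold <- function(pcc, top_fraction) {
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction >= 1)
    stop("'top_fraction' must be a single number in (0, 1)")
  vals <- pcc[upper.tri(pcc)]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no defined gene-pair correlation values")
  if (diff(range(vals)) == 0)
    stop("all correlation values are identical; no discriminating threshold")
  unname(quantile(vals, probs = 1 - top_fraction, type = 7))
}

#' Build an undirected binary relationship network
#'
#' A gene pair is a relationship iff its absolute PCC is defined and strictly
#' above the threshold.
#'
#' @param pcc a `PccMatrix`.
#' @param threshold scalar in `[0, 1]`.
#' @param condition `"parental"` or `"resistant"` (provenance label).
#' @return object of class `RelationshipNetwork`: list with `gene_ids`,
#'   symmetric binary `adjacency` (zero diagonal), `threshold`, `condition`.
#' @export
build_network <- function(pcc, threshold, condition = c("parental", "resistant")) {
  condition <- match.arg(condition)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("'threshold' must be a single number in [0, 1]")
  adj <- (!is.na(pcc) & pcc > threshold) * 1L
  diag(adj) <- 0L
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]  # symmetry guard
  relationship_network(rownames(pcc), adj, threshold, condition)
}

relationship_network <- function(gene_ids, adjacency, threshold, condition) {
  gene_ids <- as.character(gene_ids)
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  stopifnot(nrow(adjacency) == length(gene_ids),
            ncol(adjacency) == length(gene_ids),
            all(adjacency %in% c(0L, 1L)),
            all(diag(adjacency) == 0L),
            identical(adjacency, t(adjacency)))
  dimnames(adjacency) <- list(gene_ids, gene_ids)
  structure(list(gene_ids = gene_ids, adjacency = adjacency,
                 threshold = as.numeric(threshold), condition = condition),
            class = "RelationshipNetwork")
}

#' @export
print.RelationshipNetwork <- function(x, ...) {
  cat(sprintf("RelationshipNetwork (%s): %d genes, %d edges (threshold %.4g)\n",
              x$condition, length(x$gene_ids), network_edge_count(x),
              x$threshold))
  invisible(x)
}

#' Number of edges of a RelationshipNetwork
#' @param network a `RelationshipNetwork`.
#' @return integer edge count.
#' @export
network_edge_count <- function(network) sum(network$adjacency) %/% 2L

#' Number of unordered gene pairs among g genes
#' @param g positive integer.
#' @return g(g-1)/2.
#' @export
count_pairs <- function(g) {
  if (any(g < 1) || any(g != round(g))) stop("'g' must be a positive integer")
  g * (g - 1) / 2
}

#' Write a network as a node list and an edge list
#'
#' Node list: one gene symbol per line. Edge list: TSV with columns `gene_i`,
#' `gene_j`, `abs_pcc` (NA when no PCC matrix is supplied).
#'
#' @param network a `RelationshipNetwork`.
#' @param node_path,edge_path output paths.
#' @param pcc optional `PccMatrix` supplying the edge weights.
#' @export
write_network <- function(network, node_path, edge_path, pcc = NULL) {
  writeLines(network$gene_ids, node_path)
  ut <- which(upper.tri(network$adjacency) & network$adjacency == 1L,
              arr.ind = TRUE)
  w <- if (is.null(pcc)) rep(NA_real_, nrow(ut)) else pcc[ut]
  df <- data.frame(gene_i = network$gene_ids[ut[, 1L]],
                   gene_j = network$gene_ids[ut[, 2L]],
                   abs_pcc = w, stringsAsFactors = FALSE)
  write.table(df, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edge_path)
}

#' Read a network written by [write_network()]
#' @param node_path,edge_path paths written by [write_network()].
#' @param threshold,condition provenance fields to attach.
#' @return a `RelationshipNetwork`.
#' @export
read_network <- function(node_path, edge_path, threshold = NA_real_,
                         condition = c("parental", "resistant")) {
  condition <- match.arg(condition)
  genes <- readLines(node_path)
  edges <- read.delim(edge_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  adj <- matrix(0L, length(genes), length(genes),
                dimnames = list(genes, genes))
  if (nrow(edges)) {
    bad <- setdiff(c(edges$gene_i, edges$gene_j), genes)
    if (length(bad)) stop("edge gene(s) not in node list: ",
                          paste(bad, collapse = ", "))
    adj[cbind(edges$gene_i, edges$gene_j)] <- 1L
    adj[cbind(edges$gene_j, edges$gene_i)] <- 1L
  }
  relationship_network(genes, adj, threshold, condition)
}
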