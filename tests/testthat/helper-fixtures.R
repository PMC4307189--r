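# shared fixture builders -----------------------------------------------------

# small expression matrix with given values and optional labels
make_expr <- function(values, genes = NULL, samples = NULL,
                      condition = NULL, dose = NULL, replicate = NULL) {
  if (is.null(genes))
    genes <- if (!is.null(rownames(values))) rownames(values)
    else sprintf("G%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, condition = condition, dose = dose,
                    replicate = replicate)
}

# RelationshipNetwork from an adjacency matrix
make_net <- function(adj, condition = "resistant", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(nrow(adj)))
  storage.mode(adj) <- "integer"
  p1crosstalk:::relationship_network(ids, adj, 0.5, condition)
}

# all symmetric binary adjacency configurations over g nodes
all_networks <- function(g) {
  nd <- g * (g - 1) / 2
  lapply(seq_len(2^nd) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(nd)]
    adj <- matrix(0L, g, g)
    adj[upper.tri(adj)] <- bits
    adj + t(adj)
  })
}

unordered_keys <- function(a, b) p1crosstalk:::pair_key(a, b)

# two-condition expression fixture with paired replicates for the screens
make_paired_conditions <- function(par_vals, res_vals, doses, replicates) {
  list(parental = make_expr(par_vals, condition = rep("parental", ncol(par_vals)),
                            dose = doses, replicate = replicates),
       resistant = make_expr(res_vals, condition = rep("resistant", ncol(res_vals)),
                             dose = doses, replicate = replicates))
}
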