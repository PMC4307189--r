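#' Per-condition average expression profile
#'
#' Averages replicate samples within each (condition, dose) group, giving the
#' genes x conditions matrix used for heatmaps and the selection screens.
#'
#' @param expr gene-level `ExpressionMatrix` whose samples carry condition and
#'   dose labels (or supply `sample_map` to attach them).
#' @param sample_map optional data.frame from [read_sample_map()]; if given,
#'   its labels override/define the matrix's sample metadata.
#' @return object of class `ConditionProfile`: list with `gene_ids`,
#'   `conditions` (data.frame of condition/dose per column), `means`
#'   (genes x conditions matrix) and `normalized` (`NULL` until
#'   [normalize_profile()] is applied). Columns are ordered parental doses
#'   first, then resistant doses, each dose ascending.
#' @export
condition_means <- function(expr, sample_map = NULL) {
  info <- sample_info(expr)
  if (!is.null(sample_map)) {
    miss <- setdiff(colnames(expr), sample_map$sample_id)
    if (length(miss))
      stop("sample(s) absent from sample map: ", paste(miss, collapse = ", "))
    sm <- sample_map[match(colnames(expr), sample_map$sample_id), ]
    info <- data.frame(sample_id = colnames(expr), condition = sm$condition,
                       dose = sm$dose, stringsAsFactors = FALSE)
  }
  if (is.null(info$condition) || is.null(info$dose))
    stop("samples carry no condition/dose labels; supply 'sample_map'")
  grp <- data.frame(condition = info$condition, dose = info$dose)
  levels_df <- unique(grp)
  levels_df <- levels_df[order(match(levels_df$condition,
                                     c("parental", "resistant")),
                               levels_df$dose), , drop = FALSE]
  means <- sapply(seq_len(nrow(levels_df)), function(k) {
    j <- which(grp$condition == levels_df$condition[k] &
                 grp$dose == levels_df$dose[k])
    rowMeans(unclass(expr)[, j, drop = FALSE])
  })
  means <- matrix(means, nrow = nrow(expr),
                  dimnames = list(rownames(expr),
                                  paste0(levels_df$condition, "_",
                                         levels_df$dose)))
  structure(list(gene_ids = rownames(expr), conditions = levels_df,
                 means = means, normalized = NULL),
            class = "ConditionProfile")
}

#' Heatmap normalization: per-gene z-score then max-abs scaling
#'
#' Each gene row of the condition means is transformed to z-scores (zero
#' mean, unit *population* standard deviation over its condition values) and
#' then divided by the maximum absolute z-score of that gene, so every
#' non-constant gene spans exactly `[-1, 1]`; constant rows map to all zeros.
#'
#' @param profile a `ConditionProfile` from [condition_means()].
#' @return the profile with its `normalized` matrix filled.
#' @export
normalize_profile <- function(profile) {
  m <- profile$means
  z <- t(apply(m, 1L, function(row) {
    mu <- mean(row)
    s <- sqrt(mean((row - mu)^2))  # population sd
    if (s == 0) return(rep(0, length(row)))
    zz <- (row - mu) / s
    zz / max(abs(zz))
  }))
  dimnames(z) <- dimnames(m)
  profile$normalized <- z
  profile
}

# per-gene average over all condition-means of each condition (the "Avg GE"
# columns of the cross-talk table)
condition_average_ge <- function(profile) {
  cond <- profile$conditions$condition
  cbind(parental = rowMeans(profile$means[, cond == "parental", drop = FALSE]),
        resistant = rowMeans(profile$means[, cond == "resistant", drop = FALSE]))
}

#' Keep cross-talk records whose genes are both up-regulated in resistance
#'
#' A record survives iff, for *both* genes, the average of its
#' resistant-condition means is strictly greater than the average of its
#' parental-condition means.
#'
#' @param table cross-talk data.frame (from [intersect_crosstalks()]).
#' @param profile a `ConditionProfile` covering the table's genes.
#' @return list with `table` (the surviving subset, order preserved) and
#'   `genes` (sorted distinct genes involved in surviving records).
#' @export
select_upregulated_pairs <- function(table, profile) {
  if (!nrow(table))
    return(list(table = table, genes = character()))
  avg <- condition_average_ge(profile)
  up <- avg[, "resistant"] > avg[, "parental"]
  keep <- up[table$gene_i] & up[table$gene_j]
  sub <- table[keep, , drop = FALSE]
  rownames(sub) <- NULL
  list(table = sub, genes = sort(unique(c(sub$gene_i, sub$gene_j))))
}

#' Fold-change-reversal gene screen
#'
#' Identifies genes whose response to treatment flips sign upon resistance:
#' per replicate, the log2 fold-change of every parental treatment dose
#' relative to the parental basal (dose 0) sample must all share one strict
#' sign, and the log2 fold-changes of all resistant treatment doses (relative
#' to the same parental basal sample) must all have the strictly opposite
#' sign. A gene is selected if this holds in at least one replicate. The
#' resistant basal fold-change is computed and returned for reference but does
#' not enter the predicate. A log2 fold-change of exactly 0 counts as neither
#' up- nor down-regulated.
#'
#' @param parental,resistant gene-level `ExpressionMatrix` objects whose
#'   samples carry `dose` and `replicate` labels; parental must include dose 0
#'   and each (dose, replicate) cell must be a single sample.
#' @return list with `genes` (sorted selected gene symbols) and `details`
#'   (data.frame of gene, replicate, and the per-dose log2 fold-changes).
#' @export
fold_change_reversal <- function(parental, resistant) {
  ip <- sample_info(parental); ir <- sample_info(resistant)
  if (is.null(ip$replicate) || is.null(ir$replicate))
    stop("both matrices need a 'replicate' index pairing samples across conditions")
  if (!any(ip$dose == 0)) stop("parental condition must include basal (dose 0) samples")
  reps <- sort(intersect(unique(ip$replicate), unique(ir$replicate)))
  p_doses <- sort(setdiff(unique(ip$dose), 0))
  r_doses <- sort(setdiff(unique(ir$dose), 0))
  if (!length(p_doses) || !length(r_doses))
    stop("need at least one non-basal treatment dose in each condition")
  genes <- rownames(parental)
  stopifnot(identical(genes, rownames(resistant)))
  pv <- unclass(parental); rv <- unclass(resistant)
  one_col <- function(info, vals, dose, rep) {
    j <- which(info$dose == dose & info$replicate == rep)
    if (length(j) != 1L)
      stop(sprintf("expected exactly one sample at dose %g, replicate %d; found %d",
                   dose, rep, length(j)))
    vals[, j]
  }
  selected <- logical(length(genes))
  details <- list()
  n_skipped <- 0L
  for (s in reps) {
    basal <- one_col(ip, pv, 0, s)
    lfc_p <- suppressWarnings(
      sapply(p_doses, function(d) log2(one_col(ip, pv, d, s) / basal)))
    lfc_r <- suppressWarnings(
      sapply(r_doses, function(d) log2(one_col(ir, rv, d, s) / basal)))
    lfc_p <- matrix(lfc_p, ncol = length(p_doses))
    lfc_r <- matrix(lfc_r, ncol = length(r_doses))
    lfc_r_basal <- if (any(ir$dose == 0 & ir$replicate == s))
      suppressWarnings(log2(one_col(ir, rv, 0, s) / basal))
    else rep(NA_real_, length(genes))
    ok <- is.finite(rowSums(lfc_p)) & is.finite(rowSums(lfc_r)) & basal > 0
    if (any(!ok)) n_skipped <- n_skipped + sum(!ok)
    all_up_p <- rowSums(lfc_p > 0) == ncol(lfc_p)
    all_dn_p <- rowSums(lfc_p < 0) == ncol(lfc_p)
    all_up_r <- rowSums(lfc_r > 0) == ncol(lfc_r)
    all_dn_r <- rowSums(lfc_r < 0) == ncol(lfc_r)
    hit <- ok & ((all_up_p & all_dn_r) | (all_dn_p & all_up_r))
    selected <- selected | hit
    if (any(hit))
      details[[length(details) + 1L]] <- data.frame(
        gene = genes[hit], replicate = s,
        lfc_parental = apply(lfc_p[hit, , drop = FALSE], 1L, paste,
                             collapse = ";"),
        lfc_resistant = apply(lfc_r[hit, , drop = FALSE], 1L, paste,
                              collapse = ";"),
        lfc_resistant_basal = lfc_r_basal[hit],
        stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L)
    warning(n_skipped, " gene-replicate record(s) skipped: nonpositive ",
            "expression makes log2 fold-change undefined")
  details <- if (length(details)) do.call(rbind, details)
  else data.frame(gene = character(), replicate = integer(),
                  lfc_parental = character(), lfc_resistant = character(),
                  lfc_resistant_basal = numeric(), stringsAsFactors = FALSE)
  list(genes = sort(unique(genes[selected])), details = details)
}

#' Convenience heatmap of a normalized profile
#'
#' Renders the `[-1, 1]` normalized condition profile with a red (up) /
#' green (down) diverging palette. Requires the optional pheatmap package;
#' the normalized matrix itself is the contract, the image is a convenience.
#'
#' @param profile a normalized `ConditionProfile`.
#' @param ... passed to [pheatmap::pheatmap()].
#' @export
profile_heatmap <- function(profile, ...) {
  if (is.null(profile$normalized))
    profile <- normalize_profile(profile)
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("install the 'pheatmap' package to render heatmaps")
  pal <- grDevices::colorRampPalette(c("green3", "black", "red2"))(101)
  pheatmap::pheatmap(profile$normalized, color = pal,
                     breaks = seq(-1, 1, length.out = 102),
                     cluster_cols = FALSE, ...)
}
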