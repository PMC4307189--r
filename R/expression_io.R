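#' @useDynLib p1crosstalk, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor quantile rnorm rgamma rWishart runif rbinom plogis
#'   sd acf setNames
#' @importFrom utils read.delim write.table
NULL

#' Construct an expression matrix with sample metadata
#'
#' The container used throughout the package: a numeric genes x samples matrix
#' with a per-sample `condition` ("parental"/"resistant") and numeric `dose`
#' (treatment level, typically micromolar, >= 0) and an optional `replicate`
#' index pairing samples across conditions.
#'
#' @param values numeric matrix, rows = features (probes or genes), columns =
#'   samples. Must have unique, non-empty rownames and colnames.
#' @param condition character vector per sample, or `NULL` if labels are
#'   attached later via [split_conditions()].
#' @param dose numeric vector per sample (>= 0), or `NULL`.
#' @param replicate integer vector per sample, or `NULL`.
#' @return An object of class `ExpressionMatrix` (a numeric matrix with a
#'   `sample_info` attribute holding a data.frame of per-sample labels).
#' @export
expression_matrix <- function(values, condition = NULL, dose = NULL,
                              replicate = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have rownames (features) and colnames (samples)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  n <- ncol(values)
  info <- data.frame(sample_id = colnames(values),
                     stringsAsFactors = FALSE)
  if (!is.null(condition)) {
    condition <- as.character(condition)
    if (length(condition) != n) stop("'condition' must have one entry per sample")
    bad <- setdiff(unique(condition), c("parental", "resistant"))
    if (length(bad))
      stop("condition labels must be 'parental' or 'resistant'; got: ",
           paste(bad, collapse = ", "))
    info$condition <- condition
  }
  if (!is.null(dose)) {
    dose <- as.numeric(dose)
    if (length(dose) != n) stop("'dose' must have one entry per sample")
    if (any(!is.finite(dose)) || any(dose < 0))
      stop("'dose' must be finite and >= 0")
    info$dose <- dose
  }
  if (!is.null(replicate)) {
    if (length(replicate) != n) stop("'replicate' must have one entry per sample")
    info$replicate <- as.integer(replicate)
  }
  structure(values, sample_info = info, class = c("ExpressionMatrix", "matrix"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  info <- sample_info(x)
  cat(sprintf("ExpressionMatrix: %d features x %d samples\n", nrow(x), ncol(x)))
  if (!is.null(info$condition))
    cat("  conditions:", paste(sprintf("%s=%d", names(table(info$condition)),
                                       table(info$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' Per-sample metadata of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return data.frame with columns `sample_id` and, when set, `condition`,
#'   `dose`, `replicate`.
#' @export
sample_info <- function(x) attr(x, "sample_info")

# carry metadata through column subsetting done internally
subset_samples <- function(x, j) {
  info <- sample_info(x)[j, , drop = FALSE]
  vals <- unclass(x)[, j, drop = FALSE]
  attr(vals, "sample_info") <- NULL
  expression_matrix(vals,
                    condition = info$condition,
                    dose = info$dose,
                    replicate = info$replicate)
}

#' Read a tab-delimited expression table
#'
#' Expects one header row of sample identifiers and a leading feature-identifier
#' column; every data cell must parse as a finite number (missing values are a
#' parse error: upstream platform summaries are expected to be complete).
#'
#' @param path path to the TSV file.
#' @param orientation currently only `"rows_are_features"`.
#' @return An [expression_matrix()] without condition/dose labels (attach them
#'   with [split_conditions()] and a sample map).
#' @export
read_expression_table <- function(path, orientation = "rows_are_features") {
  orientation <- match.arg(orientation, "rows_are_features")
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2)
    stop("malformed header in ", path, ": need a feature column plus >= 1 sample")
  ids <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample identifier in header of ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(!is.finite(col))
    if (length(bad))
      stop(sprintf("non-numeric cell in %s at row '%s', column '%s': '%s'",
                   path, ids[bad[1L]], samples[j], raw[[j + 1L]][bad[1L]]))
    vals[, j] <- col
  }
  expression_matrix(vals)
}

#' Write an expression table (inverse of [read_expression_table()])
#' @param expr an `ExpressionMatrix` (or plain named numeric matrix).
#' @param path output TSV path.
#' @param feature_col name of the leading identifier column.
#' @export
write_expression_table <- function(expr, path, feature_col = "feature_id") {
  df <- data.frame(rownames(expr), unclass(expr)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- feature_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe -> gene-symbol annotation table
#'
#' Two tab-delimited columns: probe identifier and gene symbol. Probes with an
#' empty symbol are unmapped; probes listed with more than one distinct symbol
#' are dropped with a warning (only many-probes-to-one-symbol averaging is
#' supported).
#'
#' @param path annotation TSV path.
#' @param header whether the file carries a header row.
#' @return named character vector: `names` = probe ids, values = gene symbols.
#' @export
read_probe_annotation <- function(path, header = TRUE) {
  raw <- read.delim(path, header = header, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2) stop("annotation file must have two columns: ", path)
  probe <- trimws(raw[[1L]]); symbol <- trimws(raw[[2L]])
  keep <- nzchar(probe) & nzchar(symbol)
  probe <- probe[keep]; symbol <- symbol[keep]
  nsym <- tapply(symbol, probe, function(s) length(unique(s)))
  multi <- names(nsym)[nsym > 1L]
  if (length(multi)) {
    warning(length(multi), " probe(s) map to multiple symbols; dropped: ",
            paste(utils::head(multi, 5L), collapse = ", "),
            if (length(multi) > 5L) ", ...")
    drop <- probe %in% multi
    probe <- probe[!drop]; symbol <- symbol[!drop]
  }
  first <- !duplicated(probe)
  setNames(symbol[first], probe[first])
}

#' Collapse probe-level rows to gene-level rows
#'
#' Each output gene row is the per-sample arithmetic mean of all probe rows
#' annotated to that gene symbol; unmapped probes are dropped; output genes are
#' in lexicographic order.
#'
#' @param expr probe-level `ExpressionMatrix`.
#' @param annotation named character vector from [read_probe_annotation()]
#'   (names = probe ids, values = symbols).
#' @return gene-level `ExpressionMatrix` (sample labels carried over).
#' @export
collapse_probes <- function(expr, annotation) {
  probes <- rownames(expr)
  sym <- annotation[probes]
  mapped <- !is.na(sym) & nzchar(sym)
  if (!any(mapped))
    stop("no probe in the expression matrix maps to any gene symbol")
  n_drop <- sum(!mapped)
  if (n_drop > 0L)
    message(n_drop, " unmapped probe(s) dropped during collapse")
  vals <- unclass(expr)[mapped, , drop = FALSE]
  sym <- sym[mapped]
  genes <- sort(unique(sym))
  out <- rowsum(vals, group = sym) / as.vector(table(sym)[genes])
  out <- out[genes, , drop = FALSE]
  info <- sample_info(expr)
  expression_matrix(out, condition = info$condition, dose = info$dose,
                    replicate = info$replicate)
}

#' Read a sample map (sample_id, condition, dose[, replicate])
#' @param path TSV with header columns `sample_id`, `condition`, `dose` and
#'   optionally `replicate`.
#' @return data.frame.
#' @export
read_sample_map <- function(path) {
  sm <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "dose")
  if (!all(need %in% colnames(sm)))
    stop("sample map must have columns: ", paste(need, collapse = ", "))
  sm$dose <- as.numeric(sm$dose)
  sm
}

#' Split an expression matrix into parental and resistant matrices
#'
#' @param expr `ExpressionMatrix` (any feature level).
#' @param sample_map data.frame from [read_sample_map()] mapping every sample
#'   to a condition and dose.
#' @return named list with elements `parental` and `resistant`, each an
#'   `ExpressionMatrix` with condition/dose (and replicate, if present)
#'   attached; gene order preserved.
#' @export
split_conditions <- function(expr, sample_map) {
  ids <- colnames(expr)
  miss <- setdiff(ids, sample_map$sample_id)
  if (length(miss))
    stop("sample(s) absent from sample map: ", paste(miss, collapse = ", "))
  sm <- sample_map[match(ids, sample_map$sample_id), , drop = FALSE]
  bad <- setdiff(unique(sm$condition), c("parental", "resistant"))
  if (length(bad))
    stop("unknown condition label(s) in sample map: ", paste(bad, collapse = ", "))
  out <- lapply(c(parental = "parental", resistant = "resistant"), function(cc) {
    j <- which(sm$condition == cc)
    if (!length(j)) stop("condition '", cc, "' has zero samples")
    expression_matrix(unclass(expr)[, j, drop = FALSE],
                      condition = sm$condition[j], dose = sm$dose[j],
                      replicate = sm$replicate[j])
  })
  out
}

#' Restrict an expression matrix to a seed gene list
#'
#' Matching is case-sensitive exact string match on gene symbols; the number of
#' seeds without an expression row is reported (and stored in the
#' `missing_seeds` attribute).
#'
#' @param expr gene-level `ExpressionMatrix`.
#' @param seeds character vector of gene symbols.
#' @return `ExpressionMatrix` with the retained rows (original values,
#'   bit-exact), in seed-list order restricted to present genes.
#' @export
restrict_to_seed_genes <- function(expr, seeds) {
  seeds <- unique(as.character(seeds))
  present <- seeds[seeds %in% rownames(expr)]
  n_missing <- length(seeds) - length(present)
  if (!length(present))
    stop("none of the ", length(seeds), " seed genes has an expression row")
  message(length(present), " of ", length(seeds),
          " seed genes have expression values (", n_missing, " missing)")
  info <- sample_info(expr)
  out <- expression_matrix(unclass(expr)[present, , drop = FALSE],
                           condition = info$condition, dose = info$dose,
                           replicate = info$replicate)
  attr(out, "missing_seeds") <- n_missing
  out
}

#' Read a seed-gene list (one symbol per line)
#' @param path plain-text path.
#' @return character vector.
#' @export
read_seed_genes <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}
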