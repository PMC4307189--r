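#' Pipeline run configuration
#'
#' Validates the end-to-end configuration. Exactly one of the network
#' threshold modes must be chosen: explicit per-condition thresholds (as in
#' fixed-cutoff analyses) or a top-fraction quantile rule.
#'
#' @param expression path to the expression TSV (probe- or gene-level).
#' @param sample_map path to the sample map TSV.
#' @param seed_genes path to the seed gene list (one symbol per line).
#' @param pathways named character vector/list of GMT paths (names = source
#'   labels), each read with its `pathway_of_interest`.
#' @param pathway_of_interest pathway name of interest (recycled over
#'   sources).
#' @param annotation optional probe annotation TSV (omit for gene-level
#'   input).
#' @param threshold_parental,threshold_resistant explicit absolute-PCC
#'   thresholds, or `NULL`.
#' @param top_fraction quantile mode: fraction of pairs to keep, or `NULL`.
#' @param odds_min,pr_min cross-talk filter thresholds (inclusive).
#' @param p1 a [p1_config()] (its seed governs the whole run).
#' @param out_dir output directory for all artifacts.
#' @return validated list of class `RunConfig`.
#' @export
pipeline_config <- function(expression, sample_map, seed_genes, pathways,
                            pathway_of_interest,
                            annotation = NULL,
                            threshold_parental = NULL,
                            threshold_resistant = NULL,
                            top_fraction = NULL,
                            odds_min = 10.0, pr_min = 0.5,
                            p1 = p1_config(seed = 1L),
                            out_dir) {
  explicit <- !is.null(threshold_parental) || !is.null(threshold_resistant)
  if (explicit && (is.null(threshold_parental) || is.null(threshold_resistant)))
    stop("explicit threshold mode needs both threshold_parental and threshold_resistant")
  if (explicit == !is.null(top_fraction))
    stop("set exactly one of (threshold_parental + threshold_resistant, top_fraction)")
  stopifnot(inherits(p1, "P1Config"))
  if (is.null(names(pathways)))
    names(pathways) <- sprintf("source_%d", seq_along(pathways))
  structure(list(expression = expression, sample_map = sample_map,
                 seed_genes = seed_genes, pathways = as.list(pathways),
                 pathway_of_interest = pathway_of_interest,
                 annotation = annotation,
                 threshold_parental = threshold_parental,
                 threshold_resistant = threshold_resistant,
                 top_fraction = top_fraction,
                 odds_min = odds_min, pr_min = pr_min, p1 = p1,
                 out_dir = out_dir),
            class = "RunConfig")
}

#' Run the full cross-talk prediction pipeline
#'
#' Executes expression input, per-condition network construction, the joint
#' p1-model fit, cross-talk scoring against every pathway source, and the
#' expression-profile screens, writing every intermediate artifact plus a
#' summary and a manifest into `config$out_dir`. A stage failure aborts with
#' the stage name and leaves a `FAILED` marker file.
#'
#' @param config a [pipeline_config()].
#' @return invisible list: the manifest, per-source cross-talk tables,
#'   summary counts, fit, networks and profile.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat(sprintf("[%s] pipeline start (seed %d)\n", format(Sys.time()),
              config$p1$seed), file = log_path)
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time()), sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  stage <- "setup"
  timings <- list()
  res <- tryCatch({
    tick <- function(name, fun) {
      stage <<- name
      t0 <- proc.time()[["elapsed"]]
      out <- fun()
      timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
      out
    }

    inputs <- tick("expression_io", function() {
      for (p in c(config$expression, config$sample_map, config$seed_genes,
                  unlist(config$pathways)))
        if (!file.exists(p)) stop("input file not found: ", p)
      expr <- read_expression_table(config$expression)
      if (!is.null(config$annotation))
        expr <- collapse_probes(expr, read_probe_annotation(config$annotation))
      sm <- read_sample_map(config$sample_map)
      seeds <- read_seed_genes(config$seed_genes)
      expr <- suppressMessages(restrict_to_seed_genes(expr, seeds))
      both <- split_conditions(expr, sm)
      logmsg("expression: %d genes, %d parental + %d resistant samples (%d seeds missing)",
             nrow(expr), ncol(both$parental), ncol(both$resistant),
             attr(expr, "missing_seeds"))
      list(both = both, sm = sm)
    })

    nets <- tick("network_builder", function() {
      out <- lapply(c(parental = "parental", resistant = "resistant"),
                    function(cc) {
        pcc <- suppressMessages(abs_pcc_matrix(inputs$both[[cc]]))
        thr <- if (!is.null(config$top_fraction))
          select_threshold(pcc, config$top_fraction)
        else if (cc == "parental") config$threshold_parental
        else config$threshold_resistant
        net <- build_network(pcc, thr, cc)
        write_network(net, file.path(config$out_dir, paste0(cc, "_nodes.txt")),
                      file.path(config$out_dir, paste0(cc, "_edges.tsv")),
                      pcc = pcc)
        logmsg("network (%s): threshold %.4g, %d edges of %d pairs", cc, thr,
               network_edge_count(net), count_pairs(length(net$gene_ids)))
        net
      })
      out
    })

    fit <- tick("p1_bayes", function() {
      fit <- gibbs_fit(nets$resistant, nets$parental, config$p1)
      write_posterior(fit, config$out_dir)
      logmsg("p1 fit: %d retained draws; posterior mean theta_R %.3f, theta_P %.3f",
             nrow(fit$draws$theta), mean(fit$draws$theta[, "R"]),
             mean(fit$draws$theta[, "P"]))
      fit
    })

    cand <- tick("resistant_pairs", function() {
      cand <- filter_resistant_pairs(fit$edge_prob_R, fit$edge_prob_P,
                                     odds_min = config$odds_min,
                                     pr_min = config$pr_min)
      logmsg("candidate resistant pairs: %d (odds >= %g, pr_R >= %g)",
             nrow(cand), config$odds_min, config$pr_min)
      cand
    })

    profile <- tick("expression_profiles", function() {
      comb <- cbind(unclass(inputs$both$parental), unclass(inputs$both$resistant))
      ip <- sample_info(inputs$both$parental)
      ir <- sample_info(inputs$both$resistant)
      em <- expression_matrix(comb, condition = c(ip$condition, ir$condition),
                              dose = c(ip$dose, ir$dose),
                              replicate = c(ip$replicate, ir$replicate))
      prof <- normalize_profile(condition_means(em))
      write.table(data.frame(gene = rownames(prof$means), prof$means,
                             check.names = FALSE),
                  file.path(config$out_dir, "condition_means.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(data.frame(gene = rownames(prof$normalized),
                             prof$normalized, check.names = FALSE),
                  file.path(config$out_dir, "profile_normalized.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      prof
    })

    xt <- tick("crosstalk", function() {
      tables <- list()
      for (src in names(config$pathways)) {
        coll <- read_gmt(config$pathways[[src]], config$pathway_of_interest,
                         name = src)
        cands <- enumerate_crosstalk_pairs(coll, nets$resistant$gene_ids)
        tb <- intersect_crosstalks(cand, cands, profile = profile)
        tables[[src]] <- tb
        utils::write.csv(tb, file.path(config$out_dir,
                                       paste0("crosstalks_", src, ".csv")),
                         row.names = FALSE)
        logmsg("crosstalk (%s): %d candidates, %d predicted cross-talks", src,
               nrow(cands), nrow(tb))
      }
      tables
    })

    screens <- tick("selection_screens", function() {
      up <- lapply(xt, select_upregulated_pairs, profile = profile)
      fcr <- tryCatch(
        suppressWarnings(fold_change_reversal(inputs$both$parental,
                                              inputs$both$resistant)),
        error = function(e) {
          logmsg("fold-change-reversal screen skipped: %s", conditionMessage(e))
          NULL
        })
      if (!is.null(fcr))
        writeLines(fcr$genes, file.path(config$out_dir, "fcr_genes.txt"))
      list(upregulated = up, fold_change_reversal = fcr)
    })

    summary <- summarize_crosstalks(xt)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("p1crosstalk")),
      r_version = R.version.string,
      seed = config$p1$seed,
      config = config[c("expression", "sample_map", "seed_genes",
                        "pathway_of_interest", "threshold_parental",
                        "threshold_resistant", "top_fraction", "odds_min",
                        "pr_min")],
      p1 = config$p1[c("n_iter", "burn_in", "seed", "a0", "b0", "wishart_df",
                       "edge_prob_estimator", "sampler")],
      stage_timings_sec = timings)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    logmsg("pipeline complete: %d cross-talks (%d distinct pairs)",
           summary$n_crosstalks, summary$n_distinct_pairs)
    list(manifest = manifest, crosstalks = xt, summary = summary,
         fit = fit, networks = nets, profile = profile, screens = screens,
         candidates = cand)
  }, error = function(e) {
    writeLines(c(stage, conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

write_posterior <- function(fit, out_dir) {
  d <- fit$draws
  n <- nrow(d$theta)
  long <- rbind(
    data.frame(iteration = seq_len(n), parameter = "theta_R",
               value = d$theta[, "R"]),
    data.frame(iteration = seq_len(n), parameter = "theta_P",
               value = d$theta[, "P"]),
    data.frame(iteration = seq_len(n), parameter = "sigma_cov_RP",
               value = d$sigma[, "cov_RP"]))
  write.table(long, file.path(out_dir, "posterior_draws.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (cc in c("R", "P")) {
    con <- gzfile(file.path(out_dir, paste0("edge_prob_", cc, ".tsv.gz")), "w")
    m <- if (cc == "R") fit$edge_prob_R else fit$edge_prob_P
    write.table(data.frame(gene = rownames(m), m, check.names = FALSE), con,
                sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  write.table(data.frame(parameter = rownames(fit$diagnostics),
                         fit$diagnostics),
              file.path(out_dir, "diagnostics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
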