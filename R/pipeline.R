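#' Pipeline run configuration
#'
#' One flat configuration object carrying the simulation settings, stage
#' toggles and the analysis thresholds (TE FDR 0.05, SLAM p 0.05, coverage
#' start threshold 0.15, 250 nt coverage window, 70 bins per axis, 5 CV
#' folds, 250 top stabilized/degraded + 1500 control genes filtered at
#' p > 0.2 and TPM > 3). Round-trips losslessly through YAML.
#'
#' @param sim a [sim_config()] (its seed drives every stage).
#' @param stages character subset of
#'   `c("features", "diff", "slam", "model", "cov5")`.
#' @param fdr,slam_p,cov_threshold,cov_window,n_bins,n_folds,top_n,control_n,control_p,control_tpm
#'   analysis thresholds; see description for defaults.
#' @param n_coverage_genes cap on the number of genes with simulated
#'   coverage tracks (memory guard; tracks are only needed for the
#'   class-comparison set).
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       stages = c("features", "diff", "slam", "model",
                                  "cov5"),
                       fdr = 0.05, slam_p = 0.05, cov_threshold = 0.15,
                       cov_window = 250, n_bins = 70, n_folds = 5,
                       top_n = 250, control_n = 1500, control_p = 0.2,
                       control_tpm = 3, n_coverage_genes = 2000) {
  cfg <- list(sim = sim, stages = stages, fdr = fdr, slam_p = slam_p,
              cov_threshold = cov_threshold, cov_window = cov_window,
              n_bins = n_bins, n_folds = n_folds, top_n = top_n,
              control_n = control_n, control_p = control_p,
              control_tpm = control_tpm,
              n_coverage_genes = n_coverage_genes)
  class(cfg) <- "run_config"
  cfg
}

#' Serialize / restore a run configuration as YAML
#' @param config a `run_config`; @param file YAML path.
#' @return `write_run_config` the path; `read_run_config` a `run_config`.
#' @export
write_run_config <- function(config, file) {
  plain <- unclass(config)
  plain$sim <- unclass(plain$sim)
  yaml::write_yaml(plain, file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  plain <- yaml::read_yaml(file)
  sim <- do.call(sim_config, plain$sim)
  plain$sim <- NULL
  do.call(run_config, c(list(sim = sim), plain))
}

#' Run the full synthetic analysis cascade
#'
#' Executes the stages in dependency order -- simulate, features, per-
#' timepoint differential analysis (TE interaction test plus per-assay
#' tests), coordinate classification and binned vector field, SLAM
#' stability test, feature-importance models, and the 5'/3' coverage-decay
#' statistics with class comparisons -- writing each stage's tables under
#' `outdir` and a manifest (seed, config, per-stage row counts, output
#' checksums) as JSON. Stage failures abort naming the stage; completed
#' outputs are retained.
#'
#' @param config a [run_config()].
#' @param outdir result directory (created; one subdirectory per stage).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("gcdecay")),
                   seed = config$sim$seed, stages = list())
  res <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## --- simulate -----------------------------------------------------------
  res$annotation <- run_stage("simulate", simulate_annotation(config$sim))
  res$truth <- run_stage("simulate",
                         simulate_ground_truth(config$sim, res$annotation))
  res$counts <- run_stage("simulate",
                          simulate_counts(config$sim, res$annotation,
                                          res$truth))
  simdir <- file.path(outdir, "simulate")
  dir.create(simdir, showWarnings = FALSE)
  write_annotation(res$annotation, file.path(simdir, "annotation.gtf"),
                   file.path(simdir, "transcripts.fa"))
  manifest$stages$simulate <- list(n_genes = nrow(res$annotation$genes),
                                   n_samples = nrow(res$counts$design))

  ## --- features -----------------------------------------------------------
  if ("features" %in% config$stages) {
    res$features <- run_stage("features",
                              region_features(res$annotation, res$counts))
    write.table(res$features, file.path(outdir, "features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$features <- list(n_genes = nrow(res$features),
                                     n_columns = ncol(res$features))
  }

  ## --- differential -------------------------------------------------------
  if ("diff" %in% config$stages) {
    tps <- config$sim$timepoints
    res$te <- run_stage("diff", lapply(setNames(tps, paste0("t", tps)),
                                       function(t) te_test(res$counts, t,
                                                           config$fdr)))
    t_final <- tps[length(tps)]
    res$rna <- run_stage("diff", assay_test(res$counts, "RNA", t_final,
                                            config$fdr))
    res$ribo <- run_stage("diff", assay_test(res$counts, "Ribo", t_final,
                                             config$fdr))
    res$groups <- run_stage("diff",
                            classify_coordinate_groups(res$rna, res$ribo,
                                                       config$fdr))
    te_final <- res$te[[length(res$te)]]
    sig48 <- te_final$gene_id[te_final$class != "NS"]
    gc <- setNames(res$annotation$genes$gc_cds,
                   res$annotation$genes$gene_id)
    lfc_by_tp <- lapply(res$te, function(d) {
      data.frame(gene_id = d$gene_id, log2fc_rna = d$log2fc_rna,
                 log2fc_ribo = d$log2fc_ribo)
    })
    res$vfield <- if (length(lfc_by_tp) >= 2) {
      run_stage("diff", vector_field(lfc_by_tp, gc, config$n_bins,
                                     genes = sig48))
    } else NULL
    diffdir <- file.path(outdir, "diff")
    dir.create(diffdir, showWarnings = FALSE)
    for (nm in names(res$te)) {
      write.table(res$te[[nm]], file.path(diffdir, paste0("te_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$vfield)) {
      write.table(res$vfield, file.path(diffdir, "vector_field.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages$diff <- list(
      n_te_tests = length(res$te),
      n_sig_final = length(sig48),
      group_counts = as.list(table(res$groups)))
  }

  ## --- slam ---------------------------------------------------------------
  if ("slam" %in% config$stages) {
    res$slam <- run_stage("slam", simulate_slam(config$sim, res$truth))
    res$stability <- run_stage("slam", stability_test(res$slam,
                                                      p_cutoff = config$slam_p))
    write.table(res$stability, file.path(outdir, "stability.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$slam <- list(
      n_tested = nrow(res$stability),
      n_excluded = length(attr(res$stability, "excluded")),
      class_counts = as.list(table(res$stability$class)))
  }

  ## --- model --------------------------------------------------------------
  if ("model" %in% config$stages && "diff" %in% config$stages &&
      "features" %in% config$stages) {
    te_final <- res$te[[length(res$te)]]
    keep <- te_final$gene_id[te_final$class == "TE_down"]
    if (length(keep) >= 50) {
      feat <- res$features[res$features$gene_id %in% keep, ]
      target <- te_final$log2fc_rna[match(feat$gene_id, te_final$gene_id)]
      res$rf <- run_stage("model",
                          fit_rf_cv(feat, target, config$n_folds,
                                    seed = config$sim$seed))
      res$lasso <- run_stage("model",
                             fit_lasso_cv(feat, target, config$n_folds,
                                          seed = config$sim$seed))
      write.table(res$rf$importance, file.path(outdir, "rf_importance.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(res$lasso$importance,
                  file.path(outdir, "lasso_importance.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$model <- list(
        n_genes = nrow(feat),
        rf_top_feature = res$rf$importance$feature[1],
        rf_spearman = res$rf$performance$spearman[
          is.na(res$rf$performance$fold)])
    } else {
      manifest$stages$model <- list(skipped = "fewer than 50 TE_down genes")
    }
  }

  ## --- coverage -----------------------------------------------------------
  if ("cov5" %in% config$stages && "diff" %in% config$stages) {
    tpm_raw <- rowMeans(res$counts$counts[
      , res$counts$design$condition == "control" &
        res$counts$design$assay == "RNA", drop = FALSE]) /
      res$annotation$genes$tx_len
    tpm <- setNames(tpm_raw / sum(tpm_raw) * 1e6,
                    res$annotation$genes$gene_id)
    res$classes <- run_stage("cov5", select_comparison_classes(
      res$rna, tpm, config$top_n, config$control_n, config$control_p,
      config$control_tpm, seed = config$sim$seed))
    cov_genes <- head(res$classes$gene_id, config$n_coverage_genes)
    res$coverage <- run_stage("cov5", simulate_coverage(
      config$sim, res$annotation, res$truth, gene_ids = cov_genes))
    res$covstats <- run_stage("cov5", coverage_stats(
      res$coverage, config$cov_threshold, config$cov_window / 2))
    res$covstats3 <- run_stage("cov5", coverage_stats(
      res$coverage, config$cov_threshold, config$cov_window / 2,
      end = "three"))
    res$class_tests <- run_stage("cov5", rbind(
      compare_classes(res$covstats, res$classes, "beta_cov"),
      compare_classes(res$covstats, res$classes, "beta_start")))
    res$class_tests3 <- run_stage("cov5", compare_classes(
      res$covstats3, res$classes, "beta_cov"))
    covdir <- file.path(outdir, "cov5")
    dir.create(covdir, showWarnings = FALSE)
    write.table(res$covstats, file.path(covdir, "coverage_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$class_tests, file.path(covdir, "class_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$cov5 <- list(
      n_transcripts = nrow(res$covstats),
      n_excluded = length(attr(res$covstats, "excluded")) +
        length(res$coverage$excluded))
  }

  write.table(res$counts$design, file.path(simdir, "design.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_config(config, file.path(outdir, "config.yaml"))
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$checksums <- as.list(setNames(unname(tools::md5sum(files)),
                                         sub(paste0("^", outdir, "/?"), "",
                                             files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Summarize a pipeline run as a markdown report
#'
#' Collates the vector field, feature-importance rankings, class-wise
#' coverage-beta comparisons and SLAM retention comparisons into one
#' markdown document; sections whose inputs are missing are listed as
#' omitted and the rest of the report is still produced.
#'
#' @param results the list returned by [run_pipeline()].
#' @param file output path for the markdown report.
#' @return invisibly, the path.
#' @export
report <- function(results, file) {
  lines <- c("# Synthetic degron time-course analysis report", "")
  omitted <- character(0)

  if (!is.null(results$vfield)) {
    late <- results$vfield[results$vfield$transition ==
                             max(results$vfield$transition), ]
    lower <- late[late$bin_y < 0, ]
    lines <- c(lines, "## Fold-change dynamics (binned vector field)", "",
               sprintf("%d occupied cells over %d transitions; late-transition mean RNA delta in translationally suppressed cells (Ribo < 0): %.3f log2 units.",
                       nrow(results$vfield),
                       max(results$vfield$transition),
                       weighted.mean(lower$d_rna, lower$n)), "")
  } else omitted <- c(omitted, "vector field")

  if (!is.null(results$rf)) {
    top <- head(results$rf$importance, 5)
    lines <- c(lines, "## Feature importance (Random Forest)", "",
               sprintf("Held-out Spearman r = %.3f; top features:",
                       results$rf$performance$spearman[
                         is.na(results$rf$performance$fold)]),
               sprintf("  %d. %s (importance %.4f)", top$rank, top$feature,
                       top$importance), "")
  } else omitted <- c(omitted, "feature importance")

  if (!is.null(results$class_tests)) {
    ct <- results$class_tests
    lines <- c(lines, "## 5' coverage-decay class comparisons", "",
               sprintf("  %s [%s]: median %.3f vs %.3f, one-sided Wilcoxon p = %.3g",
                       ct$comparison, ct$metric, ct$median1, ct$median0,
                       ct$p_value), "")
  } else omitted <- c(omitted, "coverage class comparisons")

  if (!is.null(results$stability)) {
    tab <- table(results$stability$class)
    lines <- c(lines, "## SLAM-seq stability", "",
               sprintf("  %s: %d genes", names(tab), as.integer(tab)), "")
  } else omitted <- c(omitted, "SLAM stability")

  if (length(omitted)) {
    lines <- c(lines, "## Omitted sections", "",
               paste0("  - ", omitted, " (inputs missing)"), "")
  }
  writeLines(lines, file)
  invisible(file)
}
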