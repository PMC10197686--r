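#' Simulation configuration for the synthetic degron time course
#'
#' Collects every tunable of the synthetic-data generator. Defaults describe
#' a two-condition (control vs. acute protein depletion) time course at
#' 4, 8, 16, 24 and 48 h with paired RNA-seq and Ribo-seq libraries,
#' a planted class structure (translationally suppressed genes whose mRNA is
#' later stabilized, and the mirror class), and a monotone dependence of the
#' RNA stabilization amplitude on coding-sequence GC content (GCcds).
#'
#' @param n_genes number of simulated genes.
#' @param timepoints hours after depletion onset; strictly increasing.
#' @param n_replicates replicates per assay/condition/timepoint cell.
#' @param frac_te_down,frac_te_up proportions of genes planted as TE_down
#'   (translation suppressed, mRNA later stabilized) and TE_up.
#' @param gc_effect_size log2FC units of RNA stabilization per unit GCcds.
#' @param dispersion negative-binomial dispersion alpha (var = mu + alpha mu^2)
#'   shared across genes.
#' @param lag_hours delay of the RNA-level response relative to the
#'   translational response (hard onset shift).
#' @param decay_erosion_rate nucleotides of 5' coverage-boundary recession per
#'   timepoint step under baseline turnover.
#' @param baseline_mean median baseline expected count per gene.
#' @param gc_range range of per-gene target GCcds values (uniform draw).
#' @param te_amp_range magnitude range of the planted delta-TE (log2 units).
#' @param slam_init_conversion fraction of labeled reads carrying >=1 T>C
#'   conversion at chase time 0 (after a saturating 24 h labeling).
#' @param slam_background conversion fraction in unlabeled samples.
#' @param slam_depth mean total read count per gene and SLAM sample.
#' @param slam_frac_cv replicate-level coefficient of variation of the
#'   conversion fraction (labeling/chase efficiency differences between
#'   cultures); reads are then Bernoulli-converted given the noisy fraction.
#' @param seed integer seed; all generator stages derive their streams
#'   from it, so equal configs give byte-identical outputs.
#'
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 4000,
                       timepoints = c(4, 8, 16, 24, 48),
                       n_replicates = 2,
                       frac_te_down = 0.15,
                       frac_te_up = 0.10,
                       gc_effect_size = 5,
                       dispersion = 0.02,
                       lag_hours = 12,
                       decay_erosion_rate = 15,
                       baseline_mean = 300,
                       gc_range = c(0.35, 0.75),
                       te_amp_range = c(1.2, 2.0),
                       slam_init_conversion = 0.6,
                       slam_background = 0.02,
                       slam_depth = 100,
                       slam_frac_cv = 0.15,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), timepoints = as.numeric(timepoints),
    n_replicates = as.integer(n_replicates),
    frac_te_down = frac_te_down, frac_te_up = frac_te_up,
    gc_effect_size = gc_effect_size, dispersion = dispersion,
    lag_hours = lag_hours, decay_erosion_rate = decay_erosion_rate,
    baseline_mean = baseline_mean, gc_range = as.numeric(gc_range),
    te_amp_range = as.numeric(te_amp_range),
    slam_init_conversion = slam_init_conversion,
    slam_background = slam_background, slam_depth = slam_depth,
    slam_frac_cv = slam_frac_cv,
    seed = as.integer(seed))
  .assert(cfg$n_genes >= 1, "n_genes must be >= 1")
  .assert(cfg$frac_te_down + cfg$frac_te_up <= 1,
          "frac_te_down + frac_te_up must be <= 1")
  .assert(all(cfg$timepoints > 0) && !is.unsorted(cfg$timepoints, strictly = TRUE),
          "timepoints must be positive and strictly increasing")
  .assert(cfg$dispersion > 0, "dispersion must be > 0")
  .assert(cfg$baseline_mean > 0, "baseline_mean must be > 0")
  .assert(diff(cfg$gc_range) >= 0 && cfg$gc_range[1] >= 0 && cfg$gc_range[2] <= 1,
          "gc_range must be an ordered range inside [0,1]")
  .assert(cfg$n_replicates >= 1, "n_replicates must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,",
      length(x$timepoints), "timepoints (",
      paste(x$timepoints, collapse = ", "), "h ),",
      x$n_replicates, "replicates/cell\n")
  cat("  planted TE_down/TE_up fractions:", x$frac_te_down, "/", x$frac_te_up,
      "; gc_effect_size:", x$gc_effect_size, "log2FC per GC unit\n")
  cat("  NB dispersion:", x$dispersion, "; RNA lag:", x$lag_hours,
      "h; seed:", x$seed, "\n")
  invisible(x)
}
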