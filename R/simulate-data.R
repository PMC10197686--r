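#' Simulate RNA-seq and Ribo-seq count matrices
#'
#' Draws negative-binomial counts (var = mu + alpha mu^2) for every
#' gene x assay x condition x timepoint x replicate, with expected counts
#' `baseline * 2^lfc * library_factor`. Baselines are log-normal around
#' `config$baseline_mean`; Ribo-seq baselines differ from RNA-seq by a
#' log-normal baseline-TE factor. The control condition sits at log2FC = 0;
#' treated means follow the ground-truth trajectories, so translational
#' suppression precedes the lagged mRNA response for TE_down genes.
#' Per-sample library-size factors are drawn from U(0.7, 1.3) to exercise
#' normalization downstream.
#'
#' Control-sample reads are additionally allocated multinomially across
#' transcript regions (5'UTR/CDS/3'UTR/introns, with assay-specific weights:
#' ribosome footprints concentrate in the CDS, intronic signal is RNA-only)
#' to supply region-level densities for feature engineering.
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_annotation()].
#' @param truth output of [simulate_ground_truth()].
#' @return a `count_table` list: integer `counts` (genes x samples), `design`
#'   data frame (sample_id, assay, condition, timepoint, replicate,
#'   lib_factor), `baseline` per-gene table, and `region_counts` (long table
#'   of control-sample reads per gene/region/assay).
#' @export
simulate_counts <- function(config, annotation, truth) {
  stopifnot(inherits(config, "sim_config"),
            inherits(truth, "ground_truth"))
  .assert(identical(annotation$genes$gene_id, truth$genes$gene_id),
          "annotation and truth disagree on gene identifiers")
  set.seed(config$seed + 2L)
  n <- config$n_genes
  tp <- config$timepoints

  baseline_rna <- rlnorm(n, log(config$baseline_mean), 0.7)
  base_te <- rlnorm(n, 0, 0.3)
  baseline_ribo <- baseline_rna * base_te
  .assert(all(baseline_rna > 0) && all(baseline_ribo > 0),
          "non-positive baseline mean")

  design <- expand.grid(
    replicate = seq_len(config$n_replicates),
    timepoint = tp,
    condition = c("control", "treated"),
    assay = c("RNA", "Ribo"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_t%02d_r%d", design$assay,
                              design$condition, design$timepoint,
                              design$replicate)
  design$lib_factor <- runif(nrow(design), 0.7, 1.3)
  design <- design[, c("sample_id", "assay", "condition", "timepoint",
                       "replicate", "lib_factor")]

  counts <- matrix(0L, n, nrow(design),
                   dimnames = list(truth$genes$gene_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    base <- if (design$assay[j] == "RNA") baseline_rna else baseline_ribo
    lfc <- if (design$condition[j] == "control") {
      numeric(n)
    } else if (design$assay[j] == "RNA") {
      truth$rna_lfc[, paste0("t", design$timepoint[j])]
    } else {
      truth$ribo_lfc[, paste0("t", design$timepoint[j])]
    }
    mu <- base * 2^lfc * design$lib_factor[j]
    counts[, j] <- as.integer(rnbinom(n, mu = mu,
                                      size = 1 / config$dispersion))
  }

  region_counts <- .allocate_region_counts(annotation, counts, design)

  structure(list(counts = counts, design = design,
                 baseline = data.frame(gene_id = truth$genes$gene_id,
                                       baseline_rna = baseline_rna,
                                       baseline_ribo = baseline_ribo,
                                       base_te = base_te,
                                       stringsAsFactors = FALSE),
                 region_counts = region_counts),
            class = "count_table")
}

## multinomial allocation of pooled control reads across transcript regions;
## weights = region length x assay affinity (pre-mRNA fraction for introns)
.allocate_region_counts <- function(annotation, counts, design) {
  g <- annotation$genes
  ctrl <- design$condition == "control"
  pooled <- list(
    RNA = rowSums(counts[, ctrl & design$assay == "RNA", drop = FALSE]),
    Ribo = rowSums(counts[, ctrl & design$assay == "Ribo", drop = FALSE]))
  affinity <- list(RNA = c(utr5 = 1, cds = 1, utr3 = 1, intron = 0.15),
                   Ribo = c(utr5 = 0.1, cds = 1, utr3 = 0.05, intron = 0.005))
  len <- cbind(utr5 = g$utr5_len, cds = g$cds_len, utr3 = g$utr3_len,
               intron = g$intron_len_total)
  out <- vector("list", 2L)
  for (a in c("RNA", "Ribo")) {
    w <- sweep(len, 2, affinity[[a]], "*")
    reads <- pooled[[a]]
    mat <- t(vapply(seq_len(nrow(len)), function(i) {
      if (reads[i] == 0 || sum(w[i, ]) == 0) return(rep(0, 4))
      as.numeric(rmultinom(1, reads[i], prob = w[i, ]))
    }, numeric(4)))
    colnames(mat) <- colnames(len)
    out[[a]] <- data.frame(gene_id = g$gene_id, assay = a,
                           region = rep(colnames(mat), each = nrow(mat)),
                           count = as.vector(mat), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate per-transcript 5'->3' coverage tracks
#'
#' Each track is a plateau over the transcript body preceded by a linear 5'
#' ramp; the ramp onset recedes 3'-wards with cumulative decay exposure:
#' `onset = base_start + decay_erosion_rate * mult * (timepoint index - 1)`,
#' with `mult = 1` for control samples and the gene's ground-truth erosion
#' multiplier for treated samples (stabilized genes recede less, degraded
#' genes more). The 3' end of the plateau is held fixed across conditions.
#' Per-nucleotide Poisson noise is added.
#'
#' @param config a [sim_config()].
#' @param annotation,truth simulator outputs sharing gene ids.
#' @param gene_ids optional subset of genes to simulate tracks for (coverage
#'   is memory-heavy; the pipeline restricts it to the class-comparison set).
#' @param plateau expected plateau coverage depth.
#' @param ramp_len length of the 5' ramp, nucleotides.
#' @param tail3 zero-coverage 3' tail length, nucleotides.
#' @return a `coverage_set` list: `tracks` (per gene, an integer matrix
#'   samples x transcript length), `samples` data frame (condition,
#'   timepoint), `tx_len`, and `excluded` (gene ids too short for
#'   ramp + window, flagged and dropped).
#' @export
simulate_coverage <- function(config, annotation, truth, gene_ids = NULL,
                              plateau = 50, ramp_len = 50, tail3 = 30) {
  stopifnot(inherits(config, "sim_config"),
            inherits(truth, "ground_truth"))
  set.seed(config$seed + 3L)
  tp <- config$timepoints
  g <- annotation$genes
  if (is.null(gene_ids)) gene_ids <- g$gene_id
  samples <- expand.grid(timepoint = tp, condition = c("control", "treated"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("cov_%s_t%02d", samples$condition,
                               samples$timepoint)

  max_onset <- max(truth$genes$coverage_base_start) +
    config$decay_erosion_rate * max(truth$genes$erosion_mult) *
      (length(tp) - 1)
  tracks <- list()
  excluded <- character(0)
  for (gid in gene_ids) {
    i <- match(gid, g$gene_id)
    len <- g$tx_len[i]
    if (len < max_onset + ramp_len + tail3 + 50) {
      excluded <- c(excluded, gid)
      next
    }
    base_start <- truth$genes$coverage_base_start[i]
    emult <- truth$genes$erosion_mult[i]
    m <- matrix(0L, nrow(samples), len,
                dimnames = list(samples$sample_id, NULL))
    for (s in seq_len(nrow(samples))) {
      ti <- match(samples$timepoint[s], tp) - 1L
      mult <- if (samples$condition[s] == "control") 1 else emult
      onset <- round(base_start + config$decay_erosion_rate * mult * ti)
      mu <- numeric(len)
      ramp_end <- min(onset + ramp_len - 1L, len - tail3)
      if (ramp_end >= onset) {
        mu[onset:ramp_end] <- plateau * seq_len(ramp_end - onset + 1L) / ramp_len
      }
      if (ramp_end < len - tail3) mu[(ramp_end + 1L):(len - tail3)] <- plateau
      m[s, ] <- rpois(len, mu)
    }
    tracks[[gid]] <- m
  }
  structure(list(tracks = tracks, samples = samples,
                 tx_len = setNames(g$tx_len, g$gene_id)[names(tracks)],
                 excluded = excluded),
            class = "coverage_set")
}

#' Simulate a SLAM-seq conversion table
#'
#' Genes are labeled to saturation with 4sU, then chased; the fraction of
#' reads carrying >=1 T>C conversion at chase time t is
#' `background + (initial - background) * 2^(-t / half_life)`, with the
#' half-life taken from the ground truth (per condition: depletion lengthens
#' it for stabilized genes). Unlabeled (DMSO-labeling) samples sit at the
#' background conversion rate. Total reads are NB-distributed around
#' `slam_depth`; converted reads are binomial given the totals.
#'
#' Design cells: labeling {4sU, unlabeled} x chase 0 h, plus labeling x
#' degron {treated, control} at chase 8 h, each with `n_replicates`.
#'
#' @param config a [sim_config()].
#' @param truth output of [simulate_ground_truth()].
#' @param chase_hours chase duration for the degron/control contrast.
#' @return a `conversion_table` list: long `table` (gene_id, sample_id,
#'   total, tc) and `samples` metadata (labeling, degron, chase, replicate).
#' @export
simulate_slam <- function(config, truth, chase_hours = 8) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(config$seed + 4L)
  n <- nrow(truth$genes)

  samples <- rbind(
    expand.grid(labeling = c("4sU", "unlabeled"), degron = "control",
                chase = 0, replicate = seq_len(config$n_replicates),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    expand.grid(labeling = c("4sU", "unlabeled"),
                degron = c("control", "treated"),
                chase = chase_hours, replicate = seq_len(config$n_replicates),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  samples$sample_id <- sprintf("slam_%s_%s_c%02d_r%d", samples$labeling,
                               samples$degron, samples$chase,
                               samples$replicate)

  bg <- config$slam_background
  init <- config$slam_init_conversion
  rows <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    hl <- if (samples$degron[j] == "treated") truth$genes$half_life_degron
          else truth$genes$half_life_ctrl
    frac <- if (samples$labeling[j] == "4sU") {
      bg + (init - bg) * 2^(-samples$chase[j] / hl)
    } else {
      rep(bg, n)
    }
    ## replicate-level labeling/chase efficiency noise, then per-read
    ## Bernoulli conversion aggregated binomially
    sdlog <- sqrt(log(1 + config$slam_frac_cv^2))
    frac <- .clamp(frac * rlnorm(n, -sdlog^2 / 2, sdlog), 0, 1)
    total <- rnbinom(n, mu = config$slam_depth, size = 10) + 1L
    tc <- rbinom(n, total, frac)
    rows[[j]] <- data.frame(gene_id = truth$genes$gene_id,
                            sample_id = samples$sample_id[j],
                            total = total, tc = tc, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  .assert(all(tab$tc <= tab$total), "T>C reads exceed total reads")
  structure(list(table = tab, samples = samples),
            class = "conversion_table")
}
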