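test_that("simulated transcripts have well-formed structure", {
  fx <- small_sim()
  cds <- as.character(fx$ann$cds_seq)
  expect_true(all(nchar(cds) %% 3 == 0))
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  last <- substr(cds, nchar(cds) - 2, nchar(cds))
  expect_true(all(last %in% c("TAA", "TAG", "TGA")))
  ## no internal stops in frame
  internal_ok <- vapply(cds, function(s) {
    codons <- substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s) - 3, 3))
    !any(codons[-1] %in% c("TAA", "TAG", "TGA"))
  }, logical(1))
  expect_true(all(internal_ok))
  ## region intervals tile the transcript
  reg <- fx$ann$regions
  lens <- tapply(reg$end - reg$start + 1, reg$gene_id, sum)
  expect_equal(as.vector(lens[fx$ann$genes$gene_id]), fx$ann$genes$tx_len)
})

test_that("a degenerate GC target range is recovered in the emitted CDS", {
  cfg <- sim_config(n_genes = 40, gc_range = c(0.5, 0.5), seed = 3)
  ann <- simulate_annotation(cfg)
  gc <- gc_content(as.character(ann$cds_seq))
  ## positional jitter is zero-mean, discrete sampling adds binomial noise
  expect_true(all(abs(gc - 0.5) < 0.12))
  expect_lt(abs(mean(gc) - 0.5), 0.03)
})

test_that("identical configs give byte-identical FASTA and identical tables", {
  cfg <- sim_config(n_genes = 25, seed = 99)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_annotation(a1, tempfile(fileext = ".gtf"), f1)
  write_annotation(a2, tempfile(fileext = ".gtf"), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  t1 <- simulate_ground_truth(cfg, a1)
  t2 <- simulate_ground_truth(cfg, a2)
  expect_identical(t1, t2)
  expect_identical(simulate_counts(cfg, a1, t1), simulate_counts(cfg, a2, t2))
  expect_identical(simulate_slam(cfg, t1)$table, simulate_slam(cfg, t2)$table)
  cov1 <- simulate_coverage(cfg, a1, t1, gene_ids = a1$genes$gene_id[1:5])
  cov2 <- simulate_coverage(cfg, a2, t2, gene_ids = a2$genes$gene_id[1:5])
  expect_identical(cov1$tracks, cov2$tracks)
})

test_that("counts follow the NB moment identity var = mu + alpha mu^2", {
  ## many replicates at a single timepoint so per-gene moments are estimable
  cfg <- sim_config(n_genes = 300, n_replicates = 40, timepoints = 8,
                    frac_te_down = 0, frac_te_up = 0, dispersion = 0.1,
                    seed = 17)
  ann <- simulate_annotation(cfg)
  truth <- simulate_ground_truth(cfg, ann)
  cts <- simulate_counts(cfg, ann, truth)
  sel <- cts$design$assay == "RNA" & cts$design$condition == "control"
  m <- sweep(cts$counts[, sel], 2, cts$design$lib_factor[sel], "/")
  mu <- cts$baseline$baseline_rna
  ## var(count/l) = mu/l + alpha mu^2; compare observed to expected per gene
  lf <- cts$design$lib_factor[sel]
  expected <- mu * mean(1 / lf) + 0.1 * mu^2
  ratio <- apply(m, 1, var) / expected
  ## mean ratio ~ 1 within 3 standard errors of the gene-averaged ratio
  expect_lt(abs(mean(ratio) - 1), 3 * sd(ratio) / sqrt(length(ratio)))
})

test_that("null genes are unchanged and TE_down genes follow the planted lag", {
  fx <- small_sim()
  tr <- fx$truth; cfg <- fx$cfg
  expect_true(all(tr$rna_lfc[tr$genes$class == "null", ] == 0))
  down <- tr$genes$class == "TE_down"
  ## translation suppressed from the first timepoint, RNA unchanged there
  expect_true(all(tr$ribo_lfc[down, 1] < 0))
  expect_true(all(tr$rna_lfc[down, 1] == 0))
  ## RNA up at the final timepoint (by construction)
  expect_true(all(tr$rna_lfc[down, ncol(tr$rna_lfc)] > 0))
  ## onset respects lag_hours
  onset <- min(cfg$timepoints) + cfg$lag_hours
  pre <- cfg$timepoints < onset
  expect_true(all(tr$rna_lfc[down, pre] == 0))
  ## counts realize the pattern: treated/control ratio ~1 for null genes
  des <- fx$counts$design
  sel_t <- des$assay == "RNA" & des$condition == "treated" & des$timepoint == 48
  sel_c <- des$assay == "RNA" & des$condition == "control" & des$timepoint == 48
  r <- rowMeans(sweep(fx$counts$counts[, sel_t], 2,
                      des$lib_factor[sel_t], "/")) /
    rowMeans(sweep(fx$counts$counts[, sel_c], 2, des$lib_factor[sel_c], "/"))
  expect_lt(abs(median(r[tr$genes$class == "null"]) - 1), 0.1)
  expect_gt(median(r[down]), 1.3)
})

test_that("RNA stabilization amplitude increases with GCcds in TE_down genes", {
  cfg <- sim_config(n_genes = 2000, seed = 8)
  ann <- simulate_annotation(cfg)
  tr <- simulate_ground_truth(cfg, ann)
  down <- tr$genes$class == "TE_down"
  rho <- cor(tr$genes$gc_cds[down], tr$rna_lfc[down, ncol(tr$rna_lfc)],
             method = "spearman")
  expect_gt(rho, 0)
  expect_lt(cor.test(tr$genes$gc_cds[down],
                     tr$rna_lfc[down, ncol(tr$rna_lfc)],
                     method = "spearman", exact = FALSE)$p.value, 1e-6)
})

test_that("SLAM tables conserve reads and track the decay identity", {
  fx <- small_sim()
  slam <- simulate_slam(fx$cfg, fx$truth)
  expect_true(all(slam$table$tc <= slam$table$total))
  expect_true(all(slam$table$tc >= 0))
  cf <- conversion_fractions(slam)
  unl <- cf[cf$labeling == "unlabeled", ]
  expect_lt(abs(mean(unl$frac_tc) - fx$cfg$slam_background), 0.01)
  ## exponential decay: with no replicate noise and zero background, the
  ## chase-8h fraction of a gene equals its chase-0 fraction * 2^(-8/hl)
  cfg0 <- sim_config(n_genes = 400, slam_frac_cv = 0, slam_background = 0,
                     slam_depth = 2000, seed = 21)
  ann0 <- simulate_annotation(cfg0)
  tr0 <- simulate_ground_truth(cfg0, ann0)
  cf0 <- conversion_fractions(simulate_slam(cfg0, tr0))
  lab <- cf0[cf0$labeling == "4sU" & cf0$degron == "control", ]
  f0 <- tapply(lab$frac_tc[lab$chase == 0], lab$gene_id[lab$chase == 0], mean)
  f8 <- tapply(lab$frac_tc[lab$chase == 8], lab$gene_id[lab$chase == 8], mean)
  expected <- setNames(2^(-8 / tr0$genes$half_life_ctrl),
                       tr0$genes$gene_id)
  expect_lt(median(abs(f8 / f0 - expected[names(f8)])), 0.03)
  ## stabilized genes retain more label under depletion
  cfs <- cf[cf$labeling == "4sU" & cf$chase == 8, ]
  ret <- tapply(cfs$frac_tc[cfs$degron == "treated"],
                cfs$gene_id[cfs$degron == "treated"], mean) -
    tapply(cfs$frac_tc[cfs$degron == "control"],
           cfs$gene_id[cfs$degron == "control"], mean)
  cls <- setNames(fx$truth$genes$class, fx$truth$genes$gene_id)[names(ret)]
  expect_gt(median(ret[cls == "TE_down"]), median(ret[cls == "null"]))
})

test_that("zero erosion keeps coverage starts fixed across samples", {
  cfg <- sim_config(n_genes = 30, decay_erosion_rate = 0, seed = 13)
  ann <- simulate_annotation(cfg)
  tr <- simulate_ground_truth(cfg, ann)
  cov <- simulate_coverage(cfg, ann, tr)
  starts <- lapply(cov$tracks, function(m) {
    apply(m, 1, detect_start, threshold = 0.15)
  })
  spread <- vapply(starts, function(s) diff(range(s)), numeric(1))
  ## Poisson noise moves the detected crossing by a few nt at most
  expect_lte(median(spread), 8)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(frac_te_down = 0.7, frac_te_up = 0.5), "<= 1")
  expect_error(sim_config(timepoints = c(8, 4)), "increasing")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(n_genes = 0), "n_genes")
})
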