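test_that("median-of-ratios size factors recover library scaling", {
  set.seed(1)
  base <- rnbinom(500, mu = 200, size = 20) + 1L
  counts <- cbind(A = base, B = 2L * base, C = base)
  sf <- size_factors(counts)
  expect_equal(sf[["B"]] / sf[["A"]], 2, tolerance = 1e-8)
  expect_equal(sf[["C"]] / sf[["A"]], 1, tolerance = 1e-8)
})

test_that("the NB GLM recovers a planted fold change", {
  set.seed(2)
  n_genes <- 60
  mu <- 200; alpha <- 0.05
  counts <- t(vapply(seq_len(n_genes), function(i) {
    c(rnbinom(4, mu = mu, size = 1 / alpha),
      rnbinom(4, mu = mu * 2, size = 1 / alpha))
  }, numeric(8)))
  rownames(counts) <- paste0("g", seq_len(n_genes))
  design <- data.frame(condition = factor(rep(c("control", "treated"),
                                              each = 4),
                                          c("control", "treated")))
  fit <- fit_nb_glm(counts, design, ~ condition, ~ 1, sf = rep(1, 8))
  lfc <- fit$coef[, "conditiontreated"] / log(2)
  expect_lt(abs(mean(lfc) - 1), 0.1)
  ## per-gene sampling error at this design is ~0.24 log2 units
  expect_lt(median(abs(lfc - 1)), 0.3)
  expect_gt(mean(abs(lfc - 1) < 0.3), 0.7)
  ## optimizer sanity: fitted model never fits worse than the null model
  expect_true(all(fit$lrt_stat >= 0))
  ## all-zero genes are excluded with a report
  counts0 <- rbind(counts, zero = rep(0L, 8))
  fit0 <- fit_nb_glm(counts0, design, ~ condition, ~ 1, sf = rep(1, 8))
  expect_identical(fit0$excluded, "zero")
  expect_false("zero" %in% rownames(fit0$coef))
})

test_that("BH adjustment equals a brute-force sort-and-threshold oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(9)
  for (i in 1:1000) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), bh_oracle(p))
  }
})

test_that("te_test flags planted TE classes and respects assay symmetry", {
  fx <- small_sim()
  te <- te_test(fx$counts, 48)
  m <- merge(te, fx$truth$genes, by = "gene_id")
  down <- m$class.y == "TE_down"
  expect_gt(mean(m$class.x[down] == "TE_down"), 0.8)
  ## adjusted p never below raw p; NS exactly when padj >= threshold
  expect_true(all(te$padj >= te$pvalue))
  expect_identical(te$class == "NS", te$padj >= 0.05)
  ## swapping assay labels flips the sign of every interaction estimate
  cts_sw <- fx$counts
  cts_sw$design$assay <- ifelse(cts_sw$design$assay == "RNA", "Ribo", "RNA")
  te_sw <- te_test(cts_sw, 48)
  expect_equal(te_sw$log2fc_te, -te$log2fc_te, tolerance = 1e-6)
})

test_that("the re-implemented NB GLM agrees with an established reference", {
  skip_if_not_installed("DESeq2")
  set.seed(12)
  n <- 80
  mu <- rlnorm(n, log(200), 0.6)
  lfc <- rnorm(n, 0, 0.8)
  counts <- t(vapply(seq_len(n), function(i) {
    c(rnbinom(3, mu = mu[i], size = 20),
      rnbinom(3, mu = mu[i] * 2^lfc[i], size = 20))
  }, numeric(6)))
  rownames(counts) <- paste0("g", seq_len(n))
  storage.mode(counts) <- "integer"
  design <- data.frame(condition = factor(rep(c("control", "treated"),
                                              each = 3),
                                          c("control", "treated")))
  fit <- fit_nb_glm(counts, design, ~ condition, ~ 1)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(counts, design, ~ condition)
    dds <- DESeq2::DESeq(dds, test = "LRT", reduced = ~ 1, quiet = TRUE)
  })
  ## identical size-factor definition
  expect_equal(unname(fit$sf), unname(DESeq2::sizeFactors(dds)),
               tolerance = 1e-6)
  ## fold-change estimates agree closely (different dispersion moderation)
  ref <- DESeq2::results(dds)
  ours <- fit$coef[, "conditiontreated"] / log(2)
  expect_gt(cor(ours, ref$log2FoldChange), 0.99)
  expect_lt(median(abs(ours - ref$log2FoldChange)), 0.1)
  ## significance calls broadly coincide
  expect_gt(cor(-log10(fit$pvalue), -log10(ref$pvalue)), 0.9)
})

test_that("coordinate groups follow the documented membership rules", {
  mk <- function(lfc, padj) data.frame(gene_id = paste0("g", seq_along(lfc)),
                                       log2fc = lfc, pvalue = padj,
                                       padj = padj)
  rna <- mk(c(1, 1, 0.05, 1, 0), c(0.001, 0.001, 0.5, 0.001, 0.9))
  ribo <- mk(c(-1, 1, -1, 0.02, 0), c(0.001, 0.001, 0.001, 0.3, 0.9))
  grp <- classify_coordinate_groups(rna, ribo)
  expect_equal(as.character(grp), c("-xy", "xy", "y", "x", "NS"))
  ## order invariance
  perm <- c(3, 5, 1, 2, 4)
  grp_p <- classify_coordinate_groups(rna[perm, ], ribo[perm, ])
  expect_equal(as.character(grp_p), as.character(grp)[perm])
})

test_that("the vector field conserves genes and nulls out static input", {
  gc <- setNames(runif(50, 0.3, 0.8), paste0("g", 1:50))
  static <- data.frame(gene_id = paste0("g", 1:50),
                       log2fc_rna = rnorm(50), log2fc_ribo = rnorm(50))
  vf <- vector_field(list(static, static, static), gc, n_bins = 10)
  expect_true(all(vf$d_rna == 0) && all(vf$d_ribo == 0))
  for (tr in unique(vf$transition)) {
    expect_equal(sum(vf$n[vf$transition == tr]), 50)
  }
  ## per-cell mean GC stays within the observed range
  expect_true(all(vf$mean_gc >= min(gc) & vf$mean_gc <= max(gc)))
  expect_error(vector_field(list(static), gc), ">= 2 timepoints")
})

test_that("planted dynamics point toward rising RNA in suppressed cells", {
  fx <- small_sim()
  tps <- fx$cfg$timepoints
  te_by_tp <- lapply(tps, function(t) te_test(fx$counts, t))
  final <- te_by_tp[[length(te_by_tp)]]
  sig <- final$gene_id[final$class != "NS"]
  lfc <- lapply(te_by_tp, function(d) {
    data.frame(gene_id = d$gene_id, log2fc_rna = d$log2fc_rna,
               log2fc_ribo = d$log2fc_ribo)
  })
  gc <- setNames(fx$ann$genes$gc_cds, fx$ann$genes$gene_id)
  vf <- vector_field(lfc, gc, n_bins = 20, genes = sig)
  late <- vf[vf$transition >= 2 & vf$bin_y < 0, ]  # suppressed half-plane
  expect_gt(weighted.mean(late$d_rna, late$n), 0)
})
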