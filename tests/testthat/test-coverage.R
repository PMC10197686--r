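# linear-scan start detector used as the independent oracle
start_oracle <- function(v, tau) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(NA_integer_)
  for (i in seq_along(v)) {
    if ((v[i] - lo) / (hi - lo) > tau) return(i)
  }
  NA_integer_
}

test_that("detect_start finds the documented crossing positions", {
  expect_equal(detect_start(c(0, 0, 0, 1, 1, 1)), 4L)
  ramp <- (1:100) / 100          # linear 0 -> 1 over 100 nt
  expect_equal(detect_start(ramp), 16L)
  expect_true(is.na(detect_start(rep(5, 10))))   # flat: excluded
  expect_true(is.na(detect_start(rep(0, 10))))
  ## max-only normalization differs when the minimum is positive
  v <- c(20, 20, 22, 100, 100)
  expect_equal(detect_start(v), 4L)                  # min subtracted
  expect_equal(detect_start(v, max_only = TRUE), 1L) # 20/100 > 0.15
})

test_that("detect_start equals the brute-force scan across thresholds", {
  set.seed(3)
  for (i in 1:1000) {
    v <- rpois(sample(20:80, 1), lambda = sample(c(0.5, 2, 10), 1))
    for (tau in c(0.05, 0.15, 0.30)) {
      expect_identical(detect_start(v, tau), start_oracle(v, tau))
    }
  }
})

test_that("detection and window means are invariant to profile scaling", {
  set.seed(8)
  v <- c(rep(0, 30), seq(0, 50, length.out = 40), rep(50, 130)) + rpois(200, 2)
  expect_equal(detect_start(v), detect_start(v * 7.3))
  m <- rbind(a = v, b = v * 2, c = v * 0.5, d = v)
  lfc1 <- window_coverage_change(m, 60, 40, control = c(TRUE, FALSE, FALSE,
                                                        TRUE))
  m2 <- m * 13
  lfc2 <- window_coverage_change(m2, 60, 40, control = c(TRUE, FALSE, FALSE,
                                                         TRUE))
  expect_equal(lfc1, lfc2)
  ## identical treated and control profiles give log2FC 0; a doubled
  ## normalized window mean gives exactly 1 only pre-normalization, so use
  ## a synthetic normalized pair
  flat <- rbind(ctrl = c(rep(0, 10), rep(2, 30)),
                tr = c(rep(0, 10), rep(2, 30)))
  expect_equal(unname(window_coverage_change(flat, 20, 10,
                                             c(TRUE, FALSE))[2]), 0)
})

test_that("trajectory_beta matches closed-form OLS and plain differences", {
  vals <- c(0, 0.5, 1.0, 1.5, 2.0)
  expect_equal(trajectory_beta(vals, mode = "regression"), 0.5)
  expect_equal(trajectory_beta(vals, mode = "regression",
                               intercept = FALSE), 0.5)
  ## closed form with an intercept on an arbitrary series
  y <- c(1, 3, 2, 5)
  x <- 0:3
  beta_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(trajectory_beta(y, mode = "regression"), beta_hat)
  expect_equal(trajectory_beta(rep(2, 4), mode = "regression"), 0)
  expect_equal(trajectory_beta(c(120, 100), mode = "difference"), -20)
  expect_error(trajectory_beta(c(1, 2), mode = "regression"), ">= 3")
  expect_error(trajectory_beta(c(1, 2, 3), mode = "difference"), "exactly 2")
})

test_that("major-isoform selection applies the documented tie-breaks", {
  tot <- data.frame(gene_id = c("g1", "g1", "g2", "g2", "g3"),
                    tx_id = c("t1a", "t1b", "t2a", "t2b", "t3"),
                    total = c(1000, 400, 500, 500, 0),
                    tx_len = c(800, 900, 900, 1200, 700))
  res <- select_major_isoform(tot)
  expect_equal(res$tx_id[res$gene_id == "g1"], "t1a")  # higher coverage
  expect_equal(res$tx_id[res$gene_id == "g2"], "t2b")  # tie: longer wins
  expect_identical(attr(res, "excluded"), "g3")        # zero coverage
  ## exact tie in coverage and length: lexicographically smaller id
  tot2 <- data.frame(gene_id = "g", tx_id = c("tB", "tA"),
                     total = c(10, 10), tx_len = c(500, 500))
  expect_equal(select_major_isoform(tot2)$tx_id, "tA")
})

test_that("coverage statistics recover planted erosion dynamics", {
  cfg <- sim_config(n_genes = 250, seed = 9)
  ann <- simulate_annotation(cfg)
  tr <- simulate_ground_truth(cfg, ann)
  cov <- simulate_coverage(cfg, ann, tr)
  cs <- coverage_stats(cov)
  m <- merge(cs, tr$genes, by = "gene_id")
  ## treated-sample start slope = erosion rate x class multiplier,
  ## recovered within a few nt per timepoint step
  for (cl in c("null", "TE_down", "TE_up")) {
    planted <- cfg$decay_erosion_rate * unique(m$erosion_mult[m$class == cl])
    expect_lt(abs(median(m$beta_start[m$class == cl]) - planted), 2)
  }
  ## stabilized genes gain 5' coverage relative to control
  cls <- data.frame(gene_id = tr$genes$gene_id,
                    class = c(null = "control", TE_down = "stabilized",
                              TE_up = "degraded")[tr$genes$class])
  ct <- compare_classes(cs, cls, "beta_cov")
  expect_lt(ct$p_value[ct$comparison == "stabilized_vs_control"], 0.01)
  expect_lt(ct$p_value[ct$comparison == "degraded_vs_control"], 0.01)
  ct_start <- compare_classes(cs, cls, "beta_start")
  expect_lt(ct_start$p_value[ct_start$comparison == "stabilized_vs_control"],
            0.01)
  ## no effect at the 3' end (held fixed by construction)
  cs3 <- coverage_stats(cov, end = "three")
  ct3 <- compare_classes(cs3, cls, "beta_cov")
  expect_true(all(ct3$p_value > 0.01))
})

test_that("comparison classes honor ranking and control filters", {
  set.seed(4)
  rna <- data.frame(gene_id = paste0("g", 1:300),
                    log2fc = c(rnorm(100, 2), rnorm(100, -2), rnorm(100, 0)),
                    pvalue = c(runif(100, 0, 1e-4), runif(100, 0, 1e-4),
                               runif(100, 0.3, 1)))
  rna$padj <- p.adjust(rna$pvalue, "BH")
  tpm <- setNames(rep(10, 300), rna$gene_id)
  tpm[paste0("g", 201:210)] <- 1   # low-TPM genes cannot be controls
  cls <- select_comparison_classes(rna, tpm, n_top = 50, n_control = 80)
  expect_equal(sum(cls$class == "stabilized"), 50)
  expect_equal(sum(cls$class == "degraded"), 50)
  ctrl <- cls$gene_id[cls$class == "control"]
  expect_true(all(tpm[ctrl] > 3))
  expect_true(all(rna$pvalue[match(ctrl, rna$gene_id)] > 0.2))
  ## scales down proportionally when the pools are small
  cls2 <- select_comparison_classes(rna, tpm, n_top = 250, n_control = 1500)
  expect_lt(sum(cls2$class == "stabilized"), 250)
})
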