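test_that("gc_content handles plain, ambiguous and degenerate input", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATGGCGTAA"), 4 / 9)
  expect_equal(gc_content("GCNN"), 1.0)      # N excluded from denominator
  expect_true(is.na(gc_content("NNN")))
  expect_true(is.na(gc_content("")))
  expect_equal(gc_content(c("AT", "GC")), c(0, 1))  # vectorized
})

test_that("gc_content and codon_position_gc match a brute-force oracle", {
  set.seed(101)
  for (i in 1:1000) {
    s <- random_cds_string(sample(2:40, 1))
    expect_equal(gc_content(s), gc_oracle(s))
    ch <- strsplit(s, "")[[1]]
    pos <- (seq_along(ch) - 1) %% 3 + 1
    expected <- vapply(1:3, function(k) {
      b <- ch[pos == k]
      mean(b %in% c("G", "C"))
    }, numeric(1))
    expect_equal(unname(codon_position_gc(s)), expected)
  }
})

test_that("positional GC averages to overall CDS GC", {
  set.seed(7)
  for (i in 1:50) {
    s <- random_cds_string(sample(10:100, 1))
    expect_equal(mean(codon_position_gc(s)), gc_content(s))
  }
  expect_equal(unname(codon_position_gc("GCAGCAGCA")), c(1, 1, 0))
  expect_equal(unname(codon_position_gc("AAA")), c(0, 0, 0))
  expect_error(codon_position_gc("ATGC", gene_id = "gX"), "gX")
})

test_that("codon_frequencies count sense codons and exclude stops", {
  f <- codon_frequencies("ATGTAA")
  expect_equal(unname(f["ATG"]), 1)
  expect_equal(sum(f), 1)
  f2 <- codon_frequencies("ATGATGTGA")
  expect_equal(unname(f2["ATG"]), 1)
  poly <- paste0("ATG", strrep("GCT", 9), "TAA")
  f3 <- codon_frequencies(poly)
  expect_equal(unname(f3["GCT"]), 9 / 10)
  expect_equal(unname(f3["ATG"]), 1 / 10)
  expect_warning(codon_frequencies("ATGTAAATGTAA"), "internal stop")
  expect_warning(codon_frequencies("GCGGCG"), "does not start with ATG")
  expect_error(codon_frequencies("ATGC"), "divisible by 3")
})

test_that("codon_frequencies match a brute-force tabulation oracle", {
  set.seed(55)
  for (i in 1:1000) {
    s <- paste0("ATG", random_cds_string(sample(1:30, 1)))
    f <- suppressWarnings(codon_frequencies(s))
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    sense <- codons[!codons %in% c("TAA", "TAG", "TGA")]
    oracle <- vapply(sense_codons(), function(cd) sum(sense == cd), 0) /
      length(sense)
    expect_equal(unname(f), unname(oracle))
  }
  expect_equal(sum(nchar(sense_codons())), 61 * 3)
})

test_that("the feature table is complete, documented and order-insensitive", {
  fx <- small_sim()
  feat <- region_features(fx$ann, fx$counts)
  expect_equal(nrow(feat), nrow(fx$ann$genes))
  expect_true(all(c("log_tpm", "base_TE", "mature_level", "GCcds",
                    "GCpos1", "GCpos2", "GCpos3") %in% names(feat)))
  expect_equal(sum(grepl("^codonfr_", names(feat))), 61)
  gc_cols <- grep("^GC", names(feat), value = TRUE)
  for (cc in gc_cols) expect_true(all(feat[[cc]] >= 0 & feat[[cc]] <= 1))
  ## codon frequencies sum to 1 per gene
  cf <- as.matrix(feat[, grepl("^codonfr_", names(feat))])
  expect_true(all(abs(rowSums(cf) - 1) < 1e-9))
  ## GCcds identity with positional GC and with the emitted FASTA
  expect_equal(feat$GCcds, rowMeans(feat[, c("GCpos1", "GCpos2", "GCpos3")]))
  ord <- match(feat$gene_id, fx$ann$genes$gene_id)
  expect_equal(feat$GCcds,
               gc_content(as.character(
                 fx$ann$cds_seq[fx$ann$genes$tx_id[ord]])))
  ## permuting the count matrix rows leaves the table unchanged
  cts2 <- fx$counts
  perm <- sample(nrow(cts2$counts))
  cts2$counts <- cts2$counts[perm, ]
  expect_equal(region_features(fx$ann, cts2), feat)
  ## intronless genes carry sentinels, never NA
  no_int <- feat$gene_id %in%
    fx$ann$genes$gene_id[fx$ann$genes$n_introns == 0]
  if (any(no_int)) {
    expect_true(all(feat$loglen_intron[no_int] == -1))
    expect_true(all(feat$posdens_rna_intron[no_int] == 0))
  }
  expect_false(anyNA(feat[, setdiff(names(feat), "gene_id")]))
})

test_that("baseline TE is zero in log scale for equal Ribo and RNA signal", {
  fx <- small_sim()
  cts2 <- fx$counts
  des <- cts2$design
  rna_cols <- des$assay == "RNA" & des$condition == "control"
  ribo_cols <- des$assay == "Ribo" & des$condition == "control"
  cts2$counts[, ribo_cols] <- cts2$counts[, rna_cols]
  feat <- region_features(fx$ann, cts2)
  expect_true(all(abs(feat$base_TE) < 1e-12))
})

test_that("partition_by_gc cuts, tests and reports degenerate groups", {
  ## constant gc: a single populated group, tests skipped
  res <- partition_by_gc(rnorm(20), rep(0.5, 20), n_groups = 3)
  expect_equal(sum(res$summary$n > 0), 1)
  ## planted monotone signal
  gc <- rep(c(0.3, 0.5, 0.7), each = 40)
  vals <- gc + rnorm(120, sd = 0.05)
  res2 <- partition_by_gc(vals, gc, n_groups = 3)
  expect_true(all(diff(res2$summary$median) > 0))
  p_extreme <- res2$pairwise$p_value[
    res2$pairwise$group1 == res2$summary$group[1] &
      res2$pairwise$group2 == res2$summary$group[3]]
  expect_lt(p_extreme, 0.05)
  ## half-life negatively coupled to gc on ~220 genes: the GC-rich group
  ## has the lowest median half-life
  set.seed(31)
  gc3 <- runif(220, 0.35, 0.75)
  hl <- 10 - 8 * gc3 + rnorm(220, sd = 0.8)
  res3 <- partition_by_gc(hl, gc3, n_groups = 3)
  expect_equal(which.min(res3$summary$median), 3L)
  expect_error(partition_by_gc(1:5, runif(5), n_groups = 1), ">= 2")
})
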