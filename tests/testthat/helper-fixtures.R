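# Shared small simulation fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_config(n_genes = 150, seed = 42)
    ann <- simulate_annotation(cfg)
    truth <- simulate_ground_truth(cfg, ann)
    counts <- simulate_counts(cfg, ann, truth)
    .fixture_env$small <- list(cfg = cfg, ann = ann, truth = truth,
                               counts = counts)
  }
  .fixture_env$small
}

# random CDS-like sequence (length divisible by 3) for oracle loops
random_cds_string <- function(n_codons) {
  paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE),
        collapse = "")
}

# character-counting GC oracle, independent of the package implementation
gc_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  acgt <- ch[ch %in% c("A", "C", "G", "T")]
  if (!length(acgt)) return(NA_real_)
  sum(acgt %in% c("G", "C")) / length(acgt)
}
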