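#' Simulate a transcript annotation with sequences
#'
#' One transcript per gene, with 5'UTR, CDS (ATG start, stop codon, length
#' divisible by 3, no internal stops) and 3'UTR, plus 0-2 introns inserted
#' into the pre-mRNA. Per-gene target GCcds is drawn uniformly over
#' `config$gc_range`; GC targets at the three codon positions receive
#' independent jitter (wider at the wobble position) so that positional GC
#' tracks, but does not duplicate, overall GCcds. The realized GCcds of each
#' emitted CDS is recorded.
#'
#' All genes live on the plus strand, each on its own contig named after the
#' gene, so genomic and pre-mRNA coordinates coincide.
#'
#' @param config a [sim_config()].
#' @return a `transcript_annotation` list: `genes` (per-gene table with
#'   region lengths and realized GC content), `regions` (per-region intervals
#'   in 1-based transcript coordinates), `tx_seq`/`cds_seq`
#'   ([Biostrings::DNAStringSet] of mature transcript and CDS), `utr5_seq`,
#'   `utr3_seq`, `intron_seq` (per-gene concatenated introns, possibly empty),
#'   and `introns` (insertion points in transcript coordinates and lengths).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  tx_id <- sprintf("T%05d", seq_len(n))

  gc_target <- runif(n, config$gc_range[1], config$gc_range[2])
  utr5_len <- sample(50:300, n, replace = TRUE)
  n_codons <- sample(100:500, n, replace = TRUE)  # internal codons
  utr3_len <- sample(100:500, n, replace = TRUE)
  n_introns <- sample(0:2, n, replace = TRUE)
  cds_len <- 3L * (n_codons + 2L)                 # + start and stop codons

  cds_seq <- character(n)
  utr5_seq <- character(n)
  utr3_seq <- character(n)
  intron_seq <- vector("list", n)
  intron_pos <- vector("list", n)   # transcript position after which intron sits
  intron_len <- vector("list", n)

  for (i in seq_len(n)) {
    cds_seq[i] <- .random_cds(n_codons[i], gc_target[i])
    utr5_seq[i] <- .random_seq(utr5_len[i], 0.45)
    utr3_seq[i] <- .random_seq(utr3_len[i], 0.40)
    k <- n_introns[i]
    tx_len_i <- utr5_len[i] + cds_len[i] + utr3_len[i]
    if (k > 0) {
      il <- sample(100:1000, k, replace = TRUE)
      ip <- sort(sample(seq(utr5_len[i] + 3L, tx_len_i - utr3_len[i]), k))
      intron_len[[i]] <- il
      intron_pos[[i]] <- ip
      intron_seq[[i]] <- vapply(il, .random_seq, "", gc = 0.40)
    } else {
      intron_len[[i]] <- integer(0)
      intron_pos[[i]] <- integer(0)
      intron_seq[[i]] <- character(0)
    }
  }
  .assert(all(nchar(cds_seq) %% 3 == 0), "CDS length not divisible by 3")

  tx_seq <- paste0(utr5_seq, cds_seq, utr3_seq)
  tx_len <- nchar(tx_seq)
  gc_cds <- gc_content(cds_seq)

  genes <- data.frame(
    gene_id = gene_id, tx_id = tx_id,
    utr5_len = utr5_len, cds_len = cds_len, utr3_len = utr3_len,
    tx_len = tx_len, n_introns = n_introns,
    intron_len_total = vapply(intron_len, sum, 0),
    gc_target = gc_target, gc_cds = gc_cds,
    stringsAsFactors = FALSE)

  regions <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(
      gene_id = gene_id[i], tx_id = tx_id[i],
      region = c("utr5", "cds", "utr3"),
      start = c(1L, utr5_len[i] + 1L, utr5_len[i] + cds_len[i] + 1L),
      end = c(utr5_len[i], utr5_len[i] + cds_len[i], tx_len[i]),
      stringsAsFactors = FALSE)
  }))

  ann <- list(
    genes = genes, regions = regions,
    tx_seq = Biostrings::DNAStringSet(setNames(tx_seq, tx_id)),
    cds_seq = Biostrings::DNAStringSet(setNames(cds_seq, tx_id)),
    utr5_seq = setNames(utr5_seq, gene_id),
    utr3_seq = setNames(utr3_seq, gene_id),
    intron_seq = setNames(intron_seq, gene_id),
    introns = list(pos = setNames(intron_pos, gene_id),
                   len = setNames(intron_len, gene_id)))
  class(ann) <- "transcript_annotation"
  ann
}

## CDS builder: ATG + n internal sense codons + one stop codon.
## Internal codon bases are drawn position-wise with jittered positional GC
## targets; internal stops are repaired by forcing the third base to C.
.random_cds <- function(n_internal, gc) {
  g1 <- .clamp(gc + runif(1, -0.06, 0.06), 0.10, 0.90)
  g2 <- .clamp(gc + runif(1, -0.06, 0.06), 0.10, 0.90)
  g3 <- .clamp(gc + runif(1, -0.18, 0.18), 0.10, 0.90)
  draw <- function(g) {
    sample(c("A", "C", "G", "T"), n_internal, replace = TRUE,
           prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2))
  }
  b1 <- draw(g1); b2 <- draw(g2); b3 <- draw(g3)
  codons <- paste0(b1, b2, b3)
  bad <- codons %in% c("TAA", "TAG", "TGA")
  codons[bad] <- paste0(substr(codons[bad], 1, 2), "C")
  paste0("ATG", paste(codons, collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}

#' Plant the ground-truth regulatory structure
#'
#' Assigns each gene a class (`TE_down`, `TE_up`, `null`) and builds the true
#' log2 fold-change trajectories the count simulator realizes. TE_down genes
#' lose ribosome occupancy from the first timepoint (delta-TE drawn from
#' `te_amp_range`, negative) and gain mRNA from `min(timepoints) + lag_hours`
#' on, with an RNA amplitude increasing in realized GCcds:
#' `max(0.1, 1.25 + gc_effect_size * (GCcds - 0.55))`. TE_up genes mirror the
#' pattern with a GC-independent RNA loss. Ribo-seq trajectories are the sum
#' of the RNA trajectory and the delta-TE component, so translation and mRNA
#' changes anti-correlate for regulated genes. Also draws per-condition SLAM
#' half-lives (doubled under depletion for stabilized genes, 0.6x for
#' destabilized ones) and 5' coverage-erosion multipliers (0.4 stabilized /
#' 1.6 degraded / 1 otherwise).
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_annotation()].
#' @return a `ground_truth` list: `genes` table and `rna_lfc` / `ribo_lfc`
#'   matrices (genes x timepoints, log2 units, treated vs control).
#' @export
simulate_ground_truth <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "transcript_annotation"))
  set.seed(config$seed + 1L)
  n <- config$n_genes
  tp <- config$timepoints
  gc <- annotation$genes$gc_cds

  n_down <- round(config$frac_te_down * n)
  n_up <- round(config$frac_te_up * n)
  cls <- rep("null", n)
  idx <- sample.int(n, n_down + n_up)
  cls[idx[seq_len(n_down)]] <- "TE_down"
  cls[idx[n_down + seq_len(n_up)]] <- "TE_up"

  te_amp <- runif(n, config$te_amp_range[1], config$te_amp_range[2])
  te_lfc_amp <- ifelse(cls == "TE_down", -te_amp,
                       ifelse(cls == "TE_up", te_amp, 0))
  rna_amp <- numeric(n)
  rna_amp[cls == "TE_down"] <-
    pmax(0.1, 1.25 + config$gc_effect_size * (gc[cls == "TE_down"] - 0.55))
  rna_amp[cls == "TE_up"] <- -runif(sum(cls == "TE_up"), 0.6, 1.2)

  onset_rna <- min(tp) + config$lag_hours
  rna_on <- outer(rep(1, n), as.numeric(tp >= onset_rna))
  rna_lfc <- rna_amp * rna_on
  ribo_lfc <- rna_lfc + te_lfc_amp  # delta-TE active from the first timepoint

  hl_ctrl <- rlnorm(n, log(6), 0.4)
  hl_mult <- ifelse(cls == "TE_down", 2, ifelse(cls == "TE_up", 0.6, 1))
  erosion_mult <- ifelse(cls == "TE_down", 0.4,
                         ifelse(cls == "TE_up", 1.6, 1))
  base_start <- sample(30:80, n, replace = TRUE)

  genes <- data.frame(
    gene_id = annotation$genes$gene_id, class = cls, gc_cds = gc,
    te_amp = te_lfc_amp, rna_amp = rna_amp,
    half_life_ctrl = hl_ctrl, half_life_degron = hl_ctrl * hl_mult,
    coverage_base_start = base_start, erosion_mult = erosion_mult,
    stringsAsFactors = FALSE)
  dimnames(rna_lfc) <- dimnames(ribo_lfc) <-
    list(genes$gene_id, paste0("t", tp))
  truth <- list(genes = genes, rna_lfc = rna_lfc, ribo_lfc = ribo_lfc,
                timepoints = tp)
  class(truth) <- "ground_truth"
  truth
}
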