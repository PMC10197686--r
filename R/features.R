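## Sense codons: the 61 non-stop codons of the standard genetic code.
.stop_codons <- c("TAA", "TAG", "TGA")

#' The 61 sense codons of the standard genetic code
#' @return character vector, alphabetical order.
#' @export
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(setdiff(all64, .stop_codons))
}

.base_counts <- function(seqs) {
  m <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                   c("A", "C", "G", "T"))
  m
}

#' GC content of nucleotide sequences
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` (or any ambiguity code) is excluded
#' from the denominator. Vectorized over sequences.
#'
#' @param sequence character vector over A/C/G/T/N.
#' @return numeric fraction in `[0, 1]`; `NA` for empty or all-N sequences.
#' @export
gc_content <- function(sequence) {
  .assert(is.character(sequence), "sequence must be character")
  out <- rep(NA_real_, length(sequence))
  ok <- !is.na(sequence) & nzchar(sequence)
  if (any(ok)) {
    m <- .base_counts(sequence[ok])
    tot <- rowSums(m)
    gc <- (m[, "G"] + m[, "C"]) / tot
    gc[tot == 0] <- NA_real_
    out[ok] <- gc
  }
  out
}

#' GC content at the three codon positions of a CDS
#'
#' Position k takes nucleotides k, k+3, k+6, ... The unweighted mean of the
#' three equals the overall GC content of the CDS.
#'
#' @param cds a single CDS string, length divisible by 3.
#' @param gene_id optional label used in error messages.
#' @return named numeric vector `c(gc1, gc2, gc3)`.
#' @export
codon_position_gc <- function(cds, gene_id = NULL) {
  .assert(length(cds) == 1L && !is.na(cds), "cds must be a single string")
  .assert(nchar(cds) %% 3 == 0,
          "CDS length not divisible by 3%s",
          if (is.null(gene_id)) "" else paste0(" for gene ", gene_id))
  ch <- strsplit(cds, "", fixed = TRUE)[[1]]
  pos <- (seq_along(ch) - 1L) %% 3L + 1L
  vapply(1:3, function(k) {
    b <- ch[pos == k]
    b <- b[b %in% c("A", "C", "G", "T")]
    if (!length(b)) return(NA_real_)
    mean(b %in% c("G", "C"))
  }, numeric(1)) |> setNames(c("gc1", "gc2", "gc3"))
}

#' Sense-codon frequencies of a CDS
#'
#' Relative frequency of each of the 61 sense codons; stop codons are
#' excluded from numerator and denominator. An internal stop codon triggers a
#' warning (annotation noise is tolerated) but the gene is kept.
#'
#' @param cds a single CDS string, length divisible by 3.
#' @param gene_id optional label for warnings/errors.
#' @return named numeric 61-vector summing to 1.
#' @export
codon_frequencies <- function(cds, gene_id = NULL) {
  .assert(length(cds) == 1L && !is.na(cds), "cds must be a single string")
  .assert(nchar(cds) %% 3 == 0,
          "CDS length not divisible by 3%s",
          if (is.null(gene_id)) "" else paste0(" for gene ", gene_id))
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  if (substr(cds, 1, 3) != "ATG")
    warning("CDS does not start with ATG",
            if (is.null(gene_id)) "" else paste0(" (", gene_id, ")"))
  internal_stops <- which(codons %in% .stop_codons)
  internal_stops <- internal_stops[internal_stops < length(codons)]
  if (length(internal_stops))
    warning("internal stop codon in CDS",
            if (is.null(gene_id)) "" else paste0(" (", gene_id, ")"))
  sense <- codons[!codons %in% .stop_codons]
  tab <- table(factor(sense, levels = sense_codons()))
  setNames(as.numeric(tab) / max(1L, length(sense)), sense_codons())
}

## sentinels for genes lacking a region: density 0, GC 0, log-length floor
.LOGLEN_FLOOR <- -1

.region_gc <- function(seqs) {
  ifelse(is.na(seqs) | !nzchar(seqs), 0, gc_content(seqs))
}

#' Build the per-gene predictor table
#'
#' One row per gene with a CDS. Columns: `log_tpm` (log2 RNA-seq TPM + 1 on
#' control samples), `base_TE` (log2 Ribo/RNA control count ratio),
#' `mature_level` (log2 length-normalized exon:intron RNA read ratio), and
#' per region in \{5'UTR, 25 nt window either side of the start codon, same
#' around the stop codon, CDS, non-coding internal exons, introns, 3'UTR\}:
#' GC content (`GCcds` for the CDS, `GCpct_*` otherwise), log10 length
#' (`loglen_*`), and RNA/Ribo read density (`posdens_*`, reads per nt on
#' control samples). Plus the 61 sense-codon frequencies (`codonfr_*`),
#' GC at codon positions 1-3 (`GCpos1..3`), and, when supplied, an external
#' per-gene codon-optimality score (`codon_opt`).
#'
#' Genes lacking a region (e.g. intronless) get defined sentinels: density 0,
#' GC 0, log-length floored at -1 -- never silent NA propagation.
#'
#' @param annotation a `transcript_annotation`.
#' @param counts a `count_table` with control samples (and, when available,
#'   `region_counts` for region-level densities; otherwise densities fall
#'   back to a uniform-coverage allocation of gene counts).
#' @param optimality optional data frame `gene_id`, `score`.
#' @param window half-width (nt) of the start/stop-codon windows.
#' @return a `data.frame` feature table, one row per gene, invariant to input
#'   gene order.
#' @export
region_features <- function(annotation, counts, optimality = NULL,
                            window = 25) {
  g <- annotation$genes[order(annotation$genes$gene_id), ]
  n <- nrow(g)
  des <- counts$design
  ctrl <- des$condition == "control"
  cmat <- counts$counts[g$gene_id, , drop = FALSE]
  rna_ctrl <- rowMeans(cmat[, ctrl & des$assay == "RNA", drop = FALSE])
  ribo_ctrl <- rowMeans(cmat[, ctrl & des$assay == "Ribo", drop = FALSE])

  tpm_raw <- rna_ctrl / g$tx_len
  tpm <- tpm_raw / sum(tpm_raw) * 1e6
  feat <- data.frame(gene_id = g$gene_id,
                     log_tpm = log2(tpm + 1),
                     base_TE = log2((ribo_ctrl + 1) / (rna_ctrl + 1)),
                     stringsAsFactors = FALSE)

  ## region sequences in transcript coordinates
  tx <- as.character(annotation$tx_seq[g$tx_id])
  cds_start <- g$utr5_len + 1L
  cds_end <- g$utr5_len + g$cds_len
  startwin <- substr(tx, pmax(1L, cds_start - window),
                     pmin(nchar(tx), cds_start + window - 1L))
  stopwin <- substr(tx, pmax(1L, cds_end - window + 1L),
                    pmin(nchar(tx), cds_end + window))
  intron_seq <- vapply(annotation$intron_seq[g$gene_id],
                       function(s) paste(s, collapse = ""), "")
  region_seq <- list(
    utr5 = unname(annotation$utr5_seq[g$gene_id]),
    startwin = startwin, stopwin = stopwin,
    cds = as.character(annotation$cds_seq[g$tx_id]),
    ncexon = rep("", n),          # simulated genes have no non-coding exons
    intron = unname(intron_seq),
    utr3 = unname(annotation$utr3_seq[g$gene_id]))
  region_len <- vapply(region_seq, nchar, numeric(n))
  if (is.null(dim(region_len))) region_len <- t(region_len)

  for (r in names(region_seq)) {
    gccol <- if (r == "cds") "GCcds" else paste0("GCpct_", r)
    feat[[gccol]] <- .region_gc(region_seq[[r]])
    len <- region_len[, r]
    feat[[paste0("loglen_", r)]] <- ifelse(len > 0, log10(len), .LOGLEN_FLOOR)
  }

  ## read densities: region counts when the generator supplied them,
  ## else uniform allocation of gene counts across the mature transcript
  rc <- counts$region_counts
  getdens <- function(assay, region, len) {
    if (!is.null(rc) && region %in% rc$region) {
      sub <- rc[rc$assay == assay & rc$region == region, ]
      cnt <- setNames(sub$count, sub$gene_id)[g$gene_id]
      cnt[is.na(cnt)] <- 0
    } else {
      base <- if (assay == "RNA") rna_ctrl else ribo_ctrl
      cnt <- base * ifelse(g$tx_len > 0, len / g$tx_len, 0)
    }
    ifelse(len > 0, cnt / len, 0)
  }
  dens_regions <- c("utr5", "cds", "utr3", "intron", "ncexon")
  for (r in dens_regions) {
    for (a in c("RNA", "Ribo")) {
      feat[[paste0("posdens_", tolower(a), "_", r)]] <-
        getdens(a, r, region_len[, r])
    }
  }
  ## start/stop windows straddle UTR and CDS: length-weighted densities
  for (a in c("RNA", "Ribo")) {
    d_utr5 <- feat[[paste0("posdens_", tolower(a), "_utr5")]]
    d_cds <- feat[[paste0("posdens_", tolower(a), "_cds")]]
    d_utr3 <- feat[[paste0("posdens_", tolower(a), "_utr3")]]
    feat[[paste0("posdens_", tolower(a), "_startwin")]] <- (d_utr5 + d_cds) / 2
    feat[[paste0("posdens_", tolower(a), "_stopwin")]] <- (d_cds + d_utr3) / 2
  }

  ## mature RNA level: length-normalized exon vs intron RNA-seq signal
  d_rna_in <- feat$posdens_rna_intron
  d_rna_ex <- (rna_ctrl - d_rna_in * region_len[, "intron"]) / g$tx_len
  feat$mature_level <- log2((pmax(d_rna_ex, 0) + 0.01) / (d_rna_in + 0.01))

  ## codon-level features
  cds_chr <- as.character(annotation$cds_seq[g$tx_id])
  cfreq <- t(vapply(seq_len(n),
                    function(i) codon_frequencies(cds_chr[i], g$gene_id[i]),
                    numeric(61)))
  colnames(cfreq) <- paste0("codonfr_", sense_codons())
  posgc <- t(vapply(seq_len(n),
                    function(i) codon_position_gc(cds_chr[i], g$gene_id[i]),
                    numeric(3)))
  colnames(posgc) <- c("GCpos1", "GCpos2", "GCpos3")
  feat <- cbind(feat, cfreq, posgc)

  if (!is.null(optimality)) {
    .assert(all(c("gene_id", "score") %in% names(optimality)),
            "optimality table needs gene_id and score columns")
    feat$codon_opt <- optimality$score[match(feat$gene_id,
                                             optimality$gene_id)]
  }
  rownames(feat) <- NULL
  feat
}

#' Partition per-gene values by GCcds and test group differences
#'
#' Cuts the GCcds range into `n_groups` equal-width (default) or
#' equal-frequency bins, summarizes the value distribution per group and runs
#' pairwise two-sided Wilcoxon rank-sum tests. Groups with fewer than two
#' members are skipped and reported.
#'
#' @param values named (or parallel) per-gene numbers.
#' @param gc per-gene GCcds values, same length/order.
#' @param n_groups number of bins, >= 2.
#' @param method `"width"` (equal-width cut of the GC range) or
#'   `"quantile"` (tertile-style).
#' @return list: `group` factor, `summary` (n/median per group),
#'   `pairwise` data frame of Wilcoxon p-values, `skipped` group labels.
#' @export
partition_by_gc <- function(values, gc, n_groups = 3,
                            method = c("width", "quantile")) {
  method <- match.arg(method)
  .assert(n_groups >= 2, "n_groups must be >= 2")
  .assert(length(values) == length(gc), "values and gc differ in length")
  breaks <- if (method == "width") {
    if (diff(range(gc, na.rm = TRUE)) == 0) {
      c(-Inf, Inf)  # constant gc: a single group
    } else {
      seq(min(gc, na.rm = TRUE), max(gc, na.rm = TRUE),
          length.out = n_groups + 1)
    }
  } else {
    unique(quantile(gc, probs = seq(0, 1, length.out = n_groups + 1),
                    na.rm = TRUE))
  }
  grp <- cut(gc, breaks = breaks, include.lowest = TRUE)
  tab <- table(grp)
  smry <- data.frame(group = names(tab), n = as.integer(tab),
                     median = vapply(levels(grp), function(l) {
                       median(values[grp == l & !is.na(values)])
                     }, numeric(1)), row.names = NULL)
  usable <- names(tab)[tab >= 2]
  skipped <- setdiff(names(tab), usable)
  pw <- NULL
  if (length(usable) >= 2) {
    combos <- utils::combn(usable, 2)
    pw <- data.frame(
      group1 = combos[1, ], group2 = combos[2, ],
      p_value = apply(combos, 2, function(cc) {
        wilcox.test(values[grp == cc[1]], values[grp == cc[2]],
                    exact = FALSE)$p.value
      }), stringsAsFactors = FALSE)
  }
  list(group = grp, summary = smry, pairwise = pw, skipped = skipped)
}
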