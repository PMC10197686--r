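## File interfaces: GTF + FASTA for annotation, TSV for tables, bedGraph
## (transcript-coordinate space, transcript id as "chromosome") for coverage.

## map a transcript interval [s,e] to genomic pieces given intron insertion
## points `ip` (transcript position after which an intron sits) and lengths
## `il`; plus strand, gene starts at genomic position 1
.tx_pieces <- function(s, e, ip, il) {
  cuts <- ip[ip >= s & ip < e]
  starts <- c(s, cuts + 1L)
  ends <- c(cuts, e)
  shift <- vapply(starts, function(p) sum(il[ip < p]), numeric(1))
  data.frame(gstart = starts + shift, gend = ends + shift, tstart = starts)
}

#' Export a simulated annotation as GTF and FASTA
#'
#' GTF records (1-based, closed intervals, `gene_id`/`transcript_id`
#' attributes) for exon, CDS, five_prime_utr and three_prime_utr features,
#' with each gene on its own plus-strand contig; transcript (mature)
#' sequences as FASTA.
#'
#' @param annotation a `transcript_annotation`.
#' @param gtf_file,fasta_file output paths.
#' @return invisibly, the paths.
#' @export
write_annotation <- function(annotation, gtf_file, fasta_file) {
  g <- annotation$genes
  feats <- list()
  for (i in seq_len(nrow(g))) {
    ip <- annotation$introns$pos[[g$gene_id[i]]]
    il <- annotation$introns$len[[g$gene_id[i]]]
    reg <- annotation$regions[annotation$regions$gene_id == g$gene_id[i], ]
    cds_s <- reg$start[reg$region == "cds"]
    cds_pieces <- .tx_pieces(cds_s, reg$end[reg$region == "cds"], ip, il)
    cds_pieces$phase <- (3L - (cds_pieces$tstart - cds_s) %% 3L) %% 3L
    blocks <- rbind(
      cbind(.tx_pieces(1L, g$tx_len[i], ip, il), type = "exon",
            phase = NA_integer_),
      cbind(.tx_pieces(reg$start[reg$region == "utr5"],
                       reg$end[reg$region == "utr5"], ip, il),
            type = "five_prime_utr", phase = NA_integer_),
      cbind(cds_pieces[, c("gstart", "gend", "tstart")], type = "CDS",
            phase = cds_pieces$phase),
      cbind(.tx_pieces(reg$start[reg$region == "utr3"],
                       reg$end[reg$region == "utr3"], ip, il),
            type = "three_prime_utr", phase = NA_integer_))
    feats[[i]] <- data.frame(
      seqnames = g$gene_id[i], start = blocks$gstart, end = blocks$gend,
      type = blocks$type, phase = blocks$phase, gene_id = g$gene_id[i],
      transcript_id = g$tx_id[i], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    df$seqnames, IRanges::IRanges(df$start, df$end), strand = "+",
    type = df$type, source = "gcdecay_sim",
    phase = df$phase,
    gene_id = df$gene_id, transcript_id = df$transcript_id)
  rtracklayer::export(gr, gtf_file, format = "gtf")
  Biostrings::writeXStringSet(annotation$tx_seq, fasta_file)
  invisible(c(gtf = gtf_file, fasta = fasta_file))
}

#' Read a transcript annotation back from GTF + FASTA
#'
#' Reconstructs transcript-coordinate regions from plus-strand exon/CDS/UTR
#' GTF features (the layout [write_annotation()] emits) together with mature
#' transcript sequences.
#'
#' @param gtf_file,fasta_file paths written by [write_annotation()].
#' @return a `transcript_annotation` (without intron sequences, which the
#'   GTF does not carry; intron lengths are recovered from exon gaps).
#' @export
read_annotation <- function(gtf_file, fasta_file) {
  gr <- rtracklayer::import(gtf_file, format = "gtf")
  .assert(all(as.character(BiocGenerics::strand(gr)) == "+"),
          "only plus-strand annotations are supported")
  df <- data.frame(
    gene_id = gr$gene_id, tx_id = gr$transcript_id,
    type = as.character(gr$type),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE)
  tx_seq <- Biostrings::readDNAStringSet(fasta_file)
  names(tx_seq) <- sub("\\s.*", "", names(tx_seq))

  per_gene <- split(df, df$gene_id)
  rows <- lapply(per_gene, function(d) {
    ex <- d[d$type == "exon", ]
    ex <- ex[order(ex$start), ]
    ## genomic -> transcript: cumulative exon widths
    widths <- ex$end - ex$start + 1L
    offs <- cumsum(c(0L, head(widths, -1L)))
    to_tx <- function(gpos) {
      k <- findInterval(gpos, ex$start)
      offs[k] + (gpos - ex$start[k]) + 1L
    }
    reg <- d[d$type != "exon", ]
    reg$tstart <- to_tx(reg$start)
    reg$tend <- to_tx(reg$end)
    agg <- do.call(rbind, lapply(split(reg, reg$type), function(r) {
      data.frame(gene_id = r$gene_id[1], tx_id = r$tx_id[1],
                 region = c(CDS = "cds", five_prime_utr = "utr5",
                            three_prime_utr = "utr3")[r$type[1]],
                 start = min(r$tstart), end = max(r$tend),
                 stringsAsFactors = FALSE)
    }))
    il <- if (nrow(ex) > 1) ex$start[-1] - ex$end[-nrow(ex)] - 1L else integer(0)
    list(regions = agg,
         gene = data.frame(
           gene_id = d$gene_id[1], tx_id = d$tx_id[1],
           utr5_len = agg$end[agg$region == "utr5"] - agg$start[agg$region == "utr5"] + 1L,
           cds_len = agg$end[agg$region == "cds"] - agg$start[agg$region == "cds"] + 1L,
           utr3_len = agg$end[agg$region == "utr3"] - agg$start[agg$region == "utr3"] + 1L,
           tx_len = sum(widths), n_introns = nrow(ex) - 1L,
           intron_len_total = sum(il), stringsAsFactors = FALSE))
  })
  genes <- do.call(rbind, lapply(rows, `[[`, "gene"))
  genes <- genes[order(genes$gene_id), ]
  rownames(genes) <- NULL
  regions <- do.call(rbind, lapply(rows, `[[`, "regions"))
  rownames(regions) <- NULL
  tx_seq <- tx_seq[genes$tx_id]
  cds_seq <- Biostrings::DNAStringSet(setNames(substr(
    as.character(tx_seq), genes$utr5_len + 1L,
    genes$utr5_len + genes$cds_len), genes$tx_id))
  genes$gc_cds <- gc_content(as.character(cds_seq))
  structure(list(genes = genes, regions = regions, tx_seq = tx_seq,
                 cds_seq = cds_seq,
                 utr5_seq = setNames(substr(as.character(tx_seq), 1L,
                                            genes$utr5_len), genes$gene_id),
                 utr3_seq = setNames(substr(as.character(tx_seq),
                                            genes$tx_len - genes$utr3_len + 1L,
                                            genes$tx_len), genes$gene_id),
                 intron_seq = setNames(rep(list(character(0)),
                                           nrow(genes)), genes$gene_id),
                 introns = list(pos = NULL, len = NULL)),
            class = "transcript_annotation")
}

#' Export coverage tracks as per-sample bedGraph files
#'
#' Transcript-coordinate space, transcript/gene id as the "chromosome";
#' 0-based half-open intervals with run-length collapsed scores.
#'
#' @param covset a `coverage_set`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_coverage_bedgraph <- function(covset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in covset$samples$sample_id) {
    grl <- lapply(names(covset$tracks), function(gid) {
      v <- covset$tracks[[gid]][s, ]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      GenomicRanges::GRanges(gid,
                             IRanges::IRanges(ends - r$lengths + 1L, ends),
                             score = r$values)
    })
    gr <- suppressWarnings(do.call(c, grl))
    p <- file.path(dir, paste0(s, ".bedGraph"))
    rtracklayer::export(gr, p, format = "bedGraph")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write the tabular outputs of a simulation run
#'
#' Counts, sample design, ground truth and SLAM conversion tables as TSV.
#'
#' @param counts a `count_table`; @param truth a `ground_truth`;
#' @param slam optional `conversion_table`; @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_simulation_tables <- function(counts, truth, slam = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f, rn = FALSE) {
    p <- file.path(dir, f)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = rn)
    p
  }
  paths <- c(
    w(data.frame(gene_id = rownames(counts$counts), counts$counts,
                 check.names = FALSE), "counts.tsv"),
    w(counts$design, "design.tsv"),
    w(counts$region_counts, "region_counts.tsv"),
    w(truth$genes, "ground_truth.tsv"))
  if (!is.null(slam)) {
    paths <- c(paths, w(slam$table, "slam_counts.tsv"),
               w(slam$samples, "slam_design.tsv"))
  }
  invisible(paths)
}

#' Read a count matrix + design written by [write_simulation_tables()]
#' @param counts_file,design_file TSV paths.
#' @return a `count_table` list (without region counts/baselines).
#' @export
read_counts <- function(counts_file, design_file) {
  df <- read.delim(counts_file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  structure(list(counts = m, design = read.delim(design_file)),
            class = "count_table")
}
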