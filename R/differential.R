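#' Translation-efficiency test with an assay-type interaction covariate
#'
#' Stacks RNA-seq and Ribo-seq counts for one timepoint contrast and fits per
#' gene the NB GLM `~ condition + assay + condition:assay` against the
#' reduced model without the interaction, i.e. assuming no difference between
#' the two assays' responses. The likelihood-ratio chi-square p-value tests
#' for a change in translation efficiency; BH-adjusted p-values below `fdr`
#' call genes `TE_up` / `TE_down` by the sign of the interaction term.
#'
#' @param counts a `count_table` (or list with `counts` matrix and `design`).
#' @param timepoint which timepoint's treated/control contrast to test.
#' @param fdr FDR threshold for the class call.
#' @return a `data.frame`: per gene `log2fc_rna` (RNA condition effect),
#'   `log2fc_ribo`, `log2fc_te` (interaction term), `pvalue`, `padj`,
#'   `class`; attribute `"excluded"` lists all-zero genes.
#' @export
te_test <- function(counts, timepoint, fdr = 0.05) {
  des <- counts$design
  sel <- des$timepoint == timepoint
  .assert(any(sel), "timepoint %s absent from design", timepoint)
  des <- des[sel, , drop = FALSE]
  .assert(all(c("RNA", "Ribo") %in% des$assay) &&
            all(c("control", "treated") %in% des$condition),
          "both assays and both conditions are required at the timepoint")
  des$condition <- factor(des$condition, c("control", "treated"))
  des$assay <- factor(des$assay, c("RNA", "Ribo"))
  mat <- counts$counts[, sel, drop = FALSE]

  fit <- fit_nb_glm(mat, des, ~ condition + assay + condition:assay,
                    ~ condition + assay)
  b <- fit$coef
  res <- data.frame(
    gene_id = rownames(b),
    log2fc_rna = .to_log2(b[, "conditiontreated"]),
    log2fc_te = .to_log2(b[, "conditiontreated:assayRibo"]),
    pvalue = fit$pvalue, padj = fit$padj,
    stringsAsFactors = FALSE)
  res$log2fc_ribo <- res$log2fc_rna + res$log2fc_te
  res$class <- ifelse(is.na(res$padj) | res$padj >= fdr, "NS",
                      ifelse(res$log2fc_te > 0, "TE_up", "TE_down"))
  res <- res[, c("gene_id", "log2fc_rna", "log2fc_ribo", "log2fc_te",
                 "pvalue", "padj", "class")]
  rownames(res) <- NULL
  attr(res, "excluded") <- fit$excluded
  attr(res, "timepoint") <- timepoint
  res
}

#' Per-assay differential test (condition effect within one assay)
#'
#' NB GLM `~ condition` vs `~ 1` on one assay's samples at one timepoint;
#' gives the per-assay log2FC and LRT significance used for the coordinate
#' classification and for ranking stabilized/degraded genes.
#'
#' @inheritParams te_test
#' @param assay `"RNA"` or `"Ribo"`.
#' @return data frame `gene_id`, `log2fc`, `pvalue`, `padj`.
#' @export
assay_test <- function(counts, assay, timepoint, fdr = 0.05) {
  des <- counts$design
  sel <- des$timepoint == timepoint & des$assay == assay
  .assert(any(sel), "no %s samples at timepoint %s", assay, timepoint)
  des <- des[sel, , drop = FALSE]
  des$condition <- factor(des$condition, c("control", "treated"))
  mat <- counts$counts[, sel, drop = FALSE]
  fit <- fit_nb_glm(mat, des, ~ condition, ~ 1)
  res <- data.frame(gene_id = rownames(fit$coef),
                    log2fc = .to_log2(fit$coef[, "conditiontreated"]),
                    pvalue = fit$pvalue, padj = fit$padj,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "excluded") <- fit$excluded
  res
}

#' Coordinate-plane regulation groups
#'
#' Places each gene on the (RNA log2FC, Ribo log2FC) plane and labels which
#' axis dominates its regulation: `x` (RNA-level change only), `y`
#' (ribosome-occupancy change only), `xy` (both, concordant signs), `-xy`
#' (both, anticorrelated -- e.g. stabilized yet translationally suppressed),
#' `NS` otherwise. "Changing" on an axis means significant on that assay's
#' test at `fdr` with `|log2FC| > lfc_margin`. Pure function of its inputs;
#' deterministic and order-invariant.
#'
#' @param rna,ribo per-assay results from [assay_test()] sharing gene order.
#' @param fdr per-assay significance threshold.
#' @param lfc_margin minimum absolute log2FC to count an axis as changing.
#' @return factor of group labels in `x, y, xy, -xy, NS`.
#' @export
classify_coordinate_groups <- function(rna, ribo, fdr = 0.05,
                                       lfc_margin = 0) {
  .assert(identical(rna$gene_id, ribo$gene_id),
          "rna and ribo results must share gene order")
  sig_x <- !is.na(rna$padj) & rna$padj < fdr & abs(rna$log2fc) > lfc_margin
  sig_y <- !is.na(ribo$padj) & ribo$padj < fdr & abs(ribo$log2fc) > lfc_margin
  lab <- rep("NS", nrow(rna))
  lab[sig_x & !sig_y] <- "x"
  lab[!sig_x & sig_y] <- "y"
  both <- sig_x & sig_y
  lab[both & sign(rna$log2fc) == sign(ribo$log2fc)] <- "xy"
  lab[both & sign(rna$log2fc) != sign(ribo$log2fc)] <- "-xy"
  factor(lab, levels = c("x", "y", "xy", "-xy", "NS"))
}

#' Binned vector field of fold-change dynamics
#'
#' Divides the (RNA log2FC, Ribo log2FC) plane into `n_bins` bins per axis
#' (symmetric, data-driven range) and, for each transition between
#' consecutive timepoints, averages within each occupied cell the change in
#' RNA and Ribo log2FC of the genes sitting in that cell at the earlier
#' timepoint, together with their mean GCcds. Restrict `genes` to the set
#' with significant TE changes at the final timepoint to mirror the intended
#' use.
#'
#' @param lfc_by_tp list of per-timepoint data frames (`gene_id`,
#'   `log2fc_rna`, `log2fc_ribo`), in timepoint order; >= 2 entries.
#' @param gc named per-gene GCcds vector.
#' @param n_bins bins per axis.
#' @param genes optional gene-id filter.
#' @return data frame: `transition`, `bin_x`, `bin_y` (bin centres),
#'   `d_rna`, `d_ribo` (mean deltas), `n`, `mean_gc`. Per-transition `n`
#'   sums to the number of genes plotted; empty cells carry no row.
#' @export
vector_field <- function(lfc_by_tp, gc, n_bins = 70, genes = NULL) {
  .assert(length(lfc_by_tp) >= 2,
          "need >= 2 timepoints for a delta field")
  if (!is.null(genes)) {
    lfc_by_tp <- lapply(lfc_by_tp, function(d) d[d$gene_id %in% genes, ])
  }
  common <- Reduce(intersect, lapply(lfc_by_tp, `[[`, "gene_id"))
  lfc_by_tp <- lapply(lfc_by_tp, function(d) {
    d[match(common, d$gene_id), ]
  })
  allv <- unlist(lapply(lfc_by_tp, function(d) c(d$log2fc_rna, d$log2fc_ribo)))
  r <- max(abs(allv), na.rm = TRUE)
  if (r == 0) r <- 1
  breaks <- seq(-r, r, length.out = n_bins + 1)
  centres <- (head(breaks, -1) + breaks[-1]) / 2
  out <- list()
  for (t in seq_len(length(lfc_by_tp) - 1)) {
    a <- lfc_by_tp[[t]]; b <- lfc_by_tp[[t + 1]]
    bx <- .clamp(findInterval(a$log2fc_rna, breaks,
                              rightmost.closed = TRUE), 1, n_bins)
    by <- .clamp(findInterval(a$log2fc_ribo, breaks,
                              rightmost.closed = TRUE), 1, n_bins)
    key <- paste(bx, by)
    d_rna <- b$log2fc_rna - a$log2fc_rna
    d_ribo <- b$log2fc_ribo - a$log2fc_ribo
    gcv <- gc[a$gene_id]
    agg <- data.frame(
      transition = t,
      bin_x = centres[as.integer(sub(" .*", "", names(split(d_rna, key))))],
      bin_y = centres[as.integer(sub(".* ", "", names(split(d_rna, key))))],
      d_rna = vapply(split(d_rna, key), mean, 0),
      d_ribo = vapply(split(d_ribo, key), mean, 0),
      n = vapply(split(d_rna, key), length, 0L),
      mean_gc = vapply(split(gcv, key), mean, 0),
      row.names = NULL)
    out[[t]] <- agg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
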