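#' Select the major isoform per gene from pooled coverage
#'
#' The isoform with maximal total coverage summed over all pooled samples;
#' ties broken by longer transcript, then lexicographically smaller id.
#' Genes with zero coverage everywhere are excluded and reported.
#'
#' @param totals data frame: `gene_id`, `tx_id`, `total` (pooled coverage
#'   sum), `tx_len`.
#' @return data frame with one row per retained gene; attribute
#'   `"excluded"` lists zero-coverage genes.
#' @export
select_major_isoform <- function(totals) {
  .assert(all(c("gene_id", "tx_id", "total", "tx_len") %in% names(totals)),
          "totals needs gene_id, tx_id, total, tx_len")
  keep <- tapply(totals$total, totals$gene_id, sum) > 0
  excluded <- names(keep)[!keep]
  t2 <- totals[totals$gene_id %in% names(keep)[keep], ]
  t2 <- t2[order(t2$gene_id, -t2$total, -t2$tx_len, t2$tx_id), ]
  out <- t2[!duplicated(t2$gene_id), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Detect the coverage starting position of a profile
#'
#' Min/max-normalizes the per-nucleotide coverage vector to 0-1 and returns
#' the smallest 5'->3' coordinate (1-based) whose normalized value exceeds
#' `threshold`. Flat profiles (max == min) have no defined start and return
#' `NA` so callers can exclude the transcript.
#'
#' @param profile numeric coverage vector over transcript coordinates.
#' @param threshold normalized-coverage threshold (default 0.15).
#' @param max_only normalize by the maximum only, without subtracting the
#'   minimum.
#' @return integer position or `NA_integer_`.
#' @export
detect_start <- function(profile, threshold = 0.15, max_only = FALSE) {
  .assert(is.numeric(profile) && length(profile) > 0,
          "profile must be a non-empty numeric vector")
  lo <- min(profile); hi <- max(profile)
  if (hi == lo) return(NA_integer_)
  norm <- if (max_only) profile / hi else (profile - lo) / (hi - lo)
  idx <- which(norm > threshold)
  if (!length(idx)) NA_integer_ else idx[1]
}

#' Windowed 5' coverage change versus control
#'
#' Averages min/max-normalized coverage in a window of `2 * half_window` nt
#' around the pooled coverage start (clipped to the transcript) for every
#' sample, and returns the log2 fold change of each treated sample's window
#' mean against the mean of the control samples. When the control mean is 0
#' the smallest positive normalized value of the transcript is added to both
#' terms to avoid infinities while preserving ordering.
#'
#' @param mat coverage matrix, samples x positions.
#' @param pooled_start window centre (1-based transcript coordinate).
#' @param half_window window half-width in nt (250 nt total by default).
#' @param control logical vector marking control rows of `mat`.
#' @return numeric per-sample log2FC (control samples get their log2FC to
#'   the control mean too, useful as a sanity check); `NULL` when the window
#'   misses the transcript entirely.
#' @export
window_coverage_change <- function(mat, pooled_start, half_window = 125,
                                   control) {
  lo <- pooled_start - half_window
  hi <- pooled_start + half_window
  if (hi < 1 || lo > ncol(mat)) return(NULL)
  lo <- max(1L, lo); hi <- min(ncol(mat), hi)
  norm <- t(apply(mat, 1, function(v) {
    r <- range(v)
    if (r[2] == r[1]) return(rep(0, length(v)))
    (v - r[1]) / (r[2] - r[1])
  }))
  wmean <- rowMeans(norm[, lo:hi, drop = FALSE])
  ctrl_mean <- mean(wmean[control])
  guard <- 0
  if (ctrl_mean == 0) {
    pos <- norm[norm > 0]
    guard <- if (length(pos)) min(pos) else 1e-6
  }
  log2((wmean + guard) / (ctrl_mean + guard))
}

#' Per-transcript trajectory summary: regression slope or difference
#'
#' Regression mode (time courses, >= 3 points): OLS slope of
#' `value ~ time`, with the intercept omitted when the series starts at a
#' structural zero (coverage log2FC series) and included otherwise
#' (start-position series). Difference mode (two-condition designs):
#' `treated - control`.
#'
#' @param values numeric series (timepoint order, or `c(control, treated)`
#'   in difference mode).
#' @param times regression abscissa; defaults to the 0-based timepoint index.
#' @param mode `"regression"` or `"difference"`.
#' @param intercept include an intercept in regression mode.
#' @return the beta (slope or difference), `NA` if undefined.
#' @export
trajectory_beta <- function(values, times = NULL,
                            mode = c("regression", "difference"),
                            intercept = TRUE) {
  mode <- match.arg(mode)
  if (anyNA(values)) return(NA_real_)
  if (mode == "difference") {
    .assert(length(values) == 2, "difference mode needs exactly 2 values")
    return(values[2] - values[1])
  }
  .assert(length(values) >= 3, "regression mode needs >= 3 timepoints")
  x <- times %||% (seq_along(values) - 1)
  fit <- if (intercept) lm(values ~ x) else lm(values ~ x + 0)
  unname(coef(fit)["x"])
}

#' Per-transcript 5' (or 3') coverage statistics
#'
#' For every transcript in a coverage set: the pooled-sample coverage start
#' (flat profiles are excluded and reported), per-sample starts, windowed
#' coverage log2FCs of treated vs control at each timepoint, and the two
#' trajectory betas -- `beta_start` (slope of the treated start positions
#' over time, intercept included) and `beta_cov` (slope of the windowed
#' log2FC series over time, intercept omitted since the series starts at 0).
#' With `mode = "difference"` (two-condition designs) the betas are plain
#' treated-minus-control differences.
#'
#' `end = "three"` runs the identical machinery on reversed profiles
#' (scanning from the 3' end), the negative control of the 5' statistic.
#'
#' @param covset a `coverage_set`.
#' @param threshold start-detection threshold.
#' @param half_window window half-width around the pooled start (nt).
#' @param mode `"regression"` (time course) or `"difference"`.
#' @param end `"five"` or `"three"`.
#' @param time_axis `"index"` (default: 0-based timepoint rank) or
#'   `"hours"`.
#' @return data frame per transcript: `gene_id`, `pooled_start`,
#'   `beta_start`, `beta_cov`; attribute `"excluded"` (flat or windowless
#'   transcripts), attribute `"per_sample"` with starts and window log2FCs.
#' @export
coverage_stats <- function(covset, threshold = 0.15, half_window = 125,
                           mode = c("regression", "difference"),
                           end = c("five", "three"), time_axis = "index") {
  mode <- match.arg(mode)
  end <- match.arg(end)
  samples <- covset$samples
  tps <- sort(unique(samples$timepoint))
  if (mode == "regression") .assert(length(tps) >= 3,
                                    "regression mode needs >= 3 timepoints")
  control <- samples$condition == "control"
  excluded <- character(0)
  rows <- list()
  per_sample <- list()
  for (gid in names(covset$tracks)) {
    m <- covset$tracks[[gid]]
    if (end == "three") m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    pooled <- colSums(m)
    ps <- detect_start(pooled, threshold)
    if (is.na(ps)) {
      excluded <- c(excluded, gid)
      next
    }
    starts <- apply(m, 1, detect_start, threshold = threshold)
    lfc <- window_coverage_change(m, ps, half_window, control)
    if (is.null(lfc)) {
      excluded <- c(excluded, gid)
      next
    }
    treated <- !control
    ord <- order(samples$timepoint[treated])
    tt <- samples$timepoint[treated][ord]
    x <- if (identical(time_axis, "hours")) tt else seq_along(tt) - 1
    if (mode == "regression") {
      beta_start <- trajectory_beta(starts[treated][ord], times = x,
                                    mode = "regression", intercept = TRUE)
      beta_cov <- trajectory_beta(lfc[treated][ord], times = x,
                                  mode = "regression", intercept = FALSE)
    } else {
      beta_start <- mean(starts[treated]) - mean(starts[control])
      beta_cov <- mean(lfc[treated])
    }
    rows[[gid]] <- data.frame(gene_id = gid, pooled_start = ps,
                              beta_start = beta_start, beta_cov = beta_cov,
                              stringsAsFactors = FALSE)
    per_sample[[gid]] <- data.frame(gene_id = gid,
                                    sample_id = samples$sample_id,
                                    start = starts, window_log2fc = lfc,
                                    stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "per_sample") <- do.call(rbind, per_sample)
  out
}

#' Pick the stabilized / degraded / control comparison classes
#'
#' Ranks the RNA-seq differential results by p-value (stable sort by p, then
#' decreasing |log2FC|) and takes the `n_top` most stabilized (log2FC > 0)
#' and most degraded (log2FC < 0) genes; `n_control` control genes are
#' sampled from non-regulated genes with p > `control_p` and TPM >
#' `control_tpm`. When fewer genes exist the class sizes shrink
#' proportionally.
#'
#' @param rna result of [assay_test()] for RNA at the contrast of interest.
#' @param tpm named per-gene TPM values.
#' @param n_top,n_control class sizes.
#' @param control_p,control_tpm control-gene filters.
#' @param seed seed for the control sampling.
#' @return data frame `gene_id`, `class` in
#'   \{stabilized, degraded, control\}.
#' @export
select_comparison_classes <- function(rna, tpm, n_top = 250,
                                      n_control = 1500, control_p = 0.2,
                                      control_tpm = 3, seed = 1L) {
  ord <- order(rna$pvalue, -abs(rna$log2fc))
  r <- rna[ord, ]
  up <- r$gene_id[r$log2fc > 0]
  down <- r$gene_id[r$log2fc < 0]
  ctrl_pool <- r$gene_id[!is.na(r$pvalue) & r$pvalue > control_p &
                           tpm[r$gene_id] > control_tpm]
  scale <- min(1, length(up) / n_top, length(down) / n_top,
               length(ctrl_pool) / n_control)
  n_top_eff <- max(1L, floor(n_top * scale))
  n_ctrl_eff <- max(1L, floor(n_control * scale))
  set.seed(seed)
  ctrl <- sample(ctrl_pool, min(n_ctrl_eff, length(ctrl_pool)))
  out <- rbind(
    data.frame(gene_id = head(up, n_top_eff), class = "stabilized"),
    data.frame(gene_id = head(down, n_top_eff), class = "degraded"),
    data.frame(gene_id = ctrl, class = "control"))
  rownames(out) <- NULL
  out
}

#' Compare coverage betas across regulation classes
#'
#' One-sided Wilcoxon rank-sum tests of the per-transcript betas: stabilized
#' genes against controls, and degraded genes against controls. For the
#' coverage-value beta the expected direction is stabilized > control and
#' degraded < control; start-position betas move the opposite way (an
#' earlier, slower-receding start under stabilization), so the sides flip
#' when `metric = "beta_start"`. Empty classes skip their test.
#'
#' @param stats output of [coverage_stats()].
#' @param classes data frame `gene_id`, `class` from
#'   [select_comparison_classes()].
#' @param metric `"beta_cov"` or `"beta_start"`.
#' @return data frame per comparison: `comparison`, `n1`, `n0`,
#'   `median1`, `median0`, `alternative`, `p_value` (`NA` when skipped).
#' @export
compare_classes <- function(stats, classes,
                            metric = c("beta_cov", "beta_start")) {
  metric <- match.arg(metric)
  d <- merge(stats, classes, by = "gene_id")
  val <- d[[metric]]
  alt <- if (metric == "beta_cov") c(stabilized = "greater",
                                     degraded = "less")
         else c(stabilized = "less", degraded = "greater")
  rows <- lapply(names(alt), function(cl) {
    v1 <- val[d$class == cl]
    v0 <- val[d$class == "control"]
    p <- if (length(v1) >= 2 && length(v0) >= 2) {
      wilcox.test(v1, v0, alternative = alt[[cl]], exact = FALSE)$p.value
    } else NA_real_
    data.frame(comparison = paste0(cl, "_vs_control"),
               metric = metric, n1 = length(v1), n0 = length(v0),
               median1 = if (length(v1)) median(v1) else NA_real_,
               median0 = if (length(v0)) median(v0) else NA_real_,
               alternative = alt[[cl]], p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
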