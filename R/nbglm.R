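## Negative-binomial GLM machinery for count-based differential analysis.
## Log link, median-of-ratios size factors, gene-wise ML dispersion with
## Cox-Reid adjustment, moderated toward a mean-dispersion trend, and a
## chi-square likelihood-ratio test between nested designs.

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median across genes of the ratio of
#' a sample's counts to the gene's geometric mean over all samples, computed
#' on genes with all-positive counts.
#'
#' @param counts integer matrix, genes x samples.
#' @return numeric vector of size factors, one per column.
#' @export
size_factors <- function(counts) {
  lg <- rowMeans(log(counts))
  keep <- is.finite(lg)
  .assert(any(keep), "no gene with all-positive counts; cannot normalize")
  apply(counts, 2, function(k) exp(median(log(k[keep]) - lg[keep])))
}

.nb_loglik <- function(y, mu, alpha) {
  sum(dnbinom(y, size = 1 / alpha, mu = pmax(mu, 1e-10), log = TRUE))
}

## one NB IRLS fit at fixed dispersion; offset on the natural-log scale
.nb_fit <- function(y, X, offset, alpha) {
  fam <- MASS::negative.binomial(theta = 1 / alpha)
  fit <- suppressWarnings(glm.fit(X, y, family = fam, offset = offset))
  mu <- pmax(fit$fitted.values, 1e-10)
  list(coef = fit$coefficients, mu = mu,
       loglik = .nb_loglik(y, mu, alpha), converged = isTRUE(fit$converged))
}

.ALPHA_LIMS <- c(log(1e-8), log(20))

## Cox-Reid-adjusted profile log-likelihood of the dispersion, as a closure
## over the gene's counts and Poisson-fitted means:
## ll(alpha) - 0.5 log det(X' W X), W = mu / (1 + alpha mu)
.cr_profile <- function(y, X, offset) {
  pois <- suppressWarnings(glm.fit(X, y, family = poisson(), offset = offset))
  mu <- pmax(pois$fitted.values, 1e-8)
  force(X)
  function(la) {
    a <- exp(la)
    w <- mu / (1 + a * mu)
    cr <- 0.5 * determinant(crossprod(X * sqrt(w)), logarithm = TRUE)$modulus
    .nb_loglik(y, mu, a) - as.numeric(cr)
  }
}

## gene-wise ML dispersion (used stand-alone by small-design callers)
.estimate_dispersion_gene <- function(y, X, offset) {
  pll <- .cr_profile(y, X, offset)
  exp(optimize(function(la) -pll(la), .ALPHA_LIMS)$minimum)
}

## mean-dispersion trend alpha ~ a0 + a1 / meanNormCount on genes with
## interior ML estimates
.dispersion_trend <- function(alpha, mean_norm) {
  use <- alpha > 1e-6 & alpha < 10 & mean_norm > 0
  if (sum(use) < 10) return(rep(median(pmax(alpha, 1e-4)), length(alpha)))
  fit <- lm(alpha[use] ~ I(1 / mean_norm[use]))
  a0 <- max(coef(fit)[1], 1e-8)
  a1 <- max(coef(fit)[2], 0)
  pmax(a0 + a1 / pmax(mean_norm, 1e-8), 1e-8)
}

## prior variance of log dispersion around the trend: robust spread of the
## ML estimates minus the expected sampling variance at the design's
## residual df (trigamma((n-p)/2)), floored
.dispersion_prior_var <- function(alpha, trend, n_samples, n_params) {
  use <- alpha > 1e-6 & alpha < 10
  samp_var <- trigamma(max((n_samples - n_params) / 2, 0.5))
  if (sum(use) < 10) return(0.25)
  log_resid <- log(alpha[use]) - log(trend[use])
  max(stats::mad(log_resid)^2 - samp_var, 0.05)
}

#' Fit per-gene negative-binomial GLMs, optionally with a nested LRT
#'
#' The re-implemented count-model core: for each gene a log-link NB GLM with
#' median-of-ratios size factors as offsets, gene-wise ML dispersion
#' (Cox-Reid adjusted) moderated toward a mean-dispersion trend, and -- when
#' `reduced` is supplied -- a likelihood-ratio chi-square test between the
#' two designs with df = difference in parameters.
#'
#' @param counts integer matrix, genes x samples.
#' @param design data frame of sample covariates, rows matching columns of
#'   `counts`.
#' @param full,reduced model formulas over `design` columns (reduced may be
#'   `NULL` for estimation only).
#' @param sf optional size factors (computed from `counts` when `NULL`).
#' @param moderate moderate dispersions toward the trend (default TRUE).
#' @return list: `coef` matrix (natural-log scale), `dispersion`, `loglik`
#'   (full model), `lrt_stat`, `pvalue`, `padj` (BH), `converged`,
#'   `excluded` (all-zero gene ids, dropped with report), `sf`, and the
#'   design matrices' column names.
#' @export
fit_nb_glm <- function(counts, design, full, reduced = NULL, sf = NULL,
                       moderate = TRUE) {
  .assert(nrow(design) == ncol(counts),
          "design rows must match count columns")
  allzero <- rowSums(counts) == 0
  excluded <- rownames(counts)[allzero]
  counts <- counts[!allzero, , drop = FALSE]
  if (is.null(sf)) sf <- size_factors(counts)
  offset <- log(sf)
  Xf <- model.matrix(full, design)
  Xr <- if (!is.null(reduced)) model.matrix(reduced, design) else NULL
  .assert(qr(Xf)$rank == ncol(Xf), "full design matrix is not full rank")
  ngene <- nrow(counts)

  ## gene-wise ML dispersions (Cox-Reid adjusted), then a second MAP pass
  ## maximizing profile likelihood + log-normal prior centred on the trend:
  ## keeps boundary estimates (within-group variance below Poisson) from
  ## collapsing to zero and inflating the LRT
  plls <- lapply(seq_len(ngene), function(i) .cr_profile(counts[i, ], Xf,
                                                         offset))
  alpha <- vapply(plls, function(pll) {
    exp(optimize(function(la) -pll(la), .ALPHA_LIMS)$minimum)
  }, numeric(1))
  mean_norm <- rowMeans(sweep(counts, 2, sf, "/"))
  if (moderate) {
    trend <- .dispersion_trend(alpha, mean_norm)
    pv <- .dispersion_prior_var(alpha, trend, nrow(design), ncol(Xf))
    alpha <- vapply(seq_len(ngene), function(i) {
      lt <- log(trend[i])
      exp(optimize(function(la) {
        -(plls[[i]](la) - (la - lt)^2 / (2 * pv))
      }, .ALPHA_LIMS)$minimum)
    }, numeric(1))
  }

  coefs <- matrix(NA_real_, ngene, ncol(Xf),
                  dimnames = list(rownames(counts), colnames(Xf)))
  ll_full <- lrt <- pval <- rep(NA_real_, ngene)
  conv <- rep(TRUE, ngene)
  df_lrt <- if (!is.null(Xr)) ncol(Xf) - ncol(Xr) else NA_integer_
  for (i in seq_len(ngene)) {
    y <- counts[i, ]
    f1 <- .nb_fit(y, Xf, offset, alpha[i])
    if (!f1$converged) {  # fallback: restart from Poisson coefficients
      ini <- suppressWarnings(glm.fit(Xf, y, family = poisson(),
                                      offset = offset))$coefficients
      f1 <- tryCatch({
        fam <- MASS::negative.binomial(theta = 1 / alpha[i])
        fit <- suppressWarnings(glm.fit(Xf, y, family = fam, offset = offset,
                                        start = ini))
        mu <- pmax(fit$fitted.values, 1e-10)
        list(coef = fit$coefficients, mu = mu,
             loglik = .nb_loglik(y, mu, alpha[i]),
             converged = isTRUE(fit$converged))
      }, error = function(e) f1)
      conv[i] <- f1$converged
    }
    coefs[i, ] <- f1$coef
    ll_full[i] <- f1$loglik
    if (!is.null(Xr)) {
      f0 <- .nb_fit(y, Xr, offset, alpha[i])
      lrt[i] <- max(0, 2 * (f1$loglik - f0$loglik))
      pval[i] <- pchisq(lrt[i], df = df_lrt, lower.tail = FALSE)
    }
  }
  list(coef = coefs, dispersion = setNames(alpha, rownames(counts)),
       loglik = setNames(ll_full, rownames(counts)),
       lrt_stat = lrt, pvalue = pval,
       padj = if (!is.null(Xr)) p.adjust(pval, method = "BH") else NULL,
       converged = conv, excluded = excluded, sf = sf,
       terms_full = colnames(Xf),
       terms_reduced = if (!is.null(Xr)) colnames(Xr) else NULL)
}
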