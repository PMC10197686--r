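## Feature-importance modelling: Random Forest and Lasso under an outer
## cross-validation scheme, with importance measured on held-out folds.

.feature_matrix <- function(features) {
  x <- features[, setdiff(names(features), "gene_id"), drop = FALSE]
  x <- x[, vapply(x, is.numeric, TRUE), drop = FALSE]
  as.matrix(x)
}

.drop_constant <- function(x) {
  v <- apply(x, 2, var)
  drop <- colnames(x)[v == 0 | is.na(v)]
  if (length(drop)) {
    warning("dropping zero-variance features: ",
            paste(drop, collapse = ", "))
    x <- x[, !(colnames(x) %in% drop), drop = FALSE]
  }
  x
}

.make_folds <- function(n, k) sample(rep(seq_len(k), length.out = n))

#' Random-forest regression with held-out permutation importance
#'
#' Fits a Random Forest (default parameters: 500 trees, p/3 candidate
#' features per split) on each training fold of a `n_folds` cross-validation
#' and, on the held-out fold, records (i) Pearson/Spearman correlation
#' between predicted and observed values and (ii) per-feature permutation
#' importance -- the mean increase in held-out MSE when that feature's
#' column is permuted (the regression realization of mean decrease in
#' accuracy). Fold means are reported.
#'
#' @param features feature table (data frame with `gene_id` plus numeric
#'   columns) or numeric matrix.
#' @param target numeric response, one value per row of `features`.
#' @param n_folds folds of the outer CV.
#' @param seed seed controlling fold assignment, forest growth and
#'   permutations.
#' @param ntree,mtry forest size and features per split (defaults 500 and
#'   p/3).
#' @param n_perm permutations averaged per feature and fold.
#' @return list: `importance` (per-feature mean/sd across folds, ranked),
#'   `performance` (per-fold and mean held-out correlations), `folds`
#'   (assignment vector), `model = "rf"`.
#' @export
fit_rf_cv <- function(features, target, n_folds = 5, seed = 1L,
                      ntree = 500, mtry = NULL, n_perm = 1) {
  x <- if (is.matrix(features)) features else .feature_matrix(features)
  .assert(nrow(x) >= 50, "need >= 50 genes to fit")
  .assert(var(target) > 0, "target is constant")
  x <- .drop_constant(x)
  set.seed(seed)
  folds <- .make_folds(nrow(x), n_folds)
  imp <- matrix(0, ncol(x), n_folds, dimnames = list(colnames(x), NULL))
  perf <- data.frame(fold = seq_len(n_folds), pearson = NA_real_,
                     spearman = NA_real_)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    rf <- randomForest::randomForest(
      x[tr, , drop = FALSE], target[tr], ntree = ntree,
      mtry = mtry %||% max(floor(ncol(x) / 3), 1))
    xte <- x[!tr, , drop = FALSE]
    pred <- predict(rf, xte)
    obs <- target[!tr]
    perf$pearson[f] <- cor(pred, obs)
    perf$spearman[f] <- cor(pred, obs, method = "spearman")
    mse0 <- mean((pred - obs)^2)
    for (j in seq_len(ncol(x))) {
      dmse <- vapply(seq_len(n_perm), function(r) {
        xp <- xte
        xp[, j] <- sample(xp[, j])
        mean((predict(rf, xp) - obs)^2) - mse0
      }, numeric(1))
      imp[j, f] <- mean(dmse)
    }
  }
  importance <- data.frame(
    feature = rownames(imp),
    importance = rowMeans(imp),
    sd = apply(imp, 1, sd), stringsAsFactors = FALSE)
  importance <- importance[order(-importance$importance), ]
  importance$rank <- seq_len(nrow(importance))
  rownames(importance) <- NULL
  list(importance = importance,
       performance = rbind(perf,
                           data.frame(fold = NA, pearson = mean(perf$pearson),
                                      spearman = mean(perf$spearman))),
       folds = folds, model = "rf")
}

#' Lasso regression with nested cross-validation
#'
#' Outer `n_folds` CV for held-out performance; within each training fold
#' predictors are standardized (training-fold means/SDs only -- no leakage)
#' and the regularization strength is chosen by inner CV
#' ([glmnet::cv.glmnet]). Reported coefficients come from a final fit on the
#' full standardized data at the inner-CV-chosen lambda, so exact zeros are
#' meaningful for feature selection.
#'
#' @inheritParams fit_rf_cv
#' @param s which inner-CV lambda to use, `"lambda.1se"` (default,
#'   parsimonious) or `"lambda.min"`.
#' @return list: `importance` (per-feature coefficient on the standardized
#'   scale, ranked by |coefficient|), `performance`, `folds`,
#'   `model = "lasso"`.
#' @export
fit_lasso_cv <- function(features, target, n_folds = 5, seed = 1L,
                         s = c("lambda.1se", "lambda.min")) {
  s <- match.arg(s)
  x <- if (is.matrix(features)) features else .feature_matrix(features)
  x <- .drop_constant(x)
  .assert(qr(scale(x))$rank > 0, "degenerate predictor matrix")
  set.seed(seed)
  folds <- .make_folds(nrow(x), n_folds)
  if (var(target) == 0) {  # constant response: the lasso null model
    importance <- data.frame(feature = colnames(x),
                             coefficient = 0, rank = seq_len(ncol(x)))
    perf <- data.frame(fold = c(seq_len(n_folds), NA), pearson = 0,
                       spearman = 0)
    return(list(importance = importance, performance = perf,
                folds = folds, model = "lasso", heldout_colmeans = NULL))
  }
  perf <- data.frame(fold = seq_len(n_folds), pearson = NA_real_,
                     spearman = NA_real_)
  heldout_colmeans <- numeric(0)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    xs_tr <- scale(x[tr, , drop = FALSE], mu, sdv)
    xs_te <- scale(x[!tr, , drop = FALSE], mu, sdv)
    heldout_colmeans <- c(heldout_colmeans, colMeans(xs_te))
    cvfit <- glmnet::cv.glmnet(xs_tr, target[tr], alpha = 1,
                               standardize = FALSE)
    pred <- as.numeric(predict(cvfit, xs_te, s = s))
    obs <- target[!tr]
    perf$pearson[f] <- suppressWarnings(cor(pred, obs))
    perf$spearman[f] <- suppressWarnings(cor(pred, obs,
                                             method = "spearman"))
  }
  ## final coefficients: full data, standardized, inner-CV lambda
  xs <- scale(x)
  xs[, apply(x, 2, sd) == 0] <- 0
  cvfull <- glmnet::cv.glmnet(xs, target, alpha = 1, standardize = FALSE)
  beta <- as.numeric(coef(cvfull, s = s))[-1]
  importance <- data.frame(feature = colnames(x), coefficient = beta,
                           stringsAsFactors = FALSE)
  importance <- importance[order(-abs(importance$coefficient)), ]
  importance$rank <- seq_len(nrow(importance))
  rownames(importance) <- NULL
  perf$pearson[is.na(perf$pearson)] <- 0  # all-zero model predicts a constant
  perf$spearman[is.na(perf$spearman)] <- 0
  list(importance = importance,
       performance = rbind(perf,
                           data.frame(fold = NA, pearson = mean(perf$pearson),
                                      spearman = mean(perf$spearman))),
       folds = folds, model = "lasso",
       ## scaling uses training-fold parameters only, so held-out column
       ## means are near, but not exactly, zero -- kept for leakage audits
       heldout_colmeans = heldout_colmeans)
}

#' Importance-versus-performance table across datasets
#'
#' For a panel of fitted reports (e.g. one per knockdown dataset), extracts
#' each dataset's importance of a focal feature (GCcds by default) alongside
#' its held-out Spearman performance, plus optional comparison features --
#' the table behind "GCcds importance predicts model performance" panels.
#'
#' @param reports named list of [fit_rf_cv()]/[fit_lasso_cv()] outputs.
#' @param feature focal feature name.
#' @param comparison_features further features to tabulate.
#' @return data frame: `dataset`, `feature`, `importance`, `spearman`.
#' @export
importance_vs_performance <- function(reports, feature = "GCcds",
                                      comparison_features = character(0)) {
  .assert(length(reports) >= 1, "need at least one report")
  feats <- c(feature, comparison_features)
  rows <- lapply(names(reports), function(nm) {
    rep <- reports[[nm]]
    imp <- rep$importance
    valcol <- if ("importance" %in% names(imp)) "importance" else "coefficient"
    sp <- rep$performance$spearman[is.na(rep$performance$fold)]
    data.frame(dataset = nm, feature = feats,
               importance = imp[[valcol]][match(feats, imp$feature)],
               spearman = sp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
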