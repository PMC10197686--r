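#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnbinom rpois rbinom rlnorm runif rnorm optimize
#'   model.matrix pchisq p.adjust glm.fit poisson dnbinom median quantile
#'   wilcox.test cor cor.test lm coef predict var sd setNames ks.test
#'   complete.cases rmultinom weighted.mean
#' @importFrom utils write.table read.delim head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

## natural-log GLM coefficient -> log2 fold change
.to_log2 <- function(x) x / log(2)

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## random nucleotide string(s) with a target GC fraction
.random_seq <- function(len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
        collapse = "")
}
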