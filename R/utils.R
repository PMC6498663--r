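#' @importFrom methods new validObject is slot
#' @importFrom stats cor pnorm phyper p.adjust quantile median mad rnorm rpois
#'   hclust dist as.dendrogram runif complete.cases setNames lm coef
#'   binom.test loess predict sd
#' @importFrom utils head read.delim write.table combn
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic operations in the package go through
# this so that a single integer seed fixes the whole pipeline.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one master seed, kept within 32-bit
# integer range.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stopf("'%s' must be a single number in [%s, %s]", name, lower, upper)
  invisible(x)
}

# Canonical unordered-pair key used by edge hash tables.
pairKey <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}
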