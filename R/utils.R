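#' @useDynLib roiconn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef cor lm lm.fit mad median pchisq pnorm pt qnorm
#'   quantile rnorm runif rpois sd t.test kruskal.test wilcox.test anova
#' @importFrom utils read.table write.table head
"_PACKAGE"

#' Evaluate an expression with a private RNG stream
#'
#' Saves and restores `.Random.seed` so package operations never disturb (or
#' depend on) the caller's global RNG state. All randomness in the package is
#' routed through this helper with an explicit seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_rng <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a root seed
#'
#' Deterministic substreams: every stochastic operation receives its own child
#' seed so a single root seed reproduces the whole pipeline. Kept within
#' 32-bit integer range.
#'
#' @param seed root seed (integer).
#' @param k substream index (integer >= 0).
#' @return integer child seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer(((s * 69621 + as.double(k) * 1013904223) %% 2147483646) + 1)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Normalized mutual information between two partitions
#'
#' Used to quantify recovery of planted module structure by community
#' detection. Both vectors are treated as categorical labels.
#'
#' @param a,b integer/character membership vectors of equal length.
#' @return NMI in `[0, 1]` (1 for identical partitions up to relabelling).
#' @export
partition_nmi <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  n <- length(a)
  tab <- table(a, b)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi / sqrt(ha * hb)
}
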