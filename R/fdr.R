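#' Rank-conditional FDR critical value
#'
#' The rank-based false-discovery filter compares the i-th smallest p-value
#' against `i * q / (V * c(V))`: `V` total comparisons (e.g. 139 ROIs),
#' false-positive filter level `q` (0.2 in the volumetry/diffusion analyses)
#' and `c(V) = 1` for independent or positively dependent tests.
#'
#' @param rank rank i of the p-value (1 = smallest).
#' @param V total number of comparisons (`V >= rank`).
#' @param q false-positive filter level in (0, 1].
#' @param cV dependency constant (1 by default).
#' @param digits optional display rounding (e.g. 3 to match printed tables);
#'   `NULL` returns the exact value.
#' @return critical value(s).
#' @export
fdr_critical <- function(rank, V, q = 0.2, cV = 1, digits = NULL) {
  if (any(rank < 1) || any(rank > V)) stop_field("rank", "must be in 1..V")
  if (!(q > 0 && q <= 1)) stop_field("q", "must be in (0, 1]")
  if (cV <= 0) stop_field("cV", "must be > 0")
  out <- rank * q / (V * cV)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Rank-based false-discovery filter
#'
#' Sorts p-values ascending, assigns ranks i, and flags test i as passing
#' when `p(i) <= i * q / (V * cV)`. `V` may exceed the number of supplied
#' p-values (tests not run still count in the comparison budget). Results are
#' returned in the input order; the decision set is invariant to input order.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param V total comparisons (defaults to `length(pvals)`).
#' @param q false-positive filter level (default 0.2).
#' @param cV dependency constant (default 1).
#' @return data.frame in input order: p, rank, critical, passes.
#' @export
fdr_filter <- function(pvals, V = length(pvals), q = 0.2, cV = 1) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE) || anyNA(pvals)) {
    stop_field("pvals", "must lie in [0, 1]")
  }
  if (V < length(pvals)) stop_field("V", "must be >= length(pvals)")
  ord <- order(pvals)
  rank <- integer(length(pvals))
  rank[ord] <- seq_along(pvals)
  critical <- fdr_critical(rank, V = V, q = q, cV = cV)
  data.frame(p = pvals, rank = rank, critical = critical,
             passes = pvals <= critical)
}

#' Two-stage step-up FDR decisions
#'
#' Adaptive two-stage linear step-up procedure: (1) run the linear step-up at
#' level `q' = q / (1 + q)` to estimate the number of true nulls
#' `m0 = m - r1`; (2) if `0 < r1 < m`, rerun the step-up at level
#' `q' * m / m0`. Decisions are monotone in p.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param q target FDR level (default 0.05).
#' @return logical vector of discoveries in input order.
#' @export
fdr_two_stage <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE) || anyNA(pvals)) {
    stop_field("pvals", "must lie in [0, 1]")
  }
  m <- length(pvals)
  if (m == 0) return(logical())
  step_up <- function(p, level) {
    ord <- order(p)
    ps <- p[ord]
    ok <- which(ps <= seq_len(m) / m * level)
    out <- logical(m)
    if (length(ok)) out[ord[seq_len(max(ok))]] <- TRUE
    out
  }
  q1 <- q / (1 + q)
  stage1 <- step_up(pvals, q1)
  r1 <- sum(stage1)
  if (r1 == 0 || r1 == m) return(stage1)
  m0 <- m - r1
  step_up(pvals, q1 * m / m0)
}
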