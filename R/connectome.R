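#' Fisher z transform
#'
#' Variance-stabilizing transform of a Pearson correlation: `atanh(r)`, with
#' `|r|` clipped to `1 - 1e-12` beforehand so perfectly correlated pairs map
#' to a large finite value. Strictly increasing and odd.
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @return numeric vector of z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) {
    stop_field("r", "correlations must lie in [-1, 1]")
  }
  atanh(pmax(pmin(r, 1 - 1e-12), -1 + 1e-12))
}

#' Functional connectivity matrix
#'
#' Symmetric Pearson correlation matrix over all node pairs, computed on
#' non-censored frames, with the Fisher z transform applied off-diagonal and
#' an optional bootstrap significance mask.
#'
#' @param series a [roi_ts()].
#' @param bootstrap if `TRUE`, attach a significance mask from percentile
#'   bootstrap CIs of each pairwise correlation.
#' @param B bootstrap resamples (default 1000).
#' @param alpha CI level complement; a pair is significant when the
#'   `1 - alpha` percentile CI excludes 0.
#' @param seed seed for the bootstrap resampling.
#' @return object of class `conn_matrix`: list with `node_names`, `r`, `z`,
#'   `sig_mask` (logical or `NULL`).
#' @export
correlate <- function(series, bootstrap = FALSE, B = 1000L, alpha = 0.05,
                      seed = 1L) {
  stopifnot(inherits(series, "roi_ts"))
  keep <- usable_frames(series)
  if (length(keep) < 3) stop("need >= 3 non-censored frames", call. = FALSE)
  x <- series$data[, keep, drop = FALSE]
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    stop(sprintf("degenerate signal: zero variance at node(s) %s",
                 paste(series$node_names[v == 0], collapse = ", ")),
         call. = FALSE)
  }
  r <- cor(t(x))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  z <- fisher_z(r)
  diag(z) <- 0
  sig <- NULL
  if (bootstrap) {
    sig <- bootstrap_sig_matrix(x, B = B, alpha = alpha, seed = seed)
  }
  structure(list(node_names = series$node_names, r = r, z = z,
                 sig_mask = sig),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  n <- length(x$node_names)
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("Connectivity matrix: %d nodes, %d pairs\n", n, length(off)))
  cat(sprintf("  r range [%.3f, %.3f], mean %.3f%s\n", min(off), max(off),
              mean(off),
              if (is.null(x$sig_mask)) "" else
                sprintf(", %d significant pairs",
                        sum(x$sig_mask[upper.tri(x$sig_mask)]))))
  invisible(x)
}

#' Bootstrap significance of one Pearson correlation
#'
#' Percentile CI of r over `B` paired resamples of the observations; the pair
#' is significant when the CI at level `1 - alpha` excludes zero. A resample
#' in which either variable is constant contributes r = 0.
#'
#' @param x,y numeric vectors of equal length >= 10.
#' @param B number of resamples (>= 100).
#' @param alpha CI level complement (default 0.05).
#' @param seed resampling seed.
#' @return list: `is_significant`, `ci` (length 2), `r` (sample correlation).
#' @export
bootstrap_sig <- function(x, y, B = 1000L, alpha = 0.05, seed = 1L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 10) stop_field("x", "need at least 10 paired observations")
  if (B < 100) stop_field("B", "need at least 100 resamples")
  rb <- with_rng(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    xb <- matrix(x[idx], n, B)
    yb <- matrix(y[idx], n, B)
    boot_cor_cols(xb, yb)
  })
  ci <- unname(quantile(rb, c(alpha / 2, 1 - alpha / 2), type = 7))
  list(is_significant = (ci[1] > 0 || ci[2] < 0), ci = ci,
       r = cor(x, y))
}

# column-wise correlations; zero-variance columns give 0
boot_cor_cols <- function(xb, yb) {
  n <- nrow(xb)
  sx <- colSums(xb); sy <- colSums(yb)
  sxx <- colSums(xb^2) - sx^2 / n
  syy <- colSums(yb^2) - sy^2 / n
  sxy <- colSums(xb * yb) - sx * sy / n
  den <- sqrt(sxx * syy)
  out <- ifelse(den > 0, sxy / den, 0)
  pmax(pmin(out, 1), -1)
}

# full-matrix bootstrap: resample frames jointly, CI per pair
bootstrap_sig_matrix <- function(x, B = 1000L, alpha = 0.05, seed = 1L) {
  n <- nrow(x)
  tt <- ncol(x)
  vals <- array(NA_real_, dim = c(n, n, B))
  with_rng(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(tt, tt, replace = TRUE)
      rb <- suppressWarnings(cor(t(x[, idx, drop = FALSE])))
      rb[!is.finite(rb)] <- 0
      vals[, , b] <- rb
    }
  })
  lo <- apply(vals, c(1, 2), quantile, probs = alpha / 2, type = 7)
  hi <- apply(vals, c(1, 2), quantile, probs = 1 - alpha / 2, type = 7)
  sig <- (lo > 0) | (hi < 0)
  diag(sig) <- FALSE
  sig <- sig & t(sig)
  sig
}

#' Weighted graph container
#'
#' Symmetric nonnegative weights with zero diagonal; `density` is the
#' fraction of retained off-diagonal pairs. Invariants are asserted on every
#' construction.
#'
#' @param weights numeric `N x N` symmetric nonnegative matrix.
#' @param node_names character names, length N.
#' @return object of class `weighted_graph`.
#' @export
weighted_graph <- function(weights, node_names = rownames(weights)) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (is.null(node_names)) node_names <- paste0("ROI_", seq_len(n))
  if (ncol(weights) != n) stop_field("weights", "must be square")
  if (max(abs(weights - t(weights))) > 1e-12) {
    stop_field("weights", "must be symmetric")
  }
  if (any(weights < 0)) stop_field("weights", "must be nonnegative")
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  dimnames(weights) <- list(node_names, node_names)
  m <- n * (n - 1) / 2
  dens <- if (m > 0) sum(weights[upper.tri(weights)] > 0) / m else 0
  structure(list(node_names = node_names, weights = weights, density = dens),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  n <- length(x$node_names)
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("Weighted graph: %d nodes, %d edges (density %.3f)\n",
              n, ne, x$density))
  invisible(x)
}

n_edges <- function(g) sum(g$weights[upper.tri(g$weights)] > 0)

#' Threshold a connectivity matrix by |z|
#'
#' Retains edges with `|z| >= z_cut` that are also bootstrap-significant when
#' a significance mask is present. Retained weights are the z values; the
#' negative-edge policy either discards negative edges (default; graph
#' metrics assume nonnegative weights) or takes absolute values.
#'
#' @param cm a [correlate()] result.
#' @param z_cut nonnegative threshold on `|z|` (default 2.3).
#' @param negative_edges `"discard"` or `"absolute"`.
#' @return a [weighted_graph()].
#' @export
z_mask <- function(cm, z_cut = 2.3, negative_edges = c("discard", "absolute")) {
  stopifnot(inherits(cm, "conn_matrix"))
  negative_edges <- match.arg(negative_edges)
  if (z_cut < 0) stop_field("z_cut", "must be >= 0")
  w <- cm$z
  keep <- abs(w) >= z_cut
  if (!is.null(cm$sig_mask)) keep <- keep & cm$sig_mask
  w[!keep] <- 0
  if (negative_edges == "discard") w[w < 0] <- 0 else w <- abs(w)
  diag(w) <- 0
  weighted_graph(w, cm$node_names)
}

# rank off-diagonal pairs by weight (desc), ties by (i, j) lexicographic
edge_ranking <- function(w) {
  n <- nrow(w)
  ut <- which(upper.tri(w))
  ii <- row(w)[ut]
  jj <- col(w)[ut]
  wt <- w[ut]
  ord <- order(-wt, ii, jj)
  list(idx = ut[ord], i = ii[ord], j = jj[ord], w = wt[ord])
}

#' Proportional edge-density thresholding
#'
#' Keeps the `k = floor(density * N(N-1)/2)` largest-weight edges (ties broken
#' by node-index lexicographic order), preserving weights. Edges retained at a
#' lower density are always a subset of those retained at a higher one.
#'
#' @param g a [weighted_graph()].
#' @param density target fraction of retained pairs in (0, 1].
#' @return a [weighted_graph()] with at most the requested density.
#' @export
density_threshold <- function(g, density) {
  stopifnot(inherits(g, "weighted_graph"))
  if (!(density > 0 && density <= 1)) stop_field("density", "must be in (0,1]")
  n <- length(g$node_names)
  m <- n * (n - 1) / 2
  k <- floor(density * m)
  if (k == 0) {
    warning("density too low: no edges retained")
    return(weighted_graph(matrix(0, n, n), g$node_names))
  }
  rk <- edge_ranking(g$weights)
  keep_idx <- rk$idx[seq_len(min(k, sum(rk$w > 0)))]
  keep_idx <- keep_idx[g$weights[keep_idx] > 0]
  w <- matrix(0, n, n)
  w[keep_idx] <- g$weights[keep_idx]
  w <- w + t(w)
  weighted_graph(w, g$node_names)
}

#' Build the weighted graph a connectivity matrix implies
#'
#' Convenience: [z_mask()] with the given cut (0 keeps everything positive)
#' ready for density thresholding or the metric sweep.
#'
#' @param cm a [correlate()] result.
#' @param z_cut threshold on `|z|` (default 0 for sweep input).
#' @param negative_edges negative-weight policy.
#' @return a [weighted_graph()].
#' @export
as_weighted_graph <- function(cm, z_cut = 0,
                              negative_edges = c("discard", "absolute")) {
  z_mask(cm, z_cut = z_cut, negative_edges = match.arg(negative_edges))
}
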