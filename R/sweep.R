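#' Multi-threshold global metric sweep
#'
#' Thresholds the connectivity graph at each edge density (default 2-40% in
#' steps of 2%), computes the global metrics on each thresholded graph, and
#' summarizes each metric curve by its trapezoidal area under the curve over
#' density. Because proportional thresholds are nested, edges are ranked once
#' and reused across densities.
#'
#' Modularity at each density is the best Q over `q_iter` Louvain restarts
#' (a light-weight stand-in for the full consensus procedure, which is
#' available separately via [consensus_partition()]).
#'
#' @param cm a [correlate()] result or a [weighted_graph()].
#' @param densities increasing vector of edge densities in (0, 1].
#' @param metrics subset of
#'   `c("strength", "cpl", "efficiency", "clustering", "transitivity",
#'   "assortativity", "modularity")`.
#' @param q_iter Louvain restarts per density (default 5).
#' @param seed seed for the modularity restarts.
#' @param negative_edges negative-weight policy when `cm` is a connectivity
#'   matrix.
#' @return object of class `threshold_sweep`: `densities`, `values`
#'   (density x metric data.frame), `auc` (named numeric).
#' @export
metric_sweep <- function(cm, densities = seq(0.02, 0.40, by = 0.02),
                         metrics = c("strength", "cpl", "efficiency",
                                     "clustering", "transitivity",
                                     "assortativity", "modularity"),
                         q_iter = 5L, seed = 1L,
                         negative_edges = c("discard", "absolute")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (any(densities <= 0 | densities > 1) || is.unsorted(densities, strictly = TRUE)) {
    stop_field("densities", "must be strictly increasing within (0, 1]")
  }
  g0 <- if (inherits(cm, "conn_matrix")) {
    as_weighted_graph(cm, z_cut = 0, negative_edges = match.arg(negative_edges))
  } else if (inherits(cm, "weighted_graph")) cm else {
    stop_field("cm", "need a conn_matrix or weighted_graph")
  }
  n <- length(g0$node_names)
  m <- n * (n - 1) / 2
  rk <- edge_ranking(g0$weights)
  pos <- rk$w > 0
  vals <- matrix(NA_real_, length(densities), length(metrics),
                 dimnames = list(NULL, metrics))
  for (di in seq_along(densities)) {
    k <- floor(densities[di] * m)
    keep <- rk$idx[seq_len(min(k, sum(pos)))]
    keep <- keep[g0$weights[keep] > 0]
    w <- matrix(0, n, n)
    w[keep] <- g0$weights[keep]
    w <- w + t(w)
    g <- weighted_graph(w, g0$node_names)
    for (mt in metrics) {
      vals[di, mt] <- switch(
        mt,
        strength = mean(node_strength(g)),
        cpl = if (n_edges(g) > 0) char_path_length(g) else NA_real_,
        efficiency = global_efficiency(g),
        clustering = mean(clustering_coefficient(g)),
        transitivity = transitivity(g),
        assortativity = if (n_edges(g) >= 2) {
          suppressWarnings(assortativity(g))
        } else NA_real_,
        modularity = if (n_edges(g) > 0) {
          max(vapply(seq_len(q_iter), function(i) {
            modularity_louvain(g, seed = child_seed(seed, di * 1000L + i))$Q
          }, 0))
        } else NA_real_)
    }
  }
  auc <- apply(vals, 2, function(y) trapz_auc(densities, y))
  structure(list(densities = densities,
                 values = data.frame(density = densities, vals,
                                     check.names = FALSE),
                 auc = auc),
            class = "threshold_sweep")
}

#' Trapezoidal area under a metric-vs-density curve
#'
#' @param x density grid.
#' @param y metric values (NA pairs are dropped segment-wise).
#' @return scalar AUC in metric-units x density.
#' @export
trapz_auc <- function(x, y) {
  ok <- is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("Threshold sweep over %d densities (%.0f%%-%.0f%%)\n",
              length(x$densities), 100 * min(x$densities),
              100 * max(x$densities)))
  cat("AUC:\n")
  print(round(x$auc, 4))
  invisible(x)
}

#' @export
plot.threshold_sweep <- function(x, metrics = setdiff(names(x$values), "density"),
                                 ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(metrics)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (mt in metrics) {
    graphics::plot(x$densities, x$values[[mt]], type = "b", pch = 16,
                   xlab = "edge density", ylab = mt,
                   main = sprintf("AUC = %.3f", x$auc[[mt]]), ...)
  }
  invisible(x)
}

#' Node-level metrics at a fixed density
#'
#' Strength, weighted clustering, binary degree, betweenness centrality (on
#' `1/weight` lengths) and eigenvector centrality, evaluated on the graph
#' thresholded at the requested edge density (default 16%).
#'
#' @param cm a [correlate()] result or [weighted_graph()].
#' @param density edge density for the evaluation graph.
#' @param negative_edges negative-weight policy when `cm` is a matrix.
#' @return data.frame (one row per node): node, strength, clustering, degree,
#'   betweenness, eigenvector; attribute `evaluated_at_density`.
#' @export
node_metrics_at <- function(cm, density = 0.16,
                            negative_edges = c("discard", "absolute")) {
  g0 <- if (inherits(cm, "conn_matrix")) {
    as_weighted_graph(cm, z_cut = 0, negative_edges = match.arg(negative_edges))
  } else cm
  g <- density_threshold(g0, density)
  out <- data.frame(
    node = g$node_names,
    strength = unname(node_strength(g)),
    clustering = unname(clustering_coefficient(g)),
    degree = unname(node_degree(g)),
    betweenness = unname(betweenness_centrality(g)),
    eigenvector = unname(suppressWarnings(eigenvector_centrality(g))),
    stringsAsFactors = FALSE)
  attr(out, "evaluated_at_density") <- density
  out
}
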