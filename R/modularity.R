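#' Modularity statistic of a given partition
#'
#' Newman's weighted Q: `Q = sum_ij (A_ij - gamma k_i k_j / W) d(c_i, c_j) / W`
#' over ordered pairs, with `k` the node strengths and `W` the total weight
#' (both edge directions). This is the standalone evaluator every partition
#' operation is checked against.
#'
#' @param g a [weighted_graph()].
#' @param affiliation integer module membership vector.
#' @param gamma resolution parameter (default 1).
#' @return scalar Q in `[-1, 1]`.
#' @export
modularity_q <- function(g, affiliation, gamma = 1) {
  stopifnot(inherits(g, "weighted_graph"),
            length(affiliation) == length(g$node_names))
  w <- g$weights
  wtot <- sum(w)
  if (wtot == 0) stop("no edges: modularity undefined", call. = FALSE)
  k <- rowSums(w)
  same <- outer(affiliation, affiliation, "==")
  sum((w - gamma * outer(k, k) / wtot) * same) / wtot
}

relabel_contiguous <- function(aff) {
  match(aff, unique(aff))
}

#' Louvain community detection
#'
#' Greedy modularity maximization: starting from singleton groups, nodes are
#' iteratively moved to the neighboring group that most increases Q, then
#' groups are agglomerated and the procedure repeated. Node visiting order is
#' randomized, so different seeds explore different local optima;
#' deterministic given the seed.
#'
#' @param g a [weighted_graph()] with at least one edge.
#' @param gamma resolution parameter (default 1).
#' @param seed integer seed controlling node order.
#' @return object of class `community_partition`: `affiliation` (module ids
#'   contiguous from 1), `Q`, `n_modules`, `n_iterations`, `seed`.
#' @export
modularity_louvain <- function(g, gamma = 1, seed = 1L) {
  stopifnot(inherits(g, "weighted_graph"))
  if (n_edges(g) == 0) stop("no edges: cannot partition", call. = FALSE)
  aff <- relabel_contiguous(.louvain_cpp(g$weights, gamma, as.integer(seed)))
  structure(list(affiliation = stats::setNames(aff, g$node_names),
                 Q = modularity_q(g, aff, gamma),
                 n_modules = max(aff), n_iterations = 1L,
                 seed = as.integer(seed)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d modules, Q = %.4f (%d iteration%s)\n",
              x$n_modules, x$Q, x$n_iterations,
              if (x$n_iterations == 1) "" else "s"))
  invisible(x)
}

#' Consensus community partition
#'
#' Runs [modularity_louvain()] `n_iter` times under derived seeds. The
#' reported module count is the median count across runs, and the reported
#' affiliation is the run whose (module count, Q) is closest to the medians
#' (count first, then Q, then lowest run index). All runs' Q values and
#' module counts are retained for diagnostics. `method = "association"`
#' instead builds the mean co-assignment matrix across runs, thresholds it at
#' 0.5, and partitions that consensus graph once.
#'
#' @param g a [weighted_graph()].
#' @param n_iter number of Louvain restarts (default 1000).
#' @param gamma resolution parameter.
#' @param seed root seed; run i uses `child_seed(seed, i)`.
#' @param method `"representative"` (default) or `"association"`.
#' @return `community_partition` with extra fields `all_Q`, `all_n_modules`.
#' @export
consensus_partition <- function(g, n_iter = 1000L, gamma = 1, seed = 1L,
                                method = c("representative", "association")) {
  method <- match.arg(method)
  if (n_iter < 1) stop_field("n_iter", "must be >= 1")
  runs <- lapply(seq_len(n_iter), function(i) {
    modularity_louvain(g, gamma = gamma, seed = child_seed(seed, i))
  })
  qs <- vapply(runs, `[[`, 0, "Q")
  ns <- vapply(runs, `[[`, 0, "n_modules")
  if (method == "association") {
    n <- length(g$node_names)
    co <- matrix(0, n, n)
    for (r in runs) co <- co + outer(r$affiliation, r$affiliation, "==")
    co <- co / n_iter
    co[co < 0.5] <- 0
    diag(co) <- 0
    part <- modularity_louvain(weighted_graph(co, g$node_names),
                               gamma = gamma, seed = child_seed(seed, 0L))
    aff <- part$affiliation
  } else {
    med_n <- median(ns)
    med_q <- median(qs)
    score <- abs(ns - med_n) * 1e6 + abs(qs - med_q)
    pick <- which.min(score)
    aff <- runs[[pick]]$affiliation
  }
  aff <- stats::setNames(relabel_contiguous(aff), g$node_names)
  structure(list(affiliation = aff, Q = modularity_q(g, aff, gamma),
                 n_modules = max(aff), n_iterations = as.integer(n_iter),
                 seed = as.integer(seed), all_Q = qs, all_n_modules = ns),
            class = "community_partition")
}

#' Degree- and weight-preserving edge rewiring
#'
#' Double-edge swaps: repeatedly pick two edges (a-b, c-d) and exchange
#' endpoints (a-d, c-b) when that creates no self-loop or duplicate edge.
#' Weights travel with the swapped connections, so the binary degree sequence
#' and the weight multiset are preserved exactly. `swaps_per_edge * |E|`
#' effective swaps are attempted (with a bounded number of retries); if the
#' budget is exhausted early a warning reports the shortfall.
#'
#' @param g a [weighted_graph()] with >= 2 independent edges.
#' @param swaps_per_edge target effective swaps per edge (default 10).
#' @param seed integer seed.
#' @return rewired [weighted_graph()].
#' @export
rewire_null <- function(g, swaps_per_edge = 10, seed = 1L) {
  stopifnot(inherits(g, "weighted_graph"))
  w <- g$weights
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0)
  m <- length(ut)
  if (m < 2) stop("need >= 2 edges to rewire", call. = FALSE)
  ei <- row(w)[ut]
  ej <- col(w)[ut]
  ew <- w[ut]
  adj <- w > 0
  target <- ceiling(swaps_per_edge * m)
  max_attempts <- 20L * target
  done <- 0L
  with_rng(seed, {
    attempts <- 0L
    while (done < target && attempts < max_attempts) {
      attempts <- attempts + 1L
      pick <- sample.int(m, 2L)
      e1 <- pick[1]; e2 <- pick[2]
      a <- ei[e1]; b <- ej[e1]; c <- ei[e2]; d <- ej[e2]
      if (runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      # propose a-d, c-b
      if (a == d || c == b || a == c || b == d) next
      if (adj[a, d] || adj[c, b]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[c, d] <- adj[d, c] <- FALSE
      adj[a, d] <- adj[d, a] <- TRUE
      adj[c, b] <- adj[b, c] <- TRUE
      ei[e1] <- min(a, d); ej[e1] <- max(a, d)
      ei[e2] <- min(c, b); ej[e2] <- max(c, b)
      done <- done + 1L
    }
  })
  if (done < target) {
    warning(sprintf("rewiring stopped after %d of %d swaps (attempt budget)",
                    done, target))
  }
  w2 <- matrix(0, n, n)
  w2[cbind(ei, ej)] <- ew
  w2 <- w2 + t(w2)
  weighted_graph(w2, g$node_names)
}

#' Small-world index
#'
#' Ratio of the clustering ratio to the path-length ratio against an ensemble
#' of degree- and weight-preserving rewired graphs:
#' `SWI = (CC / mean CC_null) / (CPL / mean CPL_null)`. Values above 1
#' indicate small-world organization (clustering preserved, paths short).
#'
#' @param g a connected [weighted_graph()].
#' @param n_null number of rewired null graphs (default 10).
#' @param swaps_per_edge swaps per edge for each null.
#' @param seed root seed; null i uses `child_seed(seed, i)`.
#' @return scalar SWI.
#' @export
small_world_index <- function(g, n_null = 10L, swaps_per_edge = 10, seed = 1L) {
  cc_real <- mean(clustering_coefficient(g))
  cpl_real <- char_path_length(g)
  cc_null <- numeric(n_null)
  cpl_null <- numeric(n_null)
  for (i in seq_len(n_null)) {
    gn <- rewire_null(g, swaps_per_edge = swaps_per_edge,
                      seed = child_seed(seed, i))
    cc_null[i] <- mean(clustering_coefficient(gn))
    cpl_null[i] <- char_path_length(gn)
  }
  if (mean(cc_null) <= 0 || mean(cpl_null) <= 0) {
    stop("degenerate null ensemble: zero clustering or path length",
         call. = FALSE)
  }
  (cc_real / mean(cc_null)) / (cpl_real / mean(cpl_null))
}
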