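#' Node strength
#'
#' Sum of edge weights per node.
#'
#' @param g a [weighted_graph()].
#' @return named numeric vector, one value per node.
#' @export
node_strength <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  rowSums(g$weights)
}

#' Binary degree
#'
#' @param g a [weighted_graph()].
#' @return named integer vector of nonzero-edge counts per node.
#' @export
node_degree <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  rowSums(g$weights > 0)
}

#' Weighted clustering coefficient
#'
#' Per-node weighted clustering under the geometric-mean triangle definition:
#' weights are max-normalized, each triangle contributes the cube root of the
#' product of its three weights, and the total is divided by
#' `k_i (k_i - 1)` (binary degree). Nodes of degree < 2 have clustering 0.
#' The arithmetic alternative averages triangle weights linearly.
#'
#' @param g a [weighted_graph()].
#' @param variant `"geometric"` (default) or `"arithmetic"`.
#' @return named numeric vector in `[0, 1]`.
#' @export
clustering_coefficient <- function(g, variant = c("geometric", "arithmetic")) {
  stopifnot(inherits(g, "weighted_graph"))
  variant <- match.arg(variant)
  w <- g$weights
  mx <- max(w)
  if (mx == 0) return(stats::setNames(rep(0, nrow(w)), g$node_names))
  wn <- w / mx
  k <- rowSums(wn > 0)
  if (variant == "geometric") {
    w3 <- wn^(1 / 3)
    cyc <- diag(w3 %*% w3 %*% w3)
  } else {
    # arithmetic: each closed triangle contributes the mean of its 3 weights
    a <- (wn > 0) + 0
    cyc <- (2 * diag(wn %*% a %*% a) + diag(a %*% wn %*% a)) / 3
  }
  cc <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
  stats::setNames(pmin(pmax(cc, 0), 1), g$node_names)
}

#' Weighted transitivity
#'
#' Global triangle-to-triplet ratio on max-normalized weights: the sum over
#' nodes of geometric-mean triangle intensity divided by the total number of
#' connected triplets `sum_i k_i (k_i - 1)`.
#'
#' @param g a [weighted_graph()].
#' @return scalar in `[0, 1]` (0 for triplet-free graphs).
#' @export
transitivity <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  w <- g$weights
  mx <- max(w)
  if (mx == 0) return(0)
  wn <- w / mx
  k <- rowSums(wn > 0)
  w3 <- wn^(1 / 3)
  num <- sum(diag(w3 %*% w3 %*% w3))
  den <- sum(k * (k - 1))
  if (den == 0) 0 else num / den
}

# all-pairs shortest path lengths on 1/weight edge lengths
graph_distances <- function(g) {
  .dijkstra_all_cpp(g$weights)
}

#' Characteristic path length
#'
#' Mean shortest-path length over connected ordered node pairs, with edge
#' lengths `1/weight` (stronger edges are shorter). Errors when no pair is
#' connected.
#'
#' @param g a [weighted_graph()].
#' @return scalar CPL.
#' @export
char_path_length <- function(g) {
  d <- graph_distances(g)
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  if (!length(fin)) stop("CPL undefined: fully disconnected graph", call. = FALSE)
  mean(fin)
}

#' Global efficiency
#'
#' Mean of `1 / d(i, j)` over all ordered pairs, with `1/Inf = 0`; robust to
#' disconnected graphs (returns 0 when no edges exist).
#'
#' @param g a [weighted_graph()].
#' @return scalar efficiency.
#' @export
global_efficiency <- function(g) {
  d <- graph_distances(g)
  off <- d[row(d) != col(d)]
  if (!length(off)) return(0)
  mean(ifelse(is.finite(off) & off > 0, 1 / off, 0))
}

#' Strength assortativity
#'
#' Pearson correlation of node strengths at edge endpoints over all edges
#' (each undirected edge contributes both orientations). Returns 0 with a
#' warning when endpoint strengths are uniform (correlation undefined).
#'
#' @param g a [weighted_graph()].
#' @return scalar in `[-1, 1]`.
#' @export
assortativity <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  s <- node_strength(g)
  ut <- which(upper.tri(g$weights) & g$weights > 0)
  if (length(ut) < 2) stop("need at least 2 edges", call. = FALSE)
  i <- row(g$weights)[ut]
  j <- col(g$weights)[ut]
  a <- c(s[i], s[j])
  b <- c(s[j], s[i])
  if (sd(a) == 0 || sd(b) == 0) {
    warning("uniform endpoint strengths: assortativity undefined, returning 0")
    return(0)
  }
  cor(a, b)
}

#' Betweenness centrality
#'
#' Brandes' accumulation on weighted shortest paths (edge lengths
#' `1/weight`), computed per connected component. Counts of equal-length
#' geodesics use a relative tolerance of 1e-10.
#'
#' @param g a [weighted_graph()].
#' @return named numeric vector (unnormalized pair counts; each unordered
#'   pair counted once).
#' @export
betweenness_centrality <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  w <- g$weights
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  bc <- numeric(n)
  tol <- 1e-10
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    sigma <- numeric(n)
    dist[s] <- 0
    sigma[s] <- 1
    done <- logical(n)
    order_popped <- integer(0)
    pred <- vector("list", n)
    for (it in seq_len(n)) {
      cand <- which(!done & is.finite(dist))
      if (!length(cand)) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      order_popped <- c(order_popped, u)
      nb <- which(len[u, ] < Inf & !done)
      for (v in nb) {
        nd <- dist[u] + len[u, v]
        if (!is.finite(dist[v]) || nd < dist[v] - tol * max(1, nd)) {
          dist[v] <- nd
          sigma[v] <- sigma[u]
          pred[[v]] <- u
        } else if (abs(nd - dist[v]) <= tol * max(1, nd)) {
          sigma[v] <- sigma[v] + sigma[u]
          pred[[v]] <- c(pred[[v]], u)
        }
      }
    }
    delta <- numeric(n)
    for (v in rev(order_popped)) {
      for (u in pred[[v]]) {
        delta[u] <- delta[u] + sigma[u] / sigma[v] * (1 + delta[v])
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  stats::setNames(bc / 2, g$node_names)
}

#' Eigenvector centrality
#'
#' Power iteration (to 1e-10) on the weight matrix of the largest connected
#' component; nodes outside it get 0, with a warning. Scaled to unit maximum.
#'
#' @param g a [weighted_graph()].
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @return named numeric vector in `[0, 1]`.
#' @export
eigenvector_centrality <- function(g, tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(g, "weighted_graph"))
  comp <- graph_components(g)
  main <- which(comp == which.max(tabulate(comp)))
  if (length(main) < length(comp)) {
    warning("disconnected graph: eigenvector centrality on largest component, zeros elsewhere")
  }
  w <- g$weights[main, main, drop = FALSE]
  v <- rep(1 / sqrt(length(main)), length(main))
  for (it in seq_len(max_iter)) {
    v2 <- as.vector(w %*% v)
    nv <- sqrt(sum(v2^2))
    if (nv == 0) break
    v2 <- v2 / nv
    if (max(abs(v2 - v)) < tol) { v <- v2; break }
    v <- v2
  }
  out <- numeric(length(comp))
  out[main] <- abs(v)
  if (max(out) > 0) out <- out / max(out)
  stats::setNames(out, g$node_names)
}

# connected component labels from nonzero weights
graph_components <- function(g) {
  adj <- g$weights > 0
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  comp
}
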