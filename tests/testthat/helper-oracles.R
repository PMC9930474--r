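# Independent brute-force oracles used to verify the package's graph
# implementations. These deliberately use different algorithms (triple loops,
# Floyd-Warshall, direct formulas) than the package code paths.

random_test_graph <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- ut[runif(length(ut)) < p]
  w[on] <- runif(length(on), 0.2, 1)
  w <- w + t(w)
  weighted_graph(w)
}

ring_lattice_graph <- function(n, k_each_side = 3, shortcut_frac = 0,
                               seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (d in seq_len(k_each_side)) {
      j <- ((i - 1 + d) %% n) + 1
      w[i, j] <- w[j, i] <- 1
    }
  }
  if (shortcut_frac > 0) {
    ut <- which(upper.tri(w) & w > 0)
    nshort <- round(shortcut_frac * length(ut))
    drop <- sample(ut, nshort)
    for (e in drop) {
      i <- row(w)[e]; j <- col(w)[e]
      w[i, j] <- w[j, i] <- 0
      repeat {
        a <- sample.int(n, 2)
        if (w[a[1], a[2]] == 0 && a[1] != a[2]) {
          w[a[1], a[2]] <- w[a[2], a[1]] <- 1
          break
        }
      }
    }
  }
  weighted_graph(w)
}

bf_strength <- function(w) {
  n <- nrow(w)
  s <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) s[i] <- s[i] + w[i, j]
  s
}

bf_clustering <- function(w) {
  n <- nrow(w)
  wn <- w / max(w)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(wn[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (wn[i, j] > 0 && wn[i, h] > 0 && wn[j, h] > 0) {
        acc <- acc + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
      }
    }
    cc[i] <- acc / (k * (k - 1))
  }
  cc
}

bf_transitivity <- function(w) {
  n <- nrow(w)
  wn <- w / max(w)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    k <- sum(wn[i, ] > 0)
    den <- den + k * (k - 1)
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (wn[i, j] > 0 && wn[i, h] > 0 && wn[j, h] > 0) {
        num <- num + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
      }
    }
  }
  if (den == 0) 0 else num / den
}

bf_distances <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

bf_cpl <- function(w) {
  d <- bf_distances(w)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

bf_efficiency <- function(w) {
  d <- bf_distances(w)
  off <- d[row(d) != col(d)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

bf_assortativity <- function(w) {
  s <- rowSums(w)
  ut <- which(upper.tri(w) & w > 0)
  i <- row(w)[ut]; j <- col(w)[ut]
  cor(c(s[i], s[j]), c(s[j], s[i]))
}

bf_betweenness <- function(w, tol = 1e-9) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- Inf
  d <- bf_distances(w)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sig[s, s] <- 1
    for (t in order(d[s, ])) {
      if (t == s || !is.finite(d[s, t])) next
      pred <- which(is.finite(len[, t]) & is.finite(d[s, ]) &
                      abs(d[s, ] + len[, t] - d[s, t]) <=
                        tol * max(1, d[s, t]))
      sig[s, t] <- sum(sig[s, pred])
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          abs(d[s, v] + d[v, t] - d[s, t]) <= tol * max(1, d[s, t])) {
        bc[v] <- bc[v] + sig[s, v] * sig[v, t] / sig[s, t]
      }
    }
  }
  bc
}

# direct double-loop modularity evaluator
bf_modularity_q <- function(w, aff, gamma = 1) {
  n <- nrow(w)
  wtot <- sum(w)
  k <- rowSums(w)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (aff[i] == aff[j]) q <- q + w[i, j] - gamma * k[i] * k[j] / wtot
  }
  unname(q / wtot)
}

two_clique_graph <- function(m = 5) {
  w <- matrix(0, 2 * m, 2 * m)
  w[seq_len(m), seq_len(m)] <- 1
  w[(m + 1):(2 * m), (m + 1):(2 * m)] <- 1
  diag(w) <- 0
  weighted_graph(w)
}
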