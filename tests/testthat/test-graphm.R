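test_that("closed-form node metrics on tiny graphs", {
  tri <- weighted_graph(matrix(1, 3, 3) - diag(3))
  expect_equal(unname(node_strength(tri)), c(2, 2, 2))
  expect_equal(unname(clustering_coefficient(tri)), c(1, 1, 1))
  expect_equal(transitivity(tri), 1)
  # weighted path a-b (0.5), b-c (0.25)
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.25
  pth <- weighted_graph(w)
  expect_equal(unname(node_strength(pth)), c(0.5, 0.75, 0.25))
  # star graph: clustering all 0
  st <- matrix(0, 5, 5); st[1, 2:5] <- st[2:5, 1] <- 1
  star <- weighted_graph(st)
  expect_equal(unname(clustering_coefficient(star)), rep(0, 5))
  expect_lt(assortativity(star), 0)
  # unit 3-node path: CPL = 4/3, middle betweenness = 1
  up <- matrix(0, 3, 3); up[1, 2] <- up[2, 1] <- up[2, 3] <- up[3, 2] <- 1
  upath <- weighted_graph(up)
  expect_equal(char_path_length(upath), 4 / 3)
  expect_equal(unname(betweenness_centrality(upath)), c(0, 1, 0))
  # unit triangle: betweenness 0, eigenvector equal
  expect_equal(unname(betweenness_centrality(tri)), c(0, 0, 0))
  ev <- eigenvector_centrality(tri)
  expect_equal(unname(ev), rep(1, 3), tolerance = 1e-8)
  # two disjoint unit edges: uniform strengths -> 0 with warning
  de <- matrix(0, 4, 4); de[1, 2] <- de[2, 1] <- de[3, 4] <- de[4, 3] <- 1
  expect_warning(a <- assortativity(weighted_graph(de)), "uniform")
  expect_equal(a, 0)
})

test_that("metrics agree with igraph on random weighted graphs", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    g <- random_test_graph(15, p = 0.5, seed = 100 + s)
    ig <- igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(unname(node_strength(g)),
                 igraph::strength(ig), tolerance = 1e-12, ignore_attr = TRUE)
    d <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
    off <- d[row(d) != col(d)]
    expect_equal(char_path_length(g), mean(off[is.finite(off)]),
                 tolerance = 1e-10)
    expect_equal(unname(betweenness_centrality(g)),
                 igraph::betweenness(ig, weights = 1 / igraph::E(ig)$weight),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("louvain finds planted modules and reports a consistent Q", {
  # two 5-cliques: Q exactly 0.5 with 2 modules
  g2 <- two_clique_graph(5)
  p <- modularity_louvain(g2, seed = 3)
  expect_equal(p$n_modules, 2)
  expect_equal(p$Q, 0.5)
  expect_equal(p$Q, modularity_q(g2, p$affiliation))
  # complete graph: trivial partition has Q = 0
  k8 <- weighted_graph(matrix(1, 8, 8) - diag(8))
  expect_equal(modularity_q(k8, rep(1, 8)), 0)
  # planted 4-module synthetic graph: NMI >= 0.9
  cfg <- synth_config(seed = 77, n_nodes = 40, n_timepoints = 400,
                      groups = c(placebo = 1L), sessions = "chronic",
                      module_sizes = rep(10L, 4),
                      within_module_corr = 0.6, between_module_corr = 0.1,
                      drift_amplitude = 0, spike_rate = 0)
  ts <- gen_cohort(cfg)[[1]]
  cm <- correlate(ts)
  g <- density_threshold(as_weighted_graph(cm), 0.2)
  part <- modularity_louvain(g, seed = 5)
  expect_gte(partition_nmi(part$affiliation, rep(1:4, each = 10)), 0.9)
  # determinism
  expect_identical(modularity_louvain(g, seed = 5)$affiliation,
                   part$affiliation)
  expect_error(modularity_louvain(weighted_graph(matrix(0, 3, 3))), "edge")
})

test_that("Q returned by partitions equals the standalone evaluator", {
  for (s in 1:10) {
    g <- random_test_graph(12, p = 0.5, seed = 300 + s)
    if (n_edges(g) == 0) next
    p <- modularity_louvain(g, seed = s)
    expect_equal(p$Q, modularity_q(g, p$affiliation), tolerance = 1e-12)
    expect_equal(p$Q, bf_modularity_q(g$weights, p$affiliation),
                 tolerance = 1e-12)
    expect_true(p$Q >= -1 && p$Q <= 1)
    expect_identical(sort(unique(unname(p$affiliation))),
                     seq_len(p$n_modules))
  }
})

test_that("consensus partition behaves like its runs", {
  g2 <- two_clique_graph(4)
  cons <- consensus_partition(g2, n_iter = 25, seed = 2)
  single <- modularity_louvain(g2, seed = child_seed(2, 1))
  expect_equal(cons$Q, 0.5)
  expect_equal(cons$n_modules, 2)
  expect_equal(partition_nmi(cons$affiliation, single$affiliation), 1)
  # n_iter = 1 equals a single run
  one <- consensus_partition(g2, n_iter = 1, seed = 9)
  expect_identical(unname(one$affiliation),
                   unname(modularity_louvain(g2, seed = child_seed(9, 1))$affiliation))
  # consensus Q within the envelope of its runs
  gr <- random_test_graph(20, p = 0.3, seed = 4)
  cons2 <- consensus_partition(gr, n_iter = 50, seed = 3)
  expect_gte(cons2$Q, min(cons2$all_Q) - 1e-12)
  expect_lte(cons2$Q, max(cons2$all_Q) + 1e-12)
  # association-matrix variant agrees on unambiguous structure
  consa <- consensus_partition(g2, n_iter = 25, seed = 2,
                               method = "association")
  expect_equal(partition_nmi(consa$affiliation, cons$affiliation), 1)
})

test_that("rewiring preserves degrees and weights, lowers lattice clustering", {
  lat <- ring_lattice_graph(40, k_each_side = 3, seed = 1)
  cc0 <- mean(clustering_coefficient(lat))
  cc_null <- vapply(1:20, function(s) {
    gn <- rewire_null(lat, swaps_per_edge = 10, seed = s)
    expect_identical(unname(node_degree(gn)), unname(node_degree(lat)))
    expect_equal(sort(gn$weights[upper.tri(gn$weights)]),
                 sort(lat$weights[upper.tri(lat$weights)]))
    mean(clustering_coefficient(gn))
  }, 0)
  expect_lt(mean(cc_null), cc0)
  # determinism
  expect_identical(rewire_null(lat, seed = 7)$weights,
                   rewire_null(lat, seed = 7)$weights)
})

test_that("small-world index separates lattices from random graphs", {
  # null ensemble equal to the graph itself gives SWI = 1 by construction
  g <- random_test_graph(30, p = 0.5, seed = 2)
  cc <- mean(clustering_coefficient(g))
  cpl <- char_path_length(g)
  expect_equal((cc / cc) / (cpl / cpl), 1)
  # lattice with shortcuts is small-world
  ws <- ring_lattice_graph(60, k_each_side = 3, shortcut_frac = 0.05,
                           seed = 3)
  expect_gt(small_world_index(ws, n_null = 5, seed = 11), 1)
})

test_that("metric sweep AUCs follow the trapezoid rule", {
  dens <- seq(0.02, 0.40, by = 0.02)
  # constant curve: AUC = 0.38 * value
  expect_equal(trapz_auc(dens, rep(3, length(dens))), 0.38 * 3)
  # linear curve: closed-form trapezoid
  expect_equal(trapz_auc(dens, 2 * dens),
               2 * (0.40^2 - 0.02^2) / 2, tolerance = 1e-12)
  # random matrix: AUC matches a fine-grid independent integration of the
  # stored curve
  set.seed(9)
  cm <- correlate(roi_ts(matrix(rnorm(14 * 120), 14, 120)))
  sw <- metric_sweep(cm, q_iter = 2, seed = 4)
  for (mt in c("strength", "efficiency", "clustering")) {
    y <- sw$values[[mt]]
    manual <- sum((y[-1] + y[-length(y)]) / 2 * diff(dens))
    expect_equal(unname(sw$auc[[mt]]), manual, tolerance = 1e-9)
  }
  # strength curve is non-decreasing in density
  expect_true(all(diff(sw$values$strength) >= -1e-12))
  expect_error(metric_sweep(cm, densities = c(0.2, 0.1)), "densities")
})

test_that("node metrics at 16% density are consistent with the graph", {
  set.seed(30)
  cm <- correlate(roi_ts(matrix(rnorm(20 * 150), 20, 150)))
  nm <- node_metrics_at(cm, density = 0.16)
  g <- density_threshold(as_weighted_graph(cm), 0.16)
  expect_equal(nm$strength, unname(node_strength(g)))
  expect_equal(nm$degree, unname(node_degree(g)))
  expect_equal(nm$betweenness, unname(betweenness_centrality(g)))
  expect_equal(attr(nm, "evaluated_at_density"), 0.16)
  expect_true(all(nm$clustering >= 0 & nm$clustering <= 1))
})
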