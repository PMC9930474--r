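test_that("ROI volumes are voxel count times unit volume, conserving totals", {
  spec <- atlas_spec(grid_shape = c(10L, 10L, 10L),
                     voxel_dims = c(0.2, 0.2, 0.5),
                     label_voxel_counts = c(`1` = 100L, `2` = 40L, `3` = 60L))
  at <- gen_atlas(spec, seed = 8)
  vols <- roi_volumes(at$image, at$voxel_dims, at$name_table)
  expect_equal(vols$volume_mm3[vols$label == 1], 100 * 0.02)
  expect_equal(sum(vols$volume_mm3), attr(vols, "total_volume_mm3"))
  # absent label: volume 0 with warning
  nt <- rbind(at$name_table, data.frame(label = 9L, roi = "ghost"))
  expect_warning(v2 <- roi_volumes(at$image, at$voxel_dims, nt), "ghost")
  expect_equal(v2$volume_mm3[v2$label == 9], 0)
})

test_that("volume normalization makes per-subject fractions sum to 1", {
  cfg <- synth_config(seed = 3, groups = c(placebo = 3L, THC = 3L))
  tab <- gen_measure_table(cfg, seed = 6, measure = "volume_mm3",
                           rois = default_roi_names(25L))
  out <- normalize_volumes(tab)
  fr <- out[out$measure == "volume_fraction", ]
  sums <- tapply(fr$value, interaction(fr$subject_id, fr$session, drop = TRUE),
                 sum)
  expect_equal(unname(as.numeric(sums)), rep(1, length(sums)),
               tolerance = 1e-12)
  expect_true(all(fr$value >= 0 & fr$value <= 1))
  # single-ROI brain -> fraction 1
  one <- data.frame(subject_id = "s", group = "g", session = "x",
                    roi = "only", measure = "volume_mm3", value = 5)
  expect_equal(normalize_volumes(one)$value[2], 1)
})

test_that("percent pairs always split 100", {
  expect_equal(percent_pair(3, 1), list(pa = 75, pb = 25))
  expect_equal(percent_pair(2, 2), list(pa = 50, pb = 50))
  set.seed(4)
  a <- runif(50); b <- runif(50)
  pp <- percent_pair(a, b)
  expect_equal(pp$pa + pp$pb, rep(100, 50))
  expect_error(percent_pair(0, 0), "undefined")
})

test_that("paired t matches the textbook formula", {
  set.seed(13)
  x <- rnorm(12); y <- x + rnorm(12, 0.3)
  got <- paired_t(x, y)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  p_manual <- 2 * pt(-abs(t_manual), length(d) - 1)
  expect_equal(got$t, t_manual, tolerance = 1e-10)
  expect_equal(got$p, p_manual, tolerance = 1e-10)
  expect_equal(got$mean_difference, mean(d))
  # x = y -> t = 0, p = 1; constant nonzero differences are degenerate
  expect_equal(paired_t(x, x), list(t = 0, p = 1, mean_difference = 0))
  expect_error(paired_t(x, x + 1), "variance")
})

test_that("Kruskal-Wallis H matches hand-ranked computation", {
  groups <- list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22))
  got <- kruskal_wallis(groups)
  # ranks 1..9, rank sums 6/15/24 -> H = 12/(9*10) * sum(R^2/3) - 3*10 = 7.2
  expect_equal(got$H, 7.2, tolerance = 1e-10)
  expect_equal(got$p, pchisq(7.2, df = 2, lower.tail = FALSE),
               tolerance = 1e-10)
  # permutation invariance of group input order
  expect_equal(kruskal_wallis(rev(groups))$H, got$H)
  # identical groups -> H = 0, p = 1
  expect_equal(kruskal_wallis(list(rep(2, 3), rep(2, 4))), list(H = 0, p = 1))
})

test_that("Mann-Whitney exact p matches exhaustive enumeration", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(4.3, 6.2, 7.7, 8.1)
  got <- mann_whitney(x, y)
  # enumerate all C(8,4) assignments of ranks to the x group
  vals <- c(x, y)
  rks <- rank(vals)
  n1 <- length(x)
  combos <- combn(length(vals), n1)
  u_all <- apply(combos, 2, function(ix) sum(rks[ix]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(rks[1:n1]) - n1 * (n1 + 1) / 2
  p_exact <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  expect_equal(got$U, u_obs)
  expect_equal(got$p, p_exact, tolerance = 1e-10)
  # x entirely below y -> U = 0
  expect_equal(mann_whitney(c(1, 2), c(3, 4, 5))$U, 0)
  # identical multisets -> U = n1 n2 / 2
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$U, 4.5)
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  g <- list(c(4, 5, 6, 5, 5), c(7, 8, 9, 8, 8), c(4, 4, 5, 5, 4))
  got <- one_way_anova(g)
  vals <- unlist(g)
  gm <- mean(vals)
  ss_b <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, 0))
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  ms_w <- ss_w / (length(vals) - 3)
  f_manual <- (ss_b / 2) / ms_w
  expect_equal(got$F, f_manual, tolerance = 1e-10)
  expect_equal(got$omega_squared,
               (ss_b - 2 * ms_w) / (ss_b + ss_w + ms_w), tolerance = 1e-10)
  # two groups: F equals squared two-sample t (pooled variance)
  a <- c(1, 2, 3, 4); b <- c(2, 4, 5, 7)
  f2 <- one_way_anova(list(a, b))$F
  t2 <- t.test(a, b, var.equal = TRUE)$statistic^2
  expect_equal(f2, unname(t2), tolerance = 1e-10)
  # null data: omega squared is near zero / negative on average
  set.seed(77)
  om <- replicate(200, one_way_anova(list(rnorm(5), rnorm(5), rnorm(5)))$omega_squared)
  expect_lt(abs(mean(om)), 0.05)
})

test_that("two-way ANOVA recovers a pure main effect and matches lm", {
  set.seed(19)
  a <- rep(c("x", "y"), each = 12)
  b <- rep(rep(c("u", "v", "w"), each = 4), 2)
  y <- ifelse(a == "x", 0, 3) + rnorm(24, sd = 0.5)
  tab <- two_way_anova(y, a, b)
  fa <- tab$F[tab$effect == "A"]
  fb <- tab$F[tab$effect == "B"]
  fi <- tab$F[tab$effect == "A x B"]
  expect_gt(fa, 30)
  expect_lt(fb, 5)
  expect_lt(fi, 5)
  # balanced design: Type-II SS equal the classical sequential decomposition
  fit <- lm(y ~ factor(a) * factor(b))
  cls <- anova(fit)
  expect_equal(tab$sum_sq[tab$effect == "A"], cls$`Sum Sq`[1],
               tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$effect == "B"], cls$`Sum Sq`[2],
               tolerance = 1e-10)
  # all-equal data -> all F = 0
  tab0 <- two_way_anova(rep(1, 24), a, b)
  expect_true(all(tab0$F == 0))
  # empty cell: additive fallback with warning
  keep <- !(a == "y" & b == "w")
  expect_warning(two_way_anova(y[keep], a[keep], b[keep]), "empty cell")
})

test_that("investigation-ratio t-test matches the one-sample formula", {
  set.seed(23)
  ir <- 0.5 + rnorm(10, 0.08, 0.1)
  got <- ir_ttest(ir)
  t_manual <- (mean(ir) - 0.5) / (sd(ir) / sqrt(10))
  expect_equal(got$t, t_manual, tolerance = 1e-10)
  expect_equal(got$p, 2 * pt(-abs(t_manual), 9), tolerance = 1e-10)
  # exactly symmetric around 0.5 -> t = 0
  expect_equal(ir_ttest(c(0.4, 0.6, 0.45, 0.55))$t, 0)
  expect_error(ir_ttest(rep(0.5, 5)), "variance")
  expect_error(ir_ttest(0.7), "insufficient")
})

test_that("rank-based FDR filter reproduces critical values and order-invariance", {
  expect_equal(fdr_critical(139, 139, q = 0.2), 0.2) # i = V -> exactly q
  set.seed(31)
  p <- runif(30)
  a <- fdr_filter(p, V = 139)
  perm <- sample(30)
  b <- fdr_filter(p[perm], V = 139)
  expect_equal(b$passes, a$passes[perm])
  expect_equal(b$critical, a$critical[perm])
  expect_equal(a$critical, a$rank * 0.2 / 139)
  expect_error(fdr_filter(c(0.5, 1.2)), "pvals")
  expect_error(fdr_critical(140, 139), "rank")
})

test_that("FDR filter is calibrated under a global null", {
  set.seed(55)
  nsim <- 1000
  any_pass <- vapply(seq_len(nsim), function(i) {
    p <- runif(139)
    any(fdr_filter(p, V = 139, q = 0.2)$passes)
  }, TRUE)
  # under the global null the chance of any discovery is bounded by q = 0.2
  expect_lt(mean(any_pass), 0.2 + 3 * sqrt(0.2 * 0.8 / nsim))
})

test_that("two-stage step-up FDR matches a literal reference implementation", {
  ref_two_stage <- function(p, q) {
    m <- length(p)
    qp <- q / (1 + q)
    bh <- function(p, level) {
      o <- order(p)
      k <- which(p[o] <= seq_len(m) / m * level)
      rej <- logical(m)
      if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
      rej
    }
    r1 <- sum(bh(p, qp))
    if (r1 == 0) return(logical(m))
    if (r1 == m) return(rep(TRUE, m))
    bh(p, qp * m / (m - r1))
  }
  set.seed(61)
  for (i in 1:20) {
    p <- c(runif(15), runif(5, 0, 0.01))[sample(20)]
    got <- fdr_two_stage(p, q = 0.05)
    expect_identical(got, ref_two_stage(p, 0.05))
    # monotone in p
    expect_true(max(p[got], -Inf) <= min(p[!got], Inf) ||
                  all(got) || !any(got))
  }
  expect_identical(fdr_two_stage(rep(1, 10)), rep(FALSE, 10))
  expect_identical(fdr_two_stage(rep(1e-6, 10)), rep(TRUE, 10))
})

test_that("volume -> normalize -> percent chain recovers planted direction", {
  hits <- 0
  nseeds <- 100
  for (s in seq_len(nseeds)) {
    cfg <- synth_config(seed = s, groups = c(placebo = 7L, THC = 7L),
                        sessions = "chronic")
    tab <- gen_measure_table(cfg, seed = s, measure = "volume_mm3",
                             rois = default_roi_names(30L))
    tab <- normalize_volumes(tab)
    fr <- tab[tab$measure == "volume_fraction" &
                tab$roi %in% da_system_rois(), ]
    pl <- tapply(fr$value[fr$group == "placebo"],
                 fr$roi[fr$group == "placebo"], mean)
    th <- tapply(fr$value[fr$group == "THC"],
                 fr$roi[fr$group == "THC"], mean)
    pp <- percent_pair(pl, th[names(pl)])
    if (mean(pp$pa - pp$pb) > 0) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("per-ROI group statistics tables annotate FDR and ordering", {
  cfg <- synth_config(seed = 8, groups = c(placebo = 7L, CBD = 7L, THC = 7L),
                      sessions = "washout")
  tab <- gen_measure_table(cfg, seed = 12, measure = "FA",
                           rois = default_roi_names(40L),
                           effect_spec = measure_effect_spec(
                             rois = da_system_rois(),
                             shifts = list(THC = c(washout = -0.25))))
  st <- roi_group_stats(tab, measure = "FA", session = "washout",
                        test = "kruskal", groups = c("placebo", "CBD", "THC"))
  expect_equal(nrow(st), 40)
  expect_true(!is.unsorted(st$p))
  expect_equal(st$fdr_critical, st$fdr_rank * 0.2 / 40)
  # the strongly shifted DA regions dominate the top ranks
  expect_gte(sum(st$roi[1:7] %in% da_system_rois()), 5)
  expect_true(all(st$passes_fdr[st$p <= st$fdr_critical]))
  expect_true(grepl(">", st$pattern[1]))
})
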