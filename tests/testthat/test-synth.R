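test_that("cohort generation is deterministic and respects geometry", {
  cfg <- synth_config(seed = 42, n_nodes = 24, n_timepoints = 60,
                      groups = c(placebo = 2L, THC = 2L),
                      module_sizes = c(12L, 12L))
  a <- gen_cohort(cfg)
  b <- gen_cohort(cfg)
  expect_identical(a, b)
  expect_length(a, 2 * 2 * 2) # subjects x groups x sessions
  expect_true(all(vapply(a, function(x) nrow(x$data) == 24, TRUE)))
  expect_true(all(vapply(a, function(x) ncol(x$data) == 60, TRUE)))
  labs <- vapply(a, function(x) paste(x$group, x$session), "")
  expect_setequal(unique(labs), c("placebo chronic", "placebo washout",
                                  "THC chronic", "THC washout"))
})

test_that("planted within-module correlation is recovered empirically", {
  cfg <- synth_config(seed = 7, n_nodes = 20, n_timepoints = 1000,
                      groups = c(placebo = 1L), sessions = "chronic",
                      module_sizes = rep(5L, 4),
                      within_module_corr = 0.6, between_module_corr = 0,
                      drift_amplitude = 0, spike_rate = 0)
  ts <- gen_cohort(cfg)[[1]]
  r <- cor(t(ts$data))
  mem <- rep(1:4, each = 5)
  same <- outer(mem, mem, "==") & upper.tri(r)
  diff <- !outer(mem, mem, "==") & upper.tri(r)
  # sampling error of r at T=1000 is ~ (1-r^2)/sqrt(T) ~ 0.02; allow 4 sigma
  expect_equal(mean(r[same]), 0.6, tolerance = 0.1)
  expect_lt(abs(mean(r[diff])), 0.08)
})

test_that("invalid configs name the offending field", {
  expect_error(synth_config(module_sizes = c(10L, 10L)), "module_sizes")
  expect_error(synth_config(within_module_corr = 1.2), "within_module_corr")
  expect_error(synth_config(between_module_corr = 0.5,
                            within_module_corr = 0.3),
               "between_module_corr")
  expect_error(synth_config(n_timepoints = 2), "n_timepoints")
  expect_error(synth_config(effect_multipliers = list(CBD = c(washout = -1))),
               "effect_multipliers")
})

test_that("synthetic atlases place exactly the requested voxel counts", {
  spec <- atlas_spec(grid_shape = c(20L, 20L, 10L),
                     voxel_dims = c(0.2, 0.2, 0.5),
                     label_voxel_counts = c(`1` = 50L, `5` = 100L, `7` = 30L))
  at <- gen_atlas(spec, seed = 3)
  counts <- table(at$image[at$image > 0])
  expect_identical(as.integer(counts[c("1", "5", "7")]), c(50L, 100L, 30L))
  expect_equal(sum(at$image > 0), 180)
  # label 5: 100 voxels x 0.02 mm^3 = 2 mm^3 downstream
  vols <- roi_volumes(at$image, at$voxel_dims, at$name_table)
  expect_equal(vols$volume_mm3[vols$label == 5], 2.0)
  # empty map -> all-zero image
  at0 <- gen_atlas(atlas_spec(grid_shape = c(4L, 4L, 4L)), seed = 1)
  expect_true(all(at0$image == 0))
  # over-capacity errors
  expect_error(atlas_spec(grid_shape = c(2L, 2L, 2L),
                          label_voxel_counts = c(`1` = 9L)), "capacity")
})

test_that("measure tables plant the requested shifts", {
  cfg <- synth_config(seed = 11, groups = c(placebo = 4L, THC = 4L))
  rois <- default_roi_names(20L)
  # zero noise: THC chronic DA-system mean is exactly 87.83% of baseline
  tab <- gen_measure_table(cfg, seed = 5, measure = "volume_mm3",
                           rois = rois, noise_sd = 1e-12)
  base <- gen_measure_table(cfg, seed = 5, measure = "volume_mm3",
                            rois = rois, noise_sd = 1e-12,
                            effect_spec = measure_effect_spec(shifts = list()))
  for (rr in da_system_rois()) {
    b <- base$value[base$roi == rr & base$group == "THC" &
                      base$session == "chronic"][1]
    v <- tab$value[tab$roi == rr & tab$group == "THC" &
                     tab$session == "chronic"][1]
    expect_equal(v / b, 1 - 0.1217, tolerance = 1e-6)
    vw <- tab$value[tab$roi == rr & tab$group == "THC" &
                      tab$session == "washout"][1]
    bw <- base$value[base$roi == rr & base$group == "THC" &
                       base$session == "washout"][1]
    expect_equal(vw / bw, 1 + 0.1024, tolerance = 1e-6)
  }
  # placebo rows carry no shift
  expect_equal(tab$value[tab$group == "placebo"],
               base$value[base$group == "placebo"])
  # unknown ROI in the effect spec errors
  expect_error(
    gen_measure_table(cfg, seed = 1, rois = c("a", "b", "c"),
                      effect_spec = measure_effect_spec(rois = "nope")),
    "unknown ROI")
})

test_that("noisy group means recover the planted shift within Monte-Carlo error", {
  cfg <- synth_config(seed = 2, groups = c(placebo = 4L, THC = 4L),
                      sessions = "chronic")
  rois <- default_roi_names(10L)
  reps <- 100
  means <- vapply(seq_len(reps), function(i) {
    tab <- gen_measure_table(cfg, seed = i, measure = "volume_mm3",
                             rois = rois)
    mean(tab$value[tab$roi == "accumbens core" & tab$group == "THC"])
  }, 0)
  base <- gen_measure_table(cfg, seed = 1, measure = "volume_mm3",
                            rois = rois, noise_sd = 1e-12,
                            effect_spec = measure_effect_spec(shifts = list()))
  b <- base$value[base$roi == "accumbens core"][1]
  se <- sd(means) / sqrt(reps)
  expect_lt(abs(mean(means) - b * (1 - 0.1217)), 2 * se + 1e-8)
})

test_that("FA tables stay in range and use reference baselines", {
  cfg <- synth_config(seed = 4, groups = c(placebo = 6L), sessions = "washout")
  tab <- gen_measure_table(cfg, seed = 9, measure = "FA",
                           rois = default_roi_names(139L),
                           effect_spec = measure_effect_spec(shifts = list()))
  expect_true(all(tab$value > 0 & tab$value <= 1))
  ic <- tab$value[tab$roi == "internal capsule"]
  expect_equal(mean(ic), 0.54, tolerance = 0.06)
})
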