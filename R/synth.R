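#' Configuration for the synthetic cohort generator
#'
#' Describes the study geometry being emulated: three treatment groups imaged
#' at two sessions (immediately after chronic exposure, and after a two-week
#' washout), ~8 subjects per group, 148-node ROI parcellations with 200-point
#' BOLD time series. Network structure is planted as block (modular)
#' correlation: `within_module_corr` inside modules, `between_module_corr`
#' elsewhere, and per (group, session) multipliers on the within-module level
#' so that treatment effects on network segregation are recoverable
#' downstream. By default the CBD/washout cell carries an elevated multiplier
#' (increased modularity after CBD washout).
#'
#' @param seed root seed; all cohort randomness derives from it.
#' @param n_nodes number of ROIs (148 for the bilateral graph parcellation;
#'   set 139 for the atlas parcellation).
#' @param n_timepoints frames per series (default 200).
#' @param sample_interval seconds between frames.
#' @param groups named integer vector: subjects per treatment group.
#' @param sessions character vector of session names.
#' @param module_sizes integer module sizes summing to `n_nodes` (default:
#'   four equal modules).
#' @param within_module_corr baseline within-module correlation in (0, 1).
#' @param between_module_corr between-module correlation in `[0, within)`.
#' @param effect_multipliers named list `group -> named numeric by session`,
#'   each a positive multiplier applied to `within_module_corr`.
#' @param drift_amplitude per-node linear drift amplitude (signal units over
#'   the whole scan; slopes drawn uniformly in +/- this value).
#' @param spike_rate expected Poisson count of motion-spike frames per series.
#' @param noise_sd marginal signal standard deviation (signal units).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_nodes = 148L,
                         n_timepoints = 200L,
                         sample_interval = 1,
                         groups = c(placebo = 8L, CBD = 8L, THC = 8L),
                         sessions = c("chronic", "washout"),
                         module_sizes = NULL,
                         within_module_corr = 0.30,
                         between_module_corr = 0.05,
                         effect_multipliers = list(CBD = c(washout = 1.4)),
                         drift_amplitude = 0.3,
                         spike_rate = 3,
                         noise_sd = 1) {
  if (is.null(module_sizes)) {
    k <- 4L
    base <- n_nodes %/% k
    module_sizes <- rep(base, k)
    module_sizes[k] <- n_nodes - base * (k - 1L)
  }
  cfg <- structure(
    list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
         n_timepoints = as.integer(n_timepoints),
         sample_interval = sample_interval, groups = groups,
         sessions = sessions, module_sizes = as.integer(module_sizes),
         within_module_corr = within_module_corr,
         between_module_corr = between_module_corr,
         effect_multipliers = effect_multipliers,
         drift_amplitude = drift_amplitude, spike_rate = spike_rate,
         noise_sd = noise_sd),
    class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_timepoints < 3) stop_field("n_timepoints", "must be >= 3")
  if (sum(cfg$module_sizes) != cfg$n_nodes) {
    stop_field("module_sizes", "must sum to n_nodes")
  }
  if (any(cfg$module_sizes < 1)) stop_field("module_sizes", "must be positive")
  w <- cfg$within_module_corr
  b <- cfg$between_module_corr
  if (!(w > 0 && w < 1)) stop_field("within_module_corr", "must be in (0,1)")
  if (!(b >= 0 && b < w)) {
    stop_field("between_module_corr", "must be in [0, within_module_corr)")
  }
  if (is.null(names(cfg$groups)) || any(!nzchar(names(cfg$groups)))) {
    stop_field("groups", "must be a named vector of subject counts")
  }
  if (any(cfg$groups < 1)) stop_field("groups", "subject counts must be >= 1")
  for (g in names(cfg$effect_multipliers)) {
    m <- cfg$effect_multipliers[[g]]
    if (any(m <= 0)) stop_field("effect_multipliers", "must all be > 0")
    if (any(w * m >= 1)) {
      stop_field("effect_multipliers",
                 "within_module_corr x multiplier must stay below 1")
    }
  }
  if (cfg$noise_sd <= 0) stop_field("noise_sd", "must be > 0")
  if (cfg$spike_rate < 0) stop_field("spike_rate", "must be >= 0")
  if (cfg$drift_amplitude < 0) stop_field("drift_amplitude", "must be >= 0")
  invisible(cfg)
}

# planted module membership implied by module_sizes
planted_modules <- function(cfg) {
  rep(seq_along(cfg$module_sizes), cfg$module_sizes)
}

multiplier_for <- function(cfg, group, session) {
  m <- cfg$effect_multipliers[[group]]
  if (is.null(m) || is.na(m[session]) || !session %in% names(m)) return(1)
  unname(m[session])
}

# block-structured correlation matrix
block_correlation <- function(module_sizes, within, between) {
  mem <- rep(seq_along(module_sizes), module_sizes)
  r <- matrix(between, sum(module_sizes), sum(module_sizes))
  same <- outer(mem, mem, "==")
  r[same] <- within
  diag(r) <- 1
  r
}

#' Generate a synthetic cohort of ROI time series
#'
#' One `roi_ts` per subject x session. Each series is a multivariate normal
#' draw under the block correlation implied by the config (the group/session
#' multiplier scaling the within-module level), plus per-node linear drift and
#' Poisson-placed motion-spike frames. Planted spike frames are recorded in
#' the censoring metadata. Deterministic given `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list of `roi_ts`, with attributes `planted_modules` (integer
#'   membership) and `config`.
#' @export
gen_cohort <- function(config) {
  validate_synth_config(config)
  n <- config$n_nodes
  tt <- config$n_timepoints
  out <- list()
  counter <- 0L
  for (g in names(config$groups)) {
    for (s in config$sessions) {
      w_eff <- config$within_module_corr * multiplier_for(config, g, s)
      r <- block_correlation(config$module_sizes, w_eff,
                             config$between_module_corr)
      u <- chol(r)
      for (i in seq_len(config$groups[[g]])) {
        counter <- counter + 1L
        sk <- child_seed(config$seed, counter)
        out[[length(out) + 1L]] <- with_rng(sk, {
          z <- matrix(rnorm(n * tt), n, tt)
          x <- crossprod(u, z) * config$noise_sd
          slopes <- runif(n, -1, 1) * config$drift_amplitude
          x <- x + outer(slopes, seq(0, 1, length.out = tt) - 0.5)
          n_spk <- min(rpois(1, config$spike_rate), tt %/% 4L)
          spikes <- integer()
          if (n_spk > 0) {
            spikes <- sort(sample.int(tt, n_spk))
            for (f in spikes) {
              x[, f] <- sample(c(-1, 1), n, replace = TRUE) *
                runif(n, 5, 10) * config$noise_sd
            }
          }
          roi_ts(x, node_names = sprintf("ROI_%03d", seq_len(n)),
                 subject_id = sprintf("%s_%02d", g, i), group = g,
                 session = s, sample_interval = config$sample_interval,
                 censored_frames = spikes)
        })
      }
    }
  }
  attr(out, "planted_modules") <- planted_modules(config)
  attr(out, "config") <- config
  out
}

#' Atlas specification for synthetic label images
#'
#' @param grid_shape 3 positive integers (image dimensions in voxels).
#' @param voxel_dims voxel edge lengths in mm per axis.
#' @param label_voxel_counts named integer vector: label id -> voxel count.
#' @param label_names named character: label id -> ROI name (defaults to
#'   `"ROI_<id>"`).
#' @return object of class `atlas_spec`.
#' @export
atlas_spec <- function(grid_shape = c(64L, 64L, 32L),
                       voxel_dims = c(0.1, 0.1, 0.2),
                       label_voxel_counts = integer(),
                       label_names = NULL) {
  ids <- as.integer(names(label_voxel_counts))
  if (length(label_voxel_counts) && (anyNA(ids) || any(ids < 1))) {
    stop_field("label_voxel_counts", "label ids must be positive integers")
  }
  if (any(voxel_dims <= 0)) stop_field("voxel_dims", "must all be > 0")
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    stop_field("grid_shape", "need 3 positive integers")
  }
  if (sum(label_voxel_counts) > prod(grid_shape)) {
    stop_field("label_voxel_counts", "counts exceed grid capacity")
  }
  if (is.null(label_names)) {
    label_names <- stats::setNames(sprintf("ROI_%03d", ids), names(label_voxel_counts))
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_dims = voxel_dims,
                 label_voxel_counts = label_voxel_counts,
                 label_names = label_names),
            class = "atlas_spec")
}

#' Generate a synthetic integer atlas label image
#'
#' Places exactly the requested number of voxels per label at seed-randomized
#' positions, background 0. The label image plus name table feed the
#' volumetry stage ([roi_volumes()]).
#'
#' @param spec an [atlas_spec()].
#' @param seed integer seed for voxel placement.
#' @return list with `image` (3D integer array), `voxel_dims`, and
#'   `name_table` (data.frame: label, roi).
#' @export
gen_atlas <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "atlas_spec"))
  total <- prod(spec$grid_shape)
  counts <- spec$label_voxel_counts
  if (sum(counts) > total) {
    stop_field("label_voxel_counts", "counts exceed grid capacity")
  }
  img <- array(0L, dim = spec$grid_shape)
  if (length(counts)) {
    pos <- with_rng(seed, sample.int(total, sum(counts)))
    at <- 0L
    for (k in seq_along(counts)) {
      id <- as.integer(names(counts)[k])
      take <- counts[[k]]
      if (take > 0) img[pos[(at + 1L):(at + take)]] <- id
      at <- at + take
    }
  }
  name_table <- data.frame(
    label = as.integer(names(counts)),
    roi = unname(spec$label_names[names(counts)]),
    stringsAsFactors = FALSE)
  list(image = img, voxel_dims = spec$voxel_dims, name_table = name_table)
}

#' Dopaminergic-subsystem ROI names
#'
#' The dopaminergic regions examined for volumetric change: ventral tegmental
#' area, substantia nigra, caudate/putamen, olfactory tubercle, ventral
#' pallidum, and accumbens core and shell.
#'
#' @return character vector of 7 ROI names.
#' @export
da_system_rois <- function() {
  c("ventral tegmental area", "substantia nigra", "caudate putamen",
    "olfactory tubercle", "ventral pallidum", "accumbens core",
    "accumbens shell")
}

#' Reference FA baselines for synthetic tables
#'
#' Placebo-group fractional anisotropy means and SDs for a set of named
#' regions, used as generator baselines so synthetic FA tables sit in a
#' realistic range; ROIs not listed default to 0.4 +/- 0.05.
#'
#' @return data.frame with columns roi, mean, sd.
#' @export
fa_reference_baselines <- function() {
  data.frame(
    roi = c("zona incerta", "internal capsule", "globus pallidus",
            "stria medullaris", "dorsal raphe", "periaqueductal gray",
            "CA3", "endopiriform n.", "retrosplenial rostral ctx",
            "forceps minor cc", "anterior cingulate n.",
            "ventral thalamic n.", "corpus callosum", "extended amygdala",
            "ventral pallidum", "lateral septal n.", "median raphe n.",
            "medial mammillary n.", "accumbens shell", "accumbens core",
            "flocculus cerebellum", "secondary motor ctx",
            "anterior thalamic n.", "insular rostral ctx",
            "4th cerebellar lobule", "infralimbic ctx",
            "cerebellar nuclear n.", "anterior pretectal n."),
    mean = c(0.48, 0.54, 0.48, 0.40, 0.39, 0.40, 0.41, 0.38, 0.41, 0.45,
             0.38, 0.43, 0.49, 0.48, 0.42, 0.44, 0.46, 0.39, 0.38, 0.41,
             0.48, 0.36, 0.38, 0.39, 0.47, 0.33, 0.43, 0.39),
    sd = c(0.04, 0.03, 0.08, 0.07, 0.06, 0.05, 0.07, 0.05, 0.11, 0.04,
           0.05, 0.04, 0.04, 0.05, 0.04, 0.02, 0.09, 0.08, 0.05, 0.04,
           0.12, 0.09, 0.03, 0.05, 0.09, 0.09, 0.08, 0.07),
    stringsAsFactors = FALSE)
}

#' Default treatment effects for synthetic measure tables
#'
#' The dopaminergic subsystem shrinks ~12.17% under chronic THC and rebounds
#' ~+10.24% after washout, relative to placebo baseline; these are the
#' planted defaults for synthetic volume tables.
#'
#' @param rois ROI names carrying the effect.
#' @param shifts named list: group -> named numeric of relative shifts by
#'   session.
#' @return list with elements `rois` and `shifts`.
#' @export
measure_effect_spec <- function(rois = da_system_rois(),
                                shifts = list(
                                  THC = c(chronic = -0.1217,
                                          washout = 0.1024))) {
  list(rois = rois, shifts = shifts)
}

#' Default ROI name ladder for synthetic tables
#'
#' Dopaminergic-subsystem regions first, then the FA reference regions, then
#' generic `ROI_xxx` fillers up to `n`.
#'
#' @param n number of ROI names (default 139).
#' @return character vector of length `n`.
#' @export
default_roi_names <- function(n = 139L) {
  named <- unique(c(da_system_rois(), fa_reference_baselines()$roi))
  if (n <= length(named)) return(named[seq_len(n)])
  c(named, sprintf("ROI_%03d", seq_len(n - length(named))))
}

#' Generate a synthetic per-subject per-ROI measure table
#'
#' Long-form table of subject x ROI measures (volume, FA, or ADC). Values are
#' drawn as `baseline * (1 + shift) + N(0, sd)`, where the shift is taken
#' from `effect_spec` for (group, session) cells naming the ROI and zero
#' otherwise. FA baselines use [fa_reference_baselines()] where the ROI is
#' listed, else 0.4 +/- 0.05; ADC baselines default to 1.8 +/- 0.25; volume
#' baselines are a fixed log-spaced ladder (2-30 mm^3) so per-ROI scales
#' differ as real parcellations do.
#'
#' @param config a [synth_config()] (group/session geometry is reused).
#' @param seed integer seed.
#' @param measure one of "volume_mm3", "FA", "ADC".
#' @param rois ROI names; defaults to 139 regions led by the dopaminergic
#'   subsystem.
#' @param effect_spec a [measure_effect_spec()] (set `shifts = list()` for a
#'   null table).
#' @param noise_sd scalar or per-ROI named vector of noise SDs; `NULL` picks
#'   the measure-specific defaults above.
#' @return long data.frame: subject_id, group, session, roi, measure, value.
#' @export
gen_measure_table <- function(config, seed = config$seed,
                              measure = c("volume_mm3", "FA", "ADC"),
                              rois = default_roi_names(139L),
                              effect_spec = measure_effect_spec(),
                              noise_sd = NULL) {
  measure <- match.arg(measure)
  validate_synth_config(config)
  bad <- setdiff(effect_spec$rois, rois)
  if (length(bad)) {
    stop_field("effect_spec", paste("unknown ROI(s):",
                                    paste(bad, collapse = ", ")))
  }
  n_roi <- length(rois)
  ref <- fa_reference_baselines()
  if (measure == "FA") {
    base <- ifelse(rois %in% ref$roi, ref$mean[match(rois, ref$roi)], 0.4)
    sds <- ifelse(rois %in% ref$roi, ref$sd[match(rois, ref$roi)], 0.05)
  } else if (measure == "ADC") {
    base <- rep(1.8, n_roi)
    sds <- rep(0.25, n_roi)
  } else {
    base <- exp(seq(log(2), log(30), length.out = n_roi))
    sds <- 0.05 * base
  }
  names(base) <- names(sds) <- rois
  if (!is.null(noise_sd)) {
    sds[] <- if (length(noise_sd) == 1) noise_sd else noise_sd[rois]
  }

  rows <- list()
  counter <- 0L
  for (g in names(config$groups)) {
    gs <- effect_spec$shifts[[g]]
    for (s in config$sessions) {
      shift <- rep(0, n_roi)
      if (!is.null(gs) && s %in% names(gs)) {
        shift[rois %in% effect_spec$rois] <- gs[[s]]
      }
      for (i in seq_len(config$groups[[g]])) {
        counter <- counter + 1L
        val <- with_rng(child_seed(seed, 100000L + counter),
                        base * (1 + shift) + rnorm(n_roi, 0, sds))
        if (measure %in% c("FA", "volume_mm3")) val <- pmax(val, 1e-6)
        if (measure == "FA") val <- pmin(val, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("%s_%02d", g, i), group = g, session = s,
          roi = rois, measure = measure, value = val,
          stringsAsFactors = FALSE, row.names = NULL)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
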