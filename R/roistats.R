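#' ROI volumes from an atlas label image
#'
#' Volume of each labelled region = voxel count x unit voxel volume (mm^3).
#' Also reports the total labelled ("brain") volume. Labels listed in the
#' name table but absent from the image get volume 0 with a warning.
#'
#' @param label_image 3D integer array of atlas labels (0 = background).
#' @param voxel_dims voxel edge lengths in mm (length 3).
#' @param name_table data.frame with columns `label`, `roi`.
#' @return data.frame (roi, label, n_voxels, volume_mm3) with attribute
#'   `total_volume_mm3`.
#' @export
roi_volumes <- function(label_image, voxel_dims, name_table) {
  if (any(voxel_dims <= 0)) stop_field("voxel_dims", "must all be > 0")
  lab <- as.integer(label_image)
  if (anyNA(lab)) stop_field("label_image", "labels must be integers")
  unit <- prod(voxel_dims)
  counts <- table(lab[lab > 0])
  n_vox <- as.integer(counts[as.character(name_table$label)])
  n_vox[is.na(n_vox)] <- 0L
  if (any(n_vox == 0)) {
    warning(sprintf("label(s) absent from image: %s",
                    paste(name_table$roi[n_vox == 0], collapse = ", ")))
  }
  out <- data.frame(roi = name_table$roi, label = name_table$label,
                    n_voxels = n_vox, volume_mm3 = n_vox * unit,
                    stringsAsFactors = FALSE)
  attr(out, "total_volume_mm3") <- sum(lab > 0) * unit
  out
}

#' Normalize ROI volumes by total brain volume
#'
#' Adds `volume_fraction` rows to a long measure table: per subject-session,
#' each ROI's volume divided by that subject's total (summed) volume, so
#' fractions sum to 1.
#'
#' @param table long measure table with `measure == "volume_mm3"` rows.
#' @return the table with `volume_fraction` rows appended.
#' @export
normalize_volumes <- function(table) {
  vol <- table[table$measure == "volume_mm3", , drop = FALSE]
  if (!nrow(vol)) stop_field("table", "no volume_mm3 rows")
  key <- interaction(vol$subject_id, vol$session, drop = TRUE)
  totals <- tapply(vol$value, key, sum)
  if (any(totals <= 0)) {
    stop("degenerate subject: nonpositive total volume", call. = FALSE)
  }
  frac <- vol
  frac$measure <- "volume_fraction"
  frac$value <- vol$value / as.numeric(totals[as.character(key)])
  rbind(table, frac)
}

#' Paired percent-of-total decomposition
#'
#' Expresses a matched pair of volumes as complementary percentages:
#' `pa = 100 a / (a + b)`, `pb = 100 b / (a + b)`; the two always sum to 100.
#' Used to compare the same region across two conditions on a common scale.
#'
#' @param a,b nonnegative volumes (vectorized); `a + b` must be positive.
#' @return list with numeric vectors `pa`, `pb`.
#' @export
percent_pair <- function(a, b) {
  tot <- a + b
  if (any(tot <= 0)) stop("undefined pair: a + b must be > 0", call. = FALSE)
  list(pa = 100 * a / tot, pb = 100 * b / tot)
}

#' Paired t-test
#'
#' Classical paired t on the differences, two-sided.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list: `t`, `p`, `mean_difference`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (all(d == 0)) return(list(t = 0, p = 1, mean_difference = 0))
  if (sd(d) <= 1e-10 * (abs(mean(d)) + max(abs(x)))) {
    stop("degenerate: zero variance of differences", call. = FALSE)
  }
  ht <- t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_difference = mean(d))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-square reference on k - 1 df. All-identical
#' input returns H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list: `H`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1) return(list(H = 0, p = 1))
  f <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- kruskal.test(values, f)
  list(H = unname(ht$statistic), p = ht$p.value)
}

#' Mann-Whitney U test
#'
#' U computed from rank sums; exact enumeration p for small tie-free samples
#' (n1 + n2 <= 12), tie-corrected normal approximation otherwise.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param exact_max combined size up to which the exact distribution is used.
#' @return list: `U` (for `x`), `p` (two-sided).
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= exact_max) && !has_ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = FALSE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' One-way ANOVA with omega-squared effect size
#'
#' Standard between/within decomposition;
#' `omega^2 = (SS_between - (k-1) MS_within) / (SS_total + MS_within)`,
#' reported unclamped (small-effect samples can give negative values).
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list: `F`, `p`, `omega_squared`, `df` (c(between, within)).
#' @export
one_way_anova <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  values <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups)
  n <- length(values)
  ss_total <- sum((values - mean(values))^2)
  gm <- tapply(values, f, mean)
  ss_between <- sum(lengths(groups) * (gm - mean(values))^2)
  ss_within <- ss_total - ss_between
  df_b <- k - 1
  df_w <- n - k
  ms_w <- ss_within / df_w
  if (ms_w == 0 && ss_between == 0) {
    stop("degenerate: no variance within or between groups", call. = FALSE)
  }
  fstat <- (ss_between / df_b) / ms_w
  p <- stats::pf(fstat, df_b, df_w, lower.tail = FALSE)
  omega <- (ss_between - df_b * ms_w) / (ss_total + ms_w)
  list(F = fstat, p = p, omega_squared = omega, df = c(df_b, df_w))
}

#' Two-way between-subjects ANOVA (Type II)
#'
#' Type-II sums of squares for a possibly unbalanced two-factor layout with
#' interaction. When any cell is empty the interaction is dropped (additive
#' model) with a warning.
#'
#' @param values numeric response vector.
#' @param factorA,factorB factors (coerced) of the same length as `values`.
#' @return data.frame: effect, df, sum_sq, F, p.
#' @export
two_way_anova <- function(values, factorA, factorB) {
  a <- factor(factorA)
  b <- factor(factorB)
  stopifnot(length(values) == length(a), length(values) == length(b))
  full <- table(a, b)
  dat <- data.frame(y = values, A = a, B = b)
  if (stats::var(values) == 0) {
    eff <- c("A", "B", "A x B")
    dfs <- c(nlevels(a) - 1L, nlevels(b) - 1L,
             (nlevels(a) - 1L) * (nlevels(b) - 1L))
    return(data.frame(effect = eff, df = dfs, sum_sq = 0, F = 0, p = 1,
                      stringsAsFactors = FALSE))
  }
  if (any(full == 0)) {
    warning("empty cell(s): fitting additive model without interaction")
    fit <- lm(y ~ A + B, data = dat)
  } else {
    fit <- lm(y ~ A * B, data = dat)
  }
  tab <- car::Anova(fit, type = 2)
  keep <- rownames(tab) != "Residuals"
  out <- data.frame(effect = gsub(":", " x ", rownames(tab)[keep]),
                    df = tab$Df[keep], sum_sq = tab$`Sum Sq`[keep],
                    F = tab$`F value`[keep], p = tab$`Pr(>F)`[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' One-sample t-test of investigation ratios against chance
#'
#' Novel-object investigation ratio (novel time / total object time) compared
#' to the chance level 0.5, two-sided.
#'
#' @param investigation_ratios numeric vector, length >= 2.
#' @return list: `t`, `p`, `mean`.
#' @export
ir_ttest <- function(investigation_ratios) {
  if (length(investigation_ratios) < 2) {
    stop("insufficient data: need at least 2 ratios", call. = FALSE)
  }
  if (sd(investigation_ratios) == 0) {
    stop("degenerate: zero variance of ratios", call. = FALSE)
  }
  ht <- t.test(investigation_ratios, mu = 0.5)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean = mean(investigation_ratios))
}

#' Per-ROI group statistics table
#'
#' Runs a group test per ROI on a long measure table, computes omega-squared
#' (from the one-way decomposition), records the group-mean ordering pattern,
#' and annotates the rank-based FDR filter ([fdr_filter()]) over all V ROIs.
#'
#' @param table long measure table (subject_id, group, session, roi, measure,
#'   value).
#' @param measure which measure to analyze.
#' @param session which session to analyze.
#' @param test `"kruskal"` (default), `"anova"`, or `"mann_whitney"` (exactly
#'   2 groups).
#' @param groups optional subset/order of group labels.
#' @param q,cV FDR filter parameters.
#' @return data.frame, one row per ROI, ordered by p: roi, statistic, p,
#'   omega_squared, group means/SDs, pattern, fdr_rank, fdr_critical,
#'   passes_fdr.
#' @export
roi_group_stats <- function(table, measure, session,
                            test = c("kruskal", "anova", "mann_whitney"),
                            groups = NULL, q = 0.2, cV = 1) {
  test <- match.arg(test)
  sub <- table[table$measure == measure & table$session == session, ,
               drop = FALSE]
  if (!nrow(sub)) stop_field("table", "no rows for that measure/session")
  if (is.null(groups)) groups <- unique(sub$group)
  sub <- sub[sub$group %in% groups, , drop = FALSE]
  rois <- unique(sub$roi)
  rows <- lapply(rois, function(rr) {
    d <- sub[sub$roi == rr, ]
    gl <- lapply(groups, function(g) d$value[d$group == g])
    names(gl) <- groups
    stat <- switch(test,
      kruskal = { r <- kruskal_wallis(gl); c(statistic = r$H, p = r$p) },
      anova = { r <- one_way_anova(gl); c(statistic = r$F, p = r$p) },
      mann_whitney = {
        stopifnot(length(gl) == 2)
        r <- mann_whitney(gl[[1]], gl[[2]])
        c(statistic = r$U, p = r$p)
      })
    om <- tryCatch(one_way_anova(gl)$omega_squared, error = function(e) NA_real_)
    mu <- vapply(gl, mean, 0)
    sdv <- vapply(gl, sd, 0)
    glyphs <- ifelse(diff(mu) < 0, ">", "<")
    pattern <- paste(groups, c(glyphs, ""), collapse = " ")
    out <- data.frame(roi = rr, statistic = unname(stat["statistic"]),
                      p = unname(stat["p"]), omega_squared = om,
                      pattern = trimws(pattern), stringsAsFactors = FALSE)
    for (g in groups) {
      out[[paste0("mean_", g)]] <- mu[[g]]
      out[[paste0("sd_", g)]] <- sdv[[g]]
    }
    out
  })
  res <- do.call(rbind, rows)
  fdr <- fdr_filter(res$p, V = length(rois), q = q, cV = cV)
  res$fdr_rank <- fdr$rank
  res$fdr_critical <- fdr$critical
  res$passes_fdr <- fdr$passes
  res[order(res$p), , drop = FALSE]
}
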