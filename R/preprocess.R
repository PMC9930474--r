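#' Detect motion-spike frames
#'
#' Frame-to-frame displacement proxy: the cross-node mean absolute successive
#' difference d_t = mean_i |x_i(t) - x_i(t-1)| is computed for every frame
#' transition; frame t is scored by the smaller of its two adjacent
#' differences (so an isolated outlier frame is flagged, not its neighbors;
#' boundary frames use their single difference). A frame is flagged when the
#' robust z-score of its score ((s - median) / (1.4826 * MAD)) exceeds
#' `z_cut`.
#'
#' @param series a [roi_ts()].
#' @param z_cut positive robust z threshold (default 4).
#' @return integer vector of flagged frame indices (possibly empty).
#' @seealso [censor_frames()] to record them on the series.
#' @export
detect_spikes <- function(series, z_cut = 4) {
  stopifnot(inherits(series, "roi_ts"))
  if (z_cut <= 0) stop_field("z_cut", "must be > 0")
  x <- series$data
  if (ncol(x) < 3) stop_field("data", "need at least 3 frames")
  tt <- ncol(x)
  d <- colMeans(abs(x[, -1, drop = FALSE] - x[, -tt, drop = FALSE]))
  score <- c(d[1], pmin(d[-(tt - 1L)], d[-1]), d[tt - 1L])
  s <- mad(score)
  if (s == 0) return(integer())
  z <- (score - median(score)) / s
  which(z > z_cut)
}

#' Record censored frames on a series
#'
#' @param series a [roi_ts()].
#' @param frames integer frame indices to add to the censored set.
#' @return the series with an updated censored set.
#' @export
censor_frames <- function(series, frames) {
  series$censored_frames <- sort(unique(c(series$censored_frames,
                                          as.integer(frames))))
  if (length(series$censored_frames) &&
      max(series$censored_frames) > ncol(series$data)) {
    stop_field("frames", "indices outside 1..T")
  }
  series
}

#' Remove per-node linear trends
#'
#' Least-squares line (intercept + slope) fitted on non-censored frames only,
#' subtracted from all frames. Output has zero mean and zero best-fit slope
#' per node over the non-censored frames.
#'
#' @param series a [roi_ts()].
#' @return detrended `roi_ts`.
#' @export
detrend <- function(series) {
  stopifnot(inherits(series, "roi_ts"))
  keep <- usable_frames(series)
  if (length(keep) < 3) {
    stop("insufficient data: fewer than 3 usable frames", call. = FALSE)
  }
  tt <- seq_len(ncol(series$data))
  xk <- cbind(1, tt[keep])
  beta <- solve(crossprod(xk), crossprod(xk, t(series$data[, keep, drop = FALSE])))
  fit_all <- cbind(1, tt) %*% beta # T x N
  series$data <- series$data - t(fit_all)
  series
}

#' Band-pass filter ROI signals
#'
#' Zero-phase frequency-domain masking: the DFT of each node's signal is
#' multiplied by a binary mask retaining frequencies in `[low_hz, high_hz]`
#' and the result inverse-transformed. Components inside the band are
#' preserved exactly at bin frequencies; components at half the low edge or
#' twice the high edge are removed. Default band 0.01-0.1 Hz (low-frequency
#' drift and high-frequency physiological noise removed); the alternative
#' high-pass 0.009 / low-pass 0.12 Hz pair can be requested via the
#' arguments.
#'
#' @param series a [roi_ts()].
#' @param low_hz,high_hz band edges in Hz; requires
#'   `0 <= low_hz < high_hz < ` Nyquist.
#' @return filtered `roi_ts`.
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(series, "roi_ts"))
  nyq <- 0.5 / series$sample_interval
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyq)) {
    stop_field("low_hz/high_hz",
               sprintf("need 0 <= low < high < Nyquist (%g Hz)", nyq))
  }
  x <- series$data
  tt <- ncol(x)
  freqs <- seq(0, tt - 1) / (tt * series$sample_interval)
  freqs <- pmin(freqs, 1 / series$sample_interval - freqs) # fold to [0, Nyquist]
  keep <- freqs >= low_hz & freqs <= high_hz
  xf <- t(stats::mvfft(t(x)))
  xf[, !keep] <- 0
  series$data <- Re(t(stats::mvfft(t(xf), inverse = TRUE))) / tt
  series
}

#' Nuisance regressor design
#'
#' Column-bound regressors (motion parameters, mean white-matter signal, mean
#' CSF signal, spike indicator columns) with labels. An intercept is added at
#' fit time; the design must be full column rank once the intercept is
#' included.
#'
#' @param ... named numeric vectors or matrices, all with T rows.
#' @param spike_frames optional integer frame indices; each contributes a 0/1
#'   indicator column.
#' @param n_frames series length T (required if only `spike_frames` given).
#' @return object of class `nuisance_design` (matrix with `labels`).
#' @export
nuisance_design <- function(..., spike_frames = NULL, n_frames = NULL) {
  parts <- list(...)
  cols <- list()
  labels <- character()
  for (nm in names(parts)) {
    m <- as.matrix(parts[[nm]])
    cols[[length(cols) + 1]] <- m
    labels <- c(labels,
                if (ncol(m) == 1) nm else paste0(nm, "_", seq_len(ncol(m))))
  }
  if (length(cols)) n_frames <- nrow(cols[[1]])
  if (is.null(n_frames)) stop_field("n_frames", "required with spike-only designs")
  if (!is.null(spike_frames) && length(spike_frames)) {
    for (f in sort(unique(as.integer(spike_frames)))) {
      v <- numeric(n_frames)
      v[f] <- 1
      cols[[length(cols) + 1]] <- matrix(v, ncol = 1)
      labels <- c(labels, sprintf("spike_%d", f))
    }
  }
  if (!length(cols)) stop_field("design", "need at least one regressor")
  x <- do.call(cbind, cols)
  if (!all(vapply(cols, nrow, 1L) == n_frames)) {
    stop_field("design", "all regressors must have the same number of rows")
  }
  colnames(x) <- labels
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1) {
    drop_idx <- setdiff(seq_len(ncol(x) + 1), qrx$pivot[seq_len(qrx$rank)]) - 1
    stop(sprintf("collinear design: column(s) %s are redundant",
                 paste(labels[drop_idx], collapse = ", ")), call. = FALSE)
  }
  structure(x, class = c("nuisance_design", "matrix"), labels = labels)
}

#' Regress nuisance signals out of ROI series
#'
#' Per node, ordinary least-squares residuals against `[intercept | design]`,
#' with coefficients fitted on non-censored frames only and residuals formed
#' at every frame. Residuals are orthogonal to every design column on the
#' fitted frames.
#'
#' @param series a [roi_ts()].
#' @param design a [nuisance_design()] with T rows.
#' @return residualized `roi_ts`.
#' @export
nuisance_regress <- function(series, design) {
  stopifnot(inherits(series, "roi_ts"))
  x <- unclass(design)
  if (nrow(x) != ncol(series$data)) {
    stop_field("design", "row count must equal series length")
  }
  keep <- usable_frames(series)
  # columns supported only on censored frames (e.g. spike indicators) are
  # inert under censoring-by-exclusion; drop them from the fit
  live <- colSums(abs(x[keep, , drop = FALSE])) > 0
  x <- x[, live, drop = FALSE]
  if (ncol(x) == 0) return(detrend_mean_only(series, keep))
  xm <- cbind(intercept = 1, x)
  qrk <- qr(xm[keep, , drop = FALSE])
  if (qrk$rank < ncol(xm)) {
    bad <- colnames(xm)[setdiff(seq_len(ncol(xm)), qrk$pivot[seq_len(qrk$rank)])]
    stop(sprintf("collinear design on usable frames: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  beta <- qr.coef(qrk, t(series$data[, keep, drop = FALSE]))
  series$data <- series$data - t(xm %*% beta)
  series
}

# intercept-only residualization (used when every design column is inert)
detrend_mean_only <- function(series, keep) {
  mu <- rowMeans(series$data[, keep, drop = FALSE])
  series$data <- series$data - mu
  series
}

#' L2-normalize ROI signals
#'
#' Scales each node's time vector to unit Euclidean norm (the form the
#' correlation stage consumes).
#'
#' @param series a [roi_ts()].
#' @return normalized `roi_ts`.
#' @export
l2_normalize <- function(series) {
  stopifnot(inherits(series, "roi_ts"))
  nrm <- sqrt(rowSums(series$data^2))
  if (any(nrm == 0)) {
    stop(sprintf("degenerate signal: zero norm at node(s) %s",
                 paste(series$node_names[nrm == 0], collapse = ", ")),
         call. = FALSE)
  }
  series$data <- series$data / nrm
  series
}

#' Run the full cleaning chain on one series
#'
#' Default order: spike detection/censoring, detrend, band-pass, nuisance
#' regression (spike indicator columns plus any supplied design), L2
#' normalization. Steps can be reordered or dropped.
#'
#' @param series a [roi_ts()].
#' @param steps character vector drawn from
#'   `c("spikes", "detrend", "bandpass", "nuisance", "normalize")`.
#' @param z_cut spike threshold.
#' @param low_hz,high_hz band edges.
#' @param design optional [nuisance_design()]; spike indicator columns are
#'   appended automatically for censored frames.
#' @return cleaned `roi_ts`.
#' @export
preprocess_series <- function(series,
                              steps = c("spikes", "detrend", "bandpass",
                                        "nuisance", "normalize"),
                              z_cut = 4, low_hz = 0.01, high_hz = 0.1,
                              design = NULL) {
  for (st in steps) {
    series <- switch(
      st,
      spikes = censor_frames(series, detect_spikes(series, z_cut)),
      detrend = detrend(series),
      bandpass = bandpass(series, low_hz, high_hz),
      nuisance = {
        spk <- series$censored_frames
        if (is.null(design) && !length(spk)) {
          series # nothing to regress
        } else {
          d <- if (is.null(design)) {
            nuisance_design(spike_frames = spk, n_frames = ncol(series$data))
          } else if (length(spk)) {
            nuisance_design(base = unclass(design), spike_frames = spk)
          } else design
          nuisance_regress(series, d)
        }
      },
      normalize = l2_normalize(series),
      stop_field("steps", paste("unknown step", st)))
  }
  series
}
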