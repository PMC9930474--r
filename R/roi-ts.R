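#' ROI time-series container
#'
#' One subject-session block of ROI (node) signals: an `N x T` matrix of
#' arbitrary signal units sampled every `sample_interval` seconds, plus the
#' set of censored (motion-corrupted) frames. Frames are indexed 1..T.
#'
#' @param data numeric `N x T` matrix (nodes in rows).
#' @param node_names character vector of unique node names, length `N`.
#' @param subject_id subject identifier.
#' @param group treatment group label (e.g. "placebo", "CBD", "THC").
#' @param session session label (e.g. "chronic", "washout").
#' @param sample_interval sampling interval in seconds.
#' @param censored_frames integer vector of censored frame indices (1-based).
#' @return object of class `roi_ts`.
#' @export
roi_ts <- function(data, node_names = rownames(data), subject_id = "s1",
                   group = "placebo", session = "chronic",
                   sample_interval = 1, censored_frames = integer()) {
  data <- as.matrix(data)
  if (is.null(node_names)) node_names <- paste0("ROI_", seq_len(nrow(data)))
  if (nrow(data) < 2) stop_field("data", "need at least 2 nodes")
  if (ncol(data) < 3) stop_field("data", "need at least 3 timepoints")
  if (anyDuplicated(node_names)) stop_field("node_names", "must be unique")
  if (length(node_names) != nrow(data)) {
    stop_field("node_names", "length must equal nrow(data)")
  }
  if (!all(is.finite(data))) stop_field("data", "non-finite values")
  if (sample_interval <= 0) stop_field("sample_interval", "must be > 0")
  censored_frames <- sort(unique(as.integer(censored_frames)))
  if (length(censored_frames) &&
      (min(censored_frames) < 1 || max(censored_frames) > ncol(data))) {
    stop_field("censored_frames", "indices outside 1..T")
  }
  rownames(data) <- node_names
  structure(
    list(subject_id = subject_id, group = group, session = session,
         node_names = node_names, data = data,
         sample_interval = sample_interval,
         censored_frames = censored_frames),
    class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("ROI time series: %s [%s / %s]\n", x$subject_id, x$group,
              x$session))
  cat(sprintf("  %d nodes x %d timepoints, dt = %gs, %d censored frame(s)\n",
              nrow(x$data), ncol(x$data), x$sample_interval,
              length(x$censored_frames)))
  invisible(x)
}

#' @export
summary.roi_ts <- function(object, ...) {
  cat(sprintf("%d x %d ROI series, signal range [%.3g, %.3g]\n",
              nrow(object$data), ncol(object$data),
              min(object$data), max(object$data)))
  invisible(object)
}

# frames usable for fitting/correlation
usable_frames <- function(ts) {
  setdiff(seq_len(ncol(ts$data)), ts$censored_frames)
}
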