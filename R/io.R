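#' Write / read ROI time series as wide TSV
#'
#' Wide layout: first column `node`, remaining columns `t0 ... tN-1`.
#' Metadata (subject, group, session, sampling interval, censored frames) is
#' kept in a JSON sidecar next to the TSV (same path with `.json` appended).
#'
#' @param series a [roi_ts()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries_tsv <- function(series, path) {
  stopifnot(inherits(series, "roi_ts"))
  df <- data.frame(node = series$node_names, series$data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("node", paste0("t", seq_len(ncol(series$data)) - 1L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(subject_id = series$subject_id, group = series$group,
               session = series$session,
               sample_interval = series$sample_interval,
               censored_frames = series$censored_frames)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @param path TSV path written by [write_timeseries_tsv()].
#' @return a [roi_ts()].
#' @export
read_timeseries_tsv <- function(path) {
  df <- tryCatch(read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE),
                 error = function(e) {
                   stop(sprintf("parse error in %s: %s", path,
                                conditionMessage(e)), call. = FALSE)
                 })
  x <- as.matrix(df[, -1, drop = FALSE])
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  roi_ts(x, node_names = df[[1]],
         subject_id = meta$subject_id %||% "unknown",
         group = meta$group %||% "unknown",
         session = meta$session %||% "unknown",
         sample_interval = meta$sample_interval %||% 1,
         censored_frames = meta$censored_frames %||% integer())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a square matrix as CSV
#'
#' Header row and leading column carry node names.
#'
#' @param m square numeric matrix with dimnames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(nrow(m) == ncol(m))
  df <- data.frame(node = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) {
    stop(sprintf("parse error in %s: matrix not square (%d x %d)", path,
                 nrow(m), ncol(m)), call. = FALSE)
  }
  rownames(m) <- df[[1]]
  m
}

#' Write / read a long-form measure table as CSV
#'
#' Columns: subject_id, group, session, roi, measure, value.
#'
#' @param table long measure data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measure_csv <- function(table, path) {
  need <- c("subject_id", "group", "session", "roi", "measure", "value")
  stopifnot(all(need %in% names(table)))
  write.table(table[, need], path, sep = ",", quote = TRUE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measure_csv
#' @export
read_measure_csv <- function(path) {
  read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read an integer atlas as NIfTI-1
#'
#' Stores the label image with its voxel dimensions (mm) in the NIfTI header
#' and the label-name table as a companion TSV.
#'
#' @param atlas list as returned by [gen_atlas()] (`image`, `voxel_dims`,
#'   `name_table`).
#' @param path output `.nii` path (uncompressed by extension choice).
#' @return `path`, invisibly.
#' @export
write_nifti_atlas <- function(atlas, path) {
  arr <- atlas$image
  attr(arr, "pixdim") <- atlas$voxel_dims
  img <- RNifti::asNifti(arr, datatype = "int32")
  RNifti::writeNifti(img, path)
  write.table(atlas$name_table, paste0(path, ".labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nifti_atlas
#' @export
read_nifti_atlas <- function(path) {
  img <- RNifti::readNifti(path)
  name_path <- paste0(path, ".labels.tsv")
  name_table <- if (file.exists(name_path)) {
    read.table(name_path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  } else NULL
  storage.mode(img) <- "integer"
  list(image = array(as.integer(img), dim = dim(img)),
       voxel_dims = RNifti::pixdim(img)[seq_len(3)],
       name_table = name_table)
}

#' Export a graph for BrainNet-style viewers
#'
#' `.node`: one row per node with x, y, z coordinates (mm), a color value, a
#' size value (any node metric, e.g. strength AUC) and the label. `.edge`:
#' the square weight matrix, whitespace-delimited. Coordinates default to
#' points on a sphere (no anatomy is implied); pass atlas centroid
#' coordinates for real layouts.
#'
#' @param g a [weighted_graph()].
#' @param node_path,edge_path output paths.
#' @param coords optional `N x 3` matrix of node coordinates (mm).
#' @param size node size column (defaults to strength).
#' @param color node color column (defaults to 1).
#' @return invisible list of the two paths.
#' @export
write_brainnet <- function(g, node_path, edge_path, coords = NULL,
                           size = NULL, color = NULL) {
  stopifnot(inherits(g, "weighted_graph"))
  n <- length(g$node_names)
  if (is.null(coords)) {
    phi <- (seq_len(n) - 0.5) / n
    th <- pi * (3 - sqrt(5)) * seq_len(n)
    coords <- cbind(10 * sqrt(1 - (2 * phi - 1)^2) * cos(th),
                    10 * sqrt(1 - (2 * phi - 1)^2) * sin(th),
                    10 * (2 * phi - 1))
  }
  if (is.null(size)) size <- unname(node_strength(g))
  if (is.null(color)) color <- rep(1, n)
  node_df <- data.frame(coords[, 1], coords[, 2], coords[, 3], color, size,
                        gsub("[ \t]", "_", g$node_names))
  write.table(node_df, node_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(g$weights, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(list(node = node_path, edge = edge_path))
}

#' Read a BrainNet `.edge` file back as a weighted graph
#'
#' @param edge_path square whitespace-delimited matrix file.
#' @param node_names optional node names.
#' @return a [weighted_graph()].
#' @export
read_brainnet_edge <- function(edge_path, node_names = NULL) {
  m <- as.matrix(read.table(edge_path, header = FALSE))
  dimnames(m) <- NULL
  weighted_graph(m, node_names %||% paste0("ROI_", seq_len(nrow(m))))
}
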