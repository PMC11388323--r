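# Volume container and file formats: NIfTI-1 4-D volumes, TSV tables for
# markers / regressors / time courses, JSON for ground truth and reports.
# Conventions stated in every output: voxel indices 0-based, times in seconds,
# scan index 0-based at frame onset.

#' Masked 4-D volume time series
#'
#' Stores the in-mask voxel time series as a scans x voxels matrix together
#' with the logical mask, repetition time, and subject metadata. Out-of-mask
#' voxels never enter any statistic.
#'
#' @param data Numeric matrix `n_scans x n_inmask_voxels` (or a 4-D array,
#'   which is masked and flattened).
#' @param mask Logical 3-D array.
#' @param tr Repetition time in seconds.
#' @param subject_id,group Optional metadata.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, mask, tr, subject_id = NA_character_,
                          group = NA_character_) {
  stopifnot(is.array(mask) || is.logical(mask), tr > 0)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D logical array")
  if (is.array(data) && length(dim(data)) == 4L) {
    if (!all(dim(data)[1:3] == dim(mask)))
      stop(sprintf("volume spatial shape (%s) does not match mask shape (%s)",
                   paste(dim(data)[1:3], collapse = "x"),
                   paste(dim(mask), collapse = "x")))
    nt <- dim(data)[4]
    data <- t(matrix(data, prod(dim(mask)), nt)[which(mask), , drop = FALSE])
  }
  data <- as.matrix(data)
  if (ncol(data) != sum(mask))
    stop(sprintf("data has %d voxel columns but mask has %d in-mask voxels",
                 ncol(data), sum(mask)))
  if (anyNA(data)) stop("missing values inside the mask")
  structure(list(data = data, mask = mask, tr = tr,
                 subject_id = subject_id, group = group),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("<volume_series> %s%s: %d scans x %d in-mask voxels (grid %s), TR %.2f s\n",
              x$subject_id, if (is.na(x$group)) "" else sprintf(" [%s]", x$group),
              nrow(x$data), ncol(x$data),
              paste(dim(x$mask), collapse = "x"), x$tr))
  invisible(x)
}

#' Read a 4-D NIfTI volume into a volume series
#'
#' @param path Path to a 4-D NIfTI-1 file.
#' @param mask Logical array, or path to a 3-D NIfTI mask; defaults to all
#'   voxels.
#' @param tr Repetition time in seconds; defaults to the time-axis pixdim of
#'   the header and errors when neither is available.
#' @param subject_id,group Optional metadata.
#' @return A [volume_series()].
#' @export
read_volumes <- function(path, mask = NULL, tr = NULL,
                         subject_id = NA_character_, group = NA_character_) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4-D volume, got %d-D: %s", length(dim(arr)), path))
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  hdr_tr <- if (length(pd) >= 4) pd[4] else 0
  tr <- tr %||% (if (is.finite(hdr_tr) && hdr_tr > 0) hdr_tr else
    stop("TR missing from header and not supplied"))
  if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask)) > 0
  mask <- mask %||% array(TRUE, dim = dim(arr)[1:3])
  if (!all(dim(mask) == dim(arr)[1:3]))
    stop(sprintf("mask shape (%s) does not match volume shape (%s)",
                 paste(dim(mask), collapse = "x"),
                 paste(dim(arr)[1:3], collapse = "x")))
  out <- volume_series(arr, mask, tr, subject_id, group)
  attr(out, "affine") <- RNifti::xform(img)
  out
}

#' Write a volume series as a 4-D NIfTI file
#'
#' Out-of-mask voxels are written as zero; the TR is recorded in the
#' time-axis pixdim. Data are stored as 64-bit floats so a read-back is
#' bit-identical.
#'
#' @param vol A [volume_series()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volumes <- function(vol, path) {
  stopifnot(inherits(vol, "volume_series"))
  d3 <- dim(vol$mask)
  nt <- nrow(vol$data)
  big <- matrix(0, prod(d3), nt)
  big[which(vol$mask), ] <- t(vol$data)
  arr <- array(big, dim = c(d3, nt))
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  pd[4] <- vol$tr
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a statistic map (one volume) as 3-D NIfTI
#'
#' @param values Numeric vector over in-mask voxels.
#' @param mask Logical 3-D array.
#' @param path Output path.
#' @param fill Value for out-of-mask voxels.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(values, mask, path, fill = 0) {
  arr <- array(fill, dim = dim(mask))
  arr[which(mask)] <- values
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "double")
  invisible(path)
}

#' Read and write boundary-marker tables
#'
#' Tab-separated with a header row and columns `participant_id`, `group`,
#' `time_s` (seconds from stimulus onset).
#'
#' @param path File path.
#' @param duration Stimulus duration in seconds (stored as a `# duration`
#'   comment on write; required on read if the file lacks one).
#' @return `read_markers` returns a [marker_set()]; `write_markers` returns
#'   `path` invisibly.
#' @export
read_markers <- function(path, duration = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "# duration_s=")) {
    duration <- duration %||% as.numeric(sub("# duration_s=", "", first))
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "time_s")
  if (!all(need %in% names(tab)))
    stop("marker table must have columns participant_id, group, time_s")
  if (is.null(duration)) duration <- max(tab$time_s)
  marker_set(tab$participant_id, tab$group, tab$time_s, duration)
}

#' @rdname read_markers
#' @param markers A [marker_set()] to write.
#' @export
write_markers <- function(markers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_s=%.10g", attr(markers, "duration")), con)
  write.table(data.frame(participant_id = markers$participant_id,
                         group = markers$group, time_s = markers$time),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write scan-grid series tables
#'
#' Tab-separated with header `scan_index` (0-based, frame onset) and `value`.
#'
#' @param path File path.
#' @return `read_series` returns a numeric vector; `write_series` returns
#'   `path` invisibly.
#' @export
read_series <- function(path) {
  tab <- read.delim(path, comment.char = "#")
  tab$value[order(tab$scan_index)]
}

#' @rdname read_series
#' @param values Numeric scan-grid series.
#' @export
write_series <- function(values, path) {
  write.table(data.frame(scan_index = seq_along(values) - 1L, value = values),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write subject component time-course tables
#'
#' Long-format TSV with columns `subject_id`, `component`, `scan_index`
#' (0-based), `value`.
#'
#' @param path File path.
#' @return `read_timecourses` returns a named list of `n_scans x k` matrices;
#'   `write_timecourses` returns `path` invisibly.
#' @export
read_timecourses <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  lapply(split(tab, tab$subject_id), function(d) {
    comps <- split(d, d$component)
    m <- vapply(comps, function(cc) cc$value[order(cc$scan_index)],
                numeric(nrow(comps[[1]])))
    m
  })
}

#' @rdname read_timecourses
#' @param tcs Named list of `n_scans x k` matrices (one per subject).
#' @export
write_timecourses <- function(tcs, path) {
  if (is.null(names(tcs))) names(tcs) <- sprintf("S%02d", seq_along(tcs))
  rows <- lapply(names(tcs), function(sid) {
    m <- tcs[[sid]]
    comps <- colnames(m) %||% sprintf("IC%d", seq_len(ncol(m)))
    do.call(rbind, lapply(seq_len(ncol(m)), function(c)
      data.frame(subject_id = sid, component = comps[c],
                 scan_index = seq_len(nrow(m)) - 1L, value = m[, c])))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Serialize ground truth to JSON alongside generated outputs
#'
#' @param truth A [ground_truth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  x <- truth
  x$network_maps <- lapply(x$network_maps, as.vector)
  jsonlite::write_json(unclass(x), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
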