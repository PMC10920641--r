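#' Motion energy analysis over regions of interest
#'
#' Motion energy analysis (MEA) quantifies movement in fixed-camera video as
#' the number of pixels whose frame-to-frame gray-scale change exceeds a
#' threshold, counted separately within rectangular regions of interest
#' (ROIs).  With a steady camera, constant lighting and a static background,
#' pixel changes above the threshold are attributable to movement of the
#' person occupying the ROI.  Motion energy is a pixel *count*, not a summed
#' magnitude; downstream standard-deviation scaling removes the unit anyway.
#'
#' @name motion_energy
NULL

#' Construct a frame sequence
#'
#' @param frames list of numeric matrices with 8-bit gray intensities
#'   (0--255), all of identical dimension.
#' @param fps frames per second (> 0).
#' @return object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps) {
  stopifnot(is.list(frames), length(frames) >= 2L, fps > 0)
  d <- dim(frames[[1L]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d), logical(1))
  if (!all(ok)) stop("all frames must be matrices of identical dimension")
  structure(list(frames = frames, fps = fps,
                 height = d[1L], width = d[2L]),
            class = "frame_sequence")
}

#' Construct a region of interest
#'
#' Rectangles are given in 0-based, half-open pixel coordinates
#' `[x0, x1) x [y0, y1)`, with x running along columns and y along rows.
#'
#' @param role one of `"participant_head"`, `"participant_body"`,
#'   `"administrator_head"`, `"administrator_body"`.
#' @param x0,y0,x1,y1 rectangle bounds.
#' @return object of class `roi`.
#' @export
roi <- function(role, x0, y0, x1, y1) {
  role <- match.arg(role, mea_roles())
  if (x1 <= x0 || y1 <= y0) stop("roi rectangle is empty")
  if (x0 < 0 || y0 < 0) stop("roi rectangle has negative origin")
  structure(list(role = role, x0 = x0, y0 = y0, x1 = x1, y1 = y1),
            class = "roi")
}

#' @rdname roi
#' @export
mea_roles <- function() {
  c("participant_head", "participant_body",
    "administrator_head", "administrator_body")
}

roi_area <- function(r) (r$x1 - r$x0) * (r$y1 - r$y0)

check_roi_bounds <- function(r, height, width) {
  if (r$x1 > width || r$y1 > height)
    stop(sprintf("roi '%s' exceeds frame bounds (%d x %d)", r$role, height, width))
  invisible(TRUE)
}

#' Construct a motion energy series
#'
#' @param values nonnegative per-transition pixel-change counts (one value per
#'   frame-to-frame transition, i.e. `nframes - 1` values).
#' @param fps frames per second of the source video.
#' @param role ROI role the series belongs to.
#' @return numeric vector of class `mea_series` with `fps` and `role`
#'   attributes.
#' @export
mea_series <- function(values, fps, role = NULL) {
  stopifnot(is.numeric(values), all(values >= 0), fps > 0)
  structure(as.numeric(values), fps = fps, role = role, class = "mea_series")
}

#' @export
print.mea_series <- function(x, ...) {
  cat(sprintf("<mea_series> role=%s fps=%.3f length=%d nonzero=%.1f%%\n",
              attr(x, "role") %||% "?", attr(x, "fps"), length(x),
              100 * mean(x > 0)))
  invisible(x)
}

series_fps <- function(x) attr(x, "fps")

#' Motion energy of a single frame transition
#'
#' Counts the pixels inside `r` whose absolute gray-level change between two
#' consecutive frames is strictly greater than the threshold.
#'
#' @param prev,curr gray-scale intensity matrices of identical dimension.
#' @param r a [roi()].
#' @param threshold gray-level difference threshold (default 8, the value
#'   used for diagnostic-interview video).
#' @return integer pixel count in `[0, roi area]`.
#' @export
frame_motion_energy <- function(prev, curr, r, threshold = 8) {
  if (!identical(dim(prev), dim(curr)))
    stop("frames differ in dimension")
  stopifnot(threshold >= 0)
  check_roi_bounds(r, nrow(prev), ncol(prev))
  rows <- (r$y0 + 1L):r$y1
  cols <- (r$x0 + 1L):r$x1
  sum(abs(curr[rows, cols] - prev[rows, cols]) > threshold)
}

#' Extract motion energy series from a frame sequence
#'
#' @param video a [frame_sequence()].
#' @param rois list of [roi()] objects.
#' @param threshold gray-level difference threshold, see
#'   [frame_motion_energy()].
#' @return named list of [mea_series()], one per ROI role.
#' @export
extract_motion_energy <- function(video, rois, threshold = 8) {
  stopifnot(inherits(video, "frame_sequence"))
  nf <- length(video$frames)
  if (nf < 2L) stop("need at least 2 frames")
  for (r in rois) check_roi_bounds(r, video$height, video$width)
  out <- lapply(rois, function(r) {
    v <- vapply(seq_len(nf - 1L), function(i) {
      frame_motion_energy(video$frames[[i]], video$frames[[i + 1L]], r, threshold)
    }, numeric(1))
    mea_series(v, video$fps, r$role)
  })
  names(out) <- vapply(rois, `[[`, character(1), "role")
  out
}

#' Movement quantity of a motion energy series
#'
#' Fraction of frame transitions with nonzero motion energy.  The denominator
#' is the length of the difference series (`nframes - 1`); set
#' `denominator = "frames"` to divide by the frame count instead.
#'
#' @param series an [mea_series()] (any nonnegative numeric vector works).
#' @param denominator `"transitions"` (default) or `"frames"`.
#' @return fraction in `[0, 1]`.
#' @export
movement_quantity <- function(series, denominator = c("transitions", "frames")) {
  denominator <- match.arg(denominator)
  n <- length(series)
  if (n == 0L) stop("empty series")
  den <- if (denominator == "frames") n + 1L else n
  sum(series > 0) / den
}

#' Read and write gray-scale frame sequences as PNG directories
#'
#' A directory of lexicographically ordered PNG files is the canonical
#' on-disk representation of a clip.  Color images are converted to gray with
#' the Rec. 601 luma weights (0.299 R, 0.587 G, 0.114 B).
#'
#' @param dir directory containing (or to receive) the PNG frames.
#' @param fps frames per second recorded in the returned object.
#' @return [read_frames_png()] returns a [frame_sequence()];
#'   [write_frames_png()] returns the directory path invisibly.
#' @export
read_frames_png <- function(dir, fps) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) < 2L) stop("need at least 2 PNG frames in ", dir)
  frames <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3L) {
      ch <- dim(a)[3L]
      a <- if (ch >= 3L)
        0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
      else a[, , 1L]
    }
    round(a * 255)
  })
  frame_sequence(frames, fps)
}

#' @param video a [frame_sequence()] to write.
#' @rdname read_frames_png
#' @export
write_frames_png <- function(video, dir) {
  stopifnot(inherits(video, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(video$frames)) {
    png::writePNG(video$frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%05d.png", i)))
  }
  invisible(dir)
}

#' Read and write ROI specifications as JSON
#'
#' The on-disk ROI format is a JSON array of objects
#' `{role, x0, y0, x1, y1}` in 0-based, half-open pixel coordinates.
#'
#' @param rois list of [roi()] objects.
#' @param path JSON file path.
#' @return [read_roi_json()] returns a list of [roi()] objects.
#' @export
write_roi_json <- function(rois, path) {
  jsonlite::write_json(
    lapply(rois, function(r) r[c("role", "x0", "y0", "x1", "y1")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  specs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(specs, function(s) roi(s$role, s$x0, s$y0, s$x1, s$y1))
}

#' Read and write motion energy series as CSV
#'
#' One column per ROI role, one row per frame transition; the frame rate and
#' extraction settings travel in a JSON sidecar (`<path>.json`).
#'
#' @param series named list of [mea_series()] of equal length.
#' @param path CSV file path.
#' @param meta optional list of extra metadata stored in the sidecar.
#' @return [read_mea_csv()] returns a named list of [mea_series()].
#' @export
write_mea_csv <- function(series, path, meta = list()) {
  stopifnot(length(series) >= 1L)
  lens <- vapply(series, length, integer(1))
  if (length(unique(lens)) != 1L) stop("series lengths differ")
  df <- as.data.frame(lapply(series, as.numeric))
  names(df) <- names(series)
  utils::write.csv(df, path, row.names = FALSE)
  side <- c(list(fps = series_fps(series[[1L]]), columns = names(series)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mea_csv
#' @export
read_mea_csv <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  out <- lapply(names(df), function(nm) mea_series(df[[nm]], side$fps, nm))
  names(out) <- names(df)
  out
}
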