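# Leaf-pixel segmentation and per-cage area measurement.
#
# Two detection strategies, as in the original assay: (i) arithmetic
# filters on the RGB planes (or one HSB component) with an intensity
# threshold, and (ii) distance to a set of user-picked reference colours
# in RGB space (L1 or L2) with a distance threshold. Leaf area per cage is
# the number of accepted pixels inside the cage ROI.

FILTER_MODES <- c("channel_R", "channel_G", "channel_B",
                  "diff_2R", "diff_2G", "diff_2B", "mean_RGB",
                  "hsb_H", "hsb_S", "hsb_B", "ref_colors")

#' Define a leaf-pixel colour filter
#'
#' Intensity modes compute one scalar per pixel (arithmetic combinations are
#' clamped to `[0, 255]`; HSB components are rescaled to 0-255) and accept a
#' pixel iff the value is strictly greater than `threshold`. The
#' `ref_colors` mode accepts a pixel iff its minimum distance to any
#' reference colour is strictly below `threshold`.
#'
#' @param mode One of `"channel_R"`, `"channel_G"`, `"channel_B"`,
#'   `"diff_2R"` (2R - (G+B)), `"diff_2G"` (2G - (R+B)), `"diff_2B"`,
#'   `"mean_RGB"`, `"hsb_H"`, `"hsb_S"`, `"hsb_B"`, `"ref_colors"`.
#' @param threshold Intensity threshold (0-255) or distance threshold.
#' @param ref_colors For `ref_colors` mode: a matrix with one RGB reference
#'   per row (components 0-255).
#' @param metric Distance metric for `ref_colors`: `"L1"` or `"L2"`.
#' @return A `color_filter` object.
#' @examples
#' f <- color_filter("diff_2G", threshold = 35)
#' @export
color_filter <- function(mode, threshold, ref_colors = NULL, metric = c("L2", "L1")) {
  mode <- match.arg(mode, FILTER_MODES)
  metric <- match.arg(metric)
  if (threshold < 0) stop("threshold must be non-negative")
  if (mode == "ref_colors") {
    if (is.null(ref_colors)) stop("ref_colors mode requires at least one reference colour")
    if (is.numeric(ref_colors) && is.null(dim(ref_colors)))
      ref_colors <- matrix(ref_colors, ncol = 3, byrow = TRUE)
    if (nrow(ref_colors) < 1) stop("ref_colors mode requires at least one reference colour")
  }
  structure(list(mode = mode, threshold = threshold,
                 ref_colors = ref_colors, metric = metric),
            class = "color_filter")
}

#' @export
print.color_filter <- function(x, ...) {
  if (x$mode == "ref_colors")
    cat(sprintf("color_filter: %d reference colour(s), %s distance < %g\n",
                nrow(x$ref_colors), x$metric, x$threshold))
  else
    cat(sprintf("color_filter: %s > %g\n", x$mode, x$threshold))
  invisible(x)
}

#' Apply an intensity filter to an RGB frame
#'
#' @param frame An H x W x 3 numeric array with components in 0-255.
#' @param mode An intensity filter mode (see [color_filter()]).
#' @return An H x W matrix of filtered values in `[0, 255]`.
#' @export
apply_intensity_filter <- function(frame, mode) {
  mode <- match.arg(mode, setdiff(FILTER_MODES, "ref_colors"))
  if (length(dim(frame)) != 3 || dim(frame)[3] < 3)
    stop("frame must be an H x W x 3 RGB array")
  r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3]
  out <- switch(mode,
    channel_R = r, channel_G = g, channel_B = b,
    diff_2R = 2 * r - (g + b),
    diff_2G = 2 * g - (r + b),
    diff_2B = 2 * b - (r + g),
    mean_RGB = (r + g + b) / 3,
    hsb_H = , hsb_S = , hsb_B = {
      hsv <- grDevices::rgb2hsv(r = as.vector(r), g = as.vector(g),
                                b = as.vector(b), maxColorValue = 255)
      comp <- switch(mode, hsb_H = hsv[1, ], hsb_S = hsv[2, ], hsb_B = hsv[3, ])
      matrix(comp * 255, nrow = nrow(r))
    })
  clamp(out, 0, 255)
}

#' Colour distance in RGB space
#'
#' `L1` is the sum of absolute component differences; `L2` the Euclidean
#' norm of the differences.
#'
#' @param pixel,ref Length-3 RGB vectors (or matrices with 3 columns,
#'   compared row-wise against a single `ref`).
#' @param metric `"L1"` or `"L2"`.
#' @return Non-negative distance(s).
#' @export
color_distance <- function(pixel, ref, metric = c("L2", "L1")) {
  metric <- match.arg(metric)
  if (is.null(dim(pixel))) pixel <- matrix(pixel, ncol = 3)
  d <- sweep(pixel, 2, as.numeric(ref))
  out <- if (metric == "L1") rowSums(abs(d)) else sqrt(rowSums(d^2))
  if (length(out) == 1) out[[1]] else out
}

#' Apply a reference-colour filter to an RGB frame
#'
#' A pixel is accepted iff its distance to at least one reference colour is
#' strictly below the filter threshold.
#'
#' @param frame An H x W x 3 numeric array, components 0-255.
#' @param filter A `ref_colors` [color_filter()].
#' @return An H x W logical mask.
#' @export
apply_reference_filter <- function(frame, filter) {
  stopifnot(inherits(filter, "color_filter"))
  if (filter$mode != "ref_colors") stop("filter must be in ref_colors mode")
  h <- dim(frame)[1]; w <- dim(frame)[2]
  px <- cbind(as.vector(frame[, , 1]), as.vector(frame[, , 2]), as.vector(frame[, , 3]))
  mind <- rep(Inf, h * w)
  for (k in seq_len(nrow(filter$ref_colors)))
    mind <- pmin(mind, color_distance(px, filter$ref_colors[k, ], filter$metric))
  matrix(mind < filter$threshold, nrow = h)
}

#' Count accepted pixels per ROI
#'
#' For an intensity image, a pixel is accepted iff its value is strictly
#' greater than `threshold`; for a logical mask, iff it is `TRUE`.
#'
#' @param x An H x W intensity matrix or logical mask.
#' @param rois A `roi_array` lying within the frame.
#' @param threshold Intensity threshold (ignored for logical masks).
#' @return A named integer vector of counts, one per ROI.
#' @export
count_over_threshold <- function(x, rois, threshold = NULL) {
  accepted <- if (is.logical(x)) x else {
    if (is.null(threshold)) stop("threshold required for intensity input")
    x > threshold
  }
  map <- roi_index_map(rois, width = ncol(accepted), height = nrow(accepted))
  out <- as.integer(tabulate(map[accepted], nbins = length(rois$cells)))
  names(out) <- vapply(rois$cells, `[[`, character(1), "name")
  out
}

#' Read one frame as an RGB array scaled 0-255
#'
#' PNG and JPEG are supported (JPEG via the optional jpeg package).
#'
#' @param path Image file path.
#' @return An H x W x 3 numeric array with components in 0-255.
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("reading JPEG frames requires the 'jpeg' package")
    jpeg::readJPEG(path)
  } else png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

apply_filter_to_frame <- function(frame, filter) {
  if (filter$mode == "ref_colors") apply_reference_filter(frame, filter)
  else apply_intensity_filter(frame, filter$mode)
}

#' Measure leaf area per cage across an image stack
#'
#' Applies the filter to every retained frame (every `subsample_step`-th
#' frame of the sorted stack), counts accepted pixels per ROI, and smooths
#' the counts with a centered running average and running median of
#' `smooth_n` retained frames (windows shrink at the series edges).
#' Unreadable frames are skipped with a warning carrying the frame index.
#'
#' @param frame_paths Character vector of frame files, sorted by time.
#' @param rois A `roi_array`.
#' @param filter A [color_filter()].
#' @param subsample_step Analyze one frame in every `subsample_step`.
#' @param smooth_n Smoothing window length (retained frames); `1` disables.
#' @param cadence_min Minutes between consecutive frames on disk.
#' @return An `area_series` object: `time` (minutes since the first
#'   retained frame) plus `raw`, `avg` and `med` count matrices
#'   (time x ROI).
#' @export
measure_stack <- function(frame_paths, rois, filter, subsample_step = 1,
                          smooth_n = 10, cadence_min = 1) {
  if (length(frame_paths) < 1) stop("need at least one frame")
  stopifnot(subsample_step >= 1)
  keep <- seq(1, length(frame_paths), by = subsample_step)
  paths <- frame_paths[keep]
  times <- (keep - 1) * cadence_min
  n_roi <- length(rois$cells)
  raw <- matrix(NA_real_, nrow = length(paths), ncol = n_roi)
  ok <- rep(FALSE, length(paths))
  map <- NULL
  for (i in seq_along(paths)) {
    frame <- tryCatch(read_frame(paths[i]), error = function(e) {
      warning(sprintf("frame %d (%s) unreadable: %s", keep[i],
                      basename(paths[i]), conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(frame)) next
    filtered <- apply_filter_to_frame(frame, filter)
    if (is.null(map))
      map <- roi_index_map(rois, width = ncol(filtered), height = nrow(filtered))
    accepted <- if (is.logical(filtered)) filtered else filtered > filter$threshold
    tab <- tabulate(map[accepted], nbins = n_roi)
    raw[i, ] <- tab
    ok[i] <- TRUE
  }
  if (!any(ok)) stop("no frame of the stack could be read")
  raw <- raw[ok, , drop = FALSE]
  times <- times[ok]
  times <- times - times[1]
  avg <- apply(raw, 2, moving_average, n = smooth_n)
  med <- apply(raw, 2, function(col) stats_window(col, smooth_n, stats::median))
  if (!is.matrix(avg)) { avg <- matrix(avg, nrow = 1); med <- matrix(med, nrow = 1) }
  roi_names <- vapply(rois$cells, `[[`, character(1), "name")
  colnames(raw) <- colnames(avg) <- colnames(med) <- roi_names
  structure(list(time = times, raw = raw, avg = avg, med = med,
                 smooth_n = smooth_n, plate = rois$plate),
            class = "area_series")
}

#' @export
print.area_series <- function(x, ...) {
  cat(sprintf("area_series: %d time points x %d ROIs (smooth_n = %d, plate '%s')\n",
              length(x$time), ncol(x$raw), x$smooth_n, x$plate %||% "?"))
  invisible(x)
}

#' Export per-ROI area tables as CSV
#'
#' Writes three files, `<prefix>_raw.csv`, `<prefix>_avg.csv` and
#' `<prefix>_med.csv`, each with a `time` column followed by one column per
#' ROI, full precision.
#'
#' @param series An `area_series`.
#' @param prefix Output path prefix.
#' @return The three file paths, invisibly.
#' @export
export_area_table <- function(series, prefix) {
  stopifnot(inherits(series, "area_series"))
  if (length(series$time) == 0) stop("empty series")
  paths <- paste0(prefix, c("_raw.csv", "_avg.csv", "_med.csv"))
  for (i in seq_along(paths)) {
    m <- series[[c("raw", "avg", "med")[i]]]
    utils::write.csv(data.frame(time = series$time, m, check.names = FALSE),
                     paths[i], row.names = FALSE)
  }
  invisible(paths)
}

#' Read back area tables written by [export_area_table()]
#'
#' @param prefix The path prefix used when writing.
#' @param smooth_n Smoothing window recorded in the result (the CSV does
#'   not store it).
#' @return An `area_series`.
#' @export
read_area_table <- function(prefix, smooth_n = NA_integer_) {
  get_mat <- function(suffix) {
    df <- utils::read.csv(paste0(prefix, suffix), check.names = FALSE)
    as.matrix(df[, -1, drop = FALSE])
  }
  time <- utils::read.csv(paste0(prefix, "_raw.csv"), check.names = FALSE)$time
  structure(list(time = time, raw = get_mat("_raw.csv"),
                 avg = get_mat("_avg.csv"), med = get_mat("_med.csv"),
                 smooth_n = smooth_n, plate = NA_character_),
            class = "area_series")
}
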