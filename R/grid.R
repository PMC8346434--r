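# Cage-grid detection inside a user-drawn parallelogram, and ROI-array
# persistence as XML.
#
# The detection principle: pixels of a line parallel to a plate border are
# nearly uniform when the line runs along a cage wall, and highly variable
# when it crosses the cages (wall / background / leaf / larva). Wall
# positions therefore show up as local minima of the along-line intensity
# variance, profiled across the plate.

#' Construct a parallelogram from four corner points
#'
#' Corners are given in pixel coordinates (x to the right, y down, 0-based,
#' sub-pixel allowed), ordered clockwise starting at the top-left.
#'
#' @param corners A 4 x 2 numeric matrix (columns x, y) or a length-8
#'   numeric vector `c(x1, y1, ..., x4, y4)`.
#' @return A `parallelogram` object (4 x 2 matrix with class attribute).
#' @examples
#' quad <- parallelogram(c(0, 0, 100, 0, 100, 50, 0, 50))
#' @export
parallelogram <- function(corners) {
  if (is.numeric(corners) && is.null(dim(corners)) && length(corners) == 8)
    corners <- matrix(corners, ncol = 2, byrow = TRUE)
  if (!is.matrix(corners) || !identical(dim(corners), c(4L, 2L)))
    stop("corners must be a 4 x 2 matrix or a length-8 vector")
  if (anyDuplicated(corners) > 0) stop("parallelogram corners must be distinct")
  colnames(corners) <- c("x", "y")
  a <- polygon_area(corners)
  if (abs(a) < 1e-9) stop("degenerate parallelogram: zero area")
  structure(corners, class = "parallelogram")
}

# Shoelace signed area; positive for clockwise order in y-down coordinates.
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[j, 1] * p[, 2] - p[, 1] * p[j, 2]) / 2
}

# Bilinear map of unit-square coordinates (u across the top edge, v down
# the left edge) into the quad. Affine when the quad is a parallelogram.
quad_map <- function(quad, u, v) {
  p1 <- quad[1, ]; p2 <- quad[2, ]; p3 <- quad[3, ]; p4 <- quad[4, ]
  x <- (1 - v) * ((1 - u) * p1[1] + u * p2[1]) + v * ((1 - u) * p4[1] + u * p3[1])
  y <- (1 - v) * ((1 - u) * p1[2] + u * p2[2]) + v * ((1 - u) * p4[2] + u * p3[2])
  cbind(x = x, y = y)
}

#' Along-line intensity variance profiled across a plate
#'
#' For each fractional offset across the quad (step at most one pixel), the
#' population variance of pixel intensities sampled along the line parallel
#' to the corresponding plate border. Lines parallel to the top border
#' (`axis = "rows"`) sweep from the top edge to the bottom edge; lines
#' parallel to the left border (`axis = "cols"`) sweep left to right.
#' Lines are sampled with bilinear interpolation at unit steps.
#'
#' @param image Grayscale matrix or RGB array (collapsed by channel mean).
#' @param quad A [parallelogram()] enclosing the plate; must lie within the
#'   image bounds.
#' @param axis `"rows"` for horizontal separators, `"cols"` for vertical.
#' @return A data frame with columns `offset` (pixels along the sweep edge)
#'   and `variance`.
#' @export
line_variance_profile <- function(image, quad, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  img <- as_gray(image)
  quad <- as_parallelogram(quad)
  h <- nrow(img); w <- ncol(img)
  if (any(quad[, 1] < 0 | quad[, 1] > w - 1 | quad[, 2] < 0 | quad[, 2] > h - 1))
    stop("quad lies outside image bounds")
  if (axis == "rows") {
    a0 <- quad[1, ]; a1 <- quad[4, ]   # sweep down the left edge
    b0 <- quad[2, ]; b1 <- quad[3, ]
  } else {
    a0 <- quad[1, ]; a1 <- quad[2, ]   # sweep across the top edge
    b0 <- quad[4, ]; b1 <- quad[3, ]
  }
  extent <- sqrt(sum((a1 - a0)^2))
  n_off <- max(10L, ceiling(extent)) + 1L
  tt <- seq(0, 1, length.out = n_off)
  vars <- vapply(tt, function(t) {
    p <- a0 + t * (a1 - a0)
    q <- b0 + t * (b1 - b0)
    len <- sqrt(sum((q - p)^2))
    s <- seq(0, floor(len)) / len
    vals <- bilinear_sample(img, p[1] + s * (q[1] - p[1]), p[2] + s * (q[2] - p[2]))
    pop_var(vals)
  }, numeric(1))
  data.frame(offset = tt * extent, variance = vars)
}

as_parallelogram <- function(x) {
  if (inherits(x, "parallelogram")) x else parallelogram(x)
}

# Local minima of a profile with plateau handling: equal-valued runs are
# collapsed and a run is a minimum only if strictly lower values flank it
# on BOTH sides (runs touching the profile ends are never minima). Returns
# indices of run centers.
local_minima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  if (k < 3) return(integer(0))
  idx <- which(vapply(seq_len(k), function(i) {
    i > 1 && i < k && r$values[i] < r$values[i - 1] && r$values[i] < r$values[i + 1]
  }, logical(1)))
  as.integer(round((starts[idx] + ends[idx]) / 2))
}

# Select separator offsets from a variance profile: smooth, find plateau-aware
# local minima, keep only deep minima (below the midpoint of the profile
# minimum and median: lines over walls are near-uniform while most lines
# cross the cages, so the median tracks the cage-crossing variance level),
# then greedily keep minima (lowest variance first) at least min_sep_frac
# of the median pitch apart.
find_separators <- function(profile, smooth_window = 5, min_sep_frac = 0.6) {
  v <- moving_average(profile$variance, smooth_window)
  idx <- local_minima(v)
  if (length(idx) == 0) return(numeric(0))
  depth_cut <- min(v) + 0.5 * (stats::median(v) - min(v))
  idx <- idx[v[idx] <= depth_cut]
  if (length(idx) == 0) return(numeric(0))
  off <- profile$offset[idx]
  val <- v[idx]
  if (length(off) >= 2) {
    pitch <- stats::median(diff(sort(off)))
    extent <- max(profile$offset)
    # border walls produce minima hugging the quad edges; a genuine first
    # or last separator sits at least one cell pitch from the border
    inb <- off >= 0.3 * pitch & off <= extent - 0.3 * pitch
    off <- off[inb]; val <- val[inb]
    keep <- integer(0)
    for (i in order(val)) {
      if (all(abs(off[i] - off[keep]) >= min_sep_frac * pitch)) keep <- c(keep, i)
    }
    off <- sort(off[keep])
  }
  off
}

#' Detect the cage grid inside a parallelogram
#'
#' Profiles the along-line variance across both axes of the quad, places
#' row/column separators at the local variance minima, and builds a
#' [roi_array()] of one convex quadrilateral per cage. The cage count per
#' axis is inferred as (number of interior minima + 1) unless
#' `expected_shape` pins it down, in which case a mismatch is an error.
#'
#' @param image Grayscale matrix or RGB array.
#' @param quad A [parallelogram()] enclosing the plate.
#' @param expected_shape Optional `c(rows, cols)`.
#' @param plate Plate identifier stored in the result.
#' @param smooth_window Moving-average window (profile samples) applied
#'   before minima detection.
#' @return A `roi_array`.
#' @export
detect_grid <- function(image, quad, expected_shape = NULL, plate = "plate",
                        smooth_window = 5) {
  quad <- as_parallelogram(quad)
  prof_r <- line_variance_profile(image, quad, "rows")
  prof_c <- line_variance_profile(image, quad, "cols")
  sep_r <- find_separators(prof_r, smooth_window)
  sep_c <- find_separators(prof_c, smooth_window)
  if (length(sep_r) == 0 && length(sep_c) == 0)
    stop("grid detection failed: no separator minima found (uniform or contrast-free image?)")
  ext_r <- max(prof_r$offset)
  ext_c <- max(prof_c$offset)
  v_breaks <- c(0, sep_r / ext_r, 1)
  u_breaks <- c(0, sep_c / ext_c, 1)
  n_rows <- length(v_breaks) - 1L
  n_cols <- length(u_breaks) - 1L
  if (!is.null(expected_shape)) {
    if (n_rows != expected_shape[1] || n_cols != expected_shape[2])
      stop(sprintf(
        "grid detection failed: found %d x %d cells, expected %d x %d",
        n_rows, n_cols, expected_shape[1], expected_shape[2]))
  }
  roi_array(quad, u_breaks, v_breaks, plate = plate)
}

#' Build a ROI array from a quad and fractional grid breaks
#'
#' Cells are convex quadrilaterals obtained by bilinear interpolation of the
#' quad at the break positions; `u` runs across columns (top edge), `v`
#' down rows (left edge). Cell names follow `"R01C01"`; IDs are row-major
#' integers starting at 1. A pixel belongs to a cell iff its center lies
#' inside the half-open polygon (shared edges are claimed by exactly one of
#' the two adjacent cells), so cells never share a pixel.
#'
#' @param quad A [parallelogram()].
#' @param u_breaks,v_breaks Strictly increasing break vectors in `[0, 1]`
#'   starting at 0 and ending at 1.
#' @param plate Plate identifier.
#' @return A `roi_array`: list with `plate`, `n_rows`, `n_cols`, `quad`,
#'   `u_breaks`, `v_breaks` and `cells` (each with `id`, `name`, `poly`).
#' @export
roi_array <- function(quad, u_breaks, v_breaks, plate = "plate") {
  quad <- as_parallelogram(quad)
  check_breaks <- function(b, what) {
    if (length(b) < 2 || any(diff(b) <= 0) || abs(b[1]) > 1e-9 || abs(b[length(b)] - 1) > 1e-9)
      stop(sprintf("%s breaks must be strictly increasing from 0 to 1", what))
  }
  check_breaks(u_breaks, "column"); check_breaks(v_breaks, "row")
  n_rows <- length(v_breaks) - 1L
  n_cols <- length(u_breaks) - 1L
  cells <- vector("list", n_rows * n_cols)
  k <- 0L
  for (r in seq_len(n_rows)) {
    for (cc in seq_len(n_cols)) {
      k <- k + 1L
      poly <- quad_map(quad, u = c(u_breaks[cc], u_breaks[cc + 1], u_breaks[cc + 1], u_breaks[cc]),
                       v = c(v_breaks[r], v_breaks[r], v_breaks[r + 1], v_breaks[r + 1]))
      cells[[k]] <- list(id = k, name = sprintf("R%02dC%02d", r, cc), poly = poly)
    }
  }
  structure(list(plate = plate, n_rows = n_rows, n_cols = n_cols,
                 quad = quad, u_breaks = u_breaks, v_breaks = v_breaks,
                 cells = cells),
            class = "roi_array")
}

#' @export
print.roi_array <- function(x, ...) {
  cat(sprintf("ROI array '%s': %d x %d cells (%d ROIs)\n",
              x$plate, x$n_rows, x$n_cols, length(x$cells)))
  invisible(x)
}

#' Move grid separator lines
#'
#' Shifts interior row/column separator lines by pixel amounts and rebuilds
#' the cells. Interior lines are indexed 1 to `n - 1` (the plate borders are
#' fixed by the quad); moves that break the strict ordering of lines are an
#' error.
#'
#' @param rois A `roi_array` (must carry grid breaks, i.e. built by
#'   [roi_array()] / [detect_grid()] or loaded from a grid-shaped XML).
#' @param line_moves A data frame with columns `axis` (`"row"` or `"col"`),
#'   `index` (line number) and `delta_px` (signed shift in pixels).
#' @return A rebuilt `roi_array`.
#' @export
edit_grid <- function(rois, line_moves) {
  stopifnot(inherits(rois, "roi_array"))
  u <- rois$u_breaks; v <- rois$v_breaks
  if (is.null(u) || is.null(v)) stop("this roi_array does not carry grid breaks")
  ext_u <- sqrt(sum((rois$quad[2, ] - rois$quad[1, ])^2))
  ext_v <- sqrt(sum((rois$quad[4, ] - rois$quad[1, ])^2))
  if (nrow(line_moves %||% data.frame()) > 0) {
    for (i in seq_len(nrow(line_moves))) {
      ax <- line_moves$axis[i]; j <- line_moves$index[i] + 1L
      d <- line_moves$delta_px[i]
      if (ax == "col") {
        if (j < 2 || j > length(u) - 1) stop("column line index out of range (interior lines only)")
        u[j] <- u[j] + d / ext_u
      } else if (ax == "row") {
        if (j < 2 || j > length(v) - 1) stop("row line index out of range (interior lines only)")
        v[j] <- v[j] + d / ext_v
      } else stop("axis must be 'row' or 'col'")
    }
  }
  if (any(diff(u) <= 0) || any(diff(v) <= 0))
    stop("line moves violate the strict ordering of separator lines")
  # re-anchor so breaks still span [0, 1] exactly when borders were not moved
  roi_array(rois$quad, u, v, plate = rois$plate)
}

#' Save a ROI array as XML
#'
#' Schema: root `<roiarray plate="" rows="" cols="">` containing one
#' `<roi id="" name="">` element per cell with four `<pt x="" y=""/>`
#' children; coordinates are written with 2 decimal places.
#'
#' @param rois A `roi_array`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_array"))
  doc <- xml2::xml_new_root("roiarray", plate = rois$plate,
                            rows = as.character(rois$n_rows),
                            cols = as.character(rois$n_cols))
  for (cell in rois$cells) {
    node <- xml2::xml_add_child(doc, "roi", id = as.character(cell$id),
                                name = cell$name)
    for (i in 1:4)
      xml2::xml_add_child(node, "pt",
                          x = sprintf("%.2f", cell$poly[i, 1]),
                          y = sprintf("%.2f", cell$poly[i, 2]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Load a ROI array from XML
#'
#' Reads the schema written by [save_rois()]. For grid-shaped arrays the
#' enclosing quad and the fractional breaks are reconstructed from the cell
#' corners so that the result supports [edit_grid()].
#'
#' @param path XML file path.
#' @return A `roi_array`.
#' @export
load_rois <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed ROI XML: ", conditionMessage(e)))
  root <- xml2::xml_find_first(doc, "/roiarray")
  if (is.na(xml2::xml_name(root)) || xml2::xml_name(root) != "roiarray")
    stop("malformed ROI XML: missing <roiarray> root")
  n_rows <- as.integer(xml2::xml_attr(root, "rows"))
  n_cols <- as.integer(xml2::xml_attr(root, "cols"))
  plate <- xml2::xml_attr(root, "plate")
  rois_xml <- xml2::xml_find_all(root, "roi")
  if (length(rois_xml) != n_rows * n_cols)
    stop(sprintf("malformed ROI XML: %d <roi> elements for a %d x %d grid",
                 length(rois_xml), n_rows, n_cols))
  cells <- lapply(rois_xml, function(node) {
    pts <- xml2::xml_find_all(node, "pt")
    if (length(pts) != 4) stop("malformed ROI XML: each <roi> needs 4 <pt>")
    poly <- cbind(x = as.numeric(xml2::xml_attr(pts, "x")),
                  y = as.numeric(xml2::xml_attr(pts, "y")))
    list(id = as.integer(xml2::xml_attr(node, "id")),
         name = xml2::xml_attr(node, "name"), poly = poly)
  })
  ids <- vapply(cells, `[[`, integer(1), "id")
  if (anyDuplicated(ids)) stop("malformed ROI XML: duplicate ROI ids")
  # reconstruct grid structure (cells are written row-major)
  first_row <- cells[seq_len(n_cols)]
  left_col <- cells[1 + (seq_len(n_rows) - 1) * n_cols]
  quad <- parallelogram(rbind(cells[[1]]$poly[1, ],
                              first_row[[n_cols]]$poly[2, ],
                              cells[[n_rows * n_cols]]$poly[3, ],
                              left_col[[n_rows]]$poly[4, ]))
  ext_u <- sqrt(sum((quad[2, ] - quad[1, ])^2))
  ext_v <- sqrt(sum((quad[4, ] - quad[1, ])^2))
  u_breaks <- c(0, vapply(first_row, function(cl)
    sqrt(sum((cl$poly[2, ] - quad[1, ])^2)) / ext_u, numeric(1)))
  u_breaks[length(u_breaks)] <- 1
  v_breaks <- c(0, vapply(left_col, function(cl)
    sqrt(sum((cl$poly[4, ] - quad[1, ])^2)) / ext_v, numeric(1)))
  v_breaks[length(v_breaks)] <- 1
  out <- structure(list(plate = plate, n_rows = n_rows, n_cols = n_cols,
                        quad = quad, u_breaks = u_breaks, v_breaks = v_breaks,
                        cells = cells),
                   class = "roi_array")
  out
}

# Map every pixel center to its owning cell's position in rois$cells:
# integer matrix (h x w), 0 = no cell. Pixel (row i, col j) has center
# (j - 0.5, i - 0.5) in the 0-based continuous frame used by the polygons.
# Half-open membership is realised by nudging the test point by +1e-6 in x
# and y, so a center on a shared edge is claimed by exactly one adjacent
# cell.
roi_index_map <- function(rois, width, height) {
  stopifnot(inherits(rois, "roi_array"))
  map <- matrix(0L, nrow = height, ncol = width)
  eps <- 1e-6
  for (pos in seq_along(rois$cells)) {
    cell <- rois$cells[[pos]]
    poly <- cell$poly
    if (any(poly[, 1] < -1e-9 | poly[, 1] > width + 1e-9 |
            poly[, 2] < -1e-9 | poly[, 2] > height + 1e-9))
      stop(sprintf("ROI %s extends outside the frame", cell$name))
    jr <- max(1L, floor(min(poly[, 1]) + 0.5)):min(width, ceiling(max(poly[, 1]) + 0.5))
    ir <- max(1L, floor(min(poly[, 2]) + 0.5)):min(height, ceiling(max(poly[, 2]) + 0.5))
    cx <- rep(jr - 0.5 + eps, each = length(ir))
    cy <- rep(ir - 0.5 + eps, times = length(jr))
    inside <- rep(TRUE, length(cx))
    for (e in 1:4) {
      a <- poly[e, ]; b <- poly[if (e == 4) 1 else e + 1, ]
      cross <- (b[1] - a[1]) * (cy - a[2]) - (b[2] - a[2]) * (cx - a[1])
      inside <- inside & (cross > 0)
    }
    if (any(inside)) {
      ii <- rep(ir, times = length(jr))[inside]
      jj <- rep(jr, each = length(ir))[inside]
      map[cbind(ii, jj)] <- pos
    }
  }
  map
}
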