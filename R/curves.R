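# Standardized consumption curves: per-cage fraction of intact leaf disk
# versus time, cleaned, truncated at tmax and joined with experiment
# metadata.

#' Cage metadata
#'
#' Identifies one cage: treatment label i (substance + concentration),
#' batch j (date string), plate k (camera + position, e.g. `"Cam02-L"`) and
#' cage l (ROI name), plus free-form experiment fields.
#'
#' @param treatment,batch,plate,cage Identification labels.
#' @param ... Further fields (date, camera, insect population, plant
#'   genotype, ...), stored as-is.
#' @return A `cage_metadata` list.
#' @export
cage_metadata <- function(treatment = NA_character_, batch = NA_character_,
                          plate = NA_character_, cage = NA_character_, ...) {
  structure(list(treatment = treatment, batch = batch, plate = plate,
                 cage = cage, ...),
            class = "cage_metadata")
}

#' Construct a consumption curve
#'
#' @param time Minutes since the first retained frame (strictly
#'   increasing, starting at 0).
#' @param fraction_intact Fraction of the initial leaf disk remaining at
#'   each time (may transiently exceed 1 under noise; not clipped).
#' @param meta Optional [cage_metadata()].
#' @param flag Quality flag: `"ok"`, `"flagged"` or `"excluded"`.
#' @param note Free-text note (e.g. exclusion reason).
#' @return A `consumption_curve`.
#' @export
consumption_curve <- function(time, fraction_intact, meta = NULL,
                              flag = "ok", note = NA_character_) {
  stopifnot(length(time) == length(fraction_intact))
  if (length(time) > 1 && any(diff(time) <= 0)) stop("time must be strictly increasing")
  structure(list(time = time, fraction_intact = fraction_intact,
                 meta = meta %||% cage_metadata(), flag = flag, note = note),
            class = "consumption_curve")
}

#' @export
print.consumption_curve <- function(x, ...) {
  cat(sprintf("consumption_curve [%s]: %d points, t in [%g, %g] min, final fraction %.3f\n",
              x$flag, length(x$time), min(x$time), max(x$time),
              x$fraction_intact[length(x$fraction_intact)]))
  invisible(x)
}

#' Standardize area series into consumption curves
#'
#' Divides the leaf area at each time by the area at t0 (the first retained
#' time point). The denominator is always taken from the median-smoothed
#' series, so a single-frame artifact cannot define the scale. A cage whose
#' disk is already absent at t0 (denominator 0) is returned as an excluded
#' curve with an `"empty-at-start"` note.
#'
#' @param series An `area_series` (see [measure_stack()]).
#' @param source Which series the curve tracks: `"med"` (default),
#'   `"avg"` or `"raw"`.
#' @param batch,plate Labels attached to every curve's metadata.
#' @return A named list of `consumption_curve`s, one per ROI.
#' @export
standardize <- function(series, source = c("med", "avg", "raw"),
                        batch = NA_character_, plate = NULL) {
  stopifnot(inherits(series, "area_series"))
  source <- match.arg(source)
  plate <- plate %||% series$plate %||% NA_character_
  t0 <- series$time - series$time[1]
  out <- lapply(colnames(series$raw), function(nm) {
    denom <- series$med[1, nm]
    meta <- cage_metadata(batch = batch, plate = plate, cage = nm)
    if (denom <= 0)
      return(consumption_curve(t0, rep(NA_real_, length(t0)), meta = meta,
                               flag = "excluded", note = "empty-at-start"))
    consumption_curve(t0, series[[source]][, nm] / denom, meta = meta)
  })
  names(out) <- colnames(series$raw)
  out
}

#' Truncate a consumption curve at tmax
#'
#' Drops all samples with `t >= tmax` (only data strictly before `tmax` are
#' retained). Idempotent.
#'
#' @param curve A `consumption_curve`.
#' @param tmax Truncation horizon in minutes (default 2500 = 40 h).
#' @return The truncated curve.
#' @export
truncate_curve <- function(curve, tmax = 2500) {
  stopifnot(inherits(curve, "consumption_curve"))
  keep <- curve$time < tmax
  if (!any(keep)) stop("curve empty after truncation at tmax = ", tmax)
  curve$time <- curve$time[keep]
  curve$fraction_intact <- curve$fraction_intact[keep]
  curve
}

#' Flag anomalous consumption curves
#'
#' Advisory quality control for curves distorted by non-feeding events
#' (leaf rolling onto itself, a disk pushed by the larva): after a running
#' median over `smooth_n` samples (so isolated noise never triggers), a
#' curve is flagged if any single step changes by more than `jump_tol`, or
#' if the curve rises more than `rise_tol` above its running minimum (leaf
#' area cannot regrow). Exclusion remains a user decision; the flag is
#' stored on the curve.
#'
#' @param curve A standardized `consumption_curve`.
#' @param jump_tol Maximum tolerated single-step |change| in fraction.
#' @param rise_tol Maximum tolerated rise above the running minimum.
#' @param smooth_n Running-median window applied before the checks.
#' @return The curve with its `flag` set to `"ok"` or `"flagged"`.
#' @export
flag_anomalies <- function(curve, jump_tol = 0.15, rise_tol = 0.10,
                           smooth_n = 9) {
  stopifnot(inherits(curve, "consumption_curve"))
  if (curve$flag == "excluded") return(curve)
  f <- stats_window(curve$fraction_intact, smooth_n, stats::median)
  bad <- (length(f) > 1 && any(abs(diff(f)) > jump_tol)) ||
    any(f - cummin(f) > rise_tol)
  curve$flag <- if (bad) "flagged" else "ok"
  curve
}

#' Join curves with the experiment metadata table
#'
#' Matches each curve's (batch, plate) against the metadata table and fills
#' in the treatment and any further fields. Every curve must match exactly
#' one row.
#'
#' @param curves A list of `consumption_curve`s.
#' @param metadata A data frame with at least columns `batch`, `plate`,
#'   `treatment` (further columns are carried into the curve metadata).
#' @return The curves with completed metadata.
#' @export
join_metadata <- function(curves, metadata) {
  req <- c("batch", "plate", "treatment")
  if (!all(req %in% names(metadata)))
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  key <- paste(metadata$batch, metadata$plate, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate (batch, plate) rows in metadata: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  curve_keys <- vapply(curves, function(cv)
    paste(cv$meta$batch, cv$meta$plate, sep = "/"), character(1))
  missing <- setdiff(unique(curve_keys), key)
  if (length(missing) > 0)
    stop("no metadata row for plate(s): ", paste(missing, collapse = ", "))
  idx <- match(curve_keys, key)
  extra <- setdiff(names(metadata), c("batch", "plate"))
  for (i in seq_along(curves)) {
    row <- metadata[idx[i], ]
    for (fld in extra) curves[[i]]$meta[[fld]] <- row[[fld]]
  }
  curves
}

#' Interpolate curves onto a common time grid
#'
#' Linear interpolation (constant extrapolation at the ends) of each
#' curve's fraction-intact onto `grid`; excluded curves are dropped.
#'
#' @param curves A list of `consumption_curve`s.
#' @param grid Common time grid in minutes (default 0-2490 by 10: 250
#'   points covering the standard 2500-min horizon).
#' @return A numeric matrix, one row per retained curve (named by cage
#'   metadata `batch/plate/cage`), one column per grid point.
#' @export
curve_matrix <- function(curves, grid = seq(0, 2490, by = 10)) {
  keep <- vapply(curves, function(cv) cv$flag != "excluded", logical(1))
  curves <- curves[keep]
  if (length(curves) == 0) stop("no non-excluded curves")
  m <- t(vapply(curves, function(cv)
    stats::approx(cv$time, cv$fraction_intact, xout = grid, rule = 2)$y,
    numeric(length(grid))))
  rownames(m) <- vapply(curves, function(cv)
    paste(cv$meta$batch, cv$meta$plate, cv$meta$cage, sep = "/"), character(1))
  m
}

#' Write / read consumption curves as CSV
#'
#' Long format: one row per (curve, time) with the identifying metadata.
#'
#' @param curves A list of `consumption_curve`s.
#' @param path CSV path.
#' @return `path` invisibly (write); a curve list (read).
#' @export
write_curves <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(batch = cv$meta$batch %||% NA, plate = cv$meta$plate %||% NA,
               cage = cv$meta$cage %||% NA,
               treatment = cv$meta$treatment %||% NA,
               flag = cv$flag, time = cv$time,
               fraction_intact = cv$fraction_intact)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path)
  sp <- split(df, paste(df$batch, df$plate, df$cage, sep = "/"))
  lapply(sp, function(d) {
    d <- d[order(d$time), ]
    consumption_curve(d$time, d$fraction_intact,
                      meta = cage_metadata(treatment = d$treatment[1],
                                           batch = as.character(d$batch[1]),
                                           plate = d$plate[1], cage = d$cage[1]),
                      flag = d$flag[1])
  })
}
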