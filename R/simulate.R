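# Ground-truthed synthetic data for every pipeline stage: behavioural
# archetype consumption curves (closed-form kinetics), rendered plate image
# stacks, and multinomial outcome samples.

#' Default behavioural archetype parameters
#'
#' Each of the six behavioural types A-F is emulated by delayed exponential
#' consumption kinetics: consumed(t) = c_total * (1 - exp(-(t - L) / tau))
#' for t >= L, where L is the latency before feeding starts (minutes), tau
#' the consumption time constant (minutes) and c_total the asymptotic total
#' consumed fraction. Type C feeds fast initially then slows: once the
#' consumed fraction reaches `slow_after`, the rate is multiplied by
#' `slow_factor`. The defaults realise the qualitative profiles: A immediate
#' and fast, B long wait then fast, C fast start then slowdown, D late and
#' slow, E very late and partial, F essentially no consumption.
#'
#' @return A named list (letters A-F) of parameter lists with elements
#'   `L`, `tau`, `c_total`, `slow_after`, `slow_factor`.
#' @export
archetype_params <- function() {
  list(
    A = list(L = 30,   tau = 200, c_total = 1.00, slow_after = NA,  slow_factor = NA),
    B = list(L = 900,  tau = 200, c_total = 1.00, slow_after = NA,  slow_factor = NA),
    C = list(L = 30,   tau = 150, c_total = 0.90, slow_after = 0.4, slow_factor = 0.15),
    D = list(L = 900,  tau = 700, c_total = 0.80, slow_after = NA,  slow_factor = NA),
    E = list(L = 1500, tau = 600, c_total = 0.60, slow_after = NA,  slow_factor = NA),
    F = list(L = 30,   tau = 200, c_total = 0.03, slow_after = NA,  slow_factor = NA)
  )
}

# Consumed fraction at time t (vectorized, noise-free).
consumed_at <- function(t, par) {
  base <- function(t) par$c_total * pmax(0, 1 - exp(-(t - par$L) / par$tau))
  if (is.na(par$slow_after)) return(base(t))
  # two-phase: breakpoint where consumed reaches slow_after (absolute
  # fraction of the disk); afterwards the exponential rate is scaled.
  if (par$slow_after >= par$c_total) return(base(t))
  tb <- par$L - par$tau * log(1 - par$slow_after / par$c_total)
  k2 <- par$slow_factor / par$tau
  ifelse(t <= tb, base(t),
         par$c_total - (par$c_total - par$slow_after) * exp(-k2 * (t - tb)))
}

# Closed-form earliest time with consumed(t) = q; tmax if never reached.
time_to_consume <- function(q, par, tmax) {
  if (q <= 0) return(0)
  solve1 <- function(q) par$L - par$tau * log(1 - q / par$c_total)
  t <- if (q >= par$c_total) Inf
  else if (is.na(par$slow_after) || q <= par$slow_after || par$slow_after >= par$c_total) solve1(q)
  else {
    tb <- solve1(par$slow_after)
    k2 <- par$slow_factor / par$tau
    tb - log((par$c_total - q) / (par$c_total - par$slow_after)) / k2
  }
  if (t > tmax) tmax else t
}

#' Closed-form curve features of an archetype
#'
#' @param par One archetype parameter list (see [archetype_params()]).
#' @param tmax Truncation horizon in minutes.
#' @return A list with `t20`, `t50`, `t80` (capped at `tmax`) and
#'   `total_consumed` (consumed fraction at `tmax`).
#' @export
archetype_features <- function(par, tmax = 2500) {
  list(t20 = time_to_consume(0.2, par, tmax),
       t50 = time_to_consume(0.5, par, tmax),
       t80 = time_to_consume(0.8, par, tmax),
       total_consumed = consumed_at(tmax, par))
}

#' Simulate one consumption curve from a behavioural archetype
#'
#' fraction_intact(t) = 1 - consumed(t) plus i.i.d. Gaussian noise of
#' standard deviation `sigma`, clipped to `[0, 1.05]`.
#'
#' @param letter Archetype letter, `"A"` to `"F"`.
#' @param params Archetype parameter set, by default [archetype_params()].
#' @param tgrid Time grid in minutes.
#' @param sigma Noise standard deviation (fraction units).
#' @param seed Optional integer seed (local to this call).
#' @param meta Optional [cage_metadata()] attached to the curve.
#' @return A `consumption_curve` with an extra `true_features` element
#'   (closed-form, noise-free) and `true_letter`.
#' @export
simulate_curve <- function(letter, params = archetype_params(),
                           tgrid = seq(0, 2490, by = 10), sigma = 0.02,
                           seed = NULL, meta = NULL) {
  if (!letter %in% names(params)) stop("unknown archetype letter: ", letter)
  par <- params[[letter]]
  with_seed(seed, {
    frac <- 1 - consumed_at(tgrid, par)
    if (sigma > 0) frac <- frac + stats::rnorm(length(tgrid), 0, sigma)
    frac <- clamp(frac, 0, 1.05)
    curve <- consumption_curve(time = tgrid, fraction_intact = frac, meta = meta)
    curve$true_features <- archetype_features(par, tmax = max(tgrid) + diff(tgrid)[1])
    curve$true_letter <- letter
    curve
  })
}

#' Simulate a set of archetype curves
#'
#' @param letters Character vector of archetype letters, one per curve.
#' @param seed Integer seed; curve i uses `seed + i` internally.
#' @inheritParams simulate_curve
#' @return A list of `consumption_curve`s.
#' @export
simulate_curve_set <- function(letters, params = archetype_params(),
                               tgrid = seq(0, 2490, by = 10), sigma = 0.02,
                               seed = 1) {
  lapply(seq_along(letters), function(i)
    simulate_curve(letters[i], params, tgrid, sigma, seed = seed + i))
}

#' Rendering parameters for synthetic plate stacks
#'
#' Geometry mirrors the physical plates (a rows x cols array of square
#' cages separated by thin walls, imaged from below through the agar), at a
#' reduced pixel scale suitable for tests.
#'
#' @param rows,cols Cage grid shape.
#' @param cell_px Cage interior size in pixels.
#' @param wall_px Wall width in pixels.
#' @param margin_px Background margin around the plate.
#' @param disk_r Initial leaf-disk radius in pixels (must fit the cage).
#' @param leaf_rgb,leaf_sd Leaf colour mean (RGB, 0-255) and per-pixel sd.
#' @param agar_rgb Cage interior (agar over the light panel) colour.
#' @param wall_rgb,bg_rgb Wall and outside-background colours.
#' @param illum_amp Amplitude of a horizontal illumination ramp (added,
#'   intensity units peak-to-peak / 2).
#' @param noise_sd Per-pixel Gaussian noise sd (intensity units).
#' @param blob_rate Per-frame probability of one dark occluding blob (a
#'   larva crossing a disk), present in single frames only.
#' @param cadence_min Minutes between frames.
#' @param n_frames Number of frames to render.
#' @param seed Integer seed.
#' @return A `render_params` list.
#' @export
render_params <- function(rows = 5, cols = 10, cell_px = 55, wall_px = 4,
                          margin_px = 10, disk_r = 22,
                          leaf_rgb = c(70, 150, 70), leaf_sd = 6,
                          agar_rgb = c(210, 222, 210),
                          wall_rgb = c(250, 250, 250),
                          bg_rgb = c(235, 235, 235),
                          illum_amp = 6, noise_sd = 0, blob_rate = 0,
                          cadence_min = 1, n_frames = 10, seed = 1) {
  if (2 * disk_r + 2 > cell_px) stop("disk does not fit the cage")
  structure(as.list(environment()), class = "render_params")
}

# Pixel-edge coordinates of the interior wall centers, as offsets from the
# plate's top-left corner along each axis.
wall_offsets <- function(rp, n) {
  pitch <- rp$cell_px + rp$wall_px
  (seq_len(n - 1)) * pitch + rp$wall_px / 2
}

#' Render a synthetic plate image stack with ground truth
#'
#' Draws the plate (walls, agar-filled cages) and one green leaf disk per
#' cage whose pixel area tracks the cage's `fraction_intact` exactly: the
#' disk's pixels are eaten from the rim inward as an angular sweep, and the
#' ground-truth area is the count of remaining mask pixels. Optional
#' illumination gradient, pixel noise, and rare single-frame dark blobs.
#' Frames are written as PNG.
#'
#' @param rp A [render_params()] object.
#' @param fractions A matrix (n_frames x n_cages, cages row-major by cage
#'   grid position) of fraction-intact values, or a list of
#'   `consumption_curve`s (sampled at the frame times).
#' @param out_dir Directory for the frame files (created if needed).
#' @return A list: `frames` (file paths), `truth` (data frame `frame`,
#'   `cage`, `area_px`), `quad` (plate [parallelogram()]), `row_offsets`
#'   and `col_offsets` (ground-truth interior separator offsets in px from
#'   the plate corner), `initial_area` (full-disk pixel count), `rois`
#'   (ground-truth `roi_array`).
#' @export
render_plate_stack <- function(rp, fractions, out_dir) {
  stopifnot(inherits(rp, "render_params"))
  n_cage <- rp$rows * rp$cols
  if (is.list(fractions) && !is.matrix(fractions)) {
    times <- (seq_len(rp$n_frames) - 1) * rp$cadence_min
    fractions <- vapply(fractions, function(cv)
      stats::approx(cv$time, cv$fraction_intact, xout = times, rule = 2)$y,
      numeric(rp$n_frames))
    if (!is.matrix(fractions)) fractions <- matrix(fractions, nrow = rp$n_frames)
  }
  if (ncol(fractions) != n_cage)
    stop(sprintf("need one curve per cage (%d), got %d", n_cage, ncol(fractions)))
  if (nrow(fractions) != rp$n_frames) stop("fractions rows must equal n_frames")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pitch <- rp$cell_px + rp$wall_px
  plate_w <- rp$cols * pitch + rp$wall_px
  plate_h <- rp$rows * pitch + rp$wall_px
  W <- plate_w + 2 * rp$margin_px
  H <- plate_h + 2 * rp$margin_px
  m <- rp$margin_px

  with_seed(rp$seed, {
    # static base image (H x W x 3)
    base <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) base[, , ch] <- rp$bg_rgb[ch]
    px_x <- m; px_y <- m
    for (ch in 1:3) base[(px_y + 1):(px_y + plate_h), (px_x + 1):(px_x + plate_w), ch] <- rp$wall_rgb[ch]
    cage_box <- vector("list", n_cage)
    k <- 0L
    for (r in seq_len(rp$rows)) for (cc in seq_len(rp$cols)) {
      k <- k + 1L
      x0 <- px_x + rp$wall_px + (cc - 1) * pitch
      y0 <- px_y + rp$wall_px + (r - 1) * pitch
      cage_box[[k]] <- c(x0, y0)
      for (ch in 1:3)
        base[(y0 + 1):(y0 + rp$cell_px), (x0 + 1):(x0 + rp$cell_px), ch] <- rp$agar_rgb[ch]
    }

    # per-cage disk pixel lists in bite (angular sweep) order
    disk_px <- vector("list", n_cage)
    disk_col <- vector("list", n_cage)
    for (k in seq_len(n_cage)) {
      cx <- cage_box[[k]][1] + rp$cell_px / 2
      cy <- cage_box[[k]][2] + rp$cell_px / 2
      jr <- floor(cx - rp$disk_r):ceiling(cx + rp$disk_r)
      ir <- floor(cy - rp$disk_r):ceiling(cy + rp$disk_r)
      gx <- rep(jr, each = length(ir)) + 0.5
      gy <- rep(ir, times = length(jr)) + 0.5
      inside <- (gx - cx)^2 + (gy - cy)^2 <= rp$disk_r^2
      px <- cbind(row = rep(ir, times = length(jr))[inside] + 1L,
                  col = rep(jr, each = length(ir))[inside] + 1L)
      theta0 <- stats::runif(1, 0, 2 * pi)
      ang <- (atan2(gy[inside] - cy, gx[inside] - cx) - theta0) %% (2 * pi)
      ord <- order(ang)
      disk_px[[k]] <- px[ord, , drop = FALSE]
      np <- sum(inside)
      disk_col[[k]] <- cbind(
        clamp(stats::rnorm(np, rp$leaf_rgb[1], rp$leaf_sd), 0, 255),
        clamp(stats::rnorm(np, rp$leaf_rgb[2], rp$leaf_sd), 0, 255),
        clamp(stats::rnorm(np, rp$leaf_rgb[3], rp$leaf_sd), 0, 255))[ord, , drop = FALSE]
    }
    A0 <- nrow(disk_px[[1]])

    ramp <- rp$illum_amp * (2 * (seq_len(W) - 1) / (W - 1) - 1)
    ramp_img <- matrix(ramp, nrow = H, ncol = W, byrow = TRUE)

    cage_names <- unlist(lapply(seq_len(rp$rows), function(r)
      sprintf("R%02dC%02d", r, seq_len(rp$cols))))
    frames <- character(rp$n_frames)
    truth <- vector("list", rp$n_frames)
    for (f in seq_len(rp$n_frames)) {
      img <- base
      areas <- integer(n_cage)
      for (k in seq_len(n_cage)) {
        n_keep <- max(0L, min(A0, round(fractions[f, k] * A0)))
        areas[k] <- n_keep
        if (n_keep > 0) {
          keep <- seq((A0 - n_keep) + 1L, A0)   # sweep eats from the start of the order
          idx <- disk_px[[k]][keep, , drop = FALSE]
          for (ch in 1:3) {
            lin <- cbind(idx, ch)
            img[lin] <- disk_col[[k]][keep, ch]
          }
        }
      }
      for (ch in 1:3) img[, , ch] <- img[, , ch] + ramp_img
      if (rp$noise_sd > 0)
        img <- img + array(stats::rnorm(H * W * 3, 0, rp$noise_sd), dim = c(H, W, 3))
      if (rp$blob_rate > 0 && stats::runif(1) < rp$blob_rate) {
        k <- sample.int(n_cage, 1)
        bx <- cage_box[[k]][1] + stats::runif(1, 10, rp$cell_px - 10)
        by <- cage_box[[k]][2] + stats::runif(1, 10, rp$cell_px - 10)
        jr <- floor(bx - 9):ceiling(bx + 9)
        ir <- floor(by - 6):ceiling(by + 6)
        gx <- rep(jr, each = length(ir)) + 0.5
        gy <- rep(ir, times = length(jr)) + 0.5
        inside <- ((gx - bx) / 9)^2 + ((gy - by) / 5)^2 <= 1
        idx <- cbind(rep(ir, times = length(jr))[inside] + 1L,
                     rep(jr, each = length(ir))[inside] + 1L)
        for (ch in 1:3) img[cbind(idx, ch)] <- 45
      }
      img <- clamp(img, 0, 255)
      frames[f] <- file.path(out_dir, sprintf("frame_%05d.png", f))
      png::writePNG(img / 255, frames[f])
      truth[[f]] <- data.frame(frame = f, cage = cage_names, area_px = areas)
    }

    quad <- parallelogram(rbind(c(m, m), c(m + plate_w, m),
                                c(m + plate_w, m + plate_h), c(m, m + plate_h)))
    col_off <- wall_offsets(rp, rp$cols)
    row_off <- wall_offsets(rp, rp$rows)
    rois <- roi_array(quad,
                      u_breaks = c(0, col_off / plate_w, 1),
                      v_breaks = c(0, row_off / plate_h, 1),
                      plate = "synthetic")
    list(frames = frames, truth = do.call(rbind, truth), quad = quad,
         row_offsets = row_off, col_offsets = col_off,
         initial_area = A0, rois = rois,
         leaf_mask_threshold = NULL)
  })
}

#' Rotate a rendered frame and its quad
#'
#' Rotates the image by `angle_deg` about its center (bilinear resampling,
#' background fill) and returns the correspondingly rotated quad; used to
#' exercise grid detection on tilted plates.
#'
#' @param img H x W x 3 array (0-255).
#' @param quad A [parallelogram()] in the frame.
#' @param angle_deg Rotation angle, degrees (counterclockwise on screen).
#' @param fill Background fill value per channel.
#' @return A list `img`, `quad`.
#' @export
rotate_frame <- function(img, quad, angle_deg, fill = c(235, 235, 235)) {
  h <- dim(img)[1]; w <- dim(img)[2]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, byrow = TRUE)
  out <- array(0, dim = dim(img))
  gx <- rep(seq_len(w) - 1, each = h) - cx
  gy <- rep(seq_len(h) - 1, times = w) - cy
  # inverse map: source = R^{-1} (dest - c) + c ; R^{-1} = R(-th)
  sx <- cos(th) * gx + sin(th) * gy + cx
  sy <- -sin(th) * gx + cos(th) * gy + cy
  ok <- sx >= 0 & sx <= w - 1 & sy >= 0 & sy <= h - 1
  for (ch in 1:3) {
    plane <- matrix(fill[ch], nrow = h, ncol = w)
    vals <- bilinear_sample(img[, , ch], sx[ok], sy[ok])
    plane[cbind(rep(seq_len(h), times = w)[ok], rep(seq_len(w), each = h)[ok])] <- vals
    out[, , ch] <- plane
  }
  qc <- sweep(unclass(quad), 2, c(cx, cy))
  q2 <- t(R %*% t(qc))
  q2 <- sweep(q2, 2, c(cx, cy), `+`)
  list(img = out, quad = parallelogram(q2))
}

#' Sample multinomial cage outcomes
#'
#' Draws one behavioural-type outcome per cage from per-treatment
#' probability rows.
#'
#' @param prob_table Numeric matrix, one row per treatment (rownames used
#'   as treatment labels), columns the types A-F; each row must be
#'   non-negative and sum to 1.
#' @param n_per_treatment Cages per treatment (scalar or per-row vector).
#' @param seed Optional integer seed.
#' @param n_plates_per_treatment Plates the cages are spread over (labels
#'   only).
#' @return A data frame `treatment`, `plate`, `cage`, `letter`.
#' @export
simulate_outcomes <- function(prob_table, n_per_treatment, seed = NULL,
                              n_plates_per_treatment = 2) {
  prob_table <- as.matrix(prob_table)
  if (any(prob_table < 0) || any(abs(rowSums(prob_table) - 1) > 1e-8))
    stop("probability rows must be non-negative and sum to 1")
  types <- colnames(prob_table) %||% LETTERS[seq_len(ncol(prob_table))]
  trt <- rownames(prob_table) %||% paste0("T", seq_len(nrow(prob_table)))
  n <- rep_len(n_per_treatment, nrow(prob_table))
  with_seed(seed, {
    out <- lapply(seq_len(nrow(prob_table)), function(i) {
      letters_i <- sample(types, n[i], replace = TRUE, prob = prob_table[i, ])
      data.frame(treatment = trt[i],
                 plate = paste0(trt[i], "-P",
                                rep_len(seq_len(n_plates_per_treatment), n[i])),
                 cage = sprintf("C%04d", seq_len(n[i])),
                 letter = letters_i)
    })
    do.call(rbind, out)
  })
}
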