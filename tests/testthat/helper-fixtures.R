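# Shared fixtures, all generated in code.

# Small rendered plate stack, memoised per test run (rendering is cheap but
# used by several files).
local_plate <- local({
  cache <- new.env()
  function(rows = 2, cols = 3, n_frames = 5, seed = 3, noise_sd = 0,
           blob_rate = 0, sigma = 0, letters = NULL, cadence_min = 60) {
    key <- paste(rows, cols, n_frames, seed, noise_sd, blob_rate, sigma,
                 cadence_min, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_cage <- rows * cols
    letters <- letters %||% rep(c("A", "C", "D"), length.out = n_cage)
    tg <- seq(0, (n_frames - 1) * cadence_min, by = cadence_min)
    if (length(tg) < 2) tg <- c(0, cadence_min)
    cvs <- simulate_curve_set(letters, seed = seed, sigma = sigma, tgrid = tg)
    rp <- render_params(rows = rows, cols = cols, n_frames = n_frames,
                        seed = seed, noise_sd = noise_sd, margin_px = 40,
                        blob_rate = blob_rate, cadence_min = cadence_min)
    res <- render_plate_stack(rp, cvs, file.path(tempdir(), paste0("plate_", key)))
    cache[[key]] <- res
    res
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force oracle: population variance of bilinearly sampled pixels
# along the line p -> q at unit steps (independent re-implementation).
brute_line_variance <- function(img, p, q) {
  len <- sqrt(sum((q - p)^2))
  vals <- numeric(floor(len) + 1)
  for (s in 0:floor(len)) {
    t <- s / len
    x <- p[1] + t * (q[1] - p[1]); y <- p[2] + t * (q[2] - p[2])
    x0 <- floor(x); y0 <- floor(y)
    x1 <- min(x0 + 1, ncol(img) - 1); y1 <- min(y0 + 1, nrow(img) - 1)
    fx <- x - x0; fy <- y - y0
    vals[s + 1] <-
      (1 - fy) * ((1 - fx) * img[y0 + 1, x0 + 1] + fx * img[y0 + 1, x1 + 1]) +
      fy * ((1 - fx) * img[y1 + 1, x0 + 1] + fx * img[y1 + 1, x1 + 1])
  }
  mean((vals - mean(vals))^2)
}

# Brute-force oracle: per-ROI count of accepted pixels by an explicit
# per-pixel / per-polygon-edge double loop (same half-open convention:
# pixel center nudged by +1e-6 must be strictly inside).
brute_count <- function(accepted, rois) {
  counts <- integer(length(rois$cells))
  names(counts) <- vapply(rois$cells, `[[`, character(1), "name")
  for (i in seq_len(nrow(accepted))) {
    for (j in seq_len(ncol(accepted))) {
      if (!accepted[i, j]) next
      px <- j - 0.5 + 1e-6; py <- i - 0.5 + 1e-6
      for (k in seq_along(rois$cells)) {
        poly <- rois$cells[[k]]$poly
        ok <- TRUE
        for (e in 1:4) {
          a <- poly[e, ]; b <- poly[if (e == 4) 1 else e + 1, ]
          if ((b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1]) <= 0) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          counts[k] <- counts[k] + 1L
          break
        }
      }
    }
  }
  counts
}

# Exhaustive minimum within-group-sum-of-squares partition of the rows of
# z into k non-empty groups (canonical-form recursion; feasible to ~10 rows).
brute_kmeans <- function(z, k) {
  n <- nrow(z)
  best <- list(wss = Inf, assign = NULL)
  rec <- function(i, assign, used) {
    if (i > n) {
      if (used == k) {
        wss <- 0
        for (g in seq_len(k)) {
          m <- z[assign == g, , drop = FALSE]
          wss <- wss + sum(sweep(m, 2, colMeans(m))^2)
        }
        if (wss < best$wss) best <<- list(wss = wss, assign = assign)
      }
      return(invisible())
    }
    for (g in seq_len(min(used + 1, k))) {
      assign[i] <- g
      rec(i + 1, assign, max(used, g))
    }
  }
  rec(1, integer(n), 0L)
  best
}

# Simple simulated treatment data frame for the stats tests.
sim_outcome_df <- function(probs, n, seed) {
  simulate_outcomes(probs, n, seed = seed)
}
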