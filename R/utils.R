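# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed so seeded package functions do not perturb the
# session RNG stream. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Centered moving average, window truncated at the edges.
moving_average <- function(x, n) {
  if (n <= 1) return(x)
  stats_window(x, n, mean)
}

stats_window <- function(x, n, fun) {
  m <- length(x)
  hl <- floor((n - 1) / 2)
  hr <- n - 1 - hl
  vapply(seq_len(m), function(i) {
    fun(x[max(1, i - hl):min(m, i + hr)])
  }, numeric(1))
}

# Population variance (divides by N, not N-1).
pop_var <- function(x) mean((x - mean(x))^2)

# Bilinear interpolation of a numeric matrix at continuous (x, y),
# 0-based coordinates: value at integer (x, y) is img[y + 1, x + 1].
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  if (any(x < 0 | x > w - 1 | y < 0 | y > h - 1))
    stop("sample coordinates outside image bounds", call. = FALSE)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x1 + 1)]
  i10 <- img[cbind(y1 + 1, x0 + 1)]
  i11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Collapse an RGB array (H x W x 3) to grayscale by channel mean;
# pass matrices through unchanged.
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3) return((img[, , 1] + img[, , 2] + img[, , 3]) / 3)
  stop("expected a matrix or an H x W x 3 array", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
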