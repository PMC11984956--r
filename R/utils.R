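# Internal helpers shared across modules.

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

fwhm_to_sigma <- function(fwhm) fwhm / FWHM_PER_SIGMA

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) abort(sprintf("`%s` must be > %g.", name, min))
  if (!strict_min && x < min) abort(sprintf("`%s` must be >= %g.", name, min))
  if (x > max) abort(sprintf("`%s` must be <= %g.", name, max))
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single integer.", name))
  }
  if (x < min) abort(sprintf("`%s` must be >= %d.", name, min))
  invisible(as.integer(x))
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# ---- image field container ---------------------------------------------------

#' Construct a multi-channel image field
#'
#' A light container for a multi-channel 2D raster: a numeric array of
#' dimension `c(nx, ny, n_channels)` carrying its physical pixel size in
#' nanometres and channel names. All image pipelines in the package consume
#' and produce this type.
#'
#' @param data Numeric matrix (single channel) or 3D array `[x, y, channel]`.
#' @param pixel_size_nm Physical pixel size in nanometres (> 0).
#' @param channels Character vector of channel names, one per channel slab.
#' @return An `image_field` object.
#' @export
image_field <- function(data, pixel_size_nm, channels = NULL) {
  check_number(pixel_size_nm, "pixel_size_nm", min = 0, strict_min = TRUE)
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L) abort("`data` must be a matrix or 3D array.")
  channels <- channels %||% paste0("ch", seq_len(dim(data)[3L]))
  if (length(channels) != dim(data)[3L]) {
    abort("`channels` length must match the number of channel slabs.")
  }
  dimnames(data) <- list(NULL, NULL, channels)
  structure(list(data = data, pixel_size_nm = pixel_size_nm),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_field> %d x %d px, %g nm/px, channels: %s\n",
              d[1], d[2], x$pixel_size_nm,
              paste(dimnames(x$data)[[3]], collapse = ", ")))
  invisible(x)
}

#' Extract one channel of an image field as a matrix
#'
#' @param field An [image_field()].
#' @param channel Channel name or index.
#' @return Numeric matrix.
#' @export
field_channel <- function(field, channel = 1L) {
  stopifnot(inherits(field, "image_field"))
  if (is.character(channel) && !channel %in% dimnames(field$data)[[3]]) {
    abort(sprintf("channel '%s' not present in field.", channel))
  }
  field$data[, , channel]
}

n_channels <- function(field) dim(field$data)[3L]

# Render mass-normalised Gaussian spots into an nx x ny matrix.
# `amplitude` is the total integrated intensity of each spot, so the rendered
# pixel sum approaches `amplitude` for spots away from the border.
render_spots <- function(nx, ny, x_px, y_px, amplitude, sigma_px) {
  img <- matrix(0, nx, ny)
  if (length(x_px) == 0L) return(img)
  half <- ceiling(5 * max(sigma_px))
  sigma_px <- rep_len(sigma_px, length(x_px))
  for (i in seq_along(x_px)) {
    ix <- max(1L, floor(x_px[i] - half)):min(nx, ceiling(x_px[i] + half))
    iy <- max(1L, floor(y_px[i] - half)):min(ny, ceiling(y_px[i] + half))
    if (length(ix) == 0L || length(iy) == 0L) next
    gx <- dnorm(ix, mean = x_px[i], sd = sigma_px[i])
    gy <- dnorm(iy, mean = y_px[i], sd = sigma_px[i])
    img[ix, iy] <- img[ix, iy] + amplitude[i] * tcrossprod(gx, gy)
  }
  img
}

# Bilinear interpolation of matrix `img` at fractional pixel coords (x, y),
# 1-based; returns NA outside the support.
bilinear <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  ok <- x0 >= 1 & y0 >= 1 & x0 + 1 <= nx & y0 + 1 <= ny
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  x0k <- x0[ok]; y0k <- y0[ok]
  fx <- x[ok] - x0k; fy <- y[ok] - y0k
  i00 <- cbind(x0k, y0k); i10 <- cbind(x0k + 1, y0k)
  i01 <- cbind(x0k, y0k + 1); i11 <- cbind(x0k + 1, y0k + 1)
  out[ok] <- img[i00] * (1 - fx) * (1 - fy) + img[i10] * fx * (1 - fy) +
    img[i01] * (1 - fx) * fy + img[i11] * fx * fy
  out
}

# 3-point parabolic sub-sample peak refinement. Returns offset in samples,
# clamped to [-0.5, 0.5].
parabolic_offset <- function(y_m1, y_0, y_p1) {
  denom <- y_m1 - 2 * y_0 + y_p1
  if (!is.finite(denom) || denom == 0) return(0)
  max(-0.5, min(0.5, 0.5 * (y_m1 - y_p1) / denom))
}
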