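# Grayscale morphology with a non-flat (ball) structuring element.
# EBImage only provides flat brushes, so the ball kernel used by rolling-ball
# background estimation is implemented here by shift-and-combine; images at
# the sizes this package handles (<= ~1024^2, radius <= ~20) keep this fast.

ball_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  d2 <- off$dx^2 + off$dy^2
  keep <- d2 <= r^2
  list(dx = off$dx[keep], dy = off$dy[keep],
       h = sqrt(r^2 - d2[keep]))
}

shift_pad <- function(img, dx, dy, fill) {
  nx <- nrow(img); ny <- ncol(img)
  out <- matrix(fill, nx, ny)
  xs <- max(1, 1 - dx):min(nx, nx - dx)
  ys <- max(1, 1 - dy):min(ny, ny - dy)
  if (length(xs) && length(ys)) out[xs, ys] <- img[xs + dx, ys + dy]
  out
}

gray_erode_ball <- function(img, kern) {
  out <- matrix(Inf, nrow(img), ncol(img))
  for (i in seq_along(kern$dx)) {
    out <- pmin(out, shift_pad(img, kern$dx[i], kern$dy[i], Inf) - kern$h[i])
  }
  out
}

gray_dilate_ball <- function(img, kern) {
  out <- matrix(-Inf, nrow(img), ncol(img))
  for (i in seq_along(kern$dx)) {
    out <- pmax(out, shift_pad(img, kern$dx[i], kern$dy[i], -Inf) + kern$h[i])
  }
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a fluorescence image as the grayscale
#' opening with a ball-shaped structuring element of the given radius (the
#' classical rolling-ball estimate) and subtracts it. Structures narrower
#' than the ball — diffraction-limited puncta in particular — survive with
#' their full height; anything the ball can roll under is removed. The
#' result is clipped at zero and is everywhere less than or equal to the
#' input (openings are anti-extensive).
#'
#' @param image Numeric matrix (one channel) or an [image_field()]; fields
#'   are processed channel by channel.
#' @param radius_px Ball radius in pixels (default 5).
#' @return Background-subtracted image of the same type as the input.
#' @export
rolling_ball_subtract <- function(image, radius_px = 5) {
  check_count(radius_px, "radius_px", min = 1L)
  if (inherits(image, "image_field")) {
    for (ch in seq_len(n_channels(image))) {
      image$data[, , ch] <- rolling_ball_subtract(image$data[, , ch],
                                                  radius_px)
    }
    return(image)
  }
  if (2 * radius_px + 1 > min(dim(image))) {
    abort("`radius_px` exceeds the image size.")
  }
  kern <- ball_kernel(radius_px)
  background <- gray_dilate_ball(gray_erode_ball(image, kern), kern)
  pmax(image - background, 0)
}

# Binary 3x3 box dilation/erosion via EBImage flat brushes.
binary_dilate <- function(mask, iter = 1L) {
  m <- mask * 1
  brush <- EBImage::makeBrush(3, shape = "box")
  for (i in seq_len(iter)) m <- EBImage::dilate(m, brush)
  m > 0
}

binary_erode <- function(mask, iter = 1L) {
  m <- mask * 1
  brush <- EBImage::makeBrush(3, shape = "box")
  for (i in seq_len(iter)) m <- EBImage::erode(m, brush)
  m > 0
}

label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
}
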