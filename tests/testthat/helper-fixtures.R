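# Shared fixtures, built in code at test time.

# Filled digital disk mask of radius r centred in an n x n matrix.
disk_mask <- function(r, n = 2 * r + 11) {
  c0 <- (n + 1) / 2
  d2 <- (row(matrix(0, n, n)) - c0)^2 + (col(matrix(0, n, n)) - c0)^2
  d2 <= r^2
}

# Brute-force grayscale erosion/dilation with a ball structuring element,
# independent of the package's shift-and-combine implementation.
brute_gray_open_ball <- function(img, radius) {
  nx <- nrow(img); ny <- ncol(img)
  off <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  h <- sqrt(radius^2 - off$dx^2 - off$dy^2)
  er <- matrix(NA_real_, nx, ny)
  for (x in 1:nx) for (y in 1:ny) {
    vals <- Inf
    for (k in seq_len(nrow(off))) {
      xx <- x + off$dx[k]; yy <- y + off$dy[k]
      v <- if (xx >= 1 && xx <= nx && yy >= 1 && yy <= ny) {
        img[xx, yy] - h[k]
      } else Inf
      vals <- min(vals, v)
    }
    er[x, y] <- vals
  }
  di <- matrix(NA_real_, nx, ny)
  for (x in 1:nx) for (y in 1:ny) {
    vals <- -Inf
    for (k in seq_len(nrow(off))) {
      xx <- x + off$dx[k]; yy <- y + off$dy[k]
      v <- if (xx >= 1 && xx <= nx && yy >= 1 && yy <= ny) {
        er[xx, yy] + h[k]
      } else -Inf
      vals <- max(vals, v)
    }
    di[x, y] <- vals
  }
  di
}

# Clean two-cloud scene for COM / sizing tests: draws the clouds directly.
draw_cloud <- function(n, center, widths_1e2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sig <- widths_1e2 / 4
  tibble::tibble(x_nm = rnorm(n, center[1], sig[1]),
                 y_nm = rnorm(n, center[2], sig[2]),
                 z_nm = rnorm(n, center[3], sig[3]))
}
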