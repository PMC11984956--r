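# Two-colour channel registration: bead-based planar affine, then iterative
# 3D cross-correlation fine-tuning on a shared reference structure.

#' Estimate a planar affine transform from bead correspondences
#'
#' Least-squares affine (2x2 matrix plus translation) mapping bead
#' positions of the moving channel onto the fixed channel, estimated at the
#' coverslip (x, y only). Requires at least three non-collinear beads.
#'
#' @param moving,fixed Matrices or data frames of matched bead positions;
#'   columns `x_nm, y_nm` (or first two columns).
#' @return A `planar_affine` object: `A` (2x2), `t_nm` (length-2
#'   translation), `rms_residual_nm`, `n_beads`.
#' @export
estimate_affine <- function(moving, fixed) {
  mv <- as_xy(moving); fx <- as_xy(fixed)
  if (nrow(mv) != nrow(fx)) abort("bead sets must be matched (same size).")
  if (nrow(mv) < 3L) abort("at least 3 bead correspondences are required.")
  X <- cbind(mv, 1)
  qrX <- qr(X)
  if (qrX$rank < 3L) abort("degenerate bead geometry (collinear beads).")
  coef <- unname(qr.coef(qrX, fx))        # 3 x 2
  A <- t(coef[1:2, ])                     # fixed = A %*% moving + t
  t_nm <- coef[3, ]
  fit <- X %*% coef
  rms <- sqrt(mean(rowSums((fx - fit)^2)))
  structure(list(A = A, t_nm = t_nm, rms_residual_nm = rms,
                 n_beads = nrow(mv)),
            class = "planar_affine")
}

as_xy <- function(p) {
  p <- as.data.frame(p)
  if (all(c("x_nm", "y_nm") %in% names(p))) {
    cbind(p$x_nm, p$y_nm)
  } else {
    as.matrix(p[, 1:2])
  }
}

#' @export
print.planar_affine <- function(x, ...) {
  cat(sprintf(
    "<planar_affine> %d beads, RMS residual %.2f nm\n  A = [%.5f %.5f; %.5f %.5f], t = (%.1f, %.1f) nm\n",
    x$n_beads, x$rms_residual_nm, x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2],
    x$t_nm[1], x$t_nm[2]))
  invisible(x)
}

#' @export
tidy.planar_affine <- function(x, ...) {
  tibble(term = c("a11", "a12", "a21", "a22", "tx_nm", "ty_nm"),
         estimate = c(x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2],
                      x$t_nm[1], x$t_nm[2]))
}

#' Apply a planar affine transform to a localization table
#'
#' @param locs Localization tibble with `x_nm, y_nm`.
#' @param affine A [estimate_affine()] result.
#' @return Transformed tibble (z untouched).
#' @export
apply_affine <- function(locs, affine) {
  stopifnot(inherits(affine, "planar_affine"))
  locs <- as_tibble(locs)
  xy <- cbind(locs$x_nm, locs$y_nm) %*% t(affine$A)
  locs$x_nm <- xy[, 1] + affine$t_nm[1]
  locs$y_nm <- xy[, 2] + affine$t_nm[2]
  locs
}

#' Iterative 3D cross-correlation registration refinement
#'
#' Fine-tunes the residual 3D shift between two channels sharing a
#' reference structure (e.g. FOP ring localizations, affine already
#' applied): both channels are rendered into 3D count histograms at
#' `voxel_nm`, their 3D cross-correlation is computed by FFT, the
#' correlation peak is refined per axis with a 3-point parabola, and the
#' moving channel is shifted accordingly; this repeats until the
#' incremental shift is below `convergence_nm` on every axis or `max_iter`
#' is reached. The cumulative shift applied to the moving channel is
#' returned.
#'
#' @param locs_fixed,locs_moving Localization tibbles (`x_nm, y_nm, z_nm`)
#'   for the reference and moving channel.
#' @param voxel_nm Histogram voxel size (default 10 nm).
#' @param convergence_nm Per-axis convergence threshold (default 2 nm).
#' @param max_iter Maximum iterations (default 20).
#' @return A `registration_result`: `shift_nm` (length-3 cumulative shift
#'   applied to the moving channel), `iterations`, `converged`,
#'   `last_increment_nm`, `voxel_nm`, and `locs_moving` (the shifted
#'   table).
#' @export
refine_registration_3dcc <- function(locs_fixed, locs_moving, voxel_nm = 10,
                                     convergence_nm = 2, max_iter = 20) {
  check_number(voxel_nm, "voxel_nm", min = 0, strict_min = TRUE)
  check_number(convergence_nm, "convergence_nm", min = 0, strict_min = TRUE)
  fixed <- as_tibble(locs_fixed); moving <- as_tibble(locs_moving)
  if (nrow(fixed) == 0L || nrow(moving) == 0L) {
    abort("both channels need localizations.")
  }
  total <- c(0, 0, 0)
  converged <- FALSE
  inc <- c(Inf, Inf, Inf)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    inc <- xcorr3d_shift(fixed, moving, voxel_nm)
    moving$x_nm <- moving$x_nm + inc[1]
    moving$y_nm <- moving$y_nm + inc[2]
    moving$z_nm <- moving$z_nm + inc[3]
    total <- total + inc
    if (all(abs(inc) < convergence_nm)) {
      converged <- TRUE
      break
    }
  }
  structure(list(shift_nm = total, iterations = iter, converged = converged,
                 last_increment_nm = inc, voxel_nm = voxel_nm,
                 locs_moving = moving),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> shift (%.2f, %.2f, %.2f) nm after %d iteration(s), %s\n",
    x$shift_nm[1], x$shift_nm[2], x$shift_nm[3], x$iterations,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
glance.registration_result <- function(x, ...) {
  tibble(shift_x_nm = x$shift_nm[1], shift_y_nm = x$shift_nm[2],
         shift_z_nm = x$shift_nm[3], iterations = x$iterations,
         converged = x$converged, voxel_nm = x$voxel_nm)
}

# One cross-correlation pass: returns the shift (nm, length 3) to ADD to the
# moving channel so it aligns with the fixed channel.
xcorr3d_shift <- function(fixed, moving, voxel_nm, pad_vox = 16L) {
  lo <- c(min(fixed$x_nm, moving$x_nm), min(fixed$y_nm, moving$y_nm),
          min(fixed$z_nm, moving$z_nm)) - pad_vox * voxel_nm
  hi <- c(max(fixed$x_nm, moving$x_nm), max(fixed$y_nm, moving$y_nm),
          max(fixed$z_nm, moving$z_nm)) + pad_vox * voxel_nm
  dims <- pmax(4L, ceiling((hi - lo) / voxel_nm))
  hf <- hist3d(fixed, lo, dims, voxel_nm)
  hm <- hist3d(moving, lo, dims, voxel_nm)
  # circular cross-correlation: C[k] = sum_x hf[x + k] * hm[x]
  C <- Re(fft(Conj(fft(hm)) * fft(hf), inverse = TRUE))
  peak <- which(C == max(C), arr.ind = TRUE)[1, ]
  # sub-voxel parabolic refinement per axis (indices wrap circularly)
  frac <- numeric(3)
  for (ax in 1:3) {
    n <- dims[ax]
    at <- function(d) {
      idx <- peak
      idx[ax] <- ((peak[ax] - 1L + d) %% n) + 1L
      C[matrix(idx, 1)]
    }
    frac[ax] <- parabolic_offset(at(-1L), at(0L), at(1L))
  }
  # unwrap: shift k-1 in [0, n) maps to negative for the upper half
  k <- peak - 1L + frac
  k <- ifelse(k > dims / 2, k - dims, k)
  k * voxel_nm
}

hist3d <- function(locs, lo, dims, voxel_nm) {
  ix <- pmin(dims[1], pmax(1, ceiling((locs$x_nm - lo[1]) / voxel_nm)))
  iy <- pmin(dims[2], pmax(1, ceiling((locs$y_nm - lo[2]) / voxel_nm)))
  iz <- pmin(dims[3], pmax(1, ceiling((locs$z_nm - lo[3]) / voxel_nm)))
  arr <- array(0, dim = dims)
  idx <- (iz - 1) * dims[1] * dims[2] + (iy - 1) * dims[1] + ix
  tab <- tabulate(idx, nbins = prod(dims))
  array(tab, dim = dims)
}
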