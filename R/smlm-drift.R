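# Fiducial-based drift estimation and correction for localization tables.

#' Cubic smoothing spline in the csaps convention
#'
#' Fits a natural cubic smoothing spline minimizing
#' `p * sum((y - f)^2) + (1 - p) * integral(f'')^2` on the raw abscissa —
#' the convention of MATLAB's `csaps`, where `p = 0` gives the
#' least-squares line and `p = 1` the natural interpolating spline. Solved
#' directly in the Reinsch penalty-matrix form; the fit is exact, not an
#' approximation on transformed coordinates.
#'
#' @param x Strictly increasing abscissa (e.g. frame indices).
#' @param y Response values.
#' @param p Smoothing parameter in `(0, 1)`; drift smoothing uses `1e-6`.
#' @param xout Points at which to evaluate the spline (default `x`).
#' @return Fitted values at `xout`.
#' @export
csaps_spline <- function(x, y, p, xout = x) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) {
    # too few points for curvature: least-squares line
    fit <- stats::lm.fit(cbind(1, x), y)
    return(fit$coefficients[1] + fit$coefficients[2] * xout)
  }
  check_number(p, "p", min = 0, max = 1)
  if (p <= 0) p <- .Machine$double.eps
  if (p >= 1) {
    return(stats::spline(x, y, xout = xout, method = "natural")$y)
  }
  h <- diff(x)
  if (any(h <= 0)) abort("`x` must be strictly increasing.")
  mu <- (1 - p) / p
  Q <- matrix(0, n, n - 2L)
  R <- matrix(0, n - 2L, n - 2L)
  for (j in seq_len(n - 2L)) {
    Q[j, j] <- 1 / h[j]
    Q[j + 1L, j] <- -(1 / h[j] + 1 / h[j + 1L])
    Q[j + 2L, j] <- 1 / h[j + 1L]
    R[j, j] <- (h[j] + h[j + 1L]) / 3
    if (j < n - 2L) R[j, j + 1L] <- R[j + 1L, j] <- h[j + 1L] / 6
  }
  # f = y - mu * Q (R + mu Q'Q)^{-1} Q'y   (Reinsch)
  rhs <- crossprod(Q, y)
  gam <- solve(R + mu * crossprod(Q), rhs)
  f <- y - mu * as.vector(Q %*% gam)
  # a smoothing spline is the natural interpolant of its fitted values
  stats::spline(x, f, xout = xout, method = "natural")$y
}

#' Track a fiducial bead and fit a smoothed drift trace
#'
#' Collects the localizations of one fiducial bead (those within
#' `capture_radius_nm` of the seed position, averaged per frame), smooths
#' the per-frame bead positions per axis with a cubic smoothing spline
#' ([csaps_spline()], smoothing parameter `1e-6` by default), and returns
#' the trace zero-referenced to the first frame, so subtracting it from the
#' data leaves frame-1 coordinates in place.
#'
#' @param locs Localization tibble (`frame, x_nm, y_nm, z_nm, ...`),
#'   typically one channel.
#' @param fiducial_position Seed position `c(x, y)` or `c(x, y, z)` in nm.
#' @param capture_radius_nm Lateral capture radius around the seed.
#' @param smoothing csaps smoothing parameter.
#' @param n_frames Frames the trace must cover; defaults to `max(locs$frame)`.
#' @param min_coverage Minimum fraction of frames in which the bead must be
#'   found (default 0.8).
#' @param gap_limit Longest tolerated run of frames without the bead.
#' @return A `drift_trace`: tibble `frame, dx_nm, dy_nm, dz_nm` with the
#'   smoothing parameter as attribute.
#' @export
track_fiducial_and_fit_drift <- function(locs, fiducial_position,
                                         capture_radius_nm = 500,
                                         smoothing = 1e-6,
                                         n_frames = max(locs$frame),
                                         min_coverage = 0.8,
                                         gap_limit = 50) {
  locs <- as_tibble(locs)
  d2 <- (locs$x_nm - fiducial_position[1])^2 +
    (locs$y_nm - fiducial_position[2])^2
  hit <- locs[d2 <= capture_radius_nm^2, ]
  if (nrow(hit) == 0L) abort("no localizations within the capture radius.")
  per_frame <- dplyr::summarise(
    dplyr::group_by(hit, .data$frame),
    x = mean(.data$x_nm), y = mean(.data$y_nm), z = mean(.data$z_nm),
    .groups = "drop")
  per_frame <- dplyr::arrange(per_frame, .data$frame)
  frames_seen <- per_frame$frame
  if (length(frames_seen) < min_coverage * n_frames) {
    abort(sprintf("fiducial found in %d / %d frames (< %.0f%% coverage).",
                  length(frames_seen), n_frames, 100 * min_coverage))
  }
  gaps <- diff(c(0L, frames_seen, n_frames + 1L)) - 1L
  if (max(gaps) > gap_limit) {
    abort(sprintf("fiducial lost for %d consecutive frames (limit %d).",
                  max(gaps), gap_limit))
  }
  all_frames <- seq_len(n_frames)
  sm <- function(v) csaps_spline(frames_seen, v, smoothing, xout = all_frames)
  tr <- tibble(frame = all_frames,
               dx_nm = sm(per_frame$x), dy_nm = sm(per_frame$y),
               dz_nm = sm(per_frame$z))
  tr$dx_nm <- tr$dx_nm - tr$dx_nm[1]
  tr$dy_nm <- tr$dy_nm - tr$dy_nm[1]
  tr$dz_nm <- tr$dz_nm - tr$dz_nm[1]
  structure(tr, class = c("drift_trace", class(tr)), smoothing = smoothing)
}

#' Subtract a drift trace from a localization table
#'
#' @param locs Localization tibble with `frame, x_nm, y_nm, z_nm`.
#' @param trace A [track_fiducial_and_fit_drift()] trace covering every
#'   frame present in `locs`.
#' @return `locs` with drift-corrected coordinates.
#' @export
apply_drift_correction <- function(locs, trace) {
  locs <- as_tibble(locs)
  idx <- match(locs$frame, trace$frame)
  if (anyNA(idx)) abort("some frames in `locs` are outside the drift trace.")
  locs$x_nm <- locs$x_nm - trace$dx_nm[idx]
  locs$y_nm <- locs$y_nm - trace$dy_nm[idx]
  locs$z_nm <- locs$z_nm - trace$dz_nm[idx]
  locs
}
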