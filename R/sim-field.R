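#' Simulate a multi-channel centrosome field with ground truth
#'
#' Generates a wide-field-like image of centrosomal puncta: each centrosome is
#' a diffraction-limited Gaussian spot rendered in every channel, optionally
#' surrounded by a pericentriolar haze (a fraction of the spot's mass
#' redistributed into a wider Gaussian), on a constant background with
#' additive Gaussian read noise. Spot amplitudes are *integrated* intensities,
#' so the rendered pixel sum of an interior spot equals its injected
#' amplitude (mass conservation), which the intensity pipeline is scored
#' against.
#'
#' @param n_centrosomes Number of centrosomes (>= 0).
#' @param image_size_px Integer pair, image size in pixels.
#' @param pixel_size_nm Pixel size in nanometres.
#' @param channels Character vector of channel names; the first is treated as
#'   the reference (e.g. CEP170-like) channel by downstream pipelines.
#' @param amplitudes Integrated spot intensities: a matrix
#'   `n_centrosomes x n_channels`, a vector of length `n_channels` recycled
#'   across centrosomes, or `NULL` to draw log-normal amplitudes
#'   (median 5e4, geometric SD ~1.6).
#' @param psf_fwhm_nm PSF full width at half maximum (isotropic Gaussian),
#'   must be >= `pixel_size_nm`.
#' @param haze_fraction Fraction in `[0, 1]` of each spot's mass moved into a
#'   pericentriolar haze of `haze_fwhm_factor` times the PSF width.
#' @param haze_fwhm_factor Width multiplier of the haze component.
#' @param background_level Constant background offset (counts).
#' @param noise_sd Gaussian noise SD (counts); 0 for noise-free images.
#' @param min_separation_px Minimum centre-to-centre distance between
#'   centrosomes (default 25 px, ~2.5 um at 100 nm pixels — centrosomes
#'   belong to different cells and do not abut).
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @return A list with `field` (an [image_field()]) and `truth`, a tibble with
#'   one row per centrosome: `id`, `x_px`, `y_px` and one
#'   `amplitude_<channel>` column per channel.
#' @export
sim_centrosome_field <- function(n_centrosomes = 20,
                                 image_size_px = c(256L, 256L),
                                 pixel_size_nm = 100,
                                 channels = c("ref", "poi"),
                                 amplitudes = NULL,
                                 psf_fwhm_nm = 250,
                                 haze_fraction = 0.25,
                                 haze_fwhm_factor = 4,
                                 background_level = 100,
                                 noise_sd = 5,
                                 min_separation_px = 25,
                                 seed = NULL) {
  check_count(n_centrosomes, "n_centrosomes", min = 0L)
  check_number(pixel_size_nm, "pixel_size_nm", min = 0, strict_min = TRUE)
  if (length(image_size_px) != 2L || any(image_size_px < 8)) {
    abort("`image_size_px` must be two integers >= 8.")
  }
  check_number(psf_fwhm_nm, "psf_fwhm_nm", min = pixel_size_nm)
  check_number(haze_fraction, "haze_fraction", min = 0, max = 1)
  check_number(background_level, "background_level", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  nx <- as.integer(image_size_px[1]); ny <- as.integer(image_size_px[2])
  k <- length(channels)

  with_seed(seed, {
    amp <- resolve_amplitudes(amplitudes, n_centrosomes, k, channels)
    sigma_px <- fwhm_to_sigma(psf_fwhm_nm) / pixel_size_nm
    margin <- ceiling(5 * sigma_px * haze_fwhm_factor) + 2
    margin <- min(margin, floor(min(nx, ny) / 3))
    x <- numeric(n_centrosomes); y <- numeric(n_centrosomes)
    for (i in seq_len(n_centrosomes)) {
      for (try in 1:500) {
        xi <- runif(1, margin, nx - margin)
        yi <- runif(1, margin, ny - margin)
        if (i == 1L || all((x[seq_len(i - 1)] - xi)^2 +
                             (y[seq_len(i - 1)] - yi)^2 >=
                             min_separation_px^2)) break
      }
      x[i] <- xi; y[i] <- yi
    }

    data <- array(background_level, dim = c(nx, ny, k))
    for (ch in seq_len(k)) {
      core <- render_spots(nx, ny, x, y, amp[, ch] * (1 - haze_fraction),
                           sigma_px)
      layer <- core
      if (haze_fraction > 0 && n_centrosomes > 0) {
        layer <- layer + render_spots(nx, ny, x, y, amp[, ch] * haze_fraction,
                                      sigma_px * haze_fwhm_factor)
      }
      if (noise_sd > 0) layer <- layer + rnorm(nx * ny, 0, noise_sd)
      data[, , ch] <- data[, , ch] + layer
    }

    truth <- tibble(id = seq_len(n_centrosomes), x_px = x, y_px = y)
    for (ch in seq_len(k)) truth[[paste0("amplitude_", channels[ch])]] <- amp[, ch]
    list(field = image_field(data, pixel_size_nm, channels), truth = truth)
  })
}

resolve_amplitudes <- function(amplitudes, n, k, channels) {
  if (is.null(amplitudes)) {
    amp <- matrix(exp(rnorm(n * k, log(5e4), 0.5)), n, k)
  } else if (is.matrix(amplitudes)) {
    if (!all(dim(amplitudes) == c(n, k))) {
      abort("`amplitudes` matrix must be n_centrosomes x n_channels.")
    }
    amp <- amplitudes
  } else if (is.numeric(amplitudes) && length(amplitudes) %in% c(1L, k)) {
    amp <- matrix(rep(rep_len(amplitudes, k), each = n), n, k)
  } else {
    abort("`amplitudes` must be NULL, a matrix, or a per-channel vector.")
  }
  if (n > 0 && any(amp < 0)) abort("amplitudes must be non-negative.")
  amp
}

#' Simulate a field of ciliary filaments with ground truth
#'
#' Renders curved, filamentous objects (primary-cilium-like, ARL13B-channel)
#' as Gaussian-blurred tubes of known path length and integrated intensity,
#' for exercising the ciliary intensity pipeline and length measurement.
#' Each filament is a quadratic Bezier arc of known arc length.
#'
#' @inheritParams sim_centrosome_field
#' @param n_cilia Number of filaments.
#' @param length_um_range Range (min, max) of true filament lengths in
#'   micrometres.
#' @param intensity_per_um Integrated intensity injected per micrometre of
#'   filament.
#' @param curvature Bend magnitude in `[0, 1]`; 0 gives straight segments.
#' @return A list with `field` (single-channel `arl13b` [image_field()]) and
#'   `truth` tibble: `id`, `length_um`, `amplitude` (total injected mass),
#'   `x0_px`, `y0_px`, `x1_px`, `y1_px` endpoints.
#' @export
sim_cilium_field <- function(n_cilia = 5,
                             image_size_px = c(256L, 256L),
                             pixel_size_nm = 100,
                             length_um_range = c(2, 5),
                             intensity_per_um = 2e4,
                             psf_fwhm_nm = 250,
                             curvature = 0.15,
                             background_level = 100,
                             noise_sd = 5,
                             seed = NULL) {
  check_count(n_cilia, "n_cilia", min = 0L)
  nx <- as.integer(image_size_px[1]); ny <- as.integer(image_size_px[2])
  sigma_px <- fwhm_to_sigma(psf_fwhm_nm) / pixel_size_nm
  px_per_um <- 1000 / pixel_size_nm

  with_seed(seed, {
    img <- matrix(background_level, nx, ny)
    rows <- vector("list", n_cilia)
    margin <- ceiling(max(length_um_range) * px_per_um / 2 + 5 * sigma_px)
    margin <- min(margin, floor(min(nx, ny) / 2.5))
    placed <- matrix(numeric(0), 0, 3)  # cx, cy, bounding radius
    for (i in seq_len(n_cilia)) {
      len_px <- runif(1, length_um_range[1], length_um_range[2]) * px_per_um
      theta <- runif(1, 0, 2 * pi)
      # rejection-sample centres so filaments cannot cross or merge
      rad <- len_px / 2 + 5 * sigma_px + 3
      for (try in 1:200) {
        cx <- runif(1, margin, nx - margin)
        cy <- runif(1, margin, ny - margin)
        if (nrow(placed) == 0L ||
            all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                placed[, 3] + rad)) break
      }
      placed <- rbind(placed, c(cx, cy, rad))
      p0 <- c(cx - cos(theta) * len_px / 2, cy - sin(theta) * len_px / 2)
      p2 <- c(cx + cos(theta) * len_px / 2, cy + sin(theta) * len_px / 2)
      bend <- curvature * len_px * runif(1, -1, 1)
      pc <- c(cx - sin(theta) * bend, cy + cos(theta) * bend)
      tt <- seq(0, 1, length.out = 200)
      bx <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * pc[1] + tt^2 * p2[1]
      by <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * pc[2] + tt^2 * p2[2]
      seg <- sqrt(diff(bx)^2 + diff(by)^2)
      arc_px <- sum(seg)
      # resample the path at ~0.4 px spacing and deposit mass per step
      s <- cumsum(c(0, seg))
      n_pts <- max(2L, ceiling(arc_px / 0.4))
      si <- seq(0, arc_px, length.out = n_pts)
      xi <- approx(s, bx, xout = si)$y
      yi <- approx(s, by, xout = si)$y
      total <- intensity_per_um * arc_px / px_per_um
      img <- img + render_spots(nx, ny, xi, yi, rep(total / n_pts, n_pts),
                                sigma_px)
      rows[[i]] <- tibble(
        id = i, length_um = arc_px / px_per_um, amplitude = total,
        x0_px = p0[1], y0_px = p0[2], x1_px = p2[1], y1_px = p2[2])
    }
    if (noise_sd > 0) img <- img + rnorm(nx * ny, 0, noise_sd)
    truth <- if (n_cilia > 0) dplyr::bind_rows(rows) else
      tibble(id = integer(), length_um = double(), amplitude = double(),
             x0_px = double(), y0_px = double(), x1_px = double(),
             y1_px = double())
    list(field = image_field(img, pixel_size_nm, "arl13b"), truth = truth)
  })
}
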