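#' Maximum-intensity projection of a z stack
#'
#' @param stack Numeric 3D array `[x, y, z]`, or a list of matrices.
#' @return Matrix of pixelwise maxima across slices.
#' @export
max_project <- function(stack) {
  if (is.list(stack)) {
    if (length(stack) == 0L) abort("empty stack.")
    stack <- array(unlist(stack), dim = c(dim(stack[[1]]), length(stack)))
  }
  if (length(dim(stack)) == 2L) return(stack)
  if (length(dim(stack)) != 3L || dim(stack)[3] < 1L) {
    abort("`stack` must be a 3D array with at least one slice.")
  }
  apply(stack, c(1, 2), max)
}

#' Peak-to-peak ring diameter from four line profiles
#'
#' Measures the diameter of an appendage-ring image the way it is done on
#' max-projected top views: intensity profiles are extracted along full
#' lines through the ring centre at 0, 45, 90 and 135 degrees; on each side
#' of the centre the strongest local maximum is located and refined to
#' sub-pixel precision with a 3-point parabola; the per-angle diameter is
#' the distance between the two opposing peaks, and the reported diameter is
#' the mean over the four angles (averaging reduces the bias from ring
#' tilt). The centre defaults to the intensity-weighted centroid after
#' subtracting the 50th-percentile background.
#'
#' @param image Numeric matrix or single-channel [image_field()].
#' @param pixel_size_nm Pixel size in nanometres (taken from the field if an
#'   [image_field()] is given).
#' @param center Optional ring centre `c(x_px, y_px)`; estimated if `NULL`.
#' @param angles_deg Profile angles; four equally spaced by default.
#' @param step_px Profile sampling step in pixels (bilinear interpolation).
#' @return A `ring_measurement` object: list with `center_px`,
#'   `per_angle` (tibble: `angle_deg`, `diameter_nm`), `mean_diameter_nm`,
#'   `n_angles` (valid angles used).
#' @export
peak_to_peak_diameter <- function(image, pixel_size_nm = NULL, center = NULL,
                                  angles_deg = c(0, 45, 90, 135),
                                  step_px = 0.25) {
  if (inherits(image, "image_field")) {
    pixel_size_nm <- pixel_size_nm %||% image$pixel_size_nm
    image <- field_channel(image, 1L)
  }
  if (is.null(pixel_size_nm)) abort("`pixel_size_nm` is required.")
  check_number(pixel_size_nm, "pixel_size_nm", min = 0, strict_min = TRUE)
  nx <- nrow(image); ny <- ncol(image)

  if (is.null(center)) {
    bg <- quantile(image, 0.5, names = FALSE)
    w <- pmax(image - bg, 0)
    if (sum(w) == 0) abort("image has no intensity above background.")
    center <- c(sum(w * row(image)) / sum(w), sum(w * col(image)) / sum(w))
  }

  max_r <- sqrt(nx^2 + ny^2) / 2
  rs <- seq(step_px, max_r, by = step_px)
  rows <- vector("list", length(angles_deg))
  for (i in seq_along(angles_deg)) {
    th <- angles_deg[i] * pi / 180
    side <- function(sign) {
      prof <- bilinear(image, center[1] + sign * rs * cos(th),
                       center[2] + sign * rs * sin(th))
      peak_radius(rs, prof)
    }
    r_pos <- side(1); r_neg <- side(-1)
    if (is.na(r_pos) || is.na(r_neg)) next
    rows[[i]] <- tibble(angle_deg = angles_deg[i],
                        diameter_nm = (r_pos + r_neg) * pixel_size_nm)
  }
  per_angle <- dplyr::bind_rows(rows)
  if (nrow(per_angle) < 2L) {
    abort("peak_to_peak_diameter: fewer than two angles yielded two peaks.")
  }
  structure(list(center_px = center, per_angle = per_angle,
                 mean_diameter_nm = mean(per_angle$diameter_nm),
                 n_angles = nrow(per_angle),
                 pixel_size_nm = pixel_size_nm),
            class = "ring_measurement")
}

# Strongest interior local maximum of profile y(r), with 3-point parabolic
# refinement. Maxima below 10% of the profile's maximum (flat background
# plateaus, stray noise far from the ring) do not qualify. Returns the
# refined radius, or NA if no qualifying local maximum exists.
peak_radius <- function(r, y) {
  ok <- is.finite(y)
  r <- r[ok]; y <- y[ok]
  n <- length(y)
  if (n < 3L) return(NA_real_)
  i <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  i <- i[y[i] >= 0.1 * max(y)]
  if (length(i) == 0L) return(NA_real_)
  i <- i[which.max(y[i])]
  step <- r[2] - r[1]
  r[i] + parabolic_offset(y[i - 1], y[i], y[i + 1]) * step
}

#' @export
print.ring_measurement <- function(x, ...) {
  cat(sprintf(
    "<ring_measurement> mean peak-to-peak diameter %.1f nm (%d angles)\n",
    x$mean_diameter_nm, x$n_angles))
  invisible(x)
}

#' @export
tidy.ring_measurement <- function(x, ...) x$per_angle

#' @export
glance.ring_measurement <- function(x, ...) {
  tibble(mean_diameter_nm = x$mean_diameter_nm,
         sd_diameter_nm = sd(x$per_angle$diameter_nm),
         n_angles = x$n_angles,
         center_x_px = x$center_px[1], center_y_px = x$center_px[2])
}

#' Molecular-ruler model for epitope radial offsets
#'
#' Predicts how far an epitope can sit from its anchor along an extended
#' protein, as used to reconcile two antibodies against the same protein
#' labelling rings of different diameters: an alpha-helical (coiled-coil)
#' stretch contributes its helical rise per residue (0.15 nm/aa, 3.6
#' residues per turn), a disordered stretch contributes up to its contour
#' length (0.4 nm/aa), and each antibody layer (IgG) adds ~8 nm. The model
#' is linear in all three counts. With the defaults, 400 helical + 40
#' disordered residues give 76 nm, and four IgG molecules (primary plus
#' secondary on both edges) give 32 nm.
#'
#' @param n_helical_aa Residues in alpha-helical/coiled-coil conformation.
#' @param n_disordered_aa Residues in disordered (extended-contour)
#'   conformation.
#' @param n_igg IgG molecules in the detection chain.
#' @param helix_rise_nm_per_aa Helical rise per residue (nm).
#' @param contour_nm_per_aa Contour length per residue (nm).
#' @param igg_length_nm Length of one IgG (nm).
#' @return Predicted maximal extension in nanometres (single number).
#' @export
molecular_ruler <- function(n_helical_aa, n_disordered_aa = 0, n_igg = 0,
                            helix_rise_nm_per_aa = 0.15,
                            contour_nm_per_aa = 0.4,
                            igg_length_nm = 8) {
  check_number(n_helical_aa, "n_helical_aa", min = 0)
  check_number(n_disordered_aa, "n_disordered_aa", min = 0)
  check_number(n_igg, "n_igg", min = 0)
  check_number(helix_rise_nm_per_aa, "helix_rise_nm_per_aa", min = 0,
               strict_min = TRUE)
  check_number(contour_nm_per_aa, "contour_nm_per_aa", min = 0,
               strict_min = TRUE)
  check_number(igg_length_nm, "igg_length_nm", min = 0, strict_min = TRUE)
  n_helical_aa * helix_rise_nm_per_aa +
    n_disordered_aa * contour_nm_per_aa +
    n_igg * igg_length_nm
}
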