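#' Simulate a two-colour 3D single-molecule localization scene
#'
#' Builds a synthetic dSTORM-like scene with full ground truth, emulating the
#' raw material of two-colour 3D SMLM post-processing: a shared reference ring
#' structure (FOP-like, present in both channels), a vesicle-like anisotropic
#' Gaussian cloud in the red channel (RAB34-like), a partner cloud in the
#' green channel (MYO5A-like) displaced by a known centre-of-mass offset,
#' fiducial beads localized in every frame, smooth polynomial stage drift
#' applied to all emitters, a planar affine misalignment plus residual 3D
#' shift applied to the green channel, per-localization CRLB draws (true
#' positions are jittered by `N(0, CRLB)` laterally and `N(0, 2 CRLB)`
#' axially), and a fraction of uniform spurious localizations.
#'
#' Default geometry: ring radius 150 nm, vesicle 1/e2 widths 230 x 170 x
#' 190 nm (sample-1-like), partner offset magnitude 89 nm.
#'
#' @param n_frames Number of camera frames.
#' @param ring_radius_nm Radius of the shared reference ring.
#' @param ring_n_locs Localizations on the ring *per channel*.
#' @param ring_center_nm Ring centre (3-vector, nm).
#' @param vesicle_center_nm Red-cloud centre (3-vector, nm).
#' @param vesicle_widths_1e2_nm Red-cloud 1/e2 widths per axis (= 4 sigma).
#' @param vesicle_n_locs Red-cloud localization count.
#' @param partner_offset_nm True COM offset of the green cloud relative to the
#'   red cloud (3-vector); the default has magnitude 89 nm.
#' @param partner_widths_1e2_nm Green-cloud 1/e2 widths per axis.
#' @param partner_n_locs Green-cloud localization count.
#' @param fiducials Matrix or list of 3D fiducial positions (nm); beads are
#'   localized in both channels in every frame.
#' @param drift_amplitude_nm Per-axis scale of the cubic-polynomial drift
#'   trajectory; `c(0, 0, 0)` disables drift.
#' @param affine Planar affine misalignment of the green channel:
#'   `list(rotation_deg, scale, translation_nm = c(tx, ty), z_shift_nm)`.
#'   `NULL` means identity.
#' @param residual_shift_nm Residual 3D shift (nm) added to the green channel
#'   after the affine; what cross-correlation refinement must recover.
#' @param crlb_mean_nm,crlb_sd_nm Mean and SD of the per-localization lateral
#'   CRLB draws (truncated at 2 nm).
#' @param outlier_fraction Fraction of spurious uniform localizations added
#'   per channel (must be < 0.5).
#' @param seed Integer seed or `NULL`.
#' @return List with `locs` — a localization tibble
#'   (`id, frame, x_nm, y_nm, z_nm, photons, crlb_xy_nm, channel`) — and
#'   `truth`, a list carrying the drift table, the affine, the residual
#'   shift, cluster centres, the exact COM separation, fiducial positions,
#'   and a `membership` tibble mapping localization `id` to its species
#'   (`ring`, `vesicle`, `partner`, `fiducial`, `outlier`).
#' @export
sim_smlm_scene <- function(n_frames = 1000,
                           ring_radius_nm = 150,
                           ring_n_locs = 10000,
                           ring_center_nm = c(0, 0, 0),
                           vesicle_center_nm = c(600, 400, 80),
                           vesicle_widths_1e2_nm = c(230, 170, 190),
                           vesicle_n_locs = 2000,
                           partner_offset_nm = 89 * c(1, 1, 1) / sqrt(3),
                           partner_widths_1e2_nm = c(230, 170, 190),
                           partner_n_locs = 500,
                           fiducials = rbind(c(-1500, -1500, 0),
                                             c(1500, -1200, 40),
                                             c(-1200, 1500, -40),
                                             c(1400, 1400, 20)),
                           drift_amplitude_nm = c(80, 60, 40),
                           affine = list(rotation_deg = 0.5, scale = 1.002,
                                         translation_nm = c(50, -30),
                                         z_shift_nm = 20),
                           residual_shift_nm = c(30, -20, 40),
                           crlb_mean_nm = 10,
                           crlb_sd_nm = 2,
                           outlier_fraction = 0.02,
                           seed = NULL) {
  check_count(n_frames, "n_frames", min = 1L)
  check_number(outlier_fraction, "outlier_fraction", min = 0)
  if (outlier_fraction >= 0.5) abort("`outlier_fraction` must be < 0.5.")
  if (any(vesicle_widths_1e2_nm <= 0) || any(partner_widths_1e2_nm <= 0)) {
    abort("1/e2 widths must be positive.")
  }
  if (ring_n_locs + vesicle_n_locs + partner_n_locs <= 0) {
    abort("scene is empty: no localizations requested.")
  }
  fiducials <- if (is.list(fiducials)) do.call(rbind, fiducials) else fiducials

  with_seed(seed, {
    drift <- make_drift_table(n_frames, drift_amplitude_nm)

    draw_ring <- function(n) {
      ang <- runif(n, 0, 2 * pi)
      r <- rnorm(n, ring_radius_nm, 10)
      cbind(ring_center_nm[1] + r * cos(ang),
            ring_center_nm[2] + r * sin(ang),
            ring_center_nm[3] + rnorm(n, 0, 25))
    }
    draw_cloud <- function(n, center, widths) {
      sig <- widths / 4
      cbind(rnorm(n, center[1], sig[1]), rnorm(n, center[2], sig[2]),
            rnorm(n, center[3], sig[3]))
    }
    partner_center <- vesicle_center_nm + partner_offset_nm

    red <- rbind(
      draw_ring(ring_n_locs),
      draw_cloud(vesicle_n_locs, vesicle_center_nm, vesicle_widths_1e2_nm))
    red_species <- rep(c("ring", "vesicle"), c(ring_n_locs, vesicle_n_locs))
    green <- rbind(
      draw_ring(ring_n_locs),
      draw_cloud(partner_n_locs, partner_center, partner_widths_1e2_nm))
    green_species <- rep(c("ring", "partner"), c(ring_n_locs, partner_n_locs))

    # fiducials appear once per frame in each channel
    n_fid <- nrow(fiducials)
    fid_pos <- fiducials[rep(seq_len(n_fid), each = n_frames), , drop = FALSE]
    fid_frames <- rep(seq_len(n_frames), n_fid)

    assemble <- function(pos, species, channel, frames = NULL) {
      n <- nrow(pos)
      frames <- frames %||% sample.int(n_frames, n, replace = TRUE)
      n_out <- round(outlier_fraction * n)
      if (n_out > 0) {
        lo <- apply(pos, 2, min) - 500; hi <- apply(pos, 2, max) + 500
        pos <- rbind(pos, cbind(runif(n_out, lo[1], hi[1]),
                                runif(n_out, lo[2], hi[2]),
                                runif(n_out, lo[3], hi[3])))
        species <- c(species, rep("outlier", n_out))
        frames <- c(frames, sample.int(n_frames, n_out, replace = TRUE))
      }
      list(pos = pos, species = species, frames = frames, channel = channel)
    }

    red_all <- assemble(rbind(red, fid_pos),
                        c(red_species, rep("fiducial", nrow(fid_pos))),
                        "red", frames = c(sample.int(n_frames, nrow(red),
                                                     replace = TRUE),
                                          fid_frames))
    green_all <- assemble(rbind(green, fid_pos),
                          c(green_species, rep("fiducial", nrow(fid_pos))),
                          "green", frames = c(sample.int(n_frames, nrow(green),
                                                         replace = TRUE),
                                              fid_frames))

    finalize <- function(ch) {
      pos <- ch$pos
      d <- as.matrix(drift[ch$frames, c("dx_nm", "dy_nm", "dz_nm")])
      pos <- pos + d
      if (ch$channel == "green") {
        pos <- apply_affine_xy(pos, affine)
        pos <- sweep(pos, 2, residual_shift_nm, "+")
      }
      n <- nrow(pos)
      crlb <- pmax(2, rnorm(n, crlb_mean_nm, crlb_sd_nm))
      pos <- pos + cbind(rnorm(n, 0, crlb), rnorm(n, 0, crlb),
                         rnorm(n, 0, 2 * crlb))
      tibble(frame = ch$frames, x_nm = pos[, 1], y_nm = pos[, 2],
             z_nm = pos[, 3], photons = exp(rnorm(n, log(2000), 0.4)),
             crlb_xy_nm = crlb, channel = ch$channel, species = ch$species)
    }

    locs <- dplyr::bind_rows(finalize(red_all), finalize(green_all))
    locs$id <- seq_len(nrow(locs))
    membership <- locs[, c("id", "channel", "species")]
    locs <- locs[, c("id", "frame", "x_nm", "y_nm", "z_nm", "photons",
                     "crlb_xy_nm", "channel")]

    truth <- list(
      drift = drift,
      affine = affine,
      residual_shift_nm = residual_shift_nm,
      ring_center_nm = ring_center_nm,
      ring_radius_nm = ring_radius_nm,
      vesicle_center_nm = vesicle_center_nm,
      partner_center_nm = partner_center,
      partner_offset_nm = partner_offset_nm,
      com_separation_nm = sqrt(sum(partner_offset_nm^2)),
      vesicle_widths_1e2_nm = vesicle_widths_1e2_nm,
      partner_widths_1e2_nm = partner_widths_1e2_nm,
      fiducials_nm = fiducials,
      membership = as_tibble(membership))
    list(locs = as_tibble(locs), truth = truth)
  })
}

# Cubic-polynomial drift per axis over normalised time, zero at frame 1,
# scaled so the maximum absolute excursion equals the requested amplitude.
make_drift_table <- function(n_frames, amplitude_nm) {
  t <- if (n_frames == 1L) 0 else (seq_len(n_frames) - 1) / (n_frames - 1)
  one_axis <- function(amp) {
    if (amp == 0) return(rep(0, n_frames))
    cf <- rnorm(3)
    d <- cf[1] * t + cf[2] * t^2 + cf[3] * t^3
    if (max(abs(d)) == 0) return(rep(0, n_frames))
    amp * d / max(abs(d))
  }
  tibble(frame = seq_len(n_frames),
         dx_nm = one_axis(amplitude_nm[1]),
         dy_nm = one_axis(amplitude_nm[2]),
         dz_nm = one_axis(amplitude_nm[3]))
}

# Apply a planar affine (rotation + scale + translation) and a z shift to an
# n x 3 position matrix.
apply_affine_xy <- function(pos, affine) {
  if (is.null(affine)) return(pos)
  th <- (affine$rotation_deg %||% 0) * pi / 180
  s <- affine$scale %||% 1
  tr <- affine$translation_nm %||% c(0, 0)
  zs <- affine$z_shift_nm %||% 0
  R <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- pos[, 1:2, drop = FALSE] %*% t(R)
  cbind(xy[, 1] + tr[1], xy[, 2] + tr[2], pos[, 3] + zs)
}
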