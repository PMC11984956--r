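# Generators: determinism, mass conservation, geometry of the truth tables.

test_that("centrosome field generator is deterministic and mass-conserving", {
  a <- sim_centrosome_field(n_centrosomes = 5, seed = 42)
  b <- sim_centrosome_field(n_centrosomes = 5, seed = 42)
  expect_identical(a$field$data, b$field$data)
  expect_identical(a$truth, b$truth)

  # degenerate: no centrosomes, no noise -> flat background, empty truth
  empty <- sim_centrosome_field(n_centrosomes = 0, noise_sd = 0, seed = 1)
  expect_true(all(empty$field$data == 100))
  expect_equal(nrow(empty$truth), 0L)

  # single punctum, no haze/noise: integrated mass equals injected amplitude
  one <- sim_centrosome_field(
    n_centrosomes = 1, amplitudes = matrix(c(2e4, 3e4), 1, 2),
    haze_fraction = 0, noise_sd = 0, seed = 9)
  for (ch in c("ref", "poi")) {
    mass <- sum(field_channel(one$field, ch) - 100)
    truth_amp <- one$truth[[paste0("amplitude_", ch)]]
    expect_equal(mass, truth_amp, tolerance = 0.01)
  }
  # with haze the mass is redistributed, not added
  hz <- sim_centrosome_field(
    n_centrosomes = 1, amplitudes = matrix(c(2e4, 3e4), 1, 2),
    haze_fraction = 0.4, noise_sd = 0, seed = 9)
  expect_equal(sum(field_channel(hz$field, "poi") - 100), 3e4,
               tolerance = 0.02)
})

test_that("centrosome field generator validates its configuration", {
  expect_error(sim_centrosome_field(pixel_size_nm = 0), "pixel_size_nm")
  expect_error(sim_centrosome_field(image_size_px = c(0, 64)), "image_size_px")
  expect_error(sim_centrosome_field(psf_fwhm_nm = 50, pixel_size_nm = 100),
               "psf_fwhm_nm")
  expect_error(
    sim_centrosome_field(n_centrosomes = 3, amplitudes = matrix(1, 2, 2)),
    "amplitudes")
})

test_that("ring generator places blades on the requested diameter", {
  r <- sim_ring_image(diameter_nm = 513.4, seed = 1)
  d <- 2 * sqrt((r$truth$x_px - r$truth$center_x_px)^2 +
                  (r$truth$y_px - r$truth$center_y_px)^2) * 40
  expect_equal(d, rep(513.4, 9), tolerance = 1e-10)
  expect_equal(nrow(r$truth), 9L)

  # ninefold symmetry: rotating the noise-free image by 40 degrees about the
  # centre reproduces it (bilinear interpolation tolerance)
  img <- field_channel(r$field, 1)
  cx <- r$truth$center_x_px[1]; cy <- r$truth$center_y_px[1]
  th <- 2 * pi / 9
  pts <- expand.grid(x = 10:(nrow(img) - 10), y = 10:(ncol(img) - 10))
  xr <- cx + (pts$x - cx) * cos(th) - (pts$y - cy) * sin(th)
  yr <- cy + (pts$x - cx) * sin(th) + (pts$y - cy) * cos(th)
  rot <- centriolr:::bilinear(img, xr, yr)
  orig <- img[cbind(pts$x, pts$y)]
  ok <- !is.na(rot)
  # bilinear interpolation on ~1.3 px sigma peaks carries ~10-15% error; a
  # wrong symmetry would disagree at the full blade amplitude
  expect_lt(max(abs(rot[ok] - orig[ok])), 0.2 * max(img))
  # negative control: rotation by half the blade period does NOT match
  th2 <- pi / 9
  xr2 <- cx + (pts$x - cx) * cos(th2) - (pts$y - cy) * sin(th2)
  yr2 <- cy + (pts$x - cx) * sin(th2) + (pts$y - cy) * cos(th2)
  rot2 <- centriolr:::bilinear(img, xr2, yr2)
  ok2 <- !is.na(rot2)
  expect_gt(max(abs(rot2[ok2] - orig[ok2])), 0.5 * max(img))
})

test_that("tilted rings foreshorten the projected extent by cos(tilt)", {
  r <- sim_ring_image(diameter_nm = 400, tilt_deg = 60, phase_deg = 10,
                      seed = 1)
  ry <- max(r$truth$y_px) - min(r$truth$y_px)
  rx <- max(r$truth$x_px) - min(r$truth$x_px)
  # projected truth coordinates span cos(60 deg) = 0.5 of the x footprint
  # (up to ninefold sampling of the circle, identical for both axes)
  flat <- sim_ring_image(diameter_nm = 400, tilt_deg = 0, phase_deg = 10,
                         seed = 1)
  fy <- max(flat$truth$y_px) - min(flat$truth$y_px)
  expect_equal(ry / fy, 0.5, tolerance = 1e-10)
  expect_equal(rx, max(flat$truth$x_px) - min(flat$truth$x_px),
               tolerance = 1e-10)
})

test_that("ring generator rejects sub-pixel diameters", {
  expect_error(sim_ring_image(diameter_nm = 30, pixel_size_nm = 40),
               "smaller than one pixel")
})

test_that("smlm scene: fiducial positions follow the drift exactly", {
  sc <- sim_smlm_scene(ring_n_locs = 200, vesicle_n_locs = 100,
                       partner_n_locs = 60, n_frames = 50,
                       affine = NULL, residual_shift_nm = c(0, 0, 0),
                       crlb_mean_nm = 10, outlier_fraction = 0, seed = 3)
  mem <- sc$truth$membership
  fid <- sc$locs[mem$species == "fiducial" & sc$locs$channel == "red", ]
  fid1 <- fid[abs(fid$x_nm - (-1500)) < 150 &
                abs(fid$y_nm - (-1500)) < 150, ]  # first bead only
  # before localization noise the bead sits at p + d(f); with noise it is
  # within a few CRLB of that
  d <- sc$truth$drift[fid1$frame, ]
  resid <- cbind(fid1$x_nm - (-1500) - d$dx_nm,
                 fid1$y_nm - (-1500) - d$dy_nm)
  expect_lt(max(abs(resid)), 6 * 12)  # 6 sd of the max crlb draw
  expect_equal(nrow(fid1), 50L)      # localized in every frame
})

test_that("smlm scene: zero-transform channels have coincident ring COMs", {
  sc <- sim_smlm_scene(ring_n_locs = 4000, vesicle_n_locs = 100,
                       partner_n_locs = 60, drift_amplitude_nm = c(0, 0, 0),
                       affine = NULL, residual_shift_nm = c(0, 0, 0),
                       outlier_fraction = 0, seed = 4)
  mem <- sc$truth$membership
  ring_r <- sc$locs[mem$species == "ring" & sc$locs$channel == "red", ]
  ring_g <- sc$locs[mem$species == "ring" & sc$locs$channel == "green", ]
  com_r <- colMeans(cbind(ring_r$x_nm, ring_r$y_nm, ring_r$z_nm))
  com_g <- colMeans(cbind(ring_g$x_nm, ring_g$y_nm, ring_g$z_nm))
  expect_lt(sqrt(sum((com_r - com_g)^2)), 10)  # sampling error only
  # configured separation is recorded exactly
  expect_equal(sc$truth$com_separation_nm, 89, tolerance = 1e-12)
})

test_that("smlm scene is deterministic under a fixed seed and rejects empties", {
  a <- sim_smlm_scene(ring_n_locs = 100, vesicle_n_locs = 50,
                      partner_n_locs = 30, n_frames = 20, seed = 5)
  b <- sim_smlm_scene(ring_n_locs = 100, vesicle_n_locs = 50,
                      partner_n_locs = 30, n_frames = 20, seed = 5)
  expect_identical(a$locs, b$locs)
  expect_error(sim_smlm_scene(ring_n_locs = 0, vesicle_n_locs = 0,
                              partner_n_locs = 0), "empty")
  expect_error(sim_smlm_scene(outlier_fraction = 0.6), "outlier_fraction")
})

test_that("nested dataset generator reproduces its hierarchical model", {
  # degenerate: no noise at either level -> values equal mean + effect
  d0 <- sim_nested_dataset(n_conditions = 2, condition_effects = c(0, 7),
                           replicate_sd = 0, cell_sd = 1e-9, seed = 1)
  expect_equal(unique(round(d0$value[d0$condition == "cond1"], 6)), 100)
  expect_equal(unique(round(d0$value[d0$condition == "cond2"], 6)), 107)

  # pooled mean within 3 SE of the grand mean under the null
  d1 <- sim_nested_dataset(n_conditions = 1, n_replicates = 4,
                           n_cells_per_replicate = 2500, replicate_sd = 2,
                           cell_sd = 10, seed = 2)
  se <- sqrt(2^2 / 4 + 10^2 / nrow(d1))
  expect_lt(abs(mean(d1$value) - 100), 3 * se)

  expect_identical(sim_nested_dataset(seed = 3), sim_nested_dataset(seed = 3))
  expect_error(sim_nested_dataset(n_replicates = 0), "n_replicates")
})

test_that("cilium field generator records true arc lengths", {
  cf <- sim_cilium_field(n_cilia = 5, seed = 2)
  expect_equal(nrow(cf$truth), 5L)
  expect_true(all(cf$truth$length_um >= 2 & cf$truth$length_um <= 5.1))
  # endpoints are length-consistent: chord <= arc
  chord <- sqrt((cf$truth$x1_px - cf$truth$x0_px)^2 +
                  (cf$truth$y1_px - cf$truth$y0_px)^2) * 100 / 1000
  expect_true(all(chord <= cf$truth$length_um + 1e-9))
})
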