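# SMLM post-processing: drift, filtering, registration, clusters.

test_that("csaps spline matches smooth.spline under the lambda mapping", {
  set.seed(1)
  x <- 1:200
  y <- 0.05 * x + rnorm(200, 0, 3)
  for (p in c(1e-6, 1e-4, 1e-2)) {
    f1 <- csaps_spline(x, y, p)
    lam <- (1 - p) / p / diff(range(x))^3  # smooth.spline works on [0, 1]
    f2 <- stats::smooth.spline(x, y, lambda = lam, all.knots = TRUE)$y
    expect_equal(f1, f2, tolerance = 1e-5)
  }
  # p -> 0 approaches the least-squares line
  f0 <- csaps_spline(x, y, 1e-9)
  lin <- unname(fitted(stats::lm(y ~ x)))
  expect_equal(f0, lin, tolerance = 1e-3)
})

test_that("drift fitting recovers linear drift and is deterministic", {
  set.seed(2)
  n <- 1000
  truth <- 0.5 * (seq_len(n) - 1)
  locs <- tibble::tibble(
    frame = seq_len(n),
    x_nm = 0 + truth + rnorm(n, 0, 10),
    y_nm = 0 + rnorm(n, 0, 10),
    z_nm = 0 + rnorm(n, 0, 10))
  tr <- track_fiducial_and_fit_drift(locs, c(0, 0, 0),
                                     capture_radius_nm = 800)
  expect_lt(sqrt(mean((tr$dx_nm - truth)^2)), 2)
  tr2 <- track_fiducial_and_fit_drift(locs, c(0, 0, 0),
                                      capture_radius_nm = 800)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))

  # zero drift, zero noise: trace identically zero
  still <- tibble::tibble(frame = 1:100, x_nm = 5, y_nm = -3, z_nm = 1)
  tr0 <- track_fiducial_and_fit_drift(still, c(5, -3, 1))
  expect_equal(max(abs(c(tr0$dx_nm, tr0$dy_nm, tr0$dz_nm))), 0,
               tolerance = 1e-9)
})

test_that("drift fitting enforces coverage and gap limits", {
  locs <- tibble::tibble(frame = c(1:10, 500:505), x_nm = 0, y_nm = 0,
                         z_nm = 0)
  expect_error(
    track_fiducial_and_fit_drift(locs, c(0, 0, 0), n_frames = 505),
    "coverage")
  locs2 <- tibble::tibble(frame = c(1:400, 480:505), x_nm = 0, y_nm = 0,
                          z_nm = 0)
  expect_error(
    track_fiducial_and_fit_drift(locs2, c(0, 0, 0), n_frames = 505,
                                 min_coverage = 0.5),
    "lost")
})

test_that("drift correction reduces fiducial scatter on every drifting seed", {
  for (seed in 1:10) {
    sc <- sim_smlm_scene(ring_n_locs = 300, vesicle_n_locs = 100,
                         partner_n_locs = 60, n_frames = 300,
                         affine = NULL, residual_shift_nm = c(0, 0, 0),
                         outlier_fraction = 0, seed = seed)
    red <- sc$locs[sc$locs$channel == "red", ]
    fid <- red[abs(red$x_nm - (-1500)) < 300 & abs(red$y_nm - (-1500)) < 300, ]
    tr <- track_fiducial_and_fit_drift(red, c(-1500, -1500, 0),
                                       n_frames = 300)
    fid_c <- apply_drift_correction(fid, tr)
    expect_lt(sd(fid_c$x_nm), sd(fid$x_nm))
    expect_lt(sd(fid_c$y_nm), sd(fid$y_nm))
  }
})

test_that("apply_drift_correction is exact bookkeeping", {
  tr <- structure(tibble::tibble(frame = 1:5, dx_nm = 1:5 * 1.0,
                                 dy_nm = 0, dz_nm = -1),
                  class = c("drift_trace", "tbl_df", "tbl", "data.frame"))
  locs <- tibble::tibble(frame = c(1L, 5L), x_nm = c(10, 10),
                         y_nm = 0, z_nm = 0)
  out <- apply_drift_correction(locs, tr)
  expect_equal(out$x_nm, c(9, 5))
  expect_equal(out$z_nm, c(1, 1))
  expect_error(apply_drift_correction(
    tibble::tibble(frame = 9L, x_nm = 0, y_nm = 0, z_nm = 0), tr),
    "outside")
})

test_that("quality filter removes spurious points, keeps clusters, idempotent", {
  set.seed(5)
  clust <- draw_cloud(1000, c(0, 0, 0), c(200, 200, 200))
  out <- tibble::tibble(x_nm = runif(50, -3000, 3000),
                        y_nm = runif(50, -3000, 3000),
                        z_nm = runif(50, -1000, 1000))
  keep_away <- sqrt(out$x_nm^2 + out$y_nm^2 + out$z_nm^2) > 600
  out <- out[keep_away, ]
  locs <- dplyr::bind_rows(
    dplyr::mutate(clust, crlb_xy_nm = 10, planted = FALSE),
    dplyr::mutate(out, crlb_xy_nm = 10, planted = TRUE))
  f <- filter_quality(locs)
  expect_lte(sum(f$planted), 0.05 * nrow(out))      # >= 95% outliers removed
  expect_gte(sum(!f$planted), 0.99 * 1000)          # <= 1% cluster loss
  # idempotent on this scene
  f2 <- filter_quality(f)
  expect_identical(as.data.frame(f2), as.data.frame(f))

  # CRLB filter alone removes nothing when all values pass
  all_good <- dplyr::mutate(clust, crlb_xy_nm = 10)
  expect_equal(nrow(filter_quality(all_good, nn_mean_dist_max_nm = Inf)),
               1000L)
  # CRLB above the cutoff is removed
  mixed <- all_good
  mixed$crlb_xy_nm[1:100] <- 30
  expect_equal(nrow(filter_quality(mixed, nn_mean_dist_max_nm = Inf)), 900L)

  expect_warning(filter_quality(all_good[1:5, ]), "too few")
  expect_error(filter_quality(all_good[0, ]), "empty")
})

test_that("affine estimation recovers a known transform exactly", {
  set.seed(6)
  beads <- cbind(runif(10, -2000, 2000), runif(10, -2000, 2000))
  th <- 1 * pi / 180; s <- 1.002
  A_true <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fixed <- t(A_true %*% t(beads)) + rep(c(50, -30), each = 10)
  aff <- estimate_affine(beads, fixed)
  expect_equal(aff$A, A_true, tolerance = 1e-10)
  expect_equal(aff$t_nm, c(50, -30), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(aff$rms_residual_nm, 1e-8)

  # identity on identical positions
  id <- estimate_affine(beads, beads)
  expect_equal(id$A, diag(2), tolerance = 1e-10)

  # noisy beads: residual tracks the noise level
  noisy <- fixed + rnorm(20, 0, 5)
  affn <- estimate_affine(beads, noisy)
  expect_lt(abs(affn$rms_residual_nm - 5 * sqrt(2)), 5)

  # collinear beads are degenerate
  line <- cbind(1:5 * 100, 1:5 * 50)
  expect_error(estimate_affine(line, line), "collinear|degenerate")
})

test_that("apply_affine moves localization tables as the matrix says", {
  aff <- estimate_affine(cbind(c(0, 1000, 0), c(0, 0, 1000)),
                         cbind(c(10, 1010, 10), c(20, 20, 1020)))
  locs <- tibble::tibble(x_nm = 500, y_nm = 500, z_nm = 7)
  out <- apply_affine(locs, aff)
  expect_equal(out$x_nm, 510, tolerance = 1e-8)
  expect_equal(out$y_nm, 520, tolerance = 1e-8)
  expect_equal(out$z_nm, 7)
})

test_that("3D cross-correlation recovers planted shifts to < 2 nm", {
  sc <- sim_smlm_scene(ring_n_locs = 12000, vesicle_n_locs = 0,
                       partner_n_locs = 0,
                       drift_amplitude_nm = c(0, 0, 0), affine = NULL,
                       residual_shift_nm = c(30, -20, 40),
                       outlier_fraction = 0, seed = 42)
  mem <- sc$truth$membership
  red <- sc$locs[sc$locs$channel == "red" & mem$species == "ring", ]
  grn <- sc$locs[sc$locs$channel == "green" & mem$species == "ring", ]
  reg <- refine_registration_3dcc(red, grn)
  expect_true(reg$converged)
  expect_lt(max(abs(reg$shift_nm + c(30, -20, 40))), 2)

  # zero offset: converges immediately with a sub-threshold shift
  reg0 <- refine_registration_3dcc(red, red)
  expect_true(reg0$converged)
  expect_equal(reg0$iterations, 1L)
  expect_lt(max(abs(reg0$shift_nm)), 2)

  # max_iter = 1 with a huge offset cannot converge
  far <- grn
  far$x_nm <- far$x_nm + 500
  regf <- refine_registration_3dcc(red, far, max_iter = 1)
  expect_false(regf$converged)
})

test_that("registration is antisymmetric in the moving channel", {
  sc <- sim_smlm_scene(ring_n_locs = 6000, vesicle_n_locs = 0,
                       partner_n_locs = 0,
                       drift_amplitude_nm = c(0, 0, 0), affine = NULL,
                       residual_shift_nm = c(25, 15, -30),
                       outlier_fraction = 0, seed = 13)
  mem <- sc$truth$membership
  red <- sc$locs[sc$locs$channel == "red" & mem$species == "ring", ]
  grn <- sc$locs[sc$locs$channel == "green" & mem$species == "ring", ]
  ab <- refine_registration_3dcc(red, grn)$shift_nm
  ba <- refine_registration_3dcc(grn, red)$shift_nm
  expect_equal(ab, -ba, tolerance = 0.15)
})

test_that("cluster isolation is a strict box selection", {
  locs <- tibble::tibble(x_nm = c(0, 10, 100), y_nm = c(0, 10, 100),
                         z_nm = c(0, 10, 100))
  box_all <- list(x = c(-1, 101), y = c(-1, 101), z = c(-1, 101))
  expect_equal(nrow(isolate_cluster(locs, box_all)), 3L)
  box_half <- list(x = c(-1, 50), y = c(-1, 101), z = c(-1, 101))
  inside <- isolate_cluster(locs, box_half)
  expect_equal(nrow(inside), 2L)
  expect_error(isolate_cluster(locs, list(x = c(200, 300), y = c(0, 1),
                                          z = c(0, 1))),
               "no localizations")
  expect_error(isolate_cluster(locs, list(x = c(1, 1), y = c(0, 1),
                                          z = c(0, 1))),
               "volume")
})

test_that("axis fits recover 1/e2 widths and degrade gracefully", {
  cl <- draw_cloud(2000, c(100, -50, 20), c(230, 170, 190), seed = 7)
  cs <- cluster_axis_fit(cl)
  expect_equal(cs$per_axis$width_1e2_nm, c(230, 170, 190), tolerance = 0.1)
  expect_equal(unname(cs$com_nm), c(100, -50, 20), tolerance = 0.15)
  expect_true(all(cs$per_axis$fitted))
  expect_equal(cs$per_axis$width_1e2_nm, 4 * cs$per_axis$sigma_nm)

  # isotropic cloud: three widths agree
  iso <- draw_cloud(5000, c(0, 0, 0), c(200, 200, 200), seed = 8)
  csi <- cluster_axis_fit(iso)
  expect_lt(diff(range(csi$per_axis$width_1e2_nm)) /
              mean(csi$per_axis$width_1e2_nm), 0.1)

  # convergence to 4 sigma at large n (moment-level agreement, 2%)
  big <- draw_cloud(10000, c(0, 0, 0), c(230, 170, 190), seed = 9)
  csb <- cluster_axis_fit(big)
  expect_equal(csb$per_axis$width_1e2_nm, c(230, 170, 190),
               tolerance = 0.02)

  expect_error(cluster_axis_fit(cl[1:10, ]), "localizations")
})

test_that("vesicle candidate filter applies the inclusive 120 nm rule", {
  expect_true(vesicle_candidate_filter(c(230, 170, 190)))
  expect_false(vesicle_candidate_filter(c(110, 200, 200)))
  expect_true(vesicle_candidate_filter(c(120, 120, 120)))
  cl <- draw_cloud(2000, c(0, 0, 0), c(230, 170, 190), seed = 10)
  expect_true(vesicle_candidate_filter(cluster_axis_fit(cl)))
})

test_that("COM offsets recover planted separations", {
  # same draw: separation ~ 0
  cl <- draw_cloud(2000, c(0, 0, 0), c(230, 170, 190), seed = 12)
  same <- com_offset(cl, cl)
  expect_lt(same$separation_nm, 1e-9)

  # planted 89 nm separation, unequal counts
  dir <- c(1, 1, 1) / sqrt(3)
  a <- draw_cloud(2000, c(0, 0, 0), c(230, 170, 190), seed = 13)
  b <- draw_cloud(500, 89 * dir, c(230, 170, 190), seed = 14)
  co <- com_offset(a, b)
  expect_lt(abs(co$separation_nm - 89), 10)

  # single-axis offset leaves the other axes near zero
  b2 <- draw_cloud(1500, c(75, 0, 0), c(200, 200, 200), seed = 15)
  a2 <- draw_cloud(1500, c(0, 0, 0), c(200, 200, 200), seed = 16)
  co2 <- com_offset(a2, b2)
  expect_equal(unname(co2$offset_nm[1]), 75, tolerance = 0.15)
  expect_lt(max(abs(co2$offset_nm[2:3])), 12)
})

test_that("distance_to_structure is plain 3D geometry", {
  expect_equal(distance_to_structure(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(distance_to_structure(c(0, 0, 0), c(100, 0, 0)), 100)
  expect_equal(distance_to_structure(c(0, 0, 0), c(30, 40, 0)), 50)
  expect_error(distance_to_structure(c(0, 0), c(1, 2, 3)), "3D")
})

test_that("full synthetic scenes round-trip through the whole pipeline", {
  # drift + affine + residual shift, then: drift-correct both channels,
  # bead affine, 3D cross-correlation, cluster COM separation
  for (seed in c(101, 202)) {
    sc <- sim_smlm_scene(seed = seed)
    locs <- filter_quality(sc$locs, nn_mean_dist_max_nm = 300)
    red <- locs[locs$channel == "red", ]
    grn <- locs[locs$channel == "green", ]
    fids <- sc$truth$fiducials_nm

    drift_red <- track_fiducial_and_fit_drift(red, fids[1, ],
                                              n_frames = 1000)
    red_c <- apply_drift_correction(red, drift_red)
    # the green channel's bead is displaced by the affine: seed the track
    # from its transformed position
    fid_g <- centriolr:::apply_affine_xy(fids, sc$truth$affine) +
      rep(sc$truth$residual_shift_nm, each = nrow(fids))
    drift_grn <- track_fiducial_and_fit_drift(grn, fid_g[1, ],
                                              n_frames = 1000)
    grn_c <- apply_drift_correction(grn, drift_grn)

    # bead positions after drift correction
    bead_pos <- function(ch, seeds) {
      t(sapply(seq_len(nrow(seeds)), function(i) {
        sel <- (ch$x_nm - seeds[i, 1])^2 + (ch$y_nm - seeds[i, 2])^2 < 300^2
        c(mean(ch$x_nm[sel]), mean(ch$y_nm[sel]))
      }))
    }
    aff <- estimate_affine(bead_pos(grn_c, fid_g), bead_pos(red_c, fids))
    grn_a <- apply_affine(grn_c, aff)

    ring_box <- list(x = c(-400, 400), y = c(-400, 400), z = c(-400, 400))
    reg <- refine_registration_3dcc(isolate_cluster(red_c, ring_box),
                                    isolate_cluster(grn_a, ring_box))
    expect_true(reg$converged)
    grn_r <- grn_a
    grn_r$x_nm <- grn_r$x_nm + reg$shift_nm[1]
    grn_r$y_nm <- grn_r$y_nm + reg$shift_nm[2]
    grn_r$z_nm <- grn_r$z_nm + reg$shift_nm[3]

    ves_box <- list(x = c(300, 900), y = c(100, 700), z = c(-250, 400))
    ves <- isolate_cluster(red_c, ves_box)
    par <- isolate_cluster(grn_r, ves_box)
    co <- com_offset(ves, par)
    expect_lt(abs(co$separation_nm - sc$truth$com_separation_nm), 10)
  }
})
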