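#' Threshold a background-subtracted image into a binary mask
#'
#' Stand-in for the manual per-image threshold of semi-automated
#' quantification ("the minimum level that covers only the structure"): an
#' explicit, recorded rule. Three strategies are provided:
#' \describe{
#'   \item{`mean_sd`}{threshold = mean + `value` * SD of the background
#'     (default `value = 5`), with the background sampled as the dimmest
#'     95% of pixels so that bright structures cannot inflate the
#'     threshold; both statistics scale with the image, keeping the rule
#'     homogeneous under intensity scaling.}
#'   \item{`absolute`}{threshold = `value` in image counts.}
#'   \item{`percentile`}{threshold = the `value` quantile (`value` in
#'     \[0, 1\]).}
#' }
#'
#' @param image Numeric matrix, background-subtracted.
#' @param strategy One of `"mean_sd"`, `"absolute"`, `"percentile"`.
#' @param value Strategy parameter (k, absolute level, or probability).
#' @return Logical matrix; pixels at or above the threshold are `TRUE`. The
#'   chosen threshold is attached as attribute `"threshold"`.
#' @export
threshold_mask <- function(image, strategy = c("mean_sd", "absolute",
                                               "percentile"),
                           value = NULL) {
  strategy <- match.arg(strategy)
  thr <- switch(strategy,
    mean_sd = {
      bg <- image[image <= quantile(image, 0.95, names = FALSE)]
      t0 <- mean(bg) + (value %||% 5) * sd(bg)
      # noise-free background has zero SD; fall back to a token positive
      # threshold so the mask covers the structures, not the background
      if (!is.finite(t0) || t0 <= 0) t0 <- 1e-6 * max(image)
      t0
    },
    absolute = {
      if (is.null(value)) abort("`absolute` strategy needs a `value`.")
      value
    },
    percentile = quantile(image, value %||% 0.999, names = FALSE))
  mask <- image >= thr
  if (!any(mask)) warn("threshold_mask: threshold produced an empty mask.")
  attr(mask, "threshold") <- thr
  mask
}

#' Combine reference and POI masks and merge split centrosome components
#'
#' Reproduces the mask-combination step of two-channel centrosome
#' quantification: the two binary masks are stacked and max-projected
#' (pixelwise union), then iteratively dilated until the connected-component
#' count stops decreasing (so the reference and POI footprints of the same
#' centrosome merge into one particle) or `dilation_max_iter` is reached,
#' then eroded the same number of iterations to restore the footprint size.
#' Components are then labeled.
#'
#' @param mask_ref,mask_poi Logical matrices of identical shape.
#' @param dilation_max_iter Maximum dilation iterations (default 10).
#' @param erosion_iter Erosions applied after merging; `NULL` (default)
#'   erodes once per dilation performed.
#' @return Integer label matrix (0 = background). Attributes: `"dilations"`
#'   (iterations used) and `"merged"` (`FALSE` if the component count was
#'   still decreasing when `dilation_max_iter` was hit).
#' @export
combine_and_merge_masks <- function(mask_ref, mask_poi,
                                    dilation_max_iter = 10,
                                    erosion_iter = NULL) {
  if (!all(dim(mask_ref) == dim(mask_poi))) {
    abort("masks must have identical dimensions.")
  }
  combined <- mask_ref | mask_poi
  if (!any(combined)) {
    out <- matrix(0L, nrow(combined), ncol(combined))
    attr(out, "dilations") <- 0L; attr(out, "merged") <- TRUE
    return(out)
  }
  current <- combined
  n_prev <- max(label_components(current))
  dilations <- 0L
  merged <- TRUE
  while (dilations < dilation_max_iter) {
    candidate <- binary_dilate(current)
    n_new <- max(label_components(candidate))
    if (n_new >= n_prev) break  # count stable: dilation no longer merges
    current <- candidate
    dilations <- dilations + 1L
    n_prev <- n_new
  }
  if (dilations == dilation_max_iter &&
      max(label_components(binary_dilate(current))) < n_prev) {
    merged <- FALSE
  }
  # label at the merged stage, then erode the footprint while keeping the
  # pairing: a component split again by erosion keeps a single label
  out <- label_components(current)
  n_erode <- erosion_iter %||% dilations
  if (n_erode > 0) out <- out * binary_erode(current, n_erode)
  out <- matrix(as.integer(out), nrow(out), ncol(out))
  attr(out, "dilations") <- dilations
  attr(out, "merged") <- merged
  out
}

#' Measure labeled particles on an intensity image
#'
#' The particle-analysis step: every labeled component whose area lies in
#' `size_range_px2` and whose circularity (`4 * pi * area / perimeter^2`,
#' perimeter = EBImage boundary-pixel estimator, clamped at 1) lies in
#' `circularity_range` yields one measurement row. Components touching the
#' image border are discarded (their shape metrics are biased). Integrated
#' intensity is the sum of image counts under the component, per channel.
#'
#' @param labels Integer label matrix (0 = background), e.g. from
#'   [combine_and_merge_masks()].
#' @param image Numeric matrix or [image_field()] aligned with `labels`;
#'   should already be background-subtracted.
#' @param size_range_px2 Admissible component area range (pixels^2).
#' @param circularity_range Admissible circularity range within `[0, 1]`.
#' @return Tibble with one row per accepted particle: `particle_id`, `x_px`,
#'   `y_px` (centroid), `area_px2`, `circularity`, and one
#'   `intensity_<channel>` column per channel.
#' @export
analyze_particles <- function(labels, image,
                              size_range_px2 = c(4, 400),
                              circularity_range = c(0, 1)) {
  imgs <- if (inherits(image, "image_field")) {
    chn <- dimnames(image$data)[[3]]
    setNames(lapply(seq_along(chn), function(i) image$data[, , i]), chn)
  } else list(intensity = image)
  if (!all(dim(labels) == dim(imgs[[1]]))) {
    abort("`labels` and `image` dimensions differ.")
  }
  empty <- tibble(particle_id = integer(), x_px = double(), y_px = double(),
                  area_px2 = double(), circularity = double())
  for (nm in names(imgs)) empty[[paste0("intensity_", nm)]] <- double()
  n_lab <- max(labels)
  if (n_lab == 0L) return(empty)

  shp <- EBImage::computeFeatures.shape(labels)
  mom <- EBImage::computeFeatures.moment(labels)
  area <- shp[, "s.area"]
  area[is.na(area)] <- 0
  perim <- pmax(shp[, "s.perimeter"], 1)
  circ <- pmin(4 * pi * area / perim^2, 1)

  # border exclusion
  border_ids <- unique(c(labels[1, ], labels[nrow(labels), ],
                         labels[, 1], labels[, ncol(labels)]))
  keep <- area >= size_range_px2[1] & area <= size_range_px2[2] &
    circ >= circularity_range[1] & circ <= circularity_range[2] &
    !(seq_len(n_lab) %in% border_ids)
  if (!any(keep)) return(empty)

  ids <- which(keep)
  out <- tibble(particle_id = ids,
                x_px = mom[ids, "m.cx"], y_px = mom[ids, "m.cy"],
                area_px2 = area[ids], circularity = circ[ids])
  lab_vec <- as.vector(labels)
  for (nm in names(imgs)) {
    sums <- rowsum(as.vector(imgs[[nm]])[lab_vec > 0], lab_vec[lab_vec > 0])
    out[[paste0("intensity_", nm)]] <-
      unname(sums[match(ids, as.integer(rownames(sums))), 1])
  }
  out
}

#' Quantify per-centrosome fluorescence intensity in a two-channel field
#'
#' The full semi-automated centrosomal intensity pipeline: rolling-ball
#' background subtraction of the reference (centrosome-marker) and POI
#' channels, thresholding of each, mask combination by max projection with
#' dilate/erode merging, particle analysis with size and circularity gates,
#' and robust outlier flagging of the POI intensities with the ROUT method.
#' Outliers are flagged, never removed; apply the flag downstream if
#' exclusion is wanted.
#'
#' @param field An [image_field()] containing at least the reference and POI
#'   channels.
#' @param ref_channel,poi_channel Channel names.
#' @param rolling_ball_radius_px Rolling-ball radius (default 5).
#' @param threshold_strategy,threshold_value Passed to [threshold_mask()],
#'   applied to both channels.
#' @param dilation_max_iter Passed to [combine_and_merge_masks()].
#' @param size_range_px2,circularity_range Particle gates for
#'   [analyze_particles()]; defaults suit diffraction-limited centrosomal
#'   puncta at ~100 nm pixels.
#' @param rout_q ROUT false discovery rate for outlier flagging (default
#'   0.01).
#' @return Tibble of centrosome measurements ([analyze_particles()] columns)
#'   plus a logical `outlier` column (ROUT flag on the POI intensity).
#'   Attribute `"provenance"` records every parameter used.
#' @export
quantify_centrosomal_intensity <- function(field,
                                           ref_channel = "ref",
                                           poi_channel = "poi",
                                           rolling_ball_radius_px = 5,
                                           threshold_strategy = "mean_sd",
                                           threshold_value = 5,
                                           dilation_max_iter = 10,
                                           size_range_px2 = c(4, 400),
                                           circularity_range = c(0.5, 1),
                                           rout_q = 0.01) {
  stopifnot(inherits(field, "image_field"))
  chn <- dimnames(field$data)[[3]]
  if (!all(c(ref_channel, poi_channel) %in% chn)) {
    abort("field is missing the reference or POI channel.")
  }
  sub <- rolling_ball_subtract(field, rolling_ball_radius_px)
  m_ref <- threshold_mask(field_channel(sub, ref_channel),
                          threshold_strategy, threshold_value)
  m_poi <- threshold_mask(field_channel(sub, poi_channel),
                          threshold_strategy, threshold_value)
  labels <- combine_and_merge_masks(m_ref, m_poi,
                                    dilation_max_iter = dilation_max_iter)
  out <- analyze_particles(labels, sub, size_range_px2, circularity_range)
  poi_col <- paste0("intensity_", poi_channel)
  out$outlier <- if (nrow(out) >= 3) {
    rout_outliers(out[[poi_col]], q = rout_q)
  } else {
    rep(FALSE, nrow(out))
  }
  attr(out, "provenance") <- list(
    pipeline = "centrosomal_intensity",
    ref_channel = ref_channel, poi_channel = poi_channel,
    rolling_ball_radius_px = rolling_ball_radius_px,
    threshold_strategy = threshold_strategy,
    threshold_value = threshold_value,
    dilation_max_iter = dilation_max_iter,
    size_range_px2 = size_range_px2,
    circularity_range = circularity_range, rout_q = rout_q,
    version = as.character(utils::packageVersion("centriolr")))
  out
}

#' Quantify per-cilium integrated intensity
#'
#' Single-channel variant of the intensity pipeline for ciliary markers
#' (ARL13B-like): rolling-ball subtraction, thresholding of the cilium
#' channel only, component labeling, and particle analysis with
#' filament-tuned gates (larger areas, low circularity — cilia are
#' elongated). No mask merging and no second channel are involved.
#'
#' @inheritParams quantify_centrosomal_intensity
#' @param channel Cilium-marker channel name.
#' @param size_range_px2,circularity_range Filament-tuned particle gates
#'   (large areas, circularity below 0.8 — the boundary-pixel perimeter
#'   estimator rates short rods up to ~0.75, disks ~1).
#' @return Tibble of per-cilium measurements (see [analyze_particles()]).
#' @export
quantify_ciliary_intensity <- function(field,
                                       channel = "arl13b",
                                       rolling_ball_radius_px = 5,
                                       threshold_strategy = "mean_sd",
                                       threshold_value = 5,
                                       size_range_px2 = c(20, 5000),
                                       circularity_range = c(0, 0.8)) {
  stopifnot(inherits(field, "image_field"))
  if (!channel %in% dimnames(field$data)[[3]]) {
    abort(sprintf("field is missing channel '%s'.", channel))
  }
  sub <- rolling_ball_subtract(field_channel(field, channel),
                               rolling_ball_radius_px)
  mask <- threshold_mask(sub, threshold_strategy, threshold_value)
  labels <- label_components(mask)
  out <- analyze_particles(labels, sub, size_range_px2, circularity_range)
  names(out)[names(out) == "intensity_intensity"] <-
    paste0("intensity_", channel)
  attr(out, "provenance") <- list(
    pipeline = "ciliary_intensity", channel = channel,
    rolling_ball_radius_px = rolling_ball_radius_px,
    threshold_strategy = threshold_strategy,
    threshold_value = threshold_value,
    size_range_px2 = size_range_px2,
    circularity_range = circularity_range,
    version = as.character(utils::packageVersion("centriolr")))
  out
}
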