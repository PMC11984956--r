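# Cluster isolation, per-axis Gaussian sizing, COM offsets and distances.

#' Isolate localizations inside an axis-aligned 3D box
#'
#' Explicit, reproducible stand-in for the manual isolation of a structure:
#' the box is recorded with the result.
#'
#' @param locs Localization tibble with `x_nm, y_nm, z_nm`.
#' @param box List with elements `x`, `y`, `z`, each `c(min, max)` in nm.
#' @return Tibble of localizations inside the box (attribute `"box"`).
#' @export
isolate_cluster <- function(locs, box) {
  locs <- as_tibble(locs)
  if (!all(c("x", "y", "z") %in% names(box))) {
    abort("`box` needs elements x, y, z (each c(min, max)).")
  }
  if (any(sapply(box, diff) <= 0)) abort("`box` must have positive volume.")
  keep <- locs$x_nm >= box$x[1] & locs$x_nm <= box$x[2] &
    locs$y_nm >= box$y[1] & locs$y_nm <= box$y[2] &
    locs$z_nm >= box$z[1] & locs$z_nm <= box$z[2]
  if (!any(keep)) abort("ROI contains no localizations.")
  out <- locs[keep, ]
  attr(out, "box") <- box
  out
}

# Fit a single Gaussian to a 1D localization coordinate via its histogram.
# Returns mean, sigma and whether the nonlinear fit converged (otherwise
# moment estimates are used).
fit_axis_gaussian <- function(v, bin_nm = 10) {
  m0 <- mean(v); s0 <- sd(v)
  if (!is.finite(s0) || s0 == 0) {
    return(list(mean = m0, sigma = 0, fitted = FALSE))
  }
  breaks <- seq(min(v) - bin_nm, max(v) + bin_nm, by = bin_nm)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  fit <- tryCatch(
    stats::nls(y ~ a * exp(-(x - mu)^2 / (2 * sig^2)), data = df,
               start = list(a = max(df$y), mu = m0, sig = s0),
               lower = c(a = 0, mu = -Inf, sig = bin_nm / 10),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    list(mean = m0, sigma = s0, fitted = FALSE)
  } else {
    cf <- stats::coef(fit)
    list(mean = unname(cf["mu"]), sigma = abs(unname(cf["sig"])),
         fitted = TRUE)
  }
}

#' Per-axis Gaussian sizing of an isolated localization cluster
#'
#' Histograms the cluster's localizations along x, y and z (bin width
#' `bin_nm`), fits a single Gaussian per axis, and reports the fitted
#' means (the 3D centre of mass) and the 1/e2 full widths (`4 * sigma`;
#' a Gaussian falls to `exp(-2)` of its peak at two sigma from the
#' centre). Non-converging fits fall back to sample moments with a flag.
#'
#' @param locs Localization tibble with at least `min_locs` rows.
#' @param bin_nm Histogram bin width (default 10 nm).
#' @param min_locs Minimum localization count (default 50).
#' @return A `cluster_summary`: tibble-backed list with per-axis `mean_nm`,
#'   `sigma_nm`, `width_1e2_nm`, `fitted`, plus `com_nm` and `n_locs`.
#' @export
cluster_axis_fit <- function(locs, bin_nm = 10, min_locs = 50) {
  locs <- as_tibble(locs)
  if (nrow(locs) < min_locs) {
    abort(sprintf("cluster has %d localizations (< %d).", nrow(locs),
                  min_locs))
  }
  axes <- list(x = locs$x_nm, y = locs$y_nm, z = locs$z_nm)
  fits <- lapply(axes, fit_axis_gaussian, bin_nm = bin_nm)
  per_axis <- tibble(
    axis = names(axes),
    mean_nm = unname(sapply(fits, `[[`, "mean")),
    sigma_nm = unname(sapply(fits, `[[`, "sigma")),
    width_1e2_nm = 4 * unname(sapply(fits, `[[`, "sigma")),
    fitted = unname(sapply(fits, `[[`, "fitted")))
  structure(list(per_axis = per_axis,
                 com_nm = setNames(per_axis$mean_nm, per_axis$axis),
                 n_locs = nrow(locs), bin_nm = bin_nm),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf(
    "<cluster_summary> n = %d; 1/e2 widths (%.0f, %.0f, %.0f) nm; COM (%.1f, %.1f, %.1f) nm\n",
    x$n_locs, x$per_axis$width_1e2_nm[1], x$per_axis$width_1e2_nm[2],
    x$per_axis$width_1e2_nm[3], x$com_nm[1], x$com_nm[2], x$com_nm[3]))
  invisible(x)
}

#' @export
tidy.cluster_summary <- function(x, ...) x$per_axis

#' @export
glance.cluster_summary <- function(x, ...) {
  tibble(width_x_nm = x$per_axis$width_1e2_nm[1],
         width_y_nm = x$per_axis$width_1e2_nm[2],
         width_z_nm = x$per_axis$width_1e2_nm[3],
         n_locs = x$n_locs)
}

#' Vesicle-candidate size filter
#'
#' A cluster counts as a vesicle candidate only if all three 1/e2 widths
#' reach `min_dim_nm` (default 120 nm, boundary inclusive); smaller
#' clusters are excluded as non-vesicular.
#'
#' @param summary A [cluster_axis_fit()] result (or a numeric length-3
#'   vector of 1/e2 widths).
#' @param min_dim_nm Minimum admissible width per axis.
#' @return `TRUE` if the cluster qualifies.
#' @export
vesicle_candidate_filter <- function(summary, min_dim_nm = 120) {
  widths <- if (inherits(summary, "cluster_summary")) {
    summary$per_axis$width_1e2_nm
  } else {
    as.numeric(summary)
  }
  if (length(widths) != 3L) abort("three 1/e2 widths are required.")
  all(widths >= min_dim_nm)
}

#' Centre-of-mass offset between two localization species
#'
#' Fits one Gaussian per species per axis (as in [cluster_axis_fit()]),
#' takes the difference of the fitted means per axis, and reports the 3D
#' Euclidean separation of the two centres of mass.
#'
#' @param locs_a,locs_b Localization tibbles of the two species.
#' @param bin_nm Histogram bin width for the axis fits.
#' @param min_locs Minimum localization count per species.
#' @return A `com_offset` object: `offset_nm` (per-axis, b minus a),
#'   `separation_nm`, and the two [cluster_axis_fit()] summaries.
#' @export
com_offset <- function(locs_a, locs_b, bin_nm = 10, min_locs = 50) {
  fa <- cluster_axis_fit(locs_a, bin_nm = bin_nm, min_locs = min_locs)
  fb <- cluster_axis_fit(locs_b, bin_nm = bin_nm, min_locs = min_locs)
  off <- fb$com_nm - fa$com_nm
  structure(list(offset_nm = off,
                 separation_nm = sqrt(sum(off^2)),
                 summary_a = fa, summary_b = fb),
            class = "com_offset")
}

#' @export
print.com_offset <- function(x, ...) {
  cat(sprintf(
    "<com_offset> per-axis (%.1f, %.1f, %.1f) nm; 3D separation %.1f nm\n",
    x$offset_nm[1], x$offset_nm[2], x$offset_nm[3], x$separation_nm))
  invisible(x)
}

#' @export
glance.com_offset <- function(x, ...) {
  tibble(offset_x_nm = x$offset_nm[1], offset_y_nm = x$offset_nm[2],
         offset_z_nm = x$offset_nm[3], separation_nm = x$separation_nm)
}

#' Euclidean 3D distance between two centres of mass
#'
#' @param com_a,com_b Length-3 numeric vectors (nm), e.g. `com_nm` from
#'   [cluster_axis_fit()].
#' @return Distance in nm.
#' @export
distance_to_structure <- function(com_a, com_b) {
  if (length(com_a) != 3L || length(com_b) != 3L) {
    abort("both centres of mass must be 3D points.")
  }
  sqrt(sum((as.numeric(com_b) - as.numeric(com_a))^2))
}
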