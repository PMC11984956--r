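#' Quality-filter a localization table
#'
#' Removes imprecise and spurious localizations: localizations with a
#' lateral CRLB above `crlb_max_nm` are dropped, then localizations whose
#' mean 3D distance to their `nn_k` nearest neighbours exceeds
#' `nn_mean_dist_max_nm` are dropped (isolated points far from any
#' structure). With fewer than `nn_k + 1` localizations the neighbour
#' filter is skipped with a warning.
#'
#' @param locs Localization tibble (`x_nm, y_nm, z_nm, crlb_xy_nm, ...`).
#' @param crlb_max_nm Maximum admissible lateral CRLB (default 20 nm).
#' @param nn_k Number of nearest neighbours (default 8).
#' @param nn_mean_dist_max_nm Maximum admissible mean neighbour distance
#'   (default 200 nm).
#' @return Filtered tibble (never more rows than the input).
#' @export
filter_quality <- function(locs, crlb_max_nm = 20, nn_k = 8,
                           nn_mean_dist_max_nm = 200) {
  locs <- as_tibble(locs)
  if (nrow(locs) == 0L) abort("empty localization table.")
  if ("crlb_xy_nm" %in% names(locs)) {
    locs <- locs[locs$crlb_xy_nm <= crlb_max_nm, ]
  }
  n <- nrow(locs)
  if (n < nn_k + 1L) {
    warn("too few localizations for the neighbour filter; skipped.")
    return(locs)
  }
  md <- knn_mean_dist(cbind(locs$x_nm, locs$y_nm, locs$z_nm), nn_k)
  locs[md <= nn_mean_dist_max_nm, ]
}

# Mean distance to the k nearest neighbours, chunked brute force.
knn_mean_dist <- function(pts, k, chunk = 512L) {
  n <- nrow(pts)
  out <- numeric(n)
  sq <- rowSums(pts^2)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(pts[idx, , drop = FALSE],
                                                   pts)
    d2[cbind(seq_along(idx), idx)] <- Inf  # exclude self
    d2[d2 < 0] <- 0
    out[idx] <- apply(d2, 1, function(row) {
      mean(sqrt(sort.int(row, partial = k)[seq_len(k)]))
    })
  }
  out
}
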