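#' ROUT outlier flagging for a single measurement column
#'
#' Robust outlier identification at a chosen false-discovery rate,
#' specialized from the robust-regression-plus-outlier-removal (ROUT)
#' procedure of Motulsky & Brown (2006) to a constant model (one column of
#' values): the robust centre is the median; the robust scale is the RSDR —
#' the 68.27th percentile of the absolute residuals with the small-sample
#' correction `n / (n - 1)`; candidate points are then examined from the
#' most extreme inward with a t-like statistic `|residual| / RSDR`
#' (`df = n - 1`), each compared against the FDR-style threshold
#' `alpha_i = q * (n - i + 1) / n`, stopping at the first point that fails.
#' Values are flagged, never removed — exclusion is the caller's explicit
#' decision.
#'
#' @param values Numeric vector, n >= 3.
#' @param q False discovery rate in `(0, 0.5)` (default 0.01, i.e. 1%).
#' @return Logical vector parallel to `values`; `TRUE` marks an outlier.
#' @export
rout_outliers <- function(values, q = 0.01) {
  if (length(values) < 3L) abort("ROUT needs at least 3 values.")
  check_number(q, "q", min = 0, strict_min = TRUE)
  if (q >= 0.5) abort("`q` must be below 0.5.")
  n <- length(values)
  resid <- values - median(values)
  rsdr <- quantile(abs(resid), 0.6827, names = FALSE) * n / (n - 1)
  rsdr <- max(rsdr, .Machine$double.eps)
  tstat <- abs(resid) / rsdr
  p <- 2 * pt(-tstat, df = n - 1)

  ord <- order(p)                 # most extreme first
  flags <- logical(n)
  for (i in seq_len(n)) {
    alpha_i <- q * (n - i + 1) / n
    if (p[ord[i]] < alpha_i) {
      flags[ord[i]] <- TRUE
    } else {
      break
    }
  }
  flags
}
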