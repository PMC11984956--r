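#' Simulate a nested (condition / replicate / cell) measurement dataset
#'
#' Generates per-cell measurements under the hierarchical model used by
#' nested tests: `value = grand_mean + condition_effect + replicate_noise +
#' cell_noise`, with a shared replicate-level random intercept
#' `N(0, replicate_sd)` and independent per-cell noise `N(0, cell_sd)`.
#'
#' @param n_conditions Number of conditions.
#' @param n_replicates Replicates (independent experiments) per condition.
#' @param n_cells_per_replicate Cells measured per replicate.
#' @param grand_mean Baseline mean.
#' @param condition_effects Numeric vector of length `n_conditions`; additive
#'   shift of each condition.
#' @param replicate_sd SD of the replicate-level random intercept (>= 0).
#' @param cell_sd SD of the per-cell noise (> 0).
#' @param seed Integer seed or `NULL`.
#' @return Tibble with columns `condition` (factor), `replicate` (integer),
#'   `cell` (integer), `value`.
#' @export
sim_nested_dataset <- function(n_conditions = 2,
                               n_replicates = 3,
                               n_cells_per_replicate = 30,
                               grand_mean = 100,
                               condition_effects = rep(0, n_conditions),
                               replicate_sd = 5,
                               cell_sd = 15,
                               seed = NULL) {
  check_count(n_conditions, "n_conditions", min = 1L)
  check_count(n_replicates, "n_replicates", min = 1L)
  check_count(n_cells_per_replicate, "n_cells_per_replicate", min = 1L)
  check_number(replicate_sd, "replicate_sd", min = 0)
  check_number(cell_sd, "cell_sd", min = 0, strict_min = TRUE)
  if (length(condition_effects) != n_conditions) {
    abort("`condition_effects` must have one entry per condition.")
  }

  with_seed(seed, {
    grid <- tidyr::expand_grid(
      condition = factor(paste0("cond", seq_len(n_conditions)),
                         levels = paste0("cond", seq_len(n_conditions))),
      replicate = seq_len(n_replicates),
      cell = seq_len(n_cells_per_replicate))
    rep_fx <- rnorm(n_conditions * n_replicates, 0, replicate_sd)
    idx <- (as.integer(grid$condition) - 1L) * n_replicates + grid$replicate
    grid$value <- grand_mean +
      condition_effects[as.integer(grid$condition)] +
      rep_fx[idx] +
      rnorm(nrow(grid), 0, cell_sd)
    grid
  })
}
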