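#' Score the ciliated fraction of a cell population
#'
#' A cell counts as ciliated when it bears a structure that is positive for
#' the ciliary membrane marker (ARL13B), longer than 1 micrometre (strict
#' inequality), and associated with the centrosome. Cells without a
#' candidate structure simply contribute to the denominator.
#'
#' @param records Data frame with one row per candidate structure, columns
#'   `arl13b` (logical), `length_um` (numeric) and optionally
#'   `centrosome_associated` (logical; assumed `TRUE` when absent).
#' @param n_cells Number of cells scored. Defaults to `nrow(records)`
#'   (one candidate per cell); must be supplied when cells without
#'   candidates exist.
#' @param min_length_um Length threshold (default 1; comparison is strict).
#' @return One-row tibble: `n_cells`, `n_ciliated`, `ciliated_fraction`.
#' @export
score_ciliation <- function(records, n_cells = nrow(records),
                            min_length_um = 1) {
  records <- as_tibble(records)
  if (n_cells <= 0) abort("`n_cells` must be positive.")
  assoc <- records$centrosome_associated %||% rep(TRUE, nrow(records))
  hit <- records$arl13b & records$length_um > min_length_um & assoc
  n_cil <- sum(hit, na.rm = TRUE)
  if (n_cil > n_cells) abort("more ciliated structures than cells.")
  tibble(n_cells = as.integer(n_cells), n_ciliated = as.integer(n_cil),
         ciliated_fraction = n_cil / n_cells)
}

#' Score per-marker and double vesicle positivity of centrioles
#'
#' A centriole is positive for a marker when a punctum of that marker lies
#' within `radius_nm` of the centriole's reference position; double
#' positivity requires both markers on the same centriole. Mirrors the
#' "percentage of centrioles positive for indicated markers" readout.
#'
#' @param records Data frame with one row per centriole and, for each
#'   marker, a column `dist_<marker>_nm` holding the distance from the
#'   centriole to the nearest punctum of that marker (`NA` or `Inf` when no
#'   punctum exists).
#' @param markers Character vector of marker names (default the two
#'   preciliary-vesicle markers `rab34` and `myo5a`).
#' @param radius_nm Colocalization radius in nanometres (default 500).
#' @return Tibble with one row per marker plus one `double` row:
#'   `marker`, `n`, `n_positive`, `percent`.
#' @export
score_vesicle_positivity <- function(records,
                                     markers = c("rab34", "myo5a"),
                                     radius_nm = 500) {
  records <- as_tibble(records)
  check_number(radius_nm, "radius_nm", min = 0, strict_min = TRUE)
  n <- nrow(records)
  if (n == 0L) abort("no centriole records.")
  pos <- sapply(markers, function(m) {
    col <- paste0("dist_", m, "_nm")
    if (!col %in% names(records)) {
      abort(sprintf("records lack column '%s'.", col))
    }
    d <- records[[col]]
    !is.na(d) & is.finite(d) & d <= radius_nm
  })
  pos <- matrix(pos, nrow = n)
  out <- tibble(marker = c(markers, "double"),
                n = as.integer(n),
                n_positive = c(colSums(pos), sum(rowSums(pos) == length(markers))))
  out$percent <- 100 * out$n_positive / n
  out
}

#' Score CP110 dots per cell from centriole and dot positions
#'
#' Implements the CP110-removal counting rule. Per cell, the two FOP dots
#' mark the two centrioles and the CEP164 dot marks the mother centriole;
#' CP110 colocalizing (within `radius_nm`) with both FOP dots counts as two
#' dots, CP110 colocalizing only with the CEP164-negative (daughter) FOP
#' dot counts as one dot, anything else as zero. Cells with more than two
#' FOP dots are skipped with a message.
#'
#' @param dots Data frame with one row per detected dot: `cell_id`,
#'   `kind` (one of `"fop"`, `"cep164"`, `"cp110"`), `x_nm`, `y_nm` and
#'   optionally `z_nm`.
#' @param radius_nm Colocalization radius in nanometres (default 500).
#' @return Tibble with one row per scored cell: `cell_id`, `n_fop`,
#'   `cp110_dots` (0, 1 or 2).
#' @export
score_cp110 <- function(dots, radius_nm = 500) {
  dots <- as_tibble(dots)
  if (!all(c("cell_id", "kind", "x_nm", "y_nm") %in% names(dots))) {
    abort("`dots` needs columns cell_id, kind, x_nm, y_nm.")
  }
  if (!"z_nm" %in% names(dots)) dots$z_nm <- 0
  res <- lapply(split(dots, dots$cell_id), function(cell) {
    fop <- cell[cell$kind == "fop", ]
    if (nrow(fop) > 2L) {
      inform(sprintf("cell %s skipped: %d FOP dots (> 2).",
                     cell$cell_id[1], nrow(fop)))
      return(NULL)
    }
    if (nrow(fop) == 0L) return(NULL)
    cep <- cell[cell$kind == "cep164", ]
    cp <- cell[cell$kind == "cp110", ]
    near <- function(a, b) {
      if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
      d <- outer(a$x_nm, b$x_nm, "-")^2 + outer(a$y_nm, b$y_nm, "-")^2 +
        outer(a$z_nm, b$z_nm, "-")^2
      apply(sqrt(d) <= radius_nm, 1, any)
    }
    fop_has_cp110 <- near(fop, cp)
    fop_is_mother <- near(fop, cep)
    n_dots <- if (nrow(fop) == 2L && all(fop_has_cp110)) {
      2L
    } else if (any(fop_has_cp110 & !fop_is_mother) &&
               !any(fop_has_cp110 & fop_is_mother)) {
      1L
    } else {
      0L
    }
    tibble(cell_id = cell$cell_id[1], n_fop = nrow(fop), cp110_dots = n_dots)
  })
  dplyr::bind_rows(res)
}
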