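# File interfaces: 16-bit TIFF image fields with pixel-size metadata and the
# localization-table CSV dialect.

#' Write an image field as a 16-bit multi-page TIFF
#'
#' One page per channel; values are rounded to integer counts and clipped
#' to `[0, 65535]` (16-bit quantization). The pixel size and channel names
#' are recorded in a `<path>.meta.json` sidecar so [read_field_tiff()] can
#' restore the field.
#'
#' @param field An [image_field()].
#' @param path Output path.
#' @param truth Optional truth tibble written as a `<path>_truth.csv`
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path, truth = NULL) {
  stopifnot(inherits(field, "image_field"))
  chn <- dimnames(field$data)[[3]]
  pages <- lapply(seq_along(chn), function(i) {
    t(pmin(pmax(round(field$data[, , i]), 0), 65535)) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- sprintf(
    '{"pixel_size_nm": %s, "channels": [%s]}',
    format(field$pixel_size_nm, digits = 15),
    paste(sprintf('"%s"', chn), collapse = ", "))
  writeLines(meta, paste0(path, ".meta.json"))
  if (!is.null(truth)) {
    readr::write_csv(truth, paste0(tools::file_path_sans_ext(path),
                                   "_truth.csv"))
  }
  invisible(path)
}

#' Read an image field written by [write_field_tiff()]
#'
#' @param path TIFF path.
#' @param pixel_size_nm Override for the pixel size if the file has no
#'   metadata sidecar.
#' @return An [image_field()].
#' @export
read_field_tiff <- function(path, pixel_size_nm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  channels <- NULL
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- paste(readLines(meta_path, warn = FALSE), collapse = "")
    px <- regmatches(meta,
                     regexec('"pixel_size_nm"\\s*:\\s*([0-9.eE+-]+)',
                             meta))[[1]]
    if (length(px) == 2L) pixel_size_nm <- pixel_size_nm %||% as.numeric(px[2])
    ch <- regmatches(meta, regexec('"channels"\\s*:\\s*\\[([^]]*)\\]',
                                   meta))[[1]]
    if (length(ch) == 2L) {
      channels <- gsub('[" ]', "", strsplit(ch[2], ",")[[1]])
    }
  }
  if (is.null(pixel_size_nm)) {
    abort("no pixel size available; supply `pixel_size_nm`.")
  }
  mats <- lapply(pages, function(p) t(p) * 65535)
  data <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  image_field(data, pixel_size_nm, channels)
}

#' Write / read localization tables in the package CSV dialect
#'
#' Columns: `frame, x_nm, y_nm, z_nm, photons, crlb_xy_nm, channel`.
#'
#' @param locs Localization tibble.
#' @param path CSV path.
#' @return `write_locs_csv()` returns `path` invisibly; `read_locs_csv()`
#'   returns the tibble.
#' @export
write_locs_csv <- function(locs, path) {
  cols <- c("frame", "x_nm", "y_nm", "z_nm", "photons", "crlb_xy_nm",
            "channel")
  missing_cols <- setdiff(cols, names(locs))
  if (length(missing_cols)) {
    abort(paste("locs table lacks columns:",
                paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(locs[, cols], path)
  invisible(path)
}

#' @rdname write_locs_csv
#' @export
read_locs_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    frame = readr::col_integer(),
                    x_nm = readr::col_double(),
                    y_nm = readr::col_double(),
                    z_nm = readr::col_double(),
                    photons = readr::col_double(),
                    crlb_xy_nm = readr::col_double(),
                    channel = readr::col_character()))
}
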