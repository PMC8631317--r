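#' Write a rendered field of view as 16-bit TIFF
#'
#' Files are named `<plate>_<well>_f<k>.tif`, the layout a plate imager
#' produces.
#'
#' @param image Numeric matrix in ADU.
#' @param dir Output directory (created if needed).
#' @param plate_id,well_id,field Identifiers for the file name.
#' @param bit_depth 8 or 16.
#' @return The written path, invisibly.
#' @export
write_field_tiff <- function(image, dir, plate_id, well_id, field = 1L,
                             bit_depth = 16L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s_f%d.tif", plate_id, well_id, field))
  maxval <- 2^bit_depth - 1
  tiff::writeTIFF(
    pmin(pmax(image / maxval, 0), 1), path,
    bits.per.sample = as.integer(bit_depth)
  )
  invisible(path)
}

#' Read a field of view written by [write_field_tiff()]
#'
#' @param path TIFF path.
#' @param bit_depth Bit depth the file was written at.
#' @return Numeric matrix in ADU.
#' @export
read_field_tiff <- function(path, bit_depth = 16L) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * (2^bit_depth - 1)
}

#' Write / read per-cell measurement tables
#'
#' Plain-CSV round trip for the per-cell tables exchanged between the
#' morphometry and screening stages; widths and lengths are written in
#' micrometres with 4 decimals.
#'
#' @param cells Per-cell tibble.
#' @param path CSV path.
#' @return `write_cells_csv()` the path invisibly; `read_cells_csv()` a
#'   tibble.
#' @export
write_cells_csv <- function(cells, path) {
  out <- cells
  for (col in intersect(
    c("width_um", "length_um", "mean_width", "mean_length"),
    names(out)
  )) {
    out[[col]] <- round(out[[col]], 4)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
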