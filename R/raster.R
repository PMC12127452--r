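#' SAR raster stack / high-resolution image containers
#'
#' A stack holds one 2-D grid per acquisition date as a `[n_rows, n_cols,
#' n_dates]` array aligned to a [grid_spec()]; a hires image is the 3-band
#' `[rows, cols, 3]` analogue. Values are plain backscatter (dB-like) or
#' intensity numbers; no radiometric processing is done here.
#'
#' @param values Numeric array `[n_rows, n_cols, n_dates]`.
#' @param dates Strictly increasing numeric day-of-year vector, one per slice.
#' @param grid A [grid_spec()] matching the array dimensions.
#' @param polarization `"VH"` (default) or `"VV"`.
#' @return A `pitt_stack` object.
#' @export
raster_stack <- function(values, dates, grid, polarization = "VH") {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == length(dates),
            dim(values)[1] == grid$n_rows, dim(values)[2] == grid$n_cols,
            !is.unsorted(dates, strictly = TRUE))
  structure(list(values = values, dates = as.numeric(dates), grid = grid,
                 polarization = polarization),
            class = "pitt_stack")
}

#' @export
print.pitt_stack <- function(x, ...) {
  cat(sprintf("<pitt_stack> %s, %d dates (doy %g-%g), %d x %d px of %g m\n",
              x$polarization, length(x$dates), min(x$dates), max(x$dates),
              x$grid$n_rows, x$grid$n_cols, x$grid$pixel_side))
  invisible(x)
}

hires_image <- function(values, grid) {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == 3,
            dim(values)[1] == grid$n_rows, dim(values)[2] == grid$n_cols)
  structure(list(values = values, grid = grid), class = "pitt_image")
}

#' Write / read a raster stack as plain-text CSV grids
#'
#' One headerless CSV matrix per date plus `dates.csv` (band_index, date,
#' file) and `grid.csv` sidecars.
#'
#' @param stack A `pitt_stack`.
#' @param dir Output directory (created if needed).
#' @return `dir` (write) or a `pitt_stack` (read).
#' @export
write_stack_csv <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("band_%02d.csv", seq_along(stack$dates))
  for (i in seq_along(stack$dates)) {
    utils::write.table(stack$values[, , i], file.path(dir, files[i]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  readr::write_csv(tibble(band_index = seq_along(stack$dates),
                          date = stack$dates, file = files),
                   file.path(dir, "dates.csv"))
  g <- stack$grid
  readr::write_csv(tibble(n_rows = g$n_rows, n_cols = g$n_cols,
                          pixel_side = g$pixel_side, origin_x = g$origin_x,
                          origin_y = g$origin_y, polarization = stack$polarization),
                   file.path(dir, "grid.csv"))
  invisible(dir)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(dir) {
  meta <- readr::read_csv(file.path(dir, "dates.csv"), show_col_types = FALSE)
  g <- readr::read_csv(file.path(dir, "grid.csv"), show_col_types = FALSE)
  grid <- grid_spec(g$n_rows, g$n_cols, g$pixel_side, g$origin_x, g$origin_y)
  vals <- array(NA_real_, c(grid$n_rows, grid$n_cols, nrow(meta)))
  for (i in seq_len(nrow(meta))) {
    vals[, , i] <- as.matrix(utils::read.table(file.path(dir, meta$file[i]), sep = ","))
  }
  raster_stack(vals, meta$date, grid, g$polarization %||% "VH")
}
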