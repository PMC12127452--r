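#' SAR pixel grid specification
#'
#' Axis-aligned square pixels of side `pixel_side` (map units, default 10 m).
#' The origin is the upper-left corner of pixel (1,1); rows run top to bottom
#' (y decreasing), columns left to right, and footprints are half-open
#' `[x, x + L) x (y - L, y]`.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param pixel_side Pixel side length L in map units.
#' @param origin_x,origin_y Map coordinates of the upper-left grid corner.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(n_rows, n_cols, pixel_side = 10, origin_x = 0, origin_y = n_rows * pixel_side) {
  stopifnot(pixel_side > 0, n_rows >= 1, n_cols >= 1)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_side = pixel_side, origin_x = origin_x, origin_y = origin_y),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels of %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$pixel_side, x$origin_x, x$origin_y))
  invisible(x)
}

# tibble of all pixel centers (or a subset of rows/cols)
pixel_centers <- function(grid, rows = seq_len(grid$n_rows), cols = seq_len(grid$n_cols)) {
  g <- expand.grid(row = rows, col = cols)
  tibble(
    row = g$row, col = g$col,
    x = grid$origin_x + (g$col - 0.5) * grid$pixel_side,
    y = grid$origin_y - (g$row - 0.5) * grid$pixel_side
  )
}

# rows/cols of pixels whose centers could fall in an xy bounding box
bbox_pixel_range <- function(grid, bb, pad = 0) {
  L <- grid$pixel_side
  col_lo <- max(1L, floor((bb["xmin"] - grid$origin_x - pad) / L - 0.5) + 1L)
  col_hi <- min(grid$n_cols, ceiling((bb["xmax"] - grid$origin_x + pad) / L + 0.5))
  row_lo <- max(1L, floor((grid$origin_y - bb["ymax"] - pad) / L - 0.5) + 1L)
  row_hi <- min(grid$n_rows, ceiling((grid$origin_y - bb["ymin"] + pad) / L + 0.5))
  if (col_lo > col_hi || row_lo > row_hi) return(NULL)
  list(rows = row_lo:row_hi, cols = col_lo:col_hi)
}
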