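#' Scale levels used for parcel grading
#'
#' The grading ladder counts whole non-mixed pixels guaranteed at the parcel
#' centre: 0, 1, a cross of 5, a 3x3 block of 9, 16, ... Pixels are ranked by
#' centre distance from the central pixel, ties broken in row-major order.
#' @export
pitt_scale_levels <- c(0L, 1L, 5L, 9L, 16L)

# offsets (a, b) of the i lattice cells nearest the central pixel centre,
# ties broken row-major (top-to-bottom, then left-to-right)
nearest_cell_offsets <- function(i) {
  if (i == 0) return(matrix(numeric(0), 0, 2))
  m <- ceiling(sqrt(i)) + 2
  g <- expand.grid(a = -m:m, b = m:-m)
  ord <- order(g$a^2 + g$b^2, -g$b, g$a)
  as.matrix(g[ord[seq_len(i)], c("a", "b")])
}

#' Standard inscribed radius for scale level i
#'
#' The minimal radius of a circle centred on a pixel centre that fully
#' contains the `i` lattice pixels (side `L`) nearest that centre: the circle
#' must reach the farthest corner of the farthest selected pixel.
#'
#' @param i Scale level, one of [pitt_scale_levels] (any non-negative integer
#'   is accepted; the ladder values are the ones used for grading).
#' @param pixel_side Pixel side L in map units.
#' @return Radius R_i in map units (`R_0 = 0`).
#' @examples
#' standard_radius(1, 10)  # sqrt(2)/2 * 10
#' standard_radius(5, 10)  # sqrt(2.5) * 10
#' @export
standard_radius <- function(i, pixel_side = 10) {
  check_scale_level(i)
  if (i == 0) return(0)
  off <- nearest_cell_offsets(i)
  corner <- sqrt((abs(off[, 1]) + 0.5)^2 + (abs(off[, 2]) + 0.5)^2)
  max(corner) * pixel_side
}

check_scale_level <- function(i) {
  if (length(i) != 1 || is.na(i) || i < 0 || i != round(i))
    stop("scale level must be a non-negative integer; grading uses {",
         paste(pitt_scale_levels, collapse = ", "), ", ...}", call. = FALSE)
  invisible(i)
}

#' Grading radius threshold R_ti = R_i + R_b
#'
#' The buffer `R_b` absorbs misalignment between the circle centre and the
#' nearest pixel centre. The default is half the pixel diagonal,
#' `sqrt(2)/2 * L`: a circle of radius `R_i + sqrt(2)/2 * L` centred anywhere
#' still covers the same pixel arrangement around the nearest pixel centre.
#' `buffer_mode = "printed"` uses `(L/2)^2` instead (a published variant whose
#' units do not reduce to a length; kept for strict-reproduction runs), and
#' `"custom"` takes `buffer` directly.
#'
#' @inheritParams standard_radius
#' @param buffer_mode One of `"half_diagonal"` (default), `"printed"`, `"custom"`.
#' @param buffer Non-negative buffer in map units when `buffer_mode = "custom"`.
#' @return Threshold radius in map units.
#' @export
radius_threshold <- function(i, pixel_side = 10,
                             buffer_mode = c("half_diagonal", "printed", "custom"),
                             buffer = NULL) {
  buffer_mode <- match.arg(buffer_mode)
  rb <- switch(buffer_mode,
    half_diagonal = sqrt(2) / 2 * pixel_side,
    printed = (pixel_side / 2)^2,
    custom = {
      if (is.null(buffer) || is.na(buffer) || buffer < 0)
        stop("custom buffer must be a non-negative number", call. = FALSE)
      buffer
    })
  standard_radius(i, pixel_side) + rb
}

#' Compute maximum inscribed circles for a parcel table
#'
#' @param parcels Parcel tibble with a `geometry` list-column of
#'   [pitt_polygon] objects (see [read_parcels_geojson()] / [simulate_parcels()]).
#' @param precision Solver tolerance in map units; default `1e-3 * pixel_side`.
#' @param pixel_side Pixel side used to scale the default precision.
#' @return The tibble with `center_x`, `center_y`, `inscribed_radius` columns.
#' @export
compute_inscribed_circles <- function(parcels, pixel_side = 10,
                                      precision = 1e-3 * pixel_side) {
  mic <- purrr::map(parcels$geometry, max_inscribed_circle, precision = precision)
  parcels$center_x <- purrr::map_dbl(mic, ~ .x$center[[1]])
  parcels$center_y <- purrr::map_dbl(mic, ~ .x$center[[2]])
  parcels$inscribed_radius <- purrr::map_dbl(mic, "radius")
  parcels
}

#' Grade parcels by scale level and split into small / micro branches
#'
#' A parcel's scale level is the largest ladder level `i` whose threshold
#' `R_ti` its inscribed radius reaches; parcels below every threshold stay at
#' level 0. Levels at or above the `standard_level` (default 5, the point
#' where the parcel centre holds a full cross of non-mixed pixels under a
#' 10 m grid) go to the `"small"` branch (time-series classification), the
#' rest to `"micro"` (texture classification).
#'
#' @param parcels Parcel tibble with `inscribed_radius` (see
#'   [compute_inscribed_circles()]).
#' @param pixel_side Pixel side L in map units.
#' @param levels Grading ladder; default [pitt_scale_levels].
#' @param standard_level Branch cut-off level.
#' @inheritParams radius_threshold
#' @return The tibble with `scale_level` and `branch` columns.
#' @export
grade_parcels <- function(parcels, pixel_side = 10, levels = pitt_scale_levels,
                          standard_level = 5,
                          buffer_mode = c("half_diagonal", "printed", "custom"),
                          buffer = NULL) {
  buffer_mode <- match.arg(buffer_mode)
  if (!"inscribed_radius" %in% names(parcels))
    stop("run compute_inscribed_circles() first: no inscribed_radius column", call. = FALSE)
  levels <- sort(levels)
  thr <- vapply(levels, radius_threshold, 0, pixel_side = pixel_side,
                buffer_mode = buffer_mode, buffer = buffer)
  lvl <- vapply(parcels$inscribed_radius, function(r) {
    ok <- which(r >= thr)
    if (length(ok)) levels[max(ok)] else levels[1]
  }, 0L)
  parcels$scale_level <- lvl
  parcels$branch <- ifelse(lvl >= standard_level, "small", "micro")
  parcels
}

#' @rdname grade_parcels
#' @return `partition_parcels()`: a list with `small` and `micro` character
#'   vectors of parcel ids (disjoint, covering the input).
#' @export
partition_parcels <- function(parcels) {
  list(small = parcels$parcel_id[parcels$branch == "small"],
       micro = parcels$parcel_id[parcels$branch == "micro"])
}
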