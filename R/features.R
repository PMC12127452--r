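#' Classify the SAR pixels of one parcel into interior and edge sets
#'
#' A pixel is covered when its centre lies inside the polygon. A covered
#' pixel is *interior* when its whole square footprint lies strictly inside
#' (all four corners inside at positive boundary distance and no boundary
#' segment crossing the footprint); other covered pixels are *edge* pixels,
#' the candidates for mixed-signal contamination.
#'
#' @param poly A [pitt_polygon].
#' @param grid A [grid_spec()].
#' @return A list with tibbles `interior` and `edge` (columns row, col, x, y)
#'   and logical `empty` flagging a parcel that covers no pixel centre.
#' @export
classify_parcel_pixels <- function(poly, grid) {
  L <- grid$pixel_side
  rng <- bbox_pixel_range(grid, polygon_bbox(poly), pad = L)
  if (is.null(rng)) {
    warning("parcel overlaps no grid pixels", call. = FALSE)
    empty <- pixel_centers(grid, integer(0), integer(0))
    return(list(interior = empty, edge = empty, empty = TRUE))
  }
  px <- pixel_centers(grid, rng$rows, rng$cols)
  covered <- point_in_polygon(px$x, px$y, poly)
  px <- px[covered, , drop = FALSE]
  if (nrow(px) == 0) {
    warning("parcel covers no pixel centres", call. = FALSE)
    return(list(interior = px, edge = px, empty = TRUE))
  }
  eps <- 1e-9 * L
  h <- L / 2
  corner_ok <- rep(TRUE, nrow(px))
  for (s in list(c(-h, -h), c(h, -h), c(-h, h), c(h, h))) {
    corner_ok <- corner_ok &
      polygon_distance(px$x + s[1], px$y + s[2], poly) > eps
  }
  crossed <- footprint_crossed(px$x, px$y, h, poly)
  interior <- corner_ok & !crossed
  list(interior = px[interior, , drop = FALSE],
       edge = px[!interior, , drop = FALSE],
       empty = FALSE)
}

# does any polygon boundary segment intersect the closed square of half-side h
# centred at (cx, cy)? Liang-Barsky style slab test, vectorised over pixels.
footprint_crossed <- function(cx, cy, h, poly) {
  edges <- polygon_edges(poly)
  hit <- rep(FALSE, length(cx))
  for (e in seq_len(nrow(edges))) {
    x1 <- edges[e, 1] - cx; y1 <- edges[e, 2] - cy
    dx <- edges[e, 3] - cx - x1; dy <- edges[e, 4] - cy - y1
    t0 <- rep(0, length(cx)); t1 <- rep(1, length(cx)); ok <- rep(TRUE, length(cx))
    for (p in list(list(-dx, x1 + h), list(dx, h - x1), list(-dy, y1 + h), list(dy, h - y1))) {
      pi_ <- rep(p[[1]], length.out = length(cx)); qi <- p[[2]]
      para <- pi_ == 0
      ok <- ok & !(para & qi < 0)
      r <- ifelse(para, NA_real_, qi / pi_)
      t0 <- ifelse(!para & pi_ < 0, pmax(t0, r), t0)
      t1 <- ifelse(!para & pi_ > 0, pmin(t1, r), t1)
    }
    hit <- hit | (ok & t0 <= t1)
  }
  hit
}

#' Extract per-parcel SAR time series
#'
#' Per-date value is the unweighted mean of the selected pixel set:
#' * `"full"` - every covered pixel (all-pixel inclusion);
#' * `"edge_excluded"` - interior pixels only, falling back to `"full"` when
#'   a parcel has no interior pixel (recorded in `fallback`);
#' * `"central_k"` - the `k` covered pixels nearest the inscribed-circle
#'   centre (ties broken row-major); requires `center_x`/`center_y` from
#'   [compute_inscribed_circles()].
#'
#' @param parcels Parcel tibble.
#' @param stack A [raster_stack()].
#' @param method Pixel-selection strategy.
#' @param k Pixel count for `central_k` (default 9, a 3x3-equivalent core).
#' @return Long tibble: `parcel_id, date, value, method, n_pixels, fallback`.
#' @export
extract_timeseries <- function(parcels, stack,
                               method = c("full", "edge_excluded", "central_k"),
                               k = 9) {
  method <- match.arg(method)
  grid <- stack$grid
  n_dates <- length(stack$dates)
  flat <- matrix(stack$values, nrow = grid$n_rows * grid$n_cols, ncol = n_dates)
  out <- purrr::map(seq_len(nrow(parcels)), function(i) {
    sets <- suppressWarnings(classify_parcel_pixels(parcels$geometry[[i]], grid))
    covered <- rbind(sets$interior, sets$edge)
    if (nrow(covered) == 0)
      stop("parcel ", parcels$parcel_id[i], " covers no pixel centres", call. = FALSE)
    fallback <- FALSE
    sel <- switch(method,
      full = covered,
      edge_excluded = {
        if (nrow(sets$interior) == 0) { fallback <- TRUE; covered } else sets$interior
      },
      central_k = {
        cx <- parcels$center_x[i]; cy <- parcels$center_y[i]
        if (is.null(cx) || is.na(cx))
          stop("central_k needs inscribed-circle centres; run compute_inscribed_circles()",
               call. = FALSE)
        d2 <- (covered$x - cx)^2 + (covered$y - cy)^2
        ord <- order(d2, covered$row, covered$col)
        covered[ord[seq_len(min(k, nrow(covered)))], , drop = FALSE]
      })
    idx <- (sel$col - 1L) * grid$n_rows + sel$row
    vals <- colMeans(flat[idx, , drop = FALSE])
    tibble(parcel_id = parcels$parcel_id[i], date = stack$dates, value = vals,
           method = method, n_pixels = nrow(sel), fallback = fallback)
  })
  dplyr::bind_rows(out)
}

#' Standardize per-parcel time series for shape-based analysis
#'
#' Default is z-normalisation (zero mean, unit population standard
#' deviation), the preprocessing k-Shape's cross-correlation distance
#' assumes; `scaling = "center"` does mean-only centring. The pre-scaling
#' mean level of each series is preserved in `raw_mean_level` so that
#' amplitude conflicts can still be detected after shapes are made
#' comparable. Zero-variance series come back as zeros with `degenerate`
#' set.
#'
#' @param ts Long time-series tibble from [extract_timeseries()].
#' @param scaling `"z"` (default) or `"center"`.
#' @return The tibble with standardized `value`, plus `raw_mean_level` and
#'   `degenerate` columns.
#' @export
mean_standardize <- function(ts, scaling = c("z", "center")) {
  scaling <- match.arg(scaling)
  ts |>
    dplyr::group_by(.data$parcel_id) |>
    dplyr::mutate(
      raw_mean_level = mean(.data$value),
      .sd = sqrt(mean((.data$value - mean(.data$value))^2)),
      degenerate = .data$.sd == 0,
      value = dplyr::case_when(
        .data$degenerate ~ 0,
        scaling == "z" ~ (.data$value - mean(.data$value)) / .data$.sd,
        TRUE ~ .data$value - mean(.data$value)
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".sd")
}

# long tibble -> series matrix [n_parcels, n_dates], rows named by id,
# canonical id order (sorted) for determinism
ts_matrix <- function(ts) {
  wide <- ts |>
    dplyr::select("parcel_id", "date", "value") |>
    dplyr::arrange(.data$parcel_id, .data$date) |>
    tidyr::pivot_wider(names_from = "date", values_from = "value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$parcel_id
  m
}

ts_dates <- function(ts) sort(unique(ts$date))

#' Cut square texture chips centred on parcels
#'
#' A `side x side` window of the high-resolution image centred on each
#' parcel's inscribed-circle centre; windows clipped by the image border are
#' zero-padded back to full size. Following the backbone-adaptation rule,
#' chips with `side < 32` are upsampled to 32 x 32 by nearest-neighbour
#' replication before model use (`resized_to` records this); larger sides
#' are used as-is.
#'
#' @param parcels Parcel tibble with `center_x`/`center_y`.
#' @param image A hires image (list with `values` `[rows, cols, 3]` and `grid`).
#' @param side Chip side in pixels, one of 8, 16, 32, 64, 96.
#' @param mask_background Zero out pixels outside the parcel polygon
#'   (default `FALSE`: raw square window).
#' @return Tibble `parcel_id, side, resized_to, chip` (list-column of
#'   `[s, s, 3]` arrays after the resize rule).
#' @export
extract_chips <- function(parcels, image, side = 32, mask_background = FALSE) {
  stopifnot(side %in% c(8, 16, 32, 64, 96))
  if (!"center_x" %in% names(parcels))
    stop("chips need inscribed-circle centres; run compute_inscribed_circles()", call. = FALSE)
  g <- image$grid
  half <- side / 2
  chips <- purrr::map(seq_len(nrow(parcels)), function(i) {
    cx <- parcels$center_x[i]; cy <- parcels$center_y[i]
    ccol <- floor((cx - g$origin_x) / g$pixel_side) + 1
    crow <- floor((g$origin_y - cy) / g$pixel_side) + 1
    if (ccol < 1 || ccol > g$n_cols || crow < 1 || crow > g$n_rows)
      stop("parcel ", parcels$parcel_id[i], " centre lies outside the image", call. = FALSE)
    rows <- (crow - half + 1):(crow + half)
    cols <- (ccol - half + 1):(ccol + half)
    chip <- array(0, c(side, side, 3))
    rok <- rows >= 1 & rows <= g$n_rows
    cok <- cols >= 1 & cols <= g$n_cols
    chip[rok, cok, ] <- image$values[rows[rok], cols[cok], , drop = FALSE]
    if (mask_background) {
      ctr <- pixel_centers_subset(g, rows, cols)
      inside <- matrix(point_in_polygon(ctr$x, ctr$y, parcels$geometry[[i]]),
                       side, side)
      chip <- chip * as.numeric(inside)
    }
    if (side < 32) resize_nn(chip, 32) else chip
  })
  resized <- if (side < 32) 32L else NA_integer_
  tibble(parcel_id = parcels$parcel_id, side = side, resized_to = resized,
         chip = chips)
}

# centres for an arbitrary (possibly out-of-range) row/col window
pixel_centers_subset <- function(grid, rows, cols) {
  g <- expand.grid(row = rows, col = cols)
  list(x = grid$origin_x + (g$col - 0.5) * grid$pixel_side,
       y = grid$origin_y - (g$row - 0.5) * grid$pixel_side)
}

#' Nearest-neighbour upsampling of a square chip
#' @param chip `[s, s, bands]` array.
#' @param new_side Target side; must be a multiple of the current side.
#' @return `[new_side, new_side, bands]` array.
#' @export
resize_nn <- function(chip, new_side) {
  s <- dim(chip)[1]
  if (new_side %% s != 0)
    stop("nearest-neighbour resize needs an integer replication factor", call. = FALSE)
  f <- new_side / s
  idx <- rep(seq_len(s), each = f)
  chip[idx, idx, , drop = FALSE]
}
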