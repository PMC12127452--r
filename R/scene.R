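# Synthetic scene generation: irregular parcel mosaics, SAR stacks with
# crop-specific phenology and boundary mixed pixels, and a high-resolution
# texture image, all deterministic given one seed.

#' Scene configuration
#'
#' Defaults encode the emulated study conditions: a 10 m SAR grid, ten
#' acquisition dates from early January (day 8) to late May (day 140), a 2 m
#' three-band optical image, three classes, and piecewise-linear VH
#' templates in which wheat declines gradually through the season while
#' rapeseed rises to a mid-April (day 105) peak before dropping sharply.
#' Wheat's within-class spread (level and shape jitter) is set above
#' rapeseed's, so wheat groups are the noisier, less representative ones.
#'
#' @param n_per_level_class Parcels per size level per class.
#' @param size_levels Target grading levels for the strata.
#' @param classes Class names (subset of rape/wheat/other).
#' @param pixel_side SAR pixel side (m).
#' @param hires_side Optical pixel side (m).
#' @param dates Acquisition days of year.
#' @param noise_sd Per-pixel per-date Gaussian backscatter noise (dB-like).
#' @param level_sd,shape_sd,curve_sd Named per-class standard deviations of
#'   the parcel-level offset, smooth seasonal shape jitter, and per-date
#'   biological wobble of the clean curves (wheat's spread is the largest).
#' @param supersample Subsamples per pixel axis for area-weighted mixing.
#' @param texture Named list per class: `period` (px), `orientation` (deg),
#'   `contrast`, `noise`.
#' @param region_width Scene width in metres (bands of parcels stack below
#'   each other as needed).
#' @return A config list.
#' @export
scene_config <- function(n_per_level_class = 50,
                         size_levels = c(0, 1, 5, 9),
                         classes = PITT_CLASSES,
                         pixel_side = 10, hires_side = 2,
                         dates = round(seq(8, 140, length.out = 10)),
                         noise_sd = 1.2,
                         level_sd = c(rape = 0.4, wheat = 0.8, other = 0.6),
                         shape_sd = c(rape = 0.2, wheat = 0.45, other = 0.35),
                         curve_sd = c(rape = 0.15, wheat = 0.4, other = 0.3),
                         supersample = 4,
                         texture = list(
                           rape  = list(period = 8,  orientation = 0,  contrast = 0.35, noise = 0.05),
                           wheat = list(period = 8,  orientation = 90, contrast = 0.35, noise = 0.05),
                           other = list(period = 16, orientation = 45, contrast = 0.10, noise = 0.08)),
                         region_width = 1200) {
  stopifnot(all(classes %in% PITT_CLASSES), !is.unsorted(dates, strictly = TRUE))
  list(n_per_level_class = n_per_level_class, size_levels = sort(size_levels),
       classes = classes, pixel_side = pixel_side, hires_side = hires_side,
       dates = as.numeric(dates), noise_sd = noise_sd,
       level_sd = level_sd, shape_sd = shape_sd, curve_sd = curve_sd,
       supersample = supersample,
       texture = texture, region_width = region_width)
}

# piecewise-linear VH templates (day-of-year -> backscatter, dB-like)
curve_templates <- function() {
  list(
    rape  = list(doy = c(8, 40, 70, 105, 125, 140),
                 db  = c(-17, -16, -13.5, -11, -14.5, -16.5)),
    wheat = list(doy = c(8, 40, 70, 105, 140),
                 db  = c(-12, -13, -14.5, -16.5, -17.5)),
    other = list(doy = c(8, 50, 90, 140),
                 db  = c(-15.5, -15, -13.8, -13.2)),
    other_bare = list(doy = c(8, 30, 60, 140),
                      db  = c(-11, -13.2, -13.5, -13.6)),
    background = list(doy = c(8, 140), db = c(-15.2, -15.2))
  )
}

template_at <- function(name, doy) {
  tpl <- curve_templates()[[name]]
  stats::approx(tpl$doy, tpl$db, xout = doy, rule = 2)$y
}

#' Phenology references for the synthetic classes
#'
#' The class template curves themselves, the "typical sample" input of the
#' prototype-to-class mapping. The heterogeneous "other" class carries two
#' typical samples (grassland green-up and bare-land drying).
#' @param config A [scene_config()].
#' @return A [phenology_reference()].
#' @export
scene_references <- function(config = scene_config()) {
  curves <- lapply(setNames(config$classes, config$classes),
                   template_at, doy = config$dates)
  if ("other" %in% config$classes)
    curves$other <- list(template_at("other", config$dates),
                         template_at("other_bare", config$dates))
  phenology_reference(curves, config$dates)
}

# per-level target inscribed-radius windows (inside [R_ti, R_t(next)) with
# margin) and mosaic cell sizes
level_geometry <- function(levels, pixel_side) {
  ladder <- pitt_scale_levels
  thr <- vapply(ladder, radius_threshold, 0, pixel_side = pixel_side)
  upper <- c(thr[-1], thr[length(thr)] + 4 * pixel_side)
  lo <- pmax(thr + 0.04 * pixel_side, 0.75 * pixel_side)
  hi <- upper - 0.04 * pixel_side
  lo[1] <- 0.75 * pixel_side  # level-0 parcels: small but still holding a pixel centre
  i <- match(levels, ladder)
  if (anyNA(i)) stop("unsupported size level(s): ",
                     paste(levels[is.na(i)], collapse = ", "), call. = FALSE)
  tibble(level = levels, r_lo = lo[i], r_hi = hi[i],
         cell = ceiling((3.4 * hi[i] + 4) / pixel_side) * pixel_side)
}

# one irregular star-shaped polygon with an exact target inscribed radius,
# centred near (cx, cy); stays within the enclosing mosaic cell
star_parcel <- function(cx, cy, r_target) {
  n_v <- sample(10:14, 1)
  ang <- sort((seq_len(n_v) - 1) * 2 * pi / n_v + runif(n_v, -0.3, 0.3) * 2 * pi / n_v)
  rad <- r_target * runif(n_v, 1.12, 1.55)
  poly <- pitt_polygon(cbind(cx + rad * cos(ang), cy + rad * sin(ang)))
  mic <- max_inscribed_circle(poly, precision = r_target * 2e-3)
  scale_polygon(poly, mic$center, r_target / mic$radius)
}

#' Simulate an irregular parcel mosaic with known strata
#'
#' Parcels are laid out in horizontal bands, one band per size level, one
#' parcel per jittered grid cell; each polygon is an irregular star-shaped
#' ring rescaled about its pole of inaccessibility so its maximum inscribed
#' radius hits the stratum's target exactly. Non-overlap is guaranteed by
#' construction and grading recovers the intended level.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed; the output is byte-identical across runs.
#' @return List: `parcels` (parcel tibble with `label`), `truth`
#'   (`parcel_id, class, true_level`), `extent` (region width/height in m).
#' @export
simulate_parcels <- function(config = scene_config(), seed = 1) {
  geom <- level_geometry(config$size_levels, config$pixel_side)
  n_band <- config$n_per_level_class * length(config$classes)
  withr::with_seed(seed, {
    rows <- list()
    y_top <- 0
    for (b in seq_len(nrow(geom))) {
      cell <- geom$cell[b]
      per_row <- floor(config$region_width / cell)
      if (per_row < 1)
        stop("region_width too small for level ", geom$level[b],
             " parcels (cell ", cell, " m)", call. = FALSE)
      n_rows_band <- ceiling(n_band / per_row)
      cls <- sample(rep_len(config$classes, n_band))
      for (i in seq_len(n_band)) {
        rr <- (i - 1) %/% per_row; cc <- (i - 1) %% per_row
        ctr_x <- cc * cell + cell / 2 + runif(1, -0.04, 0.04) * cell
        ctr_y <- y_top - rr * cell - cell / 2 + runif(1, -0.04, 0.04) * cell
        r_t <- runif(1, geom$r_lo[b], geom$r_hi[b])
        rows[[length(rows) + 1]] <- list(
          poly = star_parcel(ctr_x, ctr_y, r_t),
          class = cls[i], level = geom$level[b])
      }
      y_top <- y_top - n_rows_band * cell
    }
    height <- -y_top
    # shift scene into y in [0, height]
    parcels <- parcel_table(
      lapply(rows, function(r) {
        shift <- function(m) cbind(m[, 1], m[, 2] + height)
        pitt_polygon(shift(r$poly$outer), lapply(r$poly$holes, shift))
      }),
      label = vapply(rows, function(r) r$class, ""))
    truth <- tibble(parcel_id = parcels$parcel_id,
                    class = vapply(rows, function(r) r$class, ""),
                    true_level = vapply(rows, function(r) r$level, 0))
    list(parcels = parcels, truth = truth,
         extent = c(width = config$region_width, height = height))
  })
}

# per-parcel clean curves: class template + seeded level / shape jitter;
# "other" parcels split 50/50 between the grassland and bare-land subtypes
parcel_curves <- function(truth, config, seed) {
  doy <- config$dates
  span <- max(doy) - min(doy)
  withr::with_seed(seed + 1L, {
    t(vapply(seq_len(nrow(truth)), function(i) {
      cl <- truth$class[i]
      tpl <- if (cl == "other" && runif(1) < 0.5) "other_bare" else cl
      bump <- rnorm(1, 0, config$shape_sd[[cl]])
      phase <- runif(1, 0, pi)
      template_at(tpl, doy) +
        rnorm(1, 0, config$level_sd[[cl]]) +
        bump * sin(pi * (doy - min(doy)) / span + phase) +
        rnorm(length(doy), 0, config$curve_sd[[cl]])
    }, numeric(length(doy))))
  })
}

#' Simulate the SAR backscatter stack over a parcel mosaic
#'
#' Each pixel's clean value is the area-weighted blend of the clean curves
#' of every parcel overlapping its footprint (area fractions estimated by
#' regular subsampling at `supersample^2` points per pixel), with remaining
#' area filled by a constant background curve - this is the mixed-pixel
#' mechanism, so boundary pixels of small parcels carry foreign signal.
#' I.i.d. Gaussian noise of sd `noise_sd` is added per pixel and date.
#'
#' @param scene Result of [simulate_parcels()].
#' @param config The same [scene_config()].
#' @param seed Integer seed.
#' @return List: `stack` (a [raster_stack()]), `clean_series` (long tibble
#'   `parcel_id, date, value` of noise-free parcel curves).
#' @export
simulate_sar_stack <- function(scene, config = scene_config(), seed = 1) {
  L <- config$pixel_side
  n_cols <- ceiling(scene$extent["width"] / L)
  n_rows <- ceiling(scene$extent["height"] / L)
  grid <- grid_spec(n_rows, n_cols, L, origin_x = 0, origin_y = n_rows * L)
  n_dates <- length(config$dates)
  curves <- parcel_curves(scene$truth, config, seed)

  s <- config$supersample
  off <- (seq_len(s) - 0.5) / s  # subsample offsets within a pixel
  w_acc <- matrix(0, n_rows, n_cols)
  v_acc <- array(0, c(n_rows, n_cols, n_dates))
  for (i in seq_len(nrow(scene$parcels))) {
    poly <- scene$parcels$geometry[[i]]
    rng <- bbox_pixel_range(grid, polygon_bbox(poly), pad = L)
    if (is.null(rng)) next
    px <- expand.grid(row = rng$rows, col = rng$cols)
    x0 <- grid$origin_x + (px$col - 1) * L
    y0 <- grid$origin_y - px$row * L
    frac <- rep(0, nrow(px))
    for (ox in off) for (oy in off) {
      frac <- frac + point_in_polygon(x0 + ox * L, y0 + oy * L, poly)
    }
    frac <- frac / s^2
    hit <- frac > 0
    idx <- cbind(px$row[hit], px$col[hit])
    w_acc[idx] <- w_acc[idx] + frac[hit]
    for (d in seq_len(n_dates)) {
      v_acc[cbind(idx, d)] <- v_acc[cbind(idx, d)] + frac[hit] * curves[i, d]
    }
  }
  w_acc <- pmin(w_acc, 1)
  bg <- template_at("background", config$dates)
  vals <- withr::with_seed(seed + 2L, {
    out <- array(0, c(n_rows, n_cols, n_dates))
    for (d in seq_len(n_dates)) {
      out[, , d] <- v_acc[, , d] + (1 - w_acc) * bg[d] +
        matrix(rnorm(n_rows * n_cols, 0, config$noise_sd), n_rows, n_cols)
    }
    out
  })
  clean <- tibble(
    parcel_id = rep(scene$truth$parcel_id, each = n_dates),
    date = rep(config$dates, nrow(scene$truth)),
    value = as.numeric(t(curves)))
  list(stack = raster_stack(vals, config$dates, grid), clean_series = clean)
}

#' Simulate the high-resolution texture image
#'
#' Within each parcel an oriented periodic (row-crop-like) pattern with
#' class-specific period, orientation and contrast, plus Gaussian pixel
#' noise; the background is a distinct flat tone. Three bands with fixed
#' band gains.
#'
#' @inheritParams simulate_sar_stack
#' @return A hires image (list with `values` `[rows, cols, 3]`, `grid`).
#' @export
simulate_texture_image <- function(scene, config = scene_config(), seed = 1) {
  h <- config$hires_side
  n_cols <- ceiling(scene$extent["width"] / h)
  n_rows <- ceiling(scene$extent["height"] / h)
  grid <- grid_spec(n_rows, n_cols, h, origin_x = 0, origin_y = n_rows * h)
  gains <- c(0.9, 1.0, 0.8)
  withr::with_seed(seed + 3L, {
    base <- matrix(0.35, n_rows, n_cols)
    for (i in seq_len(nrow(scene$parcels))) {
      poly <- scene$parcels$geometry[[i]]
      tx <- config$texture[[scene$truth$class[i]]]
      rng <- bbox_pixel_range(grid, polygon_bbox(poly), pad = h)
      if (is.null(rng)) next
      px <- pixel_centers(grid, rng$rows, rng$cols)
      inside <- point_in_polygon(px$x, px$y, poly)
      if (!any(inside)) next
      th <- tx$orientation * pi / 180
      phase <- runif(1, 0, 2 * pi)
      u <- (px$x[inside] * cos(th) + px$y[inside] * sin(th)) / (tx$period * h)
      v <- 0.5 + tx$contrast * sin(2 * pi * u + phase) +
        rnorm(sum(inside), 0, tx$noise)
      base[cbind(px$row[inside], px$col[inside])] <- v
    }
    base <- base + matrix(rnorm(n_rows * n_cols, 0, 0.02), n_rows, n_cols)
    vals <- array(0, c(n_rows, n_cols, 3))
    for (b in 1:3) vals[, , b] <- pmin(1, pmax(0, base * gains[b]))
    hires_image(vals, grid)
  })
}

#' The standard synthetic benchmark scene
#'
#' One call bundling parcels, grading, SAR stack, hires image, extracted
#' series (full-pixel method, raw and standardized) and the phenology
#' references, under a fixed configuration: 4 size levels x 3 classes x
#' `n_per_level_class` parcels, 10 dates, 10 m / 2 m grids.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param config A [scene_config()].
#' @return List with `config`, `parcels` (graded, with inscribed circles),
#'   `truth`, `stack`, `hires`, `references`, `ts_raw`, `ts_std`,
#'   `clean_series`.
#' @export
standard_scene <- function(seed = 7, config = scene_config()) {
  sc <- simulate_parcels(config, seed)
  parcels <- sc$parcels |>
    compute_inscribed_circles(pixel_side = config$pixel_side) |>
    grade_parcels(pixel_side = config$pixel_side)
  sar <- simulate_sar_stack(sc, config, seed)
  hires <- simulate_texture_image(sc, config, seed)
  ts_raw <- extract_timeseries(parcels, sar$stack, "full")
  ts_std <- mean_standardize(ts_raw)
  list(config = config, parcels = parcels, truth = sc$truth,
       extent = sc$extent, stack = sar$stack, hires = hires,
       references = scene_references(config),
       ts_raw = ts_raw, ts_std = ts_std, clean_series = sar$clean_series)
}
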