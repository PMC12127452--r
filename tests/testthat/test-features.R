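# Pixel classification, time-series extraction, standardization and chips.

grid10 <- grid_spec(10, 10, 10)
square_parcel <- function(x0, y0, side)
  pitt_polygon(rbind(c(x0, y0), c(x0 + side, y0),
                     c(x0 + side, y0 + side), c(x0, y0 + side)))

test_that("interior/edge pixel split matches footprint containment", {
  s3 <- classify_parcel_pixels(square_parcel(10, 10, 30), grid10)
  expect_equal(nrow(s3$interior), 1)
  expect_equal(nrow(s3$edge), 8)

  s5 <- classify_parcel_pixels(square_parcel(10, 10, 50), grid10)
  expect_equal(nrow(s5$interior), 9)
  expect_equal(nrow(s5$edge), 16)

  tiny <- pitt_polygon(rbind(c(1, 1), c(3, 1), c(3, 3), c(1, 3)))
  expect_warning(sets <- classify_parcel_pixels(tiny, grid10), "no pixel centres")
  expect_true(sets$empty)
  expect_equal(nrow(sets$interior) + nrow(sets$edge), 0)
})

test_that("extraction strategies average the right pixel sets", {
  vals <- array(1, c(10, 10, 3))
  # the single interior pixel of a 3x3 parcel at rows 7:9, cols 2:4 is (8, 3)
  vals[8, 3, ] <- 5
  stk <- raster_stack(vals, c(10, 20, 30), grid10)
  parcels <- parcel_table(list(square_parcel(10, 10, 30))) |>
    compute_inscribed_circles()

  full <- extract_timeseries(parcels, stk, "full")
  expect_equal(unique(full$value), (5 + 8 * 1) / 9, tolerance = 1e-12)
  expect_equal(unique(full$n_pixels), 9L)

  interior <- extract_timeseries(parcels, stk, "edge_excluded")
  expect_equal(unique(interior$value), 5)
  expect_false(any(interior$fallback))

  # central 9 of a 5x5 parcel equals the middle 3x3 block on a symmetric fixture
  vals2 <- array(0, c(10, 10, 1))
  vals2[6:8, 3:5, 1] <- 7
  stk2 <- raster_stack(vals2, 15, grid10)
  p5 <- parcel_table(list(square_parcel(10, 10, 50))) |> compute_inscribed_circles()
  central <- extract_timeseries(p5, stk2, "central_k", k = 9)
  expect_equal(unique(central$value), 7)

  # constant raster: every method returns the constant
  stk3 <- raster_stack(array(4, c(10, 10, 2)), c(1, 2), grid10)
  for (m in c("full", "edge_excluded", "central_k"))
    expect_equal(unique(extract_timeseries(p5, stk3, m)$value), 4)
})

test_that("edge_excluded falls back to full when no interior pixel exists", {
  stk <- raster_stack(array(1, c(10, 10, 1)), 1, grid10)
  thin <- parcel_table(list(square_parcel(12, 12, 16))) |> compute_inscribed_circles()
  out <- extract_timeseries(thin, stk, "edge_excluded")
  expect_true(all(out$fallback))

  off <- parcel_table(list(pitt_polygon(rbind(c(1, 1), c(3, 1), c(3, 3), c(1, 3)))))
  expect_error(suppressWarnings(extract_timeseries(off, stk, "full")),
               "covers no pixel centres")
})

test_that("full series is the pixel-count-weighted blend of interior and edge", {
  withr::with_seed(3, {
    vals <- array(rnorm(10 * 10 * 4), c(10, 10, 4))
    stk <- raster_stack(vals, c(1, 2, 3, 4), grid10)
    parcels <- parcel_table(list(square_parcel(10, 10, 50))) |>
      compute_inscribed_circles()
    sets <- classify_parcel_pixels(parcels$geometry[[1]], grid10)
    n_i <- nrow(sets$interior); n_e <- nrow(sets$edge)
    full <- extract_timeseries(parcels, stk, "full")$value
    interior <- extract_timeseries(parcels, stk, "edge_excluded")$value
    edge_mean <- (full * (n_i + n_e) - interior * n_i) / n_e
    expect_equal(full, (n_i * interior + n_e * edge_mean) / (n_i + n_e),
                 tolerance = 1e-10)
    # zero-mean noise on edge pixels leaves the interior series untouched
    vals2 <- vals
    for (r in seq_len(n_e)) {
      noise <- rnorm(4); noise <- noise - mean(noise)
      vals2[sets$edge$row[r], sets$edge$col[r], ] <-
        vals2[sets$edge$row[r], sets$edge$col[r], ] + noise
    }
    stk2 <- raster_stack(vals2, c(1, 2, 3, 4), grid10)
    interior2 <- extract_timeseries(parcels, stk2, "edge_excluded")$value
    expect_equal(interior2, interior, tolerance = 1e-10)
  })
})

test_that("mean standardization is the z-score with raw level preserved", {
  ts <- tibble::tibble(parcel_id = "x", date = 1:3, value = c(1, 2, 3))
  std <- mean_standardize(ts)
  expect_equal(std$value, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(unique(std$raw_mean_level), 2)

  flat <- mean_standardize(tibble::tibble(parcel_id = "x", date = 1:3,
                                          value = c(4, 4, 4)))
  expect_equal(flat$value, c(0, 0, 0))
  expect_true(all(flat$degenerate))

  again <- mean_standardize(dplyr::select(std, -"raw_mean_level", -"degenerate"))
  expect_equal(again$value, std$value, tolerance = 1e-9)  # idempotent

  centred <- mean_standardize(ts, scaling = "center")
  expect_equal(centred$value, c(-1, 0, 1))
})

test_that("chips are centred, padded, and upsampled by replication", {
  img_grid <- grid_spec(50, 50, 2)
  uniform <- hires_image(array(0.4, c(50, 50, 3)), img_grid)
  parcels <- parcel_table(list(square_parcel(30, 30, 40))) |>
    compute_inscribed_circles()

  chip <- extract_chips(parcels, uniform, side = 16)
  expect_equal(chip$resized_to, 32)
  expect_equal(dim(chip$chip[[1]]), c(32, 32, 3))
  expect_true(all(chip$chip[[1]] == 0.4))

  # nearest-neighbour replication: an 8-px chip becomes 4x4 blocks
  withr::with_seed(1, {
    vals <- array(runif(50 * 50 * 3), c(50, 50, 3))
  })
  img <- hires_image(vals, img_grid)
  chip8 <- extract_chips(parcels, img, side = 8)$chip[[1]]
  expect_equal(dim(chip8), c(32, 32, 3))
  for (r in seq(1, 32, by = 4))
    expect_true(all(chip8[r, , ] == chip8[min(r + 3, 32), , ]))

  # parcel near the border: out-of-image margin is zero-padded
  corner <- parcel_table(list(square_parcel(0, 0, 8))) |> compute_inscribed_circles()
  chip96 <- extract_chips(corner, img, side = 96)$chip[[1]]
  expect_true(all(chip96[, 1:40, ] == 0))

  far <- parcel_table(list(square_parcel(300, 300, 10))) |> compute_inscribed_circles()
  expect_error(extract_chips(far, img, side = 8), "outside the image")
  expect_error(extract_chips(parcels, img, side = 10), "%in%")
})

test_that("chip extraction is translation-equivariant on a periodic image", {
  img_grid <- grid_spec(60, 60, 2)
  pattern <- outer(seq_len(60), seq_len(60), function(r, c) sin(2 * pi * c / 5))
  img <- hires_image(array(rep(pattern, 3), c(60, 60, 3)), img_grid)
  # two parcels offset by exactly one pattern period (10 m = 5 px)
  p <- parcel_table(list(square_parcel(30, 40, 30), square_parcel(40, 40, 30))) |>
    compute_inscribed_circles()
  chips <- extract_chips(p, img, side = 16)
  expect_equal(chips$chip[[1]], chips$chip[[2]], tolerance = 1e-12)
})
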