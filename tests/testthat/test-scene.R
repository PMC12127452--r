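# Synthetic scene generator: parcel mosaics, SAR stacks, texture images.

small_cfg <- scene_config(n_per_level_class = 4)

test_that("parcel simulation hits the requested strata and is reproducible", {
  sc <- simulate_parcels(small_cfg, seed = 3)
  expect_equal(nrow(sc$parcels), 4 * 3 * 4)  # levels x classes x n
  graded <- compute_inscribed_circles(sc$parcels) |> grade_parcels()
  expect_gte(mean(graded$scale_level == sc$truth$true_level), 0.95)

  f1 <- tempfile(fileext = ".geojson"); f2 <- tempfile(fileext = ".geojson")
  write_parcels_geojson(simulate_parcels(small_cfg, seed = 3)$parcels, f1)
  write_parcels_geojson(simulate_parcels(small_cfg, seed = 3)$parcels, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  none <- simulate_parcels(scene_config(n_per_level_class = 0), seed = 1)
  expect_equal(nrow(none$parcels), 0)
})

test_that("clean SAR values blend parcel curves area-weighted", {
  cfg <- scene_config(noise_sd = 0)
  # hand-built scene: two rectangles sharing a vertical edge at x = 45,
  # so the pixel column centred on x = 45 straddles them 50/50
  r1 <- pitt_polygon(rbind(c(20, 20), c(45, 20), c(45, 60), c(20, 60)))
  r2 <- pitt_polygon(rbind(c(45, 20), c(70, 20), c(70, 60), c(45, 60)))
  parcels <- parcel_table(list(r1, r2), label = c("rape", "wheat"))
  scene <- list(parcels = parcels,
                truth = tibble::tibble(parcel_id = parcels$parcel_id,
                                       class = c("rape", "wheat"),
                                       true_level = c(1, 1)),
                extent = c(width = 100, height = 100))
  cfg0 <- scene_config(noise_sd = 0, level_sd = c(rape = 0, wheat = 0, other = 0),
                       shape_sd = c(rape = 0, wheat = 0, other = 0),
                       curve_sd = c(rape = 0, wheat = 0, other = 0))
  sar <- simulate_sar_stack(scene, cfg0, seed = 1)
  rape_curve <- sar$clean_series$value[sar$clean_series$parcel_id == parcels$parcel_id[1]]
  wheat_curve <- sar$clean_series$value[sar$clean_series$parcel_id == parcels$parcel_id[2]]
  # pixel fully inside the first parcel (rows for y 30..40, col for x 30..40)
  inside <- sar$stack$values[7, 4, ]
  expect_equal(unname(inside), rape_curve, tolerance = 1e-9)
  # straddling pixel (x 40..50) blends the two curves equally
  straddle <- sar$stack$values[7, 5, ]
  expect_equal(unname(straddle), (rape_curve + wheat_curve) / 2, tolerance = 1e-9)
  # zero noise: the stack is a pure function of geometry + templates
  sar2 <- simulate_sar_stack(scene, cfg0, seed = 99)
  expect_equal(sar$stack$values, sar2$stack$values, tolerance = 1e-12)
})

test_that("phenology templates carry the documented seasonal signatures", {
  doy <- seq(8, 140, by = 2)
  wheat <- template_at("wheat", doy)
  expect_true(all(diff(wheat) <= 1e-12))  # gradual decline all season
  rape <- template_at("rape", doy)
  peak <- doy[which.max(rape)]
  expect_equal(peak, 105, tolerance = 3)  # mid-April peak
  expect_lt(rape[length(rape)], max(rape) - 3)  # sharp post-peak decline
})

test_that("texture image shows the class period at the right orientation", {
  sc <- simulate_parcels(small_cfg, seed = 5)
  img <- simulate_texture_image(sc, small_cfg, seed = 5)
  parcels <- compute_inscribed_circles(sc$parcels)
  # a rape parcel: horizontal stripes of period 8 px along x
  rape_id <- which(sc$truth$class == "rape" & sc$truth$true_level == 9)[1]
  chip <- extract_chips(parcels[rape_id, ], img, side = 32)$chip[[1]]
  lum <- chip[, , 1] - mean(chip[, , 1])
  spec <- Mod(fft(lum))^2
  fr <- ifelse(seq_len(32) - 1 <= 16, seq_len(32) - 1, seq_len(32) - 1 - 32)
  peak_idx <- which(spec == max(spec), arr.ind = TRUE)[1, ]
  fx <- abs(fr[peak_idx[2]]); fy <- abs(fr[peak_idx[1]])
  period <- 32 / max(fx, fy)
  expect_equal(period, small_cfg$texture$rape$period, tolerance = 1.1)

  img2 <- simulate_texture_image(sc, small_cfg, seed = 5)
  expect_identical(img$values, img2$values)
})

test_that("mixed-pixel contamination falls as parcels grow", {
  sc <- simulate_parcels(scene_config(n_per_level_class = 6), seed = 2)
  parcels <- compute_inscribed_circles(sc$parcels)
  grid <- grid_spec(ceiling(sc$extent["height"] / 10),
                    ceiling(sc$extent["width"] / 10), 10)
  frac_mixed <- vapply(seq_len(nrow(parcels)), function(i) {
    sets <- suppressWarnings(classify_parcel_pixels(parcels$geometry[[i]], grid))
    n_i <- nrow(sets$interior); n_e <- nrow(sets$edge)
    n_e / max(1, n_i + n_e)
  }, 0)
  by_level <- tapply(frac_mixed, sc$truth$true_level, mean)
  expect_true(all(diff(by_level) < 0))
})

test_that("the scene-level PTR contrast matches the intended design", {
  sc <- scene_standard()
  # wheat's group statistics sit below rapeseed's at every shared level
  g <- gas_tas_by_scale(sc$ts_raw, sc$parcels)
  wide <- tidyr::pivot_wider(g[, c("scale_level", "label", "gas")],
                             names_from = "label", values_from = "gas")
  expect_true(all(wide$wheat < wide$rape))
})
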