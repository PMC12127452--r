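# k-Shape clustering, pseudolabel fine-tuning and the time-series classifier.

test_that("k-Shape separates two shape families and is deterministic", {
  fam <- two_family_series(n_per = 20)
  m <- rbind(fam$a, fam$b)
  fit <- kshape_fit(m, 2, seed = 7)
  truth <- rep(c(1, 2), each = 20)
  tab <- table(fit$assignments$cluster, truth)
  expect_equal(sum(apply(tab, 1, max)), 40)  # perfect agreement up to relabeling
  expect_true(all(fit$assignments$similarity >= 0 &
                  fit$assignments$similarity <= 1))

  one <- kshape_fit(m, 1, seed = 7)
  expect_equal(unique(one$assignments$cluster), 1L)

  perm <- kshape_fit(m[sample(seq_len(40)), ], 2, seed = 7)
  expect_identical(perm$assignments, fit$assignments)
  expect_error(kshape_fit(m, 100, seed = 1), "exceeds")
})

test_that("prototype extraction is monotone in the similarity threshold", {
  fam <- two_family_series(n_per = 20)
  fit <- kshape_fit(rbind(fam$a, fam$b), 2, seed = 7)
  all_kept <- extract_prototypes(fit, 1e-9)
  expect_equal(nrow(all_kept), 40)
  kept <- lapply(c(0.90, 0.95, 0.97), function(th)
    suppressWarnings(extract_prototypes(fit, th))$parcel_id)
  expect_true(all(kept[[3]] %in% kept[[2]]))
  expect_true(all(kept[[2]] %in% kept[[1]]))
  expect_true(length(kept[[1]]) <= 40)
})

test_that("amplitude conflicts are removed against the cluster median", {
  pl <- tibble::tibble(parcel_id = sprintf("p%02d", 1:10), cluster = 1L,
                       class = NA_character_, confidence = 1, stage = "kshape")
  ts <- tibble::tibble(parcel_id = rep(pl$parcel_id, each = 2), date = rep(1:2, 10),
                       value = 0,
                       raw_mean_level = rep(c(rep(-15, 9), -8), each = 2))
  out <- filter_amplitude_conflicts(pl, ts, delta = 3)
  expect_setequal(out$parcel_id, sprintf("p%02d", 1:9))  # the -8 dB member goes
  expect_equal(nrow(filter_amplitude_conflicts(pl, ts, delta = Inf)), 10)
  same <- dplyr::mutate(ts, raw_mean_level = -15)
  expect_equal(nrow(filter_amplitude_conflicts(pl, same, delta = 3)), 10)
})

test_that("cluster prototypes map to the nearest reference class", {
  dates <- seq(10, 100, by = 10)
  wheat <- seq(-12, -17, length.out = 10)
  rape <- -15 + 3 * sin(seq(0, pi, length.out = 10))
  refs <- phenology_reference(list(rape = rape, wheat = wheat), dates)
  # two clean clusters whose centroids equal the references in shape
  series <- rbind(t(replicate(6, wheat + rnorm(10, 0, 0.01))),
                  t(replicate(6, rape + rnorm(10, 0, 0.01))))
  rownames(series) <- sprintf("s%02d", 1:12)
  colnames(series) <- paste0("V", 1:10)
  ts_raw <- tidyr::pivot_longer(
    tibble::as_tibble(series, rownames = "parcel_id"), -parcel_id,
    names_to = "date", values_to = "value") |>
    dplyr::mutate(date = rep(dates, 12))
  ts_std <- mean_standardize(ts_raw)
  fit <- kshape_fit(ts_std, 2, seed = 3)
  pl <- extract_prototypes(fit, 0.9)
  out <- assign_crop_labels(pl, fit, refs, ts_raw, min_fraction = 0.01)
  truth <- rep(c("wheat", "rape"), each = 6)
  names(truth) <- rownames(series)
  expect_true(all(out$class == truth[out$parcel_id]))
  expect_equal(unique(out$stage), "ki")

  expect_error(assign_crop_labels(pl, fit,
                                  phenology_reference(list(rape = rape), dates),
                                  ts_raw,
                                  required_classes = c("rape", "wheat")),
               "missing class")
})

test_that("equidistant references fall back to deterministic tie-breaking", {
  dates <- 1:10
  up <- seq(-16, -12, length.out = 10)
  refs <- phenology_reference(list(rape = up, wheat = up), dates)  # exact tie
  series <- t(replicate(5, up + rnorm(10, 0, 0.01)))
  rownames(series) <- sprintf("s%02d", 1:5)
  colnames(series) <- paste0("V", 1:10)
  ts_raw <- tidyr::pivot_longer(
    tibble::as_tibble(series, rownames = "parcel_id"), -parcel_id,
    names_to = "date", values_to = "value") |>
    dplyr::mutate(date = rep(dates, 5))
  fit <- kshape_fit(mean_standardize(ts_raw), 1, seed = 1)
  pl <- extract_prototypes(fit, 0.5)
  expect_message(out <- assign_crop_labels(pl, fit, refs, ts_raw),
                 "tie broken by class order")
  expect_equal(unique(out$class), "rape")
})

test_that("the classifier nails separable data and is reproducible", {
  fam <- two_family_series(n_per = 15, noise = 0.1)
  m <- rbind(fam$a, fam$b)
  ts_std <- tidyr::pivot_longer(
    tibble::as_tibble(m, rownames = "parcel_id"), -parcel_id,
    names_to = "date", values_to = "value") |>
    dplyr::mutate(date = as.numeric(gsub("V", "", date)))
  pl <- tibble::tibble(parcel_id = rownames(m),
                       class = rep(c("rape", "wheat"), each = 15))
  model <- train_ts_classifier(pl, ts_std, inception_config(epochs = 150), seed = 2)
  probs <- predict_proba_ts(model, ts_std)
  expect_equal(rowSums(as.matrix(probs[, -1])), rep(1, 30), tolerance = 1e-6)
  pred <- decide_classes(probs)
  expect_equal(mean(pred$class == pl$class[match(pred$parcel_id, pl$parcel_id)]), 1)

  again <- train_ts_classifier(pl, ts_std, inception_config(epochs = 150), seed = 2)
  expect_identical(predict_proba_ts(again, ts_std), probs)

  # duplicated series get identical probability vectors
  dup <- dplyr::bind_rows(ts_std,
                          dplyr::mutate(dplyr::filter(ts_std, parcel_id == "a001"),
                                        parcel_id = "zz_copy"))
  pdup <- predict_proba_ts(model, dup)
  expect_equal(as.numeric(pdup[pdup$parcel_id == "zz_copy", -1]),
               as.numeric(pdup[pdup$parcel_id == "a001", -1]), tolerance = 1e-12)

  expect_error(train_ts_classifier(dplyr::filter(pl, class == "rape"), ts_std),
               "at least two classes")
  short <- dplyr::filter(ts_std, date <= 5)
  expect_error(predict_proba_ts(model, short), "does not match")
})

test_that("residual-depth configurations train without breaking determinism", {
  fam <- two_family_series(n_per = 8, noise = 0.1)
  m <- rbind(fam$a, fam$b)
  ts_std <- tidyr::pivot_longer(
    tibble::as_tibble(m, rownames = "parcel_id"), -parcel_id,
    names_to = "date", values_to = "value") |>
    dplyr::mutate(date = as.numeric(gsub("V", "", date)))
  pl <- tibble::tibble(parcel_id = rownames(m),
                       class = rep(c("rape", "wheat"), each = 8))
  cfg <- inception_config(n_filters = 4, depth = 3, epochs = 80)
  m1 <- train_ts_classifier(pl, ts_std, cfg, seed = 9)
  m2 <- train_ts_classifier(pl, ts_std, cfg, seed = 9)
  expect_identical(predict_proba_ts(m1, ts_std), predict_proba_ts(m2, ts_std))
  expect_equal(length(m1$params$blocks), 3)
  expect_false(is.null(m1$params$blocks[[3]]$w_short))
})
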