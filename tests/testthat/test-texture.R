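# Texture embeddings, prototype clustering, fine-tuning rules and the
# semi-supervised texture classifier.

test_that("handcrafted embeddings are deterministic and orientation-aware", {
  chips <- striped_chips(n_per = 8)
  emb <- texture_embed(chips)
  expect_equal(nrow(emb$features), 16)
  expect_true(all(is.finite(emb$features)))

  # identical chips embed identically
  dup <- chips[c(1, 1), ]
  dup$parcel_id <- c("x1", "x2")
  ed <- texture_embed(dup)$features
  expect_equal(ed[1, ], ed[2, ], tolerance = 1e-12)

  # 90-degree rotation swaps the 0- and 90-degree orientation bands
  chip <- chips$chip[[1]]
  rot <- array(0, dim(chip))
  for (b in 1:3) rot[, , b] <- t(chip[dim(chip)[1]:1, , b])
  f0 <- spectral_features(chip); f90 <- spectral_features(rot)
  expect_equal(unname(f0[paste0("o1_r", 1:3)]), unname(f90[paste0("o3_r", 1:3)]),
               tolerance = 1e-8)
  expect_equal(unname(f0[paste0("o3_r", 1:3)]), unname(f90[paste0("o1_r", 1:3)]),
               tolerance = 1e-8)

  mixed <- dplyr::bind_rows(chips[1, ],
                            dplyr::mutate(striped_chips(n_per = 1, side = 16),
                                          parcel_id = "tiny"))
  expect_error(texture_embed(mixed), "mixed chip sizes")
})

test_that("orthogonal stripe families are linearly separable in embedding space", {
  chips <- striped_chips(n_per = 12)
  emb <- texture_embed(chips)
  cls <- rep(c(0, 1), each = 12)
  # 2-fold CV with a nearest-class-centroid probe (a linear rule)
  folds <- rep(rep(1:2, 6), 2)
  for (f in 1:2) {
    tr <- folds != f
    mu0 <- colMeans(emb$features[tr & cls == 0, ])
    mu1 <- colMeans(emb$features[tr & cls == 1, ])
    d0 <- rowSums(sweep(emb$features[!tr, ], 2, mu0)^2)
    d1 <- rowSums(sweep(emb$features[!tr, ], 2, mu1)^2)
    expect_equal(as.numeric(d1 < d0), cls[!tr])
  }
})

test_that("texture clustering recovers families with margin confidences", {
  chips <- two_texture_families(n_per = 10)
  emb <- texture_embed(chips)
  protos <- texture_cluster(emb, k = 2, seed = 4)
  truth <- substr(protos$parcel_id, 1, 1)
  tab <- table(protos$prototype, truth)
  expect_equal(sum(apply(tab, 1, max)), 20)  # ARI 1 up to relabeling
  expect_true(all(protos$confidence >= 0 & protos$confidence <= 1))

  single <- texture_cluster(emb, k = nrow(emb$features), seed = 4)
  expect_equal(sort(as.integer(table(single$prototype))), rep(1L, 20))
  expect_equal(unique(single$confidence), 1)
  expect_error(texture_cluster(emb, k = 50, seed = 1), "exceeds")
})

test_that("KI-confidence pseudolabels obey the threshold contract", {
  prob <- tibble::tibble(parcel_id = c("a", "b", "c"),
                         p_rape = c(0.995, 0.6, 0.2),
                         p_wheat = c(0.004, 0.3, 0.75),
                         p_other = c(0.001, 0.1, 0.05))
  all_labels <- suppressWarnings(build_kspice1_labelset(prob, 0))
  expect_equal(all_labels$class, c("rape", "rape", "wheat"))
  none <- suppressWarnings(build_kspice1_labelset(prob, 1 + 1e-9))
  expect_equal(nrow(none), 0)
  expect_warning(one <- build_kspice1_labelset(prob, 0.99), "no parcel passes")
  expect_equal(one$parcel_id, "a")
})

test_that("the three fine-tuning rules split, prune, merge - idempotently", {
  chips <- two_texture_families(n_per = 10)
  emb <- texture_embed(chips)
  ids <- chips$parcel_id
  # one prototype containing 6 of one KI class and 4 of another splits 6/4
  protos <- tibble::tibble(parcel_id = ids[1:10], prototype = "1", confidence = 0.9)
  prob <- tibble::tibble(parcel_id = ids[1:10],
                         p_rape = rep(c(1, 0), c(6, 4)),
                         p_wheat = rep(c(0, 1), c(6, 4)), p_other = 0)
  out <- finetune_texture_pseudolabels(protos, emb, prob, sim_threshold = -1,
                                       merge_threshold = 1.1)
  expect_equal(sort(as.integer(table(out$prototype))), c(4L, 6L))
  expect_equal(as.integer(table(out$class)[c("rape", "wheat")]), c(6L, 4L))

  # same-class prototypes with similar centroids merge into one
  protos2 <- tibble::tibble(parcel_id = ids[1:10],
                            prototype = rep(c("1", "2"), 5), confidence = 0.9)
  prob2 <- dplyr::mutate(prob, p_rape = 1, p_wheat = 0)
  merged <- finetune_texture_pseudolabels(protos2, emb, prob2,
                                          sim_threshold = -1,
                                          merge_threshold = 0.4)
  expect_equal(length(unique(merged$prototype)), 1)

  # a uniform, tight prototype passes through unchanged, and the whole
  # operation is idempotent
  protos3 <- tibble::tibble(parcel_id = ids[1:10], prototype = "1",
                            confidence = 0.9)
  once <- finetune_texture_pseudolabels(protos3, emb, prob2, 0.5, 0.5)
  expect_setequal(once$parcel_id, ids[1:10])
  twice <- finetune_texture_pseudolabels(
    dplyr::select(once, parcel_id, prototype, confidence), emb, prob2, 0.5, 0.5)
  expect_equal(dplyr::arrange(twice, parcel_id),
               dplyr::arrange(once, parcel_id))
})

test_that("semi-supervised texture training hits the separable ceiling", {
  chips <- striped_chips(n_per = 12)
  truth <- tibble::tibble(parcel_id = chips$parcel_id,
                          label = rep(c("rape", "wheat"), each = 12))
  full <- tibble::tibble(parcel_id = chips$parcel_id, class = truth$label)
  model <- train_semi_texture_classifier(full, chips, texture_config(), seed = 3)
  probs <- predict_proba_texture(model, chips)
  expect_equal(rowSums(as.matrix(probs[, -1])), rep(1, 24), tolerance = 1e-6)
  ev <- evaluate_classification(decide_classes(probs), truth,
                                classes = c("rape", "wheat"))
  expect_equal(ev$mf1, 1)

  # duplicate chip -> identical probabilities
  dup <- chips[c(1, 1), ]; dup$parcel_id <- c("d1", "d2")
  pd <- predict_proba_texture(model, dup)
  expect_equal(as.numeric(pd[1, -1]), as.numeric(pd[2, -1]), tolerance = 1e-12)

  expect_error(train_semi_texture_classifier(full[0, ], chips), "empty")
  expect_error(train_semi_texture_classifier(dplyr::filter(full, class == "rape"),
                                             chips), "at least two")
})

test_that("consistency training helps at 10% labels and switches off at tau > 1", {
  chips <- striped_chips(n_per = 25, noise = 0.08)
  truth <- tibble::tibble(parcel_id = chips$parcel_id,
                          label = rep(c("rape", "wheat"), each = 25))
  labelled <- dplyr::slice(dplyr::group_by(truth, label), 1:3) |>
    dplyr::ungroup() |>
    dplyr::transmute(parcel_id, class = label)

  semi <- train_semi_texture_classifier(labelled, chips, texture_config(), seed = 6)
  ev_semi <- evaluate_classification(decide_classes(predict_proba_texture(semi, chips)),
                                     truth, classes = c("rape", "wheat"))
  sup_only <- train_semi_texture_classifier(labelled, chips,
                                            texture_config(tau = 1 + 1e-9), seed = 6)
  ev_sup <- evaluate_classification(decide_classes(predict_proba_texture(sup_only, chips)),
                                    truth, classes = c("rape", "wheat"))
  expect_gte(ev_semi$mf1, 0.85)
  expect_gte(ev_semi$mf1, ev_sup$mf1)

  # tau > 1 with a single round is plain supervised training: rerun matches
  sup_again <- train_semi_texture_classifier(labelled, chips,
                                             texture_config(tau = 1 + 1e-9), seed = 6)
  expect_identical(sup_again$w, sup_only$w)
})
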