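# Shared fixtures built once per test session. The standard scene and the
# KI stage on it are reused by the pipeline-level and acceptance tests.

.pitt_test_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.pitt_test_cache[[name]]))
    assign(name, builder(), envir = .pitt_test_cache)
  .pitt_test_cache[[name]]
}

scene_standard <- function() cached("scene7", function() standard_scene(seed = 7))

# KI stage on the standard scene's small parcels + probabilities for both branches
ki_standard <- function() cached("ki7", function() {
  sc <- scene_standard()
  small <- dplyr::filter(sc$parcels, branch == "small")
  micro <- dplyr::filter(sc$parcels, branch == "micro")
  ts_std_s <- dplyr::semi_join(sc$ts_std, small, by = "parcel_id")
  ts_raw_s <- dplyr::semi_join(sc$ts_raw, small, by = "parcel_id")
  ki <- suppressWarnings(suppressMessages(
    ki_pseudolabels(ts_std_s, ts_raw_s, sc$references, seed = 7)))
  model <- train_ts_classifier(ki$pseudolabels, ts_std_s, inception_config(),
                               seed = 7)
  list(
    small = small, micro = micro,
    ts_std_small = ts_std_s,
    ki = ki, model = model,
    truth = dplyr::select(sc$parcels, parcel_id, label),
    truth_map = stats::setNames(sc$truth$class, sc$truth$parcel_id),
    prob_small = predict_proba_ts(model, ts_std_s),
    prob_micro = predict_proba_ts(
      model, dplyr::semi_join(sc$ts_std, micro, by = "parcel_id")))
})

# micro-branch texture stage on the standard scene
texture_standard <- function() cached("tex7", function() {
  sc <- scene_standard()
  ks <- ki_standard()
  chips_micro <- extract_chips(ks$micro, sc$hires, side = 8)
  emb <- texture_embed(chips_micro)
  protos <- texture_cluster(emb, k = 6, seed = 7)
  pl2 <- finetune_texture_pseudolabels(protos, emb, ks$prob_micro)
  model <- train_semi_texture_classifier(pl2, chips_micro, texture_config(),
                                         seed = 7)
  list(chips_micro = chips_micro, embedding = emb, protos = protos,
       pseudolabels = pl2, model = model,
       prob_micro = predict_proba_texture(model, chips_micro))
})
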