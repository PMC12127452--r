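#' Build the texture pseudolabel set from high-confidence KI results
#'
#' The first texture-branch variant: small parcels whose KI probability
#' maximum reaches `threshold` (default 0.99) become image pseudolabels
#' carrying the KI class; everything else stays in the unlabeled pool for
#' the consistency step. No texture clustering stage is involved.
#'
#' @param prob_ki Probability tibble from [predict_proba_ts()].
#' @param threshold Confidence cut-off on `max(prob)`.
#' @param classes Class universe.
#' @return Pseudolabel tibble `parcel_id, class, confidence, stage = "kspice1"`;
#'   classes with no qualifying parcel trigger a warning.
#' @export
build_kspice1_labelset <- function(prob_ki, threshold = 0.99, classes = PITT_CLASSES) {
  p <- as.matrix(prob_ki[, prob_cols(classes)])
  conf <- apply(p, 1, max)
  cls <- classes[max.col(p, ties.method = "first")]
  keep <- conf >= threshold
  missing <- setdiff(classes, unique(cls[keep]))
  if (length(missing))
    warning("no parcel passes the confidence threshold for: ",
            paste(missing, collapse = ", "),
            "; the texture classifier trains on the remaining classes",
            call. = FALSE)
  tibble(parcel_id = prob_ki$parcel_id[keep], class = cls[keep],
         confidence = conf[keep], stage = "kspice1")
}

#' Texture embeddings for parcel chips
#'
#' The default `"handcrafted"` extractor is a fixed oriented band-pass
#' filter bank evaluated spectrally: the chip's luminance power spectrum is
#' integrated over 4 orientation x 3 radial-frequency bands (energy
#' fractions), joined with log total texture energy and per-band intensity
#' statistics. It is fully deterministic and rotation of a chip by 90
#' degrees permutes the orientation features. `"small_cnn"` is a seeded
#' random-filter convolutional energy embedding (deterministic given
#' `seed`).
#'
#' @param chips Chip tibble from [extract_chips()] (uniform side; run the
#'   resize rule first).
#' @param method `"handcrafted"` (default) or `"small_cnn"`.
#' @param seed Seed for the `"small_cnn"` filters (ignored by handcrafted).
#' @return A `pitt_embedding`: list with `features` (matrix, rownames =
#'   parcel ids) and `extractor_id`.
#' @export
texture_embed <- function(chips, method = c("handcrafted", "small_cnn"), seed = 1) {
  method <- match.arg(method)
  sides <- vapply(chips$chip, function(c_) dim(c_)[1], 0)
  if (length(unique(sides)) > 1)
    stop("mixed chip sizes (", paste(sort(unique(sides)), collapse = ", "),
         "); apply the resize rule first", call. = FALSE)
  feats <- switch(method,
    handcrafted = t(vapply(chips$chip, spectral_features,
                           numeric(length(spectral_feature_names())))),
    small_cnn = random_cnn_features(chips$chip, seed))
  rownames(feats) <- chips$parcel_id
  structure(list(features = feats, extractor_id = method), class = "pitt_embedding")
}

spectral_feature_names <- function() {
  c(sprintf("o%d_r%d", rep(1:4, each = 3), rep(1:3, 4)),
    "log_energy", sprintf("mean_b%d", 1:3), sprintf("sd_b%d", 1:3))
}

spectral_features <- function(chip) {
  s <- dim(chip)[1]
  lum <- (chip[, , 1] + chip[, , 2] + chip[, , 3]) / 3
  p <- Mod(fft(lum - mean(lum)))^2
  fr <- ifelse(seq_len(s) - 1 <= s / 2, seq_len(s) - 1, seq_len(s) - 1 - s)
  fy <- matrix(fr, s, s)         # row frequency (image y)
  fx <- matrix(fr, s, s, byrow = TRUE)
  ang <- (atan2(fy, fx) * 180 / pi) %% 180
  rad <- sqrt(fx^2 + fy^2) / (s / 2)
  ob <- findInterval(((ang + 22.5) %% 180), c(0, 45, 90, 135)) # 1..4: 0,45,90,135 deg
  rb <- pmin(3L, pmax(1L, ceiling(rad * 3)))
  ac <- rad > 0
  tot <- sum(p[ac])
  bins <- vapply(1:4, function(o) vapply(1:3, function(r) {
    sel <- ac & ob == o & rb == r
    if (tot > 0) sum(p[sel]) / tot else 0
  }, 0), numeric(3))
  stats_ <- c(log1p(tot / s^2),
              vapply(1:3, function(b) mean(chip[, , b]), 0),
              vapply(1:3, function(b) sd(chip[, , b]), 0))
  setNames(c(as.numeric(bins), stats_), spectral_feature_names())
}

random_cnn_features <- function(chips, seed, n_filters = 12, ksz = 5) {
  filters <- withr::with_seed(seed, replicate(n_filters, {
    f <- matrix(rnorm(ksz^2), ksz, ksz); f - mean(f)
  }, simplify = FALSE))
  t(vapply(chips, function(chip) {
    lum <- (chip[, , 1] + chip[, , 2] + chip[, , 3]) / 3
    vapply(filters, function(f) {
      r <- conv2d_valid(lum, f)
      mean(pmax(r, 0)^2)  # rectified energy pooling
    }, 0)
  }, numeric(n_filters)))
}

conv2d_valid <- function(img, ker) {
  s <- nrow(img); k <- nrow(ker)
  out <- matrix(0, s - k + 1, s - k + 1)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out <- out + ker[i, j] * img[i:(i + s - k), j:(j + s - k)]
  }
  out
}

#' Cluster texture embeddings into prototypes with confidences
#'
#' k-means on standardized embeddings; each member's confidence is the
#' normalized margin `1 - d1/d2` between its nearest and second-nearest
#' prototype centres (1 when it sits on its centre), always in `[0, 1]`.
#'
#' @param embedding A [texture_embed()] result.
#' @param k Number of texture prototypes (>= 2).
#' @param seed Seed; the partition is deterministic given it.
#' @return Tibble `parcel_id, prototype, confidence`.
#' @export
texture_cluster <- function(embedding, k, seed = 1) {
  x <- scale_features(embedding$features)$x
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds the number of chips (", n, ")", call. = FALSE)
  stopifnot(k >= 2)
  x <- x[order(rownames(x)), , drop = FALSE]
  if (k == n) {
    # singleton prototypes: every chip is its own prototype at full margin
    return(tibble(parcel_id = rownames(x),
                  prototype = as.character(seq_len(n)), confidence = 1))
  }
  km <- withr::with_seed(seed, kmeans(x, centers = k, nstart = 5, iter.max = 50))
  d <- vapply(seq_len(k), function(c_)
    rowSums(sweep(x, 2, km$centers[c_, ])^2), numeric(n))
  d <- sqrt(pmax(d, 0))
  ord <- t(apply(d, 1, sort))
  d1 <- ord[, 1]; d2 <- if (k >= 2) ord[, 2] else d1
  conf <- ifelse(d1 == 0, 1, pmin(1, pmax(0, 1 - d1 / d2)))
  tibble(parcel_id = rownames(x), prototype = as.character(km$cluster),
         confidence = conf)
}

scale_features <- function(m) {
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  scl[scl == 0] <- 1
  list(x = sweep(sweep(m, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Refine texture prototypes with KI predictions (three fine-tuning rules)
#'
#' Rule (i): a prototype containing several KI classes is split into
#' per-class sub-prototypes. Rule (ii): within a sub-prototype, members
#' whose cosine similarity to the sub-prototype's embedding centroid falls
#' below `sim_threshold` are dropped (iterated to a fixed point). Rule
#' (iii): sub-prototypes of the same class whose centroids are at least
#' `merge_threshold` similar are merged. The three rules are cycled until
#' stable, so applying the whole operation twice changes nothing.
#'
#' @param protos Tibble from [texture_cluster()].
#' @param embedding The matching [texture_embed()] result.
#' @param prob_ki KI probability tibble covering every member.
#' @param sim_threshold,merge_threshold Cosine thresholds (defaults 0.8).
#' @param classes Class universe.
#' @return Pseudolabel tibble `parcel_id, prototype, class, confidence,
#'   stage = "kspice2"`.
#' @export
finetune_texture_pseudolabels <- function(protos, embedding, prob_ki,
                                          sim_threshold = 0.8,
                                          merge_threshold = 0.8,
                                          classes = PITT_CLASSES) {
  x <- scale_features(embedding$features)$x
  p <- as.matrix(prob_ki[, prob_cols(classes)])
  ki_class <- setNames(classes[max.col(p, ties.method = "first")], prob_ki$parcel_id)
  if (!all(protos$parcel_id %in% names(ki_class)))
    stop("every prototype member needs a KI prediction", call. = FALSE)
  mem <- tibble(parcel_id = protos$parcel_id,
                proto = as.character(protos$prototype),
                class = unname(ki_class[protos$parcel_id]),
                confidence = protos$confidence)
  for (iter in 1:10) {
    before <- paste(sort(paste(mem$parcel_id, mem$proto)), collapse = ";")
    # (i) split by KI class
    mem$proto <- paste(mem$proto, mem$class, sep = "|")
    # (ii) drop members dissimilar to their sub-prototype centroid
    repeat {
      cen <- proto_centroids(mem, x)
      sim <- cosine_to_centroid(mem, x, cen)
      drop <- sim < sim_threshold & ave(seq_along(mem$proto), mem$proto, FUN = length) > 1
      if (!any(drop)) break
      mem <- mem[!drop, , drop = FALSE]
    }
    # (iii) merge same-class sub-prototypes with similar centroids
    cen <- proto_centroids(mem, x)
    ids <- names(cen)
    cls <- vapply(ids, function(i) mem$class[mem$proto == i][1], "")
    parent <- seq_along(ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (length(ids) > 1) {
      for (a in seq_along(ids)[-length(ids)]) for (b in (a + 1):length(ids)) {
        if (cls[a] == cls[b] &&
            cosine(cen[[ids[a]]], cen[[ids[b]]]) >= merge_threshold) {
          parent[find(b)] <- find(a)
        }
      }
    }
    root <- vapply(seq_along(ids), find, 0L)
    mem$proto <- ids[root][match(mem$proto, ids)]
    mem$proto <- canonical_proto_ids(mem)
    if (paste(sort(paste(mem$parcel_id, mem$proto)), collapse = ";") == before) break
  }
  tibble(parcel_id = mem$parcel_id, prototype = mem$proto, class = mem$class,
         confidence = mem$confidence, stage = "kspice2")
}

proto_centroids <- function(mem, x) {
  lapply(split(mem$parcel_id, mem$proto), function(ids)
    colMeans(x[ids, , drop = FALSE]))
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1)
  sum(a * b) / (na * nb)
}

cosine_to_centroid <- function(mem, x, cen) {
  vapply(seq_len(nrow(mem)), function(i)
    cosine(x[mem$parcel_id[i], ], cen[[mem$proto[i]]]), 0)
}

# stable prototype ids: number groups by their smallest member id
canonical_proto_ids <- function(mem) {
  first <- vapply(split(mem$parcel_id, mem$proto), min, "")
  new_id <- setNames(sprintf("t%02d", rank(first)), names(first))
  unname(new_id[mem$proto])
}

#' Configuration for the semi-supervised texture classifier
#'
#' @param tau Consistency confidence threshold; unlabeled chips predicted
#'   above it (on a weak augmentation) supervise their strong augmentation.
#'   Values above 1 switch the consistency term off.
#' @param rounds Self-training rounds re-deriving consistency targets.
#' @param epochs,lr Adam schedule of the softmax head per round.
#' @param lambda_u Weight of the consistency loss.
#' @param embed_method Embedding extractor passed to [texture_embed()].
#' @return A config list.
#' @export
texture_config <- function(tau = 0.95, rounds = 3, epochs = 200, lr = 0.05,
                           lambda_u = 1, embed_method = "handcrafted") {
  list(tau = tau, rounds = rounds, epochs = epochs, lr = lr,
       lambda_u = lambda_u, embed_method = embed_method)
}

# weak augmentation: flip and/or small integer translation
augment_weak <- function(chip) {
  if (runif(1) < 0.5) chip <- chip[dim(chip)[1]:1, , , drop = FALSE]
  if (runif(1) < 0.5) chip <- chip[, dim(chip)[2]:1, , drop = FALSE]
  shift_chip(chip, sample(-2:2, 1), sample(-2:2, 1))
}

# strong augmentation: flip + intensity jitter + cutout
augment_strong <- function(chip) {
  chip <- augment_weak(chip)
  chip <- chip * runif(1, 0.7, 1.3) + rnorm(1, 0, 0.05)
  s <- dim(chip)[1]
  cs <- max(2, floor(s / 4))
  r0 <- sample(seq_len(s - cs + 1), 1); c0 <- sample(seq_len(s - cs + 1), 1)
  chip[r0:(r0 + cs - 1), c0:(c0 + cs - 1), ] <- 0
  chip
}

shift_chip <- function(chip, dr, dc) {
  s <- dim(chip)[1]
  out <- array(0, dim(chip))
  src_r <- intersect(seq_len(s), seq_len(s) - dr)
  src_c <- intersect(seq_len(s), seq_len(s) - dc)
  out[src_r + dr, src_c + dc, ] <- chip[src_r, src_c, , drop = FALSE]
  out
}

#' Train the semi-supervised texture classifier
#'
#' A compact convolutional classifier: the fixed oriented filter-bank front
#' end of [texture_embed()] followed by a trained multinomial softmax head.
#' Pseudolabelled chips supply the supervised cross-entropy; in each round,
#' unlabeled chips whose weakly-augmented prediction clears `tau` contribute
#' a consistency cross-entropy on their strongly-augmented view. Training is
#' deterministic given `seed`.
#'
#' @param labelset Pseudolabel tibble (`parcel_id`, `class`).
#' @param chips Chip tibble covering labelled and unlabeled parcels.
#' @param config A [texture_config()].
#' @param seed Integer seed.
#' @param classes Class universe.
#' @return A `pitt_texture_model`.
#' @export
train_semi_texture_classifier <- function(labelset, chips, config = texture_config(),
                                          seed = 1, classes = PITT_CLASSES) {
  labelset <- dplyr::filter(labelset, !is.na(.data$class))
  if (nrow(labelset) == 0) stop("empty pseudolabel set", call. = FALSE)
  present <- intersect(classes, unique(labelset$class))
  if (length(present) < 2)
    stop("texture training needs at least two classes", call. = FALSE)
  chips <- dplyr::arrange(chips, .data$parcel_id)
  emb <- texture_embed(chips, config$embed_method, seed)
  sc <- scale_features(emb$features)
  x_all <- sc$x
  lab_idx <- match(intersect(labelset$parcel_id, chips$parcel_id), rownames(x_all))
  lab_cls <- labelset$class[match(rownames(x_all)[lab_idx], labelset$parcel_id)]
  unlab_idx <- setdiff(seq_len(nrow(x_all)), lab_idx)

  y_lab <- matrix(0, length(lab_idx), length(present))
  y_lab[cbind(seq_along(lab_idx), match(lab_cls, present))] <- 1

  d <- ncol(x_all)
  w <- matrix(0, d, length(present)); b0 <- rep(0, length(present))
  withr::with_seed(seed, {
    for (round in seq_len(config$rounds)) {
      x_u <- NULL; y_u <- NULL
      if (config$tau <= 1 && length(unlab_idx) > 0 && round > 1) {
        weak <- t(vapply(chips$chip[unlab_idx], function(ch)
          spectral_or_cnn(augment_weak(ch), config$embed_method, seed),
          numeric(d)))
        weak <- sweep(sweep(weak, 2, sc$center), 2, sc$scale, "/")
        pw <- softmax_rows(weak %*% w + matrix(b0, nrow(weak), length(b0), byrow = TRUE))
        conf <- apply(pw, 1, max)
        pick <- conf >= config$tau
        if (any(pick)) {
          strong <- t(vapply(chips$chip[unlab_idx[pick]], function(ch)
            spectral_or_cnn(augment_strong(ch), config$embed_method, seed),
            numeric(d)))
          x_u <- sweep(sweep(strong, 2, sc$center), 2, sc$scale, "/")
          y_u <- matrix(0, sum(pick), length(present))
          y_u[cbind(seq_len(sum(pick)), max.col(pw[pick, , drop = FALSE],
                                                ties.method = "first"))] <- 1
        }
      }
      fit <- fit_softmax_head(x_all[lab_idx, , drop = FALSE], y_lab, x_u, y_u,
                              w, b0, config)
      w <- fit$w; b0 <- fit$b
    }
  })
  structure(list(w = w, b = b0, center = sc$center, scale = sc$scale,
                 classes = present, all_classes = classes,
                 embed_method = config$embed_method, config = config, seed = seed),
            class = "pitt_texture_model")
}

spectral_or_cnn <- function(chip, method, seed) {
  if (method == "handcrafted") spectral_features(chip)
  else random_cnn_features(list(chip), seed)[1, ]
}

fit_softmax_head <- function(x_l, y_l, x_u, y_u, w, b, config) {
  theta <- c(as.numeric(w), b)
  d <- nrow(w); k <- ncol(w)
  ms <- numeric(length(theta)); vs <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n_l <- nrow(x_l)
  for (ep in seq_len(config$epochs)) {
    w_ <- matrix(theta[seq_len(d * k)], d, k); b_ <- theta[d * k + seq_len(k)]
    p_l <- softmax_rows(x_l %*% w_ + matrix(b_, n_l, k, byrow = TRUE))
    gl <- (p_l - y_l) / n_l
    gw <- crossprod(x_l, gl); gb <- colSums(gl)
    if (!is.null(x_u) && nrow(x_u) > 0) {
      p_u <- softmax_rows(x_u %*% w_ + matrix(b_, nrow(x_u), k, byrow = TRUE))
      gu <- config$lambda_u * (p_u - y_u) / nrow(x_u)
      gw <- gw + crossprod(x_u, gu); gb <- gb + colSums(gu)
    }
    gvec <- c(as.numeric(gw), gb)
    ms <- b1 * ms + (1 - b1) * gvec
    vs <- b2 * vs + (1 - b2) * gvec^2
    theta <- theta - config$lr * (ms / (1 - b1^ep)) / (sqrt(vs / (1 - b2^ep)) + eps)
  }
  list(w = matrix(theta[seq_len(d * k)], d, k), b = theta[d * k + seq_len(k)])
}

#' @export
print.pitt_texture_model <- function(x, ...) {
  cat(sprintf("<pitt_texture_model> %s front end + softmax head, classes: %s\n",
              x$embed_method, paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Class probabilities from the texture classifier
#'
#' @param model A `pitt_texture_model`.
#' @param chips Chip tibble preprocessed as in training (resize rule applied).
#' @return Tibble `parcel_id, p_rape, p_wheat, p_other`.
#' @export
predict_proba_texture <- function(model, chips) {
  emb <- texture_embed(chips, model$embed_method, model$seed)
  if (ncol(emb$features) != length(model$center))
    stop("embedding size mismatch with training", call. = FALSE)
  x <- sweep(sweep(emb$features, 2, model$center), 2, model$scale, "/")
  p <- softmax_rows(x %*% model$w + matrix(model$b, nrow(x), ncol(model$w), byrow = TRUE))
  probs_to_tbl(p, rownames(x), model$classes, model$all_classes)
}
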