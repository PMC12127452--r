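# InceptionTime-family 1-D convolutional classifier, hand-authored:
# bottleneck 1x1 conv, parallel convolutions at three kernel scales, a
# max-pool + 1x1 branch, residual connections every third block, global
# average pooling and a softmax head, trained full-batch with Adam.
# Tensors are arrays [n, T, C]; all maths is plain matrix algebra so the fit
# is exactly reproducible given a seed.

flat2 <- function(a) { d <- dim(a); dim(a) <- c(d[1] * d[2], d[3]); a }
unflat2 <- function(m, n, t_) { dim(m) <- c(n, t_, ncol(m)); m }

pad_t <- function(x, left, right, fill = 0) {
  d <- dim(x)
  out <- array(fill, c(d[1], d[2] + left + right, d[3]))
  out[, left + seq_len(d[2]), ] <- x
  out
}

w_mat <- function(w, j) matrix(w[j, , ], dim(w)[2], dim(w)[3])

conv1d_fwd <- function(x, w, b = NULL) {
  k <- dim(w)[1]; t_ <- dim(x)[2]; n <- dim(x)[1]; f <- dim(w)[3]
  p <- (k - 1) / 2
  xp <- if (k > 1) pad_t(x, p, p) else x
  out <- matrix(if (is.null(b)) 0 else rep(b, each = n * t_), n * t_, f)
  for (j in seq_len(k)) {
    out <- out + flat2(xp[, j:(j + t_ - 1), , drop = FALSE]) %*% w_mat(w, j)
  }
  unflat2(out, n, t_)
}

conv1d_bwd <- function(x, w, dout) {
  k <- dim(w)[1]; t_ <- dim(x)[2]; n <- dim(x)[1]
  p <- (k - 1) / 2
  xp <- if (k > 1) pad_t(x, p, p) else x
  dflat <- flat2(dout)
  dw <- array(0, dim(w)); dxp <- array(0, dim(xp))
  for (j in seq_len(k)) {
    sl <- j:(j + t_ - 1)
    dw[j, , ] <- crossprod(flat2(xp[, sl, , drop = FALSE]), dflat)
    dxp[, sl, ] <- dxp[, sl, , drop = FALSE] + unflat2(dflat %*% t(w_mat(w, j)), n, t_)
  }
  dx <- if (k > 1) dxp[, p + seq_len(t_), , drop = FALSE] else dxp
  list(dx = dx, dw = dw, db = colSums(dflat))
}

maxpool3_fwd <- function(x) {
  t_ <- dim(x)[2]
  xp <- pad_t(x, 1, 1, fill = -Inf)
  s1 <- xp[, 1:t_, , drop = FALSE]
  s2 <- xp[, 2:(t_ + 1), , drop = FALSE]
  s3 <- xp[, 3:(t_ + 2), , drop = FALSE]
  out <- pmax(s1, s2, s3)
  w1 <- out == s1
  w2 <- !w1 & out == s2
  w3 <- !w1 & !w2
  list(out = out, w1 = w1, w2 = w2, w3 = w3)
}

maxpool3_bwd <- function(cache, dout) {
  d <- dim(dout); t_ <- d[2]
  acc <- array(0, c(d[1], t_ + 2, d[3]))
  acc[, 1:t_, ] <- dout * cache$w1
  acc[, 2:(t_ + 1), ] <- acc[, 2:(t_ + 1), , drop = FALSE] + dout * cache$w2
  acc[, 3:(t_ + 2), ] <- acc[, 3:(t_ + 2), , drop = FALSE] + dout * cache$w3
  acc[, 1 + seq_len(t_), , drop = FALSE]
}

he_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

#' Configuration for the time-series classifier
#'
#' @param n_filters Filters per branch (a block outputs `4 * n_filters`
#'   channels: three kernel scales plus the max-pool branch).
#' @param kernel_sizes Three odd kernel widths; defaults suit ~10-step
#'   seasonal series.
#' @param depth Number of inception blocks; residual shortcuts join every
#'   third block. The default single block is the desk-scale setting.
#' @param bottleneck Bottleneck width applied when a block's input has more
#'   than one channel.
#' @param epochs,lr Full-batch Adam schedule.
#' @param min_per_class Minimum training samples required per class.
#' @return A config list.
#' @export
inception_config <- function(n_filters = 8, kernel_sizes = c(3, 5, 7), depth = 1,
                             bottleneck = 8, epochs = 400, lr = 0.01,
                             min_per_class = 2) {
  stopifnot(length(kernel_sizes) == 3, all(kernel_sizes %% 2 == 1), depth >= 1)
  list(n_filters = n_filters, kernel_sizes = kernel_sizes, depth = depth,
       bottleneck = bottleneck, epochs = epochs, lr = lr,
       min_per_class = min_per_class)
}

init_inception <- function(t_, n_classes, cfg) {
  blocks <- list()
  c_in <- 1
  seg_c <- 1  # channels at the start of the current residual segment
  for (b in seq_len(cfg$depth)) {
    blk <- list()
    c_b <- if (c_in > 1) cfg$bottleneck else c_in
    if (c_in > 1) blk$w_bottle <- he_init(c(1, c_in, c_b), c_in)
    blk$w_k <- lapply(cfg$kernel_sizes, function(k) he_init(c(k, c_b, cfg$n_filters), k * c_b))
    blk$b_k <- lapply(cfg$kernel_sizes, function(k) rep(0, cfg$n_filters))
    blk$w_pool <- he_init(c(1, c_in, cfg$n_filters), c_in)
    blk$b_pool <- rep(0, cfg$n_filters)
    c_out <- 4 * cfg$n_filters
    if (b %% 3 == 0) {
      blk$w_short <- he_init(c(1, seg_c, c_out), seg_c)
      seg_c <- c_out
    }
    blocks[[b]] <- blk
    c_in <- c_out
  }
  w_dense <- he_init(c(c_in, n_classes), c_in)
  list(blocks = blocks, w_dense = w_dense, b_dense = rep(0, n_classes))
}

forward_inception <- function(params, x, cfg, keep_cache = TRUE) {
  n <- dim(x)[1]; t_ <- dim(x)[2]
  caches <- list()
  seg_input <- x
  a <- x
  f <- cfg$n_filters
  for (b in seq_along(params$blocks)) {
    blk <- params$blocks[[b]]
    cache <- list(x = a)
    bo <- if (!is.null(blk$w_bottle)) conv1d_fwd(a, blk$w_bottle) else a
    cache$bo <- bo
    z <- array(0, c(n, t_, 4 * f))
    for (i in 1:3) z[, , (i - 1) * f + seq_len(f)] <- conv1d_fwd(bo, blk$w_k[[i]], blk$b_k[[i]])
    mp <- maxpool3_fwd(a)
    cache$mp <- mp
    z[, , 3 * f + seq_len(f)] <- conv1d_fwd(mp$out, blk$w_pool, blk$b_pool)
    if (!is.null(blk$w_short)) {
      cache$short_in <- seg_input
      z <- z + conv1d_fwd(seg_input, blk$w_short)
    }
    cache$z <- z
    a <- z * (z > 0)
    if (!is.null(blk$w_short)) seg_input <- a
    if (keep_cache) caches[[b]] <- cache
  }
  gap <- colMeans(aperm(a, c(2, 1, 3)))
  dim(gap) <- c(n, dim(a)[3])
  logits <- gap %*% params$w_dense +
    matrix(params$b_dense, n, length(params$b_dense), byrow = TRUE)
  list(probs = softmax_rows(logits), gap = gap, a = a, caches = caches)
}

softmax_rows <- function(l) {
  l <- l - apply(l, 1, max)
  e <- exp(l)
  e / rowSums(e)
}

backward_inception <- function(params, fwd, y_onehot, cfg) {
  n <- nrow(y_onehot)
  grads <- list(blocks = vector("list", length(params$blocks)))
  dlogits <- (fwd$probs - y_onehot) / n
  grads$w_dense <- crossprod(fwd$gap, dlogits)
  grads$b_dense <- colSums(dlogits)
  t_ <- dim(fwd$a)[2]
  dgap <- dlogits %*% t(params$w_dense)
  # broadcast the GAP gradient back over time
  da <- aperm(array(t(dgap / t_), c(ncol(dgap), n, t_)), c(2, 3, 1))
  pending <- list()  # shortcut gradients waiting for earlier blocks
  f <- cfg$n_filters
  for (b in rev(seq_along(params$blocks))) {
    blk <- params$blocks[[b]]
    cache <- fwd$caches[[b]]
    key <- as.character(b)
    if (!is.null(pending[[key]])) { da <- da + pending[[key]]; pending[[key]] <- NULL }
    dz <- da * (cache$z > 0)
    g <- list()
    if (!is.null(blk$w_bottle)) g$w_bottle <- NULL
    dbo_total <- NULL
    g$w_k <- vector("list", 3); g$b_k <- vector("list", 3)
    for (i in 1:3) {
      dbr <- dz[, , (i - 1) * f + seq_len(f), drop = FALSE]
      bw <- conv1d_bwd(cache$bo, blk$w_k[[i]], dbr)
      g$w_k[[i]] <- bw$dw; g$b_k[[i]] <- bw$db
      dbo_total <- if (is.null(dbo_total)) bw$dx else dbo_total + bw$dx
    }
    pw <- conv1d_bwd(cache$mp$out, blk$w_pool, dz[, , 3 * f + seq_len(f), drop = FALSE])
    g$w_pool <- pw$dw; g$b_pool <- pw$db
    dx <- maxpool3_bwd(cache$mp, pw$dx)
    if (!is.null(blk$w_bottle)) {
      bb <- conv1d_bwd(cache$x, blk$w_bottle, dbo_total)
      g$w_bottle <- bb$dw
      dx <- dx + bb$dx
    } else {
      dx <- dx + dbo_total
    }
    if (!is.null(blk$w_short)) {
      sw <- conv1d_bwd(cache$short_in, blk$w_short, dz)
      g$w_short <- sw$dw
      if (b - 3 >= 1) pending[[as.character(b - 3)]] <- sw$dx
    }
    grads$blocks[[b]] <- g
    da <- dx
  }
  grads
}

# recursive flatten / rebuild of the parameter tree, aligned by name so the
# gradient tree only needs matching names, not matching field order
flatten_tree <- function(p) {
  if (is.list(p)) unlist(lapply(seq_along(p), function(i) flatten_tree(p[[i]])),
                         use.names = FALSE)
  else as.numeric(p)
}

rebuild_tree <- function(template, v, pos = 1) {
  if (is.list(template)) {
    out <- template
    for (i in seq_along(template)) {
      r <- rebuild_tree(template[[i]], v, pos)
      out[[i]] <- r$node; pos <- r$pos
    }
    list(node = out, pos = pos)
  } else {
    n <- length(template)
    node <- v[pos:(pos + n - 1)]
    dim(node) <- dim(template)
    list(node = node, pos = pos + n)
  }
}

# pick gradients into the same tree shape as the parameters (by name)
grads_like <- function(template, grads) {
  if (is.list(template)) {
    out <- template
    nms <- names(template)
    for (i in seq_along(template)) {
      sub <- if (!is.null(nms) && nzchar(nms[i] %||% "")) grads[[nms[i]]] else grads[[i]]
      out[[i]] <- grads_like(template[[i]], sub)
    }
    out
  } else {
    if (is.null(grads)) template * 0 else grads
  }
}

#' Train the KI time-series classifier
#'
#' Fits the inception-style network on pseudolabelled, z-normalized series.
#' Training is full-batch Adam on the cross-entropy and is deterministic
#' given `seed`.
#'
#' @param pseudolabels Tibble with `parcel_id` and `class` (from
#'   [assign_crop_labels()] or any labelled subset).
#' @param ts_std Standardized long tibble covering at least the labelled ids.
#' @param config An [inception_config()].
#' @param seed Integer seed.
#' @param classes Class universe (canonical order); default rape/wheat/other.
#' @return A `pitt_ts_model`.
#' @export
train_ts_classifier <- function(pseudolabels, ts_std, config = inception_config(),
                                seed = 1, classes = PITT_CLASSES) {
  labs <- pseudolabels |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::distinct(.data$parcel_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$parcel_id)
  present <- intersect(classes, unique(labs$class))
  if (length(present) < 2)
    stop("training needs at least two classes; got: ",
         paste(unique(labs$class), collapse = ", "), call. = FALSE)
  counts <- table(factor(labs$class, present))
  if (any(counts < config$min_per_class))
    stop("classes with fewer than ", config$min_per_class, " samples: ",
         paste(names(counts)[counts < config$min_per_class], collapse = ", "),
         call. = FALSE)
  m <- ts_matrix(dplyr::semi_join(ts_std, labs, by = "parcel_id"))
  m <- m[labs$parcel_id, , drop = FALSE]
  x <- array(m, c(nrow(m), ncol(m), 1))
  y <- matrix(0, nrow(m), length(present))
  y[cbind(seq_len(nrow(m)), match(labs$class, present))] <- 1

  params <- withr::with_seed(seed, init_inception(ncol(m), length(present), config))
  theta <- flatten_tree(params)
  ms <- numeric(length(theta)); vs <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    fwd <- forward_inception(params, x, config)
    losses[ep] <- -mean(rowSums(y * log(pmax(fwd$probs, 1e-12))))
    gr <- grads_like(params, backward_inception(params, fwd, y, config))
    gvec <- flatten_tree(gr)
    ms <- b1 * ms + (1 - b1) * gvec
    vs <- b2 * vs + (1 - b2) * gvec^2
    theta <- theta - config$lr * (ms / (1 - b1^ep)) / (sqrt(vs / (1 - b2^ep)) + eps)
    params <- rebuild_tree(params, theta)$node
  }
  structure(list(params = params, config = config, classes = present,
                 all_classes = classes, t_len = ncol(m), losses = losses,
                 n_train = nrow(m), seed = seed),
            class = "pitt_ts_model")
}

#' @export
print.pitt_ts_model <- function(x, ...) {
  cat(sprintf(
    "<pitt_ts_model> inception-style 1-D CNN: depth %d, %d filters/branch,\n  classes: %s, trained on %d series (final loss %.4f)\n",
    x$config$depth, x$config$n_filters, paste(x$classes, collapse = "/"),
    x$n_train, tail(x$losses, 1)))
  invisible(x)
}

#' Class probabilities from the time-series classifier
#'
#' Applies the trained model to every parcel series (small parcels it was
#' trained on and micro parcels alike). Classes absent from training get
#' probability zero, keeping the output on the full class simplex.
#'
#' @param model A `pitt_ts_model`.
#' @param ts_std Standardized long tibble (same preprocessing as training).
#' @return Tibble `parcel_id, p_rape, p_wheat, p_other` (rows sum to 1).
#' @export
predict_proba_ts <- function(model, ts_std) {
  m <- ts_matrix(ts_std)
  if (ncol(m) != model$t_len)
    stop("series length ", ncol(m), " does not match training length ",
         model$t_len, call. = FALSE)
  x <- array(m, c(nrow(m), ncol(m), 1))
  fwd <- forward_inception(model$params, x, model$config, keep_cache = FALSE)
  probs_to_tbl(fwd$probs, rownames(m), model$classes, model$all_classes)
}

probs_to_tbl <- function(p, ids, present, classes) {
  full <- matrix(0, nrow(p), length(classes),
                 dimnames = list(NULL, prob_cols(classes)))
  full[, match(present, classes)] <- p
  dplyr::bind_cols(tibble(parcel_id = ids), as_tibble(full))
}
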