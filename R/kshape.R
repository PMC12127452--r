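#' Phenology reference curves
#'
#' Typical-sample backscatter curves used to map cluster prototypes to crop
#' types. A class may carry several typical samples (a list of vectors) when
#' it covers heterogeneous land covers.
#'
#' @param curves Named list: per class, a numeric vector or a list of
#'   numeric vectors (multiple typical samples).
#' @param dates Day-of-year vector shared by all curves.
#' @return A `phenology_reference` object.
#' @export
phenology_reference <- function(curves, dates) {
  stopifnot(length(curves) >= 1, !is.null(names(curves)))
  curves <- lapply(curves, function(cv) {
    cv <- if (is.list(cv)) cv else list(cv)
    stopifnot(all(lengths(cv) == length(dates)))
    cv
  })
  structure(list(curves = curves, dates = as.numeric(dates)),
            class = "phenology_reference")
}

# first typical sample of a class, interpolated to the requested dates
reference_curve <- function(references, label, dates) {
  cv <- references$curves[[label]]
  if (is.null(cv)) stop("reference set has no class ", label, call. = FALSE)
  stats::approx(references$dates, cv[[1]], xout = dates, rule = 2)$y
}

#' @rdname phenology_reference
#' @param path CSV with columns `class, sample, date, value` (`sample`
#'   optional, distinguishing multiple typical curves of one class).
#' @export
read_references_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!"sample" %in% names(d)) d$sample <- 1L
  dates <- sort(unique(d$date))
  curves <- lapply(split(d, d$class), function(g)
    lapply(split(g, g$sample), function(gs) gs$value[order(gs$date)]))
  phenology_reference(curves, dates)
}

#' @rdname phenology_reference
#' @param ref A `phenology_reference`.
#' @export
write_references_csv <- function(ref, path) {
  purrr::imap(ref$curves, function(cv, cls)
    purrr::imap(cv, ~ tibble(class = cls, sample = .y, date = ref$dates, value = .x)) |>
      dplyr::bind_rows()) |>
    dplyr::bind_rows() |>
    readr::write_csv(path)
  invisible(path)
}

# maximal normalized cross-correlation over shifts (coefficient normalization)
ncc_max <- function(x, y) {
  t_ <- length(x)
  den <- sqrt(sum(x^2) * sum(y^2))
  if (den == 0) return(0)
  best <- -Inf
  for (s in -(t_ - 1):(t_ - 1)) {
    i <- seq_len(t_)
    j <- i + s
    ok <- j >= 1 & j <= t_
    best <- max(best, sum(x[i[ok]] * y[j[ok]]) / den)
  }
  best
}

#' Shape-based distance between two series
#'
#' `1 - max_shift NCC`, the shift-invariant dissimilarity underlying k-Shape.
#' @param x,y Numeric series (z-normalized for the canonical behaviour).
#' @return Distance in `[0, 2]`.
#' @export
sbd <- function(x, y) 1 - ncc_max(x, y)

# shift x so its cross-correlation with ref is maximal; zero-pad
align_to <- function(x, ref) {
  t_ <- length(x)
  best <- -Inf; bs <- 0
  den <- sqrt(sum(x^2) * sum(ref^2))
  if (den > 0) {
    for (s in -(t_ - 1):(t_ - 1)) {
      i <- seq_len(t_); j <- i + s
      ok <- j >= 1 & j <= t_
      v <- sum(ref[i[ok]] * x[j[ok]]) / den
      if (v > best) { best <- v; bs <- s }
    }
  }
  out <- rep(0, t_)
  i <- seq_len(t_); j <- i + bs
  ok <- j >= 1 & j <= t_
  out[i[ok]] <- x[j[ok]]
  out
}

# k-Shape centroid: leading eigenvector of the centred Gram of aligned members
shape_extract <- function(members, ref) {
  t_ <- ncol(members)
  a <- t(apply(members, 1, align_to, ref = ref))
  if (nrow(members) == 1) a <- matrix(a, 1, t_)
  q <- diag(t_) - matrix(1 / t_, t_, t_)
  m <- q %*% crossprod(a) %*% q
  cen <- eigen(m, symmetric = TRUE)$vectors[, 1]
  if (sum(cen * colMeans(a)) < 0) cen <- -cen
  znorm(cen)
}

#' k-Shape clustering of z-normalized time series
#'
#' Shape-based clustering: members are assigned to the centroid with the
#' smallest shape-based distance (1 - maximal normalized cross-correlation
#' over shifts), and centroids are re-extracted as the leading eigenvector of
#' the centred Gram matrix of shift-aligned members. Reported per-member
#' `similarity` is `(1 + NCC_max) / 2`, mapped to `[0, 1]`, the confidence
#' scale on which prototype thresholds are applied.
#'
#' @param series Matrix of z-normalized series (rows = parcels, rownames =
#'   ids) or a standardized long tibble from [mean_standardize()].
#' @param k Number of clusters (curve types, not crop types; over-cluster
#'   relative to the class count and map to classes afterwards).
#' @param seed Integer seed; the fit is deterministic given `seed` after
#'   canonical row sorting by id.
#' @param max_iter Refinement iteration cap.
#' @param n_init Random-assignment restarts; the partition with the smallest
#'   total shape-based distance to its centroids wins.
#' @return A `pitt_kshape` list: `k`, `assignments` tibble
#'   (`parcel_id, cluster, similarity`), `centroids` matrix `[k, T]`.
#' @export
kshape_fit <- function(series, k, seed = 1, max_iter = 50, n_init = 5) {
  if (inherits(series, "data.frame")) series <- ts_matrix(series)
  series <- series[order(rownames(series)), , drop = FALSE]
  n <- nrow(series)
  if (k > n) stop("k (", k, ") exceeds the number of series (", n, ")", call. = FALSE)
  stopifnot(k >= 1, n_init >= 1)
  best <- NULL
  for (init in seq_len(n_init)) {
    cand <- kshape_once(series, k, seed + 1000L * (init - 1L), max_iter)
    if (is.null(best) || cand$total_sbd < best$total_sbd) best <- cand
  }
  ncc <- vapply(seq_len(n), function(i)
    ncc_max(series[i, ], best$cen[best$assign[i], ]), 0)
  structure(list(
    k = k,
    assignments = tibble(parcel_id = rownames(series), cluster = best$assign,
                         similarity = pmin(1, pmax(0, (1 + ncc) / 2))),
    centroids = best$cen
  ), class = "pitt_kshape")
}

kshape_once <- function(series, k, seed, max_iter) {
  n <- nrow(series)
  assign <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  cen <- matrix(0, k, ncol(series))
  for (c_ in seq_len(k)) cen[c_, ] <- shape_extract(series[assign == c_, , drop = FALSE],
                                                    colMeans(series[assign == c_, , drop = FALSE]))
  for (it in seq_len(max_iter)) {
    d <- vapply(seq_len(k), function(c_) apply(series, 1, sbd, y = cen[c_, ]),
                numeric(n))
    new_assign <- max.col(-d, ties.method = "first")
    # re-seed empty clusters with the worst-fitting member
    for (c_ in which(tabulate(new_assign, k) == 0)) {
      far <- which.max(d[cbind(seq_len(n), new_assign)])
      new_assign[far] <- c_
      d[far, ] <- Inf; d[far, c_] <- 0
    }
    if (all(new_assign == assign)) break
    assign <- new_assign
    for (c_ in seq_len(k)) {
      # a cluster drained by the re-seeding step keeps its previous centroid
      if (any(assign == c_))
        cen[c_, ] <- shape_extract(series[assign == c_, , drop = FALSE], cen[c_, ])
    }
  }
  total <- sum(vapply(seq_len(n), function(i) sbd(series[i, ], cen[assign[i], ]), 0))
  list(assign = assign, cen = cen, total_sbd = total)
}

#' @export
print.pitt_kshape <- function(x, ...) {
  cat(sprintf("<pitt_kshape> k = %d, n = %d series\n", x$k, nrow(x$assignments)))
  print(dplyr::count(x$assignments, .data$cluster))
  invisible(x)
}
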