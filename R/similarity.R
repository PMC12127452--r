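#' Pearson correlation as a phenology-shape similarity
#'
#' Plain product-moment correlation, except that zero-variance inputs return
#' 0 with a `"degenerate"` attribute instead of erroring, so flat synthetic
#' series cannot abort group statistics.
#'
#' @param x,y Equal-length numeric series (length >= 2).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(0, degenerate = TRUE))
  cor(x, y)
}

# pairwise Pearson for rows of a matrix, degenerate rows -> 0
row_pearson_matrix <- function(m) {
  sds <- apply(m, 1, sd)
  ok <- sds > 0
  r <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  if (sum(ok) >= 2) r[ok, ok] <- stats::cor(t(m[ok, , drop = FALSE]))
  diag(r)[ok] <- 1
  r
}

#' Time-weighted dynamic time warping distance
#'
#' Dynamic-programming alignment with local cost
#' `|x_i - y_j| + omega(i, j)` where the time weight is the logistic penalty
#' `omega = 1 / (1 + exp(-alpha * (g - beta)))` on the date gap
#' `g = |dates_x[i] - dates_y[j]|` in days. Symmetric step pattern
#' (match / insert / delete), full alignment, no warping window. With
#' `alpha = 0` the weight is a constant 0.5 per visited cell; as
#' `beta -> Inf` the weight vanishes and the distance approaches plain DTW.
#'
#' @param x,y Numeric series.
#' @param dates_x,dates_y Day-of-year vectors aligned with `x`, `y`.
#' @param alpha Logistic steepness per day (default 0.1).
#' @param beta Logistic midpoint in days (default 5).
#' @return Non-negative alignment cost.
#' @export
twdtw <- function(x, y, dates_x = seq_along(x), dates_y = seq_along(y),
                  alpha = 0.1, beta = 5) {
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("twdtw needs non-empty series", call. = FALSE)
  stopifnot(length(dates_x) == n, length(dates_y) == m, alpha >= 0, beta >= 0)
  g <- abs(outer(dates_x, dates_y, "-"))
  cost <- abs(outer(x, y, "-")) + 1 / (1 + exp(-alpha * (g - beta)))
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- cost[i, j] + min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  D[n + 1, m + 1]
}

#' Group-average similarity (GAS)
#'
#' Mean of all `n^2` pairwise similarities within a group, self-pairs
#' included (each contributes 1 under Pearson). Under a distance measure
#' (TWDTW) the same double average is a group-average distance, lower
#' meaning more coherent.
#'
#' @param series Matrix of series, one row per group member.
#' @param measure `"pearson"` (default) or `"twdtw"`.
#' @param dates Day-of-year vector (needed for TWDTW).
#' @param alpha,beta TWDTW parameters.
#' @return Scalar group statistic.
#' @export
gas <- function(series, measure = c("pearson", "twdtw"), dates = NULL,
                alpha = 0.1, beta = 5) {
  measure <- match.arg(measure)
  series <- as_series_matrix(series)
  n <- nrow(series)
  if (n == 0) stop("gas needs at least one series", call. = FALSE)
  if (measure == "pearson") return(mean(row_pearson_matrix(series)))
  if (is.null(dates)) dates <- seq_len(ncol(series))
  vals <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    twdtw(series[i, ], series[j, ], dates, dates, alpha, beta)))
  mean(vals)
}

#' True-average similarity (TAS)
#'
#' Mean similarity of group members to one typical sample series.
#'
#' @inheritParams gas
#' @param typical Numeric vector, the typical phenology curve.
#' @return Scalar group statistic.
#' @export
tas <- function(series, typical, measure = c("pearson", "twdtw"), dates = NULL,
                alpha = 0.1, beta = 5) {
  measure <- match.arg(measure)
  series <- as_series_matrix(series)
  n <- nrow(series)
  if (n == 0) stop("tas needs at least one series", call. = FALSE)
  if (measure == "pearson")
    return(mean(apply(series, 1, function(s) as.numeric(pearson(s, typical)))))
  if (is.null(dates)) dates <- seq_len(ncol(series))
  mean(apply(series, 1, function(s) twdtw(s, typical, dates, dates, alpha, beta)))
}

as_series_matrix <- function(series) {
  if (is.matrix(series)) series else matrix(series, nrow = 1)
}

#' Cross-crop distinguishability
#'
#' Mean of the chosen measure over all cross pairs of two groups: under
#' Pearson, low values mean the crops' curves are easy to tell apart; under
#' TWDTW, high distances do.
#'
#' @param group_a,group_b Series matrices (rows are members).
#' @inheritParams gas
#' @return Scalar mean cross-pair value.
#' @export
cross_crop_distinguishability <- function(group_a, group_b,
                                          measure = c("pearson", "twdtw"),
                                          dates = NULL, alpha = 0.1, beta = 5) {
  measure <- match.arg(measure)
  group_a <- as_series_matrix(group_a); group_b <- as_series_matrix(group_b)
  if (nrow(group_a) == 0 || nrow(group_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  if (measure == "pearson") {
    vals <- outer(seq_len(nrow(group_a)), seq_len(nrow(group_b)),
                  Vectorize(function(i, j) as.numeric(pearson(group_a[i, ], group_b[j, ]))))
  } else {
    if (is.null(dates)) dates <- seq_len(ncol(group_a))
    vals <- outer(seq_len(nrow(group_a)), seq_len(nrow(group_b)),
                  Vectorize(function(i, j)
                    twdtw(group_a[i, ], group_b[j, ], dates, dates, alpha, beta)))
  }
  mean(vals)
}

#' Pairwise similarity matrix of parcel time series
#'
#' @param ts Long time-series tibble (standardized or raw).
#' @param measure `"pearson"` or `"twdtw"`.
#' @param alpha,beta TWDTW parameters.
#' @return A `pitt_simmat`: list with `ids`, `values` (n x n), `measure`.
#' @export
similarity_matrix <- function(ts, measure = c("pearson", "twdtw"),
                              alpha = 0.1, beta = 5) {
  measure <- match.arg(measure)
  m <- ts_matrix(ts)
  dates <- ts_dates(ts)
  if (measure == "pearson") {
    v <- row_pearson_matrix(m)
  } else {
    n <- nrow(m)
    v <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      twdtw(m[i, ], m[j, ], dates, dates, alpha, beta)))
    dimnames(v) <- list(rownames(m), rownames(m))
  }
  structure(list(ids = rownames(m), values = v, measure = measure),
            class = "pitt_simmat")
}

#' GAS and TAS per size level and crop
#'
#' The per-stratum representativeness table behind the scale-grading
#' rationale: larger parcels should carry cleaner phenology, so similarity
#' statistics rise (Pearson) or distances fall (TWDTW) with scale level.
#'
#' @param ts Standardized long time-series tibble.
#' @param parcels Graded parcel tibble with `scale_level` and truth `label`.
#' @param references Optional [phenology_reference()] supplying the typical
#'   sample per crop; defaults to the group medoid (member with the highest
#'   mean similarity to its group).
#' @inheritParams similarity_matrix
#' @return Tibble: `scale_level, label, n, gas, tas, measure`; empty strata
#'   are omitted with a warning.
#' @export
gas_tas_by_scale <- function(ts, parcels, references = NULL,
                             measure = c("pearson", "twdtw"),
                             alpha = 0.1, beta = 5) {
  measure <- match.arg(measure)
  m <- ts_matrix(ts)
  dates <- ts_dates(ts)
  strata <- parcels |>
    dplyr::filter(!is.na(.data$label), .data$parcel_id %in% rownames(m)) |>
    dplyr::distinct(.data$scale_level, .data$label)
  if (nrow(strata) == 0) {
    warning("no labelled, graded parcels with series", call. = FALSE)
    return(tibble(scale_level = numeric(), label = character(), n = integer(),
                  gas = numeric(), tas = numeric(), measure = character()))
  }
  strata <- dplyr::arrange(strata, .data$scale_level, .data$label)
  purrr::pmap(strata, function(scale_level, label) {
    ids <- parcels$parcel_id[parcels$scale_level == scale_level &
                             !is.na(parcels$label) & parcels$label == label]
    ids <- intersect(ids, rownames(m))
    if (length(ids) == 0) {
      warning("empty stratum: level ", scale_level, " / ", label, call. = FALSE)
      return(NULL)
    }
    grp <- m[ids, , drop = FALSE]
    typ <- typical_series(grp, references, label, dates)
    tibble(scale_level = scale_level, label = label, n = length(ids),
           gas = gas(grp, measure, dates, alpha, beta),
           tas = tas(grp, typ, measure, dates, alpha, beta),
           measure = measure)
  }) |> dplyr::bind_rows()
}

# typical sample: the reference curve interpolated to the series dates (the
# caller supplies it in the same representation as the series: raw with raw,
# centred with centred, z-scored with z-scored), or the group medoid
typical_series <- function(group, references, label, dates) {
  if (!is.null(references)) return(reference_curve(references, label, dates))
  if (nrow(group) == 1) return(group[1, ])
  pc <- row_pearson_matrix(group)
  group[which.max(rowMeans(pc)), ]
}

znorm <- function(v) {
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
}
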