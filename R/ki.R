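#' Extract high-confidence cluster prototypes as pseudolabels
#'
#' Fine-tuning step one: keep cluster members whose `(1 + NCC)/2` similarity
#' to their own centroid reaches `prob_kshape` (default 0.97). Clusters left
#' empty by the threshold are dropped with a warning; the kept count is
#' non-increasing in the threshold.
#'
#' @param fit A [kshape_fit()] result.
#' @param prob_kshape Similarity threshold in `(0, 1]`.
#' @return Pseudolabel tibble `parcel_id, cluster, class (NA until assigned),
#'   confidence, stage = "kshape"`.
#' @export
extract_prototypes <- function(fit, prob_kshape = 0.97) {
  stopifnot(prob_kshape > 0, prob_kshape <= 1)
  kept <- dplyr::filter(fit$assignments, .data$similarity >= prob_kshape)
  empty <- setdiff(seq_len(fit$k), unique(kept$cluster))
  if (length(empty))
    warning("clusters with no member above the similarity threshold dropped: ",
            paste(empty, collapse = ", "), call. = FALSE)
  tibble(parcel_id = kept$parcel_id, cluster = kept$cluster,
         class = NA_character_, confidence = kept$similarity, stage = "kshape")
}

#' Filter amplitude conflicts out of shape clusters
#'
#' Fine-tuning step two: z-normalisation makes curves of different absolute
#' backscatter levels look alike, so within each cluster, members whose raw
#' mean level deviates from the cluster median by more than `delta`
#' (backscatter units) are removed. Clusters that share a shape but sit at
#' different raw levels simply remain separate prototypes and are mapped to
#' classes independently later.
#'
#' @param pseudolabels Tibble from [extract_prototypes()].
#' @param ts_std Standardized tibble carrying `raw_mean_level` (from
#'   [mean_standardize()]).
#' @param delta Allowed deviation from the cluster median raw level;
#'   `Inf` disables the filter.
#' @return Filtered pseudolabel tibble.
#' @export
filter_amplitude_conflicts <- function(pseudolabels, ts_std, delta = 3) {
  levels <- ts_std |>
    dplyr::distinct(.data$parcel_id, .data$raw_mean_level)
  pseudolabels |>
    dplyr::left_join(levels, by = "parcel_id") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::filter(abs(.data$raw_mean_level - median(.data$raw_mean_level)) <= delta) |>
    dplyr::ungroup() |>
    dplyr::select(-"raw_mean_level")
}

#' Map cluster prototypes to crop classes using phenology references
#'
#' Fine-tuning step three: each cluster centroid, restored to its raw
#' backscatter level (member-median mean and spread), is compared with the
#' typical curves by TWDTW; the cluster takes the class of the nearest
#' reference. Exact ties fall back to Pearson similarity, then to class
#' enumeration order (logged via message). Clusters holding fewer than
#' `min_fraction` of all pseudolabels are dropped as exceptionally rare
#' prototypes.
#'
#' @param pseudolabels Tibble from [filter_amplitude_conflicts()].
#' @param fit The [kshape_fit()] result providing centroids.
#' @param references A [phenology_reference()] covering every target class.
#' @param ts_std Standardized tibble with `raw_mean_level` (and the original
#'   spread recoverable from raw values via `ts_raw`).
#' @param ts_raw Raw (unstandardized) long tibble, used for level restoration.
#' @param min_fraction Rarity cut-off as a fraction of all pseudolabels.
#' @param alpha,beta TWDTW parameters.
#' @param required_classes Optional class vector the reference set must
#'   cover; missing classes raise an error.
#' @return Pseudolabel tibble with `class` filled and `stage = "ki"`.
#' @export
assign_crop_labels <- function(pseudolabels, fit, references, ts_raw,
                               min_fraction = 0.01, alpha = 0.1, beta = 5,
                               required_classes = NULL) {
  classes <- names(references$curves)
  if (!is.null(required_classes)) {
    miss <- setdiff(required_classes, classes)
    if (length(miss))
      stop("reference set is missing class(es): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  dates <- ts_dates(ts_raw)
  stats_raw <- ts_raw |>
    dplyr::group_by(.data$parcel_id) |>
    dplyr::summarise(mu = mean(.data$value),
                     sdev = sqrt(mean((.data$value - mean(.data$value))^2)))
  refs <- lapply(classes, function(cl)
    lapply(references$curves[[cl]], function(cv)
      stats::approx(references$dates, cv, xout = dates, rule = 2)$y))
  names(refs) <- classes

  n_total <- nrow(pseudolabels)
  out <- pseudolabels |>
    dplyr::group_by(.data$cluster) |>
    dplyr::filter(dplyr::n() >= min_fraction * n_total) |>
    dplyr::ungroup()
  dropped <- setdiff(unique(pseudolabels$cluster), unique(out$cluster))
  if (length(dropped))
    message("rare prototypes dropped (< ", min_fraction * 100, "% of pseudolabels): cluster ",
            paste(dropped, collapse = ", "))

  cluster_class <- vapply(sort(unique(out$cluster)), function(c_) {
    members <- out$parcel_id[out$cluster == c_]
    st <- stats_raw[stats_raw$parcel_id %in% members, ]
    cen_raw <- fit$centroids[c_, ] * median(st$sdev) + median(st$mu)
    d <- vapply(classes, function(cl)
      min(vapply(refs[[cl]], function(rc)
        twdtw(cen_raw, rc, dates, dates, alpha, beta), 0)), 0)
    nearest <- which(d == min(d))
    if (length(nearest) > 1) {
      r <- vapply(classes[nearest], function(cl)
        max(vapply(refs[[cl]], function(rc)
          as.numeric(pearson(cen_raw, rc)), 0)), 0)
      nearest <- nearest[which(r == max(r))]
      if (length(nearest) > 1)
        message("cluster ", c_, ": tie broken by class order -> ", classes[nearest[1]])
      nearest <- nearest[1]
    }
    classes[nearest]
  }, character(1))
  names(cluster_class) <- sort(unique(out$cluster))

  out$class <- cluster_class[as.character(out$cluster)]
  out$stage <- "ki"
  attr(out, "cluster_classes") <- cluster_class
  out
}

#' Run the full KI pseudolabel extraction chain
#'
#' Convenience wrapper: k-Shape fit, prototype extraction, amplitude-conflict
#' filtering, and crop-class assignment in one call.
#'
#' @param ts_std Standardized long tibble (small-parcel series).
#' @param ts_raw Matching raw long tibble.
#' @param references A [phenology_reference()].
#' @param k Cluster count; default three clusters per target class.
#' @param prob_kshape Prototype similarity threshold.
#' @param delta Amplitude-conflict tolerance (backscatter units).
#' @param min_fraction Rare-prototype cut-off.
#' @param seed Seed for the k-Shape fit.
#' @param alpha,beta TWDTW parameters for reference matching.
#' @return List: `fit` (k-Shape), `pseudolabels` (classed tibble).
#' @export
ki_pseudolabels <- function(ts_std, ts_raw, references,
                            k = 3 * length(references$curves),
                            prob_kshape = 0.97, delta = 3, min_fraction = 0.01,
                            seed = 1, alpha = 0.1, beta = 5) {
  fit <- kshape_fit(ts_std, k, seed = seed)
  pl <- extract_prototypes(fit, prob_kshape)
  pl <- filter_amplitude_conflicts(pl, ts_std, delta)
  pl <- assign_crop_labels(pl, fit, references, ts_raw,
                           min_fraction = min_fraction, alpha = alpha, beta = beta)
  list(fit = fit, pseudolabels = pl,
       cluster_classes = attr(pl, "cluster_classes"))
}

#' Label every clustered parcel by its cluster's crop class
#'
#' The plain clustering baseline: no classifier, every member of a cluster
#' takes the class that the prototype-to-reference mapping gave the cluster
#' (clusters without a mapped class yield `NA`).
#'
#' @param fit A [kshape_fit()] result.
#' @param cluster_classes Named class vector from [ki_pseudolabels()].
#' @return Tibble `parcel_id, class, confidence`.
#' @export
kshape_baseline_labels <- function(fit, cluster_classes) {
  a <- fit$assignments
  tibble(parcel_id = a$parcel_id,
         class = unname(cluster_classes[as.character(a$cluster)]),
         confidence = a$similarity)
}
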