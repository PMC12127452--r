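#' Fuse two class-probability streams by weighted averaging
#'
#' `p_fused = w * p_ki + (1 - w) * p_tex`, classwise. Both tables must cover
#' the same parcel ids; the result is renormalized only when accumulated
#' float drift exceeds 1e-6.
#'
#' @param prob_ki,prob_tex Probability tibbles (`parcel_id`, `p_*` columns).
#' @param w Weight on the time-series stream, in `[0, 1]` (default 0.5).
#' @param classes Class universe.
#' @return Fused probability tibble.
#' @export
fuse_probabilities <- function(prob_ki, prob_tex, w = 0.5, classes = PITT_CLASSES) {
  stopifnot(w >= 0, w <= 1)
  missing_ids <- c(setdiff(prob_ki$parcel_id, prob_tex$parcel_id),
                   setdiff(prob_tex$parcel_id, prob_ki$parcel_id))
  if (length(missing_ids))
    stop("probability streams disagree on parcel ids: ",
         paste(head(missing_ids, 10), collapse = ", "),
         if (length(missing_ids) > 10) ", ..." else "", call. = FALSE)
  cols <- prob_cols(classes)
  tex <- prob_tex[match(prob_ki$parcel_id, prob_tex$parcel_id), ]
  p <- w * as.matrix(prob_ki[, cols]) + (1 - w) * as.matrix(tex[, cols])
  drift <- abs(rowSums(p) - 1)
  if (any(drift > 1e-6)) p <- p / rowSums(p)
  dplyr::bind_cols(tibble(parcel_id = prob_ki$parcel_id), as_tibble(p))
}

#' Decide crop classes from probability vectors
#'
#' Argmax over the class simplex; exact ties fall to the earlier class in
#' canonical order (rape, wheat, other) and are flagged in `tie`.
#'
#' @param prob Probability tibble.
#' @param classes Class universe (also the tie-break order).
#' @return Tibble `parcel_id, class, confidence, tie`.
#' @export
decide_classes <- function(prob, classes = PITT_CLASSES) {
  p <- as.matrix(prob[, prob_cols(classes)])
  idx <- max.col(p, ties.method = "first")
  mx <- p[cbind(seq_len(nrow(p)), idx)]
  tie <- rowSums(p == mx) > 1
  if (any(tie))
    message(sum(tie), " parcel(s) with tied probabilities resolved by class order")
  tibble(parcel_id = prob$parcel_id, class = classes[idx], confidence = mx,
         tie = tie)
}

#' Evaluate predictions against truth labels
#'
#' One-vs-rest confusion counts per class, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, their harmonic mean F1, and the macro-F1 (unweighted mean of
#' per-class F1). Classes with no positive predictions or no positives in
#' truth get precision/recall 0 by convention.
#'
#' @param predictions Tibble with `parcel_id`, `class`.
#' @param truth Tibble with `parcel_id`, `label` (or `class`).
#' @param classes Class universe; truth labels outside it raise an error.
#' @return A `pitt_eval` list: `per_class` tibble, `mf1`, `n`.
#' @export
evaluate_classification <- function(predictions, truth, classes = PITT_CLASSES) {
  truth_col <- if ("label" %in% names(truth)) "label" else "class"
  joined <- dplyr::inner_join(
    dplyr::select(predictions, "parcel_id", pred = "class"),
    dplyr::select(truth, "parcel_id", truth = dplyr::all_of(truth_col)),
    by = "parcel_id")
  joined <- dplyr::filter(joined, !is.na(.data$truth))
  # unclassified parcels (NA prediction) count as misses for their true class
  joined$pred[is.na(joined$pred)] <- "(unclassified)"
  bad <- setdiff(unique(joined$truth), classes)
  if (length(bad))
    stop("truth contains classes outside the prediction space: ",
         paste(bad, collapse = ", "), call. = FALSE)
  n <- nrow(joined)
  per_class <- purrr::map(classes, function(cl) {
    tp <- sum(joined$pred == cl & joined$truth == cl)
    fp <- sum(joined$pred == cl & joined$truth != cl)
    fn <- sum(joined$pred != cl & joined$truth == cl)
    tn <- n - tp - fp - fn
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    tibble(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
           precision = precision, recall = recall, f1 = f1)
  }) |> dplyr::bind_rows()
  structure(list(per_class = per_class, mf1 = mean(per_class$f1), n = n),
            class = "pitt_eval")
}

#' @export
print.pitt_eval <- function(x, ...) {
  cat(sprintf("<pitt_eval> n = %d, macro-F1 = %.4f\n", x$n, x$mf1))
  print(as.data.frame(x$per_class), row.names = FALSE)
  invisible(x)
}

#' @rdname evaluate_classification
#' @param x A `pitt_eval`.
#' @param ... Unused.
#' @export
tidy.pitt_eval <- function(x, ...) x$per_class

#' @rdname evaluate_classification
#' @export
glance.pitt_eval <- function(x, ...) tibble(mf1 = x$mf1, n = x$n,
                                            n_classes = nrow(x$per_class))

#' Sweep the fusion weight and score each setting
#'
#' Evaluates the fused stream over a grid of weights (default 0.05 to 1 in
#' steps of 0.05) and reports per-class F1 and macro-F1 per weight.
#'
#' @inheritParams fuse_probabilities
#' @param truth Truth tibble (`parcel_id`, `label`).
#' @param grid Weights to evaluate, all in `[0, 1]`.
#' @return A `pitt_weight_sweep` tibble: `w`, one `f1_*` column per class,
#'   `mf1`; the best weight is in `attr(, "best_w")`.
#' @export
weight_sweep <- function(prob_ki, prob_tex, truth, grid = seq(0.05, 1, by = 0.05),
                         classes = PITT_CLASSES) {
  if (length(grid) == 0) stop("empty weight grid", call. = FALSE)
  stopifnot(all(grid >= 0 & grid <= 1))
  rows <- purrr::map(grid, function(w) {
    ev <- evaluate_classification(
      decide_classes(fuse_probabilities(prob_ki, prob_tex, w, classes), classes),
      truth, classes)
    f1 <- setNames(ev$per_class$f1, paste0("f1_", ev$per_class$class))
    dplyr::bind_cols(tibble(w = w), as_tibble(as.list(f1)), tibble(mf1 = ev$mf1))
  }) |> dplyr::bind_rows()
  structure(rows, best_w = rows$w[which.max(rows$mf1)],
            class = c("pitt_weight_sweep", class(rows)))
}
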