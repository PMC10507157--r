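#' Confusion matrix
#'
#' Counts with rows = true class, columns = predicted class, in `classes`
#' order, plus the row-normalized view whose diagonal gives per-class
#' prediction accuracy (recall). Rows with no observations normalize to zero.
#'
#' @param truth,estimate Equal-length label vectors.
#' @param classes Class order.
#' @return A `sers_confusion`: `counts` (integer matrix), `normalized`,
#'   `accuracy`.
#' @export
confusion_matrix <- function(truth, estimate, classes = aldehyde_classes()) {
  if (length(truth) != length(estimate)) {
    abort("truth and estimate must have equal length")
  }
  bad <- setdiff(unique(c(truth, estimate)), classes)
  if (length(bad) > 0) {
    abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")))
  }
  counts <- table(factor(truth, levels = classes),
                  factor(estimate, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(true = classes, predicted = classes))
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, normalized = normalized,
                 accuracy = sum(diag(counts)) / sum(counts)),
            class = "sers_confusion")
}

#' @export
print.sers_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix (accuracy %.3f)\n", x$accuracy))
  print(round(x$normalized, 3))
  invisible(x)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores (ties collapsed) and computes the
#' trapezoidal area under the FPR--TPR curve. With tied scores this equals the
#' Mann--Whitney statistic with half credit for ties.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1, logical, or two-level factor where the
#'   second level is positive).
#' @return A `sers_roc`: tibble `threshold`, `fpr`, `tpr` (from (0,0) to
#'   (1,1)) with an `auc` attribute.
#' @export
roc_curve <- function(scores, labels) {
  y <- if (is.factor(labels)) {
    as.integer(labels == levels(labels)[2])
  } else {
    as.integer(as.numeric(labels) != 0)
  }
  if (length(unique(y)) < 2) {
    abort("both classes must be present to compute a ROC curve")
  }
  if (length(scores) != length(y)) abort("scores/labels length mismatch")
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n_neg,
                numeric(1))
  curve <- tibble::tibble(threshold = c(Inf, thr),
                          fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  structure(curve, class = c("sers_roc", class(curve)), auc = auc)
}

#' Area under a ROC curve
#' @param x A `sers_roc` from [roc_curve()], or scores when `labels` given.
#' @param labels Optional binary labels (computes the curve first).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(x, labels = NULL) {
  if (!is.null(labels)) x <- roc_curve(x, labels)
  attr(x, "auc")
}

#' Evaluate a trained classifier on held-out features
#'
#' Computes test accuracy, the confusion matrix, per-class one-vs-rest ROC
#' curves and AUCs from the predicted probabilities, their unweighted mean
#' (macro AUC), and the micro-average AUC over the pooled
#' (probability, indicator) pairs of all classes.
#'
#' @param model A `sers_mlp`.
#' @param test_features Wide feature table with `label`.
#' @return A `sers_eval`: `accuracy`, `confusion`, `per_class_auc`,
#'   `macro_auc`, `micro_auc`, `roc` (named list of `sers_roc`),
#'   `probabilities`. Supports [glance()] and [autoplot()].
#' @export
evaluate_model <- function(model, test_features) {
  if (nrow(test_features) == 0) abort("empty test set")
  truth <- test_features$label
  if (length(unique(truth)) < 2) abort("test set must contain >= 2 classes")
  probs <- predict(model, test_features, type = "prob")
  pred <- model$classes[apply(probs, 1, which.max)]
  cm <- confusion_matrix(truth, pred, model$classes)
  present <- model$classes[model$classes %in% unique(truth)]
  rocs <- lapply(setNames(present, present), function(cl) {
    roc_curve(probs[, cl], as.integer(truth == cl))
  })
  per_class <- vapply(rocs, function(r) attr(r, "auc"), numeric(1))
  pooled_scores <- as.vector(probs[, present])
  pooled_labels <- as.vector(vapply(present, function(cl)
    as.integer(truth == cl), integer(length(truth))))
  micro <- auc(pooled_scores, pooled_labels)
  structure(list(accuracy = cm$accuracy, confusion = cm,
                 per_class_auc = per_class,
                 macro_auc = mean(per_class), micro_auc = micro,
                 roc = rocs, probabilities = probs, truth = truth,
                 predicted = pred),
            class = "sers_eval")
}

#' @export
print.sers_eval <- function(x, ...) {
  cat(sprintf("Test accuracy %.3f | macro AUC %.3f | micro AUC %.3f\n",
              x$accuracy, x$macro_auc, x$micro_auc))
  cat("Per-class AUC:\n")
  print(round(x$per_class_auc, 3))
  invisible(x)
}

#' PCA baseline on raw intensities
#'
#' Principal component analysis of the column-centered `n x p` intensity
#' matrix over the full 1000--2300 cm\eqn{^{-1}} range, the conventional
#' chemometric baseline the classifier is compared against. Components are
#' oriented so each one's largest-magnitude loading is positive.
#'
#' @param data A `sers_spectra` tibble.
#' @param n_components Number of score dimensions to keep (default 3).
#' @return A `sers_pca`: `scores` tibble (`spectrum_id`, `label`,
#'   `PC1`..`PCk`), `explained_variance_ratio` (length `k`, non-increasing),
#'   `loadings` (`p x k`).
#' @export
pca_scores <- function(data, n_components = 3) {
  validate_spectra(data)
  n <- n_spectra(data)
  if (n < n_components + 1) {
    abort("need at least n_components + 1 spectra")
  }
  wide <- data |>
    dplyr::select("spectrum_id", "shift", "intensity") |>
    tidyr::pivot_wider(names_from = "shift", values_from = "intensity") |>
    dplyr::arrange(.data$spectrum_id)
  x <- as.matrix(wide[, -1])
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- n_components
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scr <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scr[, j] <- -scr[, j]
    }
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  meta <- spectra_meta(data) |> dplyr::arrange(.data$spectrum_id)
  scores <- dplyr::bind_cols(
    meta[, intersect(c("spectrum_id", "label"), names(meta))],
    tibble::as_tibble(scr)
  )
  structure(list(scores = scores,
                 explained_variance_ratio = evr[seq_len(k)],
                 loadings = load),
            class = "sers_pca")
}

#' @export
print.sers_pca <- function(x, ...) {
  cat("PCA of SERS intensities\n  explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", "),
      "\n")
  invisible(x)
}
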