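# tidy()/glance() methods, broom-style.

#' @describeIn fit_calibration Coefficient table (term, estimate, std.error).
#' @param x,object A fitted object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sers_calibration <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = unname(sm[, 1]),
                 std.error = unname(sm[, 2]))
}

#' @describeIn fit_calibration One-row model summary.
#' @exportS3Method generics::glance
glance.sers_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, sigma = x$residual_sd,
                 nobs = x$n_points)
}

#' @describeIn mlp_train Network weights in long form.
#' @param x,object A fitted object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sers_mlp <- function(x, ...) {
  longify <- function(m, layer) {
    tibble::tibble(layer = layer,
                   from = rep(seq_len(nrow(m)), ncol(m)),
                   to = rep(seq_len(ncol(m)), each = nrow(m)),
                   weight = as.vector(m))
  }
  dplyr::bind_rows(longify(x$params$W1, "hidden"),
                   longify(x$params$W2, "output"))
}

#' @describeIn mlp_train One-row training summary.
#' @exportS3Method generics::glance
glance.sers_mlp <- function(x, ...) {
  tibble::tibble(
    epochs = x$config$epochs,
    learning_rate = x$config$learning_rate,
    initial_loss = if (length(x$loss_history)) x$loss_history[1] else NA_real_,
    final_loss = if (length(x$loss_history)) tail(x$loss_history, 1)
                 else NA_real_)
}

#' @describeIn confusion_matrix Long count table with normalized rates.
#' @param x A `sers_confusion`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sers_confusion <- function(x, ...) {
  classes <- rownames(x$counts)
  tibble::tibble(
    true = rep(classes, times = length(classes)),
    predicted = rep(classes, each = length(classes)),
    count = as.vector(t(x$counts)),
    rate = as.vector(t(x$normalized))
  )
}

#' @describeIn evaluate_model One-row evaluation summary.
#' @param x A `sers_eval`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.sers_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_auc = x$macro_auc,
                 micro_auc = x$micro_auc,
                 min_class_auc = min(x$per_class_auc),
                 max_class_auc = max(x$per_class_auc))
}

#' @describeIn evaluate_model Per-class AUC table.
#' @exportS3Method generics::tidy
tidy.sers_eval <- function(x, ...) {
  tibble::tibble(class = names(x$per_class_auc),
                 auc = unname(x$per_class_auc))
}

#' @describeIn pca_scores Scores in long form.
#' @param x A `sers_pca`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sers_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, dplyr::starts_with("PC"),
                      names_to = "component", values_to = "score")
}

#' @describeIn pca_scores Explained-variance summary.
#' @exportS3Method generics::glance
glance.sers_pca <- function(x, ...) {
  evr <- x$explained_variance_ratio
  out <- tibble::as_tibble(as.list(setNames(
    evr, paste0("evr", seq_along(evr)))))
  out$total <- sum(evr)
  out
}
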