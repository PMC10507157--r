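test_that("confusion matrix counts, normalization and accuracy", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"),
                         classes = c("a", "b"))
  expect_equal(unname(cm$counts), matrix(c(1, 0, 1, 1), 2))
  expect_equal(cm$accuracy, 2 / 3)
  expect_equal(unname(cm$normalized[1, ]), c(0.5, 0.5))

  # perfect predictions give a diagonal matrix with unit recall
  labs <- rep(aldehyde_classes(), each = 18)
  cmp <- confusion_matrix(labs, labs)
  expect_equal(unname(diag(cmp$normalized)), rep(1, 6))
  expect_equal(sum(cmp$counts) - sum(diag(cmp$counts)), 0)

  # trace/total equals an independently counted match fraction
  set.seed(12)
  t_lab <- sample(aldehyde_classes(), 300, replace = TRUE)
  p_lab <- sample(aldehyde_classes(), 300, replace = TRUE)
  cmr <- confusion_matrix(t_lab, p_lab)
  expect_equal(cmr$accuracy, mean(t_lab == p_lab))
  # row sums conserved under any prediction permutation
  p2 <- sample(p_lab)
  expect_equal(rowSums(confusion_matrix(t_lab, p2)$counts),
               rowSums(cmr$counts))

  expect_error(confusion_matrix(c("a"), c("a", "b"), classes = c("a", "b")),
               "equal length")
  expect_error(confusion_matrix("x", "x", classes = c("a", "b")),
               "unknown label")
})

test_that("ROC endpoints and the worked four-point example", {
  perfect <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(attr(perfect, "auc"), 1)
  inverted <- roc_curve(c(4, 3, 2, 1), c(0, 0, 1, 1))
  expect_equal(attr(inverted, "auc"), 0)

  r <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(attr(r, "auc"), 0.75)
  expect_equal(attr(r, "auc"),
               auc_paircount(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))

  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(tail(r$fpr, 1), 1); expect_equal(tail(r$tpr, 1), 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))

  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("trapezoidal AUC equals Mann-Whitney pair counting, ties included", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    # discrete scores force ties; labels guaranteed two-class
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auc(scores, labels), auc_paircount(scores, labels),
                 tolerance = 1e-12)
  }
  # independent reference implementation on one fixed set
  set.seed(5)
  sc <- round(runif(60), 2)
  lb <- sample(0:1, 60, replace = TRUE, prob = c(0.4, 0.6))
  expect_equal(auc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("model evaluation: perfect toy model and AUC aggregation", {
  # hand-built model that keys on feature f01 for a two-class problem
  params <- list(W1 = matrix(0, 12, 6), b1 = rep(0, 6),
                 W2 = matrix(0, 6, 2), b2 = rep(0, 2))
  params$W1[1, 1] <- 20; params$b1[1] <- -10
  params$W2[1, ] <- c(-40, 40); params$b2 <- c(20, -20)
  toy <- structure(list(params = params,
                        classes = c("formaldehyde", "benzaldehyde"),
                        center = rep(0, 12), scale = rep(1, 12),
                        feature_names = sprintf("f%02d", 1:12),
                        config = list(hidden_activation = "sigmoid")),
                   class = "sers_mlp")
  feats <- tibble::tibble(label = rep(c("formaldehyde", "benzaldehyde"),
                                      each = 10),
                          !!!setNames(rep(list(0), 12),
                                      sprintf("f%02d", 1:12)))
  feats$f01 <- rep(c(0, 1), each = 10)
  ev <- evaluate_model(toy, feats)
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(ev$per_class_auc), c(1, 1))
  expect_equal(ev$macro_auc, 1)
  expect_equal(ev$micro_auc, 1)

  run <- easy_run()
  ev2 <- run$report
  expect_equal(ev2$macro_auc, mean(ev2$per_class_auc), tolerance = 1e-12)
  expect_true(all(ev2$per_class_auc >= 0 & ev2$per_class_auc <= 1))
  expect_equal(sum(ev2$confusion$counts), 108)
  expect_error(evaluate_model(run$model, run$split$test[0, ]), "empty")
})

test_that("PCA: variance ratios, eigendecomposition oracle, shapes", {
  x <- default_axis()
  set.seed(8)

  # exact rank-1 data
  base <- lor(x, 1500, 3, 40)
  w <- rnorm(20)
  specs1 <- dplyr::bind_rows(lapply(1:20, function(i) {
    sersvoc:::new_spectra(i, NA, NA, NA, x, w[i] * base)
  }))
  class(specs1) <- c("sers_spectra", class(tibble::tibble()))
  p1 <- pca_scores(specs1)
  expect_equal(p1$explained_variance_ratio[1], 1, tolerance = 1e-10)
  expect_lt(sum(p1$explained_variance_ratio[2:3]), 1e-10)

  # rank-3 data: scores match the covariance eigendecomposition up to sign
  bases <- rbind(lor(x, 1200, 2, 30), lor(x, 1600, 4, 25),
                 lor(x, 2100, 3, 50))
  wts <- matrix(rnorm(30 * 3), 30, 3)
  xm <- wts %*% bases
  specs3 <- dplyr::bind_rows(lapply(1:30, function(i) {
    sersvoc:::new_spectra(i, NA, NA, NA, x, xm[i, ])
  }))
  class(specs3) <- c("sers_spectra", class(tibble::tibble()))
  p3 <- pca_scores(specs3)
  expect_equal(dim(as.matrix(p3$scores[, c("PC1", "PC2", "PC3")])), c(30, 3))
  expect_gte(sum(p3$explained_variance_ratio), 0.999)
  expect_true(all(diff(p3$explained_variance_ratio) <= 1e-12))

  xc <- scale(xm, center = TRUE, scale = FALSE)
  ev <- eigen(cov(xc), symmetric = TRUE)
  oracle <- xc %*% ev$vectors[, 1:3]
  got <- as.matrix(p3$scores[, c("PC1", "PC2", "PC3")])
  for (j in 1:3) {
    expect_true(max(abs(got[, j] - oracle[, j])) < 1e-8 ||
                  max(abs(got[, j] + oracle[, j])) < 1e-8)
  }

  expect_error(pca_scores(specs1[specs1$spectrum_id <= 3, ]), "at least")
})

test_that("tidiers and plots return well-formed objects", {
  run <- easy_run()
  ev <- run$report
  g <- glance(ev)
  expect_equal(g$accuracy, ev$accuracy)
  expect_equal(nrow(tidy(ev)), 6)
  expect_equal(nrow(tidy(ev$confusion)), 36)
  expect_equal(sum(tidy(ev$confusion)$count), 108)
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(autoplot(ev$confusion), "ggplot")

  cal <- fit_calibration(generate_calibration_series(seed = 2))
  expect_s3_class(autoplot(cal), "ggplot")
  expect_equal(nrow(tidy(run$model)), 72 + 36)
  expect_s3_class(autoplot(run$dataset), "ggplot")

  pca <- pca_scores(run$dataset)
  expect_s3_class(autoplot(pca), "ggplot")
  expect_equal(nrow(tidy(pca)), 3 * 648)
})
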