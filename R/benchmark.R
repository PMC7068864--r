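# End-to-end seeded benchmark on synthetic data, shared by the test suite
# and the acceptance script: both classification routes (hand-crafted
# features + classical classifiers, and the reduced-width CNN) on the same
# generated train/test split, plus embedding-based case retrieval.

#' Run the end-to-end synthetic benchmark
#'
#' Generates a balanced train/test split with the default class presets,
#' then (i) segments every image from its POIs, extracts the 12-feature
#' descriptor and scores k-NN and SVM classifiers on the test half, and
#' (ii) trains the reduced-width sixteen-layer network on the raw images and
#' scores it on the same test half, optionally adding embedding-based case
#' retrieval. Fully reproducible from `seed`.
#'
#' @param seed master seed (default 7).
#' @param n_train,n_test cases per class for training / testing (defaults
#'   150 and 50, the first-round split of the reference study: 300 training
#'   and 100 test images).
#' @param size image side length (default 64).
#' @param width_mult CNN width multiplier (default 0.25, the desk-scale
#'   profile).
#' @param epochs CNN training epochs (default 8).
#' @param include_cnn,include_retrieval switch the CNN / retrieval stages
#'   off for a features-only run.
#' @return List of class `lesion_benchmark` with accuracies, AUCs and the
#'   underlying predictions.
#' @export
run_lesion_benchmark <- function(seed = 7L, n_train = 150L, n_test = 50L,
                                 size = 64L, width_mult = 0.25,
                                 epochs = 8L, include_cnn = TRUE,
                                 include_retrieval = TRUE) {
  presets <- list(
    benign = synth_params("benign", image_size = c(size, size)),
    malignant = synth_params("malignant", image_size = c(size, size)))
  train_cases <- generate_dataset(n_train, presets, seed = seed)
  test_cases <- generate_dataset(n_test, presets, seed = derive_seed(seed, 999L))
  train_labels <- vapply(train_cases, `[[`, "", "label")
  test_labels <- vapply(test_cases, `[[`, "", "label")

  tr_tab <- feature_table(train_cases)
  te_tab <- feature_table(test_cases)
  tr_x <- as.matrix(tr_tab[, 1:12]); te_x <- as.matrix(te_tab[, 1:12])

  knn <- lesion_knn(tr_x, train_labels, k = 5L)
  knn_pred <- predict(knn, te_x)
  knn_counts <- confusion_from_predictions(test_labels, knn_pred$label)
  knn_roc <- roc_pr_curves(test_labels, knn_pred$score)

  svm <- lesion_svm(tr_x, train_labels)
  svm_pred <- predict(svm, te_x)
  svm_counts <- confusion_from_predictions(test_labels, svm_pred$label)
  svm_roc <- roc_pr_curves(test_labels, svm_pred$score)

  out <- list(
    seed = seed, n_train = n_train, n_test = n_test, size = size,
    knn_accuracy = metrics(knn_counts)$accuracy,
    svm_accuracy = metrics(svm_counts)$accuracy,
    knn_auc_roc = knn_roc$auc_roc, svm_auc_roc = svm_roc$auc_roc,
    knn_counts = knn_counts, svm_counts = svm_counts,
    knn_pred = knn_pred, svm_pred = svm_pred,
    test_labels = test_labels)

  if (include_cnn) {
    spec <- build_depict_net(input_shape = c(size, size, 3L), K = 2L,
                             width_mult = width_mult)
    tr <- cases_to_tensor(train_cases, size = size)
    te <- cases_to_tensor(test_cases, size = size)
    net <- train_depict_net(spec, tr$images, tr$labels,
                            train_config(epochs = epochs,
                                         seed = derive_seed(seed, 77L)))
    prob <- predict(net, te$images, type = "prob")
    cnn_labels <- CLASS_LEVELS[max.col(prob, ties.method = "first")]
    cnn_counts <- confusion_from_predictions(test_labels, cnn_labels)
    cnn_roc <- roc_pr_curves(test_labels, prob[, 2L])
    out$cnn_accuracy <- metrics(cnn_counts)$accuracy
    out$cnn_auc_roc <- cnn_roc$auc_roc
    out$cnn_counts <- cnn_counts
    out$cnn_loss_history <- net$history
    out$network <- net
    if (include_retrieval) {
      base <- build_case_base(train_cases, network = net, size = size)
      hits <- vapply(seq_along(test_cases), function(i) {
        img <- te$images[, , , i, drop = TRUE]
        r <- retrieve(base, embed(net, img), k = 5L)
        r$predicted_label == test_labels[i]
      }, logical(1))
      out$retrieval_accuracy <- mean(hits)
    }
  }
  class(out) <- "lesion_benchmark"
  out
}

#' @export
print.lesion_benchmark <- function(x, ...) {
  cat(sprintf("<lesion_benchmark> seed %d, %d/class train, %d/class test, %dx%d px\n",
              x$seed, x$n_train, x$n_test, x$size, x$size))
  cat(sprintf("  k-NN accuracy %.3f (AUC %.3f)\n", x$knn_accuracy,
              x$knn_auc_roc))
  cat(sprintf("  SVM  accuracy %.3f (AUC %.3f)\n", x$svm_accuracy,
              x$svm_auc_roc))
  if (!is.null(x$cnn_accuracy)) {
    cat(sprintf("  CNN  accuracy %.3f (AUC %.3f)\n", x$cnn_accuracy,
                x$cnn_auc_roc))
  }
  if (!is.null(x$retrieval_accuracy)) {
    cat(sprintf("  retrieval accuracy %.3f\n", x$retrieval_accuracy))
  }
  invisible(x)
}
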