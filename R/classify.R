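# Classical classifiers over the 12-feature descriptor. Both return a
# continuous malignancy score so ROC/PR analysis applies uniformly:
# k-NN scores by the fraction of malignant neighbours, the SVM by its signed
# decision value oriented so larger means more malignant.

CLASS_LEVELS <- c("benign", "malignant")

as_label_factor <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% CLASS_LEVELS)) {
    stop("labels must be 'benign' or 'malignant'", call. = FALSE)
  }
  factor(labels, levels = CLASS_LEVELS)
}

check_feature_matrix <- function(x, p = 12L) {
  x <- as.matrix(x)
  if (ncol(x) != p) {
    stop(sprintf("feature vectors must have length %d, got %d", p, ncol(x)),
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' Fit a k-nearest-neighbour lesion classifier
#'
#' Stores the (normalized) training matrix; prediction is a majority vote of
#' the `k` nearest training vectors under Euclidean distance, with ties
#' broken toward the single nearest neighbour's label. The malignancy score
#' is the fraction of malignant neighbours among the `k`.
#'
#' @param x training feature matrix (rows = cases, 12 columns), unnormalized;
#'   a min-max normalizer is fitted on it unless one is supplied.
#' @param labels vector of `"benign"` / `"malignant"` labels.
#' @param k neighbourhood size (default 5), at most `nrow(x)`.
#' @param normalizer optional pre-fitted `normalization_params`.
#' @return An object of class `c("lesion_knn", "lesion_classifier")`.
#' @export
lesion_knn <- function(x, labels, k = 5L, normalizer = NULL) {
  x <- check_feature_matrix(x)
  labels <- as_label_factor(labels)
  stopifnot(nrow(x) == length(labels))
  if (k > nrow(x)) stop("k exceeds the training-set size", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  if (is.null(normalizer)) normalizer <- fit_normalizer(x)
  structure(list(kind = "knn", k = as.integer(k),
                 train_x = apply_normalizer(x, normalizer),
                 train_y = labels, normalizer = normalizer,
                 class_order = CLASS_LEVELS),
            class = c("lesion_knn", "lesion_classifier"))
}

#' @export
predict.lesion_knn <- function(object, newdata, ...) {
  q <- apply_normalizer(check_feature_matrix(newdata), object$normalizer)
  tx <- object$train_x
  out <- data.frame(label = character(nrow(q)), score = numeric(nrow(q)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(q))) {
    d <- sqrt(colSums((t(tx) - q[i, ])^2))
    nn <- order(d)[seq_len(object$k)]
    votes <- table(object$train_y[nn])
    top <- names(votes)[votes == max(votes)]
    lab <- if (length(top) == 1L) top else as.character(object$train_y[nn[1]])
    out$label[i] <- lab
    out$score[i] <- mean(object$train_y[nn] == "malignant")
  }
  out
}

#' Fit a support-vector-machine lesion classifier
#'
#' A Gaussian radial-basis-function SVM over the min-max-normalized
#' descriptor. The optimizer is the standard libsvm implementation; this
#' function fixes the input/output contract around it (class order, score
#' orientation, embedded normalizer).
#'
#' @inheritParams lesion_knn
#' @param cost soft-margin constant `C` (default 1).
#' @param gamma RBF kernel width; defaults to
#'   `1 / (12 * mean feature variance)` of the normalized training matrix.
#' @return An object of class `c("lesion_svm", "lesion_classifier")`.
#' @export
lesion_svm <- function(x, labels, cost = 1, gamma = NULL, normalizer = NULL) {
  x <- check_feature_matrix(x)
  labels <- as_label_factor(labels)
  stopifnot(nrow(x) == length(labels))
  if (nlevels(droplevels(labels)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  if (is.null(normalizer)) normalizer <- fit_normalizer(x)
  xn <- apply_normalizer(x, normalizer)
  if (is.null(gamma)) {
    v <- mean(apply(xn, 2L, stats::var))
    gamma <- if (v <= 0) 1 / ncol(xn) else 1 / (ncol(xn) * v)
  }
  fit <- e1071::svm(xn, labels, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE, probability = FALSE)
  # libsvm orients decision values toward the first class it encounters;
  # record the sign that makes larger scores mean malignant
  sign_flip <- if (fit$labels[1L] == which(CLASS_LEVELS == "malignant")) 1 else -1
  structure(list(kind = "svm", fit = fit, cost = cost, gamma = gamma,
                 normalizer = normalizer, sign_flip = sign_flip,
                 class_order = CLASS_LEVELS),
            class = c("lesion_svm", "lesion_classifier"))
}

#' @export
predict.lesion_svm <- function(object, newdata, ...) {
  q <- apply_normalizer(check_feature_matrix(newdata), object$normalizer)
  pred <- stats::predict(object$fit, q, decision.values = TRUE)
  dv <- as.numeric(attr(pred, "decision.values")) * object$sign_flip
  data.frame(label = ifelse(dv > 0, "malignant",
                            ifelse(dv < 0, "benign", as.character(pred))),
             score = dv, stringsAsFactors = FALSE)
}

#' @export
print.lesion_classifier <- function(x, ...) {
  if (x$kind == "knn") {
    cat(sprintf("<lesion_knn> k = %d, %d training cases\n",
                x$k, nrow(x$train_x)))
  } else {
    cat(sprintf("<lesion_svm> RBF kernel, C = %g, gamma = %.4g, %d support vectors\n",
                x$cost, x$gamma, nrow(x$fit$SV)))
  }
  invisible(x)
}

#' @export
summary.lesion_classifier <- function(object, ...) print(object)

#' Persist / restore a trained classifier bundle
#'
#' The bundle embeds the classifier, its normalizer, and a format version.
#'
#' @param model a `lesion_classifier`.
#' @param path file path for the bundle.
#' @export
save_classifier <- function(model, path) {
  saveRDS(list(format = "lesionclass-classifier-1", model = model), path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "lesionclass-classifier-1")) {
    stop("not a lesionclass classifier bundle", call. = FALSE)
  }
  x$model
}
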