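# Case-based-reasoning layer: a case base stores, per labelled image, the
# network embedding and/or the 12-feature descriptor together with the label
# and an optional recommendation text. Retrieval is exact k-nearest-neighbour
# search by Euclidean distance over the chosen representation (embeddings by
# default), with deterministic ties broken by case id.

#' Create a case record
#'
#' @param case_id unique identifier string.
#' @param embedding numeric network embedding (from [embed()]), or `NULL`.
#' @param feature_vector the 12-feature descriptor, or `NULL`.
#' @param label `"benign"` or `"malignant"`.
#' @param image_path optional source-image path.
#' @param recommendation_text free text stored with the case and passed
#'   through at retrieval.
#' @return An object of class `case_record`.
#' @export
case_record <- function(case_id, embedding = NULL, feature_vector = NULL,
                        label, image_path = NA_character_,
                        recommendation_text = "") {
  stopifnot(is.character(case_id), length(case_id) == 1L,
            label %in% CLASS_LEVELS)
  if (is.null(embedding) && is.null(feature_vector)) {
    stop("a case needs an embedding and/or a feature vector", call. = FALSE)
  }
  structure(list(case_id = case_id,
                 embedding = if (is.null(embedding)) NULL
                 else as.numeric(embedding),
                 feature_vector = if (is.null(feature_vector)) NULL
                 else as.numeric(feature_vector),
                 label = label, image_path = image_path,
                 recommendation_text = recommendation_text),
            class = "case_record")
}

#' Create an empty case base
#'
#' @param representation which vector retrieval compares: `"embedding"`
#'   (default) or `"features"`.
#' @param provenance optional named list (e.g. network-spec and normalizer
#'   hashes) recorded with the base.
#' @return An object of class `case_base`.
#' @export
case_base <- function(representation = c("embedding", "features"),
                      provenance = list()) {
  representation <- match.arg(representation)
  structure(list(records = list(), representation = representation,
                 provenance = provenance),
            class = "case_base")
}

rep_vector <- function(record, representation) {
  v <- if (representation == "embedding") record$embedding
  else record$feature_vector
  if (is.null(v)) {
    stop(sprintf("case '%s' lacks the base's %s representation",
                 record$case_id, representation), call. = FALSE)
  }
  v
}

#' Add a record to a case base
#'
#' Rejects records whose representation dimension differs from the base's.
#'
#' @param base a [case_base()].
#' @param record a [case_record()].
#' @return The extended case base.
#' @export
add_case <- function(base, record) {
  stopifnot(inherits(base, "case_base"), inherits(record, "case_record"))
  v <- rep_vector(record, base$representation)
  if (length(base$records) > 0L) {
    d0 <- length(rep_vector(base$records[[1L]], base$representation))
    if (length(v) != d0) {
      stop(sprintf("representation dimension %d does not match the base (%d)",
                   length(v), d0), call. = FALSE)
    }
    if (record$case_id %in% vapply(base$records, `[[`, "", "case_id")) {
      stop(sprintf("duplicate case_id '%s'", record$case_id), call. = FALSE)
    }
  }
  base$records <- c(base$records, list(record))
  base
}

#' Retrieve the nearest cases for a query vector
#'
#' Exact k-nearest-neighbour search under Euclidean distance over the base's
#' representation, ascending by distance with ties broken by `case_id`; the
#' predicted class is the majority label among the `k` retrieved cases
#' (ties toward the closest case's label).
#'
#' @param base a non-empty [case_base()].
#' @param query numeric query vector of the base's representation dimension.
#' @param k number of cases to retrieve.
#' @return A list with `cases` (the `k` nearest records), `distances`,
#'   `case_ids` and `predicted_label`.
#' @export
retrieve <- function(base, query, k = 5L) {
  stopifnot(inherits(base, "case_base"), k >= 1L)
  n <- length(base$records)
  if (n == 0L) stop("retrieval from an empty case base", call. = FALSE)
  k <- min(k, n)
  M <- t(vapply(base$records, rep_vector, numeric(
    length(rep_vector(base$records[[1L]], base$representation))),
    base$representation))
  query <- as.numeric(query)
  if (ncol(M) != length(query)) {
    stop(sprintf("query dimension %d does not match the base (%d)",
                 length(query), ncol(M)), call. = FALSE)
  }
  d <- sqrt(rowSums(sweep(M, 2L, query)^2))
  ids <- vapply(base$records, `[[`, "", "case_id")
  ord <- order(d, ids)[seq_len(k)]
  labels <- vapply(base$records[ord], `[[`, "", "label")
  tab <- table(factor(labels, levels = CLASS_LEVELS))
  top <- names(tab)[tab == max(tab)]
  pred <- if (length(top) == 1L) top else labels[1L]
  list(cases = base$records[ord], distances = d[ord], case_ids = ids[ord],
       predicted_label = pred)
}

#' @export
print.case_base <- function(x, ...) {
  labs <- vapply(x$records, `[[`, "", "label")
  cat(sprintf("<case_base> %d cases (%d benign, %d malignant), %s representation\n",
              length(x$records), sum(labs == "benign"),
              sum(labs == "malignant"), x$representation))
  invisible(x)
}

#' Build a case base from synthetic cases and a trained network
#'
#' @param cases list of `synthetic_case` objects.
#' @param network a trained `depict_net` (used for embeddings); may be
#'   `NULL` when `representation = "features"`.
#' @param representation retrieval representation, as in [case_base()].
#' @param config segmentation configuration used for the feature route.
#' @param size network input side length for the embedding route.
#' @return A populated [case_base()].
#' @export
build_case_base <- function(cases, network = NULL,
                            representation = c("embedding", "features"),
                            config = segmentation_config(), size = 64L) {
  representation <- match.arg(representation)
  base <- case_base(representation)
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    emb <- NULL; fv <- NULL
    if (representation == "embedding") {
      img <- cs$image
      if (!all(dim(img)[1:2] == c(size, size))) {
        img <- rescale_image(img, c(size, size))
      }
      emb <- embed(network, img)
    } else {
      mask <- segment_lesion(cs$image, cs$poi, config)$mask
      fv <- extract_features(cs$image, mask)
    }
    base <- add_case(base, case_record(
      case_id = sprintf("case_%04d", i), embedding = emb,
      feature_vector = fv, label = cs$label))
  }
  base
}

#' Save / load a case base
#'
#' The base is persisted as a JSON manifest (ids, labels, recommendation
#' texts, provenance) next to a CSV matrix holding the representation
#' vectors row by row, keeping both halves human-inspectable; rankings are
#' preserved bit-exactly across a round trip.
#'
#' @param base a [case_base()].
#' @param dir directory to hold `manifest.json` and `vectors.csv`.
#' @export
save_case_base <- function(base, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    representation = base$representation,
    provenance = base$provenance,
    cases = lapply(base$records, function(r) list(
      case_id = r$case_id, label = r$label, image_path = r$image_path,
      recommendation_text = r$recommendation_text))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  M <- t(vapply(base$records, rep_vector, numeric(
    length(rep_vector(base$records[[1L]], base$representation))),
    base$representation))
  utils::write.table(format(M, digits = 17L, scientific = TRUE, trim = TRUE),
                     file.path(dir, "vectors.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname save_case_base
#' @export
load_case_base <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  M <- as.matrix(utils::read.table(file.path(dir, "vectors.csv"), sep = ","))
  base <- case_base(man$representation,
                    provenance = as.list(man$provenance))
  for (i in seq_len(nrow(M))) {
    v <- as.numeric(M[i, ])
    base <- add_case(base, case_record(
      case_id = man$cases$case_id[i],
      embedding = if (man$representation == "embedding") v else NULL,
      feature_vector = if (man$representation == "features") v else NULL,
      label = man$cases$label[i],
      image_path = man$cases$image_path[i],
      recommendation_text = man$cases$recommendation_text[i]))
  }
  base
}

#' Classify an image end to end
#'
#' Runs the configured pipeline on one image: segmentation from the POIs and
#' feature extraction for the classical route, and/or the network embedding
#' with case-base retrieval for the CBR route. Identical inputs always
#' produce identical reports.
#'
#' @param image RGB array in `[0, 1]`.
#' @param poi 0-based `(row, col)` POI matrix (required for the feature
#'   route).
#' @param classifier optional `lesion_classifier` (k-NN or SVM) applied to
#'   the extracted features.
#' @param network optional trained `depict_net`.
#' @param base optional [case_base()] for retrieval.
#' @param k retrieval depth.
#' @param config segmentation configuration.
#' @return A list of class `classification_report` with whichever of
#'   `classical` (label, score, features), `cnn` (label, prob) and
#'   `retrieval` (predicted label, case ids, distances,
#'   recommendation texts) the supplied artifacts enable.
#' @export
classify_image <- function(image, poi = NULL, classifier = NULL,
                           network = NULL, base = NULL, k = 5L,
                           config = segmentation_config()) {
  out <- list()
  if (!is.null(classifier)) {
    if (is.null(poi) || nrow(as.matrix(poi)) == 0L) {
      stop("classical route requires a POI for segmentation", call. = FALSE)
    }
    seg <- tryCatch(segment_lesion(image, poi, config), error = function(e) {
      stop("segmentation stage failed: ", conditionMessage(e), call. = FALSE)
    })
    fv <- tryCatch(extract_features(image, seg$mask), error = function(e) {
      stop("feature stage failed: ", conditionMessage(e), call. = FALSE)
    })
    pred <- predict(classifier, matrix(fv, nrow = 1L))
    out$classical <- list(label = pred$label, score = pred$score,
                          features = fv)
  }
  if (!is.null(network)) {
    size <- network$spec$input_shape[1:2]
    img <- if (all(dim(image)[1:2] == size)) image
    else rescale_image(image, size)
    prob <- predict(network, img, type = "prob")
    out$cnn <- list(label = CLASS_LEVELS[which.max(prob[1L, ])],
                    prob = prob[1L, ], score = prob[1L, 2L])
    if (!is.null(base) && base$representation == "embedding") {
      r <- retrieve(base, embed(network, img), k = k)
      out$retrieval <- list(
        predicted_label = r$predicted_label, case_ids = r$case_ids,
        distances = r$distances,
        recommendation_texts = vapply(r$cases, `[[`, "",
                                      "recommendation_text"))
    }
  }
  if (!is.null(base) && base$representation == "features" &&
      !is.null(out$classical)) {
    r <- retrieve(base, out$classical$features, k = k)
    out$retrieval <- list(
      predicted_label = r$predicted_label, case_ids = r$case_ids,
      distances = r$distances,
      recommendation_texts = vapply(r$cases, `[[`, "",
                                    "recommendation_text"))
  }
  if (length(out) == 0L) {
    stop("no trained artifacts supplied: nothing to classify with",
         call. = FALSE)
  }
  structure(out, class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  if (!is.null(x$classical)) {
    cat(sprintf("classical: %s (score %.3f)\n",
                x$classical$label, x$classical$score))
  }
  if (!is.null(x$cnn)) {
    cat(sprintf("cnn:       %s (p_malignant %.3f)\n",
                x$cnn$label, x$cnn$score))
  }
  if (!is.null(x$retrieval)) {
    cat(sprintf("retrieval: %s (top case %s at %.3f)\n",
                x$retrieval$predicted_label, x$retrieval$case_ids[1L],
                x$retrieval$distances[1L]))
  }
  invisible(x)
}
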