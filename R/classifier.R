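#' SVM training parameters
#'
#' The classifier is a multiclass support vector machine with a radial
#' basis function kernel, one-vs-one decomposition, and Platt-calibrated
#' pairwise-coupled class probabilities; the predicted category's posterior
#' probability is reported as the confidence. Hyperparameters follow the
#' common SVM defaults: `cost = 1` and, when `gamma` is `NULL`,
#' `1 / (n_features * var(features))` at fit time.
#'
#' @param cost soft-margin cost C (default 1).
#' @param gamma RBF kernel width; `NULL` (default) for the scale heuristic
#'   above.
#' @param class_weights optional named vector of per-category weights for
#'   imbalanced training sets; `NULL` (default) leaves classes unweighted.
#' @param seed integer seed for the probability-calibration shuffling,
#'   making training deterministic.
#' @return an object of class `svm_params`.
#' @export
svm_params <- function(cost = 1, gamma = NULL, class_weights = NULL,
                       seed = 1L) {
  stopifnot(cost > 0, is.null(gamma) || gamma > 0)
  structure(list(cost = cost, gamma = gamma,
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "svm_params")
}

.MODEL_VERSION <- "genelit-model-1"

#' Train the gene classifier
#'
#' Fits the RBF-kernel SVM on projected term-frequency rows. Training is
#' deterministic given the data, parameters and seed; a manifest recording
#' the seed, parameters, and hashes of the training data is embedded in
#' the model.
#'
#' @param x dense numeric matrix (genes x vocabulary terms), e.g. from
#'   [project_matrix()]; term colnames required.
#' @param labels character/factor of functional categories, one per row.
#'   At least two distinct categories, each with at least two examples
#'   (a single-category set cannot define a decision boundary, and a
#'   category with one example cannot be calibrated).
#' @param params an [svm_params()].
#' @return an object of class `genelit_model`.
#' @export
train_classifier <- function(x, labels, params = svm_params()) {
  stopifnot(is.matrix(x), inherits(params, "svm_params"))
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("one label per row required")
  if (is.null(colnames(x))) stop("x must carry vocabulary terms as colnames")
  tab <- table(labels)
  if (length(tab) < 2L) {
    stop("training needs at least two distinct categories; got ",
         length(tab), " - not enough genes to train the classifier")
  }
  if (any(tab < 2L)) {
    stop("categories with fewer than two examples: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  gamma <- if (is.null(params$gamma)) {
    v <- stats::var(as.vector(x))
    if (v == 0) 1 / ncol(x) else 1 / (ncol(x) * v)
  } else params$gamma
  set.seed(params$seed)
  fit <- e1071::svm(
    x = x, y = factor(labels), kernel = "radial",
    cost = params$cost, gamma = gamma,
    class.weights = params$class_weights,
    probability = TRUE, scale = FALSE)
  structure(
    list(fit = fit,
         terms = colnames(x),
         vocab_hash = vocabulary_hash(colnames(x)),
         categories = levels(factor(labels)),
         params = unclass(params),
         gamma = gamma,
         manifest = list(seed = params$seed,
                         n_genes = nrow(x),
                         n_terms = ncol(x),
                         data_hash = hash_object(list(x, labels)),
                         trained = format(Sys.time(), tz = "UTC")),
         version = .MODEL_VERSION),
    class = "genelit_model")
}

#' @export
print.genelit_model <- function(x, ...) {
  cat(sprintf(
    "<genelit_model> %d categories, %d vocabulary terms, %d training genes\n",
    length(x$categories), length(x$terms), x$manifest$n_genes))
  invisible(x)
}

#' Predict functional categories with confidences
#'
#' Returns, for each row, the argmax-posterior category and its calibrated
#' probability as the confidence. Per-row class probabilities sum to 1, so
#' an uninformative (e.g. all-zero) row on a balanced model gets a
#' confidence near `1/K`; such rows are additionally flagged
#' `low_information`.
#'
#' @param model a `genelit_model`.
#' @param rows numeric matrix projected on the model's vocabulary (matching
#'   column count and, if named, column names); a single named numeric
#'   vector is also accepted.
#' @return data.frame with columns `gene`, `category`, `confidence`,
#'   `low_information`, plus the full posterior matrix as attribute
#'   `probabilities`.
#' @export
predict_genes <- function(model, rows) {
  stopifnot(inherits(model, "genelit_model"))
  if (is.numeric(rows) && is.null(dim(rows))) {
    rows <- matrix(rows, nrow = 1L,
                   dimnames = list("gene", names(rows)))
  }
  stopifnot(is.matrix(rows))
  if (ncol(rows) != length(model$terms)) {
    stop(sprintf("row width %d does not match the model vocabulary (%d terms)",
                 ncol(rows), length(model$terms)))
  }
  if (!is.null(colnames(rows)) &&
      !identical(vocabulary_hash(colnames(rows)), model$vocab_hash)) {
    stop("rows were projected on a different vocabulary than the model's")
  }
  colnames(rows) <- model$terms
  if (is.null(rownames(rows))) {
    rownames(rows) <- paste0("row", seq_len(nrow(rows)))
  }
  pred <- stats::predict(model$fit, rows, probability = TRUE)
  prob <- attr(pred, "probabilities")[, model$categories, drop = FALSE]
  top <- max.col(prob, ties.method = "first")
  out <- data.frame(
    gene = rownames(rows),
    category = model$categories[top],
    confidence = prob[cbind(seq_len(nrow(prob)), top)],
    low_information = rowSums(rows != 0) == 0L,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "probabilities") <- prob
  out
}

#' Filter predictions by a confidence threshold
#'
#' Keeps predictions with `confidence >= threshold` (inclusive).
#'
#' @param predictions data.frame from [predict_genes()].
#' @param threshold minimum confidence in `[0, 1]`.
#' @return the filtered data.frame.
#' @export
threshold_predictions <- function(predictions, threshold) {
  stopifnot(is.data.frame(predictions),
            "confidence" %in% names(predictions))
  out <- predictions[predictions$confidence >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Save and load a trained model
#'
#' The model is written as a single versioned RDS archive with its
#' embedded manifest and vocabulary hash; `load_model()` refuses files
#' that are not `genelit` models of the current version, and a reloaded
#' model gives identical predictions.
#'
#' @param model a `genelit_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "genelit_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("cannot read model file %s: %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!inherits(model, "genelit_model") ||
      !identical(model$version, .MODEL_VERSION)) {
    stop(sprintf("%s is not a compatible genelit model (expected %s)",
                 path, .MODEL_VERSION))
  }
  model
}
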