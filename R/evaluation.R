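#' Confidence-thresholded precision/recall curve
#'
#' For each threshold, genes with `confidence >= threshold` are "assigned";
#' precision is the fraction of assigned genes whose predicted category
#' matches the truth, recall is the number of correctly assigned genes over
#' all genes in the truth set. With `average = "micro"` (default) both are
#' pooled over genes; with `"macro"` precision averages per predicted
#' category (over categories with at least one assignment) and recall
#' averages per true category.
#'
#' @param predictions data.frame with columns `gene`, `category`,
#'   `confidence` (from [predict_genes()]).
#' @param truth named character vector mapping gene to true category, or a
#'   data.frame with columns `gene`, `category`.
#' @param thresholds numeric vector of confidence thresholds
#'   (default 0, 0.1, ..., 0.9).
#' @param average `"micro"` or `"macro"`.
#' @return data.frame with one row per threshold: `threshold`,
#'   `precision` (`NA` when nothing is assigned), `recall`, `n_assigned`,
#'   `n_correct`.
#' @export
pr_curve <- function(predictions, truth,
                     thresholds = seq(0, 0.9, by = 0.1),
                     average = c("micro", "macro")) {
  average <- match.arg(average)
  if (is.data.frame(truth)) {
    truth <- stats::setNames(as.character(truth$category),
                             as.character(truth$gene))
  }
  if (length(truth) == 0L) stop("truth set is empty")
  stopifnot(is.data.frame(predictions),
            all(c("gene", "category", "confidence") %in% names(predictions)))
  preds <- predictions[predictions$gene %in% names(truth), , drop = FALSE]
  true_cat <- truth[preds$gene]
  correct <- preds$category == true_cat
  n_total <- length(truth)

  rows <- lapply(thresholds, function(th) {
    assigned <- preds$confidence >= th
    n_assigned <- sum(assigned)
    n_correct <- sum(assigned & correct)
    if (average == "micro") {
      precision <- if (n_assigned == 0L) NA_real_ else n_correct / n_assigned
      recall <- n_correct / n_total
    } else {
      pred_cats <- unique(preds$category[assigned])
      precision <- if (length(pred_cats) == 0L) NA_real_ else {
        mean(vapply(pred_cats, function(cc) {
          sel <- assigned & preds$category == cc
          sum(sel & correct) / sum(sel)
        }, numeric(1)))
      }
      true_cats <- unique(unname(truth))
      recall <- mean(vapply(true_cats, function(cc) {
        in_cat <- names(truth)[truth == cc]
        sel <- assigned & correct & preds$gene %in% in_cat
        sum(sel) / length(in_cat)
      }, numeric(1)))
    }
    data.frame(threshold = th, precision = precision, recall = recall,
               n_assigned = n_assigned, n_correct = n_correct)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' F-measure
#'
#' `(1 + beta^2) * p * r / (beta^2 * p + r)`; with `beta = 1` the harmonic
#' mean of precision and recall (equally weighted).
#'
#' @param precision,recall values in `[0, 1]`, not both zero.
#' @param beta recall weight (default 1).
#' @return numeric F value.
#' @examples
#' f_measure(0.84, 0.68)
#' @export
f_measure <- function(precision, recall, beta = 1) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  if (any(precision == 0 & recall == 0)) {
    stop("precision and recall must not both be zero")
  }
  (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
}

#' Replicated Monte-Carlo holdout validation
#'
#' Shuffles the labeled dataset, splits it into 90/10 train/test
#' partitions, trains the classifier on the training part and scores the
#' precision/recall curve on the held-out part; repeats over independent
#' seeded shuffles and reports the per-threshold mean and standard
#' deviation of precision and recall. A replicate whose training split
#' loses a category entirely is redrawn (and logged); results are
#' bitwise-identical for a fixed seed. A true 10-fold partition mode is
#' available via `mode = "kfold"`.
#'
#' @param x dense numeric matrix (genes x terms) with gene rownames.
#' @param labels character vector of true categories, one per row.
#' @param params an [svm_params()].
#' @param replicates number of shuffles (default 100).
#' @param holdout held-out fraction per replicate (default 0.10).
#' @param thresholds confidence thresholds for the curve.
#' @param seed master seed; replicate seeds derive from it.
#' @param average passed to [pr_curve()].
#' @param mode `"montecarlo"` (default, independent shuffles) or
#'   `"kfold"` (each replicate is one 10-fold partition; `replicates`
#'   then counts folds).
#' @return an object of class `cv_result`: list with `summary`
#'   (data.frame: threshold, mean/sd precision, mean/sd recall, mean
#'   n_assigned), `per_replicate` (list of pr_curve data.frames),
#'   `replicates`, `holdout`, `seed`.
#' @export
replicated_holdout <- function(x, labels, params = svm_params(),
                               replicates = 100L, holdout = 0.10,
                               thresholds = seq(0, 0.9, by = 0.1),
                               seed = 1L, average = c("micro", "macro"),
                               mode = c("montecarlo", "kfold")) {
  average <- match.arg(average)
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), nrow(x) >= 2L, holdout > 0, holdout < 1)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("one label per row required")
  if (is.null(rownames(x))) rownames(x) <- paste0("gene", seq_len(nrow(x)))
  small <- names(which(table(labels) < 10L))
  if (length(small) > 0L) {
    warning("categories with fewer than 10 genes: ",
            paste(small, collapse = ", "))
  }
  n <- nrow(x)
  n_test <- max(1L, round(holdout * n))

  folds <- NULL
  if (mode == "kfold") {
    k <- max(2L, round(1 / holdout))
    set.seed(seed)
    folds <- split(sample.int(n), rep_len(seq_len(k), n))
    replicates <- length(folds)
  }

  curves <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    set.seed(seed + i)
    repeat {
      test_idx <- if (mode == "kfold") folds[[i]] else sample.int(n, n_test)
      train_idx <- setdiff(seq_len(n), test_idx)
      train_lab <- labels[train_idx]
      ok <- length(unique(train_lab)) == length(unique(labels)) &&
        all(table(train_lab) >= 2L)
      if (ok) break
      if (mode == "kfold") {
        stop("a k-fold training split lost a category; use montecarlo mode")
      }
      message(sprintf("replicate %d lost a category in training; redrawn", i))
    }
    rep_params <- params
    rep_params$seed <- params$seed + i
    model <- train_classifier(x[train_idx, , drop = FALSE],
                              labels[train_idx], rep_params)
    preds <- predict_genes(model, x[test_idx, , drop = FALSE])
    preds$gene <- rownames(x)[test_idx]
    truth <- stats::setNames(labels[test_idx], preds$gene)
    curves[[i]] <- pr_curve(preds, truth, thresholds, average = average)
  }

  prec <- sapply(curves, `[[`, "precision")
  rec <- sapply(curves, `[[`, "recall")
  nass <- sapply(curves, `[[`, "n_assigned")
  if (is.null(dim(prec))) {
    prec <- matrix(prec, nrow = length(thresholds))
    rec <- matrix(rec, nrow = length(thresholds))
    nass <- matrix(nass, nrow = length(thresholds))
  }
  sd0 <- function(m) {
    if (ncol(m) < 2L) return(rep(NA_real_, nrow(m)))
    apply(m, 1L, stats::sd, na.rm = TRUE)
  }
  summary <- data.frame(
    threshold = thresholds,
    mean_precision = rowMeans(prec, na.rm = TRUE),
    sd_precision = sd0(prec),
    mean_recall = rowMeans(rec, na.rm = TRUE),
    sd_recall = sd0(rec),
    mean_n_assigned = rowMeans(nass))
  structure(list(summary = summary, per_replicate = curves,
                 replicates = replicates, holdout = holdout,
                 seed = as.integer(seed), average = average, mode = mode),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d replicates, %.0f%% holdout (%s average)\n",
              x$replicates, 100 * x$holdout, x$average))
  print(round(x$summary, 4))
  invisible(x)
}

#' Write a cross-validated precision/recall curve as TSV
#'
#' Columns: threshold, precision, recall, sd_precision, sd_recall,
#' n_assigned — directly plottable as a recall-vs-precision figure.
#'
#' @param cv a `cv_result` (or a plain pr_curve data.frame).
#' @param path output path.
#' @export
write_pr_curve <- function(cv, path) {
  df <- if (inherits(cv, "cv_result")) {
    data.frame(threshold = cv$summary$threshold,
               precision = cv$summary$mean_precision,
               recall = cv$summary$mean_recall,
               sd_precision = cv$summary$sd_precision,
               sd_recall = cv$summary$sd_recall,
               n_assigned = cv$summary$mean_n_assigned)
  } else cv
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Paired t-test between two category percentage distributions
#'
#' Compares two paired vectors of per-category percentages (e.g. the
#' category composition of a source repository vs a training subset drawn
#' from it). Identical vectors (zero-variance differences) are reported
#' with statistic 0, p = 1, and a degenerate flag instead of an error.
#'
#' @param a,b equal-length numeric vectors of paired percentages,
#'   length >= 2.
#' @return list with `statistic`, `p_value`, `df`, `degenerate`, `method`.
#' @export
compare_category_distributions <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b),
            length(a) >= 2L)
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(statistic = 0, p_value = 1.0, df = length(d) - 1L,
                degenerate = TRUE, method = "paired t-test"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE,
       method = "paired t-test")
}

#' Summarize a corpus collection
#'
#' Gene and abstract counts, mean abstracts per gene, and (when labels are
#' given) per-category gene counts with percentages. The printed mean is
#' truncated — not rounded — to one decimal, matching the reporting
#' convention of repository summary tables; the exact value is also
#' returned. Percentages are rounded to two decimals.
#'
#' @param corpora named list of `gene_corpus` (ineligible markers are
#'   ignored), or a named integer vector of per-gene abstract counts.
#' @param labels optional named character vector or `gene`/`category`
#'   data.frame of category labels.
#' @return list with `n_genes`, `n_abstracts`, `mean_abstracts`
#'   (1 decimal, truncated), `mean_abstracts_exact`, and `categories`
#'   (data.frame `category`, `n`, `pct` or `NULL`).
#' @export
summarize_corpus <- function(corpora, labels = NULL) {
  counts <- if (is.numeric(corpora)) corpora else {
    eligible <- Filter(function(x) inherits(x, "gene_corpus"), corpora)
    stats::setNames(vapply(eligible, `[[`, numeric(1), "n"),
                    vapply(eligible, `[[`, character(1), "gene_name"))
  }
  n_genes <- length(counts)
  n_abstracts <- sum(counts)
  mean_exact <- if (n_genes > 0L) n_abstracts / n_genes else NA_real_
  cats <- NULL
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      labels <- stats::setNames(as.character(labels$category),
                                as.character(labels$gene))
    }
    tab <- table(labels[names(counts)])
    cats <- data.frame(category = names(tab), n = as.integer(tab),
                       pct = round(100 * as.integer(tab) / n_genes, 2),
                       stringsAsFactors = FALSE)
  }
  list(n_genes = n_genes, n_abstracts = n_abstracts,
       mean_abstracts = trunc(mean_exact * 10) / 10,
       mean_abstracts_exact = mean_exact,
       categories = cats)
}
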