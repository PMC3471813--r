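test_that("training on separable synthetic categories fits near-perfectly", {
  fx <- synth_separable()
  model <- train_classifier(fx$mat, fx$labels, svm_params(seed = 1))
  expect_s3_class(model, "genelit_model")
  expect_setequal(model$categories, unique(fx$labels))
  preds <- predict_genes(model, fx$mat)
  expect_gte(mean(preds$category == fx$labels), 0.95)
  # confidence of a training row beats the uniform-guess floor
  expect_true(all(preds$confidence > 1 / length(model$categories)))
})

test_that("degenerate training sets are rejected", {
  fx <- synth_separable()
  one_cat <- fx$labels == fx$labels[[1]]
  expect_error(train_classifier(fx$mat[one_cat, ], fx$labels[one_cat]),
               "two distinct categories")
  # a category with a single example cannot be trained on
  keep <- c(which(fx$labels == unique(fx$labels)[1])[1],
            which(fx$labels == unique(fx$labels)[2]))
  expect_error(train_classifier(fx$mat[keep, ], fx$labels[keep]),
               "fewer than two examples")
})

test_that("prediction rejects rows from a different feature space", {
  fx <- synth_separable()
  model <- train_classifier(fx$mat, fx$labels)
  expect_error(predict_genes(model, fx$mat[, 1:3]), "row width")
  wrong <- fx$mat
  colnames(wrong) <- paste0(colnames(wrong), "x")
  expect_error(predict_genes(model, wrong), "different vocabulary")
})

test_that("class posteriors are normalized and flag uninformative rows", {
  fx <- synth_separable()
  model <- train_classifier(fx$mat, fx$labels, svm_params(seed = 1))
  zero <- matrix(0, nrow = 1, ncol = ncol(fx$mat),
                 dimnames = list("blank", colnames(fx$mat)))
  preds <- predict_genes(model, rbind(fx$mat[1:5, ], zero))
  prob <- attr(preds, "probabilities")
  expect_equal(unname(rowSums(prob)), rep(1, nrow(prob)), tolerance = 1e-9)
  expect_true(all(preds$confidence >= 0 & preds$confidence <= 1))
  blank <- preds[preds$gene == "blank", ]
  expect_true(blank$low_information)
  expect_false(any(preds$low_information[preds$gene != "blank"]))
  # an all-zero row on a balanced model carries little information:
  # its confidence sits near the uniform floor, far below the
  # training-row confidences
  k <- length(model$categories)
  expect_lt(blank$confidence, 1 / k + 0.25)
  expect_lt(blank$confidence,
            min(preds$confidence[preds$gene != "blank"]))
})

test_that("confidence thresholding is inclusive and monotone", {
  fx <- synth_separable()
  model <- train_classifier(fx$mat, fx$labels)
  preds <- predict_genes(model, fx$mat)
  expect_equal(nrow(threshold_predictions(preds, 1.01)), 0)
  expect_equal(nrow(threshold_predictions(preds, 0)), nrow(preds))
  # inclusive boundary: a gene at exactly the threshold stays
  th <- preds$confidence[3]
  expect_true(preds$gene[3] %in% threshold_predictions(preds, th)$gene)
  counts <- vapply(seq(0, 1, 0.1),
                   function(th) nrow(threshold_predictions(preds, th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("training is deterministic given data, parameters and seed", {
  fx <- synth_separable()
  m1 <- train_classifier(fx$mat, fx$labels, svm_params(seed = 5))
  m2 <- train_classifier(fx$mat, fx$labels, svm_params(seed = 5))
  expect_identical(predict_genes(m1, fx$mat)$confidence,
                   predict_genes(m2, fx$mat)$confidence)
})

test_that("models survive a save/load round trip byte-for-byte in behavior", {
  fx <- synth_separable()
  model <- train_classifier(fx$mat, fx$labels, svm_params(seed = 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  rows <- fx$mat[1:10, ]
  expect_identical(predict_genes(model, rows), predict_genes(back, rows))
  expect_identical(back$vocab_hash, model$vocab_hash)

  trunc_path <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", trunc_path)
  expect_error(load_model(trunc_path), "cannot read")

  alien <- withr::local_tempfile(fileext = ".rds")
  saveRDS(structure(list(version = "other"), class = "genelit_model"),
          alien)
  expect_error(load_model(alien), "not a compatible")
})
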