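test_that("scale_pos_weight is the square root of the class-count ratio", {
  expect_equal(compute_scale_pos_weight(6132, 2401), 1.5981, tolerance = 1e-4)
  expect_equal(compute_scale_pos_weight(5, 5), 1)
  expect_equal(compute_scale_pos_weight(4, 1), 2)
  expect_error(compute_scale_pos_weight(10, 0), "positive")
})

test_that("classify applies the threshold rule with inclusive boundaries", {
  expect_equal(classify(c(0.96, 0.04, 0.50), 0.95),
               c("pathogenic", "benign", "uncertain"))
  # boundaries are definite calls
  expect_equal(classify(c(0.95, 0.05), 0.95), c("pathogenic", "benign"))
  expect_equal(classify(c(0.991, 0.989, 0.009), 0.99),
               c("pathogenic", "uncertain", "benign"))
  # p_ct = 0.5: no abstention; 0.5 itself is pathogenic (>= wins)
  p <- c(0, 0.2, 0.499, 0.5, 0.501, 1)
  expect_false("uncertain" %in% classify(p, 0.5))
  expect_equal(classify(0.5, 0.5), "pathogenic")
  expect_error(classify(1.2), "\\[0, 1\\]")
  expect_error(classify(0.5, 0.3), "p_ct")
})

test_that("classify is monotone in p and lowering p_ct never loses calls", {
  ord <- c(benign = 0, uncertain = 1, pathogenic = 2)
  p <- seq(0, 1, by = 0.01)
  for (p_ct in c(0.5, 0.95, 0.99)) {
    calls <- ord[classify(p, p_ct)]
    expect_true(all(diff(calls) >= 0))
  }
  set.seed(8)
  pr <- runif(500)
  n_definite <- function(p_ct) sum(classify(pr, p_ct) != "uncertain")
  expect_true(n_definite(0.5) >= n_definite(0.95))
  expect_true(n_definite(0.95) >= n_definite(0.99))
})

test_that("training on separable synthetic data reaches high validation MCC", {
  sp <- loss_split()
  clf <- loss_classifier()
  sc <- annotation_schema("loss")
  p <- predict_proba(clf, sp$validation[, sc])
  m <- metrics_from_confusion(build_confusion(classify(p, 0.5),
                                              sp$validation$label))
  expect_gte(m$mcc, 0.95)
  expect_lte(clf$best_iteration, clf$config$n_rounds)
  # scale_pos_weight derived from training counts
  expect_equal(clf$scale_pos_weight,
               compute_scale_pos_weight(clf$training_counts[["n_benign"]],
                                        clf$training_counts[["n_pathogenic"]]))
})

test_that("label permutation destroys the signal (null control)", {
  sp <- loss_split()
  sc <- annotation_schema("loss")
  # Permute every label the fit can see: the validation labels steer early
  # stopping, so leaving them intact would let iteration selection recover
  # real signal from an otherwise null model. A single permuted fit has
  # high-variance MCC (its near-0.5 probabilities binarize into calls that
  # align with the feature clusters by chance), so the control is the mean
  # over permutation replicates, which estimates the null center.
  null_mcc <- vapply(1:20, function(r) {
    set.seed(55 + r)
    ytr <- sample(sp$train$label)
    yva <- sample(sp$validation$label)
    clf0 <- train_classifier(sp$train[, sc], ytr,
                             sp$validation[, sc], yva,
                             "loss", seed = 55 + r)
    p0 <- predict_proba(clf0, sp$validation[, sc])
    metrics_from_confusion(build_confusion(classify(p0, 0.5),
                                           sp$validation$label))$mcc
  }, numeric(1))
  expect_lt(abs(mean(null_mcc)), 0.15)
})

test_that("training is seed-reproducible and errors on degenerate input", {
  sp <- loss_split()
  sc <- annotation_schema("loss")
  small <- sp$validation
  a <- train_classifier(small[, sc], small$label, small[, sc], small$label,
                        "loss", boosted_tree_config(n_rounds = 10), seed = 3)
  b <- train_classifier(small[, sc], small$label, small[, sc], small$label,
                        "loss", boosted_tree_config(n_rounds = 10), seed = 3)
  expect_identical(predict_proba(a, small[, sc]), predict_proba(b, small[, sc]))
  ben <- small[small$label == "benign", ]
  expect_error(train_classifier(ben[, sc], ben$label, small[, sc],
                                small$label, "loss"), "both")
  expect_error(train_classifier(small[, 1:5], small$label, small[, sc],
                                small$label, "loss"), "schema")
})

test_that("prediction preserves order, batches consistently and checks schema", {
  sp <- loss_split()
  clf <- loss_classifier()
  sc <- annotation_schema("loss")
  x <- sp$test[1:20, sc]
  p_batch <- predict_proba(clf, x)
  p_single <- vapply(seq_len(20), function(i) {
    predict_proba(clf, x[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(p_batch, p_single, tolerance = 1e-12)
  expect_identical(p_batch, predict_proba(clf, x))
  # all-zero vector looks benign: the benign class sits near zero counts
  zeros <- as.data.frame(as.list(setNames(rep(0, 19), sc)), optional = TRUE)
  expect_lt(predict_proba(clf, zeros), 0.5)
  expect_error(predict_proba(clf, sp$test[, 1:4]), "schema")
})

test_that("grid search ranks by validation MCC with stated tie-breaks", {
  sp <- loss_split()
  sc <- annotation_schema("loss")
  set.seed(19)
  tr <- sp$train[sample(nrow(sp$train), 800), ]
  va <- sp$validation
  crippled <- boosted_tree_config(max_depth = 1, eta = 0.001, n_rounds = 2,
                                  early_stopping_rounds = 2)
  gs <- grid_search(tr[, sc], tr$label, va[, sc], va$label,
                    grid = list(crippled, boosted_tree_config()),
                    cnv_type = "loss", seed = 9)
  expect_equal(nrow(gs$ranking), 2L)
  expect_equal(gs$ranking$config[1], 2L)  # defaults dominate by construction
  expect_equal(gs$best$config$max_depth, 8L)
  # one-config grid returns that config
  gs1 <- grid_search(tr[, sc], tr$label, va[, sc], va$label,
                     grid = list(crippled), cnv_type = "loss", seed = 9)
  expect_equal(gs1$best$config$max_depth, 1L)
  expect_error(grid_search(tr[, sc], tr$label, va[, sc], va$label,
                           grid = list(), cnv_type = "loss"), "empty")
})

test_that("a saved model round-trips through the directory artifact", {
  clf <- loss_classifier()
  sp <- loss_split()
  sc <- annotation_schema("loss")
  dir <- withr::local_tempdir()
  save_classifier(clf, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  expect_true(file.exists(file.path(dir, "metadata.json")))
  clf2 <- load_classifier(dir)
  expect_equal(predict_proba(clf2, sp$test[1:50, sc]),
               predict_proba(clf, sp$test[1:50, sc]), tolerance = 1e-7)
  expect_identical(clf2$schema, clf$schema)
  expect_equal(clf2$best_iteration, clf$best_iteration)
})
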