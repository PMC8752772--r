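# Per-type gradient-boosted-tree pathogenicity classifiers and the
# probability-threshold call policy.

#' Boosted-tree hyperparameter configuration
#'
#' Defaults are the final tuned values used for both CNV-type models:
#' depth-8 trees, learning rate 0.3, split penalty gamma = 1, full row
#' subsampling, L2 penalty 0.1, 80% column subsampling per tree, 100
#' boosting rounds with early stopping after 15 stagnant rounds on the
#' validation log-loss. `scale_pos_weight = NULL` means it is derived from
#' the training class counts at fit time (see
#' [compute_scale_pos_weight()]).
#'
#' @param max_depth maximum tree depth.
#' @param eta learning rate.
#' @param gamma minimum loss reduction to split.
#' @param subsample row fraction per boosting round.
#' @param lambda L2 regularization on leaf weights.
#' @param colsample_bytree column fraction per tree.
#' @param scale_pos_weight weight of the positive (pathogenic) class, or
#'   NULL to derive it from the training counts.
#' @param n_rounds maximum boosting rounds.
#' @param early_stopping_rounds stop after this many rounds without
#'   validation improvement.
#' @return list of class `boosted_tree_config`.
#' @export
boosted_tree_config <- function(max_depth = 8L, eta = 0.3, gamma = 1,
                                subsample = 1, lambda = 0.1,
                                colsample_bytree = 0.8,
                                scale_pos_weight = NULL,
                                n_rounds = 100L,
                                early_stopping_rounds = 15L) {
  structure(list(
    max_depth = as.integer(max_depth), eta = eta, gamma = gamma,
    subsample = subsample, lambda = lambda,
    colsample_bytree = colsample_bytree,
    scale_pos_weight = scale_pos_weight,
    n_rounds = as.integer(n_rounds),
    early_stopping_rounds = as.integer(early_stopping_rounds)
  ), class = "boosted_tree_config")
}

#' Positive-class weight from class counts
#'
#' The pathogenic class is the (weighted) minority; its boosting weight is
#' the square root of the benign/pathogenic count ratio,
#' `sqrt(n_benign / n_pathogenic)`.
#'
#' @param n_benign,n_pathogenic training-set class counts, both > 0.
#' @return positive scalar.
#' @examples
#' compute_scale_pos_weight(4, 1)  # 2
#' @export
compute_scale_pos_weight <- function(n_benign, n_pathogenic) {
  if (n_benign <= 0 || n_pathogenic <= 0) {
    stop("both class counts must be positive to derive scale_pos_weight")
  }
  sqrt(n_benign / n_pathogenic)
}

# features: data.frame/matrix with schema columns; labels: "benign"/"pathogenic"
.check_schema <- function(features, schema) {
  miss <- setdiff(schema, colnames(features))
  if (length(miss) > 0L) {
    stop("feature table does not match the model schema; missing: ",
         paste(miss, collapse = ", "))
  }
  as.matrix(features[, schema, drop = FALSE])
}

.label01 <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.numeric(labels))
  }
  if (!all(labels %in% c("benign", "pathogenic"))) {
    stop("labels must be binary: 'benign' or 'pathogenic'")
  }
  as.numeric(labels == "pathogenic")
}

#' Train a pathogenicity classifier for one CNV type
#'
#' Fits a binary gradient-boosted-tree ensemble (pathogenic = positive
#' class) on count feature vectors, monitoring validation log-loss for early
#' stopping. Training is reproducible for a fixed seed.
#'
#' @param train_features,train_labels training feature table (schema
#'   columns) and binary labels (`"benign"`/`"pathogenic"` or 0/1).
#' @param val_features,val_labels validation set monitored for early
#'   stopping.
#' @param cnv_type `"loss"` or `"gain"`; fixes the expected schema.
#' @param config a [boosted_tree_config()].
#' @param seed integer seed controlling column subsampling and any other
#'   stochastic component of the fit.
#' @return object of class `cnv_classifier`: the fitted booster plus
#'   schema, config, seed, class counts and the best (early-stopped)
#'   iteration.
#' @export
train_classifier <- function(train_features, train_labels,
                             val_features, val_labels,
                             cnv_type = c("loss", "gain"),
                             config = boosted_tree_config(),
                             seed = 1L) {
  cnv_type <- match.arg(cnv_type)
  schema <- annotation_schema(cnv_type)
  xtr <- .check_schema(train_features, schema)
  xva <- .check_schema(val_features, schema)
  ytr <- .label01(train_labels)
  yva <- .label01(val_labels)
  n_benign <- sum(ytr == 0)
  n_pathogenic <- sum(ytr == 1)
  if (n_benign == 0L || n_pathogenic == 0L) {
    stop("training set must contain both benign and pathogenic records")
  }
  spw <- config$scale_pos_weight
  if (is.null(spw)) spw <- compute_scale_pos_weight(n_benign, n_pathogenic)

  params <- list(
    objective = "binary:logistic",
    eval_metric = "logloss",
    max_depth = config$max_depth,
    eta = config$eta,
    gamma = config$gamma,
    subsample = config$subsample,
    lambda = config$lambda,
    colsample_bytree = config$colsample_bytree,
    scale_pos_weight = spw,
    nthread = 1L,
    seed = as.integer(seed)
  )
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(xtr, label = ytr)
  dval <- xgboost::xgb.DMatrix(xva, label = yva)
  booster <- xgboost::xgb.train(
    params = params, data = dtrain, nrounds = config$n_rounds,
    evals = list(validation = dval),
    early_stopping_rounds = config$early_stopping_rounds,
    verbose = 0
  )
  best_it <- suppressWarnings(
    as.integer(xgboost::xgb.attributes(booster)$best_iteration)
  )
  if (length(best_it) == 0L || is.na(best_it)) best_it <- config$n_rounds
  structure(list(
    booster = booster,
    cnv_type = cnv_type,
    schema = schema,
    config = config,
    seed = as.integer(seed),
    scale_pos_weight = spw,
    best_iteration = best_it,
    training_counts = c(n_benign = n_benign, n_pathogenic = n_pathogenic)
  ), class = "cnv_classifier")
}

#' @method print cnv_classifier
#' @export
print.cnv_classifier <- function(x, ...) {
  cat("cnv_classifier (", x$cnv_type, "), ", length(x$schema),
      " attributes\n", sep = "")
  cat("  training counts: ", x$training_counts[["n_benign"]], " benign / ",
      x$training_counts[["n_pathogenic"]], " pathogenic\n", sep = "")
  cat("  scale_pos_weight: ", format(x$scale_pos_weight, digits = 5),
      "; best iteration: ", x$best_iteration, "\n", sep = "")
  invisible(x)
}

#' Predict pathogenicity probabilities
#'
#' @param clf a `cnv_classifier`.
#' @param features feature table with the model's schema columns.
#' @param output_margin if TRUE return raw log-odds margins instead of
#'   probabilities.
#' @return numeric vector, one value per row, order preserved.
#' @export
predict_proba <- function(clf, features, output_margin = FALSE) {
  stopifnot(inherits(clf, "cnv_classifier"))
  x <- .check_schema(features, clf$schema)
  as.numeric(stats::predict(clf$booster, x, outputmargin = output_margin))
}

#' Three-class call from a pathogenicity probability
#'
#' Applies the abstention policy: pathogenic when `p >= p_ct`, benign when
#' `p <= 1 - p_ct`, otherwise uncertain significance (both boundaries
#' inclusive toward a definite call). Supported presets for `p_ct` are 0.5,
#' 0.95 and 0.99; 0.95 is the default operating point. At `p_ct = 0.5` every
#' probability yields a definite call (0.5 itself is pathogenic, since
#' `>=` wins).
#'
#' @param p numeric probabilities in \[0, 1\].
#' @param p_ct probability threshold in (0.5, 1\] (0.5 allowed as the
#'   degenerate no-abstention policy).
#' @return character vector over `{"benign", "uncertain", "pathogenic"}`.
#' @export
classify <- function(p, p_ct = 0.95) {
  if (length(p_ct) != 1L || is.na(p_ct) || p_ct < 0.5 || p_ct > 1) {
    stop("p_ct must be a single value in [0.5, 1]")
  }
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  ifelse(p >= p_ct, "pathogenic",
         ifelse(p <= 1 - p_ct, "benign", "uncertain"))
}

#' Hyperparameter grid search ranked by validation MCC
#'
#' Trains one classifier per configuration and ranks them by Matthews
#' correlation coefficient of the definite (p_ct = 0.5) calls on the
#' validation set. Ties are broken by higher validation accuracy, then lower
#' `max_depth`, then grid order.
#'
#' @inheritParams train_classifier
#' @param grid non-empty list of [boosted_tree_config()] objects.
#' @return list with `best` (the winning `cnv_classifier`) and `ranking`
#'   (data.frame of per-config validation MCC and accuracy, best first).
#' @export
grid_search <- function(train_features, train_labels,
                        val_features, val_labels,
                        grid, cnv_type = c("loss", "gain"), seed = 1L) {
  cnv_type <- match.arg(cnv_type)
  if (length(grid) == 0L) stop("hyperparameter grid is empty")
  fits <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cfg <- grid[[i]]
    fits[[i]] <- train_classifier(train_features, train_labels,
                                  val_features, val_labels,
                                  cnv_type = cnv_type, config = cfg,
                                  seed = seed)
    p <- predict_proba(fits[[i]], val_features)
    calls <- classify(p, p_ct = 0.5)
    m <- metrics_from_confusion(build_confusion(calls, val_labels))
    rows[[i]] <- data.frame(
      config = i, max_depth = cfg$max_depth, eta = cfg$eta,
      n_rounds = cfg$n_rounds, mcc = m$mcc, accuracy = m$accuracy
    )
  }
  ranking <- do.call(rbind, rows)
  ord <- order(-ranking$mcc, -ranking$accuracy, ranking$max_depth,
               ranking$config)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  list(best = fits[[ranking$config[1L]]], ranking = ranking)
}

#' Save / load a trained classifier
#'
#' The artifact is a directory holding the native booster dump
#' (`model.json`) and a metadata sidecar (`metadata.json`) with the schema,
#' configuration, seed, class counts and best iteration. Loading verifies
#' that the stored schema matches the current vocabulary for the model's
#' CNV type.
#'
#' @param clf a `cnv_classifier`.
#' @param path directory to create/overwrite.
#' @return `save_classifier`: the path, invisibly. `load_classifier`: the
#'   restored `cnv_classifier`.
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "cnv_classifier"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(clf$booster, file.path(path, "model.json"))
  meta <- list(
    cnv_type = clf$cnv_type,
    schema = clf$schema,
    config = unclass(clf$config),
    seed = clf$seed,
    scale_pos_weight = clf$scale_pos_weight,
    best_iteration = clf$best_iteration,
    training_counts = as.list(clf$training_counts)
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path)) {
    stop("no model artifact at ", path, " (metadata.json missing)")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  expected <- annotation_schema(meta$cnv_type)
  if (!identical(as.character(meta$schema), expected)) {
    stop("stored schema does not match the ", meta$cnv_type,
         " attribute vocabulary")
  }
  cfg <- do.call(boosted_tree_config, meta$config[
    setdiff(names(meta$config), character(0))])
  structure(list(
    booster = xgboost::xgb.load(file.path(path, "model.json")),
    cnv_type = meta$cnv_type,
    schema = expected,
    config = cfg,
    seed = meta$seed,
    scale_pos_weight = meta$scale_pos_weight,
    best_iteration = meta$best_iteration,
    training_counts = unlist(meta$training_counts)
  ), class = "cnv_classifier")
}
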