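# Additive per-attribute explanation of individual predictions.
#
# Contributions are exact tree-path Shapley values computed over the fitted
# ensemble on the log-odds (margin) scale, where additivity
# base + sum(contributions) = margin holds to numerical precision. The
# probability scale is a display transform of the endpoints only.

.shap_matrix <- function(clf, features) {
  stopifnot(inherits(clf, "cnv_classifier"))
  x <- .check_schema(features, clf$schema)
  ctr <- stats::predict(clf$booster, x, predcontrib = TRUE)
  if (is.null(dim(ctr))) ctr <- matrix(ctr, nrow = 1L)
  colnames(ctr) <- c(clf$schema, "BIAS")
  ctr
}

#' Explain a single prediction
#'
#' Decomposes one prediction into a base value (the ensemble's prior
#' expectation over the training data) plus one signed contribution per
#' schema attribute, on the log-odds scale. `base_value + sum(contributions)`
#' equals the raw ensemble margin; `plogis()` of the endpoints gives the
#' probability-scale view.
#'
#' @param clf a `cnv_classifier`.
#' @param features a one-row feature table matching the model schema.
#' @return list of class `attribution_report`: `base_value`,
#'   `contributions` (named numeric, schema order), `output_value` (margin),
#'   `output_probability`, `base_probability`, and the feature `values`.
#' @export
explain_prediction <- function(clf, features) {
  if (nrow(features) != 1L) stop("explain_prediction takes exactly one record")
  ctr <- .shap_matrix(clf, features)
  contrib <- ctr[1L, clf$schema]
  base <- ctr[1L, "BIAS"]
  margin <- predict_proba(clf, features, output_margin = TRUE)
  structure(list(
    base_value = unname(base),
    contributions = contrib,
    output_value = margin,
    base_probability = stats::plogis(unname(base)),
    output_probability = stats::plogis(margin),
    values = unlist(features[1L, clf$schema])
  ), class = "attribution_report")
}

#' @method print attribution_report
#' @export
print.attribution_report <- function(x, ...) {
  cat("Prediction explanation (log-odds scale)\n")
  cat(sprintf("  base %.4f -> output %.4f (probability %.4f)\n",
              x$base_value, x$output_value, x$output_probability))
  top <- sort(abs(x$contributions), decreasing = TRUE)
  top <- names(top)[seq_len(min(5L, length(top)))]
  for (nm in top) {
    cat(sprintf("  %-28s %+8.4f (value %g)\n", nm, x$contributions[[nm]],
                x$values[[nm]]))
  }
  invisible(x)
}

#' Global attribute importance
#'
#' Mean absolute Shapley contribution of each attribute over a dataset,
#' ranked descending — the standard global-importance view of a tree
#' ensemble. Deterministic for a fixed model and data; invariant to row
#' order.
#'
#' @param clf a `cnv_classifier`.
#' @param features feature table (>= 1 row) matching the model schema.
#' @return data.frame with columns `attribute`, `mean_abs_contribution`,
#'   sorted descending (ties by schema order).
#' @export
global_importance <- function(clf, features) {
  if (nrow(features) == 0L) stop("importance requires a non-empty dataset")
  ctr <- .shap_matrix(clf, features)
  imp <- colMeans(abs(ctr[, clf$schema, drop = FALSE]))
  ord <- order(-imp, seq_along(imp))
  data.frame(attribute = clf$schema[ord],
             mean_abs_contribution = unname(imp[ord]),
             row.names = NULL)
}

#' Waterfall / force-plot data for one explanation
#'
#' Orders attributes by absolute contribution, keeps the `top_k` largest and
#' collapses the remainder into a single `"(other)"` row so the cumulative
#' trajectory still starts at `base_value` and ends exactly at
#' `output_value`.
#'
#' @param report an [explain_prediction()] result.
#' @param top_k number of individual attributes to keep (>= 1).
#' @return data.frame with columns `attribute`, `value`, `contribution`,
#'   `cumulative`; `cumulative` of the last row equals the output margin.
#' @export
export_waterfall <- function(report, top_k = 10L) {
  stopifnot(inherits(report, "attribution_report"), top_k >= 1L)
  contrib <- report$contributions
  ord <- order(-abs(contrib), seq_along(contrib))
  keep <- ord[seq_len(min(top_k, length(ord)))]
  rest <- setdiff(ord, keep)
  df <- data.frame(
    attribute = names(contrib)[keep],
    value = unname(report$values[names(contrib)[keep]]),
    contribution = unname(contrib[keep])
  )
  if (length(rest) > 0L) {
    df <- rbind(df, data.frame(attribute = "(other)", value = NA_real_,
                               contribution = sum(contrib[rest])))
  }
  df$cumulative <- report$base_value + cumsum(df$contribution)
  df
}
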