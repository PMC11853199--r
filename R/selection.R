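#' Kruskal-Wallis H statistic
#'
#' Ranks the pooled sample (midranks for ties) and computes
#' \deqn{H = \frac{12}{N(N+1)} \sum_{i=1}^{k} \frac{R_i^2}{n_i} - 3(N+1)}
#' where \eqn{N} is the total number of observations, \eqn{n_i} the size of
#' group \eqn{i} and \eqn{R_i} its rank sum. By default no tie-correction
#' divisor is applied, reproducing the plain rank-sum formula; set
#' `tie_correction = TRUE` to divide by
#' \eqn{1 - \sum_t (t^3 - t)/(N^3 - N)} (the form used by
#' [stats::kruskal.test()]).
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @param tie_correction Apply the tie-correction divisor (default `FALSE`).
#' @return The H statistic (non-negative up to rounding).
#' @export
#' @examples
#' kruskal_wallis_h(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))  # 7.2
kruskal_wallis_h <- function(groups, tie_correction = FALSE) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_respscreen("need at least 2 groups",
                    class = "respscreen_contract_error")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) {
    stop_respscreen("every group must be non-empty",
                    class = "respscreen_contract_error")
  }
  pooled <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(pooled))) {
    stop_respscreen("groups contain non-finite values",
                    class = "respscreen_contract_error")
  }
  n_total <- length(pooled)
  r <- rank(pooled)                       # midranks for ties
  idx <- rep(seq_along(groups), sizes)
  rank_sums <- tapply(r, idx, sum)
  h <- 12 / (n_total * (n_total + 1)) * sum(rank_sums^2 / sizes) -
    3 * (n_total + 1)
  if (tie_correction) {
    tie_sizes <- table(pooled)
    correction <- 1 - sum(tie_sizes^3 - tie_sizes) / (n_total^3 - n_total)
    if (correction == 0) {
      stop_respscreen("all pooled values identical: H is undefined under %s",
                      "tie correction", class = "respscreen_contract_error")
    }
    h <- h / correction
  }
  as.numeric(h)
}

#' Upper-tail chi-squared critical value
#'
#' The value exceeded with probability `alpha` by a chi-squared variate with
#' `df` degrees of freedom; features whose H statistic exceeds the critical
#' value at `df = k - 1` are accepted as class-discriminative.
#'
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return Critical value.
#' @export
#' @examples
#' chi2_critical(0.05, 3)  # 7.815
chi2_critical <- function(alpha, df) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_respscreen("alpha must lie in (0, 1)",
                    class = "respscreen_contract_error")
  }
  if (!is.numeric(df) || df < 1) {
    stop_respscreen("df must be >= 1", class = "respscreen_contract_error")
  }
  qchisq(1 - alpha, df = df)
}

feature_columns <- function(table) {
  intersect(feature_names(), names(table))
}

#' Rank features by the Kruskal-Wallis H statistic
#'
#' Computes one H value per feature, with groups given by the class labels,
#' sorts features by H in decreasing order, and flags each feature as
#' accepted when its H exceeds the chi-squared critical value at
#' `k - 1` degrees of freedom and significance `alpha`.
#'
#' @param table Labeled feature table ([extract_features()] output: a
#'   `label` column plus feature columns).
#' @param alpha Significance level (default 0.05).
#' @param tie_correction Passed to [kruskal_wallis_h()].
#' @return A `feature_ranking` data frame with columns `feature`, `H`,
#'   `accepted`, ordered by decreasing H; attributes `alpha`, `df` and
#'   `critical` record the acceptance rule.
#' @export
rank_features <- function(table, alpha = 0.05, tie_correction = FALSE) {
  if (!"label" %in% names(table)) {
    stop_respscreen("feature table must have a 'label' column",
                    class = "respscreen_contract_error")
  }
  labels <- table$label
  classes <- unique(labels)
  if (length(classes) < 2L) {
    stop_respscreen("need observations from at least 2 classes",
                    class = "respscreen_contract_error")
  }
  feats <- feature_columns(table)
  if (length(feats) == 0L) {
    stop_respscreen("no recognized feature columns in table",
                    class = "respscreen_contract_error")
  }
  df <- length(classes) - 1L
  critical <- chi2_critical(alpha, df)
  h <- vapply(feats, function(f) {
    kruskal_wallis_h(split(table[[f]], labels),
                     tie_correction = tie_correction)
  }, numeric(1))
  out <- data.frame(feature = feats, H = as.numeric(h),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$H), , drop = FALSE]
  out$accepted <- out$H > critical
  rownames(out) <- NULL
  structure(out, class = c("feature_ranking", "data.frame"),
            alpha = alpha, df = df, critical = critical)
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> alpha = %g, critical chi2(%d) = %.3f\n",
              attr(x, "alpha"), attr(x, "df"), attr(x, "critical")))
  print.data.frame(x, ...)
  invisible(x)
}

#' The default selected feature set
#'
#' The 10-feature subset that performed best in the incremental evaluation
#' on the reference corpus: entropy, spectral entropy, and the RMS of all
#' wavelet coefficient sets except the detail levels 1, 6 and 7. Used when a
#' caller skips running [incremental_feature_evaluation()] on their own
#' data.
#'
#' @return Character vector of 10 feature names.
#' @export
default_selected_features <- function() {
  c("Entropy", "RMScD9", "Spec.Entropy", "RMScD10", "RMScD3", "RMScD2",
    "RMScD4", "RMScD8", "RMScA", "RMScD5")
}

#' Incremental top-m feature evaluation
#'
#' Trains and evaluates the classifier on the top-1, top-2, ...
#' feature subsets of a ranking, reusing the same train/test split and seed
#' for every subset so the accuracy curve is comparable across subset sizes.
#' The selected subset is the one with the highest test accuracy, ties
#' broken toward fewer features.
#'
#' @param table Labeled feature table.
#' @param ranking A [rank_features()] result (or character vector of feature
#'   names in rank order).
#' @param config A [model_config()].
#' @param test_fraction Held-out fraction for the shared split.
#' @param max_subset Evaluate subsets up to this size (default: all ranked
#'   features).
#' @return A `feature_curve` data frame with columns `m`, `features`
#'   (`+`-joined names), `train_accuracy`, `test_accuracy`; attribute
#'   `selected` holds the chosen feature names.
#' @export
incremental_feature_evaluation <- function(table, ranking,
                                           config = model_config(),
                                           test_fraction = 0.2,
                                           max_subset = NULL) {
  ordered <- if (inherits(ranking, "feature_ranking")) ranking$feature
             else as.character(ranking)
  missing <- setdiff(ordered, names(table))
  if (length(missing) > 0L) {
    stop_respscreen("ranking names features absent from the table: %s",
                    paste(missing, collapse = ", "),
                    class = "respscreen_contract_error")
  }
  max_subset <- max_subset %||% length(ordered)
  split <- split_dataset(table, test_fraction = test_fraction,
                         seed = config$seed)
  rows <- lapply(seq_len(max_subset), function(m) {
    feats <- ordered[seq_len(m)]
    model <- train_classifier(split$train, config, features = feats)
    data.frame(
      m = m, features = paste(feats, collapse = "+"),
      train_accuracy = classification_accuracy(model, split$train),
      test_accuracy = classification_accuracy(model, split$test),
      stringsAsFactors = FALSE)
  })
  curve <- do.call(rbind, rows)
  best <- which.max(curve$test_accuracy)   # first max = smallest subset
  structure(curve, class = c("feature_curve", "data.frame"),
            selected = ordered[seq_len(best)])
}

classification_accuracy <- function(model, table) {
  pred <- predict_classes(model, table)
  mean(pred == table$label)
}
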