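#' Multiclass confusion matrix
#'
#' Counts of (true class, predicted class) pairs; rows are the true classes,
#' columns the predicted classes, both in canonical order.
#'
#' @param truth,predicted Equal-length vectors of labels from
#'   [class_labels()] (or from `classes`).
#' @param classes Class set and order (default [class_labels()]).
#' @return A `confusion_matrix` (integer matrix).
#' @export
confusion_matrix <- function(truth, predicted, classes = class_labels()) {
  if (length(truth) != length(predicted) || length(truth) == 0L) {
    stop_respscreen("truth and predicted must be equal, non-zero length",
                    class = "respscreen_contract_error")
  }
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad) > 0L) {
    stop_respscreen("labels outside the class set: %s",
                    paste(bad, collapse = ", "),
                    class = "respscreen_contract_error")
  }
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- unclass(cm)
  dimnames(cm) <- list(truth = classes, predicted = classes)
  storage.mode(cm) <- "integer"
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' One-vs-rest performance metrics from a confusion matrix
#'
#' For each class the matrix is reduced to binary counts (true positive =
#' the diagonal cell; false negative = rest of the row; false positive =
#' rest of the column; true negative = everything else) and
#' sensitivity \eqn{T_p/(T_p+F_n)}, specificity \eqn{T_n/(T_n+F_p)} and
#' precision \eqn{T_p/(T_p+F_p)} are computed. Overall accuracy is
#' trace/total, and macro metrics are unweighted means over classes. A zero
#' denominator raises an error naming the class and metric rather than
#' silently reporting 0.
#'
#' @param cm A [confusion_matrix()].
#' @return A `metrics_report`: list with `per_class` (data frame of
#'   sensitivity, specificity, precision and the one-vs-rest counts),
#'   `accuracy`, and `macro` (named vector).
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  classes <- rownames(cm)
  per <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    for (metric in c("sensitivity", "specificity", "precision")) {
      den <- switch(metric, sensitivity = tp + fn, specificity = tn + fp,
                    precision = tp + fp)
      if (den == 0) {
        stop_respscreen("%s is undefined for class '%s' (zero denominator)",
                        metric, classes[i],
                        class = "respscreen_undefined_metric_error")
      }
    }
    data.frame(class = classes[i], tp = tp, tn = tn, fp = fp, fn = fn,
               sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
               precision = tp / (tp + fp), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(
    list(per_class = per,
         accuracy = sum(diag(cm)) / total,
         macro = c(sensitivity = mean(per$sensitivity),
                   specificity = mean(per$specificity),
                   precision = mean(per$precision))),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$per_class[, c("class", "sensitivity", "specificity", "precision")],
        row.names = FALSE, digits = 4)
  cat(sprintf("accuracy: %.4f\n", x$accuracy))
  cat(sprintf("macro: sensitivity %.4f, specificity %.4f, precision %.4f\n",
              x$macro["sensitivity"], x$macro["specificity"],
              x$macro["precision"]))
  invisible(x)
}

#' Aggregate class probabilities into a screening report
#'
#' Renders per-measurement class probabilities as percentages rounded to two
#' decimals and appends, per group, the arithmetic mean and the population
#' standard deviation (divisor n, not n-1) of those rounded percentages,
#' also rounded to two decimals - the layout shown on the application's
#' screening page.
#'
#' @param groups Named list; each element is a matrix of class probabilities
#'   (rows = measurements, columns = classes; e.g. [predict_proba()]
#'   output), or a list of probability vectors.
#' @param classes Class order for the report columns.
#' @return A `screening_report` data frame with columns `group`,
#'   `measurement` (measurement number, `"mean"`, or `"sd"`), and one
#'   percentage column per class.
#' @export
screening_report <- function(groups, classes = class_labels()) {
  if (!is.list(groups) || length(groups) == 0L || is.null(names(groups))) {
    stop_respscreen("groups must be a non-empty named list",
                    class = "respscreen_contract_error")
  }
  blocks <- lapply(names(groups), function(g) {
    p <- groups[[g]]
    if (is.list(p) && !is.data.frame(p)) p <- do.call(rbind, p)
    p <- as.matrix(p)
    if (nrow(p) == 0L) {
      stop_respscreen("group '%s' is empty", g,
                      class = "respscreen_contract_error")
    }
    if (!is.null(colnames(p))) p <- p[, classes, drop = FALSE]
    pct <- round(p * 100, 2)
    mean_row <- round(colMeans(pct), 2)
    sd_row <- round(apply(pct, 2, pop_sd), 2)
    block <- rbind(pct, mean_row, sd_row)
    df <- data.frame(group = g,
                     measurement = c(as.character(seq_len(nrow(p))),
                                     "mean", "sd"),
                     stringsAsFactors = FALSE)
    stats_df <- as.data.frame(block, row.names = FALSE)
    names(stats_df) <- classes
    cbind(df, stats_df)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  structure(out, class = c("screening_report", "data.frame"))
}

# population standard deviation (divisor n)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
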