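#' Configuration of the feed-forward classifier
#'
#' One hidden layer of `n_hidden` ReLU units, a 4-way softmax output,
#' categorical cross-entropy loss with an L2 weight penalty, dropout on the
#' hidden layer during training, Adam optimization, and early stopping on a
#' validation split with best-weight restoration. Defaults follow the
#' reference configuration (250 hidden nodes, up to 1000 epochs); the
#' remaining hyperparameters use conventional values.
#'
#' @param n_hidden Hidden-layer width (default 250).
#' @param max_epochs Maximum training epochs (default 1000).
#' @param dropout_rate Hidden-unit dropout probability in \[0, 1).
#' @param l2_penalty L2 weight-penalty coefficient.
#' @param early_stopping_patience Epochs without validation-loss improvement
#'   before stopping.
#' @param validation_fraction Fraction of the training split held out for
#'   early stopping.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling initialization, shuffling, dropout
#'   and the validation split.
#' @return A `model_config` list.
#' @export
model_config <- function(n_hidden = 250L, max_epochs = 1000L,
                         dropout_rate = 0.3, l2_penalty = 1e-4,
                         early_stopping_patience = 50L,
                         validation_fraction = 0.1, batch_size = 32L,
                         learning_rate = 1e-3, seed = 1L) {
  stopifnot(n_hidden >= 1L, max_epochs >= 1L,
            dropout_rate >= 0, dropout_rate < 1,
            l2_penalty >= 0, early_stopping_patience >= 1L,
            validation_fraction > 0, validation_fraction < 1,
            batch_size >= 1L, learning_rate > 0)
  structure(
    list(n_hidden = as.integer(n_hidden), max_epochs = as.integer(max_epochs),
         dropout_rate = dropout_rate, l2_penalty = l2_penalty,
         early_stopping_patience = as.integer(early_stopping_patience),
         validation_fraction = validation_fraction,
         batch_size = as.integer(batch_size), learning_rate = learning_rate,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Stratified train/test split of a feature table
#'
#' Splits rows into disjoint, exhaustive train and test sets, stratified by
#' class, deterministically for a given seed. Per class, the test share is
#' `round(n * test_fraction)`.
#'
#' @param table Labeled feature table.
#' @param test_fraction Fraction assigned to the test split (default 0.2,
#'   the 80:20 convention).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(table, test_fraction = 0.2, seed = 1L) {
  if (!"label" %in% names(table)) {
    stop_respscreen("table must have a 'label' column",
                    class = "respscreen_contract_error")
  }
  counts <- table(table$label)
  if (any(counts < 2L)) {
    stop_respscreen("every class needs >= 2 rows to split (got min %d)",
                    min(counts), class = "respscreen_contract_error")
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(table)), table$label), function(idx) {
      n_test <- max(1L, round(length(idx) * test_fraction))
      idx[sample.int(length(idx), n_test)]
    }), use.names = FALSE)
  })
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

#' Balance classes by random oversampling
#'
#' Resamples minority classes with replacement up to the majority-class
#' count. Intended for the training split only; oversampling (rather than
#' undersampling) avoids discarding scarce disease examples.
#'
#' @param table Labeled feature table.
#' @param seed Integer seed.
#' @return Table with equal per-class counts; already-balanced input is
#'   returned with its row multiset unchanged.
#' @export
balance_classes <- function(table, seed = 1L) {
  if (!"label" %in% names(table) || nrow(table) == 0L) {
    stop_respscreen("table must be non-empty with a 'label' column",
                    class = "respscreen_contract_error")
  }
  counts <- table(table$label)
  target <- max(counts)
  extra <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(table)), table$label), function(idx) {
      deficit <- target - length(idx)
      if (deficit > 0L) {
        idx[sample.int(length(idx), deficit, replace = TRUE)]
      } else integer(0)
    }), use.names = FALSE)
  })
  out <- rbind(table, table[extra, , drop = FALSE])
  rownames(out) <- NULL
  out
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

design_matrix <- function(table, features) {
  missing <- setdiff(features, names(table))
  if (length(missing) > 0L) {
    stop_respscreen("table lacks feature columns: %s",
                    paste(missing, collapse = ", "),
                    class = "respscreen_contract_error")
  }
  x <- as.matrix(table[, features, drop = FALSE])
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) {
    stop_respscreen("features contain non-finite values",
                    class = "respscreen_contract_error")
  }
  x
}

#' Train the feed-forward screening classifier
#'
#' Minimizes categorical cross-entropy plus an L2 weight penalty by Adam on
#' minibatches, with inverted dropout on the hidden layer, a stratified
#' validation split for early stopping, and restoration of the best
#' validation-loss weights. Features are standardized internally using the
#' training means and standard deviations (stored in the model). Fully
#' deterministic for a fixed seed on a fixed platform.
#'
#' @param table Labeled training table (>= 2 classes).
#' @param config A [model_config()].
#' @param features Feature columns to use, in order (default: the canonical
#'   13 present in the table).
#' @param classes Class order for the output layer (default
#'   [class_labels()], restricted to classes present).
#' @return A `trained_model` with weights, feature order, class order,
#'   scaling, per-epoch history and the config snapshot.
#' @export
train_classifier <- function(table, config = model_config(),
                             features = NULL, classes = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (!"label" %in% names(table) || nrow(table) == 0L) {
    stop_respscreen("training table must be non-empty with labels",
                    class = "respscreen_contract_error")
  }
  features <- features %||% feature_columns(table)
  classes <- classes %||% intersect(class_labels(), unique(table$label))
  if (length(classes) < 2L) {
    stop_respscreen("need >= 2 classes to train",
                    class = "respscreen_contract_error")
  }
  x <- design_matrix(table, features)
  y <- match(table$label, classes)
  if (anyNA(y)) {
    stop_respscreen("labels outside the class set: %s",
                    paste(setdiff(unique(table$label), classes),
                          collapse = ", "),
                    class = "respscreen_contract_error")
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

  with_seed(config$seed, {
    fit <- fit_mlp(xs, y, n_classes = length(classes), config = config)
  })
  structure(
    list(w1 = fit$w1, b1 = fit$b1, w2 = fit$w2, b2 = fit$b2,
         features = features, classes = classes,
         center = center, scale = scale_,
         history = fit$history, config = config),
    class = "trained_model"
  )
}

# Core optimizer; expects standardized x and integer labels in 1..n_classes.
# RNG state is managed by the caller.
fit_mlp <- function(x, y, n_classes, config) {
  n <- nrow(x)
  p <- ncol(x)
  h <- config$n_hidden

  # stratified validation split for early stopping
  val_idx <- unlist(lapply(split(seq_len(n), y), function(idx) {
    n_val <- floor(length(idx) * config$validation_fraction)
    if (n_val >= 1L && length(idx) - n_val >= 1L) {
      idx[sample.int(length(idx), n_val)]
    } else integer(0)
  }), use.names = FALSE)
  if (length(val_idx) == 0L) {
    tr_idx <- seq_len(n)
    val_idx <- seq_len(n)      # degenerate fallback: monitor training loss
  } else {
    tr_idx <- setdiff(seq_len(n), val_idx)
  }
  xt <- x[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
  xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx]

  # He-scaled initialization
  w1 <- matrix(rnorm(p * h, sd = sqrt(2 / p)), p, h)
  b1 <- numeric(h)
  w2 <- matrix(rnorm(h * n_classes, sd = sqrt(2 / h)), h, n_classes)
  b2 <- numeric(n_classes)

  params <- list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
  m_t <- lapply(params, function(p_) p_ * 0)
  v_t <- m_t
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L

  onehot <- function(y_, k) {
    m <- matrix(0, length(y_), k)
    m[cbind(seq_along(y_), y_)] <- 1
    m
  }
  eval_loss <- function(pr, x_, y_) {
    hdd <- relu(sweep(x_ %*% pr$w1, 2, pr$b1, `+`))
    prob <- softmax_rows(sweep(hdd %*% pr$w2, 2, pr$b2, `+`))
    ce <- -mean(log(pmax(prob[cbind(seq_along(y_), y_)], 1e-12)))
    acc <- mean(max.col(prob) == y_)
    c(loss = ce + config$l2_penalty * (sum(pr$w1^2) + sum(pr$w2^2)),
      accuracy = acc)
  }

  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- vector("list", config$max_epochs)
  n_tr <- nrow(xt)
  stall <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n_tr)
    starts <- seq(1L, n_tr, by = config$batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n_tr)]
      xb <- xt[idx, , drop = FALSE]
      yb <- yt[idx]
      nb <- length(idx)

      z1 <- sweep(xb %*% params$w1, 2, params$b1, `+`)
      a1 <- relu(z1)
      if (config$dropout_rate > 0) {
        mask <- matrix(runif(nb * h) >= config$dropout_rate, nb, h) /
          (1 - config$dropout_rate)
        a1 <- a1 * mask
      }
      prob <- softmax_rows(sweep(a1 %*% params$w2, 2, params$b2, `+`))
      delta2 <- (prob - onehot(yb, n_classes)) / nb
      g_w2 <- crossprod(a1, delta2) + 2 * config$l2_penalty * params$w2
      g_b2 <- colSums(delta2)
      delta1 <- (delta2 %*% t(params$w2)) * (z1 > 0)
      if (config$dropout_rate > 0) delta1 <- delta1 * mask
      g_w1 <- crossprod(xb, delta1) + 2 * config$l2_penalty * params$w1
      g_b1 <- colSums(delta1)

      grads <- list(w1 = g_w1, b1 = g_b1, w2 = g_w2, b2 = g_b2)
      step <- step + 1L
      for (nm in names(params)) {
        m_t[[nm]] <- beta1 * m_t[[nm]] + (1 - beta1) * grads[[nm]]
        v_t[[nm]] <- beta2 * v_t[[nm]] + (1 - beta2) * grads[[nm]]^2
        m_hat <- m_t[[nm]] / (1 - beta1^step)
        v_hat <- v_t[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] -
          config$learning_rate * m_hat / (sqrt(v_hat) + eps)
      }
    }
    tr_stats <- eval_loss(params, xt, yt)
    val_stats <- eval_loss(params, xv, yv)
    if (!is.finite(tr_stats["loss"])) {
      stop_respscreen("training diverged (non-finite loss) at epoch %d",
                      epoch, class = "respscreen_training_failure")
    }
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = tr_stats["loss"],
      train_accuracy = tr_stats["accuracy"], val_loss = val_stats["loss"],
      val_accuracy = val_stats["accuracy"], row.names = NULL)
    if (val_stats["loss"] < best$loss - 1e-9) {
      best <- list(loss = val_stats["loss"], params = params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$early_stopping_patience) break
    }
  }
  history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  c(best$params, list(history = history))
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %d features -> %d hidden -> %d classes\n",
              length(x$features), x$config$n_hidden, length(x$classes)))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  trained %d epochs (best at %d by validation loss)\n",
              nrow(x$history), which.min(x$history$val_loss)))
  invisible(x)
}

#' Class probabilities for new observations
#'
#' Forward pass of the trained network (no dropout); rows of the result sum
#' to one and the argmax column is the predicted class.
#'
#' @param model A [train_classifier()] result.
#' @param newdata Feature table (data frame containing the model's feature
#'   columns), or a named numeric vector / matrix in the model's feature
#'   order.
#' @return Matrix of probabilities with one row per observation and one
#'   column per class, in the model's class order.
#' @export
predict_proba <- function(model, newdata) {
  stopifnot(inherits(model, "trained_model"))
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    if (length(newdata) != length(model$features)) {
      stop_respscreen("feature vector of width %d; model expects %d",
                      length(newdata), length(model$features),
                      class = "respscreen_contract_error")
    }
    x <- matrix(newdata, nrow = 1,
                dimnames = list(NULL, model$features))
  } else if (is.matrix(newdata)) {
    if (ncol(newdata) != length(model$features)) {
      stop_respscreen("matrix of width %d; model expects %d",
                      ncol(newdata), length(model$features),
                      class = "respscreen_contract_error")
    }
    x <- newdata
  } else {
    x <- design_matrix(newdata, model$features)
  }
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  a1 <- relu(sweep(xs %*% model$w1, 2, model$b1, `+`))
  prob <- softmax_rows(sweep(a1 %*% model$w2, 2, model$b2, `+`))
  colnames(prob) <- model$classes
  prob
}

#' @rdname predict_proba
#' @return `predict_classes()` returns the argmax class label per row.
#' @export
predict_classes <- function(model, newdata) {
  prob <- predict_proba(model, newdata)
  model$classes[max.col(prob, ties.method = "first")]
}

#' Sweep the hidden-layer width
#'
#' Trains one model per candidate hidden-node count on a shared stratified
#' split and seed, reporting train and test accuracy for each. The selected
#' count is, among counts whose test accuracy is within `accuracy_band` of
#' the best, the one with the smallest train-test accuracy gap (ties broken
#' toward fewer nodes) - the "highest accuracy with the smallest
#' overfitting gap" rule.
#'
#' @param table Labeled feature table.
#' @param node_counts Integer vector of hidden-layer widths.
#' @param config Base [model_config()] (its `n_hidden` is overridden).
#' @param features Feature subset to train on.
#' @param test_fraction Held-out fraction for the shared split.
#' @param accuracy_band Width of the top-accuracy band (default 0.01).
#' @return A `node_sweep` data frame with columns `n_hidden`,
#'   `train_accuracy`, `test_accuracy`, `gap`; attribute `selected` holds
#'   the chosen count.
#' @export
hidden_node_sweep <- function(table, node_counts = c(200L, 250L, 300L),
                              config = model_config(), features = NULL,
                              test_fraction = 0.2, accuracy_band = 0.01) {
  if (length(node_counts) == 0L) {
    stop_respscreen("node_counts must be non-empty",
                    class = "respscreen_contract_error")
  }
  split <- split_dataset(table, test_fraction = test_fraction,
                         seed = config$seed)
  rows <- lapply(node_counts, function(nh) {
    cfg <- config
    cfg$n_hidden <- as.integer(nh)
    model <- train_classifier(split$train, cfg, features = features)
    tr <- classification_accuracy(model, split$train)
    te <- classification_accuracy(model, split$test)
    data.frame(n_hidden = as.integer(nh), train_accuracy = tr,
               test_accuracy = te, gap = abs(tr - te))
  })
  sweep_df <- do.call(rbind, rows)
  top <- sweep_df$test_accuracy >= max(sweep_df$test_accuracy) - accuracy_band
  cand <- sweep_df[top, , drop = FALSE]
  cand <- cand[order(cand$gap, cand$n_hidden), , drop = FALSE]
  structure(sweep_df, class = c("node_sweep", "data.frame"),
            selected = cand$n_hidden[1])
}

#' Serialize a trained model to a JSON archive
#'
#' Writes weights, feature order, class order, feature scaling and the
#' config snapshot to a single versioned JSON file that [load_model()]
#' restores exactly.
#'
#' @param model A `trained_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  payload <- list(
    schema = "respscreen-model-1",
    features = model$features, classes = model$classes,
    center = model$center, scale = model$scale,
    w1 = model$w1, b1 = model$b1, w2 = model$w2, b2 = model$b2,
    config = unclass(model$config)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the restored `trained_model`.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "respscreen-model-1")) {
    stop_respscreen("unrecognized model schema: %s", format(p$schema),
                    class = "respscreen_format_error")
  }
  cfg <- do.call(model_config, p$config)
  structure(
    list(w1 = p$w1, b1 = as.numeric(p$b1), w2 = p$w2, b2 = as.numeric(p$b2),
         features = p$features, classes = p$classes,
         center = stats::setNames(as.numeric(p$center), p$features),
         scale = stats::setNames(as.numeric(p$scale), p$features),
         history = NULL, config = cfg),
    class = "trained_model"
  )
}
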