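#' Assemble a decoding dataset
#'
#' One sample per trial: unit activity averaged over a named time window,
#' labeled with a stimulus identity on one dimension.
#'
#' @param x Numeric matrix, trials x units (window-averaged activity).
#' @param labels Vector of class labels, one per trial (>= 2 classes).
#' @param window Character tag naming the averaging window.
#' @param units Which unit subset the columns are: `"feature"`,
#'   `"conjunctive"` or `"all"`.
#' @return A `wm_decode_data` object.
#' @export
decode_dataset <- function(x, labels, window = "delay", units = "feature") {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nrow(x) != length(labels)) {
    stop("one label per sample row is required", call. = FALSE)
  }
  if (nlevels(droplevels(labels)) < 2) {
    stop("decoding needs at least 2 label classes", call. = FALSE)
  }
  structure(list(x = x, labels = droplevels(labels), window = window,
                 units = units),
            class = "wm_decode_data")
}

centroid_fit <- function(x, labels) {
  lv <- levels(labels)
  cen <- vapply(lv, function(l) colMeans(x[labels == l, , drop = FALSE]),
                numeric(ncol(x)))
  t(cen)  # classes x units
}

centroid_predict <- function(centroids, x) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centroids))) -
    2 * x %*% t(centroids) +
    outer(rep(1, nrow(x)), rowSums(centroids^2))
  rownames(centroids)[apply(d2, 1, which.min)]
}

#' Train a linear decoder (nearest class centroid)
#'
#' The canonical decoder is a nearest-centroid linear classifier —
#' deterministic and parameter-free. Accuracy is estimated by stratified
#' k-fold cross-validation; a regularized multinomial-logistic option is
#' available for robustness checks.
#'
#' @param data A [decode_dataset()].
#' @param seed Integer seed for the fold assignment.
#' @param k Number of cross-validation folds.
#' @param method `"centroid"` (default) or `"logistic"` (weight-decay
#'   regularized multinomial logistic fit via [nnet::multinom]), kept as a
#'   robustness check.
#' @return A `wm_decoder`: fitted centroids, per-trial cross-validated
#'   predictions, `cv_accuracy`, `train_accuracy` and `chance`
#'   (1 / number of classes).
#' @export
train_linear_decoder <- function(data, seed = 1L, k = 5L,
                                 method = c("centroid", "logistic")) {
  stopifnot(inherits(data, "wm_decode_data"))
  method <- match.arg(method)
  x <- data$x
  labels <- data$labels
  n <- nrow(x)
  set.seed(seed)
  # stratified fold assignment
  folds <- integer(n)
  for (l in levels(labels)) {
    idx <- which(labels == l)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fit_predict <- function(x_tr, lab_tr, x_te) {
    if (method == "centroid") {
      centroid_predict(centroid_fit(x_tr, droplevels(lab_tr)), x_te)
    } else {
      if (!requireNamespace("nnet", quietly = TRUE)) {
        stop("method = 'logistic' requires the nnet package", call. = FALSE)
      }
      colnames(x_tr) <- colnames(x_te) <- paste0("u", seq_len(ncol(x_tr)))
      df <- data.frame(.y = droplevels(lab_tr), x_tr)
      fit <- nnet::multinom(.y ~ ., data = df, decay = 0.01, trace = FALSE)
      as.character(stats::predict(fit, newdata = data.frame(x_te)))
    }
  }
  pred <- character(n)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    if (nlevels(droplevels(labels[tr])) < 2) next
    pred[!tr] <- fit_predict(x[tr, , drop = FALSE], labels[tr],
                             x[!tr, , drop = FALSE])
  }
  structure(list(
    centroids = centroid_fit(x, labels),
    labels = labels, cv_pred = pred,
    cv_accuracy = mean(pred == as.character(labels)),
    train_accuracy = mean(fit_predict(x, labels, x) == as.character(labels)),
    chance = 1 / nlevels(labels),
    window = data$window, units = data$units, method = method
  ), class = "wm_decoder")
}

#' @export
print.wm_decoder <- function(x, ...) {
  cat(sprintf(
    "<wm_decoder> %d classes, CV accuracy %.3f (chance %.3f), window '%s'\n",
    nrow(x$centroids), x$cv_accuracy, x$chance, x$window))
  invisible(x)
}

#' @export
tidy.wm_decoder <- function(x, ...) {
  ci <- boot_ci(x$cv_pred == as.character(x$labels))
  tibble::tibble(window = x$window, units = x$units,
                 accuracy = x$cv_accuracy,
                 ci_lo = ci[1], ci_hi = ci[2], chance = x$chance,
                 n = length(x$labels))
}

#' @export
glance.wm_decoder <- function(x, ...) {
  tibble::tibble(n = length(x$labels), n_classes = nrow(x$centroids),
                 cv_accuracy = x$cv_accuracy,
                 train_accuracy = x$train_accuracy, chance = x$chance)
}

#' Cross-decoding between conditions
#'
#' Trains the decoder on one condition (e.g. trials where the item was
#' attended) and evaluates it on another (the same item unattended).
#' Below-chance outcomes are valid results — they are the model's
#' representational-inversion signature, caused by competitive inhibition
#' of the unattended pattern. Significance against chance is assessed with
#' a label-shuffle null: the training labels are permuted `n_shuffle`
#' times, the decoder refit, and the observed cross accuracy compared to
#' the null quantiles.
#'
#' @param train,test [decode_dataset()]s over the same label space and
#'   unit subset.
#' @param n_shuffle Number of label shuffles for the null distribution.
#' @param seed Integer seed.
#' @return A `wm_cross_decode` report: `accuracy`, `chance`, null band
#'   (`null_lo`, `null_hi` = 2.5/97.5 percentiles), and the training-set
#'   CV accuracy.
#' @export
cross_decode <- function(train, test, n_shuffle = 1000L, seed = 1L) {
  stopifnot(inherits(train, "wm_decode_data"),
            inherits(test, "wm_decode_data"))
  if (!identical(levels(train$labels), levels(test$labels))) {
    stop("train and test label spaces differ", call. = FALSE)
  }
  if (ncol(train$x) != ncol(test$x)) {
    stop("train and test unit subsets differ", call. = FALSE)
  }
  fit <- centroid_fit(train$x, train$labels)
  acc <- mean(centroid_predict(fit, test$x) == as.character(test$labels))
  set.seed(seed)
  null_acc <- vapply(seq_len(n_shuffle), function(i) {
    lab <- sample(train$labels)
    f <- centroid_fit(train$x, lab)
    mean(centroid_predict(f, test$x) == as.character(test$labels))
  }, 0)
  dec <- train_linear_decoder(train, seed = seed)
  structure(list(
    accuracy = acc, chance = 1 / nlevels(train$labels),
    null_lo = unname(quantile(null_acc, 0.025)),
    null_hi = unname(quantile(null_acc, 0.975)),
    null_accuracy = null_acc,
    within_cv_accuracy = dec$cv_accuracy,
    train_window = train$window, test_window = test$window
  ), class = "wm_cross_decode")
}

#' @export
print.wm_cross_decode <- function(x, ...) {
  cat(sprintf(
    "<wm_cross_decode> accuracy %.3f (chance %.3f, null band [%.3f, %.3f])\n",
    x$accuracy, x$chance, x$null_lo, x$null_hi))
  invisible(x)
}

#' @export
tidy.wm_cross_decode <- function(x, ...) {
  tibble::tibble(train_window = x$train_window, test_window = x$test_window,
                 accuracy = x$accuracy, chance = x$chance,
                 null_lo = x$null_lo, null_hi = x$null_hi,
                 within_cv_accuracy = x$within_cv_accuracy)
}

#' Pattern similarity between two activity vectors
#'
#' Pearson correlation of window-averaged activity vectors (the trial-lag
#' similarity measure applied to conjunctive delay patterns). Undefined
#' (returned as `NA`) when either vector has zero variance.
#'
#' @param a,b Equal-length numeric vectors.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
pattern_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Sliding-window decoding time course
#'
#' Applies the linear decoder independently in each time window of a set
#' of trial traces.
#'
#' @param traces List of `wm_trace` matrices (one per trial, equal
#'   durations).
#' @param labels Per-trial class labels.
#' @param windows Named list of step ranges (each `c(from, to)`, trial-
#'   relative).
#' @param units `"feature"`, `"conjunctive"` or `"all"`.
#' @param params A [wm_params()] object (for the unit layout).
#' @param seed Integer seed for fold assignment.
#' @return A `wm_decoder_report` tibble: one row per window with CV
#'   accuracy, bootstrap CI and chance.
#' @export
decode_timecourse <- function(traces, labels, windows, units = "feature",
                              params, seed = 1L) {
  n_f <- n_features(params)
  cols <- switch(units,
                 feature = seq_len(n_f),
                 conjunctive = n_f + seq_len(params$n_conj),
                 all = seq_len(n_f + params$n_conj),
                 stop("unknown unit subset: ", units, call. = FALSE))
  rows <- lapply(names(windows), function(wn) {
    w <- windows[[wn]]
    x <- t(vapply(traces, function(tr) {
      colMeans(unclass(tr)[w[1]:w[2], cols, drop = FALSE])
    }, numeric(length(cols))))
    dec <- train_linear_decoder(decode_dataset(x, labels, wn, units),
                                seed = seed)
    tidy(dec)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("wm_decoder_report", class(out))
  out
}

#' @export
autoplot.wm_decoder_report <- function(object, ...) {
  object$window <- factor(object$window, levels = unique(object$window))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$window, y = .data$accuracy)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$chance),
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::labs(x = "time window", y = "decoding accuracy") +
    ggplot2::theme_minimal()
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param x Numeric (or logical) vector.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @return Length-2 numeric vector (lower, upper).
#' @export
boot_ci <- function(x, n_boot = 2000L, level = 0.95) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  if (length(x) == 0) return(c(NA_real_, NA_real_))
  means <- vapply(seq_len(n_boot),
                  function(i) mean(x[sample.int(length(x),
                                                replace = TRUE)]), 0)
  a <- (1 - level) / 2
  unname(quantile(means, c(a, 1 - a)))
}

#' Bootstrap confidence interval for a difference of means
#'
#' Two-sample percentile bootstrap for `mean(x) - mean(y)`; the package's
#' standard direction test (a direction holds at the 95% level when the
#' interval excludes zero).
#'
#' @param x,y Numeric (or logical) vectors.
#' @inheritParams boot_ci
#' @return Length-2 numeric vector (lower, upper) for `mean(x) - mean(y)`.
#' @export
boot_diff_ci <- function(x, y, n_boot = 2000L, level = 0.95) {
  x <- as.numeric(x)[!is.na(x)]
  y <- as.numeric(y)[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) return(c(NA_real_, NA_real_))
  d <- vapply(seq_len(n_boot), function(i) {
    mean(x[sample.int(length(x), replace = TRUE)]) -
      mean(y[sample.int(length(y), replace = TRUE)])
  }, 0)
  a <- (1 - level) / 2
  unname(quantile(d, c(a, 1 - a)))
}
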