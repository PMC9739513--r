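# ROC analysis, Youden-index cutoff, LOOCV evaluation and external
# validation of the invasiveness model.

new_eval <- function(accuracy, sensitivity, specificity, auc, roc_points,
                     youden_J, cutoff, n, n_invasive, extra = list()) {
  structure(c(list(
    accuracy = accuracy, sensitivity = sensitivity, specificity = specificity,
    auc = auc, roc_points = roc_points, youden_J = youden_J, cutoff = cutoff,
    n = n, n_invasive = n_invasive), extra), class = "ggn_eval")
}

confusion_at <- function(scores, y, cutoff) {
  pred <- scores >= cutoff
  tp <- sum(pred & y == 1); fn <- sum(!pred & y == 1)
  tn <- sum(!pred & y == 0); fp <- sum(pred & y == 0)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(y))
}

roc_curve_points <- function(scores, y) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  # one ROC point per unique score (ties move diagonally in one step)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(yy)[last_of_tie]
  fp <- cumsum(1 - yy)[last_of_tie]
  P <- sum(y); N <- sum(1 - y)
  tibble::tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp / N),
    tpr = c(0, tp / P)
  )
}

#' ROC analysis with Youden-index cutoff
#'
#' Builds the empirical ROC curve by sweeping every observed score as a
#' threshold (predict invasive when `score >= threshold`), computes the AUC
#' by the trapezoidal rule — equivalent to pairwise concordance with ties
#' counted one half — and picks the cutoff maximizing the Youden index
#' `J = sensitivity + specificity - 1` (ties resolve to the highest such
#' threshold). Accuracy, sensitivity and specificity are reported at that
#' cutoff.
#'
#' @param probabilities numeric scores (higher = more invasive).
#' @param labels `AIS_MIA`/`INVASIVE` or 0/1, same length.
#' @return A `ggn_eval` with metrics, `roc_points`, `youden_J` and `cutoff`.
#'   See [generics::tidy()], [generics::glance()], [ggplot2::autoplot()].
#' @export
roc_youden <- function(probabilities, labels) {
  y <- canonical_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  stopifnot(length(probabilities) == length(y))
  pts <- roc_curve_points(probabilities, y)
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  j <- pts$tpr - pts$fpr
  best <- which.max(j[-1]) + 1L            # skip the (0,0) sentinel
  cutoff <- pts$threshold[best]
  cm <- confusion_at(probabilities, y, cutoff)
  new_eval(cm$accuracy, cm$sensitivity, cm$specificity, auc, pts,
           youden_J = j[best], cutoff = cutoff,
           n = length(y), n_invasive = sum(y))
}

# EvalResult at a frozen cutoff (external validation): ROC/AUC from the
# scores, classification metrics at the supplied cutoff
eval_at_cutoff <- function(probabilities, labels, cutoff) {
  y <- canonical_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  pts <- roc_curve_points(probabilities, y)
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  cm <- confusion_at(probabilities, y, cutoff)
  new_eval(cm$accuracy, cm$sensitivity, cm$specificity, auc, pts,
           youden_J = cm$sensitivity + cm$specificity - 1, cutoff = cutoff,
           n = length(y), n_invasive = sum(y))
}

#' @export
print.ggn_eval <- function(x, ...) {
  cat(sprintf(
    "<ggn_eval> n = %d (%d invasive)\n  AUC %.4f | accuracy %.3f | sensitivity %.3f | specificity %.3f\n  Youden J %.3f at cutoff %.4f\n",
    x$n, x$n_invasive, x$auc, x$accuracy, x$sensitivity, x$specificity,
    x$youden_J, x$cutoff))
  invisible(x)
}

#' Leave-one-out cross-validation of the invasiveness pipeline
#'
#' For each fold, z-score normalization is refitted and the logistic model
#' retrained on the remaining `n - 1` patients, and the held-out patient's
#' probability predicted with the fold's parameters. Metrics (ROC, AUC,
#' Youden cutoff) come from the pooled out-of-fold probabilities, so the
#' result is invariant to row order. Feature selection is by default
#' performed once on the full cohort (the published procedure, optimistic for
#' the selection step); `nested = TRUE` wraps selection inside every fold,
#' the unbiased alternative.
#'
#' @param data raw (unnormalized) feature table with a label column.
#' @param features predictor names; `NULL` runs [sfs_select()].
#' @param label_col label column name.
#' @param nested run selection inside each fold?
#' @param max_features cap for the selection step.
#' @return A `ggn_eval` with extra fields `oof` (tibble of out-of-fold
#'   probabilities), `selected_features`, `nested`, and `flagged_folds`.
#' @export
loocv_evaluate <- function(data, features = NULL, label_col = "label",
                           nested = FALSE, max_features = 10L) {
  y <- canonical_labels(data[[label_col]])
  n <- length(y)
  if (n < 4L || length(unique(y)) < 2L)
    stop("LOOCV needs n >= 4 with both classes present")
  if (!nested && is.null(features)) {
    zs_all <- zscore_fit_apply(data, label_col = label_col)
    features <- sfs_select(zs_all, label_col = label_col,
                           max_features = max_features)
  }
  probs <- numeric(n)
  flagged_folds <- integer(0)
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    if (length(unique(canonical_labels(train[[label_col]]))) < 2L) {
      flagged_folds <- c(flagged_folds, i)
      probs[i] <- mean(canonical_labels(train[[label_col]]))
      next
    }
    zfit <- suppressWarnings(zscore_fit(train, label_col))
    ztrain <- zscore_apply(zfit, train, label_col)
    feats_i <- if (nested) {
      sfs_select(ztrain, label_col = label_col, max_features = max_features)
    } else features
    # folds may hold a single member of a class; fit without the cohort-level
    # class-count guard
    fit <- logit_fit_matrix(as.matrix(ztrain[feats_i]),
                            canonical_labels(ztrain[[label_col]]))
    ztest <- zscore_apply(zfit, data[i, , drop = FALSE], label_col)
    eta <- fit$coefficients[1] +
      sum(as.numeric(ztest[1, feats_i]) * fit$coefficients[-1])
    probs[i] <- 1 / (1 + exp(-eta))
  }
  ev <- roc_youden(probs, y)
  ev$oof <- tibble::tibble(row = seq_len(n), probability = probs, label = y)
  ev$selected_features <- if (nested) NULL else features
  ev$nested <- nested
  ev$flagged_folds <- flagged_folds
  ev
}

#' Train the invasiveness model on a full cohort
#'
#' The end-to-end statistical recipe: z-score normalization fitted on the
#' cohort, sequential forward selection (unless `features` is given), a
#' logistic fit on the selected set, and a decision cutoff set by maximizing
#' the Youden index over LOOCV out-of-fold probabilities.
#'
#' @param data raw feature table with a label column.
#' @param features predictor names; `NULL` selects via [sfs_select()].
#' @param label_col label column name.
#' @param max_features cap for the selection step.
#' @return A list with `model` (a `ggn_model` carrying the frozen
#'   normalization and cutoff) and `loocv` (the `ggn_eval` used to set the
#'   cutoff).
#' @export
train_invasiveness_model <- function(data, features = NULL,
                                     label_col = "label", max_features = 10L) {
  zfit <- zscore_fit(data, label_col)
  zdata <- zscore_apply(zfit, data, label_col)
  if (is.null(features))
    features <- sfs_select(zdata, label_col = label_col,
                           max_features = max_features)
  ev <- loocv_evaluate(data, features = features, label_col = label_col)
  model <- fit_logistic(zdata, features, label_col, cutoff = ev$cutoff)
  model$normalization <- zfit
  list(model = model, loocv = ev)
}

#' Validate a frozen model on an external cohort
#'
#' Applies the trained model unchanged — training normalization parameters,
#' coefficients and decision cutoff — to an external feature table and
#' reports its performance there.
#'
#' @param model a `ggn_model` from [train_invasiveness_model()] (must carry
#'   normalization), or any `ggn_model` if `data` is already normalized.
#' @param data external raw feature table with a label column.
#' @param label_col label column name.
#' @return A `ggn_eval` at the frozen cutoff.
#' @export
external_validate <- function(model, data, label_col = "label") {
  stopifnot(inherits(model, "ggn_model"))
  missing <- setdiff(model$selected_features, names(data))
  if (length(missing))
    stop("external cohort lacks selected features: ",
         paste(missing, collapse = ", "))
  zdata <- if (!is.null(model$normalization)) {
    zscore_apply(model$normalization, data, label_col)
  } else data
  probs <- predict(model, zdata)
  eval_at_cutoff(probs, data[[label_col]], model$cutoff)
}
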