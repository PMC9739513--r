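# The statistical core: per-feature t-test screening, z-score normalization,
# sequential forward selection, logistic classification, LOOCV, ROC/AUC with
# Youden-index cutoff, and frozen application to an external cohort.
#
# Feature data is tabular throughout: a data frame with one row per patient,
# a label column (AIS_MIA / INVASIVE, or 0/1) and numeric feature columns.

canonical_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("AIS_MIA", "INVASIVE"))
    if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
    return(as.integer(labels == "INVASIVE"))
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be AIS_MIA/INVASIVE or 0/1")
  as.integer(labels)
}

feature_columns <- function(data, label_col = "label") {
  stopifnot(label_col %in% names(data))
  setdiff(names(data)[vapply(data, is.numeric, logical(1))], label_col)
}

#' Screen features with two-tailed two-sample t-tests
#'
#' Pooled-variance (Student) two-sample t-test of every numeric feature
#' between the invasive and AIS/MIA groups, as a univariate screen. Raw
#' two-sided p-values are reported without multiplicity correction; the
#' screen is descriptive and is not used to pre-filter the selection step
#' unless the caller chooses to.
#'
#' @param data data frame: numeric feature columns plus a label column.
#' @param label_col name of the label column (default `"label"`).
#' @param alpha significance flag threshold (default 0.05).
#' @return A tibble with one row per feature: group means, `statistic`
#'   (t, invasive minus AIS/MIA orientation), `df`, `p_value`, `significant`,
#'   and `degenerate` (zero pooled variance).
#' @export
ttest_screen <- function(data, label_col = "label", alpha = 0.05) {
  y <- canonical_labels(data[[label_col]])
  if (sum(y == 0) < 2 || sum(y == 1) < 2)
    stop("need at least two samples per class")
  feats <- feature_columns(data, label_col)
  purrr::map_dfr(feats, function(f) {
    x0 <- data[[f]][y == 0]; x1 <- data[[f]][y == 1]
    pooled_var <- (sum((x0 - mean(x0))^2) + sum((x1 - mean(x1))^2)) /
      (length(x0) + length(x1) - 2)
    if (pooled_var <= 0) {
      return(tibble::tibble(
        feature = f, mean_ais_mia = mean(x0), mean_invasive = mean(x1),
        statistic = 0, df = length(x0) + length(x1) - 2, p_value = 1,
        significant = FALSE, degenerate = TRUE))
    }
    tt <- stats::t.test(x1, x0, var.equal = TRUE)
    tibble::tibble(
      feature = f, mean_ais_mia = mean(x0), mean_invasive = mean(x1),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, significant = tt$p.value < alpha,
      degenerate = FALSE)
  })
}

#' Fit and apply z-score normalization
#'
#' `zscore_fit()` learns per-feature mean and sample (n-1) standard
#' deviation on the training rows; `zscore_apply()` transforms any table with
#' the *training* parameters only, never refitting. Constant training
#' columns are dropped with a warning.
#'
#' @param data,train data frames with numeric feature columns (a label
#'   column, if present, passes through untouched).
#' @param label_col label column name.
#' @return `zscore_fit()`: a `ggn_zscore` with `center`, `scale`, `features`;
#'   `zscore_apply()` / `zscore_fit_apply()`: the transformed tibble.
#' @export
zscore_fit <- function(train, label_col = "label") {
  feats <- if (label_col %in% names(train)) {
    feature_columns(train, label_col)
  } else {
    names(train)[vapply(train, is.numeric, logical(1))]
  }
  center <- vapply(train[feats], mean, numeric(1))
  scale <- vapply(train[feats], stats::sd, numeric(1))
  keep <- is.finite(scale) & scale > 0
  if (any(!keep))
    warning("dropping constant feature(s): ",
            paste(feats[!keep], collapse = ", "))
  structure(list(center = center[keep], scale = scale[keep],
                 features = feats[keep]),
            class = "ggn_zscore")
}

#' @rdname zscore_fit
#' @param fit a `ggn_zscore` from [zscore_fit()].
#' @export
zscore_apply <- function(fit, data, label_col = "label") {
  stopifnot(inherits(fit, "ggn_zscore"))
  missing <- setdiff(fit$features, names(data))
  if (length(missing))
    stop("data lacks normalized features: ", paste(missing, collapse = ", "))
  out <- data
  for (f in fit$features)
    out[[f]] <- (data[[f]] - fit$center[[f]]) / fit$scale[[f]]
  dropped <- setdiff(feature_columns(data, label_col), fit$features)
  out <- out[, !(names(out) %in% dropped), drop = FALSE]
  tibble::as_tibble(out)
}

#' @rdname zscore_fit
#' @param apply_to data frame transformed with the parameters fitted on
#'   `train`.
#' @export
zscore_fit_apply <- function(train, apply_to = train, label_col = "label") {
  zscore_apply(zscore_fit(train, label_col), apply_to, label_col)
}

# ---- logistic regression -------------------------------------------------

# unregularized ML fit via glm.fit; ridge-IRLS fallback (epsilon penalty) on
# separation or non-convergence, always flagged
logit_fit_matrix <- function(X, y, ridge = 1e-4) {
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial()))
  eta <- drop(Xd %*% fit$coefficients)
  separated <- all((y == 1) == (eta > 0)) && min(abs(eta)) > 8
  flagged <- !fit$converged || separated || any(!is.finite(fit$coefficients)) ||
    any(abs(fit$coefficients) > 1e3)
  if (flagged) {
    beta <- rep(0, ncol(Xd))
    for (it in 1:50) {
      eta <- drop(Xd %*% beta)
      p <- 1 / (1 + exp(-eta))
      w <- pmax(p * (1 - p), 1e-8)
      pen <- diag(ridge, ncol(Xd)); pen[1, 1] <- 0
      H <- crossprod(Xd, Xd * w) + pen
      g <- crossprod(Xd, y - p) - pen %*% beta
      step <- solve(H, g)
      beta <- beta + step
      if (max(abs(step)) < 1e-8) break
    }
    coefs <- drop(beta)
    names(coefs) <- colnames(Xd)
  } else {
    coefs <- fit$coefficients
  }
  list(coefficients = coefs, flagged = flagged, separated = separated)
}

#' Fit the logistic invasiveness model
#'
#' Maximum-likelihood logistic regression of invasiveness on the selected
#' (z-scored) features. On separation or non-convergence a lightly
#' ridge-penalized IRLS fit is substituted and flagged — never silently.
#'
#' @param data normalized feature table with a label column.
#' @param features character vector of predictor columns, in order.
#' @param label_col label column name.
#' @param cutoff decision threshold on the predicted probability stored in
#'   the model (default 0.5; [loocv_evaluate()] replaces it with the
#'   Youden-optimal value).
#' @return A `ggn_model`: selected features, coefficients, intercept,
#'   normalization parameters (if the data carries them via attribute),
#'   cutoff, and fit flags. Supports [predict()][predict.ggn_model],
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_logistic <- function(data, features, label_col = "label", cutoff = 0.5) {
  y <- canonical_labels(data[[label_col]])
  if (sum(y == 0) < 2 || sum(y == 1) < 2)
    stop("need at least two samples per class")
  missing <- setdiff(features, names(data))
  if (length(missing)) stop("missing features: ", paste(missing, collapse = ", "))
  X <- as.matrix(data[features])
  fit <- logit_fit_matrix(X, y)
  structure(list(
    selected_features = features,
    coefficients = fit$coefficients[-1],
    intercept = unname(fit$coefficients[1]),
    cutoff = cutoff,
    flagged = fit$flagged, separated = fit$separated,
    n = length(y), n_invasive = sum(y)
  ), class = "ggn_model")
}

#' @export
print.ggn_model <- function(x, ...) {
  cat(sprintf("<ggn_model> logistic, %d feature(s), cutoff %.3f%s\n",
              length(x$selected_features), x$cutoff,
              if (x$flagged) " [ridge fallback]" else ""))
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' Predict invasiveness probabilities
#'
#' @param object a `ggn_model`.
#' @param newdata feature table containing the selected features (already on
#'   the model's normalized scale).
#' @param type `"prob"` (default) or `"class"` (thresholded at the model
#'   cutoff, returning `"AIS_MIA"`/`"INVASIVE"`).
#' @param ... unused.
#' @export
predict.ggn_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$selected_features, names(newdata))
  if (length(missing))
    stop("newdata lacks selected features: ", paste(missing, collapse = ", "))
  eta <- object$intercept +
    drop(as.matrix(newdata[object$selected_features]) %*% object$coefficients)
  p <- 1 / (1 + exp(-eta))
  if (type == "prob") p else ifelse(p >= object$cutoff, "INVASIVE", "AIS_MIA")
}

# LOOCV accuracy of a candidate feature set at a 0.5 probability threshold:
# the internal criterion of the forward selection
loocv_accuracy <- function(X, y, ridge_only = FALSE) {
  n <- length(y)
  correct <- 0L
  for (i in seq_len(n)) {
    fit <- logit_fit_matrix(X[-i, , drop = FALSE], y[-i])
    eta <- fit$coefficients[1] +
      sum(X[i, ] * fit$coefficients[-1])
    correct <- correct + as.integer((eta > 0) == (y[i] == 1))
  }
  correct / n
}

#' Sequential forward feature selection
#'
#' Greedy forward selection: at each step the candidate feature whose
#' addition maximizes the criterion — by default the LOOCV accuracy of the
#' logistic model on the candidate set — joins the model; selection stops
#' when no candidate improves the criterion or `max_features` is reached.
#' Ties break toward the earlier column, making the procedure fully
#' deterministic.
#'
#' @param data normalized feature table with a label column.
#' @param label_col label column name.
#' @param max_features cap on the number of selected features.
#' @param criterion function `(X, y) -> numeric` scoring a candidate design
#'   matrix; default [loocv_accuracy()].
#' @return Character vector of selected feature names, in selection order,
#'   with a `trace` attribute (tibble of step, feature, criterion value).
#' @export
sfs_select <- function(data, label_col = "label", max_features = 10L,
                       criterion = loocv_accuracy) {
  y <- canonical_labels(data[[label_col]])
  feats <- feature_columns(data, label_col)
  if (!length(feats)) stop("no candidate features")
  X <- as.matrix(data[feats])
  selected <- integer(0)
  best_val <- -Inf
  trace <- list()
  repeat {
    remaining <- setdiff(seq_along(feats), selected)
    if (!length(remaining) || length(selected) >= max_features) break
    vals <- vapply(remaining, function(j) {
      criterion(X[, c(selected, j), drop = FALSE], y)
    }, numeric(1))
    j_best <- remaining[which.max(vals)]      # which.max: earliest tie wins
    v_best <- max(vals)
    if (v_best <= best_val) break             # no improvement: stop
    selected <- c(selected, j_best)
    best_val <- v_best
    trace[[length(trace) + 1L]] <-
      tibble::tibble(step = length(selected), feature = feats[j_best],
                     criterion = v_best)
  }
  out <- feats[selected]
  attr(out, "trace") <- dplyr::bind_rows(trace)
  out
}
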