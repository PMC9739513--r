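# ROC construction, Youden cutoff, LOOCV evaluation, external validation.

test_that("separable scores give a perfect ROC", {
  ev <- roc_youden(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(ev$auc, 1)
  expect_equal(ev$youden_J, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_error(roc_youden(c(0.2, 0.4), c(1, 1)), "both classes")
})

test_that("metrics at a cutoff follow confusion arithmetic", {
  # TP=3, FN=1, TN=7, FP=3 at cutoff 0.5
  scores <- c(rep(0.6, 3), 0.4, rep(0.3, 7), rep(0.7, 3))
  labels <- c(rep(1, 3), 1, rep(0, 7), rep(0, 3))
  ev <- ggnrad:::eval_at_cutoff(scores, labels, 0.5)
  expect_equal(ev$sensitivity, 0.75)
  expect_equal(ev$specificity, 0.70)
  expect_equal(ev$accuracy, 10 / 14)
})

test_that("trapezoidal AUC equals pairwise concordance with ties", {
  set.seed(2)
  for (r in 1:5) {
    s <- sample(seq(0, 1, 0.05), 200, replace = TRUE)
    y <- rbinom(200, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_youden(s, y)$auc, oracle_auc_concordance(s, y),
                 tolerance = 1e-12)
  }
})

test_that("the Youden cutoff equals a brute-force threshold sweep", {
  set.seed(3)
  s <- round(runif(80), 2)
  y <- rbinom(80, 1, 0.3)
  ev <- roc_youden(s, y)
  cands <- sort(unique(s))
  js <- vapply(cands, function(t) {
    cm <- ggnrad:::confusion_at(s, y, t)
    cm$sensitivity + cm$specificity - 1
  }, numeric(1))
  expect_equal(ev$youden_J, max(js), tolerance = 1e-12)
  cm <- ggnrad:::confusion_at(s, y, ev$cutoff)
  expect_equal(cm$sensitivity + cm$specificity - 1, max(js), tolerance = 1e-12)
})

test_that("ROC endpoints and AUC bounds hold; negation flips the AUC", {
  set.seed(4)
  s <- rnorm(60); y <- rbinom(60, 1, 0.5)
  ev <- roc_youden(s, y)
  pts <- generics::tidy(ev)
  expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
  expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  expect_gte(ev$auc, 0); expect_lte(ev$auc, 1)
  expect_equal(roc_youden(-s, y)$auc, 1 - ev$auc, tolerance = 1e-12)
})

test_that("LOOCV is exhaustive, order-invariant and perfect on separable data", {
  df <- tibble::tibble(label = rep(0:1, each = 5), f = c(1:5, 26:30))
  ev <- loocv_evaluate(df, features = "f")
  expect_equal(ev$auc, 1)
  expect_equal(ev$accuracy, 1)
  expect_identical(nrow(ev$oof), nrow(df))
  # permuting rows leaves the pooled metrics unchanged
  set.seed(9)
  n <- 24
  df2 <- tibble::tibble(label = rep(0:1, each = 12),
                        a = rnorm(n) + rep(0:1, each = 12),
                        b = rnorm(n))
  e1 <- loocv_evaluate(df2, features = c("a", "b"))
  perm <- sample(n)
  e2 <- loocv_evaluate(df2[perm, ], features = c("a", "b"))
  expect_equal(e1$auc, e2$auc, tolerance = 1e-12)
  expect_equal(sort(e1$oof$probability), sort(e2$oof$probability),
               tolerance = 1e-12)
})

test_that("pure-noise LOOCV AUC centres below chance by the stratification bias", {
  # With pooled out-of-fold probabilities and per-fold refits, the held-out
  # sample is always the minority of its own training fold, so the fold
  # prior anti-ranks it: the null distribution of the LOOCV AUC centres
  # below 0.5 (clearly so, but far from degenerate). The same protocol in
  # scikit-learn reproduces the effect.
  set.seed(77)
  aucs <- vapply(1:50, function(r) {
    df <- tibble::tibble(label = sample(rep(0:1, c(25, 15))),
                         a = rnorm(40), b = rnorm(40), c = rnorm(40))
    loocv_evaluate(df, features = c("a", "b", "c"))$auc
  }, numeric(1))
  expect_lt(mean(aucs), 0.5)
  expect_gt(mean(aucs), 0.3)
})

test_that("external validation freezes the trained model", {
  set.seed(12)
  n <- 40
  df <- tibble::tibble(label = rep(0:1, each = 20),
                       a = rnorm(n) + rep(0:1, each = 20) * 1.5,
                       b = rnorm(n))
  tr <- train_invasiveness_model(df, features = c("a", "b"))
  # identical external cohort: same metrics at the same cutoff
  self <- external_validate(tr$model, df)
  ztr <- zscore_apply(tr$model$normalization, df)
  probs <- predict(tr$model, ztr)
  ref <- ggnrad:::eval_at_cutoff(probs, df$label, tr$model$cutoff)
  expect_equal(generics::glance(self), generics::glance(ref))
  # flipped labels: AUC anti-symmetry
  flipped <- df; flipped$label <- 1 - df$label
  expect_equal(external_validate(tr$model, flipped)$auc, 1 - self$auc,
               tolerance = 1e-12)
  # missing feature errors
  expect_error(external_validate(tr$model, df[, c("label", "a")]), "lacks")
})

test_that("internal and external performance agree under exchangeability", {
  set.seed(13)
  gen <- function(n) {
    y <- rep(0:1, c(round(n * 0.6), n - round(n * 0.6)))
    tibble::tibble(label = y,
                   a = rnorm(n) + y * 1.2, b = rnorm(n) + y * 0.8,
                   c = rnorm(n))
  }
  gaps <- vapply(1:8, function(r) {
    tr <- train_invasiveness_model(gen(60), features = c("a", "b", "c"))
    ext <- external_validate(tr$model, gen(60))
    abs(ext$auc - tr$loocv$auc)
  }, numeric(1))
  expect_lt(median(gaps), 0.1)
})

test_that("a fold that loses a class falls back to the prior and is flagged", {
  df <- tibble::tibble(label = c(1, 0, 0, 0, 0), f = c(5, 1, 2, 1.5, 1.2))
  ev <- loocv_evaluate(df, features = "f")
  expect_identical(ev$flagged_folds, 1L)
  expect_equal(ev$oof$probability[1], 0)  # prior of an all-negative fold
})
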