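#' Simulate a tabular radiomic feature cohort
#'
#' Draws a feature matrix directly on the normalized scale, bypassing image
#' synthesis: every feature is standard normal, and the first
#' `n_informative` features carry an additive standardized mean difference of
#' `effect_size` in the invasive class. This is the test bed for the
#' statistical core under a controlled signal, including cohorts mimicking
#' the thin-slice class balance (90 vs 12).
#'
#' @param n cohort size.
#' @param n_invasive number of invasive rows (placed first).
#' @param n_features total feature columns (`F1` ... `Fn`).
#' @param n_informative leading features carrying the class signal.
#' @param effect_size standardized mean difference of informative features.
#' @param seed RNG seed.
#' @return A tibble with `label` (0/1) and `n_features` numeric columns.
#' @export
simulate_feature_cohort <- function(n = 102L, n_invasive = 12L,
                                    n_features = 50L, n_informative = 3L,
                                    effect_size = 1.0, seed = 1L) {
  stopifnot(n_invasive > 0, n_invasive < n, n_informative <= n_features)
  with_seed(seed, {
    y <- rep(c(1L, 0L), c(n_invasive, n - n_invasive))
    X <- matrix(stats::rnorm(n * n_features), n, n_features)
    if (n_informative > 0)
      X[, seq_len(n_informative)] <- X[, seq_len(n_informative), drop = FALSE] +
        y * effect_size
    colnames(X) <- sprintf("F%02d", seq_len(n_features))
    out <- tibble::as_tibble(as.data.frame(X))
    out$label <- y
    out[, c("label", colnames(X))]
  })
}
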