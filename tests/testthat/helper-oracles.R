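# Brute-force oracles: naive per-subject / per-pixel counting, kept
# independent of the package's implementations.

oracle_rates <- function(y_true, y_pred, group, g) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(y_true)) {
    if (group[i] != g) next
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1
    if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1
    if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1
    if (y_true[i] == 1 && y_pred[i] == 0) fn <- fn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       tpr = tp / (tp + fn), fpr = fp / (fp + tn))
}

oracle_rate_of_positive_pred <- function(y_pred, group, g) {
  num <- 0; den <- 0
  for (i in seq_along(y_pred)) {
    if (group[i] == g) {
      den <- den + 1
      if (y_pred[i] == 1) num <- num + 1
    }
  }
  num / den
}

oracle_theil <- function(y_true, y_pred) {
  b <- numeric(length(y_true))
  for (i in seq_along(y_true)) b[i] <- y_pred[i] - y_true[i] + 1
  mu <- sum(b) / length(b)
  acc <- 0
  for (bi in b) if (bi > 0) acc <- acc + (bi / mu) * log(bi / mu)
  acc / length(b)
}

oracle_balanced_accuracy <- function(y_true, y_pred) {
  tp <- sum(y_true == 1 & y_pred == 1); fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0); fp <- sum(y_true == 0 & y_pred == 1)
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

# Random labelled-prediction instance guaranteed to have both classes in
# both groups (so every rate is defined).
random_lp_instance <- function(n_max = 50) {
  repeat {
    n <- sample(8:n_max, 1)
    y_true <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y_pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    group <- sample(c("a", "b"), n, replace = TRUE)
    ok <- all(vapply(c("a", "b"), function(g) {
      yt <- y_true[group == g]
      length(yt) > 0 && any(yt == 1) && any(yt == 0)
    }, logical(1)))
    if (ok) {
      return(labeled_predictions(y_true, runif(n), y_pred, group))
    }
  }
}

random_mask <- function(rows = 16, cols = 16, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.2, 0.8)
  matrix(rbinom(rows * cols, 1, p), rows, cols)
}

# Predictions with a group-calibration bias in a low-prevalence screening
# regime: group "b" scores are shifted down on the logit scale, so its TPR
# and FPR both sit below group "a"'s (the under-scoring mechanism the
# score-rescaling mitigations target), with small FPRs and substantial FNRs
# as typical of clinical risk screening.
planted_disparity_lp <- function(n = 10000, seed = 1,
                                 shift = c(a = 0, b = -0.8),
                                 prevalence = 0.3) {
  withr::with_seed(seed, {
    group <- sample(names(shift), n, replace = TRUE)
    y <- rbinom(n, 1, prevalence)
    score <- stats::plogis(-2 + 3 * y + shift[group] + stats::rnorm(n))
    labeled_predictions(y, score, as.integer(score > 0.5), group)
  })
}
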