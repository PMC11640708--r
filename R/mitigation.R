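# Post-processing bias mitigation ----------------------------------------

#' Mitigation hyperparameters
#'
#' @param alpha,beta Non-negative sensitivities of the balanced probability
#'   adjustment to the TPR and FPR disparities.
#' @param theta Decision threshold in (0, 1); predictions are positive when
#'   the (adjusted) score strictly exceeds it. Default 0.5.
#' @param k_grid Ordered positive scaling factors searched by [find_k()].
#' @param lambda_fair Non-negative weight of the fairness term in
#'   [composite_fairness_loss()].
#' @param tolerance Non-negative convergence slack retained with the run
#'   provenance.
#' @return A list of class `mitigation_params`.
#' @export
mitigation_params <- function(alpha = 1, beta = 1, theta = 0.5,
                              k_grid = seq(0.5, 2, by = 0.1),
                              lambda_fair = 1, tolerance = 0) {
  if (theta <= 0 || theta >= 1) rlang::abort("`theta` must lie in (0, 1).")
  if (length(k_grid) == 0 || any(k_grid <= 0)) {
    rlang::abort("`k_grid` must be non-empty with all entries > 0.")
  }
  if (alpha < 0 || beta < 0 || lambda_fair < 0 || tolerance < 0) {
    rlang::abort("alpha, beta, lambda_fair and tolerance must be >= 0.")
  }
  structure(list(alpha = alpha, beta = beta, theta = theta,
                 k_grid = sort(k_grid), lambda_fair = lambda_fair,
                 tolerance = tolerance),
            class = "mitigation_params")
}

#' Inverse-probability reweighting of training subjects
#'
#' `w_i = 1 / p(y_i | x_i)`, the reciprocal of the model's probability of
#' the observed label, so under-served (surprising) subjects carry more
#' weight. Probabilities below `eps` are clipped so weights stay bounded at
#' `1/eps`.
#'
#' @param p_obs_label Probability of each subject's observed label, in
#'   (0, 1\].
#' @param eps Clipping floor (default `1e-3`); set `NULL` to disable, in
#'   which case non-positive probabilities are an error.
#' @return Positive weights, monotone decreasing in `p_obs_label`.
#' @export
reweight <- function(p_obs_label, eps = 1e-3) {
  if (is.null(eps)) {
    if (any(p_obs_label <= 0)) {
      rlang::abort("probabilities must be > 0 when clipping is disabled.")
    }
    return(1 / p_obs_label)
  }
  1 / pmin(pmax(p_obs_label, eps), 1)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Balanced probability adjustment (BPA)
#'
#' Rescales predicted probabilities by the observed group disparities.
#' `mode = "literal"` applies `p * (1 + alpha * dTPR + beta * dFPR)` to every
#' subject — a single factor >= 1 for all groups. `mode = "directed"` (the
#' pipeline default) signs each term per group so the adjustment pushes
#' error rates toward parity: the group with the lower TPR has its scores
#' raised by the TPR term and the group with the higher FPR has its scores
#' lowered by the FPR term (each sign mirrored for the opposite group).
#' Adjusted scores are clipped to \[0, 1\].
#'
#' @param scores Predicted probabilities in \[0, 1\].
#' @param group Group membership per score (only used in directed mode).
#' @param gr A `group_rates` object from [group_confusion()].
#' @param params A [mitigation_params()] (uses `alpha`, `beta`).
#' @param mode `"directed"` (default) or `"literal"`.
#' @return A tibble of class `adjusted_scores` with columns `original`,
#'   `adjusted`, `group`, and attributes `delta_tpr`, `delta_fpr`, `mode`.
#' @export
bpa_adjust <- function(scores, group, gr, params = mitigation_params(),
                       mode = c("directed", "literal")) {
  mode <- match.arg(mode)
  if (!inherits(gr, "group_rates")) {
    rlang::abort("`gr` must come from group_confusion().")
  }
  if (any(scores < 0 | scores > 1)) rlang::abort("scores must lie in [0, 1].")
  dtpr <- delta_tpr(gr); dfpr <- delta_fpr(gr)
  if (mode == "literal") {
    mult <- rep(1 + params$alpha * dtpr + params$beta * dfpr, length(scores))
  } else {
    low_tpr_group <- gr$group[which.min(gr$tpr)]
    high_fpr_group <- gr$group[which.max(gr$fpr)]
    s_tpr <- ifelse(as.character(group) == low_tpr_group, 1, -1)
    s_fpr <- ifelse(as.character(group) == high_fpr_group, -1, 1)
    if (dtpr == 0) s_tpr <- 0
    if (dfpr == 0) s_fpr <- 0
    mult <- 1 + s_tpr * params$alpha * dtpr + s_fpr * params$beta * dfpr
  }
  out <- tibble::tibble(original = as.numeric(scores),
                        adjusted = clip01(scores * mult),
                        group = group)
  class(out) <- c("adjusted_scores", class(out))
  attr(out, "delta_tpr") <- dtpr
  attr(out, "delta_fpr") <- dfpr
  attr(out, "mode") <- mode
  out
}

#' Threshold scores into binary predictions
#'
#' Label 1 iff the score strictly exceeds `theta` (so a score exactly at the
#' threshold is negative).
#'
#' @param scores Probabilities in \[0, 1\] (an `adjusted_scores` tibble is
#'   accepted; its `adjusted` column is used).
#' @param theta Threshold in (0, 1), default 0.5.
#' @return Integer 0/1 vector.
#' @export
threshold_predict <- function(scores, theta = 0.5) {
  if (inherits(scores, "adjusted_scores")) scores <- scores$adjusted
  if (theta <= 0 || theta >= 1) rlang::abort("`theta` must lie in (0, 1).")
  as.integer(scores > theta)
}

#' Equalised-odds score scaling
#'
#' Leaves the target group's scores untouched and multiplies every other
#' subject's score by `k`, clipped to \[0, 1\].
#'
#' @param scores Probabilities in \[0, 1\].
#' @param group Group membership per score.
#' @param target_group Group whose scores are left unscaled.
#' @param k Positive scaling factor.
#' @return A tibble of class `adjusted_scores` with attribute `k`.
#' @export
eq_odds_scale <- function(scores, group, target_group, k) {
  if (k <= 0) rlang::abort("`k` must be > 0.")
  if (any(scores < 0 | scores > 1)) rlang::abort("scores must lie in [0, 1].")
  if (!any(group == target_group)) {
    rlang::abort(sprintf("unknown target group '%s'.", target_group))
  }
  adj <- ifelse(group == target_group, scores, clip01(scores * k))
  out <- tibble::tibble(original = as.numeric(scores),
                        adjusted = as.numeric(adj), group = group)
  class(out) <- c("adjusted_scores", class(out))
  attr(out, "k") <- k
  out
}

#' Select the equalised-odds scaling factor by grid search
#'
#' For each candidate `k`, scales the non-target scores with
#' [eq_odds_scale()], re-thresholds, and evaluates the disparity objective
#' `|dTPR| + |dFPR|`. Returns the minimiser; ties are broken toward the `k`
#' closest to 1 (least intervention), then toward the smaller `k`.
#'
#' @param lp A [labeled_predictions()] tibble (the privileged/unprivileged
#'   pair for rate evaluation is taken from `privileged`/`unprivileged`).
#' @param privileged,unprivileged Group identifiers for rate evaluation.
#' @param target_group Group whose scores are never scaled (defaults to the
#'   privileged group).
#' @param k_grid Positive candidate factors.
#' @param theta Decision threshold.
#' @return A list with `k`, `objective`, `rates` (post-adjustment
#'   `group_rates`) and the full `search` tibble (`k`, `objective`).
#' @export
find_k <- function(lp, privileged, unprivileged,
                   target_group = privileged,
                   k_grid = seq(0.5, 2, by = 0.1), theta = 0.5) {
  if (length(k_grid) == 0) rlang::abort("`k_grid` must be non-empty.")
  eval_k <- function(k) {
    adj <- eq_odds_scale(lp$y_score, lp$group, target_group, k)
    pred <- threshold_predict(adj, theta)
    lp2 <- labeled_predictions(lp$y_true, adj$adjusted, pred, lp$group)
    gr <- group_confusion(lp2, privileged, unprivileged)
    list(objective = abs(delta_tpr(gr)) + abs(delta_fpr(gr)), rates = gr)
  }
  res <- purrr::map(k_grid, function(k) {
    tryCatch(eval_k(k), error = function(e) NULL)
  })
  ok <- !purrr::map_lgl(res, is.null)
  if (!any(ok)) rlang::abort("every k in the grid yields undefined rates.")
  obj <- purrr::map_dbl(res[ok], "objective")
  ks <- k_grid[ok]
  ord <- order(obj, abs(ks - 1), ks)
  best <- ord[1]
  list(k = ks[best], objective = obj[best], rates = res[ok][[best]]$rates,
       search = tibble::tibble(k = ks, objective = obj))
}

#' Exhaustive nearest-counterfactual search
#'
#' Finds the grid point closest (L2) to `x` whose predicted label equals
#' `desired`, enumerating the full axis-aligned box `[lower, upper]` at the
#' given per-feature steps. Infeasibility is a result, not an error.
#'
#' @param x Numeric feature vector (the query point).
#' @param predict_fun Function mapping a numeric vector to a label.
#' @param desired Desired label value.
#' @param lower,upper Finite per-feature bounds.
#' @param step Positive per-feature step sizes.
#' @return A list with `found` (logical); when found also `x_cf` and
#'   `distance`.
#' @examples
#' f <- function(v) as.integer(v[1] > 2)
#' counterfactual_search(1, f, 1, lower = 0, upper = 4, step = 0.25)
#' @export
counterfactual_search <- function(x, predict_fun, desired, lower, upper,
                                  step) {
  d <- length(x)
  stopifnot(length(lower) == d, length(upper) == d, length(step) == d ||
              length(step) == 1)
  step <- rep_len(step, d)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    rlang::abort("bounds must be finite.")
  }
  if (any(step <= 0)) rlang::abort("steps must be > 0.")
  axes <- purrr::map(seq_len(d), function(i) seq(lower[i], upper[i], by = step[i]))
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  labels <- apply(grid, 1, predict_fun)
  feasible <- which(labels == desired)
  if (length(feasible) == 0) return(list(found = FALSE))
  dist <- sqrt(colSums((t(grid[feasible, , drop = FALSE]) - x)^2))
  best <- feasible[order(dist, feasible)[1]]
  list(found = TRUE, x_cf = unname(grid[best, ]), distance = min(dist))
}

#' Composite task + fairness loss
#'
#' `l_task + lambda * l_fair`: the scalar combinator used to weight a
#' fairness penalty against a task loss.
#'
#' @param l_task,l_fair Non-negative finite losses.
#' @param lambda_fair Non-negative weight.
#' @return The combined loss.
#' @export
composite_fairness_loss <- function(l_task, l_fair, lambda_fair) {
  if (!all(is.finite(c(l_task, l_fair, lambda_fair)))) {
    rlang::abort("losses and lambda must be finite.")
  }
  l_task + lambda_fair * l_fair
}
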