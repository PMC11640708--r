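# Group fairness metrics ------------------------------------------------
#
# All metrics follow the unprivileged-minus-privileged sign convention
# (ratios: unprivileged / privileged). Undefined rates raise errors naming
# the offending group rather than returning silent zeros.

#' Bundle per-subject labels, scores and group membership
#'
#' The tabular substrate of every fairness metric and mitigation operator:
#' one row per subject with the true binary label, the model's predicted
#' probability of the positive class, the binary predicted label, and the
#' sensitive-attribute value.
#'
#' @param y_true Binary (0/1) true labels.
#' @param y_score Predicted probabilities in \[0, 1\].
#' @param y_pred Binary (0/1) predicted labels.
#' @param group Sensitive-attribute value per subject.
#' @return A tibble of class `labeled_predictions` with columns `y_true`,
#'   `y_score`, `y_pred`, `group`.
#' @export
labeled_predictions <- function(y_true, y_score, y_pred, group) {
  n <- length(y_true)
  if (length(y_score) != n || length(y_pred) != n || length(group) != n) {
    rlang::abort("all labeled_predictions vectors must have equal length.")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    rlang::abort("labels must be binary 0/1.")
  }
  if (any(y_score < 0 | y_score > 1)) {
    rlang::abort("scores must lie in [0, 1].")
  }
  out <- tibble::tibble(y_true = as.integer(y_true),
                        y_score = as.numeric(y_score),
                        y_pred = as.integer(y_pred),
                        group = group)
  class(out) <- c("labeled_predictions", class(out))
  out
}

check_groups_present <- function(lp, privileged, unprivileged) {
  for (g in c(privileged, unprivileged)) {
    if (!any(lp$group == g)) {
      rlang::abort(sprintf("group '%s' is absent from the data.", g))
    }
  }
}

#' Per-group confusion counts and error rates
#'
#' Computes TP/FP/TN/FN and the derived TPR, FPR and FNR for the designated
#' privileged and unprivileged groups, together with the absolute disparities
#' `delta_tpr = |TPR_1 - TPR_2|` and `delta_fpr = |FPR_1 - FPR_2|`.
#'
#' @param lp A [labeled_predictions()] tibble.
#' @param privileged,unprivileged Group identifiers.
#' @return A tibble of class `group_rates` (one row per group, the
#'   unprivileged row first) with attributes `delta_tpr`, `delta_fpr`,
#'   `privileged`, `unprivileged`.
#' @examples
#' lp <- labeled_predictions(c(1, 1, 0, 0, 1, 0), c(.9, .4, .2, .1, .8, .7),
#'                           c(1, 0, 0, 0, 1, 1), c("a", "a", "a", "a", "b", "b"))
#' group_confusion(lp, privileged = "a", unprivileged = "b")
#' @export
group_confusion <- function(lp, privileged, unprivileged) {
  check_groups_present(lp, privileged, unprivileged)
  one <- function(g) {
    d <- lp[lp$group == g, ]
    tp <- sum(d$y_true == 1 & d$y_pred == 1)
    fn <- sum(d$y_true == 1 & d$y_pred == 0)
    fp <- sum(d$y_true == 0 & d$y_pred == 1)
    tn <- sum(d$y_true == 0 & d$y_pred == 0)
    if (tp + fn == 0) {
      rlang::abort(sprintf(
        "TPR undefined for group '%s': no positive true labels.", g))
    }
    if (fp + tn == 0) {
      rlang::abort(sprintf(
        "FPR undefined for group '%s': no negative true labels.", g))
    }
    tibble::tibble(group = as.character(g), tp = tp, fp = fp, tn = tn, fn = fn,
                   tpr = tp / (tp + fn), fpr = fp / (fp + tn),
                   fnr = fn / (tp + fn))
  }
  out <- dplyr::bind_rows(one(unprivileged), one(privileged))
  out$role <- c("unprivileged", "privileged")
  class(out) <- c("group_rates", class(out))
  attr(out, "delta_tpr") <- abs(diff(out$tpr))
  attr(out, "delta_fpr") <- abs(diff(out$fpr))
  attr(out, "privileged") <- as.character(privileged)
  attr(out, "unprivileged") <- as.character(unprivileged)
  out
}

#' @rdname group_confusion
#' @param gr A `group_rates` object.
#' @export
delta_tpr <- function(gr) attr(gr, "delta_tpr")

#' @rdname group_confusion
#' @export
delta_fpr <- function(gr) attr(gr, "delta_fpr")

rate_of <- function(gr, role, which) gr[[which]][gr$role == role]

#' Difference in mean outcomes between groups
#'
#' `mean(outcome | unprivileged) - mean(outcome | privileged)`. The outcome
#' column is explicit: dataset audits use the true label, model audits the
#' predicted label.
#'
#' @inheritParams group_confusion
#' @param outcome Which column to average: `"pred"` (default) or `"true"`.
#' @return Signed difference (unprivileged minus privileged).
#' @export
mean_outcome_difference <- function(lp, privileged, unprivileged,
                                    outcome = c("pred", "true")) {
  outcome <- match.arg(outcome)
  check_groups_present(lp, privileged, unprivileged)
  col <- if (outcome == "pred") lp$y_pred else lp$y_true
  mean(col[lp$group == unprivileged]) - mean(col[lp$group == privileged])
}

#' Disparate impact ratio
#'
#' `P(pred = 1 | unprivileged) / P(pred = 1 | privileged)`; 1 is parity and
#' values below 0.8 conventionally flag adverse impact.
#'
#' @inheritParams group_confusion
#' @return Non-negative ratio.
#' @export
disparate_impact <- function(lp, privileged, unprivileged) {
  check_groups_present(lp, privileged, unprivileged)
  p_priv <- mean(lp$y_pred[lp$group == privileged])
  p_unpriv <- mean(lp$y_pred[lp$group == unprivileged])
  if (p_priv == 0) {
    rlang::abort(sprintf(
      "disparate impact undefined: privileged group '%s' has zero positive-prediction rate.",
      privileged))
  }
  p_unpriv / p_priv
}

#' Demographic parity difference
#'
#' `P(pred = 1 | unprivileged) - P(pred = 1 | privileged)`; 0 means the
#' positive-prediction rates coincide across groups.
#'
#' @inheritParams group_confusion
#' @return Signed rate difference.
#' @export
demographic_parity_difference <- function(lp, privileged, unprivileged) {
  check_groups_present(lp, privileged, unprivileged)
  mean(lp$y_pred[lp$group == unprivileged]) -
    mean(lp$y_pred[lp$group == privileged])
}

#' Equal opportunity difference
#'
#' TPR of the unprivileged group minus TPR of the privileged group.
#'
#' @param gr A `group_rates` object from [group_confusion()].
#' @return Signed TPR difference.
#' @export
equal_opportunity_difference <- function(gr) {
  stopifnot(inherits(gr, "group_rates"))
  rate_of(gr, "unprivileged", "tpr") - rate_of(gr, "privileged", "tpr")
}

#' Average odds difference
#'
#' Mean of the FPR gap and the TPR gap, unprivileged minus privileged:
#' `((FPR_u - FPR_p) + (TPR_u - TPR_p)) / 2`.
#'
#' @inheritParams equal_opportunity_difference
#' @return Signed average of the two rate gaps.
#' @export
average_odds_difference <- function(gr) {
  stopifnot(inherits(gr, "group_rates"))
  ((rate_of(gr, "unprivileged", "fpr") - rate_of(gr, "privileged", "fpr")) +
   (rate_of(gr, "unprivileged", "tpr") - rate_of(gr, "privileged", "tpr"))) / 2
}

#' Theil index of prediction benefits
#'
#' Generalized entropy index (alpha = 1) of the per-subject benefit
#' `b_i = y_pred_i - y_true_i + 1`: `T = mean((b/mu) * log(b/mu))` with
#' `0 * log(0) = 0` and `mu = mean(b)`. Zero iff every subject receives the
#' same benefit (e.g. perfect predictions).
#'
#' @param lp A [labeled_predictions()] tibble.
#' @return Non-negative index.
#' @export
theil_index <- function(lp) {
  b <- lp$y_pred - lp$y_true + 1
  mu <- mean(b)
  if (mu == 0) {
    rlang::abort("Theil index undefined: all benefits are zero.")
  }
  x <- b / mu
  mean(ifelse(b == 0, 0, x * log(x)))
}

#' Balanced accuracy of the pooled sample
#'
#' `(TPR + TNR) / 2` over all subjects regardless of group.
#'
#' @param lp A [labeled_predictions()] tibble.
#' @return Value in \[0, 1\].
#' @export
balanced_accuracy <- function(lp) {
  pos <- lp$y_true == 1
  if (!any(pos)) rlang::abort("balanced accuracy undefined: no positive labels.")
  if (all(pos)) rlang::abort("balanced accuracy undefined: no negative labels.")
  tpr <- mean(lp$y_pred[pos] == 1)
  tnr <- mean(lp$y_pred[!pos] == 0)
  (tpr + tnr) / 2
}

#' Full fairness report for one prediction set
#'
#' Computes the complete metric suite — difference in mean outcomes (on true
#' and on predicted labels), demographic parity difference, disparate impact,
#' equal opportunity difference, average odds difference, Theil index,
#' accuracy and balanced accuracy — for one privileged/unprivileged pair.
#'
#' @inheritParams group_confusion
#' @return A one-row tibble of class `fairness_report` with the group rates
#'   attached as attribute `group_rates`.
#' @export
fairness_report <- function(lp, privileged, unprivileged) {
  gr <- group_confusion(lp, privileged, unprivileged)
  out <- tibble::tibble(
    mean_outcome_difference_true =
      mean_outcome_difference(lp, privileged, unprivileged, "true"),
    mean_outcome_difference_pred =
      mean_outcome_difference(lp, privileged, unprivileged, "pred"),
    demographic_parity_difference =
      demographic_parity_difference(lp, privileged, unprivileged),
    disparate_impact = tryCatch(
      disparate_impact(lp, privileged, unprivileged),
      error = function(e) NA_real_),
    equal_opportunity_difference = equal_opportunity_difference(gr),
    average_odds_difference = average_odds_difference(gr),
    theil_index = theil_index(lp),
    accuracy = mean(lp$y_true == lp$y_pred),
    balanced_accuracy = balanced_accuracy(lp))
  class(out) <- c("fairness_report", class(out))
  attr(out, "group_rates") <- gr
  out
}

#' @method tidy fairness_report
#' @export
tidy.fairness_report <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)), dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @method glance fairness_report
#' @export
glance.fairness_report <- function(x, ...) tibble::as_tibble(unclass(x))

#' Serialise a fairness report
#'
#' @param report A [fairness_report()].
#' @param path Output file.
#' @param run_id Identifier written alongside the metrics.
#' @return The report, invisibly.
#' @export
write_fairness_report_json <- function(report, path, run_id = "run") {
  gr <- attr(report, "group_rates")
  jsonlite::write_json(
    list(run_id = run_id,
         metrics = as.list(tibble::as_tibble(unclass(report))),
         group_rates = gr,
         delta_tpr = delta_tpr(gr), delta_fpr = delta_fpr(gr)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' @rdname write_fairness_report_json
#' @export
write_fairness_report_csv <- function(report, path, run_id = "run") {
  row <- dplyr::bind_cols(tibble::tibble(run_id = run_id),
                          tibble::as_tibble(unclass(report)))
  readr::write_csv(row, path)
  invisible(report)
}

#' Bar-chart view of a fairness report
#'
#' @param object A [fairness_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fairness_report
#' @export
autoplot.fairness_report <- function(object, ...) {
  d <- tidy.fairness_report(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value,
                                  y = stats::reorder(.data$metric, .data$value))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "value", y = NULL, title = "Fairness audit metrics")
}
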