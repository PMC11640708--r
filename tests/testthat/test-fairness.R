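hand_lp <- function() {
  # group g1: y = 1,1,0,0 / yhat = 1,0,0,0 -> TPR 0.5, FPR 0
  # group g2: y = 1,0     / yhat = 1,1     -> TPR 1,   FPR 1
  labeled_predictions(c(1, 1, 0, 0, 1, 0),
                      c(.9, .4, .2, .1, .8, .7),
                      c(1, 0, 0, 0, 1, 1),
                      c("g1", "g1", "g1", "g1", "g2", "g2"))
}

test_that("group confusion rates match hand counts", {
  gr <- group_confusion(hand_lp(), privileged = "g1", unprivileged = "g2")
  expect_equal(gr$tpr[gr$group == "g1"], 0.5)
  expect_equal(gr$fpr[gr$group == "g1"], 0)
  expect_equal(gr$tpr[gr$group == "g2"], 1)
  expect_equal(gr$fpr[gr$group == "g2"], 1)
  expect_equal(delta_tpr(gr), 0.5)
  expect_equal(delta_fpr(gr), 1)
  expect_equal(gr$fnr, 1 - gr$tpr)
})

test_that("perfect predictions give perfect rates and zero disparities", {
  y <- c(1, 0, 1, 0, 1, 0)
  lp <- labeled_predictions(y, y, y, rep(c("a", "b"), each = 3))
  gr <- group_confusion(lp, "a", "b")
  expect_equal(gr$tpr, c(1, 1))
  expect_equal(gr$fpr, c(0, 0))
  expect_equal(delta_tpr(gr), 0)
  expect_equal(delta_fpr(gr), 0)
})

test_that("degenerate groups raise named undefined-rate errors", {
  lp <- labeled_predictions(c(0, 0, 1, 0), c(.1, .2, .9, .3),
                            c(0, 1, 1, 0), c("a", "a", "b", "b"))
  expect_error(group_confusion(lp, "b", "a"), "TPR undefined for group 'a'")
  lp2 <- labeled_predictions(c(1, 1, 1, 0), c(.8, .9, .9, .2),
                             c(1, 1, 1, 0), c("a", "a", "b", "b"))
  expect_error(group_confusion(lp2, "b", "a"), "FPR undefined for group 'a'")
  expect_error(group_confusion(hand_lp(), "g1", "nope"), "absent")
})

test_that("mean outcome difference is a signed group-mean gap", {
  lp <- hand_lp()
  expect_equal(mean_outcome_difference(lp, "g1", "g2", outcome = "true"),
               0.5 - 0.5)
  expect_equal(mean_outcome_difference(lp, "g1", "g2", outcome = "pred"),
               1 - 0.25)
  expect_equal(mean_outcome_difference(lp, "g2", "g1", outcome = "pred"),
               -mean_outcome_difference(lp, "g1", "g2", outcome = "pred"))
})

test_that("disparate impact is the prediction-rate ratio", {
  lp <- hand_lp()
  expect_equal(disparate_impact(lp, "g1", "g2"), 1 / 0.25)
  y <- c(1, 0, 1, 0)
  same <- labeled_predictions(y, y, y, c("a", "a", "b", "b"))
  expect_equal(disparate_impact(same, "a", "b"), 1)
  none <- labeled_predictions(c(1, 0, 1, 0), c(.9, .1, .4, .4),
                              c(1, 0, 0, 0), c("a", "a", "b", "b"))
  expect_equal(disparate_impact(none, "a", "b"), 0)
  expect_error(disparate_impact(none, "b", "a"), "zero positive-prediction")
})

test_that("demographic parity difference matches the rate gap", {
  lp <- hand_lp()
  expect_equal(demographic_parity_difference(lp, "g1", "g2"), 0.75)
  expect_error(demographic_parity_difference(lp, "g1", "gX"), "absent")
})

test_that("equal opportunity and average odds follow the rate conventions", {
  gr <- group_confusion(hand_lp(), privileged = "g2", unprivileged = "g1")
  expect_equal(equal_opportunity_difference(gr), -0.5)
  expect_equal(average_odds_difference(gr), ((0 - 1) + (0.5 - 1)) / 2)
  swapped <- group_confusion(hand_lp(), privileged = "g1",
                             unprivileged = "g2")
  expect_equal(equal_opportunity_difference(swapped), 0.5)
  expect_equal(average_odds_difference(swapped), 0.75)
})

test_that("the Theil index matches its closed forms and invariances", {
  y <- c(1, 0, 1, 0)
  perfect <- labeled_predictions(y, y, y, rep("a", 4))
  expect_equal(theil_index(perfect), 0)
  two <- labeled_predictions(c(1, 0), c(.4, .6), c(0, 1), c("a", "a"))
  expect_equal(theil_index(two), log(2))
  withr::with_seed(8, {
    lp <- random_lp_instance()
    perm <- sample(nrow(lp))
    shuffled <- labeled_predictions(lp$y_true[perm], lp$y_score[perm],
                                    lp$y_pred[perm], lp$group[perm])
    expect_equal(theil_index(shuffled), theil_index(lp))
  })
  all_wrong <- labeled_predictions(c(1, 1), c(.2, .3), c(0, 0), c("a", "a"))
  expect_error(theil_index(all_wrong), "undefined")
})

test_that("balanced accuracy averages the pooled TPR and TNR", {
  y <- c(1, 0, 1, 0)
  expect_equal(balanced_accuracy(labeled_predictions(y, y, y, rep("a", 4))), 1)
  allpos <- labeled_predictions(y, rep(1, 4), rep(1, 4), rep("a", 4))
  expect_equal(balanced_accuracy(allpos), 0.5)
  lp <- labeled_predictions(c(1, 1, 0, 0, 0), c(.9, .2, .1, .3, .8),
                            c(1, 0, 0, 0, 1), rep("a", 5))
  expect_equal(balanced_accuracy(lp), (0.5 + 2 / 3) / 2)
})

test_that("every metric agrees with brute-force counting on random instances", {
  withr::with_seed(123, {
    for (case in 1:150) {
      lp <- random_lp_instance()
      gr <- group_confusion(lp, "a", "b")
      oa <- oracle_rates(lp$y_true, lp$y_pred, lp$group, "a")
      ob <- oracle_rates(lp$y_true, lp$y_pred, lp$group, "b")
      expect_equal(gr$tpr[gr$group == "a"], oa$tpr)
      expect_equal(gr$fpr[gr$group == "b"], ob$fpr)
      expect_equal(delta_tpr(gr), abs(oa$tpr - ob$tpr))
      expect_equal(delta_fpr(gr), abs(oa$fpr - ob$fpr))
      ra <- oracle_rate_of_positive_pred(lp$y_pred, lp$group, "a")
      rb <- oracle_rate_of_positive_pred(lp$y_pred, lp$group, "b")
      expect_equal(demographic_parity_difference(lp, "a", "b"), rb - ra)
      if (ra > 0) expect_equal(disparate_impact(lp, "a", "b"), rb / ra)
      expect_equal(equal_opportunity_difference(gr), ob$tpr - oa$tpr)
      expect_equal(average_odds_difference(gr),
                   ((ob$fpr - oa$fpr) + (ob$tpr - oa$tpr)) / 2)
      expect_equal(theil_index(lp), oracle_theil(lp$y_true, lp$y_pred))
      expect_equal(balanced_accuracy(lp),
                   oracle_balanced_accuracy(lp$y_true, lp$y_pred))
    }
  })
})

test_that("disparate impact is 1 exactly when the parity difference is 0", {
  withr::with_seed(77, {
    for (case in 1:50) {
      lp <- random_lp_instance()
      pr_priv <- mean(lp$y_pred[lp$group == "a"])
      if (pr_priv == 0) next
      di <- disparate_impact(lp, "a", "b")
      dpd <- demographic_parity_difference(lp, "a", "b")
      expect_equal(di == 1, dpd == 0)
    }
  })
})

test_that("the fairness report carries the full metric suite and serialises", {
  withr::with_seed(21, lp <- random_lp_instance())
  rep <- fairness_report(lp, "a", "b")
  expect_s3_class(rep, "fairness_report")
  expect_named(
    tibble::as_tibble(unclass(rep)),
    c("mean_outcome_difference_true", "mean_outcome_difference_pred",
      "demographic_parity_difference", "disparate_impact",
      "equal_opportunity_difference", "average_odds_difference",
      "theil_index", "accuracy", "balanced_accuracy"))
  long <- tidy(rep)
  expect_equal(nrow(long), 9)
  expect_equal(long$value[long$metric == "theil_index"], theil_index(lp))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_fairness_report_json(rep, jpath, run_id = "t")
  parsed <- jsonlite::read_json(jpath)
  expect_equal(parsed$metrics$theil_index, theil_index(lp))
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_fairness_report_csv(rep, cpath)
  row <- readr::read_csv(cpath, show_col_types = FALSE)
  expect_equal(row$balanced_accuracy, balanced_accuracy(lp))
})
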