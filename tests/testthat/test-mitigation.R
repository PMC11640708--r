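# gr fixture with delta TPR = 0.2 (group "lo" below), delta FPR = 0
rates_tpr_gap <- function() {
  y_true <- c(rep(1, 5), rep(0, 5), rep(1, 5), rep(0, 5))
  y_pred <- c(1, 1, 1, 1, 0,  rep(0, 5),   # hi: TPR 0.8, FPR 0
              1, 1, 1, 0, 0,  rep(0, 5))   # lo: TPR 0.6, FPR 0
  grp <- rep(c("hi", "lo"), each = 10)
  group_confusion(labeled_predictions(y_true, runif(20), y_pred, grp),
                  privileged = "hi", unprivileged = "lo")
}

test_that("reweighting is the clipped reciprocal of the label probability", {
  expect_equal(reweight(1), 1)
  expect_equal(reweight(0.5), 2)
  expect_equal(reweight(0, eps = 1e-3), 1000)
  expect_error(reweight(0, eps = NULL), "> 0")
  p <- c(0.2, 0.5, 0.9)
  expect_true(all(diff(reweight(p)) < 0))  # monotone decreasing in p
})

test_that("literal balanced probability adjustment matches the printed rule", {
  withr::with_seed(1, gr <- rates_tpr_gap())
  expect_equal(delta_tpr(gr), 0.2)
  expect_equal(delta_fpr(gr), 0)
  params <- mitigation_params(alpha = 1, beta = 0)
  adj <- bpa_adjust(c(0.5, 0.9), c("hi", "hi"), gr, params, mode = "literal")
  expect_equal(adj$adjusted, c(0.6, 1.0))  # 0.9 * 1.2 = 1.08, clipped
})

test_that("zero disparity makes both adjustment modes the identity", {
  y <- c(1, 0, 1, 0)
  lp <- labeled_predictions(y, c(.8, .2, .7, .3), y, c("a", "a", "b", "b"))
  gr <- group_confusion(lp, "a", "b")
  s <- c(0.1, 0.5, 0.9, 0.4)
  for (mode in c("literal", "directed")) {
    adj <- bpa_adjust(s, c("a", "a", "b", "b"), gr, mode = mode)
    expect_equal(adj$adjusted, s)
  }
})

test_that("directed adjustment raises the low-TPR group and preserves order", {
  withr::with_seed(2, gr <- rates_tpr_gap())
  s <- c(0.2, 0.4, 0.6, 0.3, 0.5, 0.7)
  grp <- rep(c("lo", "hi"), each = 3)
  adj <- bpa_adjust(s, grp, gr, mitigation_params(alpha = 1, beta = 1),
                    mode = "directed")
  expect_true(all(adj$adjusted[grp == "lo"] >= s[1:3]))
  expect_true(all(adj$adjusted[grp == "hi"] <= s[4:6]))
  expect_true(all(adj$adjusted >= 0 & adj$adjusted <= 1))
  for (g in c("lo", "hi")) {
    expect_equal(order(adj$adjusted[grp == g]), order(s[grp == g]))
  }
})

test_that("thresholding is strict and monotone in the threshold", {
  expect_equal(threshold_predict(0.5, 0.5), 0L)
  expect_equal(threshold_predict(0.51, 0.5), 1L)
  expect_error(threshold_predict(0.5, 1), "theta")
  withr::with_seed(3, s <- runif(100))
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8),
                   function(th) sum(threshold_predict(s, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("equalised-odds scaling leaves the target group untouched", {
  s <- c(0.4, 0.8, 0.5)
  g <- c("x", "x", "t")
  adj <- eq_odds_scale(s, g, target_group = "t", k = 1.5)
  expect_equal(adj$adjusted, c(0.6, 1.0, 0.5))  # 0.8*1.5 clipped to 1
  expect_equal(eq_odds_scale(s, g, "t", k = 1)$adjusted, s)
  expect_error(eq_odds_scale(s, g, "missing", k = 1), "unknown")
  expect_error(eq_odds_scale(s, g, "t", k = 0), "> 0")
})

test_that("find_k returns the grid minimiser with least-intervention ties", {
  y <- c(1, 0, 1, 0, 1, 0, 1, 0)
  s <- c(.9, .1, .8, .2, .9, .1, .8, .2)
  fair <- labeled_predictions(y, s, as.integer(s > .5),
                              rep(c("a", "b"), each = 4))
  sel <- find_k(fair, "a", "b", k_grid = seq(0.5, 2, by = 0.1))
  expect_equal(sel$k, 1)
  expect_equal(sel$objective, 0)
  single <- find_k(fair, "a", "b", k_grid = 0.7)
  expect_equal(single$k, 0.7)
})

test_that("find_k matches an independent re-evaluation of the objective", {
  lp <- planted_disparity_lp(n = 2000, seed = 5)
  grid <- seq(0.5, 2, by = 0.1)
  sel <- find_k(lp, "a", "b", target_group = "a", k_grid = grid)
  # independent exhaustive re-evaluation
  objective_at <- function(k) {
    adj <- ifelse(lp$group == "a", lp$y_score, pmin(1, lp$y_score * k))
    pred <- as.integer(adj > 0.5)
    o_a <- oracle_rates(lp$y_true, pred, lp$group, "a")
    o_b <- oracle_rates(lp$y_true, pred, lp$group, "b")
    abs(o_a$tpr - o_b$tpr) + abs(o_a$fpr - o_b$fpr)
  }
  objs <- vapply(grid, objective_at, numeric(1))
  expect_equal(sel$objective, min(objs))
  expect_lte(sel$objective, objective_at(1))
})

test_that("counterfactual search equals exhaustive enumeration", {
  f <- function(v) as.integer(v[1] > 2)
  res <- counterfactual_search(1, f, 1, lower = 0, upper = 4, step = 0.25)
  expect_true(res$found)
  expect_equal(res$x_cf, 2.25)
  expect_equal(res$distance, 1.25)

  at_origin <- counterfactual_search(3, f, 1, lower = 0, upper = 4,
                                     step = 0.25)
  expect_equal(at_origin$distance, 0)
  expect_equal(at_origin$x_cf, 3)

  infeasible <- counterfactual_search(1, f, 1, lower = 0, upper = 2,
                                      step = 0.5)
  expect_false(infeasible$found)

  # random 2-D instances vs a hand loop over the same grid
  withr::with_seed(9, {
    for (case in 1:20) {
      w <- rnorm(2); b <- rnorm(1)
      pred <- function(v) as.integer(sum(w * v) + b > 0)
      x <- runif(2, -1, 1)
      res <- counterfactual_search(x, pred, 1L, lower = c(-2, -2),
                                   upper = c(2, 2), step = c(0.2, 0.2))
      best <- Inf
      for (u in seq(-2, 2, by = 0.2)) for (v in seq(-2, 2, by = 0.2)) {
        if (pred(c(u, v)) == 1L) {
          best <- min(best, sqrt(sum((c(u, v) - x)^2)))
        }
      }
      if (is.infinite(best)) {
        expect_false(res$found)
      } else {
        expect_equal(res$distance, best)
        expect_equal(pred(res$x_cf), 1L)
      }
    }
  })
})

test_that("the composite loss is the lambda-weighted sum", {
  expect_equal(composite_fairness_loss(0.7, 0.2, 1.5), 1.0)
  expect_equal(composite_fairness_loss(0.7, 0.9, 0), 0.7)
  expect_error(composite_fairness_loss(Inf, 1, 1), "finite")
  base <- composite_fairness_loss(0.5, 0.5, 1)
  expect_gte(composite_fairness_loss(0.6, 0.5, 1), base)
  expect_gte(composite_fairness_loss(0.5, 0.6, 1), base)
})

test_that("directed adjustment does not widen disparities on planted gaps", {
  for (seed in 1:5) {
    lp <- planted_disparity_lp(n = 5000, seed = seed)
    gr <- group_confusion(lp, "a", "b")
    before <- abs(delta_tpr(gr)) + abs(delta_fpr(gr))
    adj <- bpa_adjust(lp$y_score, lp$group, gr, mitigation_params(),
                      mode = "directed")
    lp2 <- labeled_predictions(lp$y_true, adj$adjusted,
                               threshold_predict(adj), lp$group)
    gr2 <- group_confusion(lp2, "a", "b")
    after <- abs(delta_tpr(gr2)) + abs(delta_fpr(gr2))
    expect_lte(after, before + 1e-12)
  }
})
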