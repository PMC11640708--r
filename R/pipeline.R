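# Audit pipeline ----------------------------------------------------------
#
# generate/load cohort -> stratified split -> logistic baseline -> fairness
# audit -> mitigations -> re-audit -> epidemic simulations -> report.

#' Audit run configuration
#'
#' Assembles and validates the configuration driving [run_audit()].
#'
#' @param cohort Either a [cohort_spec()] (generate) or a file path to a
#'   cohort CSV (load).
#' @param sensitive Sensitive-attribute column name (default `"gender"`).
#' @param privileged,unprivileged Attribute values defining the group pair.
#' @param split_fraction Training fraction in (0, 1), default 0.8.
#' @param split_seed Seed of the train/test split.
#' @param features Model features (default: all schema columns except the
#'   outcome and pack-years).
#' @param outcome Outcome column, default `"cardio"`.
#' @param mitigation A [mitigation_params()].
#' @param methods Character vector of mitigations to apply after the
#'   baseline audit; subset of `"reweight"`, `"bpa"`, `"eqodds"`.
#' @param epi Optional named list with `params` (an epi parameter object),
#'   `init`, `t_eval`, and optional `bias` (relative transmission change).
#' @param delim Cohort CSV delimiter when `cohort` is a path.
#' @return A list of class `audit_config`.
#' @export
audit_config <- function(cohort = cohort_spec(),
                         sensitive = "gender",
                         privileged = 2, unprivileged = 1,
                         split_fraction = 0.8, split_seed = 1L,
                         features = c("age", "height", "weight", "ap_hi",
                                      "ap_lo", "cholesterol", "gluc",
                                      "smoke", "alco", "active"),
                         outcome = "cardio",
                         mitigation = mitigation_params(),
                         methods = character(),
                         epi = NULL, delim = ";") {
  if (split_fraction <= 0 || split_fraction >= 1) {
    rlang::abort("`split_fraction` must lie in (0, 1).")
  }
  bad <- setdiff(methods, c("reweight", "bpa", "eqodds"))
  if (length(bad)) {
    rlang::abort(sprintf("unknown mitigation method(s): %s.",
                         paste(bad, collapse = ", ")))
  }
  structure(list(cohort = cohort, sensitive = sensitive,
                 privileged = privileged, unprivileged = unprivileged,
                 split_fraction = split_fraction,
                 split_seed = as.integer(split_seed),
                 features = features, outcome = outcome,
                 mitigation = mitigation, methods = methods,
                 epi = epi, delim = delim),
            class = "audit_config")
}

#' Read an audit configuration from YAML
#'
#' Recognised blocks: `cohort:` (either `path:` or [cohort_spec()] fields),
#' `split:` (`fraction`, `seed`), `model:` (`features`, `outcome`),
#' `mitigation:` (`alpha`, `beta`, `theta`, `k_grid`, `methods`), `epi:`
#' (`model`, `beta`, `delta`, `alpha`, `gamma`, `init`, `t_end`, `bias`),
#' and top-level `sensitive`, `privileged`, `unprivileged`.
#'
#' @param path YAML file path.
#' @return An [audit_config()].
#' @export
read_audit_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort$path)) {
    y$cohort$path
  } else {
    args <- y$cohort[intersect(names(y$cohort),
                               names(formals(cohort_spec)))]
    do.call(cohort_spec, args %||% list())
  }
  mit_args <- y$mitigation[intersect(names(y$mitigation),
                                     names(formals(mitigation_params)))]
  epi <- NULL
  if (!is.null(y$epi)) {
    params <- switch(y$epi$model %||% "scir-carrier",
      "sir" = sir_params(y$epi$beta, y$epi$gamma,
                         isTRUE(y$epi$normalised)),
      "scir-confirm" = scir_confirm_params(y$epi$beta, y$epi$alpha,
                                           y$epi$gamma,
                                           isTRUE(y$epi$normalised)),
      "scir-carrier" = scir_carrier_params(y$epi$beta, y$epi$delta,
                                           y$epi$gamma))
    init <- unlist(y$epi$init) %||% c(S = 4, C = 4, I = 1, R = 1)
    t_end <- y$epi$t_end %||% 50
    epi <- list(params = params, init = init,
                t_eval = seq(0, t_end, length.out = y$epi$n_times %||% 50),
                bias = y$epi$bias %||% 0)
  }
  audit_config(
    cohort = cohort,
    sensitive = y$sensitive %||% "gender",
    privileged = y$privileged %||% 2,
    unprivileged = y$unprivileged %||% 1,
    split_fraction = y$split$fraction %||% 0.8,
    split_seed = y$split$seed %||% 1L,
    features = y$model$features %||% formals(audit_config)$features |> eval(),
    outcome = y$model$outcome %||% "cardio",
    mitigation = do.call(mitigation_params, mit_args %||% list()),
    methods = y$mitigation$methods %||% character(),
    epi = epi)
}

#' Jointly stratified train/test split
#'
#' Splits a cohort into training and test sets, stratifying jointly on the
#' outcome and the sensitive attribute so small-group rates stay defined in
#' both splits.
#'
#' @param cohort Cohort tibble.
#' @param outcome,sensitive Column names to stratify on.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_cohort <- function(cohort, outcome = "cardio", sensitive = "gender",
                         fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) {
    rlang::abort("`fraction` must lie in (0, 1).")
  }
  strata <- interaction(cohort[[outcome]], cohort[[sensitive]], drop = TRUE)
  withr::with_seed(as.integer(seed), {
    idx_train <- unlist(lapply(split(seq_len(nrow(cohort)), strata),
                               function(ix) {
      n_tr <- round(length(ix) * fraction)
      sample(ix, n_tr)
    }))
  })
  list(train = cohort[sort(idx_train), ],
       test = cohort[setdiff(seq_len(nrow(cohort)), idx_train), ])
}

#' Fit the baseline probabilistic classifier
#'
#' A maximum-likelihood logistic regression (`stats::glm`, binomial family)
#' exposing calibrated probabilities `P(Y = 1 | x)`. Deterministic given the
#' data; the optional per-subject `weights` support reweighting-based
#' mitigation.
#'
#' @param cohort Training tibble containing the outcome and features.
#' @param outcome Outcome column name.
#' @param features Feature column names.
#' @param weights Optional non-negative case weights.
#' @return An object of class `baseline_fit`.
#' @export
fit_baseline <- function(cohort, outcome = "cardio",
                         features = c("age", "height", "weight", "ap_hi",
                                      "ap_lo", "cholesterol", "gluc",
                                      "smoke", "alco", "active"),
                         weights = NULL) {
  y <- cohort[[outcome]]
  if (length(unique(y)) < 2) {
    rlang::abort("training data must contain both outcome classes.")
  }
  features <- intersect(features, names(cohort))
  rhs <- if (length(features)) paste(features, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  dat <- cohort[, c(outcome, features)]
  dat$.w <- if (is.null(weights)) rep(1, nrow(dat)) else weights
  fit <- stats::glm(fml, family = stats::binomial(), data = dat,
                    weights = .w)
  structure(list(glm = fit, outcome = outcome, features = features),
            class = "baseline_fit")
}

#' Predicted positive-class probability
#'
#' @param object A `baseline_fit`.
#' @param newdata Tibble of subjects.
#' @param ... Unused.
#' @return Probabilities in \[0, 1\].
#' @export
predict.baseline_fit <- function(object, newdata, ...) {
  unname(stats::predict(object$glm, newdata = newdata, type = "response"))
}

#' @method tidy baseline_fit
#' @export
tidy.baseline_fit <- function(x, ...) {
  s <- summary(x$glm)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std_error = s[, 2], statistic = s[, 3], p_value = s[, 4])
}

#' @method glance baseline_fit
#' @export
glance.baseline_fit <- function(x, ...) {
  g <- x$glm
  tibble::tibble(null_deviance = g$null.deviance, deviance = g$deviance,
                 aic = g$aic, nobs = length(g$y))
}

#' Pearson correlation matrix with undefined entries flagged
#'
#' Symmetric, unit-diagonal Pearson correlations over the selected columns.
#' Zero-variance columns yield `NA` off-diagonal entries (never silent
#' zeros) and are listed in the `undefined_columns` attribute.
#'
#' @param cohort Data frame.
#' @param columns Column names (numeric or binary-coded).
#' @return A correlation matrix with attribute `undefined_columns`.
#' @export
correlation_matrix <- function(cohort, columns = names(cohort)) {
  if (nrow(cohort) < 2) rlang::abort("need at least 2 rows.")
  x <- as.matrix(cohort[, columns, drop = FALSE])
  if (!is.numeric(x)) rlang::abort("selected columns must be numeric.")
  sds <- apply(x, 2, stats::sd)
  undef <- columns[sds == 0]
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  attr(r, "undefined_columns") <- undef
  r
}

`%||%` <- rlang::`%||%`

audit_stage <- function(stage, expr) {
  message(sprintf("[fairdx] stage: %s", stage))
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("stage '%s' failed: %s", stage,
                           conditionMessage(e)), parent = e)
    }),
    warning = function(w) invokeRestart("muffleWarning"))
}

#' Run the full fairness audit pipeline
#'
#' Generates or loads the cohort, performs a jointly stratified train/test
#' split, fits the logistic baseline, audits fairness on the test split,
#' applies each configured mitigation and re-audits, and optionally runs the
#' configured epidemic simulation with bias-adjusted transmission. Fully
#' reproducible: the configuration fixes every random stream.
#'
#' @param config An [audit_config()].
#' @return A list of class `audit_bundle` with elements `reports` (named
#'   list of [fairness_report()]s, `"baseline"` first), `epi` (list with
#'   `trajectory` and `summary`, or `NULL`), `config`, and `provenance`
#'   (config hash, seeds, package version).
#' @export
run_audit <- function(config) {
  stopifnot(inherits(config, "audit_config"))
  cohort <- audit_stage("cohort", {
    if (inherits(config$cohort, "cohort_spec")) {
      generate_cohort(config$cohort)
    } else {
      read_cohort_csv(config$cohort, config$delim)
    }
  })
  sp <- audit_stage("split", split_cohort(
    cohort, config$outcome, config$sensitive,
    config$split_fraction, config$split_seed))
  fit <- audit_stage("fit", fit_baseline(sp$train, config$outcome,
                                         config$features))
  theta <- config$mitigation$theta
  lp <- audit_stage("audit", {
    p <- predict(fit, sp$test)
    labeled_predictions(sp$test[[config$outcome]], p,
                        as.integer(p > theta),
                        sp$test[[config$sensitive]])
  })
  priv <- config$privileged; unpriv <- config$unprivileged
  reports <- list(baseline = fairness_report(lp, priv, unpriv))
  for (m in config$methods) {
    reports[[m]] <- audit_stage(m, switch(m,
      reweight = {
        p_tr <- predict(fit, sp$train)
        y_tr <- sp$train[[config$outcome]]
        w <- reweight(ifelse(y_tr == 1, p_tr, 1 - p_tr))
        fit_w <- fit_baseline(sp$train, config$outcome, config$features,
                              weights = w)
        p2 <- predict(fit_w, sp$test)
        fairness_report(
          labeled_predictions(lp$y_true, p2, as.integer(p2 > theta),
                              lp$group), priv, unpriv)
      },
      bpa = {
        gr <- attr(reports$baseline, "group_rates")
        adj <- bpa_adjust(lp$y_score, lp$group, gr, config$mitigation,
                          mode = "directed")
        fairness_report(
          labeled_predictions(lp$y_true, adj$adjusted,
                              threshold_predict(adj, theta), lp$group),
          priv, unpriv)
      },
      eqodds = {
        sel <- find_k(lp, priv, unpriv,
                      k_grid = config$mitigation$k_grid, theta = theta)
        adj <- eq_odds_scale(lp$y_score, lp$group, priv, sel$k)
        rep <- fairness_report(
          labeled_predictions(lp$y_true, adj$adjusted,
                              threshold_predict(adj, theta), lp$group),
          priv, unpriv)
        attr(rep, "chosen_k") <- sel$k
        rep
      }))
  }
  epi <- NULL
  if (!is.null(config$epi)) {
    epi <- audit_stage("epi", {
      params <- config$epi$params
      bias <- config$epi$bias %||% 0
      params$beta <- apply_bias_to_beta(params$beta, bias)
      traj <- epi_integrate(params, config$epi$init, config$epi$t_eval)
      list(trajectory = traj,
           summary = summarize_trajectory(traj, params, bias_impact = bias))
    })
  }
  structure(
    list(reports = reports, epi = epi, config = config,
         provenance = list(
           config_hash = rlang::hash(config),
           split_seed = config$split_seed,
           cohort_seed = if (inherits(config$cohort, "cohort_spec"))
             config$cohort$seed else NA_integer_,
           package_version = as.character(utils::packageVersion("fairdx")))),
    class = "audit_bundle")
}

#' Flatten an audit bundle to metric rows
#'
#' @param x An `audit_bundle`.
#' @param ... Unused.
#' @return A tibble with one row per (mitigation, metric) in long form.
#' @method tidy audit_bundle
#' @export
tidy.audit_bundle <- function(x, ...) {
  purrr::imap_dfr(x$reports, function(rep, nm) {
    dplyr::bind_cols(tibble::tibble(mitigation = nm), tidy.fairness_report(rep))
  })
}

#' Write an audit bundle to disk
#'
#' Produces `report.json` (machine-readable bundle), `metrics.csv` (one row
#' per mitigation) and `summary.md` (human-readable overview) under `dir`.
#'
#' @param bundle An `audit_bundle` from [run_audit()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  csv_path <- file.path(dir, "metrics.csv")
  md_path <- file.path(dir, "summary.md")
  metrics <- purrr::imap_dfr(bundle$reports, function(rep, nm) {
    dplyr::bind_cols(tibble::tibble(mitigation = nm),
                     tibble::as_tibble(unclass(rep)))
  })
  payload <- list(
    provenance = bundle$provenance,
    metrics = metrics,
    epi = if (!is.null(bundle$epi)) list(
      summary = tibble::as_tibble(unclass(bundle$epi$summary)),
      trajectory = tibble::as_tibble(bundle$epi$trajectory)) else NULL)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  readr::write_csv(metrics, csv_path)
  lines <- c("# Fairness audit summary", "",
             sprintf("- config hash: `%s`", bundle$provenance$config_hash),
             sprintf("- mitigations: %s",
                     paste(names(bundle$reports), collapse = ", ")), "",
             paste(utils::capture.output(print(as.data.frame(metrics))),
                   collapse = "\n"))
  writeLines(lines, md_path)
  invisible(c(json = json_path, csv = csv_path, md = md_path))
}

#' Compare baseline and mitigated metrics graphically
#'
#' @param object An `audit_bundle`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot audit_bundle
#' @export
autoplot.audit_bundle <- function(object, ...) {
  d <- tidy.audit_bundle(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$metric,
                                  fill = .data$mitigation)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "value", y = NULL, fill = NULL,
                  title = "Fairness metrics: baseline vs mitigations")
}
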