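# Synthetic cohort generation ------------------------------------------------
#
# Emulates the standard cardiovascular tabular schema: age in days, height
# (cm), weight (kg), gender (1 = women, 2 = men), systolic/diastolic blood
# pressure (ap_hi/ap_lo, mmHg), cholesterol and glucose on a 1-3 ordinal
# scale, binary smoke/alco/active lifestyle flags, and a binary outcome
# (cardio). Cross-feature dependence is induced through a Gaussian copula
# whose latent correlations are calibrated so the *observed* Pearson
# correlations (after marginal discretisation) hit the requested targets.

#' Specify a synthetic cardiovascular cohort
#'
#' Builds a validated specification for [generate_cohort()]. Defaults emulate
#' a 10,000-subject cohort with the marginal distributions typical of public
#' cardiovascular screening data and the headline correlation structure of
#' such data (age-outcome r = 0.24, gender-smoking r = 0.34, age-cholesterol
#' r = 0.15, weight-outcome r = 0.18, glucose-cholesterol r = 0.45,
#' smoking-outcome r = -0.02).
#'
#' @param n_subjects Number of rows to generate (non-negative integer).
#' @param outcome_rate_by_group Named numeric vector of outcome (cardio)
#'   prevalences per gender code (`"1"` = women, `"2"` = men), each in
#'   \[0, 1\].
#' @param feature_means,feature_sds Named numeric vectors for the continuous
#'   features `age` (days), `height` (cm), `weight` (kg), `ap_hi` (mmHg).
#'   `ap_lo` is derived from `ap_hi` minus a positive pulse-pressure gap so
#'   generated rows never invert (`ap_hi >= ap_lo`).
#' @param categorical_probs Named list: `gender` = P(code 2), `cholesterol`
#'   and `gluc` = length-3 probability vectors over levels 1:3, `smoke`,
#'   `alco`, `active` = P(flag = 1).
#' @param target_correlations Data frame (or tibble) with columns `a`, `b`,
#'   `r`: requested pairwise Pearson correlations between named columns.
#'   Pairs involving both `gender` and `cardio` are disallowed because the
#'   gender-conditional outcome rates already determine that association.
#' @param pulse_pressure Mean and sd of the ap_hi - ap_lo gap (mmHg).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_subjects = 10000,
                        outcome_rate_by_group = c("1" = 0.5, "2" = 0.5),
                        feature_means = c(age = 19468, height = 164.4,
                                          weight = 74.2, ap_hi = 126.6),
                        feature_sds = c(age = 2467, height = 8.2,
                                        weight = 14.4, ap_hi = 16.7),
                        categorical_probs = list(
                          gender = 0.35,
                          cholesterol = c(0.750, 0.135, 0.115),
                          gluc = c(0.850, 0.074, 0.076),
                          smoke = 0.088, alco = 0.054, active = 0.804),
                        target_correlations = default_target_correlations(),
                        pulse_pressure = c(mean = 45, sd = 10),
                        seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 0) {
    rlang::abort("`n_subjects` must be a non-negative integer.")
  }
  if (is.null(names(outcome_rate_by_group)) ||
      any(!is.finite(outcome_rate_by_group)) ||
      any(outcome_rate_by_group < 0 | outcome_rate_by_group > 1)) {
    rlang::abort("`outcome_rate_by_group` must be named probabilities in [0, 1].")
  }
  cont <- c("age", "height", "weight", "ap_hi")
  if (!all(cont %in% names(feature_means)) || !all(cont %in% names(feature_sds))) {
    rlang::abort("`feature_means`/`feature_sds` must name age, height, weight, ap_hi.")
  }
  if (any(feature_sds[cont] < 0)) rlang::abort("feature sds must be non-negative.")
  for (nm in c("gender", "smoke", "alco", "active")) {
    p <- categorical_probs[[nm]]
    if (length(p) != 1 || !is.finite(p) || p < 0 || p > 1) {
      rlang::abort(sprintf("categorical_probs$%s must be a single probability.", nm))
    }
  }
  for (nm in c("cholesterol", "gluc")) {
    p <- categorical_probs[[nm]]
    if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      rlang::abort(sprintf(
        "categorical_probs$%s must be 3 probabilities summing to 1.", nm))
    }
  }
  tc <- tibble::as_tibble(target_correlations)
  if (nrow(tc)) {
    stopifnot(all(c("a", "b", "r") %in% names(tc)))
    if (any(abs(tc$r) > 1)) rlang::abort("target correlations must satisfy |r| <= 1.")
    both <- (tc$a == "gender" & tc$b == "cardio") |
            (tc$a == "cardio" & tc$b == "gender")
    if (any(both)) {
      rlang::abort(
        "gender-cardio association is set by `outcome_rate_by_group`, not a target correlation.")
    }
  }
  structure(
    list(n_subjects = n_subjects,
         outcome_rate_by_group = outcome_rate_by_group,
         feature_means = feature_means, feature_sds = feature_sds,
         categorical_probs = categorical_probs,
         target_correlations = tc,
         pulse_pressure = pulse_pressure,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Default correlation targets for the synthetic cohort
#'
#' The headline pairwise Pearson correlations of public cardiovascular
#' screening data of this schema.
#' @return A tibble with columns `a`, `b`, `r`.
#' @export
default_target_correlations <- function() {
  tibble::tribble(
    ~a,       ~b,            ~r,
    "age",    "cardio",      0.24,
    "gender", "smoke",       0.34,
    "age",    "cholesterol", 0.15,
    "weight", "cardio",      0.18,
    "gluc",   "cholesterol", 0.45,
    "smoke",  "cardio",     -0.02)
}

# Marginal descriptors used by the copula calibration. Each margin maps a
# standard-normal latent z to the observed column; `moments` gives the mean
# and sd of the observed variable, `cond_mean(rho, z)` the conditional
# expectation E[g(Z2) | Z1 = z] under latent correlation rho.
margin_descriptor <- function(name, spec) {
  cont <- c("age", "height", "weight", "ap_hi")
  if (name %in% cont) {
    list(type = "continuous",
         mean = 0, sd = 1,  # standardised; Pearson r is scale-invariant
         cond_mean = function(rho, z) rho * z)
  } else if (name %in% c("smoke", "alco", "active")) {
    p <- spec$categorical_probs[[name]]
    tau <- stats::qnorm(1 - p)
    list(type = "binary", mean = p, sd = sqrt(p * (1 - p)),
         cond_mean = function(rho, z)
           stats::pnorm((rho * z - tau) / sqrt(1 - rho^2)))
  } else if (name == "gender") {
    p <- spec$categorical_probs$gender     # P(code 2)
    tau <- stats::qnorm(1 - p)
    list(type = "binary", mean = 1 + p, sd = sqrt(p * (1 - p)),
         cond_mean = function(rho, z)
           1 + stats::pnorm((rho * z - tau) / sqrt(1 - rho^2)))
  } else if (name == "cardio") {
    # pooled prevalence across gender groups
    pg <- spec$categorical_probs$gender
    rates <- spec$outcome_rate_by_group
    p <- sum(rates * c((1 - pg), pg)[match(names(rates), c("1", "2"))])
    tau <- stats::qnorm(1 - p)
    list(type = "binary", mean = p, sd = sqrt(p * (1 - p)),
         cond_mean = function(rho, z)
           stats::pnorm((rho * z - tau) / sqrt(1 - rho^2)))
  } else if (name %in% c("cholesterol", "gluc")) {
    pr <- spec$categorical_probs[[name]]
    tau <- stats::qnorm(cumsum(pr)[1:2])
    m <- sum((1:3) * pr)
    s <- sqrt(sum((1:3)^2 * pr) - m^2)
    list(type = "ordinal", mean = m, sd = s,
         cond_mean = function(rho, z)
           1 +
           stats::pnorm((rho * z - tau[1]) / sqrt(1 - rho^2)) +
           stats::pnorm((rho * z - tau[2]) / sqrt(1 - rho^2)))
  } else {
    rlang::abort(sprintf("no margin named '%s' in the cohort schema.", name))
  }
}

# Value of the observed variable a as a function of its latent z (for the
# 1-D integral E[f(Z1) g(Z2)] = int f(z) E[g|z] phi(z) dz).
margin_value_fun <- function(desc, spec, name) {
  if (desc$type == "continuous") return(function(z) z)
  if (name == "gender") {
    tau <- stats::qnorm(1 - spec$categorical_probs$gender)
    return(function(z) 1 + (z > tau))
  }
  if (desc$type == "binary") {
    p <- desc$mean
    tau <- stats::qnorm(1 - p)
    return(function(z) as.numeric(z > tau))
  }
  pr <- spec$categorical_probs[[name]]
  tau <- stats::qnorm(cumsum(pr)[1:2])
  function(z) 1 + (z > tau[1]) + (z > tau[2])
}

# Observed Pearson correlation between margins a and b at latent rho.
achieved_correlation <- function(rho, da, fa, db) {
  if (abs(rho) >= 1) rho <- sign(rho) * 0.999999
  integrand <- function(z) fa(z) * db$cond_mean(rho, z) * stats::dnorm(z)
  exy <- stats::integrate(integrand, -8, 8, rel.tol = 1e-9)$value
  (exy - da$mean * db$mean) / (da$sd * db$sd)
}

# Solve for the latent correlation that yields the requested observed r.
calibrate_latent_r <- function(target, da, fa, db) {
  f <- function(rho) achieved_correlation(rho, da, fa, db) - target
  if (target == 0) return(0)
  sol <- stats::uniroot(f, lower = -0.995, upper = 0.995, tol = 1e-7,
                        extendInt = "upX")
  sol$root
}

latent_correlation_matrix <- function(spec) {
  cols <- c("age", "height", "weight", "ap_hi", "gender", "cholesterol",
            "gluc", "smoke", "alco", "active", "cardio")
  R <- diag(length(cols))
  dimnames(R) <- list(cols, cols)
  tc <- spec$target_correlations
  if (nrow(tc)) {
    for (i in seq_len(nrow(tc))) {
      a <- tc$a[i]; b <- tc$b[i]
      da <- margin_descriptor(a, spec); db <- margin_descriptor(b, spec)
      fa <- margin_value_fun(da, spec, a)
      rho <- calibrate_latent_r(tc$r[i], da, fa, db)
      R[a, b] <- R[b, a] <- rho
    }
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    dimnames(R) <- list(cols, cols)
  }
  R
}

cohort_columns <- c("age", "height", "weight", "gender", "ap_hi", "ap_lo",
                    "cholesterol", "gluc", "smoke", "alco", "active",
                    "cardio", "pack_years")

empty_cohort <- function() {
  tibble::tibble(age = integer(), height = double(), weight = double(),
                 gender = integer(), ap_hi = double(), ap_lo = double(),
                 cholesterol = integer(), gluc = integer(), smoke = integer(),
                 alco = integer(), active = integer(), cardio = integer(),
                 pack_years = double())
}

#' Generate a synthetic cardiovascular cohort
#'
#' Draws `spec$n_subjects` subjects from a Gaussian copula whose latent
#' correlations are calibrated so requested observed Pearson correlations are
#' recovered after marginal discretisation. The binary outcome `cardio` is
#' thresholded per gender group at the group's requested prevalence, so
#' group-conditional outcome rates converge to `spec$outcome_rate_by_group`.
#' Pack-years are synthesised for smokers from cigarettes-per-day and smoking
#' duration and are 0 for never-smokers.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject and the full cohort schema
#'   (`age` days, `height`, `weight`, `gender`, `ap_hi`, `ap_lo`,
#'   `cholesterol`, `gluc`, `smoke`, `alco`, `active`, `cardio`,
#'   `pack_years`). `ap_hi >= ap_lo` holds for every generated row.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 500, seed = 7))
#' dplyr::count(cohort, gender, cardio)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    rlang::abort("`spec` must be built with cohort_spec().")
  }
  n <- spec$n_subjects
  if (n == 0) return(empty_cohort())
  R <- latent_correlation_matrix(spec)
  withr::with_seed(spec$seed, {
    Z <- matrix(stats::rnorm(n * ncol(R)), n) %*% chol(R)
    colnames(Z) <- colnames(R)
    gp <- spec$categorical_probs
    gender <- 1L + as.integer(Z[, "gender"] > stats::qnorm(1 - gp$gender))
    rates <- spec$outcome_rate_by_group
    rate_i <- unname(rates[as.character(gender)])
    rate_i[is.na(rate_i)] <- mean(rates)
    cardio <- as.integer(Z[, "cardio"] > stats::qnorm(1 - rate_i))
    mk_bin <- function(col) as.integer(Z[, col] > stats::qnorm(1 - gp[[col]]))
    mk_ord <- function(col) {
      tau <- stats::qnorm(cumsum(gp[[col]])[1:2])
      1L + (Z[, col] > tau[1]) + (Z[, col] > tau[2])
    }
    mu <- spec$feature_means; sd <- spec$feature_sds
    age    <- round(mu[["age"]] + sd[["age"]] * Z[, "age"])
    height <- round(mu[["height"]] + sd[["height"]] * Z[, "height"], 1)
    weight <- round(mu[["weight"]] + sd[["weight"]] * Z[, "weight"], 1)
    ap_hi  <- round(mu[["ap_hi"]] + sd[["ap_hi"]] * Z[, "ap_hi"])
    gap <- pmax(5, stats::rnorm(n, spec$pulse_pressure[["mean"]],
                                spec$pulse_pressure[["sd"]]))
    ap_lo <- round(ap_hi - gap)
    smoke <- mk_bin("smoke")
    age_years <- age / 365.25
    cigs  <- ifelse(smoke == 1L, pmax(1, round(stats::rnorm(n, 15, 7))), 0)
    years <- ifelse(smoke == 1L,
                    pmax(0, pmin(age_years - 18,
                                 stats::rnorm(n, 20, 10))), 0)
    py <- pack_years(cigs, years)
    tibble::tibble(
      age = as.integer(age), height = height, weight = weight,
      gender = gender, ap_hi = as.numeric(ap_hi), ap_lo = as.numeric(ap_lo),
      cholesterol = as.integer(mk_ord("cholesterol")),
      gluc = as.integer(mk_ord("gluc")),
      smoke = smoke, alco = mk_bin("alco"), active = mk_bin("active"),
      cardio = cardio, pack_years = py)
  })
}

#' Cumulative smoking exposure in pack-years
#'
#' One pack-year is one 20-cigarette pack per day for one year:
#' `(cigarettes_per_day / 20) * years_smoked`.
#'
#' @param cigarettes_per_day,years_smoked Non-negative numerics (vectorised).
#' @return Non-negative numeric vector of pack-years.
#' @examples
#' pack_years(20, 10)  # 10
#' @export
pack_years <- function(cigarettes_per_day, years_smoked) {
  if (any(cigarettes_per_day < 0, na.rm = TRUE) ||
      any(years_smoked < 0, na.rm = TRUE)) {
    rlang::abort("pack_years() requires non-negative inputs.")
  }
  (cigarettes_per_day / 20) * years_smoked
}

#' Categorise pack-years exposure
#'
#' Half-open bins: \[0, 10) -> `"0-10"`, \[10, 20) -> `"10-20"`,
#' \[20, Inf) -> `">20"`.
#'
#' @param py Non-negative numeric vector of pack-years.
#' @return Factor with levels `"0-10"`, `"10-20"`, `">20"`.
#' @export
pack_year_category <- function(py) {
  if (any(py < 0, na.rm = TRUE)) {
    rlang::abort("pack_year_category() requires non-negative input.")
  }
  cut(py, breaks = c(0, 10, 20, Inf), labels = c("0-10", "10-20", ">20"),
      right = FALSE, include.lowest = TRUE)
}

#' Generate per-group transmission bias factors
#'
#' Draws one multiplicative bias factor per group, `b_g ~ N(mean_bias +
#' offset_g, sd_bias)`. A factor of -0.10 applied through
#' [apply_bias_to_beta()] reduces the transmission rate by 10%.
#'
#' @param groups Character or atomic vector of group identifiers (non-empty).
#' @param mean_bias Mean bias (default -0.10, i.e. a 10% reduction).
#' @param sd_bias Non-negative spread of the factors.
#' @param group_offsets Optional named numeric of per-group mean shifts.
#' @param seed Integer seed.
#' @return A tibble with columns `group` and `bias`.
#' @export
generate_bias_factors <- function(groups, mean_bias = -0.10, sd_bias = 0.02,
                                  group_offsets = NULL, seed = 1L) {
  if (length(groups) == 0) rlang::abort("`groups` must be non-empty.")
  if (sd_bias < 0) rlang::abort("`sd_bias` must be non-negative.")
  off <- rep(0, length(groups))
  if (!is.null(group_offsets)) {
    idx <- match(as.character(groups), names(group_offsets))
    off <- ifelse(is.na(idx), 0, group_offsets[idx])
  }
  withr::with_seed(as.integer(seed), {
    tibble::tibble(
      group = groups,
      bias = stats::rnorm(length(groups), mean_bias + off, sd_bias))
  })
}

#' Generate a ground-truth / predicted mask pair with controlled Dice overlap
#'
#' Builds two binary masks whose Dice coefficient is within +/- 0.05 of
#' `target_dice` (exactly 1 for `target_dice = 1`, disjoint for 0). The
#' ground-truth mask is an axis-aligned rectangle; the predicted mask is the
#' same rectangle shifted horizontally so the overlap fraction matches the
#' target, which makes the achieved Dice exact up to the 1-pixel column
#' granularity.
#'
#' @param shape Integer vector `c(rows, cols)`, both positive.
#' @param target_dice Desired Dice coefficient in \[0, 1\].
#' @param seed Integer seed controlling rectangle placement.
#' @return A list with binary matrices `gt` and `pred` (0 background,
#'   1 foreground) and the `achieved` Dice.
#' @export
generate_mask_pair <- function(shape, target_dice, seed = 1L) {
  if (length(shape) != 2 || any(shape < 1)) {
    rlang::abort("`shape` must be two positive integers (rows, cols).")
  }
  if (target_dice < 0 || target_dice > 1) {
    rlang::abort("`target_dice` must be in [0, 1].")
  }
  rows <- as.integer(shape[1]); cols <- as.integer(shape[2])
  h0 <- max(1L, rows %/% 2L)
  w0 <- max(1L, cols %/% 3L)
  shift <- as.integer(round(w0 * (1 - target_dice)))
  achieved <- (w0 - shift) / w0
  if (abs(achieved - target_dice) > 0.05) {
    rlang::abort(sprintf(
      "shape %dx%d is too coarse to realise Dice %.2f within 0.05.",
      rows, cols, target_dice))
  }
  withr::with_seed(as.integer(seed), {
    max_r <- rows - h0
    max_c <- cols - (w0 + shift)
    if (max_c < 0) {
      rlang::abort("mask shape too narrow for the requested overlap shift.")
    }
    r0 <- if (max_r > 0) sample.int(max_r + 1L, 1L) - 1L else 0L
    c0 <- if (max_c > 0) sample.int(max_c + 1L, 1L) - 1L else 0L
    gt <- pred <- matrix(0L, rows, cols)
    gt[r0 + seq_len(h0), c0 + seq_len(w0)] <- 1L
    pred[r0 + seq_len(h0), c0 + shift + seq_len(w0)] <- 1L
    list(gt = gt, pred = pred, achieved = achieved)
  })
}

# Cohort / annotation I/O ------------------------------------------------

#' Read or write a cohort CSV
#'
#' The public dataset of this schema ships with `";"` as delimiter; both
#' `";"` and `","` are supported through `delim`.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @param delim Field delimiter, `";"` (default) or `","`.
#' @return `write_cohort_csv()` returns `cohort` invisibly;
#'   `read_cohort_csv()` returns a tibble.
#' @export
write_cohort_csv <- function(cohort, path, delim = c(";", ",")) {
  delim <- match.arg(delim)
  readr::write_delim(cohort, path, delim = delim)
  invisible(cohort)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, delim = c(";", ",")) {
  delim <- match.arg(delim)
  readr::read_delim(path, delim = delim, show_col_types = FALSE)
}

#' Read or write a binary mask as 8-bit grayscale PNG
#'
#' Foreground pixels are written as 255, background as 0; on read, pixels
#' with intensity >= `threshold` (on the 0-255 scale) are foreground.
#'
#' @param mask Binary matrix (0/1).
#' @param path PNG file path.
#' @param threshold Intensity cut on read, default 128.
#' @return `write_mask_png()` returns `mask` invisibly; `read_mask_png()`
#'   returns a binary integer matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(mask)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path, threshold = 128) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(img * 255 >= threshold), nrow(img), ncol(img))
}

#' Read or write bounding-box annotations
#'
#' Annotation CSVs carry one box per row with columns `label`, `x0`, `y0`,
#' `w`, `h`, `name`, `img_shape_x`, `img_shape_y`.
#'
#' @param boxes Tibble of box annotations.
#' @param path CSV path.
#' @return `write_bbox_csv()` returns `boxes` invisibly; `read_bbox_csv()` a
#'   tibble.
#' @export
write_bbox_csv <- function(boxes, path) {
  readr::write_csv(boxes, path)
  invisible(boxes)
}

#' @rdname write_bbox_csv
#' @export
read_bbox_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
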