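# Regression calibration: predict the measured health condition from the
# self-reported condition plus age, sex and education on the validation
# subsample, screen self-report x covariate interactions by Wald tests at 5%,
# assess accuracy on a 70/30 split (R-squared / AUC), then substitute model
# predictions for the self-reports across the full survey.

calibration_vars <- function(outcome) {
  switch(outcome,
    height = list(meas = "meas_height", sr = "sr_height", family = "linear"),
    weight = list(meas = "meas_weight", sr = "sr_weight", family = "linear"),
    hypertension = list(meas = "meas_hypertension", sr = "sr_hypertension",
                        family = "logistic"),
    hypercholesterolemia = list(meas = "meas_hypercholesterolemia",
                                sr = "sr_hypercholesterolemia",
                                family = "logistic"),
    abort(paste("unknown calibration outcome:", outcome),
          class = "surveymime_input_error")
  )
}

fit_glm <- function(formula, data, family) {
  fit <- if (family == "linear") {
    lm(formula, data = data)
  } else {
    suppressWarnings(glm(formula, data = data, family = binomial()))
  }
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("collinear design matrix; aliased terms: ",
                 paste(bad, collapse = ", ")),
          class = "surveymime_fit_error")
  }
  fit
}

# joint Wald chi-square on a set of coefficients of a fitted lm/glm
wald_test <- function(fit, terms) {
  b <- coef(fit)[terms]
  v <- vcov(fit)[terms, terms, drop = FALSE]
  stat <- tryCatch(drop(t(b) %*% solve(v, b)), error = function(e) NA_real_)
  if (!is.finite(stat)) return(list(statistic = NA_real_, p = 1))
  list(statistic = stat, p = 1 - stats::pchisq(stat, df = length(b)))
}

# train/test split, stratified on a binary outcome to avoid single-class
# held-out sets at small n
split_indices <- function(y, train_fraction, binary) {
  n <- length(y)
  if (binary) {
    train <- unlist(lapply(split(seq_len(n), y), function(idx) {
      sample(idx, max(1L, round(train_fraction * length(idx))))
    }), use.names = FALSE)
  } else {
    train <- sample.int(n, max(2L, round(train_fraction * n)))
  }
  list(train = sort(train), test = setdiff(seq_len(n), train))
}

accuracy_metric <- function(family, observed, predicted) {
  if (family == "linear") {
    ss_res <- sum((observed - predicted)^2)
    ss_tot <- sum((observed - mean(observed))^2)
    list(metric = "r_squared", value = 1 - ss_res / ss_tot, flag = FALSE)
  } else {
    if (length(unique(observed)) < 2) {
      return(list(metric = "auc", value = NA_real_, flag = TRUE))
    }
    auc <- as.numeric(pROC::auc(pROC::roc(observed, predicted, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    list(metric = "auc", value = auc, flag = FALSE)
  }
}

#' Fit a regression-calibration model on the validation subsample
#'
#' Predicts the measured health condition from the self-reported condition
#' plus age, sex and education (linear regression for height and weight,
#' logistic for hypertension and hypercholesterolemia). Candidate
#' self-report x covariate interaction terms are screened forward, one at a
#' time in the fixed order age, sex, education, and kept when their joint
#' Wald test is significant at `alpha`. Predictive accuracy (held-out
#' R-squared or AUC) is computed from a `train_fraction`/(1 - fraction)
#' split of the validation sample, the split being stratified on the outcome
#' for binary conditions; by default the selected model is then refitted on
#' the full validation sample for substitution.
#'
#' @param data Survey tibble; only `in_validation` rows with complete model
#'   variables are used.
#' @param outcome One of `"height"`, `"weight"`, `"hypertension"`,
#'   `"hypercholesterolemia"`.
#' @param covariates Covariates offered as main effects and interaction
#'   candidates, in screening order.
#' @param alpha Wald screening level.
#' @param train_fraction Training share of the accuracy split.
#' @param refit_full Refit the selected model on the whole validation sample
#'   after the accuracy check (`FALSE` keeps the training-split fit).
#' @param seed Integer seed controlling the split.
#' @return An object of class `calibration_model`.
#' @export
fit_calibration <- function(data, outcome,
                            covariates = c("age", "sex", "education"),
                            alpha = 0.05, train_fraction = 0.7,
                            refit_full = TRUE, seed = 1L) {
  vars <- calibration_vars(outcome)
  cols <- c(vars$meas, vars$sr, covariates)
  val <- dplyr::filter(data, .data$in_validation)
  val <- droplevels(val[complete.cases(val[, cols]), , drop = FALSE])
  if (nrow(val) < 5 * (length(covariates) + 2)) {
    abort("validation sample too small for the design matrix",
          class = "surveymime_input_error")
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  binary <- vars$family == "logistic"
  idx <- split_indices(val[[vars$meas]], train_fraction, binary)
  train <- val[idx$train, , drop = FALSE]
  test <- val[idx$test, , drop = FALSE]

  base_rhs <- paste(c(vars$sr, covariates), collapse = " + ")
  form <- as.formula(paste(vars$meas, "~", base_rhs))
  fit <- fit_glm(form, train, vars$family)
  selected <- character(0)
  for (cv in covariates) {
    cand <- paste0(vars$sr, ":", cv)
    form_try <- stats::update.formula(form, paste(". ~ . +", cand))
    fit_try <- tryCatch(fit_glm(form_try, train, vars$family),
                        error = function(e) NULL)
    if (is.null(fit_try)) next
    new_terms <- setdiff(names(coef(fit_try)), names(coef(fit)))
    if (!length(new_terms)) next
    if (wald_test(fit_try, new_terms)$p < alpha) {
      form <- form_try
      fit <- fit_try
      selected <- c(selected, cand)
    }
  }

  # held-out rows with factor levels unseen in the training split cannot be
  # scored; they are excluded from the accuracy computation
  test <- test[seen_rows(fit, test), , drop = FALSE]
  pred_test <- predict(fit, newdata = test, type = "response")
  acc <- accuracy_metric(vars$family, test[[vars$meas]], pred_test)
  final_fit <- if (refit_full) fit_glm(form, val, vars$family) else fit

  structure(list(
    outcome = outcome, meas_var = vars$meas, sr_var = vars$sr,
    family = vars$family, formula = form, fit = final_fit,
    interactions = selected, accuracy_metric = acc$metric,
    accuracy = acc$value, accuracy_undefined = acc$flag,
    train_fraction = train_fraction, n_train = nrow(train),
    n_test = nrow(test), refit_full = refit_full, seed = seed
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> outcome:", x$outcome, "(", x$family, ")\n")
  cat("  interactions kept:",
      if (length(x$interactions)) paste(x$interactions, collapse = ", ")
      else "none", "\n")
  cat(sprintf("  held-out %s: %s (train n = %d, test n = %d)\n",
              x$accuracy_metric,
              ifelse(is.na(x$accuracy), "undefined", format(x$accuracy, digits = 3)),
              x$n_train, x$n_test))
  invisible(x)
}

#' Held-out predictive accuracy of a calibration model
#'
#' Re-splits the validation sample into training and held-out parts with the
#' given seed, refits the model's selected formula on the training part, and
#' returns the held-out R-squared (linear) or AUC (logistic). The same seed
#' reproduces the identical split and metric.
#'
#' @param object A `calibration_model`.
#' @param data Survey tibble containing the validation subsample.
#' @param split Training fraction, in (0, 1).
#' @param seed Integer seed for the split.
#' @return Tibble with `outcome`, `metric`, `value`, `undefined`, `n_test`.
#' @export
evaluate_accuracy <- function(object, data, split = 0.7, seed = 1L) {
  if (split <= 0 || split >= 1) {
    abort("split must lie in (0, 1)", class = "surveymime_config_error")
  }
  vars <- calibration_vars(object$outcome)
  cols <- unique(c(vars$meas, all.vars(object$formula)))
  val <- dplyr::filter(data, .data$in_validation)
  val <- val[complete.cases(val[, intersect(cols, names(val))]), , drop = FALSE]
  set.seed(as.integer(seed %% .Machine$integer.max))
  idx <- split_indices(val[[vars$meas]], split, object$family == "logistic")
  fit <- fit_glm(object$formula, val[idx$train, , drop = FALSE], object$family)
  test <- val[idx$test, , drop = FALSE]
  test <- test[seen_rows(fit, test), , drop = FALSE]
  pred <- predict(fit, newdata = test, type = "response")
  acc <- accuracy_metric(object$family, test[[vars$meas]], pred)
  tibble::tibble(outcome = object$outcome, metric = acc$metric,
                 value = acc$value, undefined = acc$flag,
                 n_test = length(idx$test))
}

seen_rows <- function(fit, newdata) {
  ok <- rep(TRUE, nrow(newdata))
  xl <- fit$xlevels
  if (is.null(xl)) return(ok)
  for (v in names(xl)) {
    vals <- as.character(newdata[[v]])
    ok <- ok & (is.na(vals) | vals %in% xl[[v]])
  }
  ok
}

check_factor_levels <- function(fit, newdata) {
  xl <- fit$xlevels
  if (is.null(xl) || !length(xl)) return(invisible(TRUE))
  for (v in names(xl)) {
    vals <- as.character(newdata[[v]])
    bad <- which(!is.na(vals) & !(vals %in% xl[[v]]))
    if (length(bad)) {
      abort(paste0("covariate '", v, "' has levels unseen in training (",
                   paste(unique(vals[bad]), collapse = ", "), ") in rows: ",
                   paste(head(bad, 10), collapse = ", ")),
            class = "surveymime_input_error")
    }
  }
  invisible(TRUE)
}

#' Substitute calibrated predictions for self-reports across the full survey
#'
#' Continuous self-reports are replaced by the fitted models' predicted
#' means (`height_cal`, `weight_cal`); binary self-reports by predicted
#' probabilities (`hypertension_cal`, `hypercholesterolemia_cal`). The
#' corrected BMI (`bmi_cal`) and the `overweight_cal`/`obesity_cal` flags are
#' then derived from the predicted height and weight.
#'
#' @param data Full survey tibble.
#' @param models Named list of `calibration_model`s for `height`, `weight`,
#'   `hypertension` and `hypercholesterolemia`.
#' @return `data` with the `*_cal` columns appended; rows with missing
#'   predictors get `NA` predictions.
#' @export
calibrate_dataset <- function(data, models) {
  needed <- c("height", "weight", "hypertension", "hypercholesterolemia")
  if (!all(needed %in% names(models))) {
    abort(paste("models must contain:", paste(needed, collapse = ", ")),
          class = "surveymime_input_error")
  }
  for (nm in needed) {
    mod <- models[[nm]]
    check_factor_levels(mod$fit, data)
    data[[paste0(nm, "_cal")]] <-
      as.numeric(predict(mod$fit, newdata = data, type = "response"))
  }
  data$height_cal <- data$height_cal
  add_bmi_indicators(data, "height_cal", "weight_cal", suffix = "_cal")
}

#' Survey-weighted prevalence from a calibrated dataset
#'
#' Point estimates are weighted means of the calibrated values: 0/1 flags
#' derived from the corrected BMI for overweight/obesity, predicted
#' probabilities for hypertension/hypercholesterolemia. With
#' `se_method = "naive"` the standard error is the Taylor-linearized design
#' SE treating the predictions as fixed values (the method's well-known
#' limitation). `se_method = "propagate"` adds calibration-model coefficient
#' uncertainty by redrawing coefficients from their approximate sampling
#' distribution `n_draws` times, recomputing the weighted prevalence for
#' each draw, and adding the variance across draws to the design variance;
#' this is the variant used in standard-error-ratio comparisons, where a
#' poorly predictive calibration model should be penalized.
#'
#' @param data Full survey tibble.
#' @param models Named list of the four `calibration_model`s.
#' @param design A [survey_design()] specification.
#' @param indicators Indicators to estimate.
#' @param se_method `"naive"` or `"propagate"`.
#' @param n_draws Coefficient draws for `"propagate"`.
#' @param seed Integer seed for the coefficient draws.
#' @return Tibble with `indicator`, `estimate`, `se`, `design_se`,
#'   `model_se`, `n`.
#' @export
calibrated_prevalence <- function(data, models, design = survey_design(),
                                  indicators = c("overweight", "obesity",
                                                 "hypertension",
                                                 "hypercholesterolemia"),
                                  se_method = c("naive", "propagate"),
                                  n_draws = 100, seed = 1L) {
  se_method <- match.arg(se_method)
  cal <- calibrate_dataset(data, models)
  value_of <- function(d, ind) {
    switch(ind,
      overweight = d$overweight_cal,
      obesity = d$obesity_cal,
      hypertension = d$hypertension_cal,
      hypercholesterolemia = d$hypercholesterolemia_cal,
      abort(paste("unknown indicator:", ind), class = "surveymime_input_error"))
  }
  draws <- NULL
  if (se_method == "propagate") {
    set.seed(as.integer(seed %% .Machine$integer.max))
    draws <- lapply(seq_len(n_draws), function(i) {
      d <- data
      for (nm in c("height", "weight", "hypertension", "hypercholesterolemia")) {
        fit <- models[[nm]]$fit
        beta <- coef(fit)
        vc <- vcov(fit)
        bstar <- beta + drop(rnorm(length(beta)) %*% chol(vc))
        mm <- model.matrix(stats::delete.response(stats::terms(fit)), data = d,
                           xlev = fit$xlevels)
        eta <- drop(mm %*% bstar)
        pred <- rep(NA_real_, nrow(d))
        pred[as.integer(rownames(mm))] <-
          if (models[[nm]]$family == "logistic") plogis(eta) else eta
        d[[paste0(nm, "_cal")]] <- pred
      }
      add_bmi_indicators(d, "height_cal", "weight_cal", suffix = "_cal")
    })
  }
  out <- lapply(indicators, function(ind) {
    y <- value_of(cal, ind)
    est <- weighted_value_estimate(cal, y, design)
    model_var <- 0
    if (se_method == "propagate") {
      ests <- vapply(draws, function(d) {
        yy <- value_of(d, ind)
        ok <- !is.na(yy)
        sum(d$weight[ok] * yy[ok]) / sum(d$weight[ok])
      }, numeric(1))
      model_var <- var(ests)
    }
    tibble::tibble(indicator = ind, estimate = est$estimate,
                   se = sqrt(est$variance + model_var),
                   design_se = sqrt(est$variance),
                   model_se = sqrt(model_var), n = est$n)
  })
  dplyr::bind_rows(out)
}
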