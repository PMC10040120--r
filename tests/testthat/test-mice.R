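test_that("chain initialization fills from observed values, deterministically", {
  d <- small_survey(n = 300, seed = 33)
  spec <- imputation_spec(d, "parametric", m = 3, n_iterations = 2, seed = 5)
  states <- initialize_chains(d, spec)
  expect_length(states, 3)
  for (st in states) {
    for (v in names(spec$plan)) {
      expect_false(anyNA(st[[v]]))
      obs_vals <- d[[v]][!is.na(d[[v]])]
      expect_true(all(st[[v]] %in% obs_vals))
    }
    # complete variables untouched
    expect_identical(st$sr_height, d$sr_height)
  }
  expect_identical(states, initialize_chains(d, spec))
})

test_that("imputation_spec validates its configuration", {
  d <- small_survey(n = 200, seed = 34)
  expect_error(imputation_spec(d, m = 1), class = "surveymime_config_error")
  expect_error(imputation_spec(d, n_iterations = 0),
               class = "surveymime_config_error")
  expect_error(imputation_spec(d, variables = "nonexistent"),
               class = "surveymime_config_error")
  d2 <- d; d2$meas_height <- NA_real_
  expect_error(imputation_spec(d2), class = "surveymime_config_error")
  expect_error(imputation_spec(d, predictors = list(meas_height = "zzz")),
               class = "surveymime_config_error")
  # default visit sequence: least missing first
  d$education[1:150] <- NA
  spec <- imputation_spec(d)
  mf <- vapply(spec$visit_sequence, function(v) mean(is.na(d[[v]])), numeric(1))
  expect_true(all(diff(mf) >= 0))
})

test_that("PMM returns donors from the observed set", {
  set.seed(12)
  X_obs <- cbind(1, rnorm(40)); X_mis <- cbind(1, rnorm(15))
  y <- rnorm(40, 100, 12)
  imp <- impute_pmm(y, X_obs, X_mis, donors = 5)
  expect_length(imp, 15)
  expect_true(all(imp %in% y))
  expect_equal(impute_pmm(rep(7, 40), X_obs, X_mis), rep(7, 15))
})

test_that("single-donor PMM on a noiseless grid returns the exact match", {
  x <- 1:20
  X_obs <- cbind(1, x)
  X_mis <- cbind(1, 7)
  y <- 2 * x
  for (s in 1:20) {
    set.seed(s)
    expect_equal(impute_pmm(y, X_obs, X_mis, donors = 1), 14)
  }
})

test_that("PMM enforces its design-matrix contracts", {
  X <- cbind(1, 1:3, c(2, 5, 3))
  expect_error(impute_pmm(rnorm(3), X, X), class = "surveymime_input_error")
  Xdup <- cbind(a = 1, b = 1:10, c = 1:10)
  expect_error(impute_pmm(rnorm(10), Xdup, Xdup),
               class = "surveymime_fit_error")
})

test_that("logistic imputation reproduces the marginal prevalence", {
  set.seed(21)
  X_obs <- matrix(1, 500, 1); X_mis <- matrix(1, 2000, 1)
  y <- rbinom(500, 1, 0.4)
  prev <- mean(replicate(10, mean(impute_logistic(y, X_obs, X_mis))))
  expect_lt(abs(prev - mean(y)), 0.04)
  expect_warning(z <- impute_logistic(rep(0, 50), matrix(1, 50, 1),
                                      matrix(1, 30, 1)),
                 regexp = "single-class")
  expect_lte(mean(z), 0.2)
})

test_that("a strong positive predictor raises imputed probabilities", {
  set.seed(22)
  diffs <- replicate(30, {
    x <- rnorm(300)
    y <- rbinom(300, 1, plogis(-0.5 + 2.5 * x))
    xm <- c(rep(-1.5, 100), rep(1.5, 100))
    imp <- impute_logistic(y, cbind(1, x), cbind(1, xm))
    mean(imp[101:200]) - mean(imp[1:100])
  })
  expect_gt(mean(diffs > 0), 0.95)
})

test_that("random-forest imputation draws donors from the observed set", {
  set.seed(23)
  X_obs <- data.frame(x = rnorm(50), s = factor(sample(c("a", "b"), 50, TRUE)))
  X_mis <- data.frame(x = rnorm(20), s = factor(sample(c("a", "b"), 20, TRUE)))
  y <- rnorm(50, 80, 10)
  imp <- impute_rf(y, X_obs, X_mis, n_trees = 15)
  expect_true(all(imp %in% y))
  expect_equal(impute_rf(rep(3, 50), X_obs, X_mis, n_trees = 5), rep(3, 20))
  expect_error(impute_rf(1, X_obs[1, , drop = FALSE], X_mis),
               class = "surveymime_input_error")
})

test_that("deep forests track a step function", {
  set.seed(24)
  x <- c(rnorm(30, -2), rnorm(30, 2))
  y <- ifelse(x > 0, 10, 0)
  X_obs <- data.frame(x = x)
  xm <- c(rep(-2, 25), rep(2, 25))
  imp <- impute_rf(y, X_obs, data.frame(x = xm), n_trees = 30)
  expect_gt(mean(imp == ifelse(xm > 0, 10, 0)), 0.9)
})

test_that("a complete dataset passes through the engine unchanged", {
  d <- small_survey(n = 200, seed = 35)
  dc <- d[d$in_validation, ]  # fully observed rows only
  spec <- imputation_spec(dc, "parametric", m = 2, n_iterations = 2, seed = 9)
  cs <- run_chained(dc, spec)
  expect_length(cs$imputations, 2)
  expect_identical(cs$imputations[[1]]$meas_height, dc$meas_height)
  expect_identical(cs$imputations[[1]]$meas_height,
                   cs$imputations[[2]]$meas_height)
  expect_equal(nrow(cs$trace), 0)
})

test_that("observed cells are never overwritten and runs are deterministic", {
  d <- small_survey(n = 400, seed = 36)
  spec <- imputation_spec(d, "parametric", m = 3, n_iterations = 3, seed = 10)
  cs <- run_chained(d, spec)
  obs <- which(d$in_validation)
  for (k in 1:3) {
    expect_identical(cs$imputations[[k]]$meas_height[obs], d$meas_height[obs])
    expect_identical(cs$imputations[[k]]$meas_hypertension[obs],
                     d$meas_hypertension[obs])
  }
  cs2 <- run_chained(d, spec)
  expect_identical(cs$imputations, cs2$imputations)
  expect_identical(cs$trace, cs2$trace)
})

test_that("donor methods keep completed values inside the observed range", {
  d <- small_survey(n = 400, seed = 37)
  for (engine in c("parametric", "rf")) {
    spec <- imputation_spec(d, engine, m = 2, n_iterations = 2, n_trees = 10,
                            seed = 11)
    cs <- run_chained(d, spec)
    obs_h <- d$meas_height[!is.na(d$meas_height)]
    obs_w <- d$meas_weight[!is.na(d$meas_weight)]
    for (k in 1:2) {
      expect_true(all(cs$imputations[[k]]$meas_height %in% obs_h |
                        d$in_validation))
      expect_true(all(cs$imputations[[k]]$meas_weight %in% obs_w |
                        d$in_validation))
    }
  }
})

test_that("passive indicators equal the thresholds in every completed copy", {
  d <- small_survey(n = 400, seed = 38)
  cs <- run_chained(d, imputation_spec(d, "rf", m = 3, n_iterations = 2,
                                       n_trees = 10, seed = 12))
  for (copy in cs$imputations) {
    ind <- derive_indicators(copy$meas_height, copy$meas_weight)
    expect_equal(copy$overweight, ind$overweight)
    expect_equal(copy$obesity, ind$obesity)
    expect_equal(copy$hypertension, copy$meas_hypertension)
  }
})

test_that("covariate item nonresponse is imputed in the same process", {
  d <- simulate_bhis(truth_params(n_respondents = 400,
                                  covariate_missingness = 0.1),
                     design = design_params(validation_fraction = 0.3),
                     seed = 39)
  expect_gt(sum(is.na(d$education)), 0)
  spec <- imputation_spec(d, "parametric", m = 2, n_iterations = 3, seed = 13)
  expect_true("education" %in% names(spec$plan))
  cs <- run_chained(d, spec)
  for (copy in cs$imputations) {
    expect_false(anyNA(copy$education))
    expect_false(anyNA(copy$household_size))
    obs <- !is.na(d$education)
    expect_identical(as.character(copy$education[obs]),
                     as.character(d$education[obs]))
  }
})

test_that("the trace logs one entry per imputation x iteration x variable", {
  d <- small_survey(n = 300, seed = 40)
  spec <- imputation_spec(d, "parametric", m = 2, n_iterations = 4, seed = 14)
  cs <- run_chained(d, spec)
  n_active <- length(spec$plan)
  expect_equal(nrow(cs$trace), 2 * 4 * n_active)
  expect_true(all(is.finite(cs$trace$mean)))
  gl <- glance(cs)
  expect_equal(gl$m, 2)
  expect_equal(gl$n_iterations, 4)
})

test_that("convergence summary flags a shifted chain and not stable ones", {
  mk <- function(means2) {
    dplyr::bind_rows(lapply(1:3, function(c) {
      tibble::tibble(imputation = c, iteration = 1:10,
                     variable = "v",
                     mean = rnorm(10, ifelse(c == 3, means2, 0), 0.1),
                     sd = 1)
    }))
  }
  set.seed(55)
  stable <- convergence_summary(mk(0), window = 5)
  expect_false(stable$flag)
  shifted <- convergence_summary(mk(8), window = 5)
  expect_true(shifted$flag)
  # constant identical traces: ratio at its minimum
  const <- dplyr::bind_rows(lapply(1:3, function(c) {
    tibble::tibble(imputation = c, iteration = 1:10, variable = "v",
                   mean = 1, sd = 0)
  }))
  expect_equal(convergence_summary(const, window = 5)$ratio, 0)
  expect_error(convergence_summary(mk(0), window = 50),
               class = "surveymime_input_error")
})
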