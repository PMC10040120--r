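test_that("generation is reproducible bit-for-bit under a fixed seed", {
  p <- truth_params(n_respondents = 300)
  expect_identical(generate_truth(p, seed = 9), generate_truth(p, seed = 9))
  expect_false(identical(generate_truth(p, seed = 9),
                         generate_truth(p, seed = 10)))
  d1 <- simulate_bhis(truth_params(n_respondents = 300), seed = 5)
  d2 <- simulate_bhis(truth_params(n_respondents = 300), seed = 5)
  expect_identical(d1, d2)
})

test_that("degenerate prevalences produce constant truth flags", {
  d0 <- generate_truth(truth_params(n_respondents = 200,
                                    prevalence_hypertension = 0), seed = 2)
  expect_true(all(d0$true_hypertension == 0))
  d1 <- generate_truth(truth_params(n_respondents = 200,
                                    prevalence_hypertension = 1), seed = 2)
  expect_true(all(d1$true_hypertension == 1))
})

test_that("empirical truth prevalence matches the target within 3 binomial SEs", {
  d <- generate_truth(truth_params(n_respondents = 10000), seed = 31)
  tol <- 3 * sqrt(0.33 * 0.67 / 10000)
  expect_lt(abs(mean(d$true_hypertension) - 0.33), tol)
  tol2 <- 3 * sqrt(0.47 * 0.53 / 10000)
  expect_lt(abs(mean(d$true_hypercholesterolemia) - 0.47), tol2)
})

test_that("identity error model reproduces the truth exactly", {
  d <- small_survey(n = 250, seed = 8, error = zero_error_params())
  expect_equal(d$sr_height, d$true_height)
  expect_equal(d$sr_weight, d$true_weight)
  expect_equal(d$sr_hypertension, d$true_hypertension)
  expect_equal(d$sr_hypercholesterolemia, d$true_hypercholesterolemia)
})

test_that("generated measurements are consistent with the binary truth", {
  d <- generate_truth(truth_params(n_respondents = 800), seed = 12)
  ind <- derive_indicators(d$true_height, d$true_weight, sbp = d$true_sbp,
                           dbp = d$true_dbp,
                           htn_medication = d$true_htn_medication,
                           total_cholesterol = d$true_total_cholesterol)
  expect_equal(ind$hypertension, d$true_hypertension)
  expect_equal(ind$hypercholesterolemia, d$true_hypercholesterolemia)
})

test_that("self-reported BMI is under-reported on average under defaults", {
  d <- small_survey(n = 4000, seed = 13)
  sr_bmi <- derive_indicators(d$sr_height, d$sr_weight)$bmi
  expect_lt(mean(sr_bmi - d$true_bmi), 0)
  # height over-reported, weight under-reported
  expect_gt(mean(d$sr_height - d$true_height), 0)
  expect_lt(mean(d$sr_weight - d$true_weight), 0)
})

test_that("validation selection blanks measurements outside the subsample", {
  d <- small_survey(n = 300, seed = 3)
  out <- !d$in_validation
  for (col in c("meas_height", "meas_weight", "meas_sbp", "meas_dbp",
                "meas_htn_medication", "meas_total_cholesterol",
                "meas_hypertension", "meas_hypercholesterolemia")) {
    expect_true(all(is.na(d[[col]][out])), label = col)
    expect_true(all(!is.na(d[[col]][!out])), label = col)
  }
  expect_equal(sum(d$in_validation), round(0.25 * 300))
})

test_that("near-total validation fractions leave at most one unmeasured row", {
  d <- generate_truth(truth_params(n_respondents = 40), seed = 4)
  d <- select_validation(d, fraction = 39 / 40, seed = 4)
  expect_lte(sum(!d$in_validation), 1)
  expect_error(select_validation(d, fraction = 1),
               class = "surveymime_config_error")
  expect_error(select_validation(d, fraction = 0),
               class = "surveymime_config_error")
})

test_that("validation selection is MCAR: a 5% age test rejects at ~5%", {
  d <- generate_truth(truth_params(n_respondents = 400), seed = 21)
  rej <- vapply(1:200, function(s) {
    ds <- select_validation(d, 0.3, seed = s)
    t.test(ds$age[ds$in_validation], ds$age[!ds$in_validation])$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.105)
})

test_that("design assignment yields positive weights and nested clusters", {
  d <- small_survey(n = 400, seed = 6)
  expect_true(all(d$weight > 0))
  expect_true(all(startsWith(d$cluster, paste0(d$stratum, ":"))))
  # uniform weights: weighted prevalence equals the sample proportion
  du <- assign_design(generate_truth(truth_params(n_respondents = 400), seed = 6),
                      design_params(weight_model = uniform_weights), seed = 6)
  du$flag <- du$true_hypertension
  wp <- weighted_prevalence(du, "flag")
  expect_equal(wp$estimate, mean(du$flag))
  # degenerate design collapses to single labels
  d11 <- assign_design(generate_truth(truth_params(n_respondents = 50), seed = 1),
                       design_params(n_strata = 1, clusters_per_stratum = 1),
                       seed = 1)
  expect_equal(length(unique(d11$stratum)), 1L)
  expect_equal(length(unique(d11$cluster)), 1L)
  expect_error(
    assign_design(d, design_params(weight_model = function(x) rep(0, nrow(x))),
                  seed = 1),
    class = "surveymime_config_error")
})

test_that("inverse-probability weights remove over-sampling bias", {
  # population with a high-prevalence subgroup; subgroup over-sampled 4:1
  set.seed(99)
  wmean <- umean <- numeric(200)
  for (r in 1:200) {
    grp <- rbinom(2000, 1, 0.3)
    y <- rbinom(2000, 1, ifelse(grp == 1, 0.6, 0.2))
    p_sel <- ifelse(grp == 1, 0.8, 0.2)
    sel <- runif(2000) < p_sel
    w <- 1 / p_sel[sel]
    wmean[r] <- sum(w * y[sel]) / sum(w)
    umean[r] <- mean(y[sel])
  }
  truth <- 0.3 * 0.6 + 0.7 * 0.2
  expect_lt(abs(mean(wmean) - truth), 0.01)
  expect_gt(mean(umean) - truth, 0.05)
})

test_that("survey CSV round-trips with empty-field encoding and sidecar", {
  d <- small_survey(n = 120, seed = 14)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(d, path, provenance = list(seed = 14))
  line2 <- readLines(path, n = 2)[2]
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_survey(path)
  expect_equal(nrow(back), 120)
  expect_s3_class(back$sex, "factor")
  expect_equal(levels(back$education),
               c("primary", "lower_secondary", "higher_secondary", "higher"))
  expect_equal(back$meas_height, d$meas_height)
  expect_equal(as.numeric(back$sr_height), d$sr_height)
})

test_that("YAML-style config simulation is reproducible", {
  cfg <- list(seed = 77, truth = list(n_respondents = 150),
              design = list(validation_fraction = 0.2))
  a <- simulate_from_config(cfg)
  b <- simulate_from_config(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 150)
  expect_equal(sum(a$in_validation), 30)
})

test_that("invalid generator parameters are rejected", {
  expect_error(truth_params(prevalence_hypertension = 1.2),
               class = "surveymime_config_error")
  expect_error(truth_params(height_sd = 0), class = "surveymime_config_error")
  expect_error(truth_params(n_respondents = 0),
               class = "surveymime_config_error")
  expect_error(error_params(slope_attenuation = 0),
               class = "surveymime_config_error")
  expect_error(error_params(sens_hypertension = 1.4),
               class = "surveymime_config_error")
  expect_error(design_params(validation_fraction = 0),
               class = "surveymime_config_error")
})
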