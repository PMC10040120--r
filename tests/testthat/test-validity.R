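test_that("Bland-Altman limits equal mean difference +/- 1.96 SD", {
  # differences -2, 0, +2: mean 0, sample SD 2, limits -/+ 3.92
  rep <- bland_altman(c(-2, 0, 2), c(0, 0, 0))
  expect_equal(rep$mean_diff, 0)
  expect_equal(rep$sd_diff, 2)
  expect_equal(rep$loa_lower, -3.92)
  expect_equal(rep$loa_upper, 3.92)
  expect_true(rep$loa_lower <= rep$mean_diff & rep$mean_diff <= rep$loa_upper)
  # symmetric band
  expect_equal(rep$loa_upper - rep$mean_diff, rep$mean_diff - rep$loa_lower)
})

test_that("identical pairs give a degenerate zero band", {
  rep <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(rep$mean_diff, 0)
  expect_equal(rep$loa_lower, 0)
  expect_equal(rep$loa_upper, 0)
})

test_that("Bland-Altman statistics are invariant to weight rescaling", {
  set.seed(4)
  s <- rnorm(40, 1); m <- rnorm(40)
  w <- runif(40, 0.5, 3)
  a <- bland_altman(s, m, w)
  b <- bland_altman(s, m, 2 * w)
  expect_equal(a, b)
  # equal weights match the unweighted computation
  expect_equal(bland_altman(s, m, rep(2, 40)), bland_altman(s, m))
})

test_that("Bland-Altman input contracts are enforced", {
  expect_error(bland_altman(1, 1), class = "surveymime_input_error")
  expect_error(bland_altman(c(1, 2), c(1, 2), weights = c(1, -1)),
               class = "surveymime_input_error")
})

test_that("paired t test matches the textbook statistic and CI duality", {
  # differences 1..4: t = mean / (sd / sqrt(n)) = 2.5 / (1.29099/2)
  res <- paired_mean_difference_test(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_equal(res$statistic, 3.8729833462, tolerance = 1e-9)
  expect_equal(res$p_value, 0.0304662917, tolerance = 1e-8)
  zero <- paired_mean_difference_test(c(1, 2), c(1, 2))
  expect_true(zero$degenerate)
  expect_true(is.na(zero$p_value))
  set.seed(7)
  for (i in 1:30) {
    s <- rnorm(12, mean = runif(1, -1, 1))
    r <- paired_mean_difference_test(s, rnorm(12))
    excl <- r$conf_lo > 0 || r$conf_hi < 0
    expect_equal(excl, r$p_value < 0.05)
  }
})

test_that("ICC equals the two-way absolute-agreement ANOVA form", {
  self <- c(170, 165, 180, 158, 175, 162)
  meas <- c(168, 166, 176, 160, 172, 161)
  got <- icc_agreement(self, meas)
  # independent ANOVA oracle via aov mean squares
  df <- data.frame(y = c(self, meas), subj = factor(rep(1:6, 2)),
                   rater = factor(rep(c("s", "m"), each = 6)))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]; msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  oracle <- (msr - mse) / (msr + mse + (2 / 6) * (msc - mse))
  expect_equal(got$icc, oracle, tolerance = 1e-10)
  expect_equal(got$icc, 0.9456352905, tolerance = 1e-8)
  expect_true(got$icc_lo < got$icc && got$icc < got$icc_hi)
})

test_that("ICC is 1 for perfect agreement and penalizes constant offsets", {
  expect_equal(icc_agreement(c(1, 2, 3), c(1, 2, 3))$icc, 1)
  set.seed(8)
  x <- rnorm(30, 170, 8)
  base <- icc_agreement(x, x + rnorm(30, 0, 1))$icc
  shifted <- icc_agreement(x + 5, x + rnorm(30, 0, 1))$icc
  expect_lt(shifted, base)
  deg <- icc_agreement(rep(1, 5), rep(1, 5))
  expect_true(deg$degenerate)
})

test_that("confusion metrics match hand arithmetic", {
  s <- c(rep(1, 30), rep(0, 10), rep(1, 5), rep(0, 55))
  m <- c(rep(1, 30), rep(1, 10), rep(0, 5), rep(0, 55))
  cs <- confusion(s, m)
  expect_equal(cs$tp, 30); expect_equal(cs$fn, 10)
  expect_equal(cs$fp, 5); expect_equal(cs$tn, 55)
  expect_equal(cs$sensitivity, 0.75)
  expect_equal(cs$specificity, 55 / 60)
  expect_equal(cs$ppv, 30 / 35)
  expect_equal(cs$npv, 55 / 65)
  expect_equal(cs$prevalence_meas, 0.4)
  expect_equal(cs$prevalence_sr, 0.35)
})

test_that("kappa matches the chance-agreement formula and its symmetries", {
  # agreement table [[40,10],[10,40]]: po 0.8, pe 0.5, kappa 0.6
  s <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  m <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  expect_equal(confusion(s, m)$kappa, 0.6)
  expect_equal(kappa_agreement(s, m), 0.6)
  expect_equal(kappa_agreement(1 - s, 1 - m), 0.6)  # label swap
  expect_equal(kappa_agreement(c(1, 0, 1), c(1, 0, 1)), 1)
})

test_that("McNemar uses unweighted discordant counts", {
  s <- rep(c(1, 1, 0, 0), c(20, 10, 20, 50))
  m <- rep(c(1, 0, 1, 0), c(20, 10, 20, 50))
  cs <- confusion(s, m)
  expect_equal(cs$mcnemar_stat, (10 - 20)^2 / 30)
  # symmetric discordance: statistic 0
  s2 <- rep(c(1, 1, 0, 0), c(20, 15, 15, 50))
  m2 <- rep(c(1, 0, 1, 0), c(20, 15, 15, 50))
  expect_equal(confusion(s2, m2)$mcnemar_stat, 0)
  expect_equal(confusion(s2, m2)$mcnemar_p, 1)
})

test_that("empty margins yield undefined metrics, not zeros", {
  cs <- confusion(c(0, 1, 0), c(0, 0, 0))
  expect_true(is.na(cs$sensitivity))
  cs2 <- confusion(c(0, 0, 0), c(0, 0, 0))
  expect_true(is.na(cs2$sensitivity))
  expect_true(is.na(cs2$ppv))
})

test_that("confusion counts are invariant to weight rescaling ratios", {
  set.seed(5)
  s <- rbinom(80, 1, 0.4); m <- rbinom(80, 1, 0.4)
  w <- runif(80, 0.5, 2)
  a <- confusion(s, m, w); b <- confusion(s, m, 2 * w)
  expect_equal(a$sensitivity, b$sensitivity)
  expect_equal(a$kappa, b$kappa)
  expect_equal(2 * a$tp, b$tp)
})

test_that("stratified confusion counts sum to the whole-population counts", {
  d <- small_survey(n = 800, seed = 17)
  res <- stratified_validity(d, "hypertension", strata = "sex")
  all_row <- res[res$stratum == "all", ]
  lev <- res[res$stratum != "all", ]
  for (col in c("tp", "fp", "fn", "tn")) {
    expect_equal(sum(lev[[col]]), all_row[[col]], tolerance = 1e-10)
  }
})

test_that("a single-level stratum reproduces the whole-population report", {
  d <- small_survey(n = 400, seed = 18)
  d$sex <- factor("female", levels = c("male", "female"))
  res <- stratified_validity(d, "height", strata = "sex")
  all_row <- res[res$stratum == "all", ]
  lev_row <- res[res$stratum == "female", ]
  expect_equal(lev_row$mean_diff, all_row$mean_diff)
  expect_equal(lev_row$loa_upper, all_row$loa_upper)
  expect_error(stratified_validity(d, "height", strata = "shoe_size"),
               class = "surveymime_input_error")
  expect_error(stratified_validity(d, "no_such_indicator"),
               class = "surveymime_input_error")
})

test_that("a stronger female weight bias shows up in the female stratum", {
  err <- error_params(weight_bias = list(base = 0, female = -4, male = 0,
                                         per_year = 0, education = rep(0, 4)))
  hits <- vapply(1:25, function(r) {
    d <- small_survey(n = 600, seed = 300 + r, error = err)
    res <- stratified_validity(d, "weight", strata = "sex")
    abs(res$mean_diff[res$stratum == "female"]) >
      abs(res$mean_diff[res$stratum == "male"])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("validity_report assembles continuous, binary and ICC blocks", {
  d <- small_survey(n = 500, seed = 19)
  rep <- validity_report(d, stratifications = "sex")
  expect_setequal(unique(rep$continuous$variable), c("height", "weight", "bmi"))
  expect_setequal(unique(rep$binary$variable),
                  c("overweight", "obesity", "hypertension",
                    "hypercholesterolemia"))
  expect_equal(nrow(rep$icc), 3)
  expect_true(all(rep$icc$icc > 0.5))  # strong agreement under defaults
})
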