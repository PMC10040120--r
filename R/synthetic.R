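#' Parameters of the synthetic target population
#'
#' Describes the "truth" layer of the synthetic health-interview survey:
#' demographic covariate distributions and the latent, error-free values of
#' height, weight, blood pressure, medication use and total cholesterol.
#' Defaults are loose emulations of the Belgian adult population surveyed by
#' a national health interview with an examination validation subsample:
#' prevalence of (measured) hypertension about 33%, hypercholesterolemia
#' about 47%, obesity about 20%.
#'
#' Binary disease truth is drawn per respondent with probability
#' `prevalence + age_gradient * (age - mean(age))`, so the *marginal*
#' prevalence matches `prevalence` while older respondents are more often
#' affected. Blood pressure, medication and cholesterol values are then drawn
#' from mixtures that are exactly consistent with the binary truth under the
#' examination cut-offs (sbp >= 140 / dbp > 90 / medication; cholesterol
#' > 190 mg/dl), so threshold logic is exercised end to end.
#'
#' @param n_respondents Number of survey respondents.
#' @param height_mean_male,height_mean_female Mean standing height in cm.
#' @param height_sd Within-sex SD of height, cm.
#' @param height_age_slope Height change per year of age beyond 45, cm/year
#'   (secular decline in older cohorts).
#' @param weight_mean Mean weight (kg) at the 170 cm reference height.
#' @param weight_height_slope Weight change per cm of height, kg/cm.
#' @param weight_sd Residual SD of weight given height, kg.
#' @param prevalence_hypertension,prevalence_hypercholesterolemia Marginal
#'   truth prevalences, in \[0, 1\].
#' @param age_gradient_hypertension,age_gradient_hypercholesterolemia Linear
#'   age gradients of the two disease probabilities, per year.
#' @param age_range Integer range of ages sampled (years).
#' @param p_female Proportion of women.
#' @param education_probs Probabilities of the four ordered education levels
#'   (primary, lower secondary, higher secondary, higher).
#' @param province_probs Named vector of province sampling probabilities.
#' @param household_size_probs Probabilities of household sizes 1..6.
#' @param covariate_missingness Proportion of MCAR item nonresponse injected
#'   into the education and household-size covariates (default 0).
#'
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(n_respondents = 9439,
                         height_mean_male = 177.5,
                         height_mean_female = 164.5,
                         height_sd = 7,
                         height_age_slope = -0.06,
                         weight_mean = 74.5,
                         weight_height_slope = 0.8,
                         weight_sd = 14,
                         prevalence_hypertension = 0.33,
                         prevalence_hypercholesterolemia = 0.47,
                         age_gradient_hypertension = 0.006,
                         age_gradient_hypercholesterolemia = 0.006,
                         age_range = c(18L, 90L),
                         p_female = 0.51,
                         education_probs = c(0.08, 0.18, 0.34, 0.40),
                         province_probs = NULL,
                         household_size_probs = c(0.30, 0.33, 0.15, 0.14, 0.06, 0.02),
                         covariate_missingness = 0) {
  if (is.null(province_probs)) {
    province_probs <- c(
      Antwerp = 0.16, Brussels = 0.10, East_Flanders = 0.13,
      Flemish_Brabant = 0.10, Hainaut = 0.12, Liege = 0.10,
      Limburg = 0.08, Luxembourg = 0.03, Namur = 0.05,
      Walloon_Brabant = 0.04, West_Flanders = 0.09
    )
  }
  p <- list(
    n_respondents = as.integer(n_respondents),
    height_mean_male = height_mean_male,
    height_mean_female = height_mean_female,
    height_sd = height_sd,
    height_age_slope = height_age_slope,
    weight_mean = weight_mean,
    weight_height_slope = weight_height_slope,
    weight_sd = weight_sd,
    prevalence_hypertension = prevalence_hypertension,
    prevalence_hypercholesterolemia = prevalence_hypercholesterolemia,
    age_gradient_hypertension = age_gradient_hypertension,
    age_gradient_hypercholesterolemia = age_gradient_hypercholesterolemia,
    age_range = as.integer(age_range),
    p_female = p_female,
    education_probs = education_probs / sum(education_probs),
    province_probs = province_probs / sum(province_probs),
    household_size_probs = household_size_probs / sum(household_size_probs),
    covariate_missingness = covariate_missingness
  )
  validate_truth_params(p)
  structure(p, class = "truth_params")
}

validate_truth_params <- function(p) {
  prevs <- c(p$prevalence_hypertension, p$prevalence_hypercholesterolemia)
  if (any(prevs < 0) || any(prevs > 1)) {
    abort("prevalences must lie in [0, 1]", class = "surveymime_config_error")
  }
  sds <- c(p$height_sd, p$weight_sd)
  if (any(sds <= 0)) {
    abort("all SDs must be strictly positive", class = "surveymime_config_error")
  }
  if (p$n_respondents < 1) {
    abort("n_respondents must be >= 1", class = "surveymime_config_error")
  }
  if (p$covariate_missingness < 0 || p$covariate_missingness >= 1) {
    abort("covariate_missingness must lie in [0, 1)",
          class = "surveymime_config_error")
  }
  invisible(p)
}

#' Parameters of the self-report error mechanism
#'
#' The continuous error model is linear in the truth with additive Gaussian
#' noise: `sr = center + slope * (true - center) + bias + noise`, where
#' `center` is the population mean of the true values. A `slope` below 1
#' produces the "flat slope syndrome" of self-reported anthropometry
#' (over-reporting of low values, under-reporting of high values), and the
#' subgroup-specific `bias` shifts the intercept by sex, age and education.
#' Binary self-reports are misclassified truth: reported positive with
#' probability `sensitivity` when truly affected and `1 - specificity`
#' otherwise.
#'
#' Default biases echo the field's typical pattern: height over-reported by
#' about +1.05 cm on average (more by women, the elderly and the
#' low-educated), weight under-reported by about -1.50 kg, and awareness-type
#' operating points of roughly 45/99 (sensitivity/specificity, %) for
#' hypertension and 22/83 for hypercholesterolemia.
#'
#' @param height_bias,weight_bias Lists with components `base` (cm or kg),
#'   `female`, `male` (additive shifts), `per_year` (per year of age, centred
#'   at the sample mean age) and `education` (length-4 additive shifts).
#' @param slope_attenuation Slope linking self-report to truth, in (0, 1].
#' @param noise_sd_height,noise_sd_weight Residual reporting noise SD, cm/kg.
#' @param sens_hypertension,spec_hypertension Sensitivity and specificity of
#'   self-reported hypertension against measured truth.
#' @param sens_hypercholesterolemia,spec_hypercholesterolemia Likewise for
#'   hypercholesterolemia.
#'
#' @return An object of class `error_params`.
#' @export
error_params <- function(height_bias = list(base = 1.05, female = 0.35,
                                            male = -0.36, per_year = 0.03,
                                            education = c(0.8, 0.2, 0, -0.25)),
                         weight_bias = list(base = -1.50, female = -0.23,
                                            male = 0.24, per_year = -0.005,
                                            education = c(0.3, 0.15, 0.1, -0.2)),
                         slope_attenuation = 0.92,
                         noise_sd_height = 2.8,
                         noise_sd_weight = 4.0,
                         sens_hypertension = 0.45,
                         spec_hypertension = 0.99,
                         sens_hypercholesterolemia = 0.22,
                         spec_hypercholesterolemia = 0.83) {
  p <- list(
    height_bias = height_bias, weight_bias = weight_bias,
    slope_attenuation = slope_attenuation,
    noise_sd_height = noise_sd_height, noise_sd_weight = noise_sd_weight,
    sens_hypertension = sens_hypertension,
    spec_hypertension = spec_hypertension,
    sens_hypercholesterolemia = sens_hypercholesterolemia,
    spec_hypercholesterolemia = spec_hypercholesterolemia
  )
  rates <- c(p$sens_hypertension, p$spec_hypertension,
             p$sens_hypercholesterolemia, p$spec_hypercholesterolemia)
  if (any(rates < 0) || any(rates > 1)) {
    abort("sensitivities/specificities must lie in [0, 1]",
          class = "surveymime_config_error")
  }
  if (p$slope_attenuation <= 0 || p$slope_attenuation > 1) {
    abort("slope_attenuation must lie in (0, 1]",
          class = "surveymime_config_error")
  }
  if (p$noise_sd_height < 0 || p$noise_sd_weight < 0) {
    abort("noise SDs must be >= 0", class = "surveymime_config_error")
  }
  structure(p, class = "error_params")
}

#' Parameters of the sampling design emulation
#'
#' Respondents are stratified (strata cut across provinces), grouped into
#' clusters nested within strata, and given positive survey weights produced
#' by `weight_model`, a function of the respondent data frame. The default
#' weight model varies weights by province and household size, emulating
#' unequal selection probabilities with post-stratification; it is not an
#' attempt to mimic any real weighting algorithm.
#'
#' @param n_strata Number of design strata.
#' @param clusters_per_stratum Number of primary sampling units per stratum.
#' @param weight_model Function `data -> positive numeric vector` of length
#'   `nrow(data)`. `NULL` selects the default model.
#' @param validation_fraction Fraction of respondents drawn completely at
#'   random into the examination validation subsample, in (0, 1).
#'
#' @return An object of class `design_params`.
#' @export
design_params <- function(n_strata = 11,
                          clusters_per_stratum = 20,
                          weight_model = NULL,
                          validation_fraction = 1184 / 9439) {
  if (is.null(weight_model)) {
    weight_model <- function(data) {
      prov <- as.integer(factor(as.character(data$province)))
      hh <- data$household_size
      # design weights exist for every respondent even under item nonresponse
      hh[is.na(hh)] <- mean(hh, na.rm = TRUE)
      w <- 0.75 + 0.05 * (prov %% 5) + 0.08 * (hh - 2.5)
      w / mean(w)
    }
  }
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    abort("validation_fraction must lie in (0, 1)",
          class = "surveymime_config_error")
  }
  structure(list(
    n_strata = as.integer(n_strata),
    clusters_per_stratum = as.integer(clusters_per_stratum),
    weight_model = weight_model,
    validation_fraction = validation_fraction
  ), class = "design_params")
}

education_levels <- function() {
  c("primary", "lower_secondary", "higher_secondary", "higher")
}

# inverse-CDF truncated normal draw using the active RNG stream
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate the truth layer of a synthetic survey population
#'
#' Draws demographic covariates and latent error-free measurements for
#' `params$n_respondents` respondents. No self-report error, design
#' assignment or validation selection is applied; see
#' [apply_self_report_error()], [assign_design()], [select_validation()] and
#' the one-call wrapper [simulate_bhis()].
#'
#' @param params A [truth_params()] object.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#'
#' @return A tibble with one row per respondent: `id`, covariates (`age`,
#'   `sex`, `education`, `province`, `household_size`, `wave_year`) and truth
#'   columns `true_height`, `true_weight`, `true_sbp`, `true_dbp`,
#'   `true_htn_medication`, `true_total_cholesterol`, `true_hypertension`,
#'   `true_hypercholesterolemia`, `true_bmi`, `true_overweight`,
#'   `true_obesity`.
#' @export
generate_truth <- function(params = truth_params(), seed = 1L) {
  validate_truth_params(params)
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- params$n_respondents

  age <- sample(seq(params$age_range[1], params$age_range[2]), n,
                replace = TRUE,
                prob = dnorm(seq(params$age_range[1], params$age_range[2]), 48, 22))
  sex <- factor(ifelse(runif(n) < params$p_female, "female", "male"),
                levels = c("male", "female"))
  education <- factor(sample(education_levels(), n, replace = TRUE,
                             prob = params$education_probs),
                      levels = education_levels())
  province <- factor(sample(names(params$province_probs), n, replace = TRUE,
                            prob = params$province_probs),
                     levels = sort(names(params$province_probs)))
  household_size <- sample(seq_along(params$household_size_probs), n,
                           replace = TRUE, prob = params$household_size_probs)

  height_mean <- ifelse(sex == "female", params$height_mean_female,
                        params$height_mean_male) +
    params$height_age_slope * (age - 45)
  true_height <- rnorm(n, height_mean, params$height_sd)
  true_weight <- params$weight_mean +
    params$weight_height_slope * (true_height - 170) +
    rnorm(n, 0, params$weight_sd)
  true_weight <- pmax(true_weight, 35)

  p_htn <- pmin(pmax(params$prevalence_hypertension +
                       params$age_gradient_hypertension * (age - mean(age)),
                     0.001), 0.999)
  if (params$prevalence_hypertension == 0) p_htn <- rep(0, n)
  if (params$prevalence_hypertension == 1) p_htn <- rep(1, n)
  true_htn <- rbinom(n, 1, p_htn)

  p_chol <- pmin(pmax(params$prevalence_hypercholesterolemia +
                        params$age_gradient_hypercholesterolemia * (age - mean(age)),
                      0.001), 0.999)
  if (params$prevalence_hypercholesterolemia == 0) p_chol <- rep(0, n)
  if (params$prevalence_hypercholesterolemia == 1) p_chol <- rep(1, n)
  true_chol_flag <- rbinom(n, 1, p_chol)

  # blood pressure / medication mixture consistent with the binary truth
  sbp <- rtruncnorm(n, 124, 10, upper = 139.9)
  dbp <- rtruncnorm(n, 78, 7, upper = 90)
  med <- integer(n)
  idx <- which(true_htn == 1)
  if (length(idx)) {
    mech <- sample(c("med", "sbp", "dbp"), length(idx), replace = TRUE,
                   prob = c(0.45, 0.40, 0.15))
    i_med <- idx[mech == "med"]
    med[i_med] <- 1L
    sbp[i_med] <- rnorm(length(i_med), 136, 11)
    dbp[i_med] <- rnorm(length(i_med), 82, 8)
    i_sbp <- idx[mech == "sbp"]
    sbp[i_sbp] <- 140 + rgamma(length(i_sbp), shape = 2, scale = 7)
    dbp[i_sbp] <- rnorm(length(i_sbp), 86, 7)
    i_dbp <- idx[mech == "dbp"]
    dbp[i_dbp] <- 90.5 + rgamma(length(i_dbp), shape = 2, scale = 3)
    sbp[i_dbp] <- rtruncnorm(length(i_dbp), 132, 6, upper = 139.9)
  }
  tchol <- ifelse(true_chol_flag == 1,
                  191 + rgamma(n, shape = 2.2, scale = 16),
                  rtruncnorm(n, 168, 16, upper = 190))

  out <- tibble::tibble(
    id = seq_len(n),
    age = as.numeric(age),
    sex = sex,
    education = education,
    province = province,
    household_size = as.numeric(household_size),
    wave_year = 2018L,
    true_height = true_height,
    true_weight = true_weight,
    true_sbp = sbp,
    true_dbp = dbp,
    true_htn_medication = med,
    true_total_cholesterol = tchol,
    true_hypertension = true_htn,
    true_hypercholesterolemia = true_chol_flag
  )
  ind <- derive_indicators(out$true_height, out$true_weight)
  out$true_bmi <- ind$bmi
  out$true_overweight <- ind$overweight
  out$true_obesity <- ind$obesity

  if (params$covariate_missingness > 0) {
    for (col in c("education", "household_size")) {
      miss <- runif(n) < params$covariate_missingness
      out[[col]][miss] <- NA
    }
  }
  out
}

#' Misclassify a binary truth vector at a given operating point
#'
#' Reported positive with probability `sensitivity` for truly affected
#' respondents and `1 - specificity` for unaffected ones, so the expected
#' reported prevalence is `sens * p + (1 - spec) * (1 - p)` for truth
#' prevalence `p`. Uses the active RNG stream.
#'
#' @param flag 0/1 truth vector (NA propagates).
#' @param sensitivity,specificity Operating point, in \[0, 1\].
#' @return Integer 0/1 vector of reported flags.
#' @export
misclassify_binary <- function(flag, sensitivity, specificity) {
  p_report <- ifelse(flag == 1, sensitivity, 1 - specificity)
  out <- rep(NA_integer_, length(flag))
  ok <- !is.na(flag)
  out[ok] <- rbinom(sum(ok), 1, p_report[ok])
  out
}

subgroup_bias <- function(data, bias) {
  edu <- bias$education[as.integer(data$education)]
  edu[is.na(edu)] <- 0
  sexshift <- ifelse(data$sex == "female", bias$female, bias$male)
  bias$base + sexshift + bias$per_year * (data$age - mean(data$age)) + edu
}

#' Apply the self-report error mechanism to a truth dataset
#'
#' Fills `sr_height`, `sr_weight`, `sr_hypertension` and
#' `sr_hypercholesterolemia` from the truth columns under the linear
#' flat-slope model and the binary misclassification model of
#' [error_params()]. With zero biases, unit slope, zero noise and perfect
#' operating points, self-reports equal truth exactly.
#'
#' @param data Output of [generate_truth()] (truth columns required).
#' @param params An [error_params()] object.
#' @param seed Integer seed.
#' @return `data` with the four `sr_*` columns added.
#' @export
apply_self_report_error <- function(data, params = error_params(), seed = 1L) {
  needed <- c("true_height", "true_weight", "true_hypertension",
              "true_hypercholesterolemia")
  if (!all(needed %in% names(data))) {
    abort(paste("missing truth columns:",
                paste(setdiff(needed, names(data)), collapse = ", ")),
          class = "surveymime_input_error")
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- nrow(data)
  b <- params$slope_attenuation

  ctr_h <- mean(data$true_height)
  data$sr_height <- ctr_h + b * (data$true_height - ctr_h) +
    subgroup_bias(data, params$height_bias) +
    rnorm(n, 0, params$noise_sd_height)
  ctr_w <- mean(data$true_weight)
  data$sr_weight <- ctr_w + b * (data$true_weight - ctr_w) +
    subgroup_bias(data, params$weight_bias) +
    rnorm(n, 0, params$noise_sd_weight)

  data$sr_hypertension <- misclassify_binary(
    data$true_hypertension, params$sens_hypertension, params$spec_hypertension)
  data$sr_hypercholesterolemia <- misclassify_binary(
    data$true_hypercholesterolemia, params$sens_hypercholesterolemia,
    params$spec_hypercholesterolemia)
  data
}

#' Select the examination validation subsample completely at random
#'
#' Draws `round(fraction * n)` respondents without replacement, independently
#' of every variable (MCAR), flags them with `in_validation`, and exposes the
#' objective measurements (`meas_height`, `meas_weight`, `meas_sbp`,
#' `meas_dbp`, `meas_htn_medication`, `meas_total_cholesterol`, plus the
#' derived binary `meas_hypertension`/`meas_hypercholesterolemia`) for those
#' respondents only; outside the subsample every measured field is `NA`.
#'
#' @param data Dataset with truth columns.
#' @param fraction Validation sampling fraction, in (0, 1).
#' @param seed Integer seed.
#' @return `data` with `in_validation` and the `meas_*` columns.
#' @export
select_validation <- function(data, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort("fraction must lie strictly inside (0, 1)",
          class = "surveymime_config_error")
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- nrow(data)
  n_val <- max(1L, round(fraction * n))
  chosen <- sample.int(n, n_val)
  data$in_validation <- FALSE
  data$in_validation[chosen] <- TRUE

  blank <- function(x) ifelse(data$in_validation, x, NA)
  data$meas_height <- blank(data$true_height)
  data$meas_weight <- blank(data$true_weight)
  data$meas_sbp <- blank(data$true_sbp)
  data$meas_dbp <- blank(data$true_dbp)
  data$meas_htn_medication <- blank(data$true_htn_medication)
  data$meas_total_cholesterol <- blank(data$true_total_cholesterol)
  ind <- derive_indicators(data$true_height, data$true_weight,
                           sbp = data$true_sbp, dbp = data$true_dbp,
                           htn_medication = data$true_htn_medication,
                           total_cholesterol = data$true_total_cholesterol)
  data$meas_hypertension <- as.integer(blank(ind$hypertension))
  data$meas_hypercholesterolemia <- as.integer(blank(ind$hypercholesterolemia))
  data
}

#' Assign strata, clusters and survey weights
#'
#' Strata are formed by grouping provinces into `n_strata` geographic strata;
#' each respondent is then placed in one of `clusters_per_stratum` primary
#' sampling units nested within its stratum, and given the positive weight
#' returned by the design's `weight_model`.
#'
#' @param data Respondent dataset (needs `province`, `household_size`).
#' @param params A [design_params()] object.
#' @param seed Integer seed (cluster assignment is random).
#' @return `data` with `stratum`, `cluster` and `weight` columns; clusters
#'   are labelled `"<stratum>:<psu>"` so labels are unique across strata.
#' @export
assign_design <- function(data, params = design_params(), seed = 1L) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- nrow(data)
  prov_idx <- as.integer(factor(as.character(data$province)))
  data$stratum <- ((prov_idx - 1L) %% params$n_strata) + 1L
  psu <- sample.int(params$clusters_per_stratum, n, replace = TRUE)
  data$cluster <- paste0(data$stratum, ":", psu)
  w <- params$weight_model(data)
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0)) {
    abort("weight_model must return a strictly positive weight per respondent",
          class = "surveymime_config_error")
  }
  data$weight <- w
  data
}

#' Simulate a full synthetic interview + examination survey
#'
#' One-call wrapper chaining [generate_truth()], [assign_design()],
#' [apply_self_report_error()] and [select_validation()]. The defaults mirror
#' the structure of a national health interview survey of 9,439 adults with
#' a 1,184-person random examination subsample.
#'
#' @param truth A [truth_params()] object.
#' @param error An [error_params()] object.
#' @param design A [design_params()] object.
#' @param seed Integer master seed; sub-stages use seeds derived from it.
#' @return A survey tibble with covariates, design variables, `sr_*`
#'   self-reports, `in_validation` and `meas_*` columns (NA outside the
#'   validation subsample), plus `true_*` truth columns retained for
#'   simulation studies.
#' @export
simulate_bhis <- function(truth = truth_params(), error = error_params(),
                          design = design_params(), seed = 1L) {
  seeds <- derive_seeds(seed, 4)
  data <- generate_truth(truth, seed = seeds[1])
  data <- assign_design(data, design, seed = seeds[2])
  data <- apply_self_report_error(data, error, seed = seeds[3])
  select_validation(data, design$validation_fraction, seed = seeds[4])
}

#' Write / read a survey dataset as CSV
#'
#' Absent measured values (respondents outside the validation subsample, or
#' item nonresponse) are encoded as empty fields. A JSON provenance sidecar
#' (`<path>.json`) records the seed and generator parameters when supplied.
#'
#' @param data Survey tibble.
#' @param path Output CSV path.
#' @param provenance Optional list (seed, parameters, ...) written as a JSON
#'   sidecar next to the CSV.
#' @return `path`, invisibly.
#' @export
write_survey <- function(data, path, provenance = NULL) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  if (!is.null(provenance)) {
    provenance$package_version <- as.character(utils::packageVersion("surveymime"))
    jsonlite::write_json(provenance, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  raw <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  out <- tibble::as_tibble(raw)
  if ("sex" %in% names(out)) {
    out$sex <- factor(out$sex, levels = c("male", "female"))
  }
  if ("education" %in% names(out)) {
    out$education <- factor(out$education, levels = education_levels())
  }
  if ("province" %in% names(out)) {
    out$province <- factor(out$province)
  }
  if ("in_validation" %in% names(out)) {
    out$in_validation <- as.logical(out$in_validation)
  }
  out
}

#' Simulate a survey from a YAML configuration file
#'
#' The YAML may override any argument of [truth_params()], [error_params()]
#' or [design_params()] under the keys `truth`, `error` and `design`, plus a
#' top-level `seed`. The dataset is written as CSV with a JSON provenance
#' sidecar recording the resolved configuration and seed.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_csv Output CSV path (`NULL` to skip writing).
#' @param seed Overrides the config seed when non-NULL.
#' @return The simulated survey tibble, invisibly when written to disk.
#' @export
simulate_from_config <- function(config, out_csv = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- seed %||% cfg$seed %||% 1L
  truth <- do.call(truth_params, cfg$truth %||% list())
  error <- do.call(error_params, cfg$error %||% list())
  design <- do.call(design_params, cfg$design %||% list())
  data <- simulate_bhis(truth, error, design, seed = seed)
  if (!is.null(out_csv)) {
    write_survey(data, out_csv,
                 provenance = list(seed = seed,
                                   config = cfg[setdiff(names(cfg), "seed")]))
    return(invisible(data))
  }
  data
}

#' @importFrom stats dnorm
NULL
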