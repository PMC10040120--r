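# Shared fixtures: reduced-scale synthetic surveys built in code.

small_survey <- function(n = 600, val_frac = 0.25, seed = 42,
                         error = error_params(), ...) {
  simulate_bhis(truth_params(n_respondents = n, ...), error,
                design_params(validation_fraction = val_frac), seed = seed)
}

# identity reporting: self-reports equal the truth exactly
zero_error_params <- function() {
  error_params(
    height_bias = list(base = 0, female = 0, male = 0, per_year = 0,
                       education = rep(0, 4)),
    weight_bias = list(base = 0, female = 0, male = 0, per_year = 0,
                       education = rep(0, 4)),
    slope_attenuation = 1, noise_sd_height = 0, noise_sd_weight = 0,
    sens_hypertension = 1, spec_hypertension = 1,
    sens_hypercholesterolemia = 1, spec_hypercholesterolemia = 1)
}

uniform_weights <- function(data) rep(1, nrow(data))

# minimal validation frame for calibration tests that need full control of
# the outcome-predictor relationship
synthetic_validation <- function(n, meas, sr, seed = 1) {
  set.seed(seed)
  out <- tibble::tibble(
    id = seq_len(n),
    in_validation = TRUE,
    age = runif(n, 18, 90),
    sex = factor(sample(c("male", "female"), n, TRUE),
                 levels = c("male", "female")),
    education = factor(sample(c("primary", "lower_secondary",
                                "higher_secondary", "higher"), n, TRUE),
                       levels = c("primary", "lower_secondary",
                                  "higher_secondary", "higher")))
  out[[sr]] <- numeric(n)
  out[[meas]] <- numeric(n)
  out
}
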