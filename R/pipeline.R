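# End-to-end orchestration: simulate (or read) -> validity report ->
# regression calibration -> chained imputation (parametric and RF) ->
# survey-weighted pooling -> method comparison and SE-ratio table.

#' Schema validation for survey datasets
#'
#' Checks column presence, types, plausible unit ranges and the
#' validation-subsample missingness pattern (measured values must be absent
#' for every respondent outside the validation subsample; missing measured
#' values inside it are tolerated as item nonresponse). Violations are
#' reported, never silently coerced.
#'
#' @param data Survey tibble.
#' @param columns Optional named mapping from canonical names to the
#'   dataset's column names (e.g. `c(weight = "wgt")`); canonical names are
#'   used when omitted.
#' @return Tibble of violations (`column`, `rule`, `n_rows`, `example_rows`);
#'   zero rows when the dataset is well formed.
#' @export
validate_schema <- function(data, columns = character(0)) {
  cname <- function(nm) if (nm %in% names(columns)) columns[[nm]] else nm
  viol <- list()
  add <- function(column, rule, rows) {
    if (length(rows)) {
      viol[[length(viol) + 1]] <<- tibble::tibble(
        column = column, rule = rule, n_rows = length(rows),
        example_rows = paste(head(rows, 5), collapse = ","))
    }
  }
  required <- c("id", "age", "sex", "education", "sr_height", "sr_weight",
                "sr_hypertension", "sr_hypercholesterolemia", "in_validation")
  for (nm in required) {
    if (!cname(nm) %in% names(data)) add(cname(nm), "column missing", 0:0)
  }
  if (nrow(dplyr::bind_rows(viol))) return(dplyr::bind_rows(viol))

  check_range <- function(nm, lo, hi) {
    col <- data[[cname(nm)]]
    add(cname(nm), sprintf("outside (%s, %s)", lo, hi),
        which(!is.na(col) & (col <= lo | col >= hi)))
  }
  check_binary <- function(nm) {
    col <- data[[cname(nm)]]
    add(cname(nm), "not 0/1", which(!is.na(col) & !(col %in% c(0, 1))))
  }
  check_range("sr_height", 100, 250)
  check_range("sr_weight", 25, 300)
  if (cname("meas_height") %in% names(data)) check_range("meas_height", 100, 250)
  if (cname("meas_weight") %in% names(data)) check_range("meas_weight", 25, 300)
  check_binary("sr_hypertension")
  check_binary("sr_hypercholesterolemia")
  if (cname("weight") %in% names(data)) {
    w <- data[[cname("weight")]]
    add(cname("weight"), "non-positive weight", which(!is.na(w) & w <= 0))
    add(cname("weight"), "missing weight", which(is.na(w)))
  }
  inval <- as.logical(data[[cname("in_validation")]])
  for (nm in c("meas_height", "meas_weight", "meas_sbp", "meas_dbp",
               "meas_htn_medication", "meas_total_cholesterol",
               "meas_hypertension", "meas_hypercholesterolemia")) {
    if (!cname(nm) %in% names(data)) next
    col <- data[[cname(nm)]]
    add(cname(nm), "measured value present outside validation subsample",
        which(!inval & !is.na(col)))
  }
  res <- dplyr::bind_rows(viol)
  if (!nrow(res)) {
    res <- tibble::tibble(column = character(0), rule = character(0),
                          n_rows = integer(0), example_rows = character(0))
  }
  res
}

#' Reduced-scale run profile
#'
#' A named configuration for fast end-to-end runs: 2,000 respondents with a
#' 300-person validation subsample, 5 imputations, 10 chained iterations and
#' 20 trees. Used throughout the package's simulation studies.
#'
#' @param n_respondents,n_validation,m,n_iterations,n_trees Overrides.
#' @return A config list accepted by [run_pipeline()].
#' @export
reduced_profile <- function(n_respondents = 2000, n_validation = 300,
                            m = 5, n_iterations = 10, n_trees = 20) {
  list(
    generator = list(
      truth = list(n_respondents = n_respondents),
      design = list(validation_fraction = n_validation / n_respondents)
    ),
    imputation = list(m = m, n_iterations = n_iterations, n_trees = n_trees)
  )
}

pipeline_indicators <- function() {
  c("overweight", "obesity", "hypertension", "hypercholesterolemia")
}

truth_prevalence <- function(data, design) {
  d <- data
  d$overweight <- d$true_overweight
  d$obesity <- d$true_obesity
  d$hypertension <- d$true_hypertension
  d$hypercholesterolemia <- d$true_hypercholesterolemia
  dplyr::bind_rows(lapply(pipeline_indicators(),
                          function(i) weighted_prevalence(d, i, design)))
}

bmi_summary <- function(x, method) {
  x <- x[!is.na(x)]
  tibble::tibble(method = method, mean = mean(x), sd = sd(x),
                 q25 = unname(quantile(x, 0.25)),
                 median = stats::median(x),
                 q75 = unname(quantile(x, 0.75)))
}

#' Run the full measurement-error-correction pipeline
#'
#' From one configuration: obtain the data (a CSV path or generator
#' parameters), validate its schema, compute the step-1 validity report on
#' the validation subsample, then estimate the four indicator prevalences by
#' every requested correction method — regression calibration, parametric
#' chained imputation (PMM + logistic) and random-forest chained imputation —
#' alongside the naive self-reported and validation-only estimates, pool the
#' imputation runs by Rubin's rules, and assemble the method-comparison and
#' SE-ratio tables plus per-method BMI distribution summaries.
#'
#' @param config A list (or YAML path) with optional entries `input` (CSV
#'   path), `generator` (`truth`/`error`/`design` parameter overrides),
#'   `methods` (subset of `"calibration"`, `"mice-parametric"`, `"mice-rf"`,
#'   or `"all"`), `imputation` (`m`, `n_iterations`, `n_trees`,
#'   `pmm_donors`, `predictors`), `design` (column mapping for
#'   strata/cluster/weight), `seed`, `output_dir`, `verbose`.
#' @param seed Overrides the config seed when non-NULL.
#' @return A list of class `mime_pipeline`: `data`, `schema_violations`,
#'   `validity`, `models` (calibration fits), `completed` (completed sets
#'   per engine), `estimates` (long method x indicator table),
#'   `se_ratios`, `convergence`, `bmi` and `manifest`.
#' @export
run_pipeline <- function(config = list(), seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- seed %||% cfg$seed %||% 1L
  verbose <- isTRUE(cfg$verbose)
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(cfg$input) && !is.null(cfg$generator)) {
    abort("config must name exactly one input source (input or generator)",
          class = "surveymime_config_error")
  }
  methods <- cfg$methods %||% "all"
  if ("all" %in% methods) {
    methods <- c("calibration", "mice-parametric", "mice-rf")
  }
  seeds <- derive_seeds(seed, 6)

  t0 <- Sys.time()
  if (!is.null(cfg$input)) {
    data <- read_survey(cfg$input)
  } else {
    gen <- cfg$generator %||% list()
    data <- simulate_bhis(
      truth = do.call(truth_params, gen$truth %||% list()),
      error = do.call(error_params, gen$error %||% list()),
      design = do.call(design_params, gen$design %||% list()),
      seed = seeds[1])
  }
  violations <- validate_schema(data, cfg$design_columns %||% character(0))
  if (nrow(violations)) {
    abort(paste0("schema violations:\n",
                 paste(utils::capture.output(print(violations)),
                       collapse = "\n")),
          class = "surveymime_input_error")
  }
  dcfg <- cfg$design %||% list()
  design <- survey_design(strata = dcfg$strata %||% "stratum",
                          cluster = dcfg$cluster %||% "cluster",
                          weight = dcfg$weight %||% "weight")
  say("data ready (n = %d) [%.1fs]", nrow(data),
      as.numeric(Sys.time() - t0, units = "secs"))

  validity <- validity_report(data)

  icfg <- cfg$imputation %||% list()
  est <- list()
  collect <- function(method, tab) {
    dplyr::bind_cols(tibble::tibble(method = method), tab)
  }
  sr <- self_report_prevalence(data, design)
  vo <- validation_prevalence(data, design)
  est$self_report <- collect("self_report",
                             dplyr::select(sr, "indicator", "estimate", "se"))
  est$validation <- collect("validation",
                            dplyr::select(vo, "indicator", "estimate", "se"))
  if (all(c("true_overweight", "true_hypertension") %in% names(data))) {
    tr <- truth_prevalence(data, design)
    est$truth <- collect("truth",
                         dplyr::select(tr, "indicator", "estimate", "se"))
  }

  models <- NULL
  completed <- list()
  conv <- list()
  ratios <- list()
  bmis <- list(
    bmi_summary(derive_indicators(data$sr_height, data$sr_weight)$bmi,
                "self_report"),
    bmi_summary(derive_indicators(data$meas_height[data$in_validation],
                                  data$meas_weight[data$in_validation])$bmi,
                "validation"))

  if ("calibration" %in% methods) {
    t0 <- Sys.time()
    models <- lapply(setNames(nm = c("height", "weight", "hypertension",
                                     "hypercholesterolemia")),
                     function(o) fit_calibration(data, o, seed = seeds[2]))
    calp <- calibrated_prevalence(data, models, design,
                                  se_method = "propagate", seed = seeds[3])
    est$calibration <- collect("calibration",
                               dplyr::select(calp, "indicator", "estimate",
                                             se = "design_se"))
    ratios$calibration <- dplyr::mutate(
      se_ratio(vo, dplyr::select(calp, "indicator", "se")),
      method = "calibration")
    cal <- calibrate_dataset(data, models)
    bmis <- c(bmis, list(bmi_summary(cal$bmi_cal, "calibration")))
    say("calibration done [%.1fs]", as.numeric(Sys.time() - t0, units = "secs"))
  }

  run_engine <- function(engine, label, seed_i) {
    t0 <- Sys.time()
    spec <- imputation_spec(
      data, engine = engine,
      predictors = icfg$predictors %||% list(),
      m = icfg$m %||% 10,
      n_iterations = icfg$n_iterations %||% 100,
      n_trees = icfg$n_trees %||% 100,
      pmm_donors = icfg$pmm_donors %||% 5,
      seed = seed_i)
    cs <- run_chained(data, spec)
    pooled <- analyze_completed(cs, pipeline_indicators(), design)
    est[[label]] <<- collect(label, dplyr::select(pooled, "indicator",
                                                  estimate = "qbar", "se"))
    ratios[[label]] <<- dplyr::mutate(se_ratio(vo, pooled), method = label)
    conv[[label]] <<- dplyr::mutate(
      convergence_summary(cs, window = min(5, spec$n_iterations)),
      method = label)
    completed[[label]] <<- cs
    bmis <<- c(bmis, list(bmi_summary(cs$imputations[[1]]$bmi, label)))
    say("%s done [%.1fs]", label, as.numeric(Sys.time() - t0, units = "secs"))
  }
  if ("mice-parametric" %in% methods) {
    run_engine("parametric", "mice_parametric", seeds[4])
  }
  if ("mice-rf" %in% methods) run_engine("rf", "mice_rf", seeds[5])

  out <- list(
    data = data,
    schema_violations = violations,
    validity = validity,
    models = models,
    completed = completed,
    estimates = dplyr::bind_rows(est),
    se_ratios = dplyr::bind_rows(ratios),
    convergence = dplyr::bind_rows(conv),
    bmi = dplyr::bind_rows(bmis),
    manifest = list(
      seed = seed, methods = methods,
      config = cfg[setdiff(names(cfg), c("seed", "verbose"))],
      package_version = as.character(utils::packageVersion("surveymime")),
      r_version = R.version.string)
  )
  class(out) <- "mime_pipeline"
  if (!is.null(cfg$output_dir)) write_pipeline(out, cfg$output_dir)
  out
}

#' @export
print.mime_pipeline <- function(x, ...) {
  cat("<mime_pipeline> n =", nrow(x$data), "| methods:",
      paste(unique(x$estimates$method), collapse = ", "), "\n\n")
  print(tidyr::pivot_wider(
    dplyr::select(x$estimates, "method", "indicator", "estimate"),
    names_from = "indicator", values_from = "estimate"))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Estimates, SE ratios, convergence and BMI tables as CSV, plus a JSON
#' manifest recording the seed, configuration and package version, so every
#' output is reproducible from the manifest alone. The input data file is
#' never modified.
#'
#' @param result A `mime_pipeline` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, nm) utils::write.csv(df, file.path(dir, nm),
                                          row.names = FALSE, na = "")
  wr(result$estimates, "estimates.csv")
  wr(result$se_ratios, "se_ratios.csv")
  if (nrow(result$convergence %||% tibble::tibble())) {
    wr(result$convergence, "convergence.csv")
  }
  wr(result$bmi, "bmi_summary.csv")
  wr(result$validity$continuous, "validity_continuous.csv")
  wr(result$validity$binary, "validity_binary.csv")
  wr(result$validity$icc, "validity_icc.csv")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
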