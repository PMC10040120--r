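# Survey-weighted prevalence with Taylor-linearized design variance
# (with-replacement sampling of clusters within strata), Rubin's-rules
# pooling across completed datasets with Barnard-Rubin degrees of freedom,
# relative efficiency, and validation-only vs adjusted SE-ratio reporting.

#' Describe the survey design columns of a dataset
#'
#' @param strata,cluster,weight Column names of the design variables; use
#'   `NULL` for designs without explicit strata or clusters (each respondent
#'   is then its own primary sampling unit).
#' @param single_cluster Policy when a stratum contains a single cluster:
#'   `"collapse"` merges it into the adjacent stratum with a warning,
#'   `"error"` aborts.
#' @return An object of class `survey_design_spec`.
#' @export
survey_design <- function(strata = "stratum", cluster = "cluster",
                          weight = "weight",
                          single_cluster = c("collapse", "error")) {
  structure(list(strata = strata, cluster = cluster, weight = weight,
                 single_cluster = match.arg(single_cluster)),
            class = "survey_design_spec")
}

design_columns <- function(data, design) {
  n <- nrow(data)
  w <- if (!is.null(design$weight) && design$weight %in% names(data)) {
    data[[design$weight]]
  } else {
    rep(1, n)
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    abort("survey weights must be strictly positive",
          class = "surveymime_input_error")
  }
  s <- if (!is.null(design$strata) && design$strata %in% names(data)) {
    as.character(data[[design$strata]])
  } else {
    rep("1", n)
  }
  cl <- if (!is.null(design$cluster) && design$cluster %in% names(data)) {
    as.character(data[[design$cluster]])
  } else {
    as.character(seq_len(n))
  }
  list(w = w, strata = s, cluster = cl)
}

# ratio estimate sum(w y)/sum(w) and its Taylor-linearized variance under
# with-replacement sampling of clusters within strata
weighted_value_estimate <- function(data, y, design = survey_design()) {
  dc <- design_columns(data, design)
  ok <- !is.na(y)
  y <- y[ok]
  w <- dc$w[ok]
  strata <- dc$strata[ok]
  cluster <- dc$cluster[ok]
  if (!length(y)) abort("no non-missing values", class = "surveymime_input_error")
  sw <- sum(w)
  p <- sum(w * y) / sw
  u <- w * (y - p) / sw

  key <- paste(strata, cluster, sep = "\r")
  t_c <- tapply(u, key, sum)
  s_of <- vapply(strsplit(names(t_c), "\r", fixed = TRUE), `[`, character(1), 1)
  n_h <- table(s_of)
  # collapse policy: strata holding one cluster are merged into the previous
  # stratum (first into the next) so a between-cluster contrast exists
  if (any(n_h < 2)) {
    if (length(n_h) == 1 || sum(n_h) == length(n_h)) {
      # degenerate: every cluster is a singleton stratum, or one cluster in
      # total; treat respondents as independent PSUs in one stratum (SRS)
      s_of <- rep("1", length(t_c))
      if (sum(n_h) == 1) {
        t_c <- u
        s_of <- rep("1", length(u))
      }
    } else {
      lev <- sort(unique(s_of))
      singletons <- names(n_h)[n_h < 2]
      if (identical(survey_single_cluster(design), "error")) {
        abort(paste("strata with a single cluster:",
                    paste(singletons, collapse = ", ")),
              class = "surveymime_input_error")
      }
      warn(paste("collapsing single-cluster strata:",
                 paste(singletons, collapse = ", ")))
      map <- setNames(lev, lev)
      for (s1 in singletons) {
        i <- match(s1, lev)
        target <- if (i > 1) lev[i - 1] else lev[i + 1]
        map[s1] <- map[target]
      }
      s_of <- unname(map[s_of])
    }
  }
  v <- 0
  for (h in unique(s_of)) {
    th <- t_c[s_of == h]
    nh <- length(th)
    if (nh < 2) next
    v <- v + nh / (nh - 1) * sum((th - mean(th))^2)
  }
  list(estimate = p, variance = v, n = length(y),
       n_clusters = length(t_c), n_strata = length(unique(s_of)))
}

survey_single_cluster <- function(design) design$single_cluster %||% "collapse"

#' Survey-weighted prevalence of a binary indicator
#'
#' Computes the ratio estimate `sum(w_i y_i) / sum(w_i)` and its
#' Taylor-linearized variance under with-replacement sampling of clusters
#' within strata. With equal weights and independent respondents this
#' reduces to the simple-random-sampling form `p (1 - p) / (n - 1)`.
#'
#' @param data Tibble containing the indicator and the design columns.
#' @param indicator Column name of the (binary or numeric) analysis variable.
#' @param design A [survey_design()] specification.
#' @return One-row tibble: `indicator`, `estimate`, `se`, `variance`, `n`,
#'   `n_clusters`, `df` (clusters minus strata).
#' @export
weighted_prevalence <- function(data, indicator, design = survey_design()) {
  if (!indicator %in% names(data)) {
    abort(paste("indicator column not found:", indicator),
          class = "surveymime_input_error")
  }
  est <- weighted_value_estimate(data, as.numeric(data[[indicator]]), design)
  tibble::tibble(indicator = indicator, estimate = est$estimate,
                 se = sqrt(est$variance), variance = est$variance,
                 n = est$n, n_clusters = est$n_clusters,
                 df = max(1, est$n_clusters - est$n_strata))
}

#' Pool estimates across completed datasets by Rubin's rules
#'
#' Combines `m` point estimates and their complete-data variances: pooled
#' point `Qbar` = mean of the estimates, within-imputation variance `W` =
#' mean variance, between-imputation variance `B` = sample variance of the
#' estimates, total variance `T = W + (1 + 1/m) B`. The fraction of missing
#' information is `gamma = (1 + 1/m) B / T`, the relative efficiency of `m`
#' imputations is `1 / (1 + gamma / m)`, and degrees of freedom use the
#' Barnard-Rubin small-sample adjustment given the complete-data degrees of
#' freedom `nu_com` (design-based: clusters minus strata; `Inf` recovers the
#' classic Rubin df).
#'
#' @param estimates Numeric vector of the m per-imputation estimates.
#' @param variances Numeric vector of the m complete-data variances.
#' @param nu_com Complete-data degrees of freedom.
#' @param conf_level Confidence level of the pooled interval.
#' @return One-row tibble of class `pooled_estimate`: `qbar`, `within_var`,
#'   `between_var`, `total_var`, `se`, `df`, `fmi`, `relative_efficiency`,
#'   `ci_lo`, `ci_hi`, `m`.
#' @export
rubin_pool <- function(estimates, variances, nu_com = Inf, conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2 || length(variances) != m) {
    abort("need m >= 2 estimates with matching variances",
          class = "surveymime_input_error")
  }
  if (any(variances < 0)) {
    abort("variances must be >= 0", class = "surveymime_input_error")
  }
  qbar <- mean(estimates)
  wbar <- mean(variances)
  b <- var(estimates)
  tv <- wbar + (1 + 1 / m) * b
  gamma <- if (tv > 0) (1 + 1 / m) * b / tv else 0
  re <- 1 / (1 + gamma / m)
  if (b == 0 || gamma == 0) {
    df <- Inf
  } else {
    nu_old <- (m - 1) / gamma^2
    df <- if (is.finite(nu_com)) {
      nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - gamma)
      1 / (1 / nu_old + 1 / nu_obs)
    } else {
      nu_old
    }
  }
  se <- sqrt(tv)
  tq <- if (is.finite(df)) qt(1 - (1 - conf_level) / 2, df) else
    qnorm(1 - (1 - conf_level) / 2)
  tibble::new_tibble(tibble::tibble(
    qbar = qbar, within_var = wbar, between_var = b, total_var = tv,
    se = se, df = df, fmi = gamma, relative_efficiency = re,
    ci_lo = qbar - tq * se, ci_hi = qbar + tq * se, m = m
  ), class = "pooled_estimate")
}

#' Pooled survey-weighted prevalences from a completed set
#'
#' Runs [weighted_prevalence()] for each indicator on every completed copy
#' and combines the per-copy estimates by [rubin_pool()], using the design's
#' clusters-minus-strata as the complete-data degrees of freedom.
#'
#' @param completed A `completed_set` from [run_chained()], or a plain list
#'   of completed tibbles.
#' @param indicators Character vector of indicator columns present in every
#'   completed copy.
#' @param design A [survey_design()] specification.
#' @param conf_level Confidence level for pooled intervals.
#' @return Tibble with one `pooled_estimate` row per indicator (column
#'   `indicator` first).
#' @export
analyze_completed <- function(completed,
                              indicators = c("overweight", "obesity",
                                             "hypertension",
                                             "hypercholesterolemia"),
                              design = survey_design(), conf_level = 0.95) {
  copies <- if (inherits(completed, "completed_set")) completed$imputations
            else completed
  if (length(copies) < 2) {
    abort("need a completed set with m >= 2", class = "surveymime_input_error")
  }
  out <- lapply(indicators, function(ind) {
    per <- lapply(copies, function(d) {
      if (!ind %in% names(d)) {
        abort(paste("indicator absent from a completed copy:", ind),
              class = "surveymime_input_error")
      }
      weighted_prevalence(d, ind, design)
    })
    ests <- vapply(per, function(x) x$estimate, numeric(1))
    vars <- vapply(per, function(x) x$variance, numeric(1))
    nu_com <- stats::median(vapply(per, function(x) x$df, numeric(1)))
    pooled <- rubin_pool(ests, vars, nu_com = nu_com, conf_level = conf_level)
    dplyr::bind_cols(tibble::tibble(indicator = ind), pooled)
  })
  dplyr::bind_rows(out)
}

#' Ratio of validation-only to adjusted standard errors
#'
#' The diagnostic behind method comparison: how much smaller (ratio > 1) or
#' larger (ratio < 1) the corrected full-sample standard error is than the
#' design-based standard error obtained from the validation subsample alone.
#'
#' @param validation_only Tibble with columns `indicator` and `se` from the
#'   validation-subsample-only analysis.
#' @param adjusted Tibble with columns `indicator` and `se` from the
#'   corrected full-sample analysis (pooled MI or calibration).
#' @return Tibble `indicator`, `se_validation_only`, `se_adjusted`, `ratio`
#'   (`NA` when the adjusted SE is zero).
#' @export
se_ratio <- function(validation_only, adjusted) {
  merged <- dplyr::inner_join(
    dplyr::select(validation_only, "indicator", se_validation_only = "se"),
    dplyr::select(adjusted, "indicator", se_adjusted = "se"),
    by = "indicator")
  dplyr::mutate(merged,
                ratio = ifelse(.data$se_adjusted > 0,
                               .data$se_validation_only / .data$se_adjusted,
                               NA_real_))
}

#' Self-reported and validation-only prevalence tables
#'
#' `self_report_prevalence()` derives the four indicators from the
#' self-reported columns of the full survey and estimates them with the
#' design; `validation_prevalence()` does the same from the measured columns
#' of the validation subsample only.
#'
#' @param data Survey tibble.
#' @param design A [survey_design()] specification.
#' @param indicators Indicators to estimate.
#' @return Tibble with `indicator`, `estimate`, `se`, `variance`, `n`, ...
#' @export
self_report_prevalence <- function(data, design = survey_design(),
                                   indicators = c("overweight", "obesity",
                                                  "hypertension",
                                                  "hypercholesterolemia")) {
  ind <- derive_indicators(data$sr_height, data$sr_weight)
  d <- data
  d$overweight <- ind$overweight
  d$obesity <- ind$obesity
  d$hypertension <- data$sr_hypertension
  d$hypercholesterolemia <- data$sr_hypercholesterolemia
  dplyr::bind_rows(lapply(indicators, function(i) weighted_prevalence(d, i, design)))
}

#' @rdname self_report_prevalence
#' @export
validation_prevalence <- function(data, design = survey_design(),
                                  indicators = c("overweight", "obesity",
                                                 "hypertension",
                                                 "hypercholesterolemia")) {
  val <- dplyr::filter(data, .data$in_validation)
  ind <- derive_indicators(val$meas_height, val$meas_weight)
  d <- val
  d$overweight <- ind$overweight
  d$obesity <- ind$obesity
  d$hypertension <- val$meas_hypertension
  d$hypercholesterolemia <- val$meas_hypercholesterolemia
  dplyr::bind_rows(lapply(indicators, function(i) weighted_prevalence(d, i, design)))
}
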