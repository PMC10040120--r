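# Step-1 agreement analysis between self-reported and measured values on the
# validation subsample: Bland-Altman limits of agreement, paired t, ICC,
# confusion-matrix accuracy, kappa and McNemar, optionally survey-weighted
# and stratified by age band / sex / education.

# Frequency-consistent weighted variance: reduces to the n-1 sample variance
# under equal weights and is invariant to rescaling all weights.
weighted_var <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  sum(w * (x - m)^2) / (sw - sum(w^2) / sw)
}

#' Bland-Altman agreement between self-reported and measured values
#'
#' Computes the (optionally survey-weighted) mean difference between paired
#' self-reported and measured values, and the limits of agreement defined as
#' the mean difference plus and minus 1.96 times the SD of the differences.
#' 95% confidence intervals use the paired-t machinery with the effective
#' sample size `(sum w)^2 / sum(w^2)` when weights are supplied.
#'
#' @param self_vals,meas_vals Paired numeric vectors (self-reported first;
#'   differences are self minus measured).
#' @param weights Optional positive survey weights; statistics are invariant
#'   to rescaling all weights by a constant.
#' @param conf_level Confidence level for the intervals.
#' @param label Optional stratum label carried into the output.
#'
#' @return A one-row tibble of class `agreement_report`: `mean_diff`,
#'   `mean_diff_lo/hi`, `sd_diff`, `loa_lower`, `loa_upper` with their CIs,
#'   `n_pairs`, `stratum`.
#'
#' @examples
#' bland_altman(c(1, 3, 5), c(3, 3, 3))
#'
#' @export
bland_altman <- function(self_vals, meas_vals, weights = NULL,
                         conf_level = 0.95, label = "all") {
  ok <- complete.cases(self_vals, meas_vals,
                       if (is.null(weights)) rep(0, length(self_vals)) else weights)
  d <- (self_vals - meas_vals)[ok]
  n <- length(d)
  if (n < 2) abort("need at least 2 complete pairs",
                   class = "surveymime_input_error")
  w <- if (is.null(weights)) rep(1, n) else weights[ok]
  if (any(w <= 0) || sum(w) == 0) {
    abort("weights must be strictly positive", class = "surveymime_input_error")
  }
  md <- sum(w * d) / sum(w)
  s <- sqrt(weighted_var(d, w))
  n_eff <- sum(w)^2 / sum(w^2)
  se_md <- s / sqrt(n_eff)
  tq <- qt(1 - (1 - conf_level) / 2, n - 1)
  # the conventional 1.96 multiplier at the default level
  z <- round(qnorm(1 - (1 - conf_level) / 2), 2)
  # SE of a limit of agreement (Bland & Altman's large-sample formula)
  se_loa <- s * sqrt(1 / n_eff + z^2 / (2 * (n - 1)))
  tibble::new_tibble(tibble::tibble(
    stratum = label,
    n_pairs = n,
    mean_diff = md,
    mean_diff_lo = md - tq * se_md,
    mean_diff_hi = md + tq * se_md,
    sd_diff = s,
    loa_lower = md - z * s,
    loa_lower_lo = md - z * s - tq * se_loa,
    loa_lower_hi = md - z * s + tq * se_loa,
    loa_upper = md + z * s,
    loa_upper_lo = md + z * s - tq * se_loa,
    loa_upper_hi = md + z * s + tq * se_loa
  ), class = "agreement_report")
}

#' Paired t test of the mean self-reported minus measured difference
#'
#' Thin wrapper around [stats::t.test()] on the paired differences, returning
#' a tidy one-row tibble. Zero-variance differences are flagged as degenerate
#' rather than producing a p-value.
#'
#' @inheritParams bland_altman
#' @return Tibble with `estimate`, `statistic`, `p_value`, `conf_lo`,
#'   `conf_hi`, `df`, `degenerate`.
#' @export
paired_mean_difference_test <- function(self_vals, meas_vals,
                                        conf_level = 0.95) {
  ok <- complete.cases(self_vals, meas_vals)
  d <- (self_vals - meas_vals)[ok]
  if (length(d) < 2) abort("need at least 2 complete pairs",
                           class = "surveymime_input_error")
  if (sd(d) == 0) {
    return(tibble::tibble(estimate = mean(d), statistic = NA_real_,
                          p_value = NA_real_, conf_lo = NA_real_,
                          conf_hi = NA_real_, df = NA_real_,
                          degenerate = TRUE))
  }
  tt <- t.test(d, conf.level = conf_level)
  tibble::tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
                 p_value = tt$p.value, conf_lo = tt$conf.int[1],
                 conf_hi = tt$conf.int[2], df = unname(tt$parameter),
                 degenerate = FALSE)
}

#' Intraclass correlation for absolute agreement of paired measurements
#'
#' Two-way absolute-agreement single-measure ICC (McGraw & Wong's ICC(A,1))
#' from the subject x rater ANOVA decomposition, with the F-based confidence
#' interval. Absolute agreement (rather than consistency) is used so that a
#' systematic self-report bias lowers the coefficient.
#'
#' @inheritParams bland_altman
#' @return Tibble with `icc`, `icc_lo`, `icc_hi`, `n_pairs`, `degenerate`.
#' @export
icc_agreement <- function(self_vals, meas_vals, conf_level = 0.95) {
  ok <- complete.cases(self_vals, meas_vals)
  y <- cbind(self_vals[ok], meas_vals[ok])
  n <- nrow(y)
  k <- 2
  if (n < 3) abort("need at least 3 complete pairs",
                   class = "surveymime_input_error")
  g <- mean(y)
  if (all(y == y[1])) {
    return(tibble::tibble(icc = NA_real_, icc_lo = NA_real_,
                          icc_hi = NA_real_, n_pairs = n, degenerate = TRUE))
  }
  ri <- rowMeans(y)
  cj <- colMeans(y)
  ssr <- k * sum((ri - g)^2)
  ssc <- n * sum((cj - g)^2)
  sst <- sum((y - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  tibble::tibble(icc = icc, icc_lo = lo, icc_hi = hi, n_pairs = n,
                 degenerate = FALSE)
}

#' Cohen's kappa for a k-level agreement table
#'
#' Unweighted (nominal) kappa: `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o` and chance agreement `p_e` from the table margins.
#'
#' @param x,y Paired categorical vectors (any common coding).
#' @return Scalar kappa; `NA` when chance agreement is 1.
#' @export
kappa_agreement <- function(x, y) {
  ok <- complete.cases(x, y)
  lev <- union(unique(x[ok]), unique(y[ok]))
  tab <- table(factor(x[ok], levels = lev), factor(y[ok], levels = lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Diagnostic accuracy of a self-reported flag against measured truth
#'
#' Cross-tabulates paired binary vectors into (optionally survey-weighted)
#' true/false positive/negative counts and derives sensitivity, specificity,
#' PPV, NPV and the self-reported and measured prevalences from the weighted
#' table. Cohen's kappa and McNemar's test use the unweighted table (the
#' McNemar statistic is `(b - c)^2 / (b + c)` on the discordant counts).
#' Metrics with an empty margin are reported as `NA` ("undefined"), never 0.
#'
#' @param self_flag,meas_flag Paired 0/1 vectors (self-reported, measured).
#' @param weights Optional positive survey weights.
#' @param label Optional stratum label carried into the output.
#' @return One-row tibble of class `confusion_summary` with the weighted
#'   counts (`tp`, `fp`, `fn`, `tn`), accuracy metrics, `kappa`,
#'   `mcnemar_stat`, `mcnemar_p`, prevalences and `n_pairs`.
#' @export
confusion <- function(self_flag, meas_flag, weights = NULL, label = "all") {
  ok <- complete.cases(self_flag, meas_flag,
                       if (is.null(weights)) rep(0, length(self_flag)) else weights)
  s <- as.integer(self_flag[ok])
  m <- as.integer(meas_flag[ok])
  w <- if (is.null(weights)) rep(1, sum(ok)) else weights[ok]
  if (any(w <= 0)) abort("weights must be strictly positive",
                         class = "surveymime_input_error")
  tp <- sum(w[s == 1 & m == 1])
  fp <- sum(w[s == 1 & m == 0])
  fn <- sum(w[s == 0 & m == 1])
  tn <- sum(w[s == 0 & m == 0])
  total <- tp + fp + fn + tn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_

  b <- sum(s == 1 & m == 0)
  cc <- sum(s == 0 & m == 1)
  if (b + cc > 0) {
    mcn <- (b - cc)^2 / (b + cc)
    mcn_p <- 1 - stats::pchisq(mcn, df = 1)
  } else {
    mcn <- 0
    mcn_p <- 1
  }
  tibble::new_tibble(tibble::tibble(
    stratum = label,
    n_pairs = length(s),
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    kappa = kappa_agreement(s, m),
    mcnemar_stat = mcn,
    mcnemar_p = mcn_p,
    prevalence_sr = ratio(tp + fp, total),
    prevalence_meas = ratio(tp + fn, total)
  ), class = "confusion_summary")
}

age_band <- function(age) {
  cut(age, breaks = c(-Inf, 24, 44, 64, Inf),
      labels = c("18-24", "25-44", "45-64", "65+"))
}

sr_meas_pair <- function(data, variable) {
  v <- data
  switch(variable,
    height = list(self = v$sr_height, meas = v$meas_height, type = "continuous"),
    weight = list(self = v$sr_weight, meas = v$meas_weight, type = "continuous"),
    bmi = {
      sr <- derive_indicators(v$sr_height, v$sr_weight)
      ms <- derive_indicators(v$meas_height, v$meas_weight)
      list(self = sr$bmi, meas = ms$bmi, type = "continuous")
    },
    overweight = ,
    obesity = {
      sr <- derive_indicators(v$sr_height, v$sr_weight)
      ms <- derive_indicators(v$meas_height, v$meas_weight)
      list(self = sr[[variable]], meas = ms[[variable]], type = "binary")
    },
    hypertension = list(self = v$sr_hypertension, meas = v$meas_hypertension,
                        type = "binary"),
    hypercholesterolemia = list(self = v$sr_hypercholesterolemia,
                                meas = v$meas_hypercholesterolemia,
                                type = "binary"),
    abort(paste("unknown validity variable:", variable),
          class = "surveymime_input_error")
  )
}

#' Stratified validity report for one indicator
#'
#' Computes the whole-population agreement report plus one report per level
#' of a stratifying variable (`age_band`, `sex` or `education`), on the
#' validation subsample. Continuous indicators (`height`, `weight`, `bmi`)
#' get Bland-Altman reports; binary indicators (`overweight`, `obesity`,
#' `hypertension`, `hypercholesterolemia`) get confusion summaries. Strata
#' with fewer pairs than `min_n` are flagged (`small_stratum`). Survey
#' weights (column `weight`) are used when present and `weighted = TRUE`.
#'
#' @param data Survey tibble (needs the `sr_*`/`meas_*` columns and
#'   `in_validation`).
#' @param variable One of `"height"`, `"weight"`, `"bmi"`, `"overweight"`,
#'   `"obesity"`, `"hypertension"`, `"hypercholesterolemia"`.
#' @param strata `NULL` for the whole population only, or one of
#'   `"age_band"`, `"sex"`, `"education"`.
#' @param weighted Use the `weight` column when available.
#' @param min_n Minimum pairs per stratum before flagging.
#' @return Tibble with one row per stratum level plus an `"all"` row.
#' @export
stratified_validity <- function(data, variable, strata = NULL,
                                weighted = TRUE, min_n = 30) {
  val <- dplyr::filter(data, .data$in_validation)
  pair <- sr_meas_pair(val, variable)
  w <- if (weighted && "weight" %in% names(val)) val$weight else NULL
  fun <- if (pair$type == "continuous") {
    function(i, lab) bland_altman(pair$self[i], pair$meas[i],
                                  weights = w[i], label = lab)
  } else {
    function(i, lab) confusion(pair$self[i], pair$meas[i],
                               weights = w[i], label = lab)
  }
  out <- list(fun(seq_len(nrow(val)), "all"))
  if (!is.null(strata)) {
    g <- switch(strata,
      age_band = age_band(val$age),
      sex = val$sex,
      education = val$education,
      abort(paste("unknown stratum variable:", strata),
            class = "surveymime_input_error"))
    for (lev in levels(droplevels(factor(g)))) {
      idx <- which(!is.na(g) & g == lev)
      if (length(idx) >= 2) out <- c(out, list(fun(idx, lev)))
    }
  }
  res <- dplyr::bind_rows(out)
  res$variable <- variable
  res$small_stratum <- res$n_pairs < min_n
  dplyr::relocate(res, "variable", "stratum")
}

#' Full step-1 validity report
#'
#' Convenience wrapper running [stratified_validity()] for every indicator
#' across the requested stratifications, plus ICC and the paired t test for
#' the continuous indicators.
#'
#' @inheritParams stratified_validity
#' @param stratifications Character vector of stratifiers (may be empty).
#' @return A list with tibbles `continuous` (Bland-Altman rows), `binary`
#'   (confusion rows) and `icc` (one row per continuous indicator).
#' @export
validity_report <- function(data, stratifications = c("age_band", "sex",
                                                      "education"),
                            weighted = TRUE, min_n = 30) {
  cont <- c("height", "weight", "bmi")
  bin <- c("overweight", "obesity", "hypertension", "hypercholesterolemia")
  runs <- function(vars) {
    dplyr::bind_rows(lapply(vars, function(v) {
      dplyr::bind_rows(c(
        list(stratified_validity(data, v, NULL, weighted, min_n)),
        lapply(stratifications, function(s) {
          dplyr::filter(stratified_validity(data, v, s, weighted, min_n),
                        .data$stratum != "all")
        })
      ))
    }))
  }
  val <- dplyr::filter(data, .data$in_validation)
  icc <- dplyr::bind_rows(lapply(cont, function(v) {
    pair <- sr_meas_pair(val, v)
    out <- icc_agreement(pair$self, pair$meas)
    tt <- paired_mean_difference_test(pair$self, pair$meas)
    out$variable <- v
    out$t_statistic <- tt$statistic
    out$t_p_value <- tt$p_value
    dplyr::relocate(out, "variable")
  }))
  list(continuous = runs(cont), binary = runs(bin), icc = icc)
}
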