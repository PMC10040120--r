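# broom-style accessors for the package's fitted objects

#' Tidy a calibration model's coefficients
#'
#' @param x A `calibration_model` from [fit_calibration()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.calibration_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std.error = sm[, 2], statistic = sm[, 3],
                 p.value = sm[, 4])
}

#' One-row summary of a calibration model
#'
#' @inheritParams tidy.calibration_model
#' @return Tibble with outcome, family, held-out accuracy, split sizes and
#'   the interactions kept by the Wald screen.
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, family = x$family,
                 accuracy_metric = x$accuracy_metric, accuracy = x$accuracy,
                 accuracy_undefined = x$accuracy_undefined,
                 n_train = x$n_train, n_test = x$n_test,
                 n_interactions = length(x$interactions),
                 interactions = paste(x$interactions, collapse = "; "))
}

#' Tidy the trace of a completed set
#'
#' @param x A `completed_set` from [run_chained()].
#' @param ... Unused.
#' @return The long trace tibble (imputation, iteration, variable, mean, sd).
#' @export
tidy.completed_set <- function(x, ...) x$trace

#' One-row summary of a completed set
#'
#' @inheritParams tidy.completed_set
#' @return Tibble with m, iterations, engine, number of imputed variables
#'   and cells.
#' @export
glance.completed_set <- function(x, ...) {
  tibble::tibble(m = length(x$imputations),
                 n_iterations = x$spec$n_iterations,
                 engine = x$spec$engine,
                 n_variables = sum(vapply(x$miss_idx, length, integer(1)) > 0),
                 n_missing_cells = sum(vapply(x$miss_idx, length, integer(1))))
}

#' Tidy a pipeline result into its method-by-indicator estimates
#'
#' @param x A `mime_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return The long estimates tibble (`method`, `indicator`, `estimate`,
#'   `se`).
#' @export
tidy.mime_pipeline <- function(x, ...) x$estimates
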