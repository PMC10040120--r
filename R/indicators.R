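#' Derive cardiometabolic risk-factor indicators from measurements
#'
#' Applies the examination-survey case definitions to raw measurements:
#' BMI = weight (kg) / height (m)^2; overweight is BMI >= 25 kg/m^2;
#' obesity is BMI >= 30 kg/m^2; hypertension is systolic blood pressure
#' >= 140 mmHg, or diastolic blood pressure > 90 mmHg (strict), or use of
#' antihypertensive medication; hypercholesterolemia is total serum
#' cholesterol > 190 mg/dl (strict; lipid-lowering medication is
#' deliberately not part of the definition because statins are commonly
#' prescribed preventively).
#'
#' @param height Height in cm (values > 3 are taken as cm; values <= 3 as m).
#' @param weight Weight in kg.
#' @param sbp Systolic blood pressure, mmHg. Optional.
#' @param dbp Diastolic blood pressure, mmHg. Optional.
#' @param htn_medication Antihypertensive medication use, 0/1 or logical.
#'   Optional.
#' @param total_cholesterol Total serum cholesterol, mg/dl. Optional.
#'
#' @return A tibble with columns `bmi`, `overweight`, `obesity` and, when the
#'   corresponding measurements are supplied, `hypertension` and
#'   `hypercholesterolemia`. Binary indicators are integer 0/1; `NA` inputs
#'   propagate.
#'
#' @examples
#' derive_indicators(height = c(179, 180), weight = c(80, 81))
#'
#' @export
derive_indicators <- function(height, weight, sbp = NULL, dbp = NULL,
                              htn_medication = NULL, total_cholesterol = NULL) {
  if (any(height <= 0, na.rm = TRUE) || any(weight <= 0, na.rm = TRUE)) {
    abort("heights and weights must be strictly positive")
  }
  height_m <- ifelse(height > 3, height / 100, height)
  bmi <- weight / height_m^2
  out <- tibble::tibble(
    bmi = bmi,
    overweight = as.integer(bmi >= 25),
    obesity = as.integer(bmi >= 30)
  )
  if (!is.null(sbp) || !is.null(dbp) || !is.null(htn_medication)) {
    if (is.null(sbp) || is.null(dbp) || is.null(htn_medication)) {
      abort("hypertension requires sbp, dbp and htn_medication together")
    }
    out$hypertension <- as.integer(sbp >= 140 | dbp > 90 |
                                     as.integer(htn_medication) == 1L)
  }
  if (!is.null(total_cholesterol)) {
    out$hypercholesterolemia <- as.integer(total_cholesterol > 190)
  }
  out
}

# Passive BMI-based indicators from height/weight columns of a completed or
# calibrated dataset; prefix selects the source columns, suffix the outputs.
add_bmi_indicators <- function(data, height_col, weight_col, suffix = "") {
  ind <- derive_indicators(data[[height_col]], data[[weight_col]])
  data[[paste0("bmi", suffix)]] <- ind$bmi
  data[[paste0("overweight", suffix)]] <- ind$overweight
  data[[paste0("obesity", suffix)]] <- ind$obesity
  data
}
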