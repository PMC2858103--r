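#' HOMA-IR insulin resistance index
#'
#' `HOMA_IR = G_b * (I_b / conversion) / 22.5`, with fasting glucose in mM
#' and fasting insulin converted from pM to uIU/mL.  The reciprocal
#' `1/HOMA-IR` serves as a basal insulin sensitivity surrogate.  The pM to
#' uIU/mL conversion factor is an assay convention, defaulting to 6.0
#' pmol/L per uIU/mL.
#'
#' @param G_b Fasting glucose (mM), positive.
#' @param I_b Fasting insulin (pM), positive.
#' @param pmol_per_microIU Conversion factor, default 6.0.
#' @return A tibble with `HOMA_IR` and `inv_HOMA_IR`.
#' @export
#' @examples
#' homa_ir(4.5, 67.5)   # HOMA_IR = 2.25
homa_ir <- function(G_b, I_b, pmol_per_microIU = 6.0) {
  if (any(!is.finite(c(G_b, I_b))) || any(G_b <= 0) || any(I_b <= 0) ||
      pmol_per_microIU <= 0) {
    abort("homa_ir requires positive fasting values and conversion factor",
          class = "ivgttsdm_domain_error")
  }
  h <- G_b * (I_b / pmol_per_microIU) / 22.5
  tibble(HOMA_IR = h, inv_HOMA_IR = 1 / h)
}

#' Acute insulin response (AIR)
#'
#' First-phase insulin increment over basal divided by the first-order
#' insulin disappearance rate: `AIR = I_delta / K_xi`, where by the SDM
#' initial condition `I_delta = I(0) - I_b = I_deltaG * G_delta`.
#' (A figure caption of the source literature prints AIR as
#' `I_deltaG / K_xgI`; the body-text definition `I_delta / K_xi` is the one
#' implemented.)
#'
#' @param I_deltaG First-phase insulin rise per mM glucose (pM/mM).
#' @param G_delta Glucose rise at t = 0 (mM).
#' @param K_xi Insulin disappearance rate (min^-1), positive.
#' @return AIR in pM min.
#' @export
#' @examples
#' acute_insulin_response(30, 10, 0.05)
acute_insulin_response <- function(I_deltaG, G_delta, K_xi) {
  if (any(!is.finite(K_xi)) || any(K_xi <= 0)) {
    abort("acute_insulin_response requires K_xi > 0",
          class = "ivgttsdm_domain_error")
  }
  (I_deltaG * G_delta) / K_xi
}

#' Disposition index
#'
#' Product of insulin secretion and insulin sensitivity, `DI = AIR * K_xgI`
#' (dimensionless): approximately constant across adequately compensated
#' subjects regardless of adiposity.
#'
#' @param AIR Acute insulin response (pM min), non-negative.
#' @param K_xgI SDM insulin sensitivity (min^-1 pM^-1), non-negative.
#' @return DI, dimensionless.
#' @export
disposition_index <- function(AIR, K_xgI) {
  if (any(AIR < 0, na.rm = TRUE) || any(K_xgI < 0, na.rm = TRUE)) {
    abort("disposition_index requires non-negative inputs",
          class = "ivgttsdm_domain_error")
  }
  AIR * K_xgI
}

#' BMI class of a subject
#'
#' Lean: BMI <= 24; overweight: 24 < BMI <= 30; obese: 30 < BMI <= 40;
#' morbidly obese: BMI > 40 (kg/m^2).
#'
#' @param bmi Body mass index, positive.
#' @return Factor with levels `lean`, `overweight`, `obese`, `morbid`.
#' @export
#' @examples
#' classify_bmi(c(22.4, 25.8, 34.3, 48.7))
classify_bmi <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    abort("classify_bmi requires positive BMI", class = "ivgttsdm_domain_error")
  }
  cut(bmi, breaks = c(0, 24, 30, 40, Inf),
      labels = bmi_class_levels(), right = TRUE)
}

bmi_class_levels <- function() c("lean", "overweight", "obese", "morbid")

#' Flag extreme Minimal Model S_I estimates
#'
#' Marks S_I values that are implausibly small (the "zero-S_I" phenomenon,
#' `<= 1.5e-12` by default) or implausibly large (`>= 3.99` by default) and
#' should be excluded from agreement analyses.
#'
#' @param S_I Insulin sensitivity estimates (min^-1 pM^-1).
#' @param low_threshold,high_threshold Exclusion thresholds.
#' @return Logical vector; `NA` values flag as extreme.
#' @export
#' @examples
#' flag_extreme_si(c(1e-4, 1.5e-12, 890))
flag_extreme_si <- function(S_I, low_threshold = 1.5e-12,
                            high_threshold = 3.99) {
  is.na(S_I) | S_I <= low_threshold | S_I >= high_threshold
}

#' Per-subject index panel
#'
#' Combines SDM and MM fits with the basal measurements into one row per
#' subject: `K_xgI` with its CV, `S_I` with its CV, `HOMA_IR` and its
#' reciprocal, `AIR`, `DI = AIR * K_xgI`, identifiability flags at the CV
#' threshold, the extreme-S_I flag and the BMI class.  `K_xgI` is the SDM
#' fit estimate verbatim (no recomputation).  An optional `HOMA2` column is
#' passed through untouched, but blanked for subjects whose basal insulin is
#' below 20 pmol/L (the published calculator's validity gate).
#'
#' @param sdm_fits List of [gls_fit_sdm()] results, one per subject.
#' @param mm_fits List of [wls_fit_mm()] results in the same order (or
#'   `NULL` to omit MM columns).
#' @param bmi Numeric vector of BMI values in the same order.
#' @param pmol_per_microIU HOMA pM to uIU/mL conversion, default 6.0.
#' @param cv_threshold Identifiability threshold in %, default 52.
#' @param si_low,si_high Extreme-S_I thresholds.
#' @param HOMA2 Optional externally computed HOMA2 values to pass through.
#' @return An `index_panel` tibble, one row per subject.
#' @export
index_panel <- function(sdm_fits, mm_fits = NULL, bmi,
                        pmol_per_microIU = 6.0, cv_threshold = 52,
                        si_low = 1.5e-12, si_high = 3.99, HOMA2 = NULL) {
  stopifnot(length(sdm_fits) == length(bmi))
  rows <- purrr::imap(sdm_fits, function(f, i) {
    stopifnot(inherits(f, "sdm_fit"))
    h <- homa_ir(f$G_b, f$I_b, pmol_per_microIU)
    air <- acute_insulin_response(f$estimates[["I_deltaG"]],
                                  f$estimates[["G_delta"]],
                                  f$estimates[["K_xi"]])
    tibble(
      subject_id = f$subject_id,
      G_b = f$G_b, I_b = f$I_b,
      K_xgI = f$estimates[["K_xgI"]],
      cv_K_xgI = f$cv_percent[["K_xgI"]],
      HOMA_IR = h$HOMA_IR, inv_HOMA_IR = h$inv_HOMA_IR,
      AIR = air,
      DI = disposition_index(air, f$estimates[["K_xgI"]]),
      sdm_identifiable = is_identifiable(f$cv_percent[["K_xgI"]], cv_threshold),
      sdm_converged = f$converged
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(mm_fits)) {
    stopifnot(length(mm_fits) == length(sdm_fits))
    mm <- purrr::map(mm_fits, function(f) {
      stopifnot(inherits(f, "mm_fit"))
      tibble(S_I = f$S_I, cv_S_I = f$cv_S_I,
             mm_identifiable = is_identifiable(f$cv_S_I, cv_threshold))
    })
    out <- dplyr::bind_cols(out, dplyr::bind_rows(mm))
    out$si_extreme <- flag_extreme_si(out$S_I, si_low, si_high)
  }
  out$bmi <- bmi
  out$bmi_class <- classify_bmi(bmi)
  if (!is.null(HOMA2)) {
    stopifnot(length(HOMA2) == nrow(out))
    out$HOMA2 <- ifelse(out$I_b < 20, NA_real_, HOMA2)
  }
  class(out) <- c("index_panel", class(out))
  out
}
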