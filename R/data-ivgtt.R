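#' Standard IVGTT sampling schedule
#'
#' The frequently sampled IVGTT draws blood at 23 fixed times: three
#' pre-bolus samples at -30, -15 and 0 minutes (averaged into the baseline)
#' and twenty post-bolus samples out to 180 minutes.
#'
#' @return Numeric vector of 23 sampling times in minutes.
#' @export
#' @examples
#' ivgtt_schedule()
ivgtt_schedule <- function() {
  c(-30, -15, 0, 2, 4, 6, 8, 10, 12, 15, 20, 25, 30, 35, 40,
    50, 60, 80, 100, 120, 140, 160, 180)
}

#' Baseline glucose and insulin from pre-bolus samples
#'
#' Pre-bolus plasma values (conventionally drawn at -30, -15 and 0 minutes)
#' are averaged to yield the basal concentrations `G_b` and `I_b` referred
#' to time 0.
#'
#' @param glucose Pre-bolus plasma glucose samples (mM).
#' @param insulin Pre-bolus plasma insulin samples (pM).
#' @return A one-row tibble with columns `G_b` (mM) and `I_b` (pM).
#' @export
#' @examples
#' compute_baselines(c(4.4, 4.5, 4.6), c(55, 60, 65))
compute_baselines <- function(glucose, insulin) {
  if (length(glucose) == 0 || length(insulin) == 0) {
    abort("at least one pre-bolus sample per analyte is required to form baselines",
          class = "ivgttsdm_missing_baseline")
  }
  if (any(!is.finite(glucose)) || any(!is.finite(insulin)) ||
      any(glucose <= 0) || any(insulin <= 0)) {
    abort("pre-bolus samples must be finite and strictly positive",
          class = "ivgttsdm_domain_error")
  }
  tibble(G_b = mean(glucose), I_b = mean(insulin))
}

#' Convert a glucose dose from g/kg to mmol/kg body weight
#'
#' Bridges the administered bolus (grams of glucose per kg body weight, the
#' protocol's 0.33 g/kg) to the molar dose `D_g` used by the model, via the
#' molar mass of glucose (180.16 g/mol).
#'
#' @param dose_g_per_kg Dose in g glucose per kg body weight; must be positive.
#' @return Dose in mmol per kg body weight.
#' @export
#' @examples
#' dose_to_mmol_per_kg(0.33)
dose_to_mmol_per_kg <- function(dose_g_per_kg) {
  if (any(!is.finite(dose_g_per_kg)) || any(dose_g_per_kg <= 0)) {
    abort("glucose dose must be strictly positive", class = "ivgttsdm_domain_error")
  }
  dose_g_per_kg / GLUCOSE_MOLAR_MASS
}

#' Assemble and validate a single-subject IVGTT record
#'
#' An `ivgtt_dataset` is a tibble with columns `time_min`, `glucose_mM` and
#' `insulin_pM`, one row per blood sample, carrying subject metadata and the
#' derived baselines as attributes: `subject_id`, `body_weight` (kg), `bmi`
#' (kg/m^2), `dose_g_per_kg`, `D_g` (mmol/kgBW), `G_b` (mM), `I_b` (pM).
#' Baselines are the means of the samples at non-positive times; t = 0 is
#' the bolus instant, so pre-bolus rows (time <= 0) are used only for the
#' baselines and never enter model fitting.
#'
#' @param samples Data frame with columns `time_min`, `glucose_mM`,
#'   `insulin_pM`; times strictly increasing, concentrations positive.
#' @param subject_id Subject identifier.
#' @param body_weight Body weight in kg.
#' @param bmi Body mass index in kg/m^2.
#' @param dose_g_per_kg Glucose bolus in g per kg body weight (default 0.33).
#' @return An `ivgtt_dataset` tibble.
#' @export
#' @examples
#' d <- ivgtt_dataset(
#'   tibble::tibble(
#'     time_min = ivgtt_schedule(),
#'     glucose_mM = c(4.5, 4.5, 4.5, rep(6, 20)),
#'     insulin_pM = c(60, 60, 60, rep(100, 20))
#'   ),
#'   subject_id = "s1", body_weight = 70, bmi = 24
#' )
#' ivgtt_meta(d)
ivgtt_dataset <- function(samples, subject_id = "subject",
                          body_weight = NA_real_, bmi = NA_real_,
                          dose_g_per_kg = 0.33) {
  required <- c("time_min", "glucose_mM", "insulin_pM")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("IVGTT samples are missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ivgttsdm_schema_error")
  }
  samples <- as_tibble(samples)[required]
  t <- samples$time_min
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1
    abort(sprintf("sampling times must be strictly increasing (violated at row %d, t = %g)",
                  bad, t[bad]),
          class = "ivgttsdm_validation_error")
  }
  for (col in c("glucose_mM", "insulin_pM")) {
    v <- samples[[col]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      bad <- which(!is.finite(v) | v <= 0)[1]
      abort(sprintf("%s must be finite and strictly positive (violated at row %d)",
                    col, bad),
            class = "ivgttsdm_validation_error")
    }
  }
  pre <- t <= 0
  if (!any(pre)) {
    abort("record has no pre-bolus samples (time <= 0); baselines undefined",
          class = "ivgttsdm_missing_baseline")
  }
  base <- compute_baselines(samples$glucose_mM[pre], samples$insulin_pM[pre])
  out <- samples
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "G_b") <- base$G_b
  attr(out, "I_b") <- base$I_b
  attr(out, "body_weight") <- as.numeric(body_weight)
  attr(out, "bmi") <- as.numeric(bmi)
  attr(out, "dose_g_per_kg") <- as.numeric(dose_g_per_kg)
  attr(out, "D_g") <- dose_to_mmol_per_kg(dose_g_per_kg)
  class(out) <- c("ivgtt_dataset", class(out))
  out
}

#' Subject metadata and baselines of an IVGTT record
#'
#' @param data An `ivgtt_dataset`.
#' @return A one-row tibble: `subject_id`, `G_b`, `I_b`, `body_weight`,
#'   `bmi`, `dose_g_per_kg`, `D_g`.
#' @export
ivgtt_meta <- function(data) {
  stopifnot(inherits(data, "ivgtt_dataset"))
  tibble(
    subject_id = attr(data, "subject_id"),
    G_b = attr(data, "G_b"),
    I_b = attr(data, "I_b"),
    body_weight = attr(data, "body_weight"),
    bmi = attr(data, "bmi"),
    dose_g_per_kg = attr(data, "dose_g_per_kg"),
    D_g = attr(data, "D_g")
  )
}

#' Post-bolus rows of an IVGTT record
#'
#' The observations at `time_min > 0` -- the only samples that enter model
#' fitting (pre-bolus rows contribute solely to the baselines).
#'
#' @param data An `ivgtt_dataset`.
#' @return A plain tibble of the post-bolus rows.
#' @export
ivgtt_post <- function(data) {
  stopifnot(inherits(data, "ivgtt_dataset"))
  as_tibble(data)[data$time_min > 0, , drop = FALSE]
}

#' Read / write a single-subject IVGTT record as CSV
#'
#' One row per blood sample with metadata repeated on every row:
#' `subject_id,time_min,glucose_mM,insulin_pM,body_weight_kg,bmi,dose_g_per_kg`.
#' Reading validates the record (monotone times, positive concentrations)
#' and recomputes the baselines from the pre-bolus rows; the round trip is
#' lossless to full double precision.
#'
#' @param path File path.
#' @param data An `ivgtt_dataset` (for writing).
#' @return `read_ivgtt_csv` returns an `ivgtt_dataset`;
#'   `write_ivgtt_csv` returns `path` invisibly.
#' @export
read_ivgtt_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "time_min", "glucose_mM", "insulin_pM",
                "body_weight_kg", "bmi", "dose_g_per_kg")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ivgttsdm_schema_error")
  }
  ivgtt_dataset(
    raw[c("time_min", "glucose_mM", "insulin_pM")],
    subject_id = raw$subject_id[1],
    body_weight = raw$body_weight_kg[1],
    bmi = raw$bmi[1],
    dose_g_per_kg = raw$dose_g_per_kg[1]
  )
}

#' @rdname read_ivgtt_csv
#' @export
write_ivgtt_csv <- function(data, path) {
  stopifnot(inherits(data, "ivgtt_dataset"))
  meta <- ivgtt_meta(data)
  out <- tibble(
    subject_id = meta$subject_id,
    time_min = data$time_min,
    glucose_mM = data$glucose_mM,
    insulin_pM = data$insulin_pM,
    body_weight_kg = meta$body_weight,
    bmi = meta$bmi,
    dose_g_per_kg = meta$dose_g_per_kg
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read / write an IVGTT cohort
#'
#' A cohort is a tibble with one row per subject: `subject_id`, `bmi`,
#' `body_weight`, `dose_g_per_kg`, optionally `M` (clamp index, passed
#' through untouched) and a list-column `data` of `ivgtt_dataset` records.
#' On disk it is a manifest CSV
#' (`subject_id,file,body_weight_kg,bmi,dose_g_per_kg[,M]`) plus one
#' per-subject CSV each.
#'
#' @param manifest Path to the manifest CSV.
#' @param cohort Cohort tibble (for writing).
#' @param dir Output directory (created if needed).
#' @return `read_ivgtt_cohort` returns the cohort tibble;
#'   `write_ivgtt_cohort` returns the manifest path invisibly.
#' @export
read_ivgtt_cohort <- function(manifest) {
  man <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "file", "body_weight_kg", "bmi", "dose_g_per_kg")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols) > 0) {
    abort(paste0(manifest, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ivgttsdm_schema_error")
  }
  base_dir <- dirname(manifest)
  datasets <- purrr::pmap(man, function(subject_id, file, body_weight_kg,
                                        bmi, dose_g_per_kg, ...) {
    d <- read_ivgtt_csv(file.path(base_dir, file))
    attr(d, "subject_id") <- as.character(subject_id)
    attr(d, "body_weight") <- body_weight_kg
    attr(d, "bmi") <- bmi
    d
  })
  out <- tibble(
    subject_id = as.character(man$subject_id),
    bmi = man$bmi,
    body_weight = man$body_weight_kg,
    dose_g_per_kg = man$dose_g_per_kg,
    data = datasets
  )
  if ("M" %in% names(man)) out$M <- man$M
  out
}

#' @rdname read_ivgtt_cohort
#' @export
write_ivgtt_cohort <- function(cohort, dir) {
  stopifnot(is.data.frame(cohort), "data" %in% names(cohort))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- paste0(cohort$subject_id, ".csv")
  purrr::walk2(cohort$data, files,
               function(d, f) write_ivgtt_csv(d, file.path(dir, f)))
  man <- tibble(
    subject_id = cohort$subject_id,
    file = files,
    body_weight_kg = cohort$body_weight,
    bmi = cohort$bmi,
    dose_g_per_kg = cohort$dose_g_per_kg
  )
  if ("M" %in% names(cohort)) man$M <- cohort$M
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(man, manifest)
  invisible(manifest)
}

#' @export
print.ivgtt_dataset <- function(x, ...) {
  meta <- ivgtt_meta(x)
  cat(sprintf("<IVGTT record: %s>  %d samples, G_b = %.3g mM, I_b = %.3g pM\n",
              meta$subject_id, nrow(x), meta$G_b, meta$I_b))
  print(as_tibble(x), ...)
  invisible(x)
}
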