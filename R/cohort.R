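# Synthetic IVGTT cohort generator.
#
# Emulates the four-BMI-class study population: per-class anthropometric and
# basal anchors (means and SDs) for G_b, I_b, BMI, height and the class-mean
# insulin sensitivity K_xgI, the standard 23-point sampling schedule, the
# 0.33 g/kg bolus, and multiplicative observation noise with per-analyte
# coefficients of variation matching the error model assumed by the GLS fit.

#' Per-class population anchors
#'
#' Published class statistics for the four BMI classes (lean, overweight,
#' obese, morbidly obese): means and SDs of basal glucose (mM), basal insulin
#' (pM), BMI (kg/m^2) and height (cm), and the class mean of the insulin
#' sensitivity `K_xgI` (min^-1 pM^-1).
#'
#' @return A tibble, one row per class.
#' @export
cohort_class_anchors <- function() {
  tibble(
    bmi_class = bmi_class_levels(),
    G_b_mean = c(4.4, 4.6, 4.3, 4.8),
    G_b_sd = c(0.6, 0.5, 0.5, 0.4),
    I_b_mean = c(33.0, 46.1, 70.0, 96.4),
    I_b_sd = c(13.2, 26.5, 46.4, 59.7),
    bmi_mean = c(22.4, 25.8, 34.3, 48.7),
    bmi_sd = c(1.7, 1.3, 2.7, 6.7),
    height_mean = c(166.8, 166.0, 163.0, 162.0),
    height_sd = c(9.8, 7.9, 8.3, 8.4),
    K_xgI_mean = c(1.6e-4, 1.3e-4, 8.4e-5, 2.8e-5),
    bmi_lower = c(14, 24, 30, 40),
    bmi_upper = c(24, 30, 40, 70)
  )
}

#' Specification of a synthetic IVGTT cohort
#'
#' @param n_per_class Named counts for `lean`, `overweight`, `obese`,
#'   `morbid`; defaults to the study's class sizes 19/22/22/11.
#' @param noise_cv_glucose,noise_cv_insulin Observation-noise CVs in percent
#'   (defaults 1.5 and 7).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param schedule Sampling times (min), default [ivgtt_schedule()].
#' @param dose_g_per_kg Glucose bolus, default 0.33 g/kg.
#' @param kxgi_cv Between-subject CV of `K_xgI` within class, %, default 50.
#' @param anchors Class anchor table, default [cohort_class_anchors()].
#' @param ib_kxgi_rho Optional correlation between basal insulin and
#'   log `K_xgI` (negative couples insulin resistance to hyperinsulinemia);
#'   default 0 (off).
#' @param G_star,V_i Fixed SDM configuration constants used in simulation.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_class = c(lean = 19, overweight = 22,
                                        obese = 22, morbid = 11),
                        noise_cv_glucose = 1.5, noise_cv_insulin = 7,
                        seed = NULL, schedule = ivgtt_schedule(),
                        dose_g_per_kg = 0.33, kxgi_cv = 50,
                        anchors = cohort_class_anchors(),
                        ib_kxgi_rho = 0, G_star = 9, V_i = 0.25) {
  stopifnot(all(bmi_class_levels() %in% names(n_per_class)),
            all(n_per_class >= 0),
            noise_cv_glucose >= 0, noise_cv_insulin >= 0,
            abs(ib_kxgi_rho) < 1)
  structure(list(
    n_per_class = n_per_class[bmi_class_levels()],
    noise_cv_glucose = noise_cv_glucose,
    noise_cv_insulin = noise_cv_insulin,
    seed = seed, schedule = schedule, dose_g_per_kg = dose_g_per_kg,
    kxgi_cv = kxgi_cv, anchors = anchors, ib_kxgi_rho = ib_kxgi_rho,
    G_star = G_star, V_i = V_i
  ), class = "cohort_spec")
}

# truncated normal by resampling; errors out if the window is implausible
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (lower >= upper) {
    abort("impossible truncation window", class = "ivgttsdm_spec_error")
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (tries in 1:1000) {
      x <- rnorm(1, mean, sd)
      if (x > lower && x <= upper) { out[i] <- x; break }
      if (tries == 1000) {
        abort("truncated-normal sampler failed: window too far in the tail",
              class = "ivgttsdm_spec_error")
      }
    }
  }
  out
}

#' Draw one synthetic subject's ground truth
#'
#' Physiology (`G_b`, `I_b`, BMI, height) comes from truncated normals at
#' the class anchors (BMI truncated to the class's defining interval);
#' `K_xgI` is log-normal with the class mean and the spec's between-subject
#' CV; the remaining SDM parameters are drawn uniformly from fixed plausible
#' ranges (`K_xi` 0.02-0.12 min^-1, `tau_g` 5-40 min, `gamma` 1-5,
#' `I_deltaG` 20-120 pM/mM); the glucose distribution volume `V_g` is normal
#' around 0.16 L/kgBW (30% CV, truncated) and fixes
#' `G_delta = D_g / V_g`.  Consumes the current RNG state.
#'
#' @param class One of `lean`, `overweight`, `obese`, `morbid`.
#' @param spec A [cohort_spec()].
#' @return One-row tibble of ground-truth parameters and anthropometrics.
#' @export
sample_subject <- function(class, spec) {
  stopifnot(inherits(spec, "cohort_spec"), class %in% bmi_class_levels())
  a <- spec$anchors[spec$anchors$bmi_class == class, ]

  G_b <- rtrunc_norm(1, a$G_b_mean, a$G_b_sd,
                     lower = max(2.5, a$G_b_mean - 2.5 * a$G_b_sd),
                     upper = a$G_b_mean + 2.5 * a$G_b_sd)
  bmi <- rtrunc_norm(1, a$bmi_mean, a$bmi_sd, a$bmi_lower, a$bmi_upper)
  height <- rtrunc_norm(1, a$height_mean, a$height_sd,
                        a$height_mean - 2.5 * a$height_sd,
                        a$height_mean + 2.5 * a$height_sd)
  body_weight <- bmi * (height / 100)^2

  # K_xgI log-normal at the class mean; optionally coupled to I_b through a
  # Gaussian copula so resistant subjects run hyperinsulinemic
  cvk <- spec$kxgi_cv / 100
  sdlog <- sqrt(log(1 + cvk^2))
  mulog <- log(a$K_xgI_mean) - sdlog^2 / 2
  z_k <- rnorm(1)
  K_xgI <- exp(mulog + sdlog * z_k)
  rho <- spec$ib_kxgi_rho
  z_i <- rho * z_k + sqrt(1 - rho^2) * rnorm(1)
  ib_lower <- max(10, a$I_b_mean - 2.5 * a$I_b_sd)
  ib_upper <- a$I_b_mean + 2.5 * a$I_b_sd
  I_b <- a$I_b_mean + a$I_b_sd * z_i
  if (I_b <= ib_lower || I_b > ib_upper) {
    I_b <- rtrunc_norm(1, a$I_b_mean, a$I_b_sd, ib_lower, ib_upper)
  }

  K_xi <- runif(1, 0.02, 0.12)
  tau_g <- runif(1, 5, 40)
  gamma <- runif(1, 1, 5)
  I_deltaG <- runif(1, 20, 120)
  V_g <- rtrunc_norm(1, 0.16, 0.048, 0.08, 0.28)
  D_g <- dose_to_mmol_per_kg(spec$dose_g_per_kg)
  G_delta <- D_g / V_g

  tibble(bmi_class = class, G_b = G_b, I_b = I_b, bmi = bmi,
         height = height, body_weight = body_weight,
         K_xgI = K_xgI, K_xi = K_xi, tau_g = tau_g, gamma = gamma,
         G_delta = G_delta, I_deltaG = I_deltaG, V_g = V_g, D_g = D_g)
}

# multiplicative Gaussian noise at a given CV, resampling non-positive draws
noisy_positive <- function(x, cv_fraction) {
  if (cv_fraction == 0) return(x)
  out <- x * (1 + cv_fraction * rnorm(length(x)))
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- x[bad] * (1 + cv_fraction * rnorm(length(bad)))
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Generate one noisy IVGTT record from ground truth
#'
#' Simulates the SDM at the schedule's post-bolus times, applies independent
#' multiplicative Gaussian noise at the spec's CVs (non-positive draws
#' resampled), sets the pre-bolus samples to the basal values with the same
#' noise, and assembles an [ivgtt_dataset] whose baselines are recomputed
#' from the noisy pre-bolus samples, as in the protocol.  Consumes the
#' current RNG state.
#'
#' @param truth One row as returned by [sample_subject()].
#' @param spec A [cohort_spec()].
#' @param subject_id Identifier for the record.
#' @return An [ivgtt_dataset].
#' @export
generate_ivgtt <- function(truth, spec, subject_id = "synthetic") {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- sdm_params(truth$K_xgI, truth$K_xi, truth$tau_g, truth$gamma,
                  truth$G_delta, truth$I_deltaG,
                  G_star = spec$G_star, V_i = spec$V_i)
  sched <- spec$schedule
  pre_t <- sched[sched <= 0]
  post_t <- sched[sched > 0]
  sim <- simulate_sdm(p, truth$G_b, truth$I_b, post_t)
  cg <- spec$noise_cv_glucose / 100
  ci <- spec$noise_cv_insulin / 100
  glucose <- c(noisy_positive(rep(truth$G_b, length(pre_t)), cg),
               noisy_positive(sim$glucose_mM, cg))
  insulin <- c(noisy_positive(rep(truth$I_b, length(pre_t)), ci),
               noisy_positive(sim$insulin_pM, ci))
  ivgtt_dataset(
    tibble(time_min = sched, glucose_mM = glucose, insulin_pM = insulin),
    subject_id = subject_id,
    body_weight = truth$body_weight, bmi = truth$bmi,
    dose_g_per_kg = spec$dose_g_per_kg
  )
}

#' Generate a synthetic IVGTT cohort with ground truth
#'
#' Draws every subject's ground truth with [sample_subject()], simulates and
#' perturbs each record with [generate_ivgtt()], and returns a cohort tibble
#' (one row per subject: identifiers, anthropometrics, true parameters, and
#' the record in the `data` list-column).  Fully deterministic under a fixed
#' `spec$seed`.  If `outdir` is given, per-subject CSVs, a manifest and a
#' ground-truth CSV are written there.
#'
#' @param spec A [cohort_spec()].
#' @param outdir Optional output directory.
#' @return Cohort tibble with attribute `spec`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(
#'   n_per_class = c(lean = 2, overweight = 1, obese = 1, morbid = 1),
#'   seed = 1))
#' co$bmi_class
generate_cohort <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rows <- purrr::map(bmi_class_levels(), function(cl) {
    n <- spec$n_per_class[[cl]]
    if (n == 0) return(NULL)
    purrr::map(seq_len(n), function(i) sample_subject(cl, spec))
  })
  truth <- dplyr::bind_rows(purrr::flatten(rows))
  truth$subject_id <- sprintf("S%03d", seq_len(nrow(truth)))
  truth <- dplyr::relocate(truth, "subject_id")
  truth$data <- purrr::map(seq_len(nrow(truth)), function(i) {
    generate_ivgtt(truth[i, ], spec, subject_id = truth$subject_id[i])
  })
  attr(truth, "spec") <- spec
  if (!is.null(outdir)) {
    cohort <- truth
    cohort$dose_g_per_kg <- spec$dose_g_per_kg
    write_ivgtt_cohort(cohort, outdir)
    readr::write_csv(dplyr::select(truth, -"data"),
                     file.path(outdir, "truth.csv"))
  }
  truth
}
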