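# broom-style tidiers for fitted model objects.

#' Tidy a fitted SDM or MM model
#'
#' One row per free parameter: estimate, asymptotic standard error, CV% and
#' the identifiability grade at the fit's CV threshold.
#'
#' @param x An `sdm_fit` or `mm_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std_error`,
#'   `cv_percent`, `identifiable`.
#' @export
tidy.sdm_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$covariance), 0))
  tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std_error = if (all(is.finite(se))) unname(se) else NA_real_,
    cv_percent = unname(x$cv_percent),
    identifiable = is_identifiable(unname(x$cv_percent), x$cv_threshold)
  )
}

#' @rdname tidy.sdm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  out <- tidy.sdm_fit(x, ...)
  dplyr::bind_rows(out, tibble(
    term = "S_I",
    estimate = x$S_I,
    std_error = if (is.finite(x$cv_S_I)) x$S_I * x$cv_S_I / 100 else NA_real_,
    cv_percent = x$cv_S_I,
    identifiable = is_identifiable(x$cv_S_I, x$cv_threshold)
  ))
}

#' One-row fit summary
#'
#' @param x An `sdm_fit` or `mm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the objective value, error CVs,
#'   convergence flag, iteration count and observation count.
#' @export
glance.sdm_fit <- function(x, ...) {
  tibble(
    model = x$model, subject_id = x$subject_id,
    objective = x$objective_value,
    error_cv_glucose = x$error_cv_glucose,
    error_cv_insulin = x$error_cv_insulin,
    converged = x$converged, n_iterations = x$n_iterations, n_obs = x$n_obs
  )
}

#' @rdname glance.sdm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(
    model = x$model, subject_id = x$subject_id,
    objective = x$objective_value,
    error_cv_glucose = x$error_cv_glucose,
    S_I = x$S_I, cv_S_I = x$cv_S_I,
    converged = x$converged, n_iterations = x$n_iterations, n_obs = x$n_obs
  )
}

#' @export
print.ivgtt_fit <- function(x, ...) {
  cat(sprintf("<%s fit: %s>  converged: %s, objective %.4g\n",
              x$model, x$subject_id, x$converged, x$objective_value))
  print(tidy(x))
  invisible(x)
}
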