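# Weighted least squares estimation of the decoupled Minimal Model.

mm_default_bounds <- function() {
  list(
    lower = c(p1 = 1e-6, p2 = 1e-4, p3 = 1e-14, G0 = 1),
    upper = c(p1 = 0.5, p2 = 1, p3 = 1e-2, G0 = 60)
  )
}

mm_fit_options <- function(options = list()) {
  defaults <- list(
    h = 0.1,
    t_start = 8,            # glucose before 8 min disregarded
    cv_glucose = 1.5,       # fixed weighting CV, %
    maxit = 300L,
    factr = 1e7,
    bounds = mm_default_bounds(),
    cv_threshold = 52
  )
  utils::modifyList(defaults, options)
}

#' Fit the decoupled Minimal Model by weighted least squares
#'
#' Fits `p1, p2, p3, G0` to post-window glucose observations with weights
#' \eqn{1/(0.015\,\hat G_j)^2} (inverse squared expectations at a fixed 1.5%
#' glucose CV), using the linearly interpolated observed insulin as the
#' forcing input.  Glucose samples before 8 minutes and insulin samples
#' before the first post-bolus peak are disregarded.  Parameters are
#' log-transformed (`p3` may reach its lower bound, reproducing the
#' "zero-S_I" phenomenon) and optimized by the `L-BFGS-B` quasi-Newton
#' search; covariance, per-parameter CV% and the delta-method CV of
#' `S_I = p3/p2` are derived as in [gls_fit_sdm()].
#'
#' @param data An [ivgtt_dataset].
#' @param init Optional [mm_params] start; defaults to
#'   [default_initial_guesses()].
#' @param options Named list overriding defaults (`h`, `t_start`,
#'   `cv_glucose`, `maxit`, `bounds`, `cv_threshold`).
#' @return An object of class `mm_fit` (also `ivgtt_fit`) with `S_I` and
#'   `cv_S_I` alongside the per-parameter results.
#' @export
wls_fit_mm <- function(data, init = NULL, options = list()) {
  stopifnot(inherits(data, "ivgtt_dataset"))
  opt <- mm_fit_options(options)
  meta <- ivgtt_meta(data)
  post <- ivgtt_post(data)
  window <- post[post$time_min >= opt$t_start, , drop = FALSE]
  if (nrow(window) < 5) {
    abort("need at least 5 glucose samples at or after 8 min to fit the MM",
          class = "ivgttsdm_input_error")
  }
  if (is.null(init)) init <- default_initial_guesses(data)$mm
  stopifnot(inherits(init, "mm_params"))

  ins <- interpolate_insulin(post$time_min, post$insulin_pM)

  free <- mm_free_names()
  b <- opt$bounds
  lb <- log(b$lower[free]); ub <- log(b$upper[free])
  th0 <- pmin(pmax(unlist(init[free]), b$lower[free] * 1.0001),
              b$upper[free] * 0.9999)
  ltheta <- log(th0)

  times <- window$time_min
  y <- window$glucose_mM
  cvf <- opt$cv_glucose / 100

  predict_g <- function(ltheta) {
    theta <- setNames(exp(ltheta), free)
    g <- tryCatch(
      .mm_integrate_cpp(times, theta[["p1"]], theta[["p2"]], theta[["p3"]],
                        theta[["G0"]], meta$G_b, meta$I_b,
                        ins$knot_times, ins$knot_values, opt$t_start, opt$h),
      error = function(e) NULL)
    if (is.null(g) || any(!is.finite(g)) || any(g <= 0)) return(NULL)
    g
  }
  obj <- function(ltheta) {
    gh <- predict_g(ltheta)
    if (is.null(gh)) return(1e12)
    sum(((y - gh) / (cvf * gh))^2)
  }

  fit <- optim(ltheta, obj, method = "L-BFGS-B", lower = lb, upper = ub,
               control = list(maxit = opt$maxit, factr = opt$factr))
  ltheta <- fit$par
  theta <- setNames(exp(ltheta), free)
  yhat <- predict_g(ltheta)
  w_cv <- rep(cvf, length(y))

  covinfo <- fit_covariance(predict_g, ltheta, yhat, w_cv, theta)

  # S_I = p3/p2 and its CV by the delta method on the log scale:
  # Var(log S_I) = Var(log p3) + Var(log p2) - 2 Cov(log p3, log p2)
  s_i <- theta[["p3"]] / theta[["p2"]]
  cl <- covinfo$cov_log
  cv_s_i <- Inf
  if (all(is.finite(cl[c("p2", "p3"), c("p2", "p3")]))) {
    v <- cl["p3", "p3"] + cl["p2", "p2"] - 2 * cl["p3", "p2"]
    if (is.finite(v) && v >= 0) cv_s_i <- 100 * sqrt(v)
  }

  at_lower <- abs(ltheta - lb) < 1e-6
  residuals <- tibble(
    time_min = times, analyte = "glucose", observed = y,
    fitted = if (is.null(yhat)) NA_real_ else yhat
  )
  residuals$residual <- residuals$observed - residuals$fitted
  residuals$std_residual <- residuals$residual / (cvf * residuals$fitted)

  structure(list(
    model = "MM",
    subject_id = meta$subject_id,
    estimates = theta,
    params = mm_params(theta[["p1"]], theta[["p2"]], theta[["p3"]], theta[["G0"]]),
    S_I = unname(s_i),
    cv_S_I = unname(cv_s_i),
    G_b = meta$G_b, I_b = meta$I_b,
    covariance = covinfo$cov_natural,
    cov_log = covinfo$cov_log,
    cv_percent = covinfo$cv_percent,
    error_cv_glucose = opt$cv_glucose,
    converged = fit$convergence == 0,
    n_iterations = fit$counts[["function"]],
    objective_value = fit$value,
    n_obs = length(y),
    at_lower_bound = setNames(at_lower, free),
    residuals = residuals,
    insulin_input = ins,
    cv_threshold = opt$cv_threshold,
    options = opt,
    data = data
  ), class = c("mm_fit", "ivgtt_fit"))
}
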