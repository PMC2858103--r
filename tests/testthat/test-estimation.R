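test_that("noiseless data at the true parameters are recovered exactly", {
  p <- sdm_params(1.1e-4, 0.05, 20, 3, 10, 40)
  d <- make_test_dataset(p, cv_g = 0, cv_i = 0)
  f <- gls_fit_sdm(d, init = p)
  rel <- abs(f$estimates / unlist(p[ivgttsdm:::sdm_free_names()]) - 1)
  expect_true(all(rel < 1e-3))
  # residuals vanish: the weighted SSE at the starting error CVs is ~zero
  # (the reported objective is rescaled by the shrunken phase-2 CVs)
  wsse <- with(f$residuals, sum((residual / (0.015 * fitted))^2))
  expect_lt(wsse, 1e-6)
  expect_lt(f$error_cv_glucose, 0.01)
  expect_lt(f$error_cv_insulin, 0.01)
})

test_that("a noisy record is fitted with identifiable K_xgI", {
  set.seed(101)
  p <- sdm_params(1.1e-4, 0.05, 20, 3, 10, 40)
  d <- make_test_dataset(p, cv_g = 1.5, cv_i = 7)
  f <- gls_fit_sdm(d)
  expect_true(f$converged)
  expect_lt(abs(f$estimates[["K_xgI"]] / 1.1e-4 - 1), 0.25)
  expect_true(is_identifiable(f$cv_percent[["K_xgI"]]))
  # covariance is symmetric with non-negative diagonal
  expect_equal(f$covariance, t(f$covariance), tolerance = 1e-8)
  expect_true(all(diag(f$covariance) >= 0))
  expect_true(all(f$cv_percent >= 0))
})

test_that("the GLS objective never increases within an accepted iteration", {
  set.seed(55)
  for (k in 1:3) {
    p <- draw_sdm_params()
    d <- make_test_dataset(p, cv_g = 1.5, cv_i = 7,
                           subject_id = paste0("mono", k))
    f <- gls_fit_sdm(d)
    expect_true(all(f$trace$objective_end <= f$trace$objective_start + 1e-8))
  }
})

test_that("estimates are equivariant under insulin unit rescaling", {
  set.seed(77)
  p <- sdm_params(1.1e-4, 0.05, 20, 3, 10, 40)
  d <- make_test_dataset(p, cv_g = 1.5, cv_i = 7)
  c_scale <- 2
  d2 <- ivgtt_dataset(
    tibble::tibble(time_min = d$time_min, glucose_mM = d$glucose_mM,
                   insulin_pM = d$insulin_pM * c_scale),
    subject_id = "scaled", body_weight = 70, bmi = 24)
  f1 <- gls_fit_sdm(d)
  f2 <- gls_fit_sdm(d2)
  expect_equal(f2$estimates[["K_xgI"]], f1$estimates[["K_xgI"]] / c_scale,
               tolerance = 0.01)
  expect_equal(f2$estimates[["I_deltaG"]], f1$estimates[["I_deltaG"]] * c_scale,
               tolerance = 0.01)
})

test_that("phase 2 recovers the generating error CVs", {
  set.seed(303)
  p <- sdm_params(1.1e-4, 0.05, 20, 3, 10, 40)
  cvg <- replicate(5, {
    d <- make_test_dataset(p, cv_g = 1.5, cv_i = 7)
    f <- gls_fit_sdm(d)
    f$error_cv_glucose
  })
  expect_true(mean(cvg) > 1.0 && mean(cvg) < 2.0)
})

test_that("identifiability grading follows the 52% CV rule", {
  expect_false(is_identifiable(68.83))  # the one non-identifiable subject
  expect_true(is_identifiable(51.9))
  expect_false(is_identifiable(52))     # threshold itself is not identifiable
  expect_false(is_identifiable(Inf))
  expect_false(is_identifiable(NA_real_))
  expect_identical(is_identifiable(c(10, 60), threshold = 40), c(TRUE, FALSE))
})

test_that("default initial guesses track the generating excursions", {
  set.seed(99)
  p <- sdm_params(1.3e-4, 0.06, 18, 2.5, G_delta = 10, I_deltaG = 50)
  d <- make_test_dataset(p, cv_g = 1.5, cv_i = 7)
  g <- default_initial_guesses(d)
  expect_lt(abs(g$sdm$G_delta / 10 - 1), 0.2)
  expect_lt(abs(g$sdm$K_xi / 0.06 - 1), 0.8)
  b <- ivgttsdm:::sdm_default_bounds()
  est <- unlist(g$sdm[ivgttsdm:::sdm_free_names()])
  expect_true(all(est > b$lower & est < b$upper))
})

test_that("flat records fall back to fixed starting constants", {
  sched <- ivgtt_schedule()
  d <- ivgtt_dataset(
    tibble::tibble(time_min = sched, glucose_mM = rep(4.5, 23),
                   insulin_pM = rep(60, 23)),
    subject_id = "flat", body_weight = 70, bmi = 24)
  expect_warning(g <- default_initial_guesses(d), regexp = "flat")
  expect_s3_class(g$sdm, "sdm_params")
  expect_s3_class(g$mm, "mm_params")
})

test_that("MM fit recovers S_I from its own simulations", {
  set.seed(5)
  sched <- ivgtt_schedule()
  post <- sched[sched > 0]
  p_ins <- sdm_params(1.1e-4, 0.05, 20, 3, 10, 40)
  tr <- simulate_sdm(p_ins, 4.5, 57.3, post)
  inp <- interpolate_insulin(post, tr$insulin_pM)
  true_mm <- mm_params(p1 = 0.015, p2 = 0.03, p3 = 4e-6, G0 = 12)
  si_true <- mm_insulin_sensitivity(true_mm)
  win <- post[post >= 8]
  early <- post[post < 8]
  errs <- replicate(5, {
    g_true <- simulate_mm(true_mm, inp, 4.5, 57.3, win)$glucose_mM
    g_early <- approx(c(0, win), c(16, g_true), xout = early)$y *
      (1 + 0.015 * rnorm(length(early)))
    d <- ivgtt_dataset(tibble::tibble(
      time_min = sched,
      glucose_mM = c(4.5 * (1 + 0.015 * rnorm(3)), g_early,
                     g_true * (1 + 0.015 * rnorm(length(win)))),
      insulin_pM = c(57.3 * (1 + 0.07 * rnorm(3)), tr$insulin_pM)),
      subject_id = "mmrec", bmi = 24, body_weight = 70)
    f <- wls_fit_mm(d)
    abs(f$S_I / si_true - 1)
  })
  expect_lt(median(errs), 0.2)
})

test_that("the zero-S_I phenomenon is reported, never hidden", {
  # glucose recovering from below basal despite elevated insulin: any
  # insulin action worsens the fit, so p3 is driven into the flat region
  # at its lower bound and the information matrix loses that direction
  set.seed(61)
  sched <- ivgtt_schedule()
  post <- sched[sched > 0]
  g_rise <- 4.5 - 1.8 * exp(-0.03 * post)
  ins <- 60 + 500 * exp(-0.08 * post)
  d <- ivgtt_dataset(tibble::tibble(
    time_min = sched,
    glucose_mM = c(rep(4.5, 3), g_rise) * (1 + 0.01 * rnorm(23)),
    insulin_pM = c(rep(60, 3), ins) * (1 + 0.01 * rnorm(23))),
    subject_id = "zero-si", bmi = 28, body_weight = 80)
  f <- wls_fit_mm(d, init = mm_params(0.03, 0.03, 2e-14, 4))
  expect_lte(f$S_I, 1.5e-12)
  expect_true(flag_extreme_si(f$S_I))
  expect_false(is_identifiable(f$cv_S_I))
})
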