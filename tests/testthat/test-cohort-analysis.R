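test_that("correlations behave on exact and monotone relationships", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1)$estimate, 1)
  expect_equal(correlate(x, exp(x), method = "spearman")$estimate, 1)
  expect_error(correlate(x, rep(1, 10)), class = "ivgttsdm_domain_error")
  expect_error(correlate(1:2, 1:2), class = "ivgttsdm_input_error")
  # missing pairs are dropped
  r <- correlate(c(x, NA), c(2 * (1:10), 5))
  expect_equal(r$n, 10)
  expect_equal(r$estimate, 1)
})

test_that("independent samples show near-zero correlation", {
  set.seed(19)
  x <- rnorm(1e4)
  y <- rnorm(1e4)
  expect_lt(abs(correlate(x, y)$estimate), 0.03)
})

test_that("Bland-Altman log ratios have closed-form bias and limits", {
  v <- c(1e-4, 2e-4, 5e-5)
  ba <- bland_altman_log(v, v)
  expect_equal(attr(ba, "bias"), 0)
  expect_equal(unname(attr(ba, "limits")), c(0, 0))
  ba2 <- bland_altman_log(v, 2 * v)
  expect_equal(attr(ba2, "bias"), -log(2), tolerance = 1e-12)
  expect_equal(attr(ba2, "sd"), 0, tolerance = 1e-12)
  expect_equal(ba2$pair_mean, (v + 2 * v) / 2)
  expect_error(bland_altman_log(v, c(1e-4, 0, 1e-4)),
               class = "ivgttsdm_domain_error")
})

test_that("Bland-Altman bias flips sign under argument swap", {
  set.seed(13)
  a <- exp(rnorm(30, log(1e-4), 0.3))
  b <- exp(rnorm(30, log(1e-4), 0.3))
  ba <- bland_altman_log(a, b)
  ba_sw <- bland_altman_log(b, a)
  expect_equal(attr(ba_sw, "bias"), -attr(ba, "bias"))
  w <- function(x) diff(unname(attr(x, "limits")))
  expect_equal(w(ba_sw), w(ba))
})

test_that("about 95% of normal log ratios fall inside the limits", {
  set.seed(29)
  k <- exp(rnorm(4000, log(1e-4), 0.2))
  s <- k * exp(rnorm(4000, 0, 0.25))
  ba <- bland_altman_log(k, s)
  lim <- attr(ba, "limits")
  inside <- mean(ba$log_ratio > lim[1] & ba$log_ratio < lim[2])
  expect_gt(inside, 0.93)
  expect_lt(inside, 0.97)
})

test_that("one-way ANOVA matches the squared pooled t for two groups", {
  set.seed(37)
  v <- c(rnorm(12, 1), rnorm(15, 1.4))
  g <- rep(c("a", "b"), c(12, 15))
  res <- oneway_anova(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(res$F_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA F is invariant under adding a constant", {
  set.seed(43)
  v <- rnorm(40)
  g <- rep(letters[1:4], each = 10)
  expect_equal(oneway_anova(v + 100, g)$F_statistic,
               oneway_anova(v, g)$F_statistic, tolerance = 1e-10)
  expect_error(oneway_anova(v, rep("a", 40)), class = "ivgttsdm_input_error")
})

test_that("LSD contrasts are unadjusted pooled-variance t tests", {
  set.seed(47)
  v <- c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 2))
  g <- rep(c("a", "b", "c"), each = 10)
  lsd <- lsd_posthoc(v, g)
  expect_equal(nrow(lsd), 3)
  # cross-check against pairwise.t.test with pooled SD and no correction
  ref <- pairwise.t.test(v, g, p.adjust.method = "none", pool.sd = TRUE)
  expect_equal(lsd$p_value[lsd$group1 == "a" & lsd$group2 == "b"],
               ref$p.value["b", "a"], tolerance = 1e-10)
  expect_equal(lsd$p_value[lsd$group1 == "b" & lsd$group2 == "c"],
               ref$p.value["c", "b"], tolerance = 1e-10)
})

test_that("AIR-on-BMI regression recovers an exact slope", {
  bmi <- seq(20, 50, length.out = 30)
  air <- 764 * bmi - 8000
  # the constructed exact line trips lm's perfect-fit warning
  res <- suppressWarnings(regress_air_on_bmi(air, bmi))
  expect_equal(res$beta, 764, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-10)
  expect_error(regress_air_on_bmi(air, rep(30, 30)),
               class = "ivgttsdm_domain_error")
})

test_that("population report subsets purely and summarizes classes", {
  set.seed(53)
  n <- 40
  panel <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    K_xgI = exp(rnorm(n, log(1e-4), 0.4)),
    cv_K_xgI = runif(n, 5, 30),
    S_I = exp(rnorm(n, log(1e-4), 0.5)),
    cv_S_I = runif(n, 5, 80),
    HOMA_IR = runif(n, 0.5, 4),
    inv_HOMA_IR = 1 / HOMA_IR,
    AIR = runif(n, 2000, 25000),
    DI = AIR * K_xgI,
    si_extreme = rep(c(FALSE, TRUE), c(32, 8)),
    bmi = runif(n, 19, 55),
    bmi_class = classify_bmi(runif(n, 19, 55))
  )
  full <- population_report(panel, "full")
  red <- population_report(panel, "reduced")
  expect_equal(full$n, 40)
  expect_equal(red$n, 32)  # reduced subset excludes exactly the flagged rows
  # full-sample statistics unchanged by the existence of the reduced report
  expect_identical(full$class_summary,
                   population_report(panel, "full")$class_summary)
  tot <- full$class_summary[full$class_summary$bmi_class == "total", ]
  expect_equal(tot$mean[tot$index == "K_xgI"], mean(panel$K_xgI))
  expect_false(is.null(red$bland_altman))
  expect_true(all(c("K_xgI", "S_I") %in% red$correlations$x |
                    c("K_xgI", "S_I") %in% red$correlations$y))
})

test_that("degenerate single-value cohorts summarize with zero spread", {
  panel <- tibble::tibble(
    subject_id = c("a", "b"),
    K_xgI = c(1e-4, 1e-4), HOMA_IR = c(1, 1), inv_HOMA_IR = c(1, 1),
    AIR = c(5000, 5000), DI = c(0.5, 0.5),
    bmi = c(22, 22), bmi_class = classify_bmi(c(22, 22))
  )
  rep <- population_report(panel, "full")
  lean <- rep$class_summary[rep$class_summary$bmi_class == "lean", ]
  expect_true(all(lean$sd == 0))
  expect_true(all(lean$se == 0))
  empty <- rep$class_summary[rep$class_summary$bmi_class == "morbid", ]
  expect_true(all(empty$N == 0))
  expect_true(all(is.na(empty$mean)))
})
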