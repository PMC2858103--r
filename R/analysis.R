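# Population-level statistics: correlations between sensitivity indices,
# log-ratio Bland-Altman agreement, one-way ANOVA with LSD post-hoc
# contrasts across BMI classes, and the AIR-BMI regression.

#' Correlation between two insulin sensitivity indices
#'
#' Pearson product-moment or Spearman rank correlation with a two-sided
#' p-value; pairs with missing entries are dropped (pairwise deletion).
#'
#' @param x,y Equal-length numeric vectors.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return One-row tibble: `estimate`, `p_value`, `n`, `method`.
#' @export
#' @examples
#' correlate(1:10, 2 * (1:10) + 1)
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    abort("need at least 3 complete pairs", class = "ivgttsdm_input_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance", class = "ivgttsdm_domain_error")
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
         n = length(x), method = method)
}

#' Log-ratio Bland-Altman agreement between K_xgI and S_I
#'
#' Because the spread of the index differences grows with the index
#' magnitude, agreement is assessed on the natural logarithms of the
#' per-subject ratios `ln(K_xgI / S_I)` against the per-subject arithmetic
#' means of the pair; the 95% limits of agreement are
#' `bias +/- 1.96 * SD(log ratios)`.  Both inputs must be strictly positive:
#' extreme or zero S_I estimates are to be excluded by the caller before the
#' procedure (it is not defined on such samples).
#'
#' @param k_xgi SDM insulin sensitivity estimates, positive.
#' @param s_i MM insulin sensitivity estimates, positive, same length.
#' @return A `bland_altman` object: tibble of per-subject `pair_mean` and
#'   `log_ratio`, plus attributes `bias`, `sd`, `limits`.
#' @export
#' @examples
#' ba <- bland_altman_log(c(1e-4, 2e-4), c(1.1e-4, 1.8e-4))
#' attr(ba, "bias")
bland_altman_log <- function(k_xgi, s_i) {
  stopifnot(length(k_xgi) == length(s_i))
  if (any(!is.finite(k_xgi)) || any(!is.finite(s_i)) ||
      any(k_xgi <= 0) || any(s_i <= 0)) {
    abort(paste("bland_altman_log requires strictly positive indices;",
                "exclude extreme/zero S_I subjects first"),
          class = "ivgttsdm_domain_error")
  }
  lr <- log(k_xgi / s_i)
  bias <- mean(lr)
  s <- if (length(lr) > 1) sd(lr) else 0
  out <- tibble(pair_mean = (k_xgi + s_i) / 2, log_ratio = lr)
  attr(out, "bias") <- bias
  attr(out, "sd") <- s
  attr(out, "limits") <- c(lower = bias - 1.96 * s, upper = bias + 1.96 * s)
  class(out) <- c("bland_altman", class(out))
  out
}

#' One-way ANOVA across BMI classes
#'
#' Classical one-way fixed-effects F test of equality of group means.
#'
#' @param values Numeric response (e.g. `K_xgI`).
#' @param class_labels Grouping factor (e.g. BMI class).
#' @return One-row tibble: `F_statistic`, `p_value`, `df_between`,
#'   `df_within`.
#' @export
oneway_anova <- function(values, class_labels) {
  keep <- is.finite(values) & !is.na(class_labels)
  values <- values[keep]
  g <- droplevels(factor(class_labels[keep]))
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    abort("one-way ANOVA needs >= 2 groups with >= 2 members each",
          class = "ivgttsdm_input_error")
  }
  fit <- aov(values ~ g)
  s <- summary(fit)[[1]]
  tibble(F_statistic = s$`F value`[1], p_value = s$`Pr(>F)`[1],
         df_between = s$Df[1], df_within = s$Df[2])
}

#' Fisher's LSD post-hoc pairwise contrasts
#'
#' Unadjusted pairwise t tests using the pooled within-group variance from
#' the one-way ANOVA (the least-significant-difference procedure; no
#' multiplicity correction, by construction).
#'
#' @inheritParams oneway_anova
#' @return Tibble of pairwise contrasts: `group1`, `group2`, `mean_diff`,
#'   `p_value`.
#' @export
lsd_posthoc <- function(values, class_labels) {
  keep <- is.finite(values) & !is.na(class_labels)
  values <- values[keep]
  g <- droplevels(factor(class_labels[keep]))
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    abort("LSD post-hoc needs >= 2 groups with >= 2 members each",
          class = "ivgttsdm_input_error")
  }
  n <- table(g)
  m <- tapply(values, g, mean)
  # pooled within-group variance = ANOVA mean square error
  mse <- sum(tapply(values, g, function(v) sum((v - mean(v))^2))) /
    (length(values) - nlevels(g))
  df <- length(values) - nlevels(g)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(mse * (1 / n[[a]] + 1 / n[[b]]))
    tstat <- (m[[a]] - m[[b]]) / se
    tibble(group1 = a, group2 = b, mean_diff = m[[a]] - m[[b]],
           p_value = 2 * pt(-abs(tstat), df))
  })
}

#' Linear regression of AIR on BMI
#'
#' Ordinary least-squares slope of the acute insulin response on BMI with a
#' two-sided p-value, testing whether first-phase secretion rises with
#' adiposity.
#'
#' @param air Acute insulin response values (pM min).
#' @param bmi BMI values (kg/m^2).
#' @return One-row tibble: `beta` (slope), `intercept`, `p_value`, `n`.
#' @export
regress_air_on_bmi <- function(air, bmi) {
  keep <- is.finite(air) & is.finite(bmi)
  air <- air[keep]; bmi <- bmi[keep]
  if (length(air) < 3) {
    abort("need at least 3 complete pairs", class = "ivgttsdm_input_error")
  }
  if (sd(bmi) == 0) {
    abort("regression undefined: constant BMI", class = "ivgttsdm_domain_error")
  }
  fit <- lm(air ~ bmi)
  co <- summary(fit)$coefficients
  tibble(beta = co["bmi", "Estimate"], intercept = co["(Intercept)", "Estimate"],
         p_value = co["bmi", "Pr(>|t|)"], n = length(air))
}

#' Population summary of an index panel
#'
#' Per-class and total mean/SD/SE/N for each sensitivity and secretion
#' index, on the full sample or on the reduced sub-sample that excludes
#' extreme-S_I subjects; plus the pairwise correlations among `K_xgI`,
#' `S_I` and `1/HOMA-IR` on the chosen subset, and (on the reduced subset)
#' the log-ratio Bland-Altman of `K_xgI` vs `S_I`.
#'
#' @param panel An [index_panel] tibble.
#' @param subset `"full"` or `"reduced"` (reduced drops `si_extreme` rows).
#' @return A list with `class_summary` (tibble), `correlations` (tibble) and
#'   `bland_altman` (for the reduced subset, else `NULL`), plus `subset` and
#'   `n`.
#' @export
population_report <- function(panel, subset = c("full", "reduced")) {
  subset <- match.arg(subset)
  stopifnot(is.data.frame(panel))
  sub <- panel
  if (subset == "reduced" && "si_extreme" %in% names(panel)) {
    sub <- panel[!panel$si_extreme, , drop = FALSE]
  }
  idx_cols <- intersect(c("K_xgI", "S_I", "inv_HOMA_IR", "HOMA_IR",
                          "AIR", "DI", "HOMA2"), names(sub))
  summarize_group <- function(d, label) {
    purrr::map_dfr(idx_cols, function(col) {
      v <- d[[col]][is.finite(d[[col]])]
      n <- length(v)
      tibble(bmi_class = label, index = col, N = n,
             mean = if (n > 0) mean(v) else NA_real_,
             sd = if (n > 1) sd(v) else NA_real_,
             se = if (n > 1) sd(v) / sqrt(n) else NA_real_)
    })
  }
  by_class <- purrr::map_dfr(bmi_class_levels(), function(cl) {
    summarize_group(sub[sub$bmi_class == cl, , drop = FALSE], cl)
  })
  total <- summarize_group(sub, "total")
  class_summary <- dplyr::bind_rows(by_class, total)

  cor_pairs <- list(c("K_xgI", "S_I"), c("K_xgI", "inv_HOMA_IR"),
                    c("S_I", "inv_HOMA_IR"))
  correlations <- purrr::map_dfr(cor_pairs, function(pr) {
    if (!all(pr %in% names(sub))) return(NULL)
    ok <- is.finite(sub[[pr[1]]]) & is.finite(sub[[pr[2]]])
    if (sum(ok) < 3) return(NULL)
    res <- tryCatch(correlate(sub[[pr[1]]], sub[[pr[2]]]),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    dplyr::mutate(res, x = pr[1], y = pr[2], .before = 1)
  })

  ba <- NULL
  if (subset == "reduced" && all(c("K_xgI", "S_I") %in% names(sub))) {
    ok <- is.finite(sub$K_xgI) & is.finite(sub$S_I) &
      sub$K_xgI > 0 & sub$S_I > 0
    if (sum(ok) >= 3) ba <- bland_altman_log(sub$K_xgI[ok], sub$S_I[ok])
  }

  list(subset = subset, n = nrow(sub), class_summary = class_summary,
       correlations = correlations, bland_altman = ba)
}
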