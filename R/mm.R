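#' Bergman Minimal Model parameter set
#'
#' Glucose kinetics with a remote insulin-action compartment:
#' \deqn{dG/dt = -(p_1 + X) G + p_1 G_b}
#' \deqn{dX/dt = -p_2 X + p_3 (I(t) - I_b)}
#' driven by the interpolated observed insulin `I(t)` (decoupled fitting).
#' `p1` is glucose effectiveness (min^-1), `p2` the remote-compartment decay
#' (min^-1), `p3` the insulin-action gain (min^-2 pM^-1) and `G0` the modelled
#' glucose at the start of the fit window (8 min).  The insulin sensitivity
#' index is `S_I = p3 / p2` (min^-1 pM^-1).
#'
#' @param p1,p2,p3,G0 Model parameters; `p2 > 0`, `p1, p3 >= 0`, `G0 > 0`.
#' @return A one-row `mm_params` tibble.
#' @export
#' @examples
#' mm_params(p1 = 0.02, p2 = 0.03, p3 = 5e-6, G0 = 15)
mm_params <- function(p1, p2, p3, G0) {
  vals <- c(p1 = p1, p2 = p2, p3 = p3, G0 = G0)
  if (any(!is.finite(vals)) || p2 <= 0 || p1 < 0 || p3 < 0 || G0 <= 0) {
    abort("invalid MM parameters: need p2 > 0, p1 >= 0, p3 >= 0, G0 > 0",
          class = "ivgttsdm_domain_error")
  }
  out <- tibble(p1 = p1, p2 = p2, p3 = p3, G0 = G0)
  class(out) <- c("mm_params", class(out))
  out
}

mm_free_names <- function() c("p1", "p2", "p3", "G0")

#' Decoupled insulin input for the Minimal Model
#'
#' Builds the insulin forcing function from observed post-bolus insulin:
#' samples before the first post-bolus insulin peak are disregarded; from the
#' peak to the last sample the input is piecewise linear; before the peak
#' time it is held at the peak value and after the last sample at the last
#' value.  Ties for the peak go to the earliest time.
#'
#' @param times Post-bolus sampling times (min), strictly increasing.
#' @param insulin Observed insulin (pM) at `times`.
#' @return A list with `fun` (vectorised function of t), and the retained
#'   knots `knot_times`, `knot_values`.
#' @export
#' @examples
#' inp <- interpolate_insulin(c(2, 4, 8, 20), c(400, 300, 200, 150))
#' inp$fun(c(0, 3, 100))
interpolate_insulin <- function(times, insulin) {
  if (length(times) != length(insulin) || length(times) < 2) {
    abort("need at least 2 post-bolus insulin samples",
          class = "ivgttsdm_input_error")
  }
  if (any(diff(times) <= 0)) {
    abort("insulin sample times must be strictly increasing",
          class = "ivgttsdm_validation_error")
  }
  peak <- which.max(insulin)  # which.max takes the earliest tie
  kt <- times[peak:length(times)]
  kv <- insulin[peak:length(insulin)]
  if (length(kt) < 2) {
    # peak at the final sample: degenerate interpolant, hold everywhere
    kt <- c(times[peak - 1], times[peak])
    kv <- c(insulin[peak], insulin[peak])
  }
  f <- function(t) {
    approx(kt, kv, xout = pmin(pmax(t, kt[1]), kt[length(kt)]),
           rule = 2)$y
  }
  list(fun = f, knot_times = kt, knot_values = kv)
}

#' Simulate Minimal Model glucose kinetics
#'
#' Integrates the two-state system from the start of the fit window
#' (`t_start = 8` min, with `G(t_start) = G0` and remote action
#' `X(t_start) = 0`) under the piecewise-linear insulin input, with
#' fourth-order Runge-Kutta stepping broken at the input's knots.
#'
#' @param params An [mm_params] set.
#' @param insulin_input Result of [interpolate_insulin()].
#' @param G_b,I_b Basal glucose (mM) and insulin (pM).
#' @param output_times Times (min) at which to report glucose; all
#'   `>= t_start`.
#' @param t_start Start of the fit window (min), default 8.
#' @param h Maximum integration step (min), default 0.1.
#' @return A tibble with `time_min` and `glucose_mM`.
#' @export
simulate_mm <- function(params, insulin_input, G_b, I_b, output_times,
                        t_start = 8, h = 0.1) {
  stopifnot(inherits(params, "mm_params"))
  if (any(output_times < t_start)) {
    abort(sprintf("output_times must lie in the fit window (>= %g min)", t_start),
          class = "ivgttsdm_domain_error")
  }
  ord <- order(output_times)
  g <- .mm_integrate_cpp(as.numeric(output_times[ord]),
                         params$p1, params$p2, params$p3, params$G0,
                         G_b, I_b,
                         as.numeric(insulin_input$knot_times),
                         as.numeric(insulin_input$knot_values),
                         t_start, h)
  out <- tibble(time_min = output_times, glucose_mM = NA_real_)
  out$glucose_mM[ord] <- g
  out
}

#' Minimal Model insulin sensitivity index
#'
#' `S_I = p3 / p2`: the steady-state insulin action per unit insulin above
#' basal, in min^-1 pM^-1 -- the same units as the SDM's `K_xgI`.
#'
#' @param params An [mm_params] set.
#' @return `S_I` (min^-1 pM^-1).
#' @export
#' @examples
#' mm_insulin_sensitivity(mm_params(0.02, 0.02, 1e-5, 15))
mm_insulin_sensitivity <- function(params) {
  stopifnot(inherits(params, "mm_params"))
  if (params$p2 == 0) {
    abort("S_I undefined: p2 = 0", class = "ivgttsdm_domain_error")
  }
  params$p3 / params$p2
}
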