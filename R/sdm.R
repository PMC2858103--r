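#' Single Delay Model parameter set
#'
#' The SDM couples plasma glucose `G` (mM) and insulin `I` (pM) through
#'
#' \deqn{dG/dt = -K_{xgI} I G + T_{gh}/V_g}
#' \deqn{dI/dt = -K_{xi} I + (T_{igmax}/V_i)\,\phi(G(t-\tau_g))}
#'
#' with sigmoidal pancreatic response
#' \eqn{\phi(G) = (G/G^*)^\gamma / (1 + (G/G^*)^\gamma)} and jump initial
#' conditions \eqn{G(0) = G_b + G_\Delta}, \eqn{I(0) = I_b + I_{\Delta G} G_\Delta}
#' over the constant pre-bolus history \eqn{G \equiv G_b}.  Six parameters are
#' free: `K_xgI` (insulin sensitivity, min^-1 pM^-1), `K_xi` (insulin
#' disappearance rate, min^-1), `tau_g` (pancreatic delay, min), `gamma`
#' (progressivity of the pancreatic response, dimensionless), `G_delta`
#' (theoretical glucose rise at t = 0, mM) and `I_deltaG` (first-phase insulin
#' rise per mM glucose, pM/mM).  `G_star` (half-maximal secretion glycemia,
#' default 9 mM) and `V_i` (insulin distribution volume, default 0.25 L/kgBW)
#' are fixed configuration constants; `T_gh` and `T_igmax` are tied to the
#' baseline steady state and only their ratios to the distribution volumes
#' enter the dynamics, so the choice of `V_i` cannot affect simulated
#' concentrations.
#'
#' @param K_xgI,K_xi,tau_g,gamma,G_delta,I_deltaG Free parameters (see above).
#' @param G_star Glycemia of half-maximal insulin secretion (mM), fixed.
#' @param V_i Insulin distribution volume (L/kgBW), fixed.
#' @return A one-row `sdm_params` tibble.
#' @export
#' @examples
#' sdm_params(K_xgI = 1.1e-4, K_xi = 0.05, tau_g = 20, gamma = 3,
#'            G_delta = 10, I_deltaG = 40)
sdm_params <- function(K_xgI, K_xi, tau_g, gamma, G_delta, I_deltaG,
                       G_star = 9, V_i = 0.25) {
  vals <- c(K_xgI = K_xgI, K_xi = K_xi, tau_g = tau_g, gamma = gamma,
            G_delta = G_delta, I_deltaG = I_deltaG, G_star = G_star, V_i = V_i)
  if (any(!is.finite(vals))) {
    abort("all SDM parameters must be finite", class = "ivgttsdm_domain_error")
  }
  if (K_xgI <= 0 || K_xi <= 0 || G_delta < 0 || I_deltaG < 0 ||
      G_star <= 0 || V_i <= 0 || tau_g < 0 || gamma < 0) {
    abort(paste("invalid SDM parameters: K_xgI, K_xi, G_star, V_i must be",
                "positive; tau_g, gamma, G_delta, I_deltaG non-negative"),
          class = "ivgttsdm_domain_error")
  }
  out <- tibble(K_xgI = K_xgI, K_xi = K_xi, tau_g = tau_g, gamma = gamma,
                G_delta = G_delta, I_deltaG = I_deltaG,
                G_star = G_star, V_i = V_i)
  class(out) <- c("sdm_params", class(out))
  out
}

# names of the six free parameters, in estimation order
sdm_free_names <- function() {
  c("K_xgI", "K_xi", "tau_g", "gamma", "G_delta", "I_deltaG")
}

#' Pancreatic response function
#'
#' Fraction of the maximal second-phase insulin release rate delivered at
#' glycemia `G`: \eqn{(G/G^*)^\gamma / (1 + (G/G^*)^\gamma)}.  Equals 1/2 at
#' `G = G_star` for any positive `gamma`; `gamma = 0` gives the constant 1/2
#' (a pancreas unresponsive to circulating glucose); `gamma = 1` is
#' Michaelis-Menten, larger values increasingly sigmoidal.
#'
#' @param G Glucose concentration (mM), positive.
#' @param G_star Half-maximal glycemia (mM), positive.
#' @param gamma Progressivity exponent, non-negative.
#' @return Release fraction in `[0, 1)`.
#' @export
#' @examples
#' pancreatic_response(9, 9, 3)        # half-maximal
#' pancreatic_response(18, 9, 1)       # Michaelis-Menten: 2/3
pancreatic_response <- function(G, G_star, gamma) {
  if (any(!is.finite(G)) || any(G <= 0) || G_star <= 0 || gamma < 0) {
    abort("pancreatic_response requires G > 0, G_star > 0, gamma >= 0",
          class = "ivgttsdm_domain_error")
  }
  if (gamma == 0) return(rep(0.5, length(G)))
  r <- (G / G_star)^gamma
  r / (1 + r)
}

#' Baseline steady-state constraints on T_gh and T_igmax
#'
#' At basal equilibrium the net glucose and insulin drifts vanish, which ties
#' the zero-order hepatic glucose balance and the maximal secretion rate to
#' the other parameters: `T_gh = K_xgI * I_b * G_b * V_g` and
#' `T_igmax = K_xi * I_b * V_i / pancreatic_response(G_b, G_star, gamma)`.
#'
#' @param K_xgI,K_xi SDM rate parameters.
#' @param V_g,V_i Glucose and insulin distribution volumes (L/kgBW).
#' @param G_b,I_b Basal glucose (mM) and insulin (pM).
#' @param G_star,gamma Pancreatic response parameters.
#' @return One-row tibble with `T_gh` (mmol min^-1 kgBW^-1) and `T_igmax`
#'   (pmol min^-1 kgBW^-1).
#' @export
#' @examples
#' steady_state_constraints(1e-4, 0.05, V_g = 0.16, V_i = 0.25,
#'                          G_b = 5, I_b = 60, G_star = 9, gamma = 3)
steady_state_constraints <- function(K_xgI, K_xi, V_g, V_i, G_b, I_b,
                                     G_star, gamma) {
  vals <- c(K_xgI, K_xi, V_g, V_i, G_b, I_b, G_star)
  if (any(!is.finite(vals)) || any(vals <= 0) || gamma < 0) {
    abort("steady_state_constraints requires positive arguments",
          class = "ivgttsdm_domain_error")
  }
  resp <- pancreatic_response(G_b, G_star, gamma)
  if (resp <= 0) {
    abort("degenerate baseline: pancreatic response is zero at G_b",
          class = "ivgttsdm_domain_error")
  }
  tibble(T_gh = K_xgI * I_b * G_b * V_g,
         T_igmax = K_xi * I_b * V_i / resp)
}

#' Right-hand side of the delayed glucose-insulin system
#'
#' Evaluates the instantaneous derivatives at state `(G, I)` with lagged
#' glucose `G_lagged = G(t - tau_g)`, under the baseline steady-state
#' constraints for the given basal pair, so that
#' `sdm_rhs(G_b, I_b, G_b, ...)` is identically `(0, 0)`.
#'
#' @param G,I Current glucose (mM) and insulin (pM).
#' @param G_lagged Glucose at `t - tau_g` (mM).
#' @param params An [sdm_params] set.
#' @param G_b,I_b Basal concentrations.
#' @return One-row tibble with `dG_dt` (mM/min) and `dI_dt` (pM/min).
#' @export
sdm_rhs <- function(G, I, G_lagged, params, G_b, I_b) {
  if (any(c(G, I, G_lagged, G_b, I_b) <= 0)) {
    abort("sdm_rhs requires positive state, lagged glucose and baselines",
          class = "ivgttsdm_domain_error")
  }
  resp_b <- pancreatic_response(G_b, params$G_star, params$gamma)
  tgh_vg <- params$K_xgI * I_b * G_b          # T_gh / V_g
  tig_vi <- params$K_xi * I_b / resp_b        # T_igmax / V_i
  tibble(
    dG_dt = -params$K_xgI * I * G + tgh_vg,
    dI_dt = -params$K_xi * I +
      tig_vi * pancreatic_response(G_lagged, params$G_star, params$gamma)
  )
}

#' Simulate the Single Delay Model
#'
#' Integrates the delayed system by the method of steps: breakpoints at every
#' multiple of `tau_g` (where the initial jump propagates derivative
#' discontinuities), fourth-order Runge-Kutta inside each segment, and a
#' cubic-Hermite dense history supplying the lagged glucose between nodes.
#' `tau_g = 0` degenerates to an ordinary ODE solved with the lag equal to
#' current glucose.  The pre-bolus history is constant `G_b` on
#' `[-tau_g, 0)`.
#'
#' @param params An [sdm_params] set.
#' @param G_b,I_b Basal glucose (mM) and insulin (pM).
#' @param output_times Post-bolus times (min) at which to report the state;
#'   non-negative, typically the post-bolus part of [ivgtt_schedule()].
#' @param h Maximum integration step (min); default 0.1.
#' @return A tibble with `time_min`, `glucose_mM`, `insulin_pM`.
#' @export
#' @examples
#' p <- sdm_params(K_xgI = 1.1e-4, K_xi = 0.05, tau_g = 20, gamma = 3,
#'                 G_delta = 10, I_deltaG = 40)
#' simulate_sdm(p, G_b = 4.5, I_b = 57.3, output_times = c(0, 10, 60, 180))
simulate_sdm <- function(params, G_b, I_b, output_times, h = 0.1) {
  stopifnot(inherits(params, "sdm_params"))
  if (G_b <= 0 || I_b <= 0) {
    abort("basal concentrations must be positive", class = "ivgttsdm_domain_error")
  }
  if (any(output_times < 0)) {
    abort("output_times must be post-bolus (>= 0)", class = "ivgttsdm_domain_error")
  }
  ord <- order(output_times)
  res <- .sdm_integrate_cpp(as.numeric(output_times[ord]),
                            params$K_xgI, params$K_xi, params$tau_g,
                            params$gamma, params$G_delta, params$I_deltaG,
                            params$G_star, G_b, I_b, h)
  out <- tibble(time_min = output_times, glucose_mM = NA_real_,
                insulin_pM = NA_real_)
  out$glucose_mM[ord] <- res[, 1]
  out$insulin_pM[ord] <- res[, 2]
  out
}
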