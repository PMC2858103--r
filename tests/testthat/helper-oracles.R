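# Independent brute-force oracles: fixed-step explicit Euler integration of
# the two model systems, written directly from the model equations and kept
# free of any package integrator code.

euler_sdm <- function(K_xgI, K_xi, tau_g, gamma, G_delta, I_deltaG,
                      G_star, G_b, I_b, out_times, dt = 1e-3) {
  phi <- function(G) {
    if (gamma == 0) return(0.5)
    r <- (G / G_star)^gamma
    r / (1 + r)
  }
  tgh_vg <- K_xgI * I_b * G_b
  tig_vi <- K_xi * I_b / phi(G_b)
  t_end <- max(out_times)
  n <- round(t_end / dt)
  lag_frac <- tau_g / dt           # fractional lag, linearly interpolated
  lag_lo <- floor(lag_frac)
  lag_w <- lag_frac - lag_lo
  Gh <- numeric(n + 1)
  G <- G_b + G_delta
  I <- I_b + I_deltaG * G_delta
  Gh[1] <- G
  out <- matrix(NA_real_, length(out_times), 2)
  grab <- function(i, G, I) {
    hit <- which(abs(out_times - i * dt) < dt / 2)
    if (length(hit) > 0) out[hit, ] <<- matrix(c(G, I), length(hit), 2,
                                               byrow = TRUE)
  }
  grab(0, G, I)
  for (i in seq_len(n)) {
    glag <- if (tau_g == 0) G else {
      j <- i - 1 - lag_lo          # index of G((i-1)dt - lag_lo*dt), 0-based
      if (j < 1) G_b   # lag argument still inside the pre-bolus history
      else (1 - lag_w) * Gh[j + 1] + lag_w * Gh[j]
    }
    dG <- -K_xgI * I * G + tgh_vg
    dI <- -K_xi * I + tig_vi * phi(glag)
    G <- G + dt * dG
    I <- I + dt * dI
    Gh[i + 1] <- G
    grab(i, G, I)
  }
  out
}

euler_mm <- function(p1, p2, p3, G0, G_b, I_b, ins_t, ins_v, out_times,
                     t_start = 8, dt = 1e-3) {
  ins <- function(t) {
    if (t <= ins_t[1]) return(ins_v[1])
    if (t >= ins_t[length(ins_t)]) return(ins_v[length(ins_v)])
    approx(ins_t, ins_v, xout = t)$y
  }
  t_end <- max(out_times)
  n <- round((t_end - t_start) / dt)
  G <- G0; X <- 0
  out <- rep(NA_real_, length(out_times))
  grab <- function(tt, G) {
    hit <- which(abs(out_times - tt) < dt / 2)
    if (length(hit) > 0) out[hit] <<- G
  }
  grab(t_start, G)
  for (i in seq_len(n)) {
    tt <- t_start + (i - 1) * dt
    dG <- -(p1 + X) * G + p1 * G_b
    dX <- -p2 * X + p3 * (ins(tt) - I_b)
    G <- G + dt * dG
    X <- X + dt * dX
    grab(t_start + i * dt, G)
  }
  out
}

# random-but-valid SDM parameter draws for property tests
draw_sdm_params <- function() {
  sdm_params(
    K_xgI = exp(runif(1, log(2e-5), log(3e-4))),
    K_xi = runif(1, 0.02, 0.12),
    tau_g = runif(1, 5, 40),
    gamma = runif(1, 1, 5),
    G_delta = runif(1, 6, 16),
    I_deltaG = runif(1, 20, 120)
  )
}

post_schedule <- function() {
  s <- ivgtt_schedule()
  s[s > 0]
}

# small synthetic record built straight from a simulated trajectory
make_test_dataset <- function(params = NULL, G_b = 4.5, I_b = 57.3,
                              cv_g = 0, cv_i = 0, subject_id = "T1",
                              bmi = 24, body_weight = 70) {
  if (is.null(params)) {
    params <- sdm_params(1.1e-4, 0.05, 20, 3, 10, 40)
  }
  sched <- ivgtt_schedule()
  post <- sched[sched > 0]
  sim <- simulate_sdm(params, G_b, I_b, post)
  ng <- length(post)
  g <- sim$glucose_mM * (1 + cv_g / 100 * rnorm(ng))
  i <- sim$insulin_pM * (1 + cv_i / 100 * rnorm(ng))
  pre <- sched[sched <= 0]
  gpre <- G_b * (1 + cv_g / 100 * rnorm(length(pre)))
  ipre <- I_b * (1 + cv_i / 100 * rnorm(length(pre)))
  ivgtt_dataset(
    tibble::tibble(time_min = sched,
                   glucose_mM = pmax(c(gpre, g), 1e-6),
                   insulin_pM = pmax(c(ipre, i), 1e-6)),
    subject_id = subject_id, body_weight = body_weight, bmi = bmi
  )
}
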