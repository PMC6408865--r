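# Independent oracles used across tests. These reimplement model quantities
# from first principles (closed forms, brute-force integration) and never
# call the package's own solvers.

# Bateman function: one-compartment oral closed form, per-unit amount.
oracle_bateman <- function(t, amt, ka, v, ke) {
  ifelse(t > 0, amt * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t)), 0)
}

# Placebo TAG excursion for a single challenge: double-exponential closed
# form around the baseline steady state.
oracle_placebo_tag <- function(t, r0, a_mg, v_tag, ka_tag, kout, t_load) {
  tau <- pmax(t - t_load, 0)
  r0 + (a_mg / v_tag) * (ka_tag / (ka_tag - kout)) *
    (exp(-kout * tau) - exp(-ka_tag * tau))
}

# Fixed-step classical Runge-Kutta integration of the TAG ODE with an
# arbitrary inhibition input; scalar, deliberately brute force.
oracle_rk4_tag <- function(times_out, r0, a_g, v_tag, ka_tag, kout,
                           t_chal, tlag, inh_fun, h = 1e-3) {
  L <- t_chal + tlag
  m <- a_g * 1000
  f <- function(t, C) {
    a <- if (t >= L) m * exp(-ka_tag * (t - L)) else 0
    r0 * kout + a / v_tag * ka_tag * inh_fun(t) - kout * C
  }
  tmax <- max(times_out)
  n <- ceiling(tmax / h)
  tcur <- 0; C <- r0
  out <- numeric(length(times_out)); oi <- 1
  for (k in seq_len(n + 1)) {
    while (oi <= length(times_out) && abs(tcur - times_out[oi]) < h / 2) {
      out[oi] <- C; oi <- oi + 1
    }
    if (oi > length(times_out)) break
    k1 <- f(tcur, C)
    k2 <- f(tcur + h / 2, C + h / 2 * k1)
    k3 <- f(tcur + h / 2, C + h / 2 * k2)
    k4 <- f(tcur + h, C + h * k3)
    C <- C + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    tcur <- tcur + h
  }
  out
}

# Composite Simpson rule on a regular grid (odd number of points).
oracle_simpson <- function(y, h) {
  n <- length(y) - 1
  stopifnot(n %% 2 == 0)
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  sum(w * y) * h / 3
}

# Small noise-free rat-like dataset and spec for estimation tests.
tiny_rat_setup <- function(n_per_arm = c(2, 3, 3, 3, 0), resid = NULL,
                           omega_cv = c(), seed = 11, sim_h = 0.02,
                           tag_times = NULL) {
  design <- make_design("rat", n_per_arm = n_per_arm)
  if (!is.null(tag_times)) design$tag_times <- tag_times
  truth <- species_truth("rat")
  truth$omega_cv <- omega_cv
  if (!is.null(resid)) truth$resid <- resid
  spec <- default_model_spec("rat")
  spec$omega_cv <- omega_cv
  # fits start from the species default residual error regardless of the
  # simulation noise (a near-zero sigma start makes the objective
  # needle-sharp around the starting point)
  list(design = design, truth = truth, spec = spec,
       data = simulate_study(design, truth, seed = seed, sim_h = sim_h))
}
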