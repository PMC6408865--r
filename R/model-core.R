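#' Fractional inhibition of exogenous TAG input
#'
#' Saturable inhibition of the dietary TAG input by a DGAT1 inhibitor:
#' `Inh(C) = 1 - C / (C + IC50)`, where `C` is the free drug concentration.
#' The value is the fraction of the exogenous input that still reaches
#' plasma: 1 with no drug, 0.5 at `C = IC50`, approaching 0 at saturating
#' exposure.
#'
#' @param c_free free drug concentration(s), umol/L, non-negative.
#' @param ic50 free concentration giving 50% inhibition (umol/L), > 0.
#' @return Fraction(s) in (0, 1].
#' @examples
#' inhibition(c(0, 0.0078, 3 * 0.0078), 0.0078)
#' @export
inhibition <- function(c_free, ic50) {
  if (!is.numeric(ic50) || length(ic50) != 1L || !is.finite(ic50) || ic50 <= 0)
    stop("inhibition: 'ic50' must be a single positive number", call. = FALSE)
  if (any(c_free < 0)) stop("inhibition: concentrations must be >= 0",
                            call. = FALSE)
  ic50 / (c_free + ic50)
}

#' Free drug concentration from total concentration
#'
#' Applies a constant plasma free fraction: `c_free = total * fu`. Used when
#' importing total-concentration assay data; all model computations are on
#' the free scale.
#'
#' @param total_conc total plasma concentration(s), >= 0.
#' @param fu unbound fraction in (0, 1].
#' @export
free_concentration <- function(total_conc, fu) {
  if (!is.numeric(fu) || length(fu) != 1L || fu <= 0 || fu > 1)
    stop("free_concentration: 'fu' must lie in (0, 1]", call. = FALSE)
  if (any(total_conc < 0))
    stop("free_concentration: concentrations must be >= 0", call. = FALSE)
  total_conc * fu
}

#' Grams of TAG delivered by a mixed meal
#'
#' Converts the fat energy content of a meal to grams of triglyceride using
#' 9 kcal of fat per gram of TAG.
#'
#' @param energy_kcal total energy content of the meal (kcal), >= 0.
#' @param fat_fraction fraction of energy from fat, in \[0, 1\].
#' @return grams of TAG.
#' @examples
#' meal_tag_dose(1100, 0.60)
#' @export
meal_tag_dose <- function(energy_kcal, fat_fraction) {
  if (any(fat_fraction < 0 | fat_fraction > 1))
    stop("meal_tag_dose: 'fat_fraction' must lie in [0, 1]", call. = FALSE)
  if (any(energy_kcal < 0))
    stop("meal_tag_dose: 'energy_kcal' must be >= 0", call. = FALSE)
  energy_kcal * fat_fraction / 9
}

#' Grams of TAG delivered by an oil gavage
#'
#' Converts a per-kg oil (or oil emulsion) gavage volume to grams of TAG:
#' `volume_per_kg * body_weight * oil_fraction * density`. The oil is
#' assumed to be 100% fat; for emulsions `oil_fraction` is the oil content.
#'
#' @param volume_per_kg administered volume per kg body weight (mL/kg).
#' @param body_weight subject body weight (kg).
#' @param oil_fraction oil fraction of the formulation, in (0, 1].
#' @param density oil density (g/mL), e.g. 0.9 for corn oil and 0.917 for
#'   soybean oil.
#' @return grams of TAG.
#' @examples
#' oil_tag_dose(5, 0.23, 1, 0.9)        # corn oil gavage, rat
#' oil_tag_dose(10, 0.025, 0.2, 0.917)  # 20% soybean emulsion, mouse
#' @export
oil_tag_dose <- function(volume_per_kg, body_weight, oil_fraction = 1,
                         density = 0.9) {
  if (any(oil_fraction <= 0 | oil_fraction > 1))
    stop("oil_tag_dose: 'oil_fraction' must lie in (0, 1]", call. = FALSE)
  if (any(volume_per_kg < 0) || any(body_weight < 0) || any(density < 0))
    stop("oil_tag_dose: inputs must be >= 0", call. = FALSE)
  volume_per_kg * body_weight * oil_fraction * density
}

# Unit impulse responses (free concentration per umol dosed) ----------------

pk_unit_1cpt <- function(tau, ka, v, ke) {
  tau <- pmax(tau, 0)
  if (abs(ka - ke) < 1e-7 * ka) {
    k <- (ka + ke) / 2
    k * tau * exp(-k * tau) / v
  } else {
    ka / (v * (ka - ke)) * (exp(-ke * tau) - exp(-ka * tau))
  }
}

pk_unit_2cpt <- function(tau, ka, v, k10, k12, k21) {
  tau <- pmax(tau, 0)
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  al <- (s + disc) / 2
  be <- (s - disc) / 2
  # nudge ka away from a macro rate constant to keep coefficients finite
  if (min(abs(ka - al), abs(ka - be)) < 1e-8 * ka) ka <- ka * (1 + 1e-6)
  ca <- (k21 - al) / ((ka - al) * (be - al))
  cb <- (k21 - be) / ((ka - be) * (al - be))
  ck <- (k21 - ka) / ((al - ka) * (be - ka))
  ka / v * (ca * exp(-al * tau) + cb * exp(-be * tau) + ck * exp(-ka * tau))
}

#' Free drug concentration profile under multiple dosing
#'
#' Evaluates the closed-form one- or two-compartment first-order-absorption
#' model by linear superposition over dosing events and returns free plasma
#' concentrations (PK parameters are defined on the free-concentration
#' scale). Concentration is zero before the first dose.
#'
#' @param times evaluation grid (h), non-decreasing.
#' @param doses data frame with columns `time` (h) and `amount` (mg, or
#'   mg/kg when `params` are per-kg rodent parameters); amounts >= 0.
#' @param params a [pk_params()] object.
#' @return numeric vector of free concentrations (umol/L) at `times`.
#' @examples
#' p <- species_truth("human")$pk
#' pk_profile(0:12, data.frame(time = 0, amount = 20), p)
#' @export
pk_profile <- function(times, doses, params) {
  stopifnot(inherits(params, "pk_params"))
  if (is.unsorted(times)) stop("pk_profile: 'times' must be ordered",
                               call. = FALSE)
  if (!all(c("time", "amount") %in% names(doses)))
    stop("pk_profile: 'doses' needs columns 'time' and 'amount'",
         call. = FALSE)
  if (any(doses$amount < 0))
    stop("pk_profile: dose amounts must be >= 0", call. = FALSE)
  conc <- numeric(length(times))
  if (nrow(doses) == 0L) return(conc)
  ke <- params$cl / params$v
  for (i in seq_len(nrow(doses))) {
    amt_umol <- doses$amount[i] / params$mw * 1000
    if (amt_umol == 0) next
    tau <- times - doses$time[i]
    u <- if (n_compartments(params) == 1L) {
      pk_unit_1cpt(tau, params$ka, params$v, ke)
    } else {
      pk_unit_2cpt(tau, params$ka, params$v, ke,
                   params$cl2 / params$v, params$cl2 / params$v2)
    }
    conc <- conc + amt_umol * ifelse(tau > 0, u, 0)
  }
  conc
}

# Step kernels for the exponential integrator ------------------------------
# J0 = int_0^d exp(-kout (d-u) - katag u) du; J1 adds a factor u. Series
# branches keep the kout ~ katag limit accurate.

step_J0 <- function(d, kout, katag) {
  mu <- kout - katag
  e0 <- exp(-kout * d)
  x <- mu * d
  small <- abs(x) < 1e-3
  out <- numeric(length(d))
  out[!small] <- (exp(-katag * d[!small]) - e0[!small]) / mu
  ds <- d[small]; xs <- x[small]
  out[small] <- ds * e0[small] * (1 + xs / 2 + xs^2 / 6 + xs^3 / 24)
  out
}

step_J1 <- function(d, kout, katag) {
  mu <- kout - katag
  e0 <- exp(-kout * d)
  x <- mu * d
  small <- abs(x) < 1e-3
  out <- numeric(length(d))
  if (any(!small)) {
    emu <- exp(x[!small])
    out[!small] <- e0[!small] *
      (d[!small] * emu / mu - (emu - 1) / mu^2)
  }
  ds <- d[small]; xs <- x[small]
  out[small] <- ds^2 * e0[small] * (1 / 2 + xs / 3 + xs^2 / 8 + xs^3 / 30)
  out
}

# Stable cumulative solution of D[j] = D[j-1] * exp(-kout h_j) + q[j],
# blocked so no intermediate exponential exceeds exp(200).
decay_accumulate <- function(t, q, kout) {
  n <- length(q)
  D <- numeric(n)
  start <- 1L
  Dprev <- 0
  while (start <= n) {
    tb <- t[start]
    end <- start
    while (end < n && kout * (t[end + 2L] - tb) <= 200) end <- end + 1L
    idx <- start:end
    te <- t[idx + 1L]
    # carry enters as the value at t[start] (= tb) decayed across the block
    acc <- cumsum(q[idx] * exp(kout * (te - tb))) + Dprev
    D[idx] <- exp(-kout * (te - tb)) * acc
    Dprev <- D[end]
    start <- end + 1L
  }
  D
}

#' Simulate the plasma TAG excursion
#'
#' Integrates the TAG turnover system for a single subject: each lipid
#' challenge loads the depot with its TAG mass (grams, converted to mg) at
#' `challenge time + tlag_tag`; the depot empties with rate `ka_tag`; the
#' fraction `inhibition_input(t)` of the depot outflow reaches plasma (the
#' inhibited remainder is malabsorbed and leaves the system); plasma TAG
#' turns over with rate `kout` around the baseline `r0`.
#'
#' The integrator takes exact exponential steps: within each step the depot
#' is analytic and only the inhibition input is linearly interpolated, so
#' with a constant inhibition input (e.g. placebo) the solution is exact to
#' floating-point accuracy.
#'
#' @param params a [tag_params()] object.
#' @param challenges data frame with columns `time` (h) and `tag_mass`
#'   (grams of TAG, >= 0). May have zero rows.
#' @param inhibition_input function of time returning the fraction of
#'   exogenous input reaching plasma (in \[0, 1\]); default is no drug.
#' @param times output grid (h), strictly increasing, starting at or after
#'   0; the system is at baseline steady state at time 0.
#' @param h internal refinement step (h) used between output points.
#' @return A tibble with columns `time`, `c_tag` (mg/dL), `a_tag`
#'   (remaining depot mass, mg) and `exog_rate` (realized exogenous input
#'   rate, mg/dL/h).
#' @examples
#' p <- species_truth("human")$tag
#' sim <- simulate_tag(p, data.frame(time = 0, tag_mass = 73.3),
#'                     times = seq(0, 8, 0.5))
#' @export
simulate_tag <- function(params, challenges,
                         inhibition_input = function(t) rep(1, length(t)),
                         times, h = 0.02) {
  stopifnot(inherits(params, "tag_params"))
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE))
    stop("simulate_tag: 'times' must be strictly increasing", call. = FALSE)
  if (times[1] < 0) stop("simulate_tag: times must be >= 0", call. = FALSE)
  if (nrow(challenges) > 0 && any(challenges$tag_mass < 0))
    stop("simulate_tag: 'tag_mass' must be >= 0", call. = FALSE)
  ka <- params$ka_tag; vt <- params$v_tag; kout <- params$kout
  r0 <- params$r0; lag <- params$tlag_tag

  load_t <- if (nrow(challenges)) challenges$time + lag else numeric(0)
  load_m <- if (nrow(challenges)) challenges$tag_mass * 1000 else numeric(0)

  tmax <- max(times)
  grid <- sort(unique(round(c(0, times, seq(0, tmax, by = h),
                              load_t[load_t <= tmax]), 9)))
  n <- length(grid) - 1L
  if (n == 0L) {
    ct <- r0
  } else {
    ts <- grid[-length(grid)]            # step starts
    te <- grid[-1L]                      # step ends
    hh <- te - ts
    inh <- inhibition_input(grid)
    if (any(inh < 0 | inh > 1 | !is.finite(inh)))
      stop("simulate_tag: inhibition input must lie in [0, 1]", call. = FALSE)
    c0 <- inh[-length(inh)]
    slope <- (inh[-1L] - c0) / hh
    q <- numeric(n)
    J0 <- step_J0(hh, kout, ka)
    J1 <- step_J1(hh, kout, ka)
    for (ci in seq_along(load_t)) {
      act <- ts >= load_t[ci] - 1e-12
      if (!any(act)) next
      A0 <- load_m[ci] * exp(-ka * (ts[act] - load_t[ci]))
      q[act] <- q[act] +
        (ka / vt) * A0 * (c0[act] * J0[act] + slope[act] * J1[act])
    }
    D <- decay_accumulate(grid, q, kout)
    ct <- r0 + c(0, D)
  }
  a_tag <- rep(0, length(grid))
  for (ci in seq_along(load_t)) {
    on <- grid >= load_t[ci] - 1e-12
    a_tag[on] <- a_tag[on] + load_m[ci] * exp(-ka * (grid[on] - load_t[ci]))
  }
  keep <- match(round(times, 9), grid)
  inh_out <- inhibition_input(times)
  tibble::tibble(
    time = times,
    c_tag = ct[keep],
    a_tag = a_tag[keep],
    exog_rate = ka * a_tag[keep] / vt * inh_out
  )
}
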