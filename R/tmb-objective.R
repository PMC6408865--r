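# Internal bridge between long-format observation tables and the compiled
# likelihood template.

.slot_index <- function(names) {
  i <- match(names, .par_slots)
  if (anyNA(i)) stop("unknown parameter name(s): ",
                     paste(names[is.na(i)], collapse = ", "), call. = FALSE)
  i - 1L
}

#' Default model specification for a species
#'
#' Bundles everything the estimation layer needs to know about a species
#' template: starting values (the published population estimates), the IIV
#' structure (which parameters carry random effects and their magnitudes),
#' residual error, covariate model, conventionally fixed parameters, the
#' compartment count, and the quadrature resolution of the likelihood.
#'
#' @param species `"human"`, `"rat"` or `"mouse"`.
#' @param mw molecular weight for dose conversion (g/mol).
#' @param iiv_convention how IIV percentages map to log-scale SDs, see
#'   [cv_to_omega()].
#' @param n_quad even number of Simpson panels used for the per-challenge
#'   convolution integral in the likelihood; 32 resolves the fastest
#'   turnover time scales of all three species to well below the residual
#'   error.
#' @return A list of class `oltt_spec`.
#' @export
default_model_spec <- function(species = c("human", "rat", "mouse"),
                               mw = 420,
                               iiv_convention = c("cv", "omega"),
                               n_quad = 32) {
  species <- match.arg(species)
  iiv_convention <- match.arg(iiv_convention)
  truth <- species_truth(species, mw = mw)
  if (n_quad %% 2 != 0) stop("'n_quad' must be even", call. = FALSE)
  structure(list(
    species = species,
    init = truth,
    omega_cv = truth$omega_cv,
    resid = truth$resid,
    covariates = truth$covariates,
    fixed = truth$fixed,
    dose_unit = truth$dose_unit,
    n_cmt = n_compartments(truth$pk),
    mw = mw,
    fu = truth$pk$fu,
    n_quad = as.integer(n_quad),
    lag_smooth = 0.01,
    iiv_convention = iiv_convention,
    estimate_bmi = species == "human"
  ), class = "oltt_spec")
}

# Assemble TMB data/parameters/map for one likelihood stage.
# par: named natural-scale 11-vector; omega_cv named %CV vector (defines the
# eta structure); sig: c(pk, tag); stage: "pk", "tag" or "joint".
make_tmb_inputs <- function(data, spec, par, omega_cv, sig,
                            stage = c("joint", "pk", "tag")) {
  stage <- match.arg(stage)
  validate_dataset(data)
  # the PK stage has no random effects (no IIV on PK in the study
  # templates): drop the eta structure so its OFV carries no prior terms
  if (stage == "pk") omega_cv <- omega_cv[0]
  kinds <- switch(stage, pk = "pk", tag = "tag", joint = c("pk", "tag"))
  data$.row <- seq_len(nrow(data))
  obs <- data[data$kind %in% kinds, , drop = FALSE]
  obs$row <- obs$.row
  if (nrow(obs) == 0L) stop("no '", paste(kinds, collapse = "/"),
                            "' observations in the dataset", call. = FALSE)
  subjects <- sort(unique(obs$subject))
  n_subj <- length(subjects)

  cov <- spec$covariates
  sub1 <- data[!duplicated(data$subject), , drop = FALSE]
  sub1 <- sub1[match(subjects, sub1$subject), , drop = FALSE]
  bw <- if ("bw" %in% names(sub1)) sub1$bw else rep(cov$bw_ref, n_subj)
  bmi <- if ("bmi" %in% names(sub1)) sub1$bmi else rep(cov$bmi_ref, n_subj)
  bw[is.na(bw)] <- cov$bw_ref
  bmi[is.na(bmi)] <- cov$bmi_ref

  doses <- data[data$kind == "dose" & data$amount > 0, , drop = FALSE]
  chals <- data[data$kind == "challenge" & data$amount > 0, , drop = FALSE]

  obs_l <- dose_l <- chal_l <- vector("list", n_subj)
  for (i in seq_len(n_subj)) {
    sid <- subjects[i]
    oi <- obs[obs$subject == sid, , drop = FALSE]
    oi <- oi[order(oi$kind, oi$time), , drop = FALSE]
    obs_l[[i]] <- data.frame(type = as.integer(oi$kind == "tag"),
                             time = oi$time, y = oi$value, row = oi$row)
    di <- doses[doses$subject == sid, , drop = FALSE]
    ci <- chals[chals$subject == sid, , drop = FALSE]
    # drug-free challenges (no dosing, or a baseline occasion completed
    # long before the first dose) admit the analytic placebo solution
    ci$drugfree <- if (nrow(di) == 0L) rep(1L, nrow(ci)) else
      as.integer(ci$time + 12 <= min(di$time))
    dose_l[[i]] <- di
    chal_l[[i]] <- ci
  }
  lens <- function(l) vapply(l, NROW, integer(1))
  starts <- function(n) c(0L, cumsum(n))[seq_along(n)]
  obs_all <- do.call(rbind, obs_l)

  n_eta <- length(omega_cv)
  eta_par <- if (n_eta) .slot_index(names(omega_cv)) else integer(0)

  tmb_data <- list(
    n_cmt = spec$n_cmt,
    n_subj = n_subj,
    n_quad = spec$n_quad,
    lag_smooth = spec$lag_smooth %||% 0.01,
    obs_start = starts(lens(obs_l)), obs_len = lens(obs_l),
    obs_type = obs_all$type, obs_time = obs_all$time, obs_y = obs_all$y,
    dose_start = starts(lens(dose_l)), dose_len = lens(dose_l),
    dose_time = as.numeric(unlist(lapply(dose_l, `[[`, "time"))),
    dose_umol = as.numeric(unlist(lapply(dose_l, `[[`, "amount"))) /
      spec$mw * 1000,
    chal_start = starts(lens(chal_l)), chal_len = lens(chal_l),
    chal_time = as.numeric(unlist(lapply(chal_l, `[[`, "time"))),
    chal_mg = as.numeric(unlist(lapply(chal_l, `[[`, "amount"))) * 1000,
    chal_drugfree = as.integer(unlist(lapply(chal_l, `[[`, "drugfree"))),
    bw_frac = bw / cov$bw_ref,
    bmi_frac = bmi / cov$bmi_ref,
    eta_par = eta_par
  )

  omega <- cv_to_omega(unname(omega_cv), spec$iiv_convention)
  parameters <- list(
    logtheta = log(unname(par[.par_slots])),
    theta_bmi = cov$bmi_on_r0,
    theta_allo_cl = cov$bw_on_cl,
    theta_allo_v = cov$bw_on_v,
    log_omega = log(pmax(omega, 1e-4)),
    log_sig_pk = log(sig[["pk"]]),
    log_sig_tag = log(sig[["tag"]]),
    eta = matrix(0, n_subj, n_eta)
  )

  pk_slots <- c("ka", "v", "cl", if (spec$n_cmt == 2) c("v2", "cl2"))
  pd_slots <- c("r0", "kout", "ka_tag", "v_tag", "tlag_tag", "ic50")
  est_slots <- switch(stage,
    pk = pk_slots,
    tag = pd_slots,
    joint = c(pk_slots, pd_slots))
  est_slots <- setdiff(est_slots, spec$fixed)

  fac <- rep(NA_integer_, 11)
  fac[.slot_index(est_slots) + 1L] <- seq_along(est_slots)
  map <- list(
    logtheta = factor(fac),
    theta_allo_cl = factor(NA),
    theta_allo_v = factor(NA),
    theta_bmi = factor(
      if (stage != "pk" && isTRUE(spec$estimate_bmi)) 1 else NA),
    log_sig_pk = factor(if (stage == "tag") NA else 1),
    log_sig_tag = factor(if (stage == "pk") NA else 1)
  )

  list(data = tmb_data, parameters = parameters, map = map,
       random = if (n_eta > 0 && stage != "pk") "eta" else NULL,
       n_eta = n_eta, omega_names = names(omega_cv),
       subjects = subjects, est_slots = est_slots,
       obs_rows = obs_all$row, stage = stage)
}

make_tmb_obj <- function(inp) {
  TMB::MakeADFun(data = inp$data, parameters = inp$parameters,
                 map = inp$map, random = inp$random,
                 DLL = "olttmod", silent = TRUE)
}
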