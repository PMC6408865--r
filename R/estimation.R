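#' Optimizer settings for population fits
#'
#' @param eval.max,iter.max `nlminb` budget for the outer optimization.
#' @param rel.tol relative OFV convergence tolerance.
#' @param par_tol relative parameter-change tolerance (`x.tol`).
#' @param n_starts number of optimization starts; starts beyond the first
#'   jitter the initial log-parameters with SD `jitter_sd` (seeded).
#' @param jitter_sd log-scale SD of the start jitter.
#' @param seed seed for the (optional) stochastic restarts.
#' @export
fit_control <- function(eval.max = 600, iter.max = 400, rel.tol = 1e-6,
                        par_tol = 1e-4, n_starts = 1, jitter_sd = 0.2,
                        seed = 1L) {
  list(eval.max = eval.max, iter.max = iter.max, rel.tol = rel.tol,
       par_tol = par_tol, n_starts = n_starts, jitter_sd = jitter_sd,
       seed = as.integer(seed))
}

# One likelihood stage: build the TMB objective and minimize it.
fit_stage <- function(data, spec, par, omega_cv, sig, stage, control) {
  inp <- make_tmb_inputs(data, spec, par, omega_cv, sig, stage)
  obj <- make_tmb_obj(inp)
  n_flag <- 0L
  fn <- function(p) {
    v <- tryCatch(as.numeric(obj$fn(p)), error = function(e) NaN)
    if (!is.finite(v)) { n_flag <<- n_flag + 1L; return(1e10) }
    v
  }
  gr <- function(p) {
    g <- tryCatch(obj$gr(p), error = function(e) NULL)
    if (is.null(g) || any(!is.finite(g))) rep(0, length(p)) else as.numeric(g)
  }
  nm <- names(obj$par)
  lower <- ifelse(nm == "log_omega", -8, -25)
  upper <- ifelse(nm == "log_omega", 3, 25)
  ctl <- list(eval.max = control$eval.max, iter.max = control$iter.max,
              rel.tol = control$rel.tol, x.tol = control$par_tol)
  starts <- list(obj$par)
  if (control$n_starts > 1) {
    set.seed(control$seed)
    for (s in seq_len(control$n_starts - 1))
      starts[[s + 1]] <- obj$par +
        rnorm(length(obj$par), 0, control$jitter_sd)
  }
  run_nlminb <- function(p0) {
    tryCatch(nlminb(p0, fn, gr, lower = lower, upper = upper,
                    control = ctl),
             error = function(e) list(par = p0, objective = Inf,
                                      convergence = 1L,
                                      message = conditionMessage(e),
                                      iterations = 0L))
  }
  gmax <- function(p) {
    g <- tryCatch(max(abs(as.numeric(obj$gr(p)))), error = function(e) Inf)
    if (is.finite(g)) g else Inf
  }
  best <- NULL
  best_stalled <- FALSE
  for (p0 in starts) {
    opt <- run_nlminb(p0)
    # polish: restarting resets the trust region and either walks off a
    # premature stop or certifies stationarity (no further progress)
    stalled <- FALSE
    for (r in 1:2) {
      if (opt$convergence == 0 && gmax(opt$par) < 0.1) break
      opt2 <- run_nlminb(opt$par)
      improved <- opt$objective - opt2$objective >
        ctl$rel.tol * max(1, abs(opt$objective))
      if (opt2$objective <= opt$objective) opt <- opt2
      if (!improved) { stalled <- TRUE; break }
    }
    if (is.null(best) || opt$objective < best$objective) {
      best <- opt
      best_stalled <- stalled
    }
  }
  grad_max <- gmax(best$par)
  list(obj = obj, opt = best, inp = inp, n_flag = n_flag,
       grad_max = grad_max, stalled = best_stalled)
}

# Natural-scale estimates out of a fitted stage.
stage_estimates <- function(st, spec) {
  obj <- st$obj; opt <- st$opt; inp <- st$inp
  pl <- obj$env$parList(x = opt$par)
  theta <- setNames(exp(pl$logtheta), .par_slots)
  est <- theta[inp$est_slots]
  omega_hat <- if (inp$n_eta && !is.null(inp$random))
    setNames(omega_to_cv(exp(pl$log_omega), spec$iiv_convention),
             inp$omega_names)
  else NULL
  sig <- c(pk = exp(pl$log_sig_pk), tag = exp(pl$log_sig_tag))
  etas <- if (inp$n_eta && !is.null(inp$random)) {
    m <- pl$eta
    dimnames(m) <- list(inp$subjects, names(omega_hat))
    m
  } else NULL
  list(theta = theta, estimates = est, omega_hat = omega_hat, sig = sig,
       theta_bmi = pl$theta_bmi, etas = etas, ofv = 2 * opt$objective)
}

new_fit_result <- function(stages, spec, data, seed = NA_integer_) {
  se <- stage_estimates(stages[[length(stages)]]$st, spec)
  # each estimated slot takes its value from the last stage estimating it;
  # the final stage's theta already carries earlier-stage values it fixed
  slots <- unique(unlist(lapply(stages, function(s) s$st$inp$est_slots)))
  est <- se$theta[.slot_index(slots) + 1L]
  # nlminb's "false convergence" is common at a genuine optimum of a
  # Laplace objective, and gradients are unreliable on its non-smooth
  # creases; accept a clean return code, a small final gradient, or a
  # restart-certified stationary point (grad_max stays on record)
  conv <- vapply(stages, function(s) {
    ok <- s$st$opt$convergence == 0 || s$st$grad_max < 0.1 ||
      isTRUE(s$st$stalled)
    if (ok) 0 else s$st$opt$convergence
  }, numeric(1))
  structure(list(
    estimates = est,
    theta = se$theta,
    theta_bmi = se$theta_bmi,
    omega_hat = se$omega_hat,
    resid_hat = se$sig,
    ofv = sum(vapply(stages, function(s) 2 * s$st$opt$objective, numeric(1))),
    etas = se$etas,
    cv_percent = NULL,
    convergence = list(
      status = if (all(conv == 0)) "converged" else "not-converged",
      codes = conv,
      grad_max = vapply(stages, function(s) s$st$grad_max, numeric(1)),
      iterations = vapply(stages, function(s)
        as.integer(s$st$opt$iterations %||% NA_integer_), integer(1)),
      flagged_evals = vapply(stages, function(s) s$st$n_flag, integer(1))),
    stages = setNames(lapply(stages, `[[`, "st"),
                      vapply(stages, `[[`, "", "label")),
    spec = spec,
    seed = seed
  ), class = "oltt_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sequential population fit: PK first, then TAG
#'
#' Stage 1 fits the drug disposition parameters to the PK observations by
#' maximum likelihood (the study templates carry no IIV on PK, so this is a
#' pooled fit with covariate scaling). Stage 2 fixes the stage-1 PK
#' parameters — hence the individual drug exposure — and fits the TAG
#' structural parameters, their IIV magnitudes, and the TAG residual error
#' by Laplace-approximated marginal likelihood. Non-convergence is reported
#' in the result status, never thrown away.
#'
#' @param data an observation table with both `pk` and `tag` records.
#' @param spec an `oltt_spec` from [default_model_spec()].
#' @param init optional starting parameter list (`tag` + `pk`); defaults to
#'   the published species estimates in `spec$init`.
#' @param fixed names of structural parameters to fix at their initial
#'   values (rodent templates fix `ka` by convention).
#' @param control a [fit_control()] list.
#' @return An `oltt_fit` with elements `estimates`, `omega_hat` (%CV),
#'   `resid_hat`, `ofv` (sum of the stage OFVs, equal to the joint OFV at
#'   the sequential optimum), `etas`, `convergence`, and the per-stage TMB
#'   objects under `stages`.
#' @export
fit_sequential <- function(data, spec, init = NULL, fixed = NULL,
                           control = fit_control()) {
  init <- init %||% spec$init
  fixed <- fixed %||% spec$fixed
  spec$fixed <- fixed
  par <- flatten_params(init)
  # the IIV structure comes from the spec; init contributes magnitudes only
  omega_cv <- spec$omega_cv
  shared <- intersect(names(omega_cv), names(init$omega_cv))
  omega_cv[shared] <- init$omega_cv[shared]
  sig <- c(pk = (init$resid %||% spec$resid)$pk_prop,
           tag = (init$resid %||% spec$resid)$tag_prop)

  s1 <- fit_stage(data, spec, par, omega_cv, sig, stage = "pk", control)
  e1 <- stage_estimates(s1, spec)
  par2 <- par
  par2[names(e1$estimates)] <- e1$estimates
  sig["pk"] <- e1$sig[["pk"]]

  s2 <- fit_stage(data, spec, par2, omega_cv, sig, stage = "tag", control)
  new_fit_result(list(list(st = s1, label = "pk"),
                      list(st = s2, label = "tag")), spec, data)
}

#' Simultaneous population fit of PK and TAG
#'
#' Joint Laplace-approximated maximum-likelihood fit of all structural
#' parameters, IIV magnitudes and residual errors, initialized at the
#' sequential fit by default. The joint OFV is no larger than the joint
#' likelihood evaluated at the sequential estimates.
#'
#' @inheritParams fit_sequential
#' @param init optional starting values: either a parameter list or an
#'   `oltt_fit` (typically the sequential result). `NULL` runs
#'   [fit_sequential()] first.
#' @return An `oltt_fit`; `stages` holds the single joint stage.
#' @export
fit_simultaneous <- function(data, spec, init = NULL, fixed = NULL,
                             control = fit_control()) {
  fixed <- fixed %||% spec$fixed
  spec$fixed <- fixed
  omega_cv <- spec$omega_cv
  if (is.null(init)) init <- fit_sequential(data, spec, fixed = fixed,
                                            control = control)
  if (inherits(init, "oltt_fit")) {
    par <- init$theta
    shared <- intersect(names(omega_cv), names(init$omega_hat))
    omega_cv[shared] <- pmax(init$omega_hat[shared], 1)
    sig <- c(pk = init$resid_hat[["pk"]], tag = init$resid_hat[["tag"]])
    if (!is.null(init$theta_bmi)) spec$covariates$bmi_on_r0 <- init$theta_bmi
  } else {
    par <- flatten_params(init)
    shared <- intersect(names(omega_cv), names(init$omega_cv))
    omega_cv[shared] <- init$omega_cv[shared]
    sig <- c(pk = (init$resid %||% spec$resid)$pk_prop,
             tag = (init$resid %||% spec$resid)$tag_prop)
  }
  st <- fit_stage(data, spec, par, omega_cv, sig, stage = "joint", control)
  new_fit_result(list(list(st = st, label = "joint")), spec, data)
}

#' Relative standard errors from the Hessian
#'
#' Numerically differentiates the (Laplace) marginal -2 log-likelihood at
#' the optimum on the estimation (log) scale and reports per-parameter
#' relative standard errors, `%CV = 100 * SD(theta)/theta`, obtained by the
#' delta method (for a log-scale parameter this equals `100 * SE(log
#' theta)`). Parameters whose curvature submatrix is not positive definite
#' are flagged `NA` rather than fabricated.
#'
#' @param fit an `oltt_fit` (the last stage's objective is used).
#' @param stage which stage of the fit to differentiate (default: last).
#' @return named numeric vector of %CV values for the estimated fixed
#'   effects (structural parameters and, where estimated, IIV SDs and
#'   residual SDs).
#' @export
cv_from_hessian <- function(fit, stage = length(fit$stages)) {
  st <- fit$stages[[stage]]
  nm <- names(st$opt$par)
  lab <- nm
  lab[nm == "logtheta"] <- st$inp$est_slots
  if (!is.null(st$inp$random) && st$inp$n_eta)
    lab[nm == "log_omega"] <- paste0("omega_", st$inp$omega_names)
  se <- hessian_se(st$obj$fn, st$opt$par, st$obj$gr)
  # estimation is on the log scale, so SE(log theta) is the relative SD of
  # theta (delta method): %CV = 100 * SE(log theta)
  setNames(100 * se, lab)
}

#' Standard errors from the curvature of a negative log-likelihood
#'
#' Numerically differentiates a negative log-likelihood at its minimum and
#' returns `sqrt(diag(H^-1))`. Parameters whose inverse-curvature diagonal
#' is not positive (non-positive-definite Hessian) come back `NA`.
#'
#' @param fn negative log-likelihood function of the parameter vector.
#' @param par parameter vector at the optimum.
#' @param gr optional gradient function.
#' @return numeric vector of standard errors (NA where undefined).
#' @export
hessian_se <- function(fn, par, gr = NULL) {
  H <- tryCatch(optimHess(par, fn, gr), error = function(e) NULL)
  se <- rep(NA_real_, length(par))
  if (is.null(H)) return(se)
  co <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(co)) return(se)
  d <- diag(co)
  ok <- is.finite(d) & d > 0
  se[ok] <- sqrt(d[ok])
  se
}

#' Compare two nested fits by likelihood ratio
#'
#' Applies [lrt_significant()] to the OFVs of two nested fits on the same
#' data and returns a one-row report. If the fits do not look nested (the
#' full fit estimates no additional parameters), the LRT is suppressed with
#' a warning.
#'
#' @param fit_full,fit_reduced `oltt_fit` objects on identical data.
#' @param df degrees of freedom of the comparison; default is the
#'   difference in the number of estimated parameters.
#' @return A one-row tibble: OFVs, delta, threshold, significance.
#' @export
compare_models <- function(fit_full, fit_reduced, df = NULL) {
  n_par <- function(f) sum(vapply(f$stages, function(s)
    length(s$opt$par), numeric(1)))
  if (is.null(df)) df <- n_par(fit_full) - n_par(fit_reduced)
  if (df < 1) {
    warning("fits do not look nested; LRT suppressed", call. = FALSE)
    return(tibble::tibble(ofv_full = fit_full$ofv,
                          ofv_reduced = fit_reduced$ofv,
                          delta = NA_real_, df = df,
                          threshold = NA_real_, significant = NA))
  }
  lrt <- lrt_significant(fit_reduced$ofv, fit_full$ofv, df)
  tibble::tibble(ofv_full = fit_full$ofv, ofv_reduced = fit_reduced$ofv,
                 delta = lrt$delta, df = df, threshold = lrt$threshold,
                 significant = lrt$significant)
}

#' @export
print.oltt_fit <- function(x, ...) {
  cat("OLTT population fit (", x$spec$species, ", ",
      paste(names(x$stages), collapse = " + "), ")\n", sep = "")
  cat("  status:", x$convergence$status,
      " OFV:", formatC(x$ofv, format = "f", digits = 2), "\n")
  tab <- estimates_table(x)
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' Estimates table in the conventional reporting layout
#'
#' One row per parameter with units, the population estimate, the IIV %CV
#' where estimated, and the relative standard error when
#' [cv_from_hessian()] results are attached.
#'
#' @param fit an `oltt_fit`.
#' @param cv optional output of [cv_from_hessian()].
#' @return a tibble with columns `parameter`, `units`, `value`, `iiv_cv`,
#'   `rse_cv`.
#' @export
estimates_table <- function(fit, cv = NULL) {
  nm <- names(fit$estimates)
  tab <- tibble::tibble(
    parameter = nm,
    units = unname(.par_units[nm]),
    value = unname(fit$estimates),
    iiv_cv = unname(fit$omega_hat[nm])
  )
  extra <- tibble::tibble(
    parameter = c("sigma_tag", "sigma_pk"),
    units = c("", ""),
    value = c(fit$resid_hat[["tag"]], fit$resid_hat[["pk"]]),
    iiv_cv = NA_real_)
  tab <- rbind(tab, extra)
  tab$rse_cv <- if (!is.null(cv)) unname(cv[match(
    tab$parameter, names(cv))]) else NA_real_
  tab
}
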