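# Config-driven pipeline commands. Each command is pure with respect to
# (config, seed): identical inputs give identical outputs.

#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML mappings; each command documents its required
#' keys and validates them with named errors.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  yaml::read_yaml(path)
}

need_keys <- function(config, keys, cmd) {
  miss <- setdiff(keys, names(config))
  if (length(miss))
    stop(cmd, ": missing config key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(config)
}

as_config <- function(config) {
  if (is.character(config) && length(config) == 1L) read_run_config(config)
  else config
}

# Deterministic per-replicate seeds below 2^31.
derive_seeds <- function(seed, n) {
  (abs(as.integer(seed)) %% 1000000L) * 1000L + 997L * seq_len(n)
}

truth_to_list <- function(truth) {
  rapply(truth, unclass, how = "replace")
}

truth_from_list <- function(x, species) {
  base <- species_truth(species)
  tg <- modifyList(lapply(base$tag, identity), as.list(x$tag %||% list()))
  pk <- modifyList(lapply(base$pk, identity), as.list(x$pk %||% list()))
  list(species = species,
       tag = do.call(tag_params, tg[names(base$tag)]),
       pk = pk_params(ka = pk$ka, v = pk$v, cl = pk$cl, v2 = pk$v2,
                      cl2 = pk$cl2, fu = pk$fu, mw = pk$mw),
       omega_cv = unlist(x$omega_cv %||% base$omega_cv),
       resid = do.call(residual_spec, as.list(x$resid %||% base$resid)),
       covariates = do.call(covariate_model,
                            as.list(x$covariates %||% base$covariates)))
}

design_from_config <- function(config) {
  make_design(config$template,
              doses = config$doses,
              n_active = config$n_active,
              n_placebo = config$n_placebo,
              n_per_arm = config$n_per_arm)
}

#' Simulate a study from a run configuration
#'
#' Required keys: `template`, `seed`, `out`. Optional: `truth` (overrides
#' of the species defaults), `doses`, `n_active`, `n_placebo`,
#' `n_per_arm`. Writes `dataset.csv`, the design echo `design.json` and
#' the exact simulation truth `truth.yaml` (for later recovery scoring)
#' into `out`.
#'
#' @param config a named list or path to a YAML file.
#' @return the simulated observation table (invisibly).
#' @export
cmd_simulate <- function(config) {
  config <- as_config(config)
  need_keys(config, c("template", "seed", "out"), "cmd_simulate")
  design <- design_from_config(config)
  truth <- truth_from_list(config$truth %||% list(), design$species)
  dat <- simulate_study(design, truth, seed = config$seed)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  write_dataset(dat, file.path(config$out, "dataset.csv"))
  yaml::write_yaml(truth_to_list(truth), file.path(config$out, "truth.yaml"))
  jsonlite::write_json(
    list(template = design$template, species = design$species,
         arms = design$arms, dose_times = design$dose_times,
         tag_times = design$tag_times, pk_times = design$pk_times,
         seed = config$seed),
    file.path(config$out, "design.json"), auto_unbox = TRUE, digits = NA)
  invisible(dat)
}

write_fit_outputs <- function(fit, data, out, cv = NULL) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  tab <- estimates_table(fit, cv)
  utils::write.csv(tab, file.path(out, "estimates.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(estimates = as.list(fit$estimates),
         theta_bmi = fit$theta_bmi,
         omega_cv = as.list(fit$omega_hat %||% numeric(0)),
         resid = as.list(fit$resid_hat),
         ofv = fit$ofv,
         convergence = fit$convergence[c("status", "codes")]),
    file.path(out, "fit.json"), auto_unbox = TRUE, digits = NA)
  g <- gof_table(fit, data)
  utils::write.csv(g, file.path(out, "gof.csv"), row.names = FALSE)
  if (!is.null(fit$etas))
    utils::write.csv(data.frame(subject = rownames(fit$etas), fit$etas),
                     file.path(out, "etas.csv"), row.names = FALSE)
  invisible(tab)
}

#' Fit a dataset from a run configuration
#'
#' Required keys: `data` (CSV path), `species`, `out`. Optional: `fixed`
#' (parameter names), `method` (`"simultaneous"`, the default, runs the
#' sequential fit first for initial values; `"sequential"` stops there),
#' `init` (YAML truth-style overrides for starting values), `seed`,
#' `n_starts`, `se` (compute Hessian %CV, default TRUE). Writes
#' `estimates.csv` (parameter, units, value, IIV %CV, relative SE),
#' `fit.json`, `gof.csv` and `etas.csv`.
#'
#' @param config a named list or YAML path.
#' @return the `oltt_fit` (invisibly).
#' @export
cmd_fit <- function(config) {
  config <- as_config(config)
  need_keys(config, c("data", "species", "out"), "cmd_fit")
  data <- read_dataset(config$data)
  spec <- default_model_spec(config$species)
  init <- if (!is.null(config$init))
    truth_from_list(as_config(config$init), config$species) else NULL
  control <- fit_control(seed = config$seed %||% 1L,
                         n_starts = config$n_starts %||% 1)
  method <- config$method %||% "simultaneous"
  fixed <- config$fixed %||% spec$fixed
  fit <- if (method == "sequential")
    fit_sequential(data, spec, init = init, fixed = fixed,
                   control = control)
  else fit_simultaneous(data, spec, init = init, fixed = fixed,
                        control = control)
  cv <- if (isTRUE(config$se %||% TRUE)) cv_from_hessian(fit) else NULL
  write_fit_outputs(fit, data, config$out, cv)
  if (fit$convergence$status != "converged")
    warning("cmd_fit: optimizer did not report clean convergence; ",
            "partial results written to ", config$out, call. = FALSE)
  invisible(fit)
}

#' Visual predictive check from a run configuration
#'
#' Required keys: `data`, `template`, `out`. Optional: `params` (truth
#' overrides; defaults to species truth), `n_reps` (default 1000), `seed`.
#' Writes `vpc.csv` and `vpc.pdf`.
#'
#' @param config a named list or YAML path.
#' @return the `oltt_vpc` (invisibly).
#' @export
cmd_vpc <- function(config) {
  config <- as_config(config)
  need_keys(config, c("data", "template", "out"), "cmd_vpc")
  design <- design_from_config(config)
  data <- read_dataset(config$data)
  truth <- truth_from_list(config$params %||% list(), design$species)
  v <- vpc(truth, design, observed = data,
           n_reps = config$n_reps %||% 1000, seed = config$seed %||% 1)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(v), file.path(config$out, "vpc.csv"),
                   row.names = FALSE)
  plot_vpc(v, observed = data, path = file.path(config$out, "vpc.pdf"))
  invisible(v)
}

#' Parameter-recovery study from a run configuration
#'
#' The executable recovery surface: simulates `n_seeds` replicate studies
#' from the species truth, fits each one, and reports per-parameter
#' recovery statistics. Required keys: `template`, `n_seeds`, `seed`.
#' Optional: `out`, design overrides (`doses`, `n_active`, `n_placebo`,
#' `n_per_arm`), `method` (`"simultaneous"` default, `"sequential"`, or
#' `"pk"` for the drug-disposition stage alone), `truth` overrides.
#'
#' @param config a named list or YAML path.
#' @return list with `report` (per-parameter tibble: truth, median and
#'   geometric-mean estimate, mean log-scale bias, median absolute
#'   relative error, replicate count) and `estimates` (per-seed tibble).
#' @export
cmd_recover <- function(config) {
  config <- as_config(config)
  need_keys(config, c("template", "n_seeds", "seed"), "cmd_recover")
  if (config$n_seeds < 1)
    stop("cmd_recover: 'n_seeds' must be >= 1", call. = FALSE)
  design <- design_from_config(config)
  species <- design$species
  truth <- truth_from_list(config$truth %||% list(), species)
  spec <- default_model_spec(species)
  method <- config$method %||% "simultaneous"
  seeds <- derive_seeds(config$seed, config$n_seeds)
  per_seed <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    dat <- simulate_study(design, truth, seed = seeds[k])
    fit <- switch(method,
      simultaneous = fit_simultaneous(dat, spec),
      sequential = fit_sequential(dat, spec),
      pk = {
        st <- fit_stage(dat, spec, flatten_params(spec$init),
                        spec$omega_cv,
                        c(pk = spec$resid$pk_prop, tag = spec$resid$tag_prop),
                        stage = "pk", fit_control())
        new_fit_result(list(list(st = st, label = "pk")), spec, dat)
      },
      stop("cmd_recover: unknown method '", method, "'", call. = FALSE))
    per_seed[[k]] <- tibble::tibble(
      seed = seeds[k], parameter = names(fit$estimates),
      estimate = unname(fit$estimates),
      converged = fit$convergence$status == "converged",
      ofv = fit$ofv)
  }
  est <- do.call(rbind, per_seed)
  tv <- flatten_params(truth)
  report <- do.call(rbind, lapply(split(est, est$parameter), function(d) {
    tr <- tv[[d$parameter[1]]]
    tibble::tibble(
      parameter = d$parameter[1], truth = tr,
      median_est = median(d$estimate),
      gmean_est = exp(mean(log(d$estimate))),
      log_bias = mean(log(d$estimate / tr)),
      mad_rel = median(abs(d$estimate / tr - 1)),
      n = nrow(d), n_converged = sum(d$converged))
  }))
  out <- list(report = report, estimates = est, truth = tv,
              seeds = seeds, method = method)
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(config$out, "recovery.csv"),
                     row.names = FALSE)
    utils::write.csv(est, file.path(config$out, "estimates_by_seed.csv"),
                     row.names = FALSE)
  }
  out
}
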