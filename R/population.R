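#' Individual parameters from population values, random effects and
#' covariates
#'
#' Builds one subject's parameter set as
#' `p_i = p_pop * covariate_factor * exp(eta_p)`. Random effects are
#' log-normal, so individual parameters are positive for any real `etas`.
#' Covariate factors follow the power models of [covariate_model()]; absent
#' covariates default to the reference values (factor 1).
#'
#' @param pop list with elements `tag` ([tag_params()]) and `pk`
#'   ([pk_params()]).
#' @param etas named numeric vector of log-scale random effects; names must
#'   be structural parameter names; missing entries default to 0.
#' @param covs optional list with elements `bw` (kg) and/or `bmi` (kg/m^2).
#' @param model a [covariate_model()].
#' @return A list like `pop` with individualized `tag` and `pk` components.
#' @examples
#' truth <- species_truth("human")
#' individualize(truth, etas = c(r0 = 0.2), covs = list(bmi = 30),
#'               model = truth$covariates)
#' @export
individualize <- function(pop, etas = NULL, covs = NULL,
                          model = covariate_model()) {
  par <- flatten_params(pop)
  if (!is.null(etas) && length(etas)) {
    bad <- setdiff(names(etas), .par_slots)
    if (length(bad))
      stop("individualize: eta for unknown parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  fac <- setNames(rep(1, length(par)), names(par))
  if (!is.null(covs$bw)) {
    fac["cl"] <- (covs$bw / model$bw_ref)^model$bw_on_cl
    fac["v"] <- (covs$bw / model$bw_ref)^model$bw_on_v
  }
  if (!is.null(covs$bmi))
    fac["r0"] <- (covs$bmi / model$bmi_ref)^model$bmi_on_r0
  par <- par * fac
  if (!is.null(etas) && length(etas))
    par[names(etas)] <- par[names(etas)] * exp(unname(etas))
  pk0 <- pop$pk
  list(
    species = pop$species,
    tag = tag_params(ka_tag = par[["ka_tag"]], v_tag = par[["v_tag"]],
                     tlag_tag = par[["tlag_tag"]], r0 = par[["r0"]],
                     kout = par[["kout"]], ic50 = par[["ic50"]]),
    pk = pk_params(ka = par[["ka"]], v = par[["v"]], cl = par[["cl"]],
                   v2 = if (is.null(pk0$v2)) NULL else par[["v2"]],
                   cl2 = if (is.null(pk0$cl2)) NULL else par[["cl2"]],
                   fu = pk0$fu, mw = pk0$mw)
  )
}

#' Apply proportional residual error to model predictions
#'
#' Draws noisy observations `y = f * (1 + eps)`, `eps ~ N(0, sigma^2)`,
#' with `sigma` taken from the channel-specific proportional error of a
#' [residual_spec()]. The expectation equals the prediction.
#'
#' @param prediction positive model prediction(s).
#' @param spec a [residual_spec()].
#' @param which `"tag"` or `"pk"` observation channel.
#' @return noisy observation(s), same length as `prediction`.
#' @export
observe <- function(prediction, spec, which = c("tag", "pk")) {
  which <- match.arg(which)
  if (any(prediction <= 0))
    stop("observe: predictions must be positive", call. = FALSE)
  sigma <- if (which == "tag") spec$tag_prop else spec$pk_prop
  prediction * (1 + rnorm(length(prediction), 0, sigma))
}

#' Marginal -2 log-likelihood of an observation table
#'
#' Evaluates the population objective function value (OFV): minus twice the
#' marginal log-likelihood of the data under the structural model, the
#' log-normal IIV defined by `truth$omega_cv`, and proportional residual
#' error. Random effects are marginalized by a Laplace approximation around
#' the per-subject empirical-Bayes modes (the same objective the fitting
#' engine minimizes); with an empty IIV specification the value reduces to
#' the exact sum of Gaussian -2 log-densities. Deterministic given data and
#' parameters.
#'
#' Subjects at which the structural prediction is not finite are flagged in
#' the `"flagged"` attribute and the value is replaced by a large penalty
#' (1e10) rather than silently propagated.
#'
#' @param data an observation table (see [simulate_study()]).
#' @param truth parameter list with `tag`, `pk`, `omega_cv`, `resid` (and
#'   optionally `covariates`), as returned by [species_truth()].
#' @param mode `"joint"` (PK and TAG observations), `"pk"` or `"tag"`.
#' @param spec model specification, defaults to the species of `truth`.
#' @return OFV (numeric scalar), possibly with attribute `flagged`.
#' @export
neg2ll <- function(data, truth, mode = c("joint", "pk", "tag"),
                   spec = default_model_spec(truth$species)) {
  mode <- match.arg(mode)
  if (!is.null(truth$covariates)) spec$covariates <- truth$covariates
  omega_cv <- truth$omega_cv
  omega_cv <- omega_cv[omega_cv > 0]
  spec$estimate_bmi <- FALSE
  inp <- make_tmb_inputs(
    data, spec, par = flatten_params(truth), omega_cv = omega_cv,
    sig = c(pk = truth$resid$pk_prop, tag = truth$resid$tag_prop),
    stage = mode)
  obj <- make_tmb_obj(inp)
  val <- tryCatch(2 * obj$fn(obj$par), error = function(e) NaN)
  if (!is.finite(val)) {
    rep <- tryCatch(obj$report(), error = function(e) NULL)
    bad <- if (!is.null(rep)) {
      idx <- which(!is.finite(rep$pred))
      unique(unlist(lapply(idx, function(k) {
        inp$subjects[findInterval(k - 1, inp$data$obs_start)]
      })))
    } else inp$subjects
    val <- 1e10
    attr(val, "flagged") <- bad
    warning("non-finite structural prediction; penalized objective returned",
            call. = FALSE)
  }
  val
}

#' Likelihood-ratio significance of a nested model improvement
#'
#' Compares the OFV drop between nested hierarchical models against the
#' chi-squared critical value at P = 0.001; with one degree of freedom the
#' threshold is 10.83. Negative improvements are allowed and simply not
#' significant.
#'
#' @param ofv_reduced OFV of the reduced (fewer-parameter) model.
#' @param ofv_full OFV of the full model.
#' @param df additional parameters in the full model (>= 1).
#' @param alpha significance level (default 0.001).
#' @return list with `significant`, `delta`, `threshold`, `df`.
#' @examples
#' lrt_significant(110.83, 100, df = 1)$significant
#' @export
lrt_significant <- function(ofv_reduced, ofv_full, df = 1, alpha = 0.001) {
  if (df < 1) stop("lrt_significant: 'df' must be >= 1", call. = FALSE)
  threshold <- qchisq(1 - alpha, df = df)
  delta <- ofv_reduced - ofv_full
  list(significant = delta >= threshold, delta = delta,
       threshold = threshold, df = df)
}
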