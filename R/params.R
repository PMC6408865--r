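#' TAG turnover model parameters
#'
#' Container for the pharmacodynamic side of the OLTT model: a gut lipid
#' depot emptying with first-order rate `ka_tag` after a lag `tlag_tag`,
#' feeding an indirect-response turnover model of plasma TAG with baseline
#' `r0` and fractional turnover `kout`. The endogenous production rate is
#' the derived quantity `kin = r0 * kout` (mg/dL/h). `ic50` is the free drug
#' concentration halving the exogenous TAG input.
#'
#' @param ka_tag first-order TAG absorption rate from the depot (1/h).
#' @param v_tag apparent distribution volume of exogenous TAG (dL).
#' @param tlag_tag absorption lag time between lipid intake and depot
#'   loading (h).
#' @param r0 baseline plasma TAG concentration (mg/dL).
#' @param kout fractional turnover rate of plasma TAG (1/h).
#' @param ic50 free drug concentration giving 50% inhibition of exogenous
#'   TAG input (umol/L).
#' @return An object of class `tag_params` (named list). The derived
#'   production rate is available as `kin(x)`.
#' @examples
#' p <- tag_params(ka_tag = 0.74, v_tag = 250.4, tlag_tag = 1.63,
#'                 r0 = 97.8, kout = 0.70, ic50 = 0.0078)
#' kin(p)
#' @export
tag_params <- function(ka_tag, v_tag, tlag_tag, r0, kout, ic50) {
  x <- list(ka_tag = ka_tag, v_tag = v_tag, tlag_tag = tlag_tag,
            r0 = r0, kout = kout, ic50 = ic50)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("tag_params: '", nm, "' must be a single finite positive number",
           call. = FALSE)
  }
  structure(x, class = "tag_params")
}

#' @rdname tag_params
#' @param x a `tag_params` object.
#' @export
kin <- function(x) x$r0 * x$kout

#' Drug disposition parameters
#'
#' One- or two-compartment linear PK with first-order absorption. All
#' volumes and clearances are defined on the free-concentration scale (the
#' OLTT analysis is carried out entirely in free drug concentrations);
#' `fu` converts measured total concentrations to free ones on data import,
#' and `mw` converts dose mass (mg) to amount (umol). For rodent study
#' templates doses are per kg body weight and `v`/`cl` are per-kg
#' quantities; the amount/volume ratio is unit-consistent either way.
#'
#' @param ka absorption rate constant (1/h).
#' @param v central volume of distribution, free-concentration scale (L).
#' @param cl clearance, free-concentration scale (L/h).
#' @param v2 peripheral volume (L); `NULL` for a one-compartment model.
#' @param cl2 inter-compartmental clearance (L/h); `NULL` with `v2`.
#' @param fu unbound (free) drug fraction in plasma, in (0, 1].
#' @param mw molecular weight used for the mg to umol dose conversion
#'   (g/mol). The default is a documented configuration assumption.
#' @return An object of class `pk_params`.
#' @examples
#' human_pk <- pk_params(ka = 5.19, v = 320.2, cl = 28.1,
#'                       v2 = 136.8, cl2 = 50.8, fu = 0.055)
#' n_compartments(human_pk)
#' @export
pk_params <- function(ka, v, cl, v2 = NULL, cl2 = NULL, fu = 1, mw = 420) {
  if (is.null(v2) != is.null(cl2))
    stop("pk_params: 'v2' and 'cl2' must be both present or both absent",
         call. = FALSE)
  for (nm in c("ka", "v", "cl", "mw")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop("pk_params: '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  if (!is.null(v2) && (v2 <= 0 || cl2 <= 0))
    stop("pk_params: 'v2' and 'cl2' must be positive", call. = FALSE)
  if (!is.numeric(fu) || length(fu) != 1L || fu <= 0 || fu > 1)
    stop("pk_params: 'fu' must lie in (0, 1]", call. = FALSE)
  structure(list(ka = ka, v = v, cl = cl, v2 = v2, cl2 = cl2,
                 fu = fu, mw = mw),
            class = "pk_params")
}

#' @rdname pk_params
#' @param x a `pk_params` object.
#' @export
n_compartments <- function(x) if (is.null(x$v2)) 1L else 2L

#' Convert a log-normal coefficient of variation to a log-scale SD
#'
#' Inter-individual variability magnitudes are reported as %CV of a
#' log-normal distribution. Under the default convention the log-scale SD is
#' `omega = sqrt(log(1 + (cv/100)^2))`; some estimation software instead
#' reports `100 * omega` directly, selectable via
#' `convention = "omega"`.
#'
#' @param cv_percent IIV magnitude in percent (vectorised).
#' @param convention `"cv"` (log-normal CV, default) or `"omega"`
#'   (percentage is `100 * omega`).
#' @return log-scale standard deviation(s) `omega`.
#' @examples
#' cv_to_omega(38.3) # ~0.37
#' @export
cv_to_omega <- function(cv_percent, convention = c("cv", "omega")) {
  convention <- match.arg(convention)
  if (any(cv_percent < 0)) stop("cv_to_omega: %CV must be >= 0", call. = FALSE)
  if (convention == "cv") sqrt(log(1 + (cv_percent / 100)^2))
  else cv_percent / 100
}

#' @rdname cv_to_omega
#' @param omega log-scale SD(s).
#' @export
omega_to_cv <- function(omega, convention = c("cv", "omega")) {
  convention <- match.arg(convention)
  if (convention == "cv") 100 * sqrt(exp(omega^2) - 1) else 100 * omega
}

#' Residual error specification
#'
#' Proportional residual error SDs for the two observation channels:
#' plasma TAG and drug PK. An observation is `y = f * (1 + eps)` with
#' `eps ~ N(0, sigma^2)`.
#'
#' @param tag_prop proportional SD for TAG observations.
#' @param pk_prop proportional SD for PK observations.
#' @export
residual_spec <- function(tag_prop, pk_prop = 0.15) {
  if (tag_prop < 0 || pk_prop < 0)
    stop("residual_spec: error SDs must be >= 0", call. = FALSE)
  structure(list(tag_prop = tag_prop, pk_prop = pk_prop),
            class = "residual_spec")
}

#' Covariate model for the human population layer
#'
#' Power models: individual baseline TAG scales as
#' `r0_i = r0 * (BMI_i / bmi_ref)^bmi_on_r0`, and human PK scales
#' allometrically with body weight, `cl_i = cl * (BW_i / bw_ref)^bw_on_cl`
#' and `v_i = v * (BW_i / bw_ref)^bw_on_v`. Exponents of zero disable a
#' covariate effect; rodent templates use the null model.
#'
#' @param bmi_on_r0 exponent of the BMI power model on baseline TAG.
#' @param bw_on_cl,bw_on_v allometric exponents on clearance and volume.
#' @param bmi_ref,bw_ref reference BMI (kg/m^2) and body weight (kg).
#' @export
covariate_model <- function(bmi_on_r0 = 0, bw_on_cl = 0, bw_on_v = 0,
                            bmi_ref = 25, bw_ref = 70) {
  if (bmi_ref <= 0 || bw_ref <= 0)
    stop("covariate_model: reference values must be positive", call. = FALSE)
  structure(list(bmi_on_r0 = bmi_on_r0, bw_on_cl = bw_on_cl,
                 bw_on_v = bw_on_v, bmi_ref = bmi_ref, bw_ref = bw_ref),
            class = "covariate_model")
}

#' Species default parameter sets
#'
#' Published population estimates for the DGAT1 inhibitor OLTT model in
#' human, rat and mouse: structural PK and TAG parameters, IIV magnitudes
#' (%CV of log-normal random effects, only on the parameters for which IIV
#' was estimable in each species), proportional residual error, free
#' fraction, and the covariate model. These sets serve both as simulation
#' truth for the synthetic-study generator and as starting values for
#' fitting new OLTT data.
#'
#' Conventions: human doses are absolute mg against absolute V/Cl; rodent
#' doses are mg/kg against per-kg V/Cl (all on the free-concentration
#' scale). `v_tag` is an absolute volume (dL) in every species.
#'
#' @param species `"human"`, `"rat"` or `"mouse"`.
#' @param mw molecular weight for the mg to umol conversion (g/mol).
#' @return A list with elements `species`, `tag` (`tag_params`), `pk`
#'   (`pk_params`), `omega_cv` (named %CV vector), `resid`
#'   (`residual_spec`), `covariates` (`covariate_model`), `fixed`
#'   (parameters conventionally fixed, not estimated), and `dose_unit`.
#' @examples
#' species_truth("rat")$tag$ic50
#' @export
species_truth <- function(species = c("human", "rat", "mouse"), mw = 420) {
  species <- match.arg(species)
  switch(species,
    human = list(
      species = "human",
      tag = tag_params(ka_tag = 0.74, v_tag = 250.4, tlag_tag = 1.63,
                       r0 = 97.8, kout = 0.70, ic50 = 0.0078),
      pk = pk_params(ka = 5.19, v = 320.2, cl = 28.1, v2 = 136.8,
                     cl2 = 50.8, fu = 0.055, mw = mw),
      omega_cv = c(ka_tag = 20.3, v_tag = 57.2, r0 = 38.3,
                   kout = 65.0, ic50 = 223.4),
      resid = residual_spec(tag_prop = 0.192),
      covariates = covariate_model(bmi_on_r0 = 1, bw_on_cl = 0.75,
                                   bw_on_v = 1),
      fixed = character(),
      dose_unit = "mg"
    ),
    rat = list(
      species = "rat",
      tag = tag_params(ka_tag = 0.37, v_tag = 2.19, tlag_tag = 1.24,
                       r0 = 109.2, kout = 0.28, ic50 = 0.162),
      pk = pk_params(ka = 3, v = 8.66, cl = 0.73, fu = 0.03, mw = mw),
      omega_cv = c(tlag_tag = 4.53, ka_tag = 99.2, v_tag = 55.9, r0 = 18.5),
      resid = residual_spec(tag_prop = 0.3),
      covariates = covariate_model(),
      fixed = "ka",
      dose_unit = "mg/kg"
    ),
    mouse = list(
      species = "mouse",
      tag = tag_params(ka_tag = 2.10, v_tag = 0.012, tlag_tag = 0.98,
                       r0 = 178.0, kout = 4.41, ic50 = 0.081),
      pk = pk_params(ka = 3, v = 13.14, cl = 2.17, fu = 0.1, mw = mw),
      omega_cv = c(tlag_tag = 0.19, ka_tag = 35.3, r0 = 17.7, ic50 = 62.0),
      resid = residual_spec(tag_prop = 0.198),
      covariates = covariate_model(),
      fixed = "ka",
      dose_unit = "mg/kg"
    )
  )
}

# Flatten a truth/init list into the named 11-slot structural vector used by
# the likelihood template (unused 2-compartment slots filled with 1).
flatten_params <- function(truth) {
  pk <- truth$pk
  tg <- truth$tag
  c(ka = pk$ka, v = pk$v, cl = pk$cl,
    v2 = if (is.null(pk$v2)) 1 else pk$v2,
    cl2 = if (is.null(pk$cl2)) 1 else pk$cl2,
    r0 = tg$r0, kout = tg$kout, ka_tag = tg$ka_tag, v_tag = tg$v_tag,
    tlag_tag = tg$tlag_tag, ic50 = tg$ic50)
}
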