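#' Study design templates for the cross-species OLTT programme
#'
#' Returns the default design for one of the four study templates:
#'
#' * `"sad"` — human single ascending dose: cohorts of 6 active + 2
#'   placebo, doses spanning 1-60 mg, a standardized mixed meal (1100 kcal,
#'   60% or 45% fat energy by cohort) served as a pre-dose baseline
#'   occasion and again 4 h after dosing; TAG sampled over 8 h post meal,
#'   rich PK sampling post dose.
#' * `"mad"` — human multiple ascending dose: 42 active (1-20 mg/day, 7
#'   daily doses) + 20 placebo; 45% fat meal on the baseline day and 1 h
#'   after the day-2 and day-7 doses.
#' * `"rat"` — 53 rats: vehicle (n = 11), 0.1/0.3/3 mg/kg (n = 12 each)
#'   and 6 naive controls without lipid challenge; corn oil 5 mL/kg by
#'   gavage 2 h post compound; TAG at 2, 2.5, 3.5, 5, 8, 11 h post dose;
#'   3 animals per active group are serially bled for PK instead of TAG,
#'   the remaining active animals contribute a terminal PK sample.
#' * `"mouse"` — 41 mice: vehicle (n = 8) and 0.1/1/3 mg/kg (n = 11 each);
#'   20% soybean-oil emulsion 10 mL/kg 0.5 h post compound; TAG at
#'   0.5-4.5 h; 3 animals per active group serially bled for PK.
#'
#' @param template one of `"sad"`, `"mad"`, `"rat"`, `"mouse"`.
#' @param doses optional dose levels overriding the template (per cohort
#'   for `"sad"`).
#' @param n_active,n_placebo per-cohort sizes for `"sad"`.
#' @param n_per_arm optional named or unnamed override of arm sizes.
#' @return An `oltt_design` list: `species`, `template`, `arms` (tibble),
#'   `dose_times`, `challenges` (times and composition), `tag_times`,
#'   `pk_times`, `pk_times_sparse`, and covariate generator settings.
#' @examples
#' make_design("rat")$tag_times
#' @export
make_design <- function(template = c("sad", "mad", "rat", "mouse"),
                        doses = NULL, n_active = NULL, n_placebo = NULL,
                        n_per_arm = NULL) {
  if (is.character(template) &&
      !template[1] %in% c("sad", "mad", "rat", "mouse"))
    stop("unknown template '", template[1],
         "'; valid templates: sad, mad, rat, mouse", call. = FALSE)
  template <- match.arg(template)
  tag_offsets <- c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 8)
  pk_offsets <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12)
  d <- switch(template,
    sad = {
      dl <- doses %||% c(1, 2.5, 5, 10, 15, 20, 30, 40, 50, 60)
      na <- n_active %||% 6L
      np <- n_placebo %||% 2L
      arms <- tibble::tibble(
        arm = c(paste0("sad_", dl, "mg"), "placebo"),
        dose = c(dl, 0),
        n = c(rep(na, length(dl)), np * length(dl)),
        placebo = c(rep(FALSE, length(dl)), TRUE),
        n_pk_serial = c(rep(na, length(dl)), 0L),
        fat_fraction = NA_real_)
      # meal fat energy alternates 60%/45% across cohorts; placebo subjects
      # are recruited within cohorts and inherit the cohort meal
      arms$fat_fraction <- c(rep_len(c(0.6, 0.45), length(dl)), 0.6)
      list(species = "human", arms = arms, dose_times = 24,
           challenges = tibble::tibble(time = c(0, 28), kind = "meal",
                                       energy_kcal = 1100),
           tag_times = sort(c(tag_offsets, 28 + tag_offsets)),
           pk_times = 24 + pk_offsets, pk_times_sparse = numeric(0))
    },
    mad = {
      dl <- doses %||% c(1, 2.5, 5, 10, 20)
      nn <- n_active %||% c(6L, 6L, 12L, 12L, 6L)
      nn <- rep_len(nn, length(dl))
      arms <- tibble::tibble(
        arm = c(paste0("mad_", dl, "mg"), "placebo"),
        dose = c(dl, 0),
        n = c(nn, n_placebo %||% 20L),
        placebo = c(rep(FALSE, length(dl)), TRUE),
        n_pk_serial = c(nn, 0L),
        fat_fraction = 0.45)
      meal_t <- c(0, 49, 169)
      list(species = "human", arms = arms, dose_times = 24 * (1:7),
           challenges = tibble::tibble(time = meal_t, kind = "meal",
                                       energy_kcal = 1100),
           tag_times = sort(as.numeric(outer(tag_offsets, meal_t, `+`))),
           pk_times = 168 + pk_offsets, pk_times_sparse = numeric(0))
    },
    rat = {
      dl <- doses %||% c(0.1, 0.3, 3)
      arms <- tibble::tibble(
        arm = c("vehicle", paste0("rat_", dl, "mgkg"), "naive"),
        dose = c(0, dl, 0),
        n = c(11L, rep(12L, length(dl)), 6L),
        placebo = c(TRUE, rep(FALSE, length(dl)), TRUE),
        n_pk_serial = c(0L, rep(3L, length(dl)), 0L),
        fat_fraction = NA_real_)
      list(species = "rat", arms = arms, dose_times = 0,
           challenges = tibble::tibble(time = 2, kind = "oil",
                                       volume_per_kg = 5, oil_fraction = 1,
                                       density = 0.9),
           tag_times = c(2, 2.5, 3.5, 5, 8, 11),
           pk_times = c(2, 3.5, 5, 8, 11), pk_times_sparse = 11)
    },
    mouse = {
      dl <- doses %||% c(0.1, 1, 3)
      arms <- tibble::tibble(
        arm = c("vehicle", paste0("mouse_", dl, "mgkg")),
        dose = c(0, dl),
        n = c(8L, rep(11L, length(dl))),
        placebo = c(TRUE, rep(FALSE, length(dl))),
        n_pk_serial = c(0L, rep(3L, length(dl))),
        fat_fraction = NA_real_)
      list(species = "mouse", arms = arms, dose_times = 0,
           challenges = tibble::tibble(time = 0.5, kind = "oil",
                                       volume_per_kg = 10,
                                       oil_fraction = 0.2, density = 0.917),
           tag_times = c(0.5, 1.5, 2.5, 3.5, 4.5),
           pk_times = 1:4, pk_times_sparse = numeric(0))
    })
  if (!is.null(n_per_arm)) {
    n_per_arm <- rep_len(as.integer(n_per_arm), nrow(d$arms))
    d$arms$n <- n_per_arm
    # shrink the serial-PK contingent with the arm so downsized rodent
    # arms keep TAG-bled animals
    d$arms$n_pk_serial <- pmin(d$arms$n_pk_serial,
                               as.integer(ceiling(d$arms$n / 3)))
  }
  d$template <- template
  # naive arms skip the lipid challenge
  d$arms$challenged <- !(d$arms$arm == "naive")
  d$covariates <- switch(d$species,
    human = list(bw_median = 80, bw_cv = 0.15, bmi_mean = 27, bmi_sd = 3,
                 bmi_range = c(18, 40)),
    rat = list(bw = 0.23, bw_cv = 0),
    mouse = list(bw = 0.025, bw_cv = 0))
  structure(d, class = "oltt_design")
}

draw_covariates <- function(design, n) {
  cv <- design$covariates
  if (design$species == "human") {
    bw <- exp(rnorm(n, log(cv$bw_median), sqrt(log(1 + cv$bw_cv^2))))
    bmi <- rnorm(n, cv$bmi_mean, cv$bmi_sd)
    bmi <- pmin(pmax(bmi, cv$bmi_range[1]), cv$bmi_range[2])
  } else {
    bw <- if (cv$bw_cv > 0)
      exp(rnorm(n, log(cv$bw), sqrt(log(1 + cv$bw_cv^2)))) else rep(cv$bw, n)
    bmi <- rep(NA_real_, n)
  }
  list(bw = bw, bmi = bmi)
}

#' Simulate a synthetic OLTT study
#'
#' Draws covariates and log-normal random effects for every subject of a
#' design, simulates each subject's free drug concentrations and plasma TAG
#' excursion with the structural model, and applies proportional residual
#' error, returning a long-format observation table. Placebo, vehicle and
#' naive subjects produce TAG-only records (their inhibition input is
#' identically 1); animals assigned to serial PK bleeding produce PK-only
#' records. Deterministic for a given seed.
#'
#' @param design an [make_design()] object.
#' @param truth full parameter set for the species: `tag`, `pk`,
#'   `omega_cv`, `resid`, `covariates` as in [species_truth()].
#' @param seed integer RNG seed.
#' @param iiv_convention see [cv_to_omega()].
#' @param sim_h internal refinement step (h) of the TAG integrator.
#' @return A tibble with columns `subject`, `arm`, `time` (h), `kind`
#'   (`dose`, `challenge`, `pk`, `tag`), `amount` (dose: mg or mg/kg;
#'   challenge: g TAG), `value` (pk: umol/L free; tag: mg/dL), `unit`,
#'   `bw`, `bmi`, `fat_fraction`.
#' @examples
#' dat <- simulate_study(make_design("mouse"), species_truth("mouse"),
#'                       seed = 1)
#' @export
simulate_study <- function(design, truth, seed,
                           iiv_convention = c("cv", "omega"),
                           sim_h = 0.02) {
  stopifnot(inherits(design, "oltt_design"))
  iiv_convention <- match.arg(iiv_convention)
  for (comp in c("tag", "pk", "resid"))
    if (is.null(truth[[comp]]))
      stop("simulate_study: truth is missing component '", comp, "'",
           call. = FALSE)
  set.seed(as.integer(seed))
  omega <- cv_to_omega(truth$omega_cv %||% numeric(0), iiv_convention)
  covm <- truth$covariates %||% covariate_model()
  dose_unit <- if (design$species == "human") "mg" else "mg/kg"

  arms <- design$arms
  subj_arm <- rep(seq_len(nrow(arms)), arms$n)
  n <- length(subj_arm)
  cov <- draw_covariates(design, n)
  # within-arm role: first n_pk_serial challenged actives are PK-only
  role_pk_only <- unlist(lapply(seq_len(nrow(arms)), function(a) {
    k <- arms$n_pk_serial[a]
    if (design$species == "human") rep(FALSE, arms$n[a])
    else c(rep(TRUE, k), rep(FALSE, arms$n[a] - k))
  }))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    a <- subj_arm[i]
    covs <- list(bw = cov$bw[i])
    if (!is.na(cov$bmi[i])) covs$bmi <- cov$bmi[i]
    etas <- if (length(omega))
      setNames(rnorm(length(omega), 0, omega), names(omega)) else NULL
    ind <- individualize(truth, etas = etas, covs = covs, model = covm)
    active <- !arms$placebo[a] && arms$dose[a] > 0
    dose_rows <- tibble::tibble(
      time = design$dose_times, kind = "dose",
      amount = if (active) arms$dose[a] else 0,
      value = NA_real_, unit = dose_unit)
    chal <- if (arms$challenged[a]) design$challenges else
      design$challenges[0, , drop = FALSE]
    if (nrow(chal)) {
      grams <- if (chal$kind[1] == "meal")
        meal_tag_dose(chal$energy_kcal, arms$fat_fraction[a])
      else oil_tag_dose(chal$volume_per_kg, cov$bw[i], chal$oil_fraction,
                        chal$density)
      chal_rows <- tibble::tibble(time = chal$time, kind = "challenge",
                                  amount = grams, value = NA_real_,
                                  unit = "g")
    } else chal_rows <- NULL

    doses_df <- data.frame(time = design$dose_times,
                           amount = if (active) rep(arms$dose[a],
                                                    length(design$dose_times))
                                    else numeric(length(design$dose_times)))
    conc_fun <- function(t) pk_profile(t, doses_df, ind$pk)
    inh_fun <- if (active)
      function(t) inhibition(conc_fun(t), ind$tag$ic50)
    else function(t) rep(1, length(t))

    pk_rows <- NULL
    if (active && design$species == "human" ||
        (active && role_pk_only[i])) {
      tpk <- design$pk_times
      pred <- conc_fun(tpk)
      pk_rows <- tibble::tibble(time = tpk, kind = "pk",
                                amount = NA_real_,
                                value = observe(pred, truth$resid, "pk"),
                                unit = "umol/L")
    } else if (active && length(design$pk_times_sparse)) {
      tpk <- design$pk_times_sparse
      pred <- conc_fun(tpk)
      pk_rows <- tibble::tibble(time = tpk, kind = "pk",
                                amount = NA_real_,
                                value = observe(pred, truth$resid, "pk"),
                                unit = "umol/L")
    }

    tag_rows <- NULL
    if (!(role_pk_only[i])) {
      chal_sim <- if (is.null(chal_rows))
        data.frame(time = numeric(0), tag_mass = numeric(0))
      else data.frame(time = chal_rows$time, tag_mass = chal_rows$amount)
      sim <- simulate_tag(ind$tag, chal_sim, inh_fun,
                          times = design$tag_times, h = sim_h)
      tag_rows <- tibble::tibble(time = design$tag_times, kind = "tag",
                                 amount = NA_real_,
                                 value = observe(sim$c_tag, truth$resid,
                                                 "tag"),
                                 unit = "mg/dL")
    }
    sub_rows <- rbind(dose_rows, chal_rows, pk_rows, tag_rows)
    sub_rows$subject <- i
    sub_rows$arm <- arms$arm[a]
    sub_rows$bw <- cov$bw[i]
    sub_rows$bmi <- cov$bmi[i]
    sub_rows$fat_fraction <- arms$fat_fraction[a]
    rows[[i]] <- sub_rows
  }
  out <- do.call(rbind, rows)
  tibble::as_tibble(out[, c("subject", "arm", "time", "kind", "amount",
                            "value", "unit", "bw", "bmi", "fat_fraction")])
}

.dataset_cols <- c("subject", "arm", "time", "kind", "amount", "value",
                   "unit", "bw", "bmi", "fat_fraction")

validate_dataset <- function(data) {
  miss <- setdiff(c("subject", "time", "kind"), names(data))
  if (length(miss))
    stop("dataset is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(data$kind), c("dose", "challenge", "pk", "tag"))
  if (length(bad))
    stop("dataset has malformed 'kind' value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  obs <- data$kind %in% c("pk", "tag")
  if (any(obs) && (!"value" %in% names(data) || anyNA(data$value[obs])))
    stop("dataset observation rows must carry a 'value'", call. = FALSE)
  invisible(data)
}

#' Write / read an observation table as CSV
#'
#' Lossless CSV round trip of the long-format dataset with schema
#' validation on read (required columns present, `kind` values well
#' formed, observation rows carrying values).
#'
#' @param data an observation table.
#' @param path file path.
#' @return `read_dataset` returns the validated tibble.
#' @export
write_dataset <- function(data, path) {
  validate_dataset(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  # all-NA numeric columns come back logical from read.csv
  for (cc in intersect(c("time", "amount", "value", "bw", "bmi",
                         "fat_fraction"), names(df)))
    df[[cc]] <- as.numeric(df[[cc]])
  validate_dataset(df)
  tibble::as_tibble(df)
}
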