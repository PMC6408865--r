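test_that("study templates encode the published designs", {
  rat <- make_design("rat")
  expect_equal(rat$tag_times, c(2, 2.5, 3.5, 5, 8, 11))
  expect_equal(sum(rat$arms$n), 53)
  expect_equal(rat$arms$n[rat$arms$arm == "vehicle"], 11L)
  expect_equal(rat$arms$n[rat$arms$arm == "naive"], 6L)
  expect_equal(rat$challenges$time, 2)
  expect_false(rat$arms$challenged[rat$arms$arm == "naive"])

  sad <- make_design("sad")
  expect_equal(sad$arms$n[!sad$arms$placebo], rep(6L, 10))
  expect_equal(sad$arms$n[sad$arms$placebo], 2L * 10L)
  expect_equal(range(sad$arms$dose[!sad$arms$placebo]), c(1, 60))
  expect_equal(sad$challenges$time, c(0, 28)) # baseline meal + 4 h post dose
  expect_equal(sad$dose_times, 24)

  mad <- make_design("mad")
  expect_equal(sum(mad$arms$n[!mad$arms$placebo]), 42)
  expect_equal(mad$arms$n[mad$arms$placebo], 20L)
  expect_equal(length(mad$dose_times), 7)

  mouse <- make_design("mouse")
  expect_equal(sum(mouse$arms$n), 41)
  expect_equal(mouse$challenges$time, 0.5)

  expect_error(make_design("dog"), "sad, mad, rat, mouse")
  # arm-size overrides scale row counts linearly
  half <- make_design("rat", n_per_arm = c(4, 4, 4, 4, 2))
  expect_equal(sum(half$arms$n), 18)
})

test_that("simulated observation counts follow the design arithmetic", {
  design <- make_design("rat")
  dat <- simulate_study(design, species_truth("rat"), seed = 1)
  expect_equal(length(unique(dat$subject)), 53)
  # 3 animals per active group are serially bled for PK only
  tag_subjects <- unique(dat$subject[dat$kind == "tag"])
  pk_subjects <- unique(dat$subject[dat$kind == "pk"])
  expect_equal(length(tag_subjects), 53 - 9)
  expect_equal(sum(dat$kind == "tag"), (53 - 9) * 6)
  expect_equal(sum(dat$kind == "pk"), 9 * 5 + 27 * 1)
  expect_equal(length(intersect(tag_subjects, pk_subjects)), 27)
  # naive animals carry no challenge row
  naive <- unique(dat$subject[dat$arm == "naive"])
  expect_equal(length(naive), 6)
  expect_equal(sum(dat$kind == "challenge" & dat$subject %in% naive), 0)

  mouse <- simulate_study(make_design("mouse"), species_truth("mouse"),
                          seed = 1)
  expect_equal(sum(mouse$kind == "tag"), (41 - 9) * 5)
  expect_equal(sum(mouse$kind == "pk"), 9 * 4)
})

test_that("a noise-free placebo arm sits exactly on the baseline at
           pre-challenge times", {
  truth <- species_truth("human")
  truth$omega_cv <- c()
  truth$resid <- residual_spec(0, 0)
  truth$covariates <- covariate_model() # reference covariates
  design <- make_design("sad", doses = 5, n_active = 0, n_placebo = 3)
  dat <- simulate_study(design, truth, seed = 9)
  base <- dat$value[dat$kind == "tag" & dat$time == 0]
  expect_equal(base, rep(truth$tag$r0, length(base)))
})

test_that("fixed seeds reproduce the table exactly and different seeds do
           not", {
  design <- make_design("mouse")
  truth <- species_truth("mouse")
  a <- simulate_study(design, truth, seed = 33)
  b <- simulate_study(design, truth, seed = 33)
  expect_identical(a, b)
  c <- simulate_study(design, truth, seed = 34)
  expect_false(identical(a, c))
})

test_that("log-normal IIV centres the individual baselines on the
           population geometric mean", {
  truth <- species_truth("human")
  truth$resid <- residual_spec(0, 0)
  truth$covariates <- covariate_model() # isolate the random effect
  design <- make_design("sad", doses = 1, n_active = 0, n_placebo = 1000)
  dat <- simulate_study(design, truth, seed = 4)
  r0_i <- dat$value[dat$kind == "tag" & dat$time == 0]
  expect_equal(length(r0_i), 1000)
  gm <- exp(mean(log(r0_i)))
  expect_lt(abs(gm / 97.8 - 1), 0.02)
})

test_that("pre-dose baseline meal occasions are unaffected by the drug", {
  truth <- species_truth("human")
  truth$omega_cv <- c()
  truth$resid <- residual_spec(0, 0)
  truth$covariates <- covariate_model() # same baseline for everyone
  design <- make_design("sad", doses = 60, n_active = 2, n_placebo = 2)
  dat <- simulate_study(design, truth, seed = 21)
  active <- unique(dat$subject[dat$kind == "dose" & dat$amount > 0])
  baseline <- dat$kind == "tag" & dat$time <= 8
  for (s in active) {
    a <- dat$value[baseline & dat$subject == s]
    pl <- dat$value[baseline & !(dat$subject %in% active)]
    pl <- matrix(pl, ncol = length(a), byrow = TRUE)[1, ]
    expect_equal(a, pl, tolerance = 1e-10)
  }
  # while the post-dose excursion is visibly suppressed at 60 mg
  post <- dat$kind == "tag" & dat$time >= 28
  peak_active <- max(dat$value[post & dat$subject == active[1]])
  peak_placebo <- max(dat$value[post & !(dat$subject %in% active)])
  expect_lt(peak_active, 0.75 * peak_placebo)
})

test_that("dataset CSV round trip is lossless and validated", {
  dat <- simulate_study(make_design("mouse"), species_truth("mouse"),
                        seed = 3)
  path <- tempfile(fileext = ".csv")
  write_dataset(dat, path)
  back <- read_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(dat), tolerance = 1e-12)
  # header-only file round trips
  write_dataset(dat[0, ], path)
  expect_equal(nrow(read_dataset(path)), 0)
  # schema violations are named
  bad <- dat
  bad$kind[3] <- "banana"
  expect_error(write_dataset(bad, path), "banana")
  miss <- dat[, setdiff(names(dat), "kind")]
  utils::write.csv(miss, path, row.names = FALSE)
  expect_error(read_dataset(path), "kind")
})

test_that("simulation truth components are checked before use", {
  truth <- species_truth("rat")
  truth$resid <- NULL
  expect_error(simulate_study(make_design("rat"), truth, seed = 1),
               "resid")
})
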