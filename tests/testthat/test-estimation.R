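# Fitting tests run on deliberately small designs so the whole suite stays
# fast; recovery at the published design scale lives in the acceptance
# tests.

# noise-free rich-data fixture: densified TAG sampling, refined simulator
# step (so the independent simulator and likelihood discretizations agree
# to ~1e-9), a sane residual starting value (estimating sigma on
# noise-free data is an exponentially deepening canyon), and jittered
# multistart as the guard against the rate-exchange mode
dense_noise_free <- function() {
  tiny_rat_setup(n_per_arm = c(2, 4, 4, 4, 0),
                 resid = residual_spec(1e-10, 1e-10), sim_h = 0.001,
                 tag_times = seq(2, 11, 0.5))
}

test_that("sequential fit recovers generating values from noise-free
           rich data", {
  setup <- dense_noise_free()
  init <- setup$truth
  init$resid <- residual_spec(0.1, 0.1)
  fit <- fit_sequential(setup$data, setup$spec, init = init,
                        control = fit_control(eval.max = 2000,
                                              iter.max = 1500,
                                              n_starts = 3))
  truth <- olttmod:::flatten_params(setup$truth)
  est <- fit$estimates
  expect_equal(unname(est / truth[names(est)]), rep(1, length(est)),
               tolerance = 1e-3)
  expect_length(fit$stages, 2)
})

test_that("identifiability: a threefold-distorted start still recovers the
           optimum on noise-free data", {
  setup <- dense_noise_free()
  init <- setup$truth
  init$tag <- do.call(tag_params, lapply(unclass(init$tag), `*`, 3))
  init$pk <- pk_params(ka = init$pk$ka, v = init$pk$v * 3,
                       cl = init$pk$cl * 3, fu = init$pk$fu,
                       mw = init$pk$mw)
  init$resid <- residual_spec(0.1, 0.1)
  fit <- fit_sequential(setup$data, setup$spec, init = init,
                        control = fit_control(eval.max = 2000,
                                              iter.max = 1500,
                                              n_starts = 3))
  truth <- olttmod:::flatten_params(setup$truth)
  est <- fit$estimates
  expect_equal(unname(est / truth[names(est)]), rep(1, length(est)),
               tolerance = 1e-3)
})

test_that("simultaneous fit equals the sequential fit when nothing is
           random and attains no worse an objective with noise", {
  setup <- dense_noise_free()
  init0 <- setup$truth
  init0$resid <- residual_spec(0.1, 0.1)
  seq_fit <- fit_sequential(setup$data, setup$spec, init = init0)
  sim_fit <- fit_simultaneous(setup$data, setup$spec, init = seq_fit)
  expect_equal(unname(sim_fit$estimates[names(seq_fit$estimates)] /
                        seq_fit$estimates), rep(1, 8), tolerance = 1e-3)
  noisy <- tiny_rat_setup(resid = residual_spec(0.2, 0.15),
                          omega_cv = c(r0 = 18.5), seed = 12)
  s1 <- fit_sequential(noisy$data, noisy$spec)
  s2 <- fit_simultaneous(noisy$data, noisy$spec, init = s1)
  # allowance: the two objectives locate per-subject empirical-Bayes modes
  # independently, which perturbs the Laplace value by ~1e-2 OFV units
  expect_lte(s2$ofv, s1$ofv + 0.05)
})

test_that("estimates are exchangeable under relabelling of subjects and
           bit-identical on refit", {
  noisy <- tiny_rat_setup(resid = residual_spec(0.2, 0.15),
                          omega_cv = c(r0 = 18.5), seed = 13)
  fit1 <- fit_simultaneous(noisy$data, noisy$spec)
  fit1b <- fit_simultaneous(noisy$data, noisy$spec)
  expect_identical(fit1$estimates, fit1b$estimates)
  expect_identical(fit1$ofv, fit1b$ofv)
  # relabel subjects in reverse order: the objective itself is invariant
  dat2 <- noisy$data
  ids <- sort(unique(dat2$subject))
  dat2$subject <- rev(ids)[match(dat2$subject, ids)]
  dat2 <- dat2[order(dat2$subject), ]
  expect_equal(neg2ll(dat2, noisy$truth, mode = "joint"),
               neg2ll(noisy$data, noisy$truth, mode = "joint"),
               tolerance = 1e-8)
  # and so are the fitted estimates, where the optimizer's endpoint is
  # stable (fixed-effects-only fit)
  fe <- tiny_rat_setup(resid = residual_spec(0.2, 0.15), seed = 13)
  f1 <- fit_sequential(fe$data, fe$spec)
  dat3 <- fe$data
  ids <- sort(unique(dat3$subject))
  dat3$subject <- rev(ids)[match(dat3$subject, ids)]
  dat3 <- dat3[order(dat3$subject), ]
  f2 <- fit_sequential(dat3, fe$spec)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
})

test_that("reported estimates are positive and produced on the log scale", {
  noisy <- tiny_rat_setup(resid = residual_spec(0.3, 0.15),
                          omega_cv = c(r0 = 18.5), seed = 14)
  fit <- fit_simultaneous(noisy$data, noisy$spec)
  expect_true(all(fit$estimates > 0))
  expect_true(all(fit$resid_hat > 0))
  st <- fit$stages[[1]]
  expect_true(all(names(st$opt$par) %in%
    c("logtheta", "theta_bmi", "log_omega", "log_sig_pk", "log_sig_tag")))
})

test_that("standard errors from a quadratic objective match the closed
           form", {
  # -logL = 0.5 * (x - mu)' H (x - mu) with known curvature
  H <- matrix(c(4, 1, 1, 2), 2)
  fn <- function(x) 0.5 * drop(t(x) %*% H %*% x)
  se <- hessian_se(fn, c(0, 0))
  expect_equal(se, sqrt(diag(solve(H))), tolerance = 1e-6)
  # a flat direction is flagged, not fabricated
  fn_flat <- function(x) 0.5 * x[1]^2 - 0.5 * x[2]^2
  se_flat <- hessian_se(fn_flat, c(0, 0))
  expect_true(is.na(se_flat[2]) && !is.na(se_flat[1]))
})

test_that("relative standard errors shrink as the design grows", {
  small <- tiny_rat_setup(resid = residual_spec(0.3, 0.15), seed = 15,
                          n_per_arm = c(2, 2, 2, 2, 0))
  big <- tiny_rat_setup(resid = residual_spec(0.3, 0.15), seed = 15,
                        n_per_arm = c(8, 8, 8, 8, 0))
  cv_small <- cv_from_hessian(fit_sequential(small$data, small$spec))
  cv_big <- cv_from_hessian(fit_sequential(big$data, big$spec))
  common <- intersect(names(cv_small), names(cv_big))
  expect_lt(median(cv_big[common], na.rm = TRUE),
            median(cv_small[common], na.rm = TRUE))
  expect_true(all(cv_big[common] >= 0, na.rm = TRUE))
})

test_that("relative standard errors do not depend on the dose/conc unit
           convention", {
  noisy <- tiny_rat_setup(resid = residual_spec(0.2, 0.15), seed = 16)
  fit1 <- fit_sequential(noisy$data, noisy$spec)
  # halving the molecular weight doubles every concentration-scale value
  spec2 <- noisy$spec
  spec2$mw <- noisy$spec$mw / 2
  spec2$init$pk <- pk_params(ka = 3, v = noisy$truth$pk$v * 2,
                             cl = noisy$truth$pk$cl * 2,
                             fu = 0.03, mw = spec2$mw)
  spec2$init$tag <- do.call(tag_params, modifyList(
    unclass(noisy$truth$tag), list(ic50 = noisy$truth$tag$ic50)))
  fit2 <- fit_sequential(noisy$data, spec2)
  cv1 <- cv_from_hessian(fit1)
  cv2 <- cv_from_hessian(fit2)
  expect_equal(cv1[c("r0", "kout", "tlag_tag")],
               cv2[c("r0", "kout", "tlag_tag")], tolerance = 0.02)
  # and the concentration-scale estimate rescales exactly
  expect_equal(fit2$estimates[["v"]], fit1$estimates[["v"]] * 2,
               tolerance = 1e-3)
})

test_that("model comparison applies the likelihood-ratio rule to nested
           fits", {
  noisy <- tiny_rat_setup(resid = residual_spec(0.2, 0.15),
                          omega_cv = c(r0 = 18.5), seed = 17)
  full <- fit_simultaneous(noisy$data, noisy$spec)
  reduced_spec <- noisy$spec
  reduced_spec$fixed <- c("ka", "ic50")
  reduced <- fit_simultaneous(noisy$data, reduced_spec)
  rep <- compare_models(full, reduced)
  expect_equal(rep$delta, reduced$ofv - full$ofv)
  expect_equal(rep$df, 1)
  expect_identical(rep$significant, rep$delta >= rep$threshold)
  expect_warning(compare_models(reduced, full), "nested")
})
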