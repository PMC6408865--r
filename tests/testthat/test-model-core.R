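test_that("inhibition follows the saturable concentration-response curve", {
  ic50 <- 0.0078
  expect_equal(inhibition(0, ic50), 1)
  expect_equal(inhibition(ic50, ic50), 0.5)
  expect_equal(inhibition(3 * ic50, ic50), 0.25)
  # bounded in (0, 1] and strictly decreasing
  cc <- 10^seq(-4, 2, length.out = 50)
  v <- inhibition(cc, ic50)
  expect_true(all(v > 0 & v <= 1))
  expect_true(all(diff(v) < 0))
  expect_error(inhibition(1, 0), "ic50")
  expect_error(inhibition(-1, 0.1), ">= 0")
})

test_that("free-fraction correction scales total concentrations", {
  expect_equal(free_concentration(1.0, 0.055), 0.055)
  expect_equal(free_concentration(0, 0.03), 0)
  expect_equal(free_concentration(2.0, 0.1), 0.2)
  expect_error(free_concentration(1, 0), "fu")
  expect_error(free_concentration(1, 1.2), "fu")
})

test_that("meal and oil challenges convert to grams of TAG", {
  expect_equal(meal_tag_dose(1100, 0.60), 73.33, tolerance = 1e-3)
  expect_equal(meal_tag_dose(1100, 0.45), 55.0)
  expect_equal(meal_tag_dose(0, 0.45), 0)
  expect_error(meal_tag_dose(1100, 1.2), "fat_fraction")
  expect_equal(oil_tag_dose(5, 0.23, 1, 0.9), 1.035)
  expect_equal(oil_tag_dose(10, 0.025, 0.2, 0.917), 0.04585)
  expect_equal(oil_tag_dose(0, 0.23, 1, 0.9), 0)
  expect_error(oil_tag_dose(5, 0.23, 0, 0.9), "oil_fraction")
})

test_that("one-compartment PK matches the Bateman closed form and an
           adaptive ODE integration", {
  p <- pk_params(ka = 3, v = 8.66, cl = 0.73, fu = 0.03, mw = 420)
  tt <- seq(1, 12, length.out = 50)
  doses <- data.frame(time = 1, amount = 0.69)
  conc <- pk_profile(tt, doses, p)
  amt <- 0.69 / 420 * 1000
  ref <- oracle_bateman(tt - 1, amt, 3, 8.66, 0.73 / 8.66)
  expect_equal(conc, ref, tolerance = 1e-8)
  # independent oracle: stiff-capable adaptive integration of the
  # absorption-elimination system
  sol <- deSolve::lsoda(
    c(gut = amt, central = 0),
    times = tt - 1,
    func = function(t, y, parms)
      list(c(-3 * y[1], 3 * y[1] - 0.73 / 8.66 * y[2])),
    rtol = 1e-10, atol = 1e-12)
  expect_equal(conc, sol[, "central"] / 8.66, tolerance = 1e-8)
  expect_equal(pk_profile(0.5, doses, p), 0)
})

test_that("two-compartment PK conserves mass: AUC equals dose over CL", {
  p <- species_truth("human")$pk
  dose_mg <- 20
  f <- function(t) { # integrate() does not promise sorted abscissae
    o <- order(t)
    out <- numeric(length(t))
    out[o] <- pk_profile(t[o], data.frame(time = 0, amount = dose_mg), p)
    out
  }
  # piecewise adaptive quadrature (integrate needs sorted inputs per call)
  auc <- integrate(f, 0, 24, rel.tol = 1e-9)$value +
    integrate(f, 24, 400, rel.tol = 1e-9)$value
  expect_equal(auc, dose_mg / 420 * 1000 / p$cl, tolerance = 1e-4)
})

test_that("PK superposition over multiple doses is linear and ordered", {
  p <- species_truth("human")$pk
  tt <- seq(0, 72, 0.5)
  one <- pk_profile(tt, data.frame(time = 24, amount = 10), p)
  two <- pk_profile(tt, data.frame(time = c(24, 48), amount = 10), p)
  expect_equal(two, one + c(rep(0, 48), one[seq_len(length(tt) - 48)]),
               tolerance = 1e-10)
  expect_error(pk_profile(c(1, 0, 2), data.frame(time = 0, amount = 1), p),
               "ordered")
})

test_that("placebo TAG excursion is the closed-form double exponential", {
  p <- species_truth("human")$tag
  tt <- seq(0, 24, 0.25)
  sim <- simulate_tag(p, data.frame(time = 0, tag_mass = 73.33), times = tt)
  ref <- oracle_placebo_tag(tt, p$r0, 73330, p$v_tag, p$ka_tag, p$kout,
                            p$tlag_tag)
  expect_equal(sim$c_tag, ref, tolerance = 1e-6)
  # no challenge: the system stays at its baseline steady state
  flat <- simulate_tag(p, data.frame(time = numeric(0),
                                     tag_mass = numeric(0)), times = tt)
  expect_equal(flat$c_tag, rep(p$r0, length(tt)))
})

test_that("incremental AUC under constant inhibition is i*A/(V*kout)", {
  p <- species_truth("human")$tag
  for (i in c(1, 0.6, 0.25)) {
    tt <- seq(0, 150, 0.01)
    sim <- simulate_tag(p, data.frame(time = 0, tag_mass = 10),
                        inhibition_input = function(t) rep(i, length(t)),
                        times = tt, h = 0.05)
    iauc <- oracle_simpson(sim$c_tag - p$r0, 0.01)
    expect_equal(iauc, i * 10000 / (p$v_tag * p$kout), tolerance = 1e-4)
  }
})

test_that("TAG response is linear in the challenge mass", {
  p <- species_truth("rat")$tag
  tt <- seq(0, 12, 0.5)
  pk <- species_truth("rat")$pk
  inh <- function(t) inhibition(
    pk_profile(t, data.frame(time = 0, amount = 3), pk), p$ic50)
  s1 <- simulate_tag(p, data.frame(time = 2, tag_mass = 1), inh, tt)
  s2 <- simulate_tag(p, data.frame(time = 2, tag_mass = 2), inh, tt)
  expect_equal(s2$c_tag - p$r0, 2 * (s1$c_tag - p$r0), tolerance = 1e-10)
  # placebo reduction: zero drug makes the curve independent of PK params
  s3 <- simulate_tag(p, data.frame(time = 2, tag_mass = 1), times = tt)
  pk2 <- species_truth("mouse")$pk
  inh0 <- function(t) inhibition(
    pk_profile(t, data.frame(time = 0, amount = 0), pk2), p$ic50)
  s4 <- simulate_tag(p, data.frame(time = 2, tag_mass = 1), inh0, tt)
  expect_equal(s3$c_tag, s4$c_tag)
})

test_that("ODE output matches a brute-force fine-step integrator", {
  tr <- species_truth("human")
  p <- tr$tag
  inh <- function(t) inhibition(
    pk_profile(t, data.frame(time = 0, amount = 20), tr$pk), p$ic50)
  tt <- seq(0.5, 12, 0.5)
  sim <- simulate_tag(p, data.frame(time = 0, tag_mass = 73.33), inh,
                      times = tt, h = 0.02)
  ref <- oracle_rk4_tag(tt, p$r0, 73.33, p$v_tag, p$ka_tag, p$kout,
                        0, p$tlag_tag, inh, h = 1e-3)
  expect_equal(sim$c_tag, ref, tolerance = 1e-4)
})

test_that("depot bookkeeping: outflow equals ka times the depot integral", {
  p <- species_truth("rat")$tag
  tt <- seq(4, 10, 0.005) # challenge-free interval after loading
  sim <- simulate_tag(p, data.frame(time = 2, tag_mass = 1.035), times = tt)
  lost <- sim$a_tag[1] - sim$a_tag[length(tt)]
  expect_equal(lost, p$ka_tag * oracle_simpson(sim$a_tag, 0.005),
               tolerance = 1e-6)
  # depot is non-increasing between challenges
  expect_true(all(diff(sim$a_tag) <= 0))
})

test_that("structural model rejects malformed inputs", {
  p <- species_truth("rat")$tag
  expect_error(simulate_tag(p, data.frame(time = 1, tag_mass = -1),
                            times = 1:5), "tag_mass")
  expect_error(simulate_tag(p, data.frame(time = 1, tag_mass = 1),
                            times = c(2, 1)), "increasing")
  expect_error(tag_params(1, 1, 1, -1, 1, 1), "r0")
  expect_error(pk_params(ka = 1, v = 1, cl = 1, v2 = 5), "both")
  expect_error(pk_params(ka = 1, v = 1, cl = 1, fu = 2), "fu")
})
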