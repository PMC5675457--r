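test_that("single-meal Ra curve peaks at t_max_g and is mass-consistent", {
  ra <- ra_signal(meal_events(0, 50), absorption_params(t_max_g = 50,
                                                        cho_bio = 0.8),
                  dt = 1, duration = 500)
  expect_equal(signal_time(ra)[which.max(ra$values)], 50)

  # numerical integral over a long horizon recovers cho_bio of the mass
  ra_long <- ra_signal(meal_events(0, 50), absorption_params(), dt = 1,
                       duration = 5000)
  v <- ra_long$values
  integ <- sum((v[-1] + v[-length(v)]) / 2)     # trapezoid, dt = 1
  expect_equal(integ / 50, 0.8, tolerance = 1e-3)
  # cross-check the quadrature with an independent integrator
  skip_if_not_installed("pracma")
  expect_equal(pracma::trapz(signal_time(ra_long), v) / 50, 0.8,
               tolerance = 1e-3)
})

test_that("Ra is nonnegative, linear in mass and superposes over meals", {
  p <- absorption_params()
  one <- ra_signal(meal_events(30, 40), p, dt = 5, duration = 1000)
  two <- ra_signal(meal_events(200, 25), p, dt = 5, duration = 1000)
  both <- ra_signal(meal_events(c(30, 200), c(40, 25)), p, dt = 5,
                    duration = 1000)
  dbl <- ra_signal(meal_events(30, 80), p, dt = 5, duration = 1000)
  expect_true(all(both$values >= 0))
  expect_equal(both$values, one$values + two$values)
  expect_equal(dbl$values, 2 * one$values)
  expect_true(all(one$values[signal_time(one) < 30] == 0))
})

test_that("Ra handles empty meal lists and rejects bad parameters", {
  z <- ra_signal(meal_events(), absorption_params(), dt = 1, duration = 100)
  expect_true(all(z$values == 0))
  expect_error(ra_signal(meal_events(0, 50), absorption_params(), dt = -1,
                         duration = 100), "dt")
  expect_error(absorption_params(t_max_g = -5))
  expect_error(absorption_params(cho_bio = 1.4))
  expect_error(meal_events(10, -3))
})

test_that("IOB of zero input is zero and impulse response decays", {
  quiet <- insulin_delivery(basal = 0, duration = 300)
  io <- iob_signal(quiet, iob_params(), dt = 1, duration = 300)
  expect_true(all(io$values == 0))

  del <- insulin_delivery(basal = 0, bolus_time = 0, bolus_units = 1,
                          duration = 400)
  imp <- iob_signal(del, iob_params(), dt = 1, duration = 400)
  expect_true(all(diff(imp$values) <= 1e-12))   # monotone non-increasing
  expect_true(all(imp$values >= 0))
})

test_that("discrete IOB converges to the closed-form impulse response", {
  closed <- function(t, K = 0.039) exp(-K * t) * (1 + K * t)
  del <- insulin_delivery(basal = 0, bolus_time = 0, bolus_units = 1,
                          duration = 400)
  errs <- vapply(c(1, 0.5, 0.25), function(dt) {
    io <- iob_signal(del, iob_params(), dt = dt, duration = 400)
    max(abs(io$values - closed(signal_time(io))))
  }, numeric(1))
  expect_lt(errs[1], 0.01)
  # halving dt at least (about) halves the maximum deviation
  expect_lt(errs[2], errs[1] / 1.8)
  expect_lt(errs[3], errs[2] / 1.8)
  io1 <- iob_signal(del, iob_params(), dt = 0.125, duration = 200)
  expect_equal(signal_at(io1, 120), closed(120), tolerance = 0.01)
})

test_that("IOB compartments stay nonnegative under nonnegative dosing", {
  set.seed(1)
  basal <- uniform_signal(runif(500, 0, 0.05), t0 = 0, dt = 1)
  del <- insulin_delivery(basal, bolus_time = c(30, 200),
                          bolus_units = c(4, 6))
  io <- iob_signal(del, iob_params(), dt = 1)
  expect_true(all(io$values >= 0))
})

test_that("bolus calculator follows the clinical correction convention", {
  p <- bolus_therapy_params(cr = 10, cf = 40, g_target = 120)
  expect_equal(bolus_dose(60, p, g_b = 120), 6)     # correction vanishes
  expect_equal(bolus_dose(0, p, g_b = 120), 0)
  expect_equal(bolus_dose(60, p, g_b = 200), 8)     # 6 + 80/40
  # far below target: correction clamps the dose at zero
  expect_equal(bolus_dose(10, p, g_b = 60), max(0, 1 - 60 / 40))
  expect_equal(bolus_dose(0, p, g_b = 40), 0)
  # the printed (target - reading) convention remains available
  q <- bolus_therapy_params(cr = 10, cf = 40, g_target = 120,
                            correction_sign = "target-minus-reading")
  expect_equal(bolus_dose(60, q, g_b = 200), 4)     # 6 - 80/40
  expect_error(bolus_therapy_params(cr = 0))
  expect_error(bolus_therapy_params(cf = -1))
  expect_error(bolus_dose(-5, p, g_b = 120))
})

test_that("uniform signals index time consistently and round to grid", {
  s <- uniform_signal(1:10, t0 = 100, dt = 5)
  expect_equal(signal_time(s), seq(100, 145, by = 5))
  expect_equal(signal_at(s, c(100, 145)), c(1, 10))
  expect_error(signal_at(s, 102), "grid")
  expect_error(signal_at(s, 150), "support")
  expect_error(uniform_signal(numeric(0)))
  expect_error(uniform_signal(1:3, dt = 0))
})
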