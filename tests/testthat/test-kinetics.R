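test_that("exponential fit recovers generating parameters on noise-free traces", {
  for (k in c(0.05, 0.16, 1, 2)) {
    for (A in c(0.3, 0.8, 2)) {
      f <- fit_exponential(exp_trace(k, A))
      expect_true(f$converged)
      expect_lt(rel_err(coef(f)[["k"]], k), 1e-6)
      expect_lt(rel_err(coef(f)[["amplitude"]], A), 1e-6)
    }
  }
  # decay direction
  t <- seq(0, 20, by = 0.25)
  tr <- kinetic_trace(t, 0.1 + 0.6 * exp(-0.3 * t), "min", "delta_fret")
  f <- fit_exponential(tr, direction = "decay")
  expect_lt(rel_err(coef(f)[["k"]], 0.3), 1e-6)
  expect_lt(rel_err(coef(f)[["amplitude"]], 0.6), 1e-6)
})

test_that("exponential fit with linear term separates the two components", {
  tr <- exp_trace(2, 0.5, t = seq(0, 3, by = 0.05), slope = 0.01)
  f <- fit_exponential(tr, with_linear_term = TRUE)
  expect_lt(rel_err(coef(f)[["k"]], 2), 1e-6)
  expect_lt(rel_err(coef(f)[["linear_slope"]], 0.01), 1e-5)
})

test_that("exponential fit handles flat traces and rejects short ones", {
  f <- fit_exponential(kinetic_trace(1:10, rep(0.3, 10), "min", "rfu"))
  expect_equal(coef(f)[["amplitude"]], 0)
  expect_equal(coef(f)[["offset"]], 0.3)
  expect_error(fit_exponential(kinetic_trace(1:3, c(1, 2, 3), "min", "rfu")),
               "at least")
  expect_error(fit_exponential(kinetic_trace(1:4, c(1, 2, 3, 4), "min", "rfu"),
                               with_linear_term = TRUE), "at least")
})

test_that("Hill fit recovers parameters and honors the half-max definition", {
  cc <- c(1, 3, 10, 30, 100, 300, 1000, 3000)
  resp <- 1 * cc^2 / (100^2 + cc^2)
  f <- fit_hill(cc, resp)
  expect_lt(rel_err(coef(f)[["half_max"]], 100), 1e-6)
  expect_lt(rel_err(coef(f)[["hill_n"]], 2), 1e-6)
  expect_lt(rel_err(coef(f)[["response_max"]], 1), 1e-6)
  # response at c = half_max is baseline + response_max / 2 by definition
  expect_equal(predict(f, coef(f)[["half_max"]]),
               coef(f)[["baseline"]] + coef(f)[["response_max"]] / 2,
               tolerance = 1e-8)
  # a hyperbola fits with hill_n ~ 1
  f1 <- fit_hill(cc, 0.1 + 0.9 * cc / (50 + cc))
  expect_lt(rel_err(coef(f1)[["hill_n"]], 1), 1e-5)
  expect_error(fit_hill(cc, rep(0.5, length(cc))), "flat")
  expect_error(fit_hill(cc[1:4], resp[1:4]), "at least 5")
})

test_that("initial rate finds the linear regime and excludes the plateau", {
  tr <- kinetic_trace(0:19, 2 * 0:19, "min", "rfu")
  ir <- suppressWarnings(initial_rate(tr))
  expect_equal(ir$slope, 2, tolerance = 1e-12)
  expect_equal(ir$window[2], 20L)
  # linear segment then plateau: window must stop at the kink
  tr2 <- kinetic_trace(0:19, pmin(2 * 0:19, 20), "min", "rfu")
  ir2 <- suppressWarnings(initial_rate(tr2))
  expect_equal(ir2$slope, 2, tolerance = 1e-12)
  expect_lte(ir2$window[2], 11L)
  # early window of an exponential approximates the t = 0 derivative A*k
  # (a tight linearity threshold keeps the window in the near-linear onset)
  tr3 <- exp_trace(0.5, 2, t = seq(0, 10, by = 0.05))
  ir3 <- suppressWarnings(initial_rate(tr3, r2_threshold = 0.9999))
  expect_lt(rel_err(ir3$slope, 2 * 0.5), 0.05)
  # fallback warns when nothing is linear enough
  set.seed(1)
  trn <- kinetic_trace(1:8, rnorm(8), "min", "rfu")
  expect_warning(initial_rate(trn, r2_threshold = 0.99999), "falling back")
})

test_that("time-to-fraction arithmetic is exact and unit-aware", {
  for (k in c(0.001, 0.1, 2, 50))
    expect_equal(as.numeric(t_fraction(rate_constant(k, "hr"), 0.9)) * k,
                 log(10), tolerance = 1e-12)
  # limit f -> 0 gives t -> 0
  expect_lt(as.numeric(t_fraction(rate_constant(1, "hr"), 1e-12)), 1e-10)
  expect_error(t_fraction(rate_constant(0, "hr"), 0.9), "k > 0")
  expect_error(t_fraction(rate_constant(1, "hr"), 1), "strictly between")
  expect_equal(convert_time(120, "min", "hr"), 2)
  expect_equal(convert_rate(1, "min", "hr"), 60)
})

test_that("rate-basis conversion doubles per site to per dimer and round-trips", {
  r <- rate_constant(0.5808, "hr", "per_site")
  d <- convert_rate_basis(r)
  expect_equal(d$value, 1.1616)
  expect_identical(d$basis, "per_dimer")
  back <- convert_rate_basis(d)
  expect_identical(back$value, r$value)
  expect_identical(back$basis, "per_site")
  expect_equal(convert_rate_basis(rate_constant(0, "hr", "per_site"))$value, 0)
  expect_error(convert_rate_basis(rate_constant(1, "hr", "none")), "basis")
})

test_that("FRET ratio traces start at zero and are scale invariant", {
  t <- 0:20
  don <- kinetic_trace(t, rep(100, 21), "min", "rfu")
  acc <- kinetic_trace(t, seq(100, 200, length.out = 21), "min", "rfu")
  dtr <- fret_ratio_trace(don, acc)
  expect_identical(dtr$values[1], 0)
  expect_equal(dtr$values, seq(0, 1, length.out = 21))
  # acceptor = donor: all zeros
  expect_equal(fret_ratio_trace(don, don)$values, rep(0, 21))
  # common scaling of both channels leaves the delta-ratio unchanged
  don2 <- kinetic_trace(t, don$values * 3.7, "min", "rfu")
  acc2 <- kinetic_trace(t, acc$values * 3.7, "min", "rfu")
  expect_equal(fret_ratio_trace(don2, acc2)$values, dtr$values)
  expect_error(fret_ratio_trace(kinetic_trace(t + 1, don$values, "min", "rfu"),
                                acc), "identical time grid")
  donz <- kinetic_trace(t, c(0, rep(100, 20)), "min", "rfu")
  expect_error(fret_ratio_trace(donz, acc), "positive")
})

test_that("phosphate calibration fits below the cap and inverts exactly", {
  cal <- suppressWarnings(fit_phosphate_calibration(c(0, 1, 2),
                                                    c(500, 2500, 4500)))
  expect_equal(cal$slope, 2000)
  expect_equal(cal$intercept, 500)
  tr <- kinetic_trace(1:3, c(500, 2500, 4500), "min", "rfu")
  conc <- apply_calibration(cal, tr)
  expect_equal(conc$values, c(0, 1, 2))
  expect_identical(conc$kind, "concentration_uM")
  # a standard above the detector linearity is excluded from the fit
  cal2 <- suppressWarnings(fit_phosphate_calibration(c(0, 1, 2, 12),
                                                     c(500, 2500, 4500, 25000)))
  expect_equal(cal2$points_used, 3L)
  expect_identical(cal2$excluded, 4L)
  expect_equal(cal2$slope, 2000)
  expect_error(fit_phosphate_calibration(c(0, 1), c(500, 2500)), "at least 3")
  # noisy standards: recovery within 2 SE
  set.seed(42)
  pi_std <- seq(0, 8, by = 1)
  rfu <- 500 + 2000 * pi_std + rnorm(9, 0, 80)
  cal3 <- fit_phosphate_calibration(pi_std, rfu)
  expect_lt(abs(cal3$slope - 2000), 2 * cal3$se[["slope"]] + 1e-9)
  expect_lt(abs(cal3$intercept - 500), 2 * cal3$se[["intercept"]] + 1e-9)
})

test_that("NADH absorbance slopes convert to ATPase rates by Beer-Lambert", {
  expect_equal(nadh_slope_to_atpase(0, 1), 0)
  expect_equal(nadh_slope_to_atpase(-0.00622, 1), 1.0)
  expect_equal(nadh_slope_to_atpase(-0.00622, 0.5),
               2 * nadh_slope_to_atpase(-0.00622, 1))
  expect_error(nadh_slope_to_atpase(-0.01, 0), "positive")
})

test_that("trace CSV round trip preserves data and units", {
  tr <- exp_trace(0.2, 1, t = seq(0, 10, by = 0.5))
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  tr2 <- read_trace_csv(f)
  expect_equal(tr2$times, tr$times)
  expect_equal(tr2$values, tr$values)
  expect_identical(tr2$time_unit, tr$time_unit)
  expect_identical(tr2$kind, tr$kind)
  unlink(f)
})

test_that("trace construction enforces its invariants", {
  expect_error(kinetic_trace(c(1, 2, 2), 1:3, "min", "rfu"), "increasing")
  expect_error(kinetic_trace(1:3, 1:2, "min", "rfu"), "same length")
  expect_error(kinetic_trace(1:3, 1:3, "fortnight", "rfu"), "unit")
  expect_error(kinetic_trace(1:3, 1:3, "min", "volts"))
})
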