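test_that("state enumeration builds the expected wild-type graph", {
  g <- enumerate_states(cycle_rates("mg"), variant_wildtype())
  cls <- table(g$states$class)
  expect_equal(unname(cls[["open_2T"]]), 1L)
  expect_equal(unname(cls[["closed_tt"]]), 2L)   # buckling-resolved
  expect_equal(unname(cls[["hemi_pre"]]), 2L)
  expect_equal(unname(cls[["hemi_post"]]), 2L)
  expect_equal(unname(cls[["closed_dd"]]), 2L)
  # reopening resets to the ATP/ATP open state (nucleotide exchange is fast)
  re <- g$edges[g$edges$type == "reopen", ]
  expect_true(all(g$states$class[re$to] == "open_2T"))
  # buckled is defined iff closed
  expect_true(all((g$states$conf == "closed") == (g$states$buckled > 0)))
})

test_that("hemi-dead heterodimer has a single absorbing hemi-hydrolyzed state", {
  g <- enumerate_states(cycle_rates("mg"), variant_hemi_dead())
  outflow <- rowSums(g$Q - diag(diag(g$Q)))
  absorbing <- which(-diag(g$Q) < 1e-12)
  expect_length(absorbing, 1L)
  expect_identical(g$states$class[absorbing], "hemi_post")
  # the dead protomer (2) carries the remaining ATP there, buckled
  expect_identical(g$states$n2[absorbing], "T")
  expect_identical(g$states$buckled[absorbing], 2L)
  # no hydrolysis edge leaves any state where the dead protomer is the
  # buckled ATP carrier
  hyd <- g$edges[g$edges$type == "hydrolysis", ]
  from_dead_buckled <- g$states$buckled[hyd$from] == 2L
  expect_false(any(from_dead_buckled))
})

test_that("sensor-broken protomer pins the asymmetry of every closed state", {
  g <- enumerate_states(cycle_rates("mg"), variant_sensor_broken())
  closed <- g$states$conf == "closed"
  expect_true(all(g$states$buckled[closed] == 1L))
  expect_error(
    dimer_variant(protomer_spec(gamma_sensor_intact = FALSE),
                  protomer_spec(gamma_sensor_intact = FALSE)),
    "pinned")
})

test_that("sequentiality: the second hydrolysis requires the flip", {
  # structurally: every edge into the ADP/ADP closed state leaves a
  # post-flip hemi state, and disabling the flip removes ADP/ADP entirely
  g <- enumerate_states(cycle_rates("mg"), variant_wildtype())
  into_dd <- g$edges[g$states$class[g$edges$to] == "closed_dd", ]
  expect_true(all(g$states$class[into_dd$from] == "hemi_post"))
  g0 <- enumerate_states(cycle_rates("mg", k_flip = 0), variant_wildtype())
  expect_false("closed_dd" %in% g0$states$class)
})

test_that("an instantaneous flip collapses the pre-flip hemi state", {
  g <- enumerate_states(cycle_rates("mg", k_flip = Inf), variant_wildtype())
  expect_false("hemi_pre" %in% g$states$class)
  hyd <- g$edges[g$edges$type == "hydrolysis" &
                   g$states$class[g$edges$from] == "closed_tt", ]
  expect_true(all(g$states$class[hyd$to] == "hemi_post"))
})

test_that("master equation conserves probability and matches closed forms", {
  # pure closure reduces to 1 - exp(-k_close t)
  r <- cycle_rates("mg", k_hyd_buckled = 0, k_swap = 0, k_flip = 0,
                   k_open_dd = 0)
  tg <- seq(0, 30, length.out = 61)
  sim <- simulate_master(r, variant_wildtype(), tg)
  expect_equal(sim$observables$fraction_closed, 1 - exp(-0.16 * tg),
               tolerance = 1e-7)
  expect_lt(max(abs(rowSums(sim$occupancy) - 1)), 1e-9)
  # identity at t = 0
  expect_equal(unname(sim$occupancy[1, ]),
               c(1, rep(0, ncol(sim$occupancy) - 1)))
  # cumulative Pi is non-decreasing
  full <- simulate_master(cycle_rates("mg"), variant_wildtype(), tg)
  expect_true(all(diff(full$observables$pi_per_dimer) >= -1e-12))
})

test_that("first in-crystal conversion splits by the competing rates", {
  # integrated flux into the straight-converted state equals k_s/(k_s+k_b)
  kb <- 1; ks <- 0.25
  r <- crystal_rates(k_hyd_buckled = kb, k_hyd_straight = ks)
  tg <- seq(0, 60, length.out = 2001)
  sim <- simulate_master(r, variant_wildtype(), tg, mode = "crystal")
  p_tt <- rowSums(sim$occupancy[, sim$states$class == "closed_tt", drop = FALSE])
  flux_straight <- ks * sum((p_tt[-1] + p_tt[-length(p_tt)]) / 2 * diff(tg))
  expect_equal(flux_straight, ks / (ks + kb), tolerance = 1e-3)
})

test_that("crystal mode with a dead straight rate never reaches ADP/ADP", {
  r <- crystal_rates(k_hyd_buckled = 1, k_hyd_straight = 0)
  ck <- crystal_mode_timecourse(r, c(1, 5, 50))
  expect_equal(ck$P_DD, rep(0, 3), tolerance = 1e-12)
  expect_equal(ck$P_T_on_straight, rep(1, 3), tolerance = 1e-9)
})

test_that("SSA is reproducible under a fixed seed and respects invariants", {
  r <- cycle_rates("mg")
  s1 <- simulate_ssa(r, variant_wildtype(), n_dimers = 500, t_max = 30,
                     seed = 11)
  s2 <- simulate_ssa(r, variant_wildtype(), n_dimers = 500, t_max = 30,
                     seed = 11)
  expect_identical(s1$occupancy, s2$occupancy)
  expect_identical(s1$first_closure_buckled, s2$first_closure_buckled)
  s3 <- simulate_ssa(r, variant_wildtype(), n_dimers = 500, t_max = 30,
                     seed = 12)
  expect_false(identical(s1$occupancy, s3$occupancy))
  expect_true(all(abs(rowSums(s1$occupancy) - 1) < 1e-12))
  expect_true(all(diff(s1$observables$pi_per_dimer) >= -1e-12))
})

test_that("SSA and master engines agree within sampling error", {
  r <- cycle_rates("mg")
  tg <- seq(0, 40, length.out = 41)
  m <- simulate_master(r, variant_wildtype(), tg)
  s <- simulate_ssa(r, variant_wildtype(), n_dimers = 4000, t_grid = tg,
                    seed = 5)
  se <- sqrt(pmax(m$occupancy * (1 - m$occupancy), 1e-6) / 4000)
  expect_true(all(abs(s$occupancy - m$occupancy) < 4 * se + 0.005))
})

test_that("single-turnover asymptotes count the reachable hydrolysis events", {
  r <- cycle_rates("mg")
  expect_equal(single_turnover_fraction(r, variant_wildtype())$asymptote, 1)
  expect_equal(single_turnover_fraction(r, variant_hemi_dead())$asymptote, 0.5)
  expect_equal(single_turnover_fraction(r, variant_dead_dead(),
                                        t_max = 20)$asymptote, 0)
  # a reopening leak unlocks the second ATP: slow further phase toward 1
  rl <- cycle_rates("mg", k_open_leak = 0.02)
  st <- single_turnover_fraction(rl, variant_hemi_dead(), t_max = 400)
  expect_equal(st$asymptote, 1)
  mid <- st$trace$values[which.min(abs(st$trace$times - 100))]
  expect_gt(mid, 0.55)
  expect_lt(mid, 0.95)
})

test_that("buckled fraction conditions on state classes correctly", {
  r <- cycle_rates("mg")
  s <- simulate_ssa(r, variant_sensor_broken("intact"), n_dimers = 1000,
                    t_max = 30, seed = 2)
  expect_equal(buckled_fraction(s, "closed")$fraction, 1)
  s2 <- simulate_ssa(r, variant_sensor_broken("broken"), n_dimers = 1000,
                     t_max = 30, seed = 2)
  expect_equal(buckled_fraction(s2, "closed")$fraction, 0)
  # wild type: hemi-pre states put the label's D on either protomer equally
  m <- simulate_master(r, variant_wildtype(), seq(0, 40, length.out = 81))
  expect_equal(buckled_fraction(m, "closed_tt")$fraction, 0.5,
               tolerance = 1e-6)
  expect_error(buckled_fraction(
    simulate_master(r, dimer_variant(protomer_spec(), protomer_spec()),
                    seq(0, 10, length.out = 11)), "closed"), "label")
})

test_that("multiple-turnover FRET contrast: hemi-dead accumulates, wild type cycles", {
  r <- cycle_rates("mg")
  tg <- seq(0, 60, length.out = 61)
  wt <- simulate_master(r, variant_wildtype(), tg)
  hd <- simulate_master(r, variant_hemi_dead(), tg)
  expect_gt(utils::tail(hd$observables$fraction_closed, 1), 0.95)
  expect_lt(utils::tail(wt$observables$fraction_closed, 1), 0.5)
  # the hemi-dead buildup is closure-limited: effective rate near k_close
  tr <- kinetic_trace(tg, hd$observables$fraction_closed, "min",
                      "fraction_hydrolyzed")
  f <- fit_exponential(tr)
  expect_lt(rel_err(coef(f)[["k"]], 0.16), 0.35)
})
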