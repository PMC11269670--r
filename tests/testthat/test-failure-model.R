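test_that("parameter validation rejects out-of-range inputs", {
  expect_error(failure_params(1, 1e-6), "b")
  expect_error(failure_params(-0.1, 1e-6), "b")
  expect_error(failure_params(0.2, 1), "mu")
  expect_error(failure_params(0.2, 1e-6, E0 = 0, F0 = 0), "E0 \\+ F0")
  expect_error(solve_deterministic(failure_params(0.2, 0), d_max = -1),
               "d_max")
  expect_error(simulate_stochastic(failure_params(0.2, 0), d_max = 0),
               "d_max")
})

test_that("deterministic solver matches the closed form across parameters", {
  for (b in c(0, 0.2, 0.45, 0.6)) {
    for (mu in c(0, 1e-8, 1e-4)) {
      traj <- solve_deterministic(failure_params(b, mu), d_max = 30)
      o <- oracle_closed_form(b, mu, 1, 0, traj$time)
      expect_lt(max(abs(traj$E - o$E) / pmax(o$E, 1e-300)), 1e-8)
      expect_lt(max(abs(traj$F - o$F) / pmax(o$F, 1e-300)), 1e-8)
    }
  }
})

test_that("without mutation no failed cells appear and D grows at (1-b)", {
  traj <- solve_deterministic(failure_params(0.2, 0), d_max = 20)
  expect_true(all(traj$F == 0))
  expect_equal(traj$doublings, 0.8 * traj$time / log(2), tolerance = 1e-8)
  expect_equal(doublings(traj), 0.8 * traj$time / log(2), tolerance = 1e-8)
})

test_that("with no burden the total population grows exactly at rate 1", {
  traj <- solve_deterministic(failure_params(0, 1e-6), d_max = 25)
  expect_equal(traj$E + traj$F, exp(traj$time), tolerance = 1e-8)
})

test_that("failed fraction is non-decreasing whenever mutation occurs", {
  for (b in c(0.2, 0.5)) {
    traj <- solve_deterministic(failure_params(b, 1e-5), d_max = 40)
    expect_true(all(diff(traj$failed_fraction) >= -1e-12))
  }
})

test_that("doublings uses the founding-population origin with an absolute option", {
  tr <- new_traj <- tibble::tibble(E = c(1, 8), F = c(0, 0))
  expect_equal(doublings(tr), c(0, 3))
  tr2 <- tibble::tibble(E = 4, F = 4)
  expect_equal(doublings(tr2, absolute = TRUE), 3)
  expect_error(doublings(tibble::tibble(E = numeric(), F = numeric())),
               "empty")
  expect_error(doublings(tibble::tibble(E = 0, F = 0)), "positive")
})

test_that("time to half failure interpolates and handles edge cases", {
  traj <- solve_deterministic(failure_params(0.2, 0), d_max = 10)
  expect_true(is.na(time_to_half_failure(traj)))
  # trajectory already past the threshold at its first stored point
  tr <- tibble::tibble(E = c(4, 4), F = c(6, 12),
                       failed_fraction = c(0.6, 0.75))
  expect_equal(time_to_half_failure(tr), doublings(tr)[1])
  # deterministic run against the closed-form root-finding oracle
  traj2 <- solve_deterministic(failure_params(0.2, 1e-4), d_max = 80)
  expect_lt(abs(time_to_half_failure(traj2) -
                  oracle_half_failure(0.2, 1e-4)), 0.05)
})

test_that("stochastic runs are seed-reproducible and mutation-free runs stay pure", {
  p <- failure_params(0.3, 0)
  t1 <- simulate_stochastic(p, 12, seed = 5)
  expect_true(all(t1$F == 0))
  p2 <- failure_params(0.3, 1e-3)
  a <- simulate_stochastic(p2, 15, seed = 42)
  b <- simulate_stochastic(p2, 15, seed = 42)
  expect_identical(a$E, b$E)
  expect_identical(a$F, b$F)
  c <- simulate_stochastic(p2, 15, seed = 43)
  expect_false(identical(a$E, c$E))
  # integer-valued counts
  expect_true(all(a$E == round(a$E)))
  expect_true(all(a$F == round(a$F)))
})

test_that("exact SSA refuses infeasible population sizes", {
  expect_error(simulate_stochastic(failure_params(0.2, 1e-6), d_max = 40,
                                   seed = 1, method = "exact"),
               "exact_cap")
  expect_silent(simulate_stochastic(failure_params(0.2, 1e-6), d_max = 10,
                                    seed = 1, method = "exact"))
  expect_error(simulate_stochastic(failure_params(0.2, 1e-6), d_max = 70,
                                   seed = 1), "overflow")
})

test_that("ensemble CDF is zero without mutation and respects monotonicity in mu", {
  ens0 <- ensemble_failure_curve(failure_params(0.5, 0), n_runs = 20,
                                 d_max = 15, seed = 1)
  expect_true(all(ens0$cdf$frac_failed == 0))
  expect_equal(sum(!is.na(ens0$half_failure_doublings)), 0)

  hi <- ensemble_failure_curve(failure_params(0.5, 1e-4), n_runs = 120,
                               d_max = 40, seed = 2)
  lo <- ensemble_failure_curve(failure_params(0.5, 1e-6), n_runs = 120,
                               d_max = 40, seed = 2)
  expect_true(all(hi$cdf$frac_failed >= lo$cdf$frac_failed))
  expect_gt(max(hi$cdf$frac_failed), max(lo$cdf$frac_failed))
  # CDFs are valid distribution functions
  expect_true(all(diff(hi$cdf$frac_failed) >= 0))
  expect_true(all(hi$cdf$frac_failed >= 0 & hi$cdf$frac_failed <= 1))
  # tidy/glance accessors
  expect_equal(tidy(hi), hi$cdf)
  expect_equal(glance(hi)$n_runs, 120)
})

test_that("culture-scale arithmetic reproduces colony and test-tube division counts", {
  colony <- divisions_for_culture(final_cells = 8e6)
  expect_equal(colony$divisions, log2(8e6), tolerance = 1e-12)
  expect_equal(colony$divisions_rounded, 23)
  tube <- divisions_for_culture(4, 5e9, start_cells = 8e6)
  expect_equal(tube$divisions_rounded, 11)
  expect_equal(divisions_for_culture(final_cells = 10, start_cells = 10)$divisions, 0)
  expect_error(divisions_for_culture(final_cells = 1, start_cells = 10),
               "below")
})

test_that("failure-rate arithmetic is linear with the documented caps", {
  expect_equal(substitution_failure_rate(1000, 0.2, 5e-10), 1e-7)
  expect_equal(substitution_failure_rate(0, 0.5, 5e-10), 0)
  expect_equal(substitution_failure_rate(2000, 0.2, 5e-10),
               2 * substitution_failure_rate(1000, 0.2, 5e-10))
  expect_error(substitution_failure_rate(-1, 0.2, 5e-10), "non-negative")
  expect_equal(effective_plasmid_rate(1e-9, 100), 1e-7)
  expect_equal(effective_plasmid_rate(3e-8, 1), 3e-8)
  expect_equal(effective_plasmid_rate(0.5, 100), 1)
  expect_error(effective_plasmid_rate(1e-9, 0), "copy_number")
})

test_that("trajectory and ensemble plots build without error", {
  traj <- solve_deterministic(failure_params(0.3, 1e-4), d_max = 20)
  expect_s3_class(autoplot(traj), "ggplot")
  ens <- ensemble_failure_curve(failure_params(0.5, 1e-4), n_runs = 10,
                                d_max = 20, seed = 3)
  expect_s3_class(autoplot(ens), "ggplot")
})
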