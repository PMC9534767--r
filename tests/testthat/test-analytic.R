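test_that("the closed-form ecDNA+ fraction decays as 2/(2+t)", {
  expect_equal(neutral_fraction_positive(0), 1)
  expect_equal(neutral_fraction_positive(2), 0.5)
  # t * f+(t) -> 2 in the long-time limit
  expect_equal(1e6 * neutral_fraction_positive(1e6), 2, tolerance = 1e-5)
  expect_error(neutral_fraction_positive(-1),
               class = "ecdnadyn_parameter_error")
})

test_that("the density right-hand side conserves mass and matches hand kernels", {
  # the ecDNA-free state is absorbing
  rho0 <- c(1, numeric(10))
  expect_equal(density_rhs(rho0, s = 1), numeric(11))
  expect_equal(density_rhs(rho0, s = 2), numeric(11))

  # from all mass at k = 1: inflow to k = 0 is 2 * C(2,0) * 2^-2 = 1/2
  rho1 <- c(0, 1, numeric(9))
  expect_equal(density_rhs(rho1, s = 1)[1], 0.5)

  # density conservation, neutral and under selection (ample truncation)
  rho <- c(0.3, 0.3, 0.2, 0.1, 0.1, numeric(20))
  expect_lt(abs(sum(density_rhs(rho, s = 1))), 1e-12)
  expect_lt(abs(sum(density_rhs(rho, s = 1.7))), 1e-12)
})

test_that("neutral integration conserves M1 and grows M2 linearly", {
  sol <- integrate_density(init = 1, s = 1, t_max = 10, k_max = 128)
  expect_true(all(abs(sol$moments$m1 - 1) < 1e-6))
  # dM2/dt = M1: M2(t) - M2(0) = t
  drift <- sol$moments$m2 - sol$moments$m2[1] - sol$moments$t
  expect_true(all(abs(drift[-1] / sol$moments$t[-1]) < 0.01))
  expect_lt(sol$leaked_mass, 1e-8)
  expect_error(integrate_density(init = c(0.5, 0.2), s = 1),
               class = "ecdnadyn_validation_error")
})

test_that("selection moments match their closed forms", {
  # s = 1: exponent vanishes
  tt <- seq(0, 5, 0.1)
  expect_equal(selection_m1(1, tt, rep(0.3, length(tt))),
               rep(1, length(tt)))
  # rho0 = 1 at s = 2 gives M1 = e^t
  expect_equal(selection_m1(2, tt, rep(1, length(tt))), exp(tt),
               tolerance = 1e-10)

  # cross-check against the full density integration at s = 1.5
  sol <- integrate_density(init = 1, s = 1.5, t_max = 8,
                           times = seq(0, 8, 0.01), k_max = 256)
  pred <- selection_m1(1.5, sol$times, sol$moments$rho0)
  expect_lt(max(abs(sol$moments$m1 - pred)), 1e-4)
  # selection runs also conserve total density
  expect_lt(sol$leaked_mass, 1e-7)

  # M2 = t * M1
  m1 <- rep(1, length(tt))
  expect_equal(selection_m2(tt, m1), tt)
  expect_equal(selection_m2(0, 1), 0)
  expect_error(selection_m2(1:3, 1:2), class = "ecdnadyn_validation_error")
})

test_that("the two-population solution grows exponentially and tends to ecDNA dominance", {
  tt <- seq(0, 4, 0.05)
  # no ecDNA-free cells: pure exponential growth at rate s
  pure <- two_population_selection(2, tt, rep(0, length(tt)))
  expect_equal(pure$n_plus, exp(2 * tt), tolerance = 1e-10)
  expect_equal(pure$n_plus[1], 1 - pure$f_minus[1])

  # with the rho0 path from the density model at s = 2, f+ rises toward 1
  sol <- integrate_density(init = 1, s = 2, t_max = 12, k_max = 512)
  tp <- two_population_selection(2, sol$times, sol$moments$rho0)
  late <- tp$f_plus[sol$times >= 6]
  expect_true(all(diff(late) > 0))
  expect_gt(tail(tp$f_plus, 1), 0.9)

  expect_error(two_population_selection(1, tt, rep(0, length(tt))),
               class = "ecdnadyn_parameter_error")
})

test_that("neutral moments obey the late-time scaling laws and f+ ~ 1/t", {
  sol <- integrate_density(init = 1, s = 1, t_max = 50,
                           times = c(seq(0, 9.5, 0.5), seq(10, 50, 1)),
                           k_max = 256)
  # M2 ~ t and M3 ~ t^2 over the last decade
  expect_lt(abs(moment_scaling_check(sol$times, sol$moments$m2,
                                     window = c(5, 50)) - 1), 0.1)
  expect_lt(abs(moment_scaling_check(sol$times, sol$moments$m3,
                                     window = c(5, 50)) - 2) / 2, 0.1)
  # f+ decays like 1/t: log-log slope in [-1.15, -0.85] on t in [10, 50]
  slope <- moment_scaling_check(sol$times, sol$moments$frac_pos,
                                window = c(10, 50), min_span = 5)
  expect_gt(slope, -1.15)
  expect_lt(slope, -0.85)

  expect_equal(moment_scaling_check(1:100, rep(2, 100)), 0)
  expect_error(moment_scaling_check(seq(8, 10, 0.5), seq(8, 10, 0.5)^2),
               class = "ecdnadyn_estimation_error")
})

test_that("the stochastic simulator agrees with the master equation", {
  # pooled ensemble distribution at t = 3 versus integrated density
  ens <- run_gillespie_ensemble(n0 = 1, s = 1, t_max = 3,
                                record_times = c(0, 3), replicates = 4000,
                                seed = 21)
  sol <- integrate_density(init = 1, s = 1, t_max = 3, times = c(0, 3),
                           k_max = 64)
  q <- ens$pooled[2, ] / sum(ens$pooled[2, ])
  expect_lt(tv_distance(q, sol$rho[2, ]), 0.02)
  # simulated variance tracks the analytic M2(0) + t - M1^2 value (here 3),
  # judged against the Monte-Carlo error estimated from independent batches
  batch_var <- vapply(1:10, function(b) {
    eb <- run_gillespie_ensemble(n0 = 1, s = 1, t_max = 3,
                                 record_times = c(0, 3), replicates = 400,
                                 seed = 3000 + 400 * b)
    eb$moments$variance[2]
  }, numeric(1))
  expect_lt(abs(mean(batch_var) - sol$moments$variance[2]),
            4 * sd(batch_var) / sqrt(10))
})
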