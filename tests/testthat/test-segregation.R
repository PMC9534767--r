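test_that("binomial division conserves copies and matches the exact binomial pmf", {
  # a mother with no copies yields two empty daughters
  out0 <- divide_ecdna(0, p = 0.5, seed = 1)
  expect_identical(c(out0$n1, out0$n2), c(0L, 0L))
  expect_true(is.na(out0$f1))

  # copy conservation over many random founders
  set.seed(11)
  founders <- sample(0:300, 1e5, replace = TRUE)
  div <- divide_ecdna(founders, p = 0.5)
  expect_identical(div$n1 + div$n2, 2L * founders)
  expect_true(all(abs(div$f1 + div$f2 - 1)[founders > 0] < 1e-12))

  # empirical pmf of n1 against the closed-form Binomial(2n, p), n <= 5
  for (n in c(1L, 3L, 5L)) {
    draws <- divide_ecdna(rep(n, 4e4), p = 0.5, seed = 20 + n)$n1
    phat <- tabulate(draws + 1L, nbins = 2 * n + 1) / 4e4
    pexp <- dbinom(0:(2 * n), size = 2 * n, prob = 0.5)
    tol <- 4 * sqrt(pexp * (1 - pexp) / 4e4)
    expect_true(all(abs(phat - pexp) <= tol + 1e-12))
  }

  # mean inherited fraction is 1/2 under unbiased segregation
  f1 <- divide_ecdna(rep(50, 1e5), p = 0.5, seed = 3)$f1
  expect_lt(abs(mean(f1) - 0.5), 3 * sd(f1) / sqrt(length(f1)))

  expect_error(divide_ecdna(10, p = 1), class = "ecdnadyn_parameter_error")
  expect_error(divide_ecdna(-1), class = "ecdnadyn_parameter_error")
})

test_that("chromosomal division is exact at u = 0 and mis-segregates by one copy", {
  perfect <- divide_chromosomal(rep(37, 100), u = 0, seed = 1)
  expect_true(all(perfect$f1 == 0.5) && all(perfect$f2 == 0.5))

  # u = 1 with n = 2 forces f1 into {1/4, 3/4}
  forced <- divide_chromosomal(rep(2, 500), u = 1, seed = 2)
  expect_true(all(forced$f1 %in% c(0.25, 0.75)))

  # P(f1 = 0.55) = u/2 for n = 10 (gain of one copy)
  draws <- divide_chromosomal(rep(10, 4e4), u = 0.05, seed = 3)
  phat <- mean(draws$f1 == 0.55)
  expect_lt(abs(phat - 0.025), 4 * sqrt(0.025 * 0.975 / 4e4))
  # conservation holds here too
  expect_true(all(draws$n1 + draws$n2 == 20L))

  expect_error(divide_chromosomal(0), class = "ecdnadyn_parameter_error")
})

test_that("fraction distributions are symmetric, reproducible, and ordered in spread", {
  chrom0 <- fraction_distribution(segregation_model("chromosomal", u = 0),
                                  n_divisions = 2000, seed = 5)
  centre_bin <- findInterval(0.5, chrom0$breaks, rightmost.closed = TRUE)
  expect_equal(chrom0$masses[centre_bin], 1)
  expect_equal(sum(chrom0$masses), 1)

  binom <- fraction_distribution(segregation_model("ecdna_binomial", p = 0.5),
                                 n_divisions = 1e5, seed = 6)
  # recording both daughters makes the fraction distribution symmetric about
  # 1/2. The histogram mirrors bin-for-bin away from the centre; the atom at
  # exactly f = 1/2 (P(n1 = n) is a few percent) sits on the central bin
  # boundary and goes whole to one side, so the central pair is excluded.
  centre <- c(25L, 26L)
  mirrored <- rev(binom$masses)
  expect_lt(max(abs(binom$masses[-centre] - mirrored[-centre])), 0.005)
  expect_gt(mean(binom$fractions == 0.5), 0.03)
  expect_lt(abs(mean(binom$fractions) - 0.5), 1e-12)
  # bell shape: the mode sits in the central fifth of the unit interval
  expect_true(abs(binom$breaks[which.max(binom$masses)] - 0.5) < 0.1)

  # determinism under a fixed seed
  binom2 <- fraction_distribution(segregation_model("ecdna_binomial", p = 0.5),
                                  n_divisions = 1e4, seed = 77)
  binom3 <- fraction_distribution(segregation_model("ecdna_binomial", p = 0.5),
                                  n_divisions = 1e4, seed = 77)
  expect_identical(binom2$masses, binom3$masses)

  # binomial segregation is far more dispersed than chromosomal u = 0.05
  chrom <- fraction_distribution(segregation_model("chromosomal", u = 0.05),
                                 n_divisions = 1e5, seed = 8)
  expect_gt(var(binom$fractions), var(chrom$fractions))

  expect_error(
    fraction_distribution(segregation_model("ecdna_binomial"),
                          founder_min = 50, founder_max = 10, seed = 1),
    class = "ecdnadyn_parameter_error")
})

test_that("daughter-pair comparison detects matched and mismatched segregation models", {
  model <- segregation_model("ecdna_binomial", p = 0.5)

  # a sample compared against itself has D = 0 and p = 1
  self <- ks_two_sample(c(0.4, 0.5, 0.6), c(0.4, 0.5, 0.6))
  expect_equal(self$D, 0)
  expect_equal(self$p, 1)

  # perfectly even observed fractions are strongly rejected against binomial
  even <- data.frame(n1 = rep(50L, 100), n2 = rep(50L, 100))
  res <- compare_segregation(even, model, n_null = 5e3, seed = 2)
  expect_gt(res$D, 0.3)
  expect_lt(res$p, 1e-6)

  # calibration: matched model is accepted (p > 0.05) in >= 90% of trials
  accepted <- vapply(seq_len(500), function(r) {
    obs <- make_daughter_pairs(model, n_pairs = 100, seed = 4000 + r)
    compare_segregation(obs, model, n_null = 2000, seed = 9000 + r)$p > 0.05
  }, logical(1))
  expect_gte(mean(accepted), 0.9)

  # zero-total pairs are excluded with a warning
  withzero <- data.frame(n1 = c(0L, 30L, 40L), n2 = c(0L, 34L, 38L))
  expect_warning(compare_segregation(withzero, model, n_null = 500, seed = 1),
                 "zero total")
  expect_error(compare_segregation(data.frame(n1 = 1L, n2 = 1L), model),
               class = "ecdnadyn_validation_error")
})
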