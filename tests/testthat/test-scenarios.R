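test_that("selection schedules are contiguous and validated", {
  sched <- selection_schedule(s = c(0.5, 2), durations = c(4, 14))
  expect_equal(sched$t_start, c(0, 4))
  expect_equal(sched$t_end, c(4, 18))
  expect_error(selection_schedule(s = c(1, -1), durations = c(1, 1)),
               class = "ecdnadyn_parameter_error")
  expect_error(selection_schedule(s = 1, durations = numeric(0)),
               class = "ecdnadyn_parameter_error")
})

test_that("the chromosomal scar frequency is a martingale under any schedule", {
  # strong ecDNA selection, scar independent: scar frequency is unbiased
  ends <- vapply(1:120, function(r) {
    cfg <- crispr_config(n0 = 1000, q_ecdna = 0.15, q_scar = 0.15,
                         schedule = selection_schedule(c(0.5, 2), c(4, 8)),
                         passage_cap = 4000, seed = 1000 + r)
    tail(run_crispr_c(cfg, record_dt = 4)$moments$scar_frequency, 1)
  }, numeric(1))
  expect_lt(abs(mean(ends) - 0.15), 3 * sd(ends) / sqrt(length(ends)))

  # no induced ecDNA: junction frequency identically zero
  cfg0 <- crispr_config(n0 = 500, q_ecdna = 0, q_scar = 0.15,
                        schedule = selection_schedule(1, 5),
                        passage_cap = 2000, seed = 3)
  res0 <- run_crispr_c(cfg0)
  expect_true(all(res0$junction_series$ecdna_junction_frequency == 0))
})

test_that("neutral induction keeps the mean copy number while ecDNA+ cells dwindle", {
  runs <- lapply(1:80, function(r) {
    cfg <- crispr_config(n0 = 1000, q_ecdna = 0.15, q_scar = 0.15,
                         schedule = selection_schedule(1, 10),
                         passage_cap = 4000, seed = 2000 + r)
    run_crispr_c(cfg, record_dt = 2.5)$moments
  })
  m1_end <- vapply(runs, function(m) tail(m$m1, 1), numeric(1))
  expect_lt(abs(mean(m1_end) - 0.15), 3 * sd(m1_end) / sqrt(length(m1_end)))
  # the fraction of ecDNA+ cells declines even though the mean holds
  fp <- colMeans(do.call(rbind, lapply(runs, function(m) m$frac_pos)))
  expect_lt(tail(fp, 1), fp[1])
  expect_true(all(diff(fp) < 0))
})

test_that("drug dose-response: stronger second-phase selection raises final copy number", {
  finals <- vapply(c(1, 2, 4), function(s2) {
    mean(vapply(1:12, function(r) {
      cfg <- crispr_config(n0 = 2000, q_ecdna = 0.15, q_scar = 0.15,
                           schedule = selection_schedule(c(0.5, s2), c(4, 14)),
                           passage_cap = 8000, seed = 300 * s2 + r)
      tail(run_crispr_c(cfg, record_dt = 6)$moments$m1, 1)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(finals) > 0))
})

test_that("cell-line expansion keeps the founder mean and is extremely wide", {
  dists <- lapply(1:5, function(r) run_cellline(100, s = 1, n_target = 1e5,
                                                seed = 40 + r))
  means <- vapply(dists, function(d) sum(d$k * d$q), numeric(1))
  expect_lt(abs(mean(means) - 100), 3 * sd(means) / sqrt(5))

  d1 <- dists[[1]]
  sm <- summarize_population(d1)
  # heavy spread: low-copy cells and cells with several-fold the founder load
  expect_gt(sm$variance, 100)
  expect_gt(sum(d1$q[d1$k < 50]), 0)
  expect_gt(max(d1$k[d1$q > 0]), 200)

  # reproducibility under a fixed seed
  expect_identical(run_cellline(30, s = 1, n_target = 1e4, seed = 9)$q,
                   run_cellline(30, s = 1, n_target = 1e4, seed = 9)$q)
})

test_that("drug adaptation depresses copy number and withdrawal restores it", {
  shift_stats <- function(s_drug, s_off, r) {
    init <- run_cellline(20, s = 1, n_target = 3000, seed = 600 + r)
    ser <- run_drug_shift(init, s_drug = s_drug, t_drug = 4, s_off = s_off,
                          t_off = 7, n_init = 3000, record_dt = 1,
                          seed = 700 + r)
    c(start = ser$m1[1], trough = ser$m1[ser$t == 4],
      end = tail(ser$m1, 1))
  }
  runs <- vapply(1:30, function(r) shift_stats(0.5, 2, r), numeric(3))
  expect_lt(mean(runs["trough", ]), mean(runs["start", ]))
  expect_gt(mean(runs["end", ]), mean(runs["trough", ]))

  # neutral control: no systematic shift
  ctrl <- vapply(1:30, function(r) shift_stats(1, 1, 1000 + r), numeric(3))
  drift <- ctrl["end", ] - ctrl["start", ]
  expect_lt(abs(mean(drift)), 3 * sd(drift) / sqrt(ncol(ctrl)))

  # deeper suppression under stronger drug effect
  strong <- vapply(1:30, function(r) shift_stats(0.25, 2, 2000 + r),
                   numeric(3))
  weak <- vapply(1:30, function(r) shift_stats(0.75, 2, 2000 + r),
                 numeric(3))
  expect_lt(mean(strong["trough", ]), mean(weak["trough", ]))
})
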