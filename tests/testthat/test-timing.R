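small <- c("20", "21", "22")

test_that("multiplicity inversion is exact arithmetic", {
  snv <- data.frame(sample_id = "S", vaf = c(0.5, 0.25),
                    depth = c(100, 100), n_major = c(2, 1),
                    n_total = c(4, 2))
  # rho = 1, 2+2, f = 0.5 -> m_raw 2;  rho = 0.5, 1+1, f = 0.25 -> 1
  est1 <- estimate_multiplicity(snv[1, ], purity = 1)
  expect_equal(est1$m_raw, 2)
  expect_equal(est1$m, 2)
  est2 <- estimate_multiplicity(snv[2, ], purity = 0.5)
  expect_equal(est2$m_raw, 1)
  expect_equal(est2$m, 1)
  expect_error(estimate_multiplicity(snv, purity = 1.2), "purity")
})

test_that("integer multiplicities are mostly recovered at depth 100", {
  sim <- simulate_tumour(sim_config(purity = 0.8, depth = 100, mu = 2,
                                    gd_time = 0.5, chroms = small),
                         seed = 12)
  ann <- estimate_multiplicity(
    assign_snvs_to_segments(sim$snvs, sim$segments), purity = 0.8)
  acc <- mean(ann$m == sim$truth$snv$multiplicity)
  expect_gte(acc, 0.9)
})

test_that("per-segment timing formulas and edge cases", {
  expect_equal(time_segment(n1 = 0, n2 = 10), 1)
  expect_equal(time_segment(n1 = 20, n2 = 0), 0)
  expect_equal(time_segment(n1 = 60, n2 = 30), 0.5)
  expect_equal(time_segment(n1 = 60, n2 = 30, state = "2+0"), 0.5)
  # single-copy gain: 3 n2 / (2 n2 + n1), clamped at 1
  expect_equal(time_segment(n1 = 30, n2 = 30, state = "2+1"), 1)
  expect_equal(time_segment(n1 = 90, n2 = 10, state = "2+1"),
               30 / 110)
  expect_true(is.na(time_segment(n1 = 4, n2 = 3)))  # below minimum
  expect_error(time_segment(1, 1, state = "3+1"), "state")
})

test_that("timing matches the brute-force event-list oracle", {
  for (t in c(0.3, 0.7)) {
    orc <- oracle_gd_counts(rate = 4000, t = t, state = "2+2",
                            seed = round(100 * t))
    pi_hat <- time_segment(orc$n1, orc$n2)
    expect_lt(abs(pi_hat - t), 0.02)
    orc0 <- oracle_gd_counts(rate = 8000, t = t, state = "2+0",
                             seed = round(100 * t) + 1)
    expect_lt(abs(time_segment(orc0$n1, orc0$n2, "2+0") - t), 0.02)
  }
})

test_that("pi is monotone in n2 for fixed n1", {
  pis <- time_segment(n1 = 50, n2 = 0:50)
  expect_true(all(diff(pis) >= 0))
})

test_that("purity inversion is exact in noise-free mode", {
  base <- list(depth = 200, mu = 2, gd_time = 0.4, chroms = small,
               noise_free = TRUE)
  sim1 <- simulate_tumour(do.call(sim_config, c(base, purity = 1)),
                          seed = 5)
  sim2 <- simulate_tumour(do.call(sim_config, c(base, purity = 0.6)),
                          seed = 5)
  est1 <- time_genome_doubling(sim1$snvs, sim1$segments, 1, seed = 1)
  est2 <- time_genome_doubling(sim2$snvs, sim2$segments, 0.6, seed = 1)
  expect_identical(est1$pi_gd, est2$pi_gd)
})

test_that("aggregate equals the single-segment estimate when only one segment", {
  sim <- simulate_tumour(sim_config(purity = 1, depth = 100, mu = 2,
                                    gd_time = 0.3, chroms = "22",
                                    noise_free = TRUE), seed = 6)
  est <- time_genome_doubling(sim$snvs, sim$segments, 1, seed = 1)
  expect_true(est$timeable)
  expect_equal(est$n_segments, 1L)
  expect_identical(est$pi_gd,
                   time_segment(est$per_segment$n1, est$per_segment$n2))
  expect_lte(est$ci_lower, est$pi_gd)
  expect_gte(est$ci_upper, est$pi_gd)
})

test_that("bootstrap intervals shrink with SNV count", {
  cfg_lo <- sim_config(purity = 1, depth = 100, mu = 0.07,
                       gd_time = 0.5, chroms = c("1", "2"))
  cfg_hi <- sim_config(purity = 1, depth = 100, mu = 0.7,
                       gd_time = 0.5, chroms = c("1", "2"))
  e_lo <- with(simulate_tumour(cfg_lo, seed = 8),
               time_genome_doubling(snvs, segments, 1, seed = 1))
  e_hi <- with(simulate_tumour(cfg_hi, seed = 8),
               time_genome_doubling(snvs, segments, 1, seed = 1))
  expect_true(e_lo$timeable && e_hi$timeable)
  expect_gt(e_hi$n_snvs, 5 * e_lo$n_snvs)
  expect_lt(e_hi$ci_upper - e_hi$ci_lower,
            e_lo$ci_upper - e_lo$ci_lower)
})

test_that("samples without timing-informative segments are untimeable", {
  sim <- simulate_tumour(sim_config(mu = 1, chroms = "22"), seed = 9)
  est <- time_genome_doubling(sim$snvs, sim$segments, 0.8, seed = 1)
  expect_false(est$timeable)
  expect_true(is.na(est$pi_gd))
  # and so is a sample with no SNVs at all
  est0 <- time_genome_doubling(sim$snvs[0, ], sim$segments, 0.8)
  expect_false(est0$timeable)
})

test_that("time_cohort returns one row per GD sample", {
  groups <- list(
    list(label = "GD", n = 2,
         config = sim_config(purity = 1, depth = 80, mu = 1,
                             gd_time = 0.5, chroms = small)),
    list(label = "DIP", n = 1,
         config = sim_config(purity = 1, mu = 1, chroms = small)))
  co <- simulate_cohort(groups, seed = 14)
  gd_calls <- data.frame(sample_id = co$truth$sample$sample_id,
                         gd = co$truth$sample$gd)
  purity <- setNames(co$meta$purity, co$meta$sample_id)
  tc <- time_cohort(co$snvs, co$segments, purity, gd_calls, seed = 1)
  expect_equal(nrow(tc), 2L)
  expect_true(all(tc$timeable))
  expect_true(all(abs(tc$pi_gd - 0.5) < 0.15))
})
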