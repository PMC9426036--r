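small <- c("20", "21", "22")

test_that("null model: diploid, purity 1, all multiplicities 1", {
  sim <- simulate_tumour(sim_config(purity = 1, mu = 1, chroms = small),
                         seed = 1)
  expect_true(all(sim$segments$n_major == 1 & sim$segments$n_minor == 1))
  expect_true(all(sim$truth$snv$multiplicity == 1))
  expect_equal(sim$truth$sample$ploidy, 2)
  expect_false(sim$truth$sample$gd)
})

test_that("multiplicity-2 fraction at gd_time 0.5 matches the model and oracle", {
  # closed form: 2 pi / (2 pi + 4 (1 - pi)) = 1/3 at pi = 0.5
  sim <- simulate_tumour(sim_config(purity = 1, mu = 10, gd_time = 0.5,
                                    chroms = small), seed = 2)
  frac <- mean(sim$truth$snv$multiplicity == 2)
  n <- nrow(sim$truth$snv)
  expect_lt(abs(frac - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / n))
  # brute-force event-list oracle at matched expected event count
  orc <- oracle_gd_counts(rate = n / 3, t = 0.5, state = "2+2", seed = 3)
  frac_orc <- orc$n2 / (orc$n1 + orc$n2)
  expect_lt(abs(frac - frac_orc), 4 * sqrt(1 / 3 * 2 / 3 / n))
})

test_that("haploidisation forces >= hp_fraction LOH as 2+0 after GD", {
  sim <- simulate_tumour(sim_config(mu = 0.1, gd_time = 0.5,
                                    hp_fraction = 0.6), seed = 4)
  expect_gte(sim$truth$sample$loh_fraction, 0.6)
  loh <- sim$segments[sim$segments$n_minor == 0, ]
  expect_true(all(loh$n_major == 2))
  expect_lt(sim$truth$sample$ploidy, 4)
  expect_true(sim$truth$sample$hp && sim$truth$sample$gd)
})

test_that("segment lengths always sum to the simulated genome size", {
  for (cfg in list(sim_config(chroms = small, mu = 0.1),
                   sim_config(mu = 0.01, gd_time = 0.3,
                              hp_fraction = 0.5),
                   sim_config(chroms = small, mu = 0.1, gd_time = 0.7,
                              arm_loss_prob = 0.5,
                              arm_gain_prob = 0.5))) {
    sim <- simulate_tumour(cfg, seed = 9)
    expect_equal(sum(sim$segments$length),
                 sum(grch38_chrom_lengths()[cfg$chroms]))
  }
})

test_that("noise-free purity-1 VAFs invert exactly to multiplicity", {
  sim <- simulate_tumour(sim_config(purity = 1, depth = 100, mu = 2,
                                    gd_time = 0.4, chroms = small,
                                    noise_free = TRUE), seed = 5)
  ann <- assign_snvs_to_segments(sim$snvs, sim$segments)
  expect_equal(ann$vaf * ann$n_total, as.numeric(sim$truth$snv$multiplicity))
})

test_that("expected SNV count matches mu x length x copy-time integral", {
  # diploid chr22: E[n] = mu * L_Mb * 2 copies * 1 time unit
  mu <- 1
  L <- grch38_chrom_lengths()[["22"]] / 1e6
  counts <- vapply(1:200, function(s)
    nrow(simulate_tumour(sim_config(mu = mu, chroms = "22"),
                         seed = s)$snvs), numeric(1))
  expected <- mu * L * 2
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("identical config and seed reproduce outputs exactly", {
  cfg <- sim_config(mu = 1, gd_time = 0.5, hp_fraction = 0.3,
                    chroms = c("1", "2", "21", "22"))
  expect_identical(simulate_tumour(cfg, seed = 77),
                   simulate_tumour(cfg, seed = 77))
})

test_that("cohort files are byte-identical across runs with one seed", {
  g <- list(list(label = "A", n = 2,
                 config = sim_config(mu = 0.5, chroms = small)),
            list(label = "B", n = 2,
                 config = sim_config(mu = 0.5, gd_time = 0.5,
                                     chroms = small)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(g, seed = 3, outdir = d1)
  simulate_cohort(g, seed = 3, outdir = d2)
  for (f in c("segments.tsv", "snvs.vcf", "meta.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("configuration errors are caught", {
  expect_error(sim_config(hp_fraction = 1), "hp_fraction")
  expect_error(sim_config(hp_fraction = 0.5), "requires gd_time")
  expect_error(sim_config(gd_time = 1.2), "gd_time")
  expect_error(sim_config(purity = 0), "purity")
  g <- list(list(label = "A", n = 0, config = sim_config(chroms = "22")),
            list(label = "B", n = 1, config = sim_config(chroms = "22")))
  expect_warning(co <- simulate_cohort(g, seed = 1), "n = 0")
  expect_equal(nrow(co$meta), 1L)
  gdup <- list(list(label = "A", n = 1, config = sim_config(chroms = "22")),
               list(label = "A", n = 1, config = sim_config(chroms = "22")))
  expect_error(simulate_cohort(gdup, seed = 1), "duplicate")
})
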