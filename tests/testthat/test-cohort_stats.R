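# independent closed-form oracle for the 2x2 exact test
hyper_2x2_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  k <- max(0, c1 - r2):min(r1, c1)
  d <- dhyper(k, r1, r2, c1)
  sum(d[d <= dhyper(tab[1, 1], r1, r2, c1) * (1 + 1e-7)])
}

test_that("fisher_exact handles canonical 2x2 cases", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  tab <- matrix(c(10, 0, 0, 10), 2)
  fe <- fisher_exact(tab)
  expect_equal(fe$p_value, hyper_2x2_p(tab), tolerance = 1e-12)
  expect_equal(fe$method, "exact_enumeration")
  expect_true(is.infinite(fe$odds_ratio))
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integer")
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "integer|negative")
})

test_that("fisher_exact agrees with stats::fisher.test on random tables", {
  set.seed(17)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-8)
  }
  for (i in 1:8) {
    tab <- matrix(rpois(6, 5), nrow = 3)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-8)
  }
})

test_that("fisher_exact is symmetric under transposition", {
  set.seed(23)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 8), 2)
    expect_equal(fisher_exact(tab)$p_value,
                 fisher_exact(t(tab))$p_value, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo p converges to the enumeration p", {
  tab <- matrix(c(12, 3, 5, 9, 2, 8), nrow = 3)
  en <- fisher_exact(tab)
  mc <- fisher_exact(tab, max_enum_total = 0, n_mc = 2e4, seed = 3)
  expect_equal(mc$method, "monte_carlo")
  expect_lt(abs(mc$p_value - en$p_value), 3 * mc$mc_se + 1e-3)
})

test_that("wilcoxon rank-sum: exact enumeration and basic properties", {
  # identical samples sit at the null centre
  w0 <- wilcoxon_rank_sum(c(1, 2, 3), c(1.5, 2.5, 3.5))
  expect_gt(w0$p_value, 0.6)
  # complete separation of 3 vs 3: p = 2 / choose(6, 3)
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(w$method, "exact_enumeration")
  expect_equal(w$p_value, 2 / choose(6, 3))
  expect_equal(w$p_value,
               stats::wilcox.test(c(1, 2, 3), c(10, 11, 12))$p.value)
  # shift invariance (rank statistic)
  x <- c(0.3, 2.2, 5.1, 0.9); y <- c(1.4, 3.3, 7.2)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               wilcoxon_rank_sum(x + 100, y + 100)$p_value)
  expect_error(wilcoxon_rank_sum(numeric(0), y), "non-empty")
})

test_that("wilcoxon agrees with stats::wilcox.test in both regimes", {
  set.seed(41)
  # exact regime, no ties
  for (i in 1:10) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), 0.5)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 stats::wilcox.test(x, y)$p.value, tolerance = 1e-12)
  }
  # normal approximation with ties
  x <- c(rep(1, 6), rep(2, 8), rnorm(10))
  y <- c(rep(1, 4), rep(3, 9), rnorm(10, 0.7))
  w <- wilcoxon_rank_sum(x, y)
  expect_equal(w$method, "normal_approximation")
  expect_equal(w$p_value,
               suppressWarnings(stats::wilcox.test(x, y)$p.value),
               tolerance = 1e-12)
})

arm_len <- function(arm) {
  a <- grch38_arms()
  a$length[a$arm == arm]
}

test_that("arm events follow the 50%-of-arm baseline rule", {
  arms <- grch38_arms()
  # diploid genome with all of 15q at 1+0
  seg <- flat_genome("S", 1, 1)
  q15 <- arms[arms$arm == "15q", ]
  seg <- seg[seg$chrom != "15", ]
  seg <- rbind(seg,
               make_segments("S", "15", 1, q15$start - 1, 1, 1),
               make_segments("S", "15", q15$start, q15$end, 1, 0))
  ev <- call_arm_events(seg, gd = c(S = FALSE))
  expect_equal(ev$call[ev$arm == "15q"], "loss")
  expect_equal(ev$fraction[ev$arm == "15q"], 1)
  expect_true(all(ev$call[ev$arm != "15q"] == "neutral"))

  # genome-doubled sample (baseline 4): whole 19p at 5 copies -> gain
  seggd <- flat_genome("G", 2, 2)
  p19 <- arms[arms$arm == "19p", ]
  seggd <- seggd[seggd$chrom != "19", ]
  seggd <- rbind(seggd,
                 make_segments("G", "19", p19$start, p19$end, 3, 2),
                 make_segments("G", "19", p19$end + 1,
                               grch38_chrom_lengths()[["19"]], 2, 2))
  evgd <- call_arm_events(seggd, gd = c(G = TRUE))
  expect_equal(evgd$call[evgd$arm == "19p"], "gain")
  expect_true(all(evgd$call[evgd$arm != "19p"] == "neutral"))

  # only 40% of the arm deviating stays neutral
  cut40 <- q15$start + round(0.4 * q15$length) - 1
  seg40 <- rbind(flat_genome("S", 1, 1)[flat_genome("S", 1, 1)$chrom != "15", ],
                 make_segments("S", "15", 1, q15$start - 1, 1, 1),
                 make_segments("S", "15", q15$start, cut40, 1, 0),
                 make_segments("S", "15", cut40 + 1, q15$end, 1, 1))
  ev40 <- call_arm_events(seg40, gd = c(S = FALSE))
  expect_equal(ev40$call[ev40$arm == "15q"], "neutral")
})

test_that("arm frequency comparison applies Bonferroni correctly", {
  set.seed(3)
  arms <- paste0(rep(1:5, each = 2), c("p", "q"))
  ev <- expand.grid(sample_id = sprintf("S%02d", 1:20), arm = arms,
                    stringsAsFactors = FALSE)
  ev$call <- "neutral"
  groups <- setNames(rep(c("A", "B"), each = 10), sprintf("S%02d", 1:20))
  # plant a strong loss enrichment on 3q in group A
  ev$call[ev$arm == "3q" & grepl("S0|S10", ev$sample_id)] <- "loss"
  res <- arm_frequency_comparison(ev, groups)
  expect_equal(nrow(res), length(arms) * 2)
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  expect_true(all(res$p_adj <= 1))
  expect_equal(res$p_adj, pmin(res$p_raw * nrow(res), 1))
  hit <- res[res$arm == "3q" & res$event == "loss", ]
  expect_lt(hit$p_adj, 0.05)
  expect_error(arm_frequency_comparison(ev, setNames(rep("A", 20),
                                                     names(groups))),
               "two groups")
})

test_that("high-breakage counting merges, thresholds, ignores order", {
  # one segment per chromosome: no breakpoints anywhere
  expect_equal(count_high_breakage(
    flat_genome("S", 1, 1))$high_breakage_count, 0)
  # chromosome 1 split into 15 alternating-state segments
  bounds <- round(seq(1, 2e6, length.out = 16))
  seg1 <- make_segments("S", "1", head(bounds, -1),
                        c(bounds[2:15] - 1, bounds[16]),
                        rep(c(1, 2), length.out = 15),
                        rep(1, 15))
  seg <- rbind(seg1, flat_genome("S", 1, 1)[-1, ])
  hb <- count_high_breakage(seg, k = 10)
  expect_equal(hb$high_breakage_count, 1)
  expect_equal(unname(hb$per_chrom[["1"]]), 14L)
  # k = 1 counts any multi-segment chromosome
  expect_equal(count_high_breakage(seg, k = 1)$high_breakage_count, 1)
  # segment order does not matter
  shuffled <- seg[sample(nrow(seg)), ]
  expect_equal(count_high_breakage(shuffled, k = 10)$high_breakage_count,
               1)
  # splitting a segment into identical-state halves changes nothing
  sp <- rbind(seg[-1, ],
              transform(seg[1, ], end = floor((start + end) / 2)),
              transform(seg[1, ], start = floor((start + end) / 2) + 1))
  expect_equal(count_high_breakage(sp, k = 10)$per_chrom,
               hb$per_chrom)
})

test_that("cohort high-breakage summary returns one row per sample", {
  seg <- rbind(flat_genome("A", 1, 1), flat_genome("B", 2, 2))
  hs <- high_breakage_summary(seg)
  expect_equal(hs$sample_id, c("A", "B"))
  expect_equal(hs$high_breakage_count, c(0L, 0L))
})
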