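#' @title Cohort-level statistics
#'
#' @description
#' Exact contingency tests (Fisher) implemented by enumeration over
#' margin-fixed tables with a seeded Monte-Carlo fallback, rank-sum
#' tests with exact small-sample enumeration, arm-level gain/loss
#' calling and frequency comparison with Bonferroni correction, and
#' the chromosome high-breakage (fragmentation) statistic.
#' @name cohort_stats
NULL

# log hypergeometric/multinomial probability of a margin-fixed table
.log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# depth-first enumeration of all r x c tables with the given margins,
# accumulating total probability of tables no more probable than
# log_cut; bails out (returns NULL) after max_tables leaves
.enum_tables <- function(rs, cs, log_cut, max_tables = 2e6) {
  r <- length(rs); cc <- length(cs)
  n <- sum(rs)
  lg_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  acc <- 0
  count <- 0L
  cells <- matrix(0, r, cc)
  rec <- function(i, j, row_left, col_left) {
    if (count > max_tables) return(FALSE)
    if (i == r && j == cc) {
      v <- min(row_left[i], col_left[j])
      if (row_left[i] != col_left[j]) return(TRUE)
      cells[i, j] <<- v
      count <<- count + 1L
      lp <- lg_const - sum(lgamma(cells + 1))
      if (lp <= log_cut) acc <<- acc + exp(lp)
      return(TRUE)
    }
    ni <- if (j == cc) i + 1L else i
    nj <- if (j == cc) 1L else j + 1L
    if (j == cc) {
      # last cell of a row is forced
      v <- row_left[i]
      if (v > col_left[j]) return(TRUE)
      cells[i, j] <<- v
      cl <- col_left; cl[j] <- cl[j] - v
      rl <- row_left; rl[i] <- 0
      return(rec(ni, nj, rl, cl))
    }
    if (i == r) {
      # last row: cells forced by column remainders
      v <- col_left[j]
      if (v > row_left[i]) return(TRUE)
      cells[i, j] <<- v
      rl <- row_left; rl[i] <- rl[i] - v
      cl <- col_left; cl[j] <- 0
      return(rec(ni, nj, rl, cl))
    }
    for (v in 0:min(row_left[i], col_left[j])) {
      cells[i, j] <<- v
      rl <- row_left; rl[i] <- rl[i] - v
      cl <- col_left; cl[j] <- cl[j] - v
      if (!rec(ni, nj, rl, cl)) return(FALSE)
    }
    TRUE
  }
  ok <- rec(1L, 1L, rs, cs)
  if (!ok) NULL else acc
}

#' Fisher exact test by enumeration
#'
#' Two-sided exact test of independence for an r x c table of counts.
#' The p-value is the total null probability of all margin-fixed
#' tables whose probability does not exceed that of the observed table
#' (with the customary relative tolerance of 1e-7 on the comparison).
#' Tables with a grand total up to `max_enum_total` are solved by full
#' enumeration (2x2 reduces to the hypergeometric distribution);
#' larger tables fall back to seeded Monte-Carlo sampling of
#' margin-fixed tables (Patefield's algorithm via [stats::r2dtable()]),
#' with the method recorded in the result.
#'
#' @param tab Matrix of non-negative integer counts, at least 2x2.
#' @param max_enum_total Largest grand total attempted by enumeration;
#'   default 200.
#' @param n_mc Monte-Carlo draws; default 1e5.
#' @param seed Monte-Carlo seed.
#' @return List of class `contingency_result`: `table`, `p_value`,
#'   `odds_ratio` (sample cross-product ratio, 2x2 only), `method`
#'   (`"exact_enumeration"` or `"monte_carlo"`), `mc_se`, `n_mc`,
#'   `seed`.
#' @export
#' @examples
#' fisher_exact(matrix(c(10, 0, 0, 10), 2))$p_value
fisher_exact <- function(tab, max_enum_total = 200, n_mc = 1e5,
                         seed = 1) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)) || anyNA(tab))
    stop("counts must be non-negative integers", call. = FALSE)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("table must be at least 2x2", call. = FALSE)
  storage.mode(tab) <- "double"
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  or <- if (all(dim(tab) == 2L))
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]) else NA_real_
  if (n == 0)
    return(structure(list(table = tab, p_value = 1, odds_ratio = or,
                          method = "exact_enumeration", mc_se = NA_real_,
                          n_mc = NA_integer_, seed = NA_integer_),
                     class = "contingency_result"))
  lp_obs <- .log_table_prob(tab)
  log_cut <- lp_obs + log1p(1e-7)
  p <- if (n <= max_enum_total) .enum_tables(rs, cs, log_cut) else NULL
  if (!is.null(p)) {
    return(structure(list(table = tab, p_value = min(p, 1),
                          odds_ratio = or,
                          method = "exact_enumeration",
                          mc_se = NA_real_, n_mc = NA_integer_,
                          seed = NA_integer_),
                     class = "contingency_result"))
  }
  set.seed(as.integer(seed))
  draws <- stats::r2dtable(n_mc, rs, cs)
  lp <- vapply(draws, .log_table_prob, numeric(1L))
  hits <- sum(lp <= log_cut)
  p_mc <- (hits + 1) / (n_mc + 1)
  structure(list(table = tab, p_value = p_mc, odds_ratio = or,
                 method = "monte_carlo",
                 mc_se = sqrt(p_mc * (1 - p_mc) / n_mc),
                 n_mc = as.integer(n_mc), seed = as.integer(seed)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Fisher exact test (%s): p = %.4g", x$method, x$p_value))
  if (!is.na(x$odds_ratio)) cat(sprintf(", OR = %.3g", x$odds_ratio))
  cat("\n")
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test.  For combined sample sizes up to
#' `exact_max` with no ties, the null distribution of the Mann-Whitney
#' U statistic is obtained by full enumeration of all rank
#' assignments; otherwise a normal approximation with tie correction
#' and continuity correction is used, and the method is recorded.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param exact_max Largest combined n for exact enumeration;
#'   default 20.
#' @return List: `statistic` (U for `x`), `p_value`, `method`
#'   (`"exact_enumeration"` or `"normal_approximation"`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 20) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n <= exact_max && !ties) {
    combos <- utils::combn(n, nx)
    u_all <- colSums(matrix(seq_len(n)[combos], nrow = nx)) -
      nx * (nx + 1) / 2
    p <- 2 * min(mean(u_all <= u), mean(u_all >= u))
    return(list(statistic = u, p_value = min(p, 1),
                method = "exact_enumeration"))
  }
  mu <- nx * ny / 2
  tie_tab <- table(c(x, y))
  sigma2 <- nx * ny / 12 *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
  list(statistic = u, p_value = min(max(p, 0), 1),
       method = "normal_approximation")
}

#' Merge adjacent segments with identical copy state
#'
#' Consecutive segments of a sample on the same chromosome with equal
#' `(n_major, n_minor)` are merged into one, regardless of any
#' unsegmented gap between them.  This removes segmentation-dialect
#' differences before breakpoints are counted.
#'
#' @param segments Validated segment `data.frame`.
#' @return Merged segment `data.frame`.
#' @export
merge_adjacent_segments <- function(segments) {
  segments <- validate_segments(segments)
  key <- paste(segments$sample_id, segments$chrom)
  new_run <- c(TRUE, key[-1L] != key[-nrow(segments)] |
                 segments$n_major[-1L] != segments$n_major[-nrow(segments)] |
                 segments$n_minor[-1L] != segments$n_minor[-nrow(segments)])
  run <- cumsum(new_run)
  out <- segments[new_run, , drop = FALSE]
  out$end <- tapply(segments$end, run, max)
  out$length <- out$end - out$start + 1
  rownames(out) <- NULL
  out
}

#' Chromosome high-breakage statistic
#'
#' Counts, per chromosome of one sample, the number of copy-number
#' breakpoints (segments minus one, after [merge_adjacent_segments()])
#' and reports how many chromosomes have at least `k` breakpoints — a
#' simple chromosomal-instability proxy for fragmentation.
#'
#' @param segments Segment `data.frame` of one sample.
#' @param k Breakpoint threshold for calling a chromosome
#'   "high breakage"; default 10.
#' @return List: `sample_id`, `per_chrom` (named breakpoint counts),
#'   `high_breakage_count`, `k`.
#' @export
count_high_breakage <- function(segments, k = 10) {
  .check_one_sample(segments)
  merged <- merge_adjacent_segments(segments)
  bp <- table(merged$chrom) - 1L
  per_chrom <- stats::setNames(as.integer(bp), names(bp))
  list(sample_id = segments$sample_id[1L], per_chrom = per_chrom,
       high_breakage_count = sum(per_chrom >= k), k = k)
}

#' High-breakage counts for a cohort
#'
#' @param segments Multi-sample segment `data.frame`.
#' @param k Breakpoint threshold; default 10.
#' @return `data.frame` with `sample_id` and `high_breakage_count`.
#' @export
high_breakage_summary <- function(segments, k = 10) {
  by_sample <- split(segments, segments$sample_id)
  out <- data.frame(
    sample_id = names(by_sample),
    high_breakage_count = vapply(by_sample, function(s)
      count_high_breakage(s, k = k)$high_breakage_count, integer(1L)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call arm-level gain/loss events
#'
#' An arm is called gained (lost) in a sample if at least
#' `min_fraction` of its segmented length carries total copy number
#' above (below) the sample's rounded ploidy baseline: 2 for diploid
#' samples, 4 for genome-doubled ones.  Otherwise the arm is neutral.
#' Arms with no segment coverage are neutral with fraction `NA`.
#'
#' @param segments Multi-sample segment `data.frame`.
#' @param gd Named logical vector of GD calls indexed by `sample_id`.
#' @param arms Arm boundary table; default [grch38_arms()].
#' @param min_fraction Minimum deviating length fraction; default 0.5.
#' @return `data.frame`: `sample_id`, `arm`, `call` (`"gain"`,
#'   `"loss"`, `"neutral"`), `fraction` (supporting length fraction).
#' @export
call_arm_events <- function(segments, gd, arms = grch38_arms(),
                            min_fraction = 0.5) {
  segments <- validate_segments(segments)
  missing_chr <- setdiff(unique(segments$chrom), arms$chrom)
  if (length(missing_chr))
    stop("chromosome(s) missing from arm table: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  samples <- unique(segments$sample_id)
  if (!all(samples %in% names(gd)))
    stop("gd must be a named logical vector covering every sample",
         call. = FALSE)
  res <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    seg <- segments[segments$sample_id == samples[s], , drop = FALSE]
    base <- if (gd[[samples[s]]]) 4 else 2
    total <- seg$n_major + seg$n_minor
    rows <- lapply(seq_len(nrow(arms)), function(i) {
      a <- arms[i, ]
      ov_start <- pmax(seg$start, a$start)
      ov_end <- pmin(seg$end, a$end)
      w <- pmax(ov_end - ov_start + 1, 0) * (seg$chrom == a$chrom)
      covered <- sum(w)
      if (covered == 0)
        return(data.frame(sample_id = samples[s], arm = a$arm,
                          call = "neutral", fraction = NA_real_,
                          stringsAsFactors = FALSE))
      f_gain <- sum(w[total > base]) / covered
      f_loss <- sum(w[total < base]) / covered
      call <- if (f_gain >= min_fraction && f_gain >= f_loss) "gain"
        else if (f_loss >= min_fraction) "loss" else "neutral"
      frac <- switch(call, gain = f_gain, loss = f_loss,
                     neutral = max(f_gain, f_loss))
      data.frame(sample_id = samples[s], arm = a$arm, call = call,
                 fraction = frac, stringsAsFactors = FALSE)
    })
    res[[s]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Arm-level gain/loss frequency comparison across groups
#'
#' For every arm and event type, tests event presence against group
#' membership with [fisher_exact()] and applies the Bonferroni
#' correction with the number of tests actually performed as the
#' factor.
#'
#' @param arm_events Output of [call_arm_events()].
#' @param groups Named character vector of group labels indexed by
#'   `sample_id`; at least two distinct groups.
#' @param event_types Event types to test; default gain and loss.
#' @param ... Passed to [fisher_exact()].
#' @return `data.frame`: `arm`, `event`, `p_raw`, `p_adj` (capped at
#'   1), `n_event` (per group, comma-separated), `method`.
#' @export
arm_frequency_comparison <- function(arm_events, groups,
                                     event_types = c("gain", "loss"),
                                     ...) {
  if (length(unique(groups)) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (!all(arm_events$sample_id %in% names(groups)))
    stop("groups must cover every sample in arm_events", call. = FALSE)
  arm_events$group <- groups[arm_events$sample_id]
  arms <- unique(arm_events$arm)
  grid <- expand.grid(arm = arms, event = event_types,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- arm_events[arm_events$arm == grid$arm[i], , drop = FALSE]
    has <- sub$call == grid$event[i]
    tab <- table(factor(has, levels = c(TRUE, FALSE)), sub$group)
    fe <- fisher_exact(unclass(tab), ...)
    data.frame(arm = grid$arm[i], event = grid$event[i],
               p_raw = fe$p_value,
               n_event = paste(tab[1L, ], collapse = ","),
               method = fe$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(out$p_raw * nrow(out), 1)
  out[, c("arm", "event", "p_raw", "p_adj", "n_event", "method")]
}
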