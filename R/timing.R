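#' Assign SNVs to copy-number segments
#'
#' Annotates each SNV row with the allele-specific copy numbers of the
#' segment containing it (matched on `sample_id`, `chrom` and
#' position).  SNVs falling outside every segment are dropped and their
#' count reported with a message.
#'
#' @param snvs SNV `data.frame` (see [io_formats]).
#' @param segments Validated segment `data.frame`.
#' @return `snvs` with added columns `n_major`, `n_minor`, `n_total`.
#' @export
assign_snvs_to_segments <- function(snvs, segments) {
  segments <- validate_segments(segments)
  snvs$n_major <- NA_real_
  snvs$n_minor <- NA_real_
  snvs$seg_index <- NA_integer_
  key_snv <- paste(snvs$sample_id, snvs$chrom)
  key_seg <- paste(segments$sample_id, segments$chrom)
  for (k in unique(key_snv)) {
    seg_rows <- which(key_seg == k)
    seg <- segments[seg_rows, , drop = FALSE]
    idx <- which(key_snv == k)
    if (nrow(seg) == 0L) next
    j <- findInterval(snvs$pos[idx], seg$start)
    ok <- j >= 1L & snvs$pos[idx] <= seg$end[pmax(j, 1L)]
    snvs$n_major[idx[ok]] <- seg$n_major[j[ok]]
    snvs$n_minor[idx[ok]] <- seg$n_minor[j[ok]]
    snvs$seg_index[idx[ok]] <- seg_rows[j[ok]]
  }
  dropped <- is.na(snvs$n_major)
  if (any(dropped))
    message("assign_snvs_to_segments: ", sum(dropped),
            " SNV(s) outside all segments, excluded")
  out <- snvs[!dropped, , drop = FALSE]
  out$n_total <- out$n_major + out$n_minor
  rownames(out) <- NULL
  out
}

#' Estimate SNV multiplicities
#'
#' Inverts the purity-diluted VAF model: an SNV present on `m` of the
#' `n_t` tumour copies at purity `rho` has expected VAF
#' `f = m * rho / (rho * n_t + 2 * (1 - rho))`, so
#' `m_raw = f * (rho * n_t + 2 * (1 - rho)) / rho`.  The integer
#' multiplicity is `m_raw` rounded and clamped to `[1, n_major]`
#' (a somatic SNV sits on one parental haplotype, so it can occupy at
#' most the major-allele copy count).  Hard assignment by rounding is
#' adequate at depth >= 60; a binomial-likelihood soft assignment is a
#' possible extension, not implemented.
#'
#' @param snvs SNV `data.frame` already annotated by
#'   [assign_snvs_to_segments()] (columns `vaf`, `n_major`, `n_total`).
#' @param purity Scalar purity in (0, 1], or a named vector indexed by
#'   `sample_id`.
#' @return `snvs` with added columns `m_raw` and `m`.
#' @export
estimate_multiplicity <- function(snvs, purity) {
  rho <- if (length(purity) == 1L && is.null(names(purity)))
    rep(purity, nrow(snvs)) else as.numeric(purity[snvs$sample_id])
  if (anyNA(rho) || any(rho <= 0 | rho > 1))
    stop("purity must be in (0, 1] and cover every sample",
         call. = FALSE)
  if (any(snvs$depth <= 0)) stop("depth must be > 0", call. = FALSE)
  snvs$m_raw <- snvs$vaf * (rho * snvs$n_total + 2 * (1 - rho)) / rho
  snvs$m <- pmin(pmax(round(snvs$m_raw), 1), pmax(snvs$n_major, 1))
  snvs
}

#' Time one segment from multiplicity counts
#'
#' For a segment created by genome doubling, pre-doubling SNVs have
#' multiplicity 2 and post-doubling SNVs multiplicity 1.  With `n2`
#' multiplicity-2 and `n1` multiplicity-1 SNVs, the fraction of
#' mutational time before doubling is
#' `pi = 2 n2 / (2 n2 + n1)` for 2+2 and 2+0 segments (pre-GD accrual
#' on 2 resp. 1 copies, post-GD on 4 resp. 2: the copy ratio cancels),
#' and `pi = 3 n2 / (2 n2 + n1)` for 2+1 segments (single-copy gain),
#' clamped to \[0, 1\].
#'
#' @param n1,n2 Non-negative counts of multiplicity-1/-2 SNVs
#'   (vectorised).
#' @param state Segment state, `"2+2"`, `"2+0"` or `"2+1"` (recycled).
#' @param min_snvs Minimum `n1 + n2` for an informative estimate;
#'   below it `NA` is returned.  Default 10.
#' @return Numeric vector of `pi` estimates in \[0, 1\] (`NA` where
#'   uninformative).
#' @export
#' @examples
#' time_segment(n1 = 60, n2 = 30, state = "2+2")  # 0.5
time_segment <- function(n1, n2, state = "2+2", min_snvs = 10) {
  if (!all(state %in% c("2+2", "2+0", "2+1")))
    stop("state must be one of '2+2', '2+0', '2+1'", call. = FALSE)
  num <- ifelse(state == "2+1", 3 * n2, 2 * n2)
  pi <- pmin(pmax(num / (2 * n2 + n1), 0), 1)
  pi[n1 + n2 < min_snvs] <- NA_real_
  pi[n1 + n2 == 0] <- NA_real_
  pi
}

.seg_state <- function(n_major, n_minor) {
  out <- rep(NA_character_, length(n_major))
  out[n_major == 2 & n_minor == 2] <- "2+2"
  out[n_major == 2 & n_minor == 0] <- "2+0"
  out[n_major == 2 & n_minor == 1] <- "2+1"
  out
}

#' Time genome doubling for one sample
#'
#' Molecular-clock estimate of the relative mutational time of genome
#' doubling.  SNV multiplicities are estimated by
#' [estimate_multiplicity()], counted per timing-informative segment,
#' converted to per-segment `pi` by [time_segment()], and aggregated as
#' the SNV-count-weighted mean over 2+2 and 2+0 segments (both are
#' created simultaneously by the doubling; 2+1 gains need not be
#' synchronous with it and enter only with `include_2_1 = TRUE`).
#' A seeded bootstrap (resampling SNVs within segments) provides a
#' percentile 95% interval.
#'
#' @param snvs SNV `data.frame` of one sample.
#' @param segments Segment `data.frame` of the same sample.
#' @param purity Sample purity in (0, 1].
#' @param n_boot Bootstrap replicates; default 200.
#' @param seed Bootstrap seed.
#' @param min_snvs_segment Minimum SNVs for a segment to be
#'   informative; default 10.
#' @param min_snvs_sample Minimum informative SNVs for the sample to be
#'   timed at all; default 50.
#' @param include_2_1 Also aggregate over 2+1 segments; default FALSE.
#' @return List of class `timing_estimate`: `timeable` (logical),
#'   `pi_gd`, `ci_lower`, `ci_upper`, `n_segments`, `n_snvs`,
#'   `per_segment` (`data.frame` with `chrom`, `state`, `n1`, `n2`,
#'   `pi`).  When no informative segment exists the sample
#'   is explicitly untimeable (`timeable = FALSE`, `pi_gd = NA`).
#' @export
time_genome_doubling <- function(snvs, segments, purity, n_boot = 200,
                                 seed = 1, min_snvs_segment = 10,
                                 min_snvs_sample = 50,
                                 include_2_1 = FALSE) {
  untimeable <- structure(
    list(timeable = FALSE, pi_gd = NA_real_, ci_lower = NA_real_,
         ci_upper = NA_real_, n_segments = 0L, n_snvs = 0L,
         per_segment = NULL),
    class = "timing_estimate")
  if (nrow(snvs) == 0L) return(untimeable)
  ann <- assign_snvs_to_segments(snvs, segments)
  if (nrow(ann) == 0L) return(untimeable)
  ann <- estimate_multiplicity(ann, purity)
  ann$state <- .seg_state(ann$n_major, ann$n_minor)
  keep_states <- c("2+2", "2+0", if (include_2_1) "2+1")
  ann <- ann[!is.na(ann$state) & ann$state %in% keep_states, ,
             drop = FALSE]
  if (nrow(ann) == 0L) return(untimeable)

  by_seg <- split(ann, ann$seg_index)
  per_seg <- do.call(rbind, lapply(by_seg, function(s)
    data.frame(chrom = s$chrom[1L], state = s$state[1L],
               n1 = sum(s$m == 1), n2 = sum(s$m >= 2),
               stringsAsFactors = FALSE)))
  per_seg$pi <- time_segment(per_seg$n1, per_seg$n2, per_seg$state,
                             min_snvs = min_snvs_segment)
  inf_seg <- per_seg[!is.na(per_seg$pi), , drop = FALSE]
  n_inf <- sum(inf_seg$n1 + inf_seg$n2)
  if (nrow(inf_seg) == 0L || n_inf < min_snvs_sample)
    return(untimeable)

  agg <- function(tab) {
    w <- tab$n1 + tab$n2
    sum(tab$pi * w) / sum(w)
  }
  pi_gd <- agg(inf_seg)

  set.seed(as.integer(seed))
  inf_keys <- rownames(inf_seg)
  boot <- replicate(n_boot, {
    tab <- inf_seg
    for (i in seq_len(nrow(tab))) {
      s <- by_seg[[inf_keys[i]]]
      m <- sample(s$m, nrow(s), replace = TRUE)
      tab$n1[i] <- sum(m == 1)
      tab$n2[i] <- sum(m >= 2)
    }
    tab$pi <- time_segment(tab$n1, tab$n2, tab$state, min_snvs = 0)
    agg(tab[!is.na(tab$pi), , drop = FALSE])
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  structure(list(timeable = TRUE, pi_gd = pi_gd,
                 ci_lower = min(ci[1L], pi_gd),
                 ci_upper = max(ci[2L], pi_gd),
                 n_segments = nrow(inf_seg), n_snvs = n_inf,
                 per_segment = per_seg),
            class = "timing_estimate")
}

#' @export
print.timing_estimate <- function(x, ...) {
  if (!x$timeable) {
    cat("GD timing: untimeable (no informative segments/SNVs)\n")
  } else {
    cat(sprintf(
      "GD timing: pi = %.3f [%.3f, %.3f] (%d segments, %d SNVs)\n",
      x$pi_gd, x$ci_lower, x$ci_upper, x$n_segments, x$n_snvs))
  }
  invisible(x)
}

#' Time genome doubling across a cohort
#'
#' Applies [time_genome_doubling()] to every sample flagged GD and
#' returns one row per sample.
#'
#' @param snvs Multi-sample SNV `data.frame`.
#' @param segments Multi-sample segment `data.frame`.
#' @param purity Named vector of purities indexed by `sample_id`.
#' @param gd_calls `data.frame` with `sample_id` and logical `gd`.
#' @param ... Passed on to [time_genome_doubling()].
#' @return `data.frame` with `sample_id`, `timeable`, `pi_gd`,
#'   `ci_lower`, `ci_upper`, `n_segments`, `n_snvs`.
#' @export
time_cohort <- function(snvs, segments, purity, gd_calls, ...) {
  ids <- gd_calls$sample_id[gd_calls$gd]
  rows <- lapply(ids, function(id) {
    est <- time_genome_doubling(
      snvs[snvs$sample_id == id, , drop = FALSE],
      segments[segments$sample_id == id, , drop = FALSE],
      purity[[id]], ...)
    data.frame(sample_id = id, timeable = est$timeable,
               pi_gd = est$pi_gd, ci_lower = est$ci_lower,
               ci_upper = est$ci_upper, n_segments = est$n_segments,
               n_snvs = est$n_snvs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(), timeable = logical(),
                      pi_gd = numeric(), ci_lower = numeric(),
                      ci_upper = numeric(), n_segments = integer(),
                      n_snvs = integer(), stringsAsFactors = FALSE)
  out
}
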