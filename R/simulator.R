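#' Simulation configuration for one synthetic tumour
#'
#' Describes the generative model used by [simulate_tumour()]: a
#' diploid autosomal genome that optionally undergoes partial
#' haploidisation (HP, whole-chromosome loss of one allele) followed by
#' whole-genome doubling (GD) at a specified point in mutational time,
#' with clock-like SNV accrual on every allele copy, purity dilution of
#' VAFs and binomial read sampling.
#'
#' Mutational time is normalised to \[0, 1\] (the tumour's whole
#' mutational history); `gd_time` is the fraction of that time elapsed
#' before doubling, i.e. the quantity the timing module estimates.
#' HP is placed at `hp_time` (default 0, the earliest possible point;
#' the ordering HP before GD is enforced).  Mutations that arose on a
#' chromosome copy lost during HP are never observed and are not
#' generated.
#'
#' @param purity Tumour cell fraction rho in (0, 1]; default 0.8.
#' @param depth Mean sequencing depth (Poisson); default 60.
#' @param mu Per-copy mutation rate, SNVs per Mb per unit mutational
#'   time; default 0.3 (a few thousand SNVs in a diploid genome over
#'   its full history, typical of a quiet adult solid tumour).
#' @param gd_time GD time in \[0, 1\], or `NA` for no doubling.
#' @param hp_fraction Minimum fraction of the autosomal genome rendered
#'   1+0 by HP, in \[0, 1); 0 disables HP.  Whole chromosomes are
#'   converted in a seeded random order until the fraction is reached,
#'   so the realised LOH fraction is >= `hp_fraction`.
#' @param hp_time Mutational time of HP in \[0, `gd_time`\]; default 0.
#' @param arm_gain_prob,arm_loss_prob Per-arm probability of a late
#'   (post-mutation-accrual) one-copy arm gain/loss; scalar or named
#'   vector (names like `"15q"`).  Default 0.  These events modify copy
#'   states only — they are applied after SNV accrual and are meant for
#'   copy-number-only cohort simulations, so timing-informative
#'   segments stay clean.
#' @param chroms Autosomes to simulate (default `"1".."22"`); a subset
#'   gives small fast genomes for property tests.
#' @param noise_free If `TRUE`, read depth is fixed at `depth` and
#'   `alt_reads = round(depth * vaf)` (deterministic "infinite depth"
#'   mode for exact-inversion tests).
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(purity = 0.8, depth = 60, mu = 0.3,
                       gd_time = NA, hp_fraction = 0, hp_time = 0,
                       arm_gain_prob = 0, arm_loss_prob = 0,
                       chroms = as.character(1:22),
                       noise_free = FALSE) {
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  if (depth <= 0) stop("depth must be positive")
  if (mu < 0) stop("mu must be >= 0")
  if (hp_fraction < 0 || hp_fraction >= 1)
    stop("hp_fraction must be in [0, 1)")
  if (!is.na(gd_time) && (gd_time < 0 || gd_time > 1))
    stop("gd_time must be in [0, 1] or NA")
  if (hp_fraction > 0 && is.na(gd_time))
    stop("hp_fraction > 0 requires gd_time (HP occurs only with GD)")
  if (!is.na(gd_time) && hp_time > gd_time)
    stop("hp_time must not exceed gd_time")
  if (hp_time < 0 || hp_time > 1) stop("hp_time must be in [0, 1]")
  chroms <- normalise_chrom(chroms)
  if (!all(chroms %in% as.character(1:22)))
    stop("chroms must be autosomes 1-22")
  structure(list(purity = purity, depth = depth, mu = mu,
                 gd_time = gd_time, hp_fraction = hp_fraction,
                 hp_time = hp_time, arm_gain_prob = arm_gain_prob,
                 arm_loss_prob = arm_loss_prob, chroms = chroms,
                 noise_free = noise_free),
            class = "sim_config")
}

.arm_prob <- function(prob, arms) {
  if (is.null(names(prob))) return(stats::setNames(rep(prob[1L], length(arms)), arms))
  out <- stats::setNames(rep(0, length(arms)), arms)
  out[intersect(names(prob), arms)] <- prob[intersect(names(prob), arms)]
  out
}

# split segments at arm boundaries and apply one-copy arm events
.apply_arm_events <- function(seg, cfg) {
  arms <- grch38_arms()
  arms <- arms[arms$chrom %in% cfg$chroms, ]
  p_gain <- .arm_prob(cfg$arm_gain_prob, arms$arm)
  p_loss <- .arm_prob(cfg$arm_loss_prob, arms$arm)
  lost   <- stats::runif(nrow(arms)) < p_loss
  gained <- !lost & stats::runif(nrow(arms)) < p_gain
  if (!any(lost | gained)) return(seg)
  pieces <- lapply(which(lost | gained), function(i) {
    a <- arms[i, ]
    hit <- seg$chrom == a$chrom & seg$start <= a$end & seg$end >= a$start
    part <- seg[hit, , drop = FALSE]
    part$start <- pmax(part$start, a$start)
    part$end <- pmin(part$end, a$end)
    if (lost[i]) {
      drop0 <- part$n_minor > 0
      part$n_minor[drop0] <- part$n_minor[drop0] - 1L
    } else {
      part$n_major <- part$n_major + 1L
    }
    part
  })
  hit_arms <- arms[lost | gained, ]
  untouched <- lapply(seq_len(nrow(seg)), function(j) {
    s <- seg[j, , drop = FALSE]
    ov <- hit_arms[hit_arms$chrom == s$chrom, , drop = FALSE]
    if (nrow(ov) == 0L) return(s)
    keep_start <- s$start; keep <- NULL
    for (k in seq_len(nrow(ov))) {
      a <- ov[k, ]
      if (a$start > keep_start) {
        piece <- s; piece$start <- keep_start
        piece$end <- min(s$end, a$start - 1)
        if (piece$end >= piece$start) keep <- rbind(keep, piece)
      }
      keep_start <- max(keep_start, a$end + 1)
    }
    if (keep_start <= s$end) {
      piece <- s; piece$start <- keep_start; piece$end <- s$end
      keep <- rbind(keep, piece)
    }
    keep
  })
  out <- rbind(do.call(rbind, pieces), do.call(rbind, untouched))
  out$length <- out$end - out$start + 1
  out[order(match(out$chrom, cfg$chroms), out$start), ]
}

#' Simulate one tumour genome
#'
#' Runs the generative model described in [sim_config()] and returns
#' Battenberg-style segments, Strelka-style SNVs with read counts, and
#' a ground-truth record.
#'
#' The copy-time bookkeeping per segment: a chromosome that never
#' doubles carries 2 copies for the whole history (all SNVs
#' multiplicity 1); a doubled chromosome carries 2 copies before
#' `gd_time` (those SNVs end at multiplicity 2) and 4 after; a
#' haploidised-then-doubled chromosome carries 1 surviving copy before
#' `gd_time` (multiplicity 2) and 2 after.  Expected SNV counts are
#' `mu * length_Mb * copies * time`.  The observed VAF of a
#' multiplicity-`m` SNV in a segment of total copy number `n_t` at
#' purity `rho` is `f = m * rho / (rho * n_t + 2 * (1 - rho))`.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; identical config + seed gives identical
#'   output.
#' @param sample_id Sample name for the output tables.
#' @return List with elements `segments`, `snvs` (see [io_formats]) and
#'   `truth`: a list with `sample` (one-row `data.frame`: `sample_id`,
#'   `gd`, `hp`, `gd_time`, `loh_fraction`, `ploidy`) and `snv`
#'   (`chrom`, `pos`, `multiplicity`).
#' @export
simulate_tumour <- function(config, seed, sample_id = "SIM_1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  lens <- grch38_chrom_lengths()[config$chroms]
  total <- sum(lens)
  gd <- !is.na(config$gd_time)
  pi_gd <- if (gd) config$gd_time else NA_real_

  # HP: whole chromosomes to 1+0 in random order until >= hp_fraction
  hp_chroms <- character(0)
  if (config$hp_fraction > 0) {
    ord <- sample(config$chroms)
    cum <- cumsum(lens[ord]) / total
    hp_chroms <- ord[seq_len(which(cum >= config$hp_fraction)[1L])]
  }
  hp <- config$hp_fraction > 0

  seg <- data.frame(sample_id = sample_id, chrom = config$chroms,
                    start = 1, end = as.numeric(lens),
                    n_major = 1L, n_minor = 1L,
                    stringsAsFactors = FALSE)
  seg$n_minor[seg$chrom %in% hp_chroms] <- 0L
  if (gd) {
    seg$n_major <- 2L * seg$n_major
    seg$n_minor <- 2L * seg$n_minor
  }
  seg$length <- seg$end - seg$start + 1

  # SNV accrual per segment (before any late arm events)
  mu_bp <- config$mu / 1e6
  pre_copies <- ifelse(seg$chrom %in% hp_chroms, 1L, 2L)
  post_copies <- seg$n_major + seg$n_minor
  if (gd) {
    # the copy lost at HP takes its private mutations with it, so the
    # surviving lineage accrues multiplicity-2 SNVs over all of
    # [0, gd_time] regardless of hp_time (HP timing is unobservable
    # under whole-chromosome loss)
    n2 <- stats::rpois(nrow(seg), mu_bp * seg$length * pre_copies * pi_gd)
    n1 <- stats::rpois(nrow(seg), mu_bp * seg$length * post_copies * (1 - pi_gd))
  } else {
    n2 <- rep(0L, nrow(seg))
    n1 <- stats::rpois(nrow(seg), mu_bp * seg$length * post_copies)
  }

  snv_list <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    n <- n2[i] + n1[i]
    if (n == 0L) next
    pos <- sort(sample.int(seg$length[i], n)) + seg$start[i] - 1
    m <- sample(rep(c(2L, 1L), c(n2[i], n1[i])))
    nt <- post_copies[i]
    f <- m * config$purity / (config$purity * nt + 2 * (1 - config$purity))
    if (config$noise_free) {
      depth <- rep(config$depth, n)
      alt <- round(depth * f)
    } else {
      depth <- pmax(1L, stats::rpois(n, config$depth))
      alt <- stats::rbinom(n, depth, f)
    }
    ref_b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt_b <- vapply(ref_b, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1L),
      USE.NAMES = FALSE)
    snv_list[[i]] <- data.frame(sample_id = sample_id,
                                chrom = seg$chrom[i], pos = pos,
                                ref = ref_b, alt = alt_b,
                                alt_reads = alt, depth = depth,
                                vaf = alt / depth,
                                multiplicity = m,
                                stringsAsFactors = FALSE)
  }
  snvs <- do.call(rbind, snv_list[!vapply(snv_list, is.null, logical(1L))])
  if (is.null(snvs))
    snvs <- data.frame(sample_id = character(), chrom = character(),
                       pos = numeric(), ref = character(),
                       alt = character(), alt_reads = numeric(),
                       depth = numeric(), vaf = numeric(),
                       multiplicity = integer(),
                       stringsAsFactors = FALSE)

  seg <- .apply_arm_events(seg, config)
  seg <- validate_segments(seg)

  truth_sample <- data.frame(
    sample_id = sample_id, gd = gd, hp = hp, gd_time = pi_gd,
    loh_fraction = loh_fraction(seg), ploidy = sample_ploidy(seg),
    stringsAsFactors = FALSE)
  truth_snv <- snvs[, c("chrom", "pos", "multiplicity")]
  rownames(truth_snv) <- NULL
  snvs$multiplicity <- NULL
  rownames(snvs) <- NULL

  list(segments = seg, snvs = snvs,
       truth = list(sample = truth_sample, snv = truth_snv))
}

#' Simulate a structured cohort
#'
#' Generates several groups of tumours (e.g. an all-diploid and an
#' all-GD group) under per-group configurations and returns them in the
#' shared data model, optionally writing the three interchange files
#' (segment TSV, VCF, metadata CSV).  Deterministic given `seed`.
#'
#' @param groups List of group specifications; each a list with
#'   elements `label` (string), `n` (samples), `config`
#'   ([sim_config()]), and optionally `grade`, `idh_group`,
#'   `tert_status` metadata defaults.
#' @param seed Integer seed.
#' @param outdir Optional directory; if given, writes `segments.tsv`,
#'   `snvs.vcf` and `meta.csv` there.
#' @return List with `segments`, `snvs`, `meta`, `truth` (list with
#'   `sample` and `snv` tables, the latter keyed by `sample_id`).
#' @export
simulate_cohort <- function(groups, seed, outdir = NULL) {
  if (length(groups) == 0L) stop("need at least one group")
  keep <- vapply(groups, function(g) g$n > 0, logical(1L))
  if (!all(keep)) {
    warning("omitting ", sum(!keep), " group(s) with n = 0")
    groups <- groups[keep]
  }
  labels <- vapply(groups, `[[`, character(1L), "label")
  ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%02d", g$label, seq_len(g$n))))
  if (anyDuplicated(ids)) stop("duplicate sample ids across groups")
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, length(ids))

  seg_l <- snv_l <- meta_l <- tr_s <- tr_m <- list()
  k <- 0L
  for (g in groups) {
    for (i in seq_len(g$n)) {
      k <- k + 1L
      sim <- simulate_tumour(g$config, seeds[k], sample_id = ids[k])
      seg_l[[k]] <- sim$segments
      snv_l[[k]] <- sim$snvs
      tr_s[[k]] <- cbind(sim$truth$sample, group = g$label,
                         stringsAsFactors = FALSE)
      if (nrow(sim$truth$snv))
        tr_m[[k]] <- cbind(sample_id = ids[k], sim$truth$snv,
                           stringsAsFactors = FALSE)
      meta_l[[k]] <- data.frame(
        sample_id = ids[k],
        grade = if (is.null(g$grade)) "G2/3" else g$grade,
        idh_group = if (is.null(g$idh_group)) "unknown" else g$idh_group,
        tert_status = if (is.null(g$tert_status)) "unknown" else g$tert_status,
        purity = g$config$purity, group = g$label,
        stringsAsFactors = FALSE)
    }
  }
  out <- list(segments = do.call(rbind, seg_l),
              snvs = do.call(rbind, snv_l),
              meta = validate_sample_meta(do.call(rbind, meta_l)),
              truth = list(sample = do.call(rbind, tr_s),
                           snv = do.call(rbind, tr_m)))
  rownames(out$segments) <- rownames(out$snvs) <- rownames(out$meta) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_segments(out$segments, file.path(outdir, "segments.tsv"))
    write_snvs_vcf(out$snvs, file.path(outdir, "snvs.vcf"))
    write_sample_meta(out$meta, file.path(outdir, "meta.csv"))
  }
  out
}
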