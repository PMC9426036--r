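#' Build the per-sample cohort summary table
#'
#' Joins sample metadata with every derived per-sample quantity the
#' package computes: ploidy, major-allele ploidy, LOH fraction, GD and
#' HP calls, the high-breakage chromosome count and the hotspot driver
#' genotype.  This is the table consumed by the cohort statistics and
#' written by [write_cohort_table()].
#'
#' @param segments Multi-sample segment `data.frame`.
#' @param snvs Multi-sample SNV `data.frame` (may be empty; the
#'   genotype columns then default to wild type).
#' @param meta Validated sample metadata (see [read_sample_meta()]).
#' @param hotspots Hotspot table for genotyping; default
#'   [default_hotspots()].
#' @param k_breakage Breakpoint threshold for [count_high_breakage()].
#' @param gd_boundary,min_cohort,seed Passed to [call_gd_hp()].
#' @return Cohort `data.frame`, one row per sample in `meta`.
#' @export
build_cohort_table <- function(segments, snvs, meta,
                               hotspots = default_hotspots(),
                               k_breakage = 10, gd_boundary = 1.6,
                               min_cohort = 10, seed = 1) {
  meta <- validate_sample_meta(meta)
  calls <- call_gd_hp(segments, boundary = gd_boundary,
                      min_cohort = min_cohort, seed = seed)
  brk <- high_breakage_summary(segments, k = k_breakage)
  geno <- genotype_cohort(snvs, hotspots,
                          sample_ids = meta$sample_id)
  out <- meta
  m <- match(out$sample_id, calls$sample_id)
  for (col in c("ploidy", "major_ploidy", "loh_fraction", "gd", "hp"))
    out[[col]] <- calls[[col]][m]
  out$high_breakage_count <-
    brk$high_breakage_count[match(out$sample_id, brk$sample_id)]
  m <- match(out$sample_id, geno$sample_id)
  out$wgs_idh_group <- geno$idh_group[m]
  out$wgs_idh_label <- geno$idh_label[m]
  out$wgs_tert_status <- geno$tert_status[m]
  out$wgs_tert_label <- geno$tert_label[m]
  out
}
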