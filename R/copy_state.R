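#' Copy-state classes
#'
#' The four copy-state categories used throughout:
#' `diploid` (1+1), `gain` (2+1 trisomy or 2+2 tetrasomy),
#' `cnLOH` (2+0 copy-neutral loss of heterozygosity) and `other`
#' (every remaining state).
#'
#' @return Character vector of the class labels, in canonical order.
#' @export
copy_state_levels <- function() c("diploid", "gain", "cnLOH", "other")

#' Classify segments into copy-state classes
#'
#' Maps allele-specific copy numbers onto the named classes: 1+1 is
#' `diploid`; 2+1 and 2+2 are `gain`; 2+0 is `cnLOH`; everything else
#' (including e.g. 3+1, 1+0, 0+0) is `other`.  The enumeration is
#' deliberately narrow — `gain` covers exactly trisomy and tetrasomy —
#' so states such as 3+0 land in `other`.
#'
#' @param n_major,n_minor Integer vectors of major/minor allele copy
#'   number (recycled against each other).
#' @return Factor with levels [copy_state_levels()].
#' @export
#' @examples
#' classify_segment(c(1, 2, 2, 2, 3), c(1, 1, 2, 0, 0))
classify_segment <- function(n_major, n_minor) {
  cls <- rep("other", length(n_major))
  cls[n_major == 1 & n_minor == 1] <- "diploid"
  cls[n_major == 2 & n_minor %in% c(1, 2)] <- "gain"
  cls[n_major == 2 & n_minor == 0] <- "cnLOH"
  factor(cls, levels = copy_state_levels())
}

.check_one_sample <- function(segments) {
  if (nrow(segments) == 0L)
    stop("empty segment set", call. = FALSE)
  if (length(unique(segments$sample_id)) > 1L)
    stop("expected segments of a single sample", call. = FALSE)
}

#' LOH genome fraction
#'
#' Length-weighted fraction of a sample's autosomal segmented genome
#' with minor allele copy number 0 (loss of heterozygosity), the
#' statistic thresholded by [call_hp()].
#'
#' @param segments Segment `data.frame` of one sample.
#' @return Fraction in \[0, 1\].
#' @export
loh_fraction <- function(segments) {
  .check_one_sample(segments)
  auto <- segments[segments$chrom %in% as.character(1:22), ]
  if (nrow(auto) == 0L)
    stop("no autosomal segments", call. = FALSE)
  sum(auto$length[auto$n_minor == 0]) / sum(auto$length)
}

#' Length-weighted sample ploidy
#'
#' Mean total copy number weighted by segment length over autosomes.
#'
#' @param segments Segment `data.frame` of one sample.
#' @return Ploidy (2 for a fully diploid genome, 4 for doubled).
#' @export
sample_ploidy <- function(segments) {
  .check_one_sample(segments)
  auto <- segments[segments$chrom %in% as.character(1:22), ]
  if (nrow(auto) == 0L)
    stop("no autosomal segments", call. = FALSE)
  sum((auto$n_major + auto$n_minor) * auto$length) / sum(auto$length)
}

#' Length-weighted major-allele ploidy
#'
#' Mean major-allele copy number weighted by segment length.  This is
#' the genome-doubling clustering feature: haploidisation lowers total
#' ploidy but not major-allele ploidy, so a haploidised-then-doubled
#' genome (mostly 2+0) still sits near 2 on this scale, with diploid
#' genomes near 1.
#'
#' @param segments Segment `data.frame` of one sample.
#' @return Major-allele ploidy.
#' @export
major_ploidy <- function(segments) {
  .check_one_sample(segments)
  auto <- segments[segments$chrom %in% as.character(1:22), ]
  if (nrow(auto) == 0L)
    stop("no autosomal segments", call. = FALSE)
  sum(auto$n_major * auto$length) / sum(auto$length)
}

#' Amplification rule
#'
#' A total copy number counts as amplified at five or more copies in a
#' diploid genome and at nine or more in a genome-doubled one.
#'
#' @param total_cn Integer vector of total copy numbers.
#' @param gd Logical vector: is the sample genome doubled? (recycled)
#' @return Logical vector.
#' @export
#' @examples
#' is_amplified(5, gd = FALSE)  # TRUE
#' is_amplified(8, gd = TRUE)   # FALSE
is_amplified <- function(total_cn, gd) {
  if (any(total_cn < 0)) stop("total_cn must be >= 0", call. = FALSE)
  ifelse(gd, total_cn >= 9, total_cn >= 5)
}

#' Per-sample ploidy profiles
#'
#' Summarises a multi-sample segment table into one row per sample:
#' ploidy, major-allele ploidy, LOH fraction, and the genome length in
#' each copy-state class.  The class lengths always sum to the total
#' segmented autosomal length.  GD and HP flags are added downstream by
#' [call_gd_hp()].
#'
#' @param segments Validated segment `data.frame` (any number of
#'   samples).
#' @return `data.frame` with columns `sample_id`, `ploidy`,
#'   `major_ploidy`, `loh_fraction`, `len_diploid`, `len_gain`,
#'   `len_cnLOH`, `len_other`, `total_length`.
#' @export
ploidy_profile <- function(segments) {
  segments <- validate_segments(segments)
  auto <- segments[segments$chrom %in% as.character(1:22), ]
  if (nrow(auto) == 0L) stop("no autosomal segments", call. = FALSE)
  auto$class <- classify_segment(auto$n_major, auto$n_minor)
  by_sample <- split(auto, auto$sample_id)
  rows <- lapply(by_sample, function(s) {
    cl <- tapply(s$length, s$class, sum, default = 0)
    data.frame(sample_id = s$sample_id[1L],
               ploidy = sample_ploidy(s),
               major_ploidy = major_ploidy(s),
               loh_fraction = loh_fraction(s),
               len_diploid = cl[["diploid"]], len_gain = cl[["gain"]],
               len_cnLOH = cl[["cnLOH"]], len_other = cl[["other"]],
               total_length = sum(s$length),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
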