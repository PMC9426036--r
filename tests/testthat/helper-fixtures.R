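# shared fixtures: quick constructors and independent oracles

make_segments <- function(sample_id, chrom, start, end, n_major,
                          n_minor) {
  data.frame(sample_id = sample_id, chrom = as.character(chrom),
             start = start, end = end, n_major = n_major,
             n_minor = n_minor, length = end - start + 1,
             stringsAsFactors = FALSE)
}

# one-row-per-autosome segment table at a constant copy state
flat_genome <- function(sample_id, n_major, n_minor,
                        chroms = as.character(1:22)) {
  lens <- grch38_chrom_lengths()[chroms]
  make_segments(sample_id, chroms, 1, as.numeric(lens),
                n_major, n_minor)
}

# Brute-force event-list oracle for GD timing: simulate every mutation
# event on an explicit per-copy lineage with doubling at time t, return
# multiplicity counts.  Independent of the package's closed forms.
oracle_gd_counts <- function(rate, t, state = c("2+2", "2+0"),
                             seed = 1) {
  state <- match.arg(state)
  set.seed(seed)
  pre_copies <- if (state == "2+2") 2L else 1L
  post_copies <- if (state == "2+2") 4L else 2L
  # each pre-GD copy accrues events over [0, t); every event is
  # inherited by both daughter copies at GD (multiplicity 2)
  n2 <- sum(stats::rpois(pre_copies, rate * t))
  # each post-GD copy accrues private events over [t, 1]
  n1 <- sum(stats::rpois(post_copies, rate * (1 - t)))
  list(n1 = n1, n2 = n2)
}

# minimal VCF text fixture writer
write_vcf_lines <- function(body, path,
                            format_defs = c("GT", "AD", "DP"),
                            samples = "S1") {
  defs <- c(
    GT = "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    AD = "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    DP = "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">")
  writeLines(c("##fileformat=VCFv4.2", unname(defs[format_defs]),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               body), path)
  path
}
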