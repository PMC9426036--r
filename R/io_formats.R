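#' @title File formats and the shared data model
#'
#' @description
#' The package's in-memory model is deliberately plain: each domain
#' object is a `data.frame` with a fixed set of columns, so results
#' compose with base R and the tidyverse without adaptor code.
#'
#' * **Segments** — one row per allele-specific copy-number interval:
#'   `sample_id`, `chrom`, `start`, `end` (1-based inclusive bp),
#'   `n_major`, `n_minor`, `length`.
#' * **SNVs** — one row per somatic single-nucleotide variant per
#'   sample: `sample_id`, `chrom`, `pos`, `ref`, `alt`, `alt_reads`,
#'   `depth`, `vaf`.
#' * **Sample metadata** — `sample_id`, `grade`, `idh_group`,
#'   `tert_status`, `purity`, plus optional clinical columns.
#'
#' All coordinates are 1-based inclusive (Battenberg/VCF convention)
#' and chromosome names are normalised by stripping any `"chr"` prefix.
#' @name io_formats
NULL

.seg_aliases <- function() {
  list(sample_id = c("sample_id", "sample", "samplename"),
       chrom     = c("chrom", "chr", "chromosome"),
       start     = c("start", "startpos", "start_pos"),
       end       = c("end", "endpos", "end_pos"),
       n_major   = c("n_major", "nmajor", "nmaj", "major", "nmajor_a"),
       n_minor   = c("n_minor", "nminor", "nmin", "minor", "nminor_a"))
}

.resolve_column <- function(header, wanted, aliases) {
  hit <- match(aliases[[wanted]], tolower(header))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L)
    stop("segment table is missing a recognisable '", wanted,
         "' column (accepted aliases: ",
         paste(aliases[[wanted]], collapse = ", "), ")", call. = FALSE)
  hit[1L]
}

#' Validate a segment table
#'
#' Checks the segment invariants: non-negative copy numbers with
#' `n_major >= n_minor`, `end >= start`, and per sample/chromosome
#' sorted, non-overlapping intervals.  Returns the table sorted by
#' sample, chromosome and start, with `length` recomputed.
#'
#' @param segments Segment `data.frame` (see [io_formats]).
#' @return The validated, sorted segment `data.frame`.
#' @export
validate_segments <- function(segments) {
  need <- c("sample_id", "chrom", "start", "end", "n_major", "n_minor")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    stop("segment table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  segments$chrom <- normalise_chrom(segments$chrom)
  if (any(segments$n_minor < 0) || any(segments$n_major < 0))
    stop("negative copy numbers in segment table", call. = FALSE)
  if (any(segments$n_major < segments$n_minor))
    stop("n_major < n_minor: major/minor alleles must be ordered",
         call. = FALSE)
  bad <- segments$end < segments$start
  if (any(bad))
    stop("segment with end < start (sample ", segments$sample_id[bad][1L],
         ", chrom ", segments$chrom[bad][1L], ")", call. = FALSE)
  ord <- order(segments$sample_id,
               match(segments$chrom, c(as.character(1:22), "X", "Y")),
               segments$chrom, segments$start)
  segments <- segments[ord, , drop = FALSE]
  key <- paste(segments$sample_id, segments$chrom)
  same <- key[-1L] == key[-length(key)]
  if (any(same & segments$start[-1L] <= segments$end[-length(key)])) {
    i <- which(same & segments$start[-1L] <= segments$end[-length(key)])[1L]
    stop("overlapping segments for sample ", segments$sample_id[i],
         " on chromosome ", segments$chrom[i], call. = FALSE)
  }
  segments$length <- segments$end - segments$start + 1
  rownames(segments) <- NULL
  segments
}

#' Read an allele-specific copy-number segment table
#'
#' Reads a Battenberg-style tab-separated segment table.  Column names
#' are matched case-insensitively against a set of aliases so that both
#' this package's header (`sample_id`, `chrom`, `startpos`, `endpos`,
#' `nMajor`, `nMinor`) and common variants parse without renaming.
#' Coordinates are 1-based inclusive.
#'
#' @param path Path to a TSV file with a header line.
#' @param aliases Optional named list overriding the default column
#'   aliases (names `sample_id`, `chrom`, `start`, `end`, `n_major`,
#'   `n_minor`; values are character vectors of accepted lower-case
#'   header names).
#' @return Validated segment `data.frame` (see [io_formats]).
#' @export
read_segments <- function(path, aliases = NULL) {
  al <- .seg_aliases()
  if (!is.null(aliases)) al[names(aliases)] <- aliases
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  idx <- vapply(names(al), .resolve_column,
                integer(1L), header = names(raw), aliases = al)
  seg <- raw[, idx]
  names(seg) <- names(al)
  seg$sample_id <- as.character(seg$sample_id)
  for (col in c("start", "end", "n_major", "n_minor")) {
    v <- suppressWarnings(as.numeric(seg[[col]]))
    if (anyNA(v))
      stop("non-numeric values in segment column '", col, "'",
           call. = FALSE)
    seg[[col]] <- v
  }
  validate_segments(seg)
}

#' Write a segment table
#'
#' Inverse of [read_segments()]; columns are written under the
#' Battenberg-flavoured header accepted by the default aliases.
#'
#' @param segments Validated segment `data.frame`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- segments[, c("sample_id", "chrom", "start", "end",
                      "n_major", "n_minor")]
  names(out) <- c("sample_id", "chrom", "startpos", "endpos",
                  "nMajor", "nMinor")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read somatic SNVs from a VCF file
#'
#' Parses a VCF 4.x file with per-sample `AD` (allelic depths) and `DP`
#' (total depth) FORMAT fields and returns one row per biallelic SNV
#' per sample carrying the variant.  Indels and multiallelic records
#' are skipped and their count reported with a message; samples whose
#' genotype column is missing (`.`) at a record do not contribute a
#' row.  Positions are 1-based.
#'
#' @param path Path to a VCF file.
#' @return SNV `data.frame` (see [io_formats]).
#' @export
read_snvs <- function(path) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  if (!all(c("AD", "DP") %in% names(VariantAnnotation::geno(vcf))))
    stop("VCF lacks AD and/or DP FORMAT fields: ", path, call. = FALSE)
  rr  <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt_l <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_l)
  alt1 <- rep(NA_character_, length(rr))
  alt1[n_alt == 1L] <- as.character(unlist(alt_l[n_alt == 1L]))
  keep <- n_alt == 1L & nchar(ref) == 1L &
    !is.na(alt1) & nchar(alt1) == 1L & alt1 != "*"
  n_skip <- sum(!keep)
  if (n_skip > 0L)
    message("read_snvs: skipped ", n_skip,
            " non-SNV or multiallelic record(s)")
  if (!any(keep))
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = numeric(), ref = character(),
                      alt = character(), alt_reads = numeric(),
                      depth = numeric(), vaf = numeric(),
                      stringsAsFactors = FALSE))
  vcf <- vcf[keep]
  ad <- VariantAnnotation::geno(vcf)$AD
  dp <- VariantAnnotation::geno(vcf)$DP
  chrom <- normalise_chrom(as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(vcf))))
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(vcf))
  samples <- colnames(ad)
  out <- vector("list", length(samples))
  for (j in seq_along(samples)) {
    adj <- ad[, j]
    has <- !vapply(adj, function(x) length(x) < 2L || anyNA(x), logical(1L))
    if (!any(has)) next
    alt_reads <- vapply(adj[has], function(x) as.numeric(x[2L]), numeric(1L))
    depth <- as.numeric(dp[has, j])
    # fall back to AD sum where DP is missing
    na_dp <- is.na(depth)
    if (any(na_dp))
      depth[na_dp] <- vapply(adj[has][na_dp],
                             function(x) sum(as.numeric(x)), numeric(1L))
    out[[j]] <- data.frame(sample_id = samples[j], chrom = chrom[has],
                           pos = pos[has], ref = ref[keep][has],
                           alt = alt1[keep][has], alt_reads = alt_reads,
                           depth = depth, vaf = alt_reads / depth,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(sample_id = character(), chrom = character(),
                      pos = numeric(), ref = character(),
                      alt = character(), alt_reads = numeric(),
                      depth = numeric(), vaf = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write somatic SNVs to a VCF file
#'
#' Emits a minimal VCF 4.2 with `GT:AD:DP` genotype columns, one column
#' per sample present in `snvs`; samples not carrying a variant are
#' written as missing (`./.:.:.`).  Round-trips through [read_snvs()].
#'
#' @param snvs SNV `data.frame` (see [io_formats]).
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_snvs_vcf <- function(snvs, path) {
  samples <- sort(unique(snvs$sample_id))
  if (length(samples) == 0L) samples <- "SAMPLE"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=wgdclock",
           paste0("##contig=<ID=", names(grch38_chrom_lengths()),
                  ",length=", grch38_chrom_lengths(), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths (ref,alt)\">"),
           paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                  "Description=\"Read depth\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(snvs) == 0L) return(invisible(path))
  ord <- order(match(snvs$chrom, names(grch38_chrom_lengths())),
               snvs$pos, snvs$sample_id)
  snvs <- snvs[ord, ]
  geno_str <- paste0("0/1:", snvs$depth - snvs$alt_reads, ",",
                     snvs$alt_reads, ":", snvs$depth)
  cols <- matrix("./.:.:.", nrow = nrow(snvs), ncol = length(samples))
  cols[cbind(seq_len(nrow(snvs)), match(snvs$sample_id, samples))] <-
    geno_str
  body <- paste(snvs$chrom, format(snvs$pos, scientific = FALSE,
                                   trim = TRUE),
                ".", snvs$ref, snvs$alt, ".", "PASS", ".", "GT:AD:DP",
                sep = "\t")
  body <- paste(body, apply(cols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

.meta_levels <- list(grade = c("ACT/G1", "G2/3", "DD"),
                     idh_group = c("IDH1", "IDH2", "IDHwt", "unknown"),
                     tert_status = c("mutant", "wildtype", "unknown"))

#' Validate a sample metadata table
#'
#' @param meta `data.frame` with at least `sample_id`, `grade`,
#'   `idh_group`, `tert_status`, `purity`.
#' @return The validated table.
#' @export
validate_sample_meta <- function(meta) {
  need <- c("sample_id", "grade", "idh_group", "tert_status", "purity")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  for (col in names(.meta_levels)) {
    bad <- !meta[[col]] %in% .meta_levels[[col]]
    if (any(bad))
      stop("invalid ", col, " value(s): ",
           paste(unique(meta[[col]][bad]), collapse = ", "), call. = FALSE)
  }
  if (any(meta$purity <= 0 | meta$purity > 1))
    stop("purity must lie in (0, 1]", call. = FALSE)
  meta
}

#' Read sample metadata from CSV
#'
#' Expected header: `sample_id`, `grade` (`ACT/G1` | `G2/3` | `DD`),
#' `idh_group` (`IDH1` | `IDH2` | `IDHwt` | `unknown`), `tert_status`
#' (`mutant` | `wildtype` | `unknown`), `purity` in (0, 1]; any
#' additional columns (age, size, outcome, ...) are carried through.
#'
#' @param path CSV path.
#' @return Validated metadata `data.frame`.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  validate_sample_meta(meta)
}

#' Write sample metadata to CSV
#' @param meta Metadata `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort summary table
#'
#' Writes the per-sample cohort table (metadata joined with derived
#' flags such as `gd`, `hp`, `loh_fraction`, `ploidy`) as TSV with the
#' column order preserved.  Numeric columns are written with full
#' double precision so that [read_cohort_table()] round-trips within
#' 1e-12.
#'
#' @param table Cohort `data.frame`, `sample_id` unique.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  if (anyDuplicated(table$sample_id))
    stop("duplicate sample_id in cohort table", call. = FALSE)
  out <- table
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cohort summary table written by [write_cohort_table()]
#' @param path TSV path.
#' @return Cohort `data.frame`.
#' @export
read_cohort_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
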