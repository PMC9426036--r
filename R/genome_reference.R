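#' GRCh38 autosome lengths
#'
#' Chromosome lengths (bp) of the 22 human autosomes on the GRCh38
#' primary assembly.  The whole package works in 1-based inclusive
#' coordinates and restricts genome-fraction denominators to autosomes;
#' X and Y are deliberately excluded to avoid sex-specific ploidy
#' artefacts.
#'
#' @return Named integer-valued numeric vector, names `"1"`..`"22"`.
#' @export
#' @examples
#' sum(grch38_chrom_lengths()) / 1e9  # ~2.88 Gb of autosomal sequence
grch38_chrom_lengths <- function() {
  c(`1` = 248956422, `2` = 242193529, `3` = 198295559, `4` = 190214555,
    `5` = 181538259, `6` = 170805979, `7` = 159345973, `8` = 145138636,
    `9` = 138394717, `10` = 133797422, `11` = 135086622, `12` = 133275309,
    `13` = 114364328, `14` = 107043718, `15` = 101991189, `16` = 90338345,
    `17` = 83257441, `18` = 80373285, `19` = 58617616, `20` = 64444167,
    `21` = 46709983, `22` = 50818468)
}

# Approximate GRCh38 centromere midpoints (bp), from UCSC cytoband
# annotation.  Arm-level calling only needs arm boundaries to ~Mb
# precision, so a single coordinate per chromosome suffices.
.grch38_centromeres <- function() {
  c(`1` = 123400000, `2` = 93900000, `3` = 90900000, `4` = 50000000,
    `5` = 48800000, `6` = 59800000, `7` = 60100000, `8` = 45200000,
    `9` = 43000000, `10` = 39800000, `11` = 53400000, `12` = 35500000,
    `13` = 17700000, `14` = 17200000, `15` = 19000000, `16` = 36800000,
    `17` = 25100000, `18` = 18500000, `19` = 26200000, `20` = 28100000,
    `21` = 12000000, `22` = 15000000)
}

#' GRCh38 chromosome arm boundaries
#'
#' Arm intervals for the 22 autosomes: the p arm runs from position 1 to
#' the (approximate) centromere midpoint, the q arm from there to the
#' chromosome end.  Acrocentric p arms (13p, 14p, 15p, 21p, 22p) are
#' included; callers that follow cytogenetic convention may simply
#' ignore them.
#'
#' @return `data.frame` with columns `chrom`, `arm` (e.g. `"15q"`),
#'   `start`, `end`, `length` (1-based inclusive, bp).
#' @export
grch38_arms <- function() {
  len <- grch38_chrom_lengths()
  cen <- .grch38_centromeres()
  chrom <- names(len)
  p <- data.frame(chrom = chrom, arm = paste0(chrom, "p"),
                  start = 1, end = cen[chrom],
                  stringsAsFactors = FALSE)
  q <- data.frame(chrom = chrom, arm = paste0(chrom, "q"),
                  start = cen[chrom] + 1, end = len[chrom],
                  stringsAsFactors = FALSE)
  arms <- rbind(p, q)
  arms <- arms[order(match(arms$chrom, chrom), arms$start), ]
  arms$length <- arms$end - arms$start + 1
  rownames(arms) <- NULL
  arms
}

#' Normalise chromosome names
#'
#' Strips a leading `"chr"` prefix (case-insensitive) so that `"chr1"`
#' and `"1"` refer to the same chromosome throughout the package.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector without the prefix.
#' @export
normalise_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}
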