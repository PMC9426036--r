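#' Read a hotspot definition table
#'
#' Parses a TSV with columns `gene`, `label` (protein or promoter
#' change, e.g. `R132H`, `C228T`), `chrom`, `pos` (1-based), `ref`,
#' `alts` (comma-separated alternate bases) and `build`.  Rows are
#' expanded to one per alternate allele and the `(chrom, pos, alt)`
#' keys must be unique.
#'
#' @param path TSV path; lines starting with `#` are comments.
#' @return `data.frame` with one row per `(chrom, pos, ref, alt)`.
#' @export
read_hotspots <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("gene", "label", "chrom", "pos", "ref", "alts")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("hotspot table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  alts <- strsplit(as.character(tab$alts), ",", fixed = TRUE)
  out <- tab[rep(seq_len(nrow(tab)), lengths(alts)), ]
  out$alt <- unlist(alts)
  out$alts <- NULL
  out$chrom <- normalise_chrom(out$chrom)
  key <- paste(out$chrom, out$pos, out$alt)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos, alt) keys in hotspot table",
         call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Bundled GRCh38 hotspot table
#'
#' The default hotspots: IDH1 R132C/G/H/L/S, IDH2 R172G/K/M/S/W and the
#' canonical TERT promoter mutations C228T (g.1295113) and C250T
#' (g.1295135), curated from the canonical transcripts.  Ships as a
#' versioned TSV under `inst/extdata`.
#'
#' @return Expanded hotspot `data.frame` (see [read_hotspots()]).
#' @export
default_hotspots <- function() {
  read_hotspots(system.file("extdata", "hotspots_grch38.tsv",
                            package = "wgdclock", mustWork = TRUE))
}

#' Genotype one sample against a hotspot table
#'
#' Requires an exact `(chrom, pos, ref, alt)` match — no fuzzy
#' matching.  A sample is `IDH1` or `IDH2` if it carries a matching
#' hotspot in that gene and `IDHwt` otherwise; if hotspots of both
#' genes match (biologically implausible, usually an artefact) the
#' `conflict` flag is set and the gene whose variant has the higher
#' VAF wins.  TERT status is `mutant` iff any TERT promoter hotspot
#' matches.
#'
#' @param snvs SNV `data.frame` of one sample (see [io_formats]).
#' @param hotspots Expanded hotspot table; default [default_hotspots()].
#' @return One-row `data.frame`: `sample_id`, `idh_group`, `idh_label`,
#'   `tert_status`, `tert_label`, `conflict`.
#' @export
genotype_sample <- function(snvs, hotspots = default_hotspots()) {
  sid <- if (nrow(snvs)) snvs$sample_id[1L] else NA_character_
  key_snv <- paste(normalise_chrom(snvs$chrom), snvs$pos,
                   snvs$ref, snvs$alt)
  key_hot <- paste(hotspots$chrom, hotspots$pos,
                   hotspots$ref, hotspots$alt)
  hit <- match(key_snv, key_hot)
  matched <- which(!is.na(hit))
  gene <- hotspots$gene[hit[matched]]
  label <- hotspots$label[hit[matched]]
  vaf <- snvs$vaf[matched]

  top_label <- function(g) {
    i <- which(gene == g)
    if (!length(i)) return(NA_character_)
    label[i][which.max(vaf[i])]
  }
  has_idh1 <- any(gene == "IDH1")
  has_idh2 <- any(gene == "IDH2")
  conflict <- has_idh1 && has_idh2
  idh_group <- if (!has_idh1 && !has_idh2) "IDHwt"
    else if (conflict) {
      if (max(vaf[gene == "IDH1"]) >= max(vaf[gene == "IDH2"]))
        "IDH1" else "IDH2"
    } else if (has_idh1) "IDH1" else "IDH2"
  idh_label <- if (idh_group == "IDHwt") NA_character_
    else top_label(idh_group)
  tert_label <- top_label("TERT")
  data.frame(sample_id = sid, idh_group = idh_group,
             idh_label = idh_label,
             tert_status = if (is.na(tert_label)) "wildtype" else "mutant",
             tert_label = tert_label, conflict = conflict,
             stringsAsFactors = FALSE)
}

#' Genotype a cohort against a hotspot table
#'
#' Applies [genotype_sample()] per sample.  `sample_ids` lets samples
#' with no somatic calls at all still receive an `IDHwt` / `wildtype`
#' row.  `overrides` implements orthogonal-assay precedence (e.g. a
#' ddPCR result superseding the sequencing call): a `data.frame` with
#' `sample_id` and any of `idh_group`, `idh_label`, `tert_status`,
#' `tert_label`; non-`NA` entries replace the sequencing-derived value
#' and such rows are flagged in the `overridden` column.
#'
#' @param snvs Multi-sample SNV `data.frame`.
#' @param hotspots Expanded hotspot table.
#' @param sample_ids Samples to report; default those present in
#'   `snvs`.
#' @param overrides Optional manual override table.
#' @return `data.frame`, one row per sample.
#' @export
genotype_cohort <- function(snvs, hotspots = default_hotspots(),
                            sample_ids = NULL, overrides = NULL) {
  if (is.null(sample_ids)) sample_ids <- sort(unique(snvs$sample_id))
  rows <- lapply(sample_ids, function(id) {
    g <- genotype_sample(snvs[snvs$sample_id == id, , drop = FALSE],
                         hotspots)
    g$sample_id <- id
    g
  })
  out <- do.call(rbind, rows)
  out$overridden <- FALSE
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      j <- match(overrides$sample_id[i], out$sample_id)
      if (is.na(j)) next
      for (col in intersect(c("idh_group", "idh_label", "tert_status",
                              "tert_label"), names(overrides))) {
        v <- overrides[[col]][i]
        if (!is.na(v)) {
          out[[col]][j] <- v
          out$overridden[j] <- TRUE
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}
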