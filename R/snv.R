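#' Filter SNV calls by PASS status, allele fraction and oncogenicity
#'
#' Keeps calls that (i) carry FILTER status `PASS` (when `require_pass`),
#' (ii) have a variant allele fraction of at least `min_vaf` (inclusive: a
#' call exactly at the threshold passes; calls *below* it are excluded),
#' and (iii) are annotated `Oncogenic` or `Likely Oncogenic` in the flat
#' annotation snapshot. Filtering is idempotent.
#'
#' @param calls data.frame of SNV calls as from [read_snv_vcf()].
#' @param annotation_table data.frame mapping `(gene, alteration)` to
#'   `oncogenicity` (see [read_annotation_tsv()]); matched against the
#'   calls' `gene` and `protein_change`.
#' @param min_vaf minimum variant allele fraction (default 0.10).
#' @param require_pass require FILTER == "PASS" (default TRUE).
#' @return the kept calls with an added `oncogenicity` column.
#' @export
filter_snvs <- function(calls, annotation_table, min_vaf = 0.10,
                        require_pass = TRUE) {
  calls <- as.data.frame(calls)
  annotation_table <- as.data.frame(annotation_table)
  if (!nrow(calls)) {
    calls$oncogenicity <- character()
    return(calls)
  }
  key <- paste(calls$gene, calls$protein_change, sep = "\r")
  akey <- paste(annotation_table$gene, annotation_table$alteration,
                sep = "\r")
  onc <- annotation_table$oncogenicity[match(key, akey)]
  calls$oncogenicity <- onc
  keep <- !is.na(onc) & onc %in% c("Oncogenic", "Likely Oncogenic") &
    !is.na(calls$vaf) & calls$vaf >= min_vaf
  if (require_pass) keep <- keep & calls$filter_status == "PASS"
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count reads supporting an alternate allele, with their barcodes
#'
#' Sequence-level realignment is out of scope for this pipeline, so the
#' reads carrying the alternate allele are identified by id (e.g. from
#' simulation truth, or from manual inspection of an alignment viewer).
#' Returns how many of those reads overlap the locus, and the barcode set
#' linking them — the input to [snv_sv_barcode_overlap()].
#'
#' @param reads alignment table.
#' @param chrom,pos locus (pos is 1-based, VCF convention).
#' @param alt_carrier_ids character vector of `read_id`s carrying the
#'   alternate allele.
#' @return list with `count` and `barcodes`.
#' @export
count_allele_support <- function(reads, chrom, pos, alt_carrier_ids) {
  dt <- as_reads_table(reads)
  pos0 <- pos - 1  # VCF 1-based -> 0-based
  chr <- chrom
  hit <- dt[chrom == chr & pos <= pos0 & end > pos0 &
              read_id %in% alt_carrier_ids]
  list(count = nrow(hit), barcodes = sort(unique(hit$barcode)))
}
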