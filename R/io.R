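## On-disk formats: barcoded alignments (TSV dialect or BAM with BX tags),
## target BED, SV/truth BEDPE, molecules/CN TSV, SNV VCF, network JSON.

ALIGNMENT_COLUMNS <- c("read_id", "chrom", "pos", "end", "strand", "mapq",
                       "barcode", "mate_chrom", "mate_pos", "mate_strand",
                       "proper_pair")

#' Read barcoded alignments
#'
#' Reads coordinate-sorted barcoded alignments either from the package's
#' tab-separated dialect (`read_id, chrom, pos, end, strand, mapq, barcode,
#' mate_chrom, mate_pos, mate_strand, proper_pair`; header line required;
#' 0-based half-open coordinates) or from a coordinate-sorted BAM carrying
#' `BX:Z` barcode tags. Records below `min_mapq` or lacking a barcode are
#' excluded and counted (see the `"excluded"` attribute of the result).
#'
#' @param path input file.
#' @param min_mapq minimum mapping quality retained (default 30).
#' @param format `"tsv"`, `"bam"`, or `"auto"` (by file extension).
#' @param dedup if `TRUE`, drop duplicated `(read_id, chrom, pos)` records.
#' @return data.table of alignments sorted by (chrom, pos) with attribute
#'   `excluded = c(low_mapq = ..., no_barcode = ...)`.
#' @export
read_alignments <- function(path, min_mapq = 30, format = c("auto", "tsv", "bam"),
                            dedup = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "tsv"
  if (!file.exists(path)) stop("no such file: ", path)
  reads <- switch(format,
                  tsv = read_alignments_tsv(path),
                  bam = read_alignments_bam(path))
  no_bc <- is.na(reads$barcode) | reads$barcode == "" | reads$barcode == "-"
  low_mq <- !no_bc & reads$mapq < min_mapq
  excluded <- c(low_mapq = sum(low_mq), no_barcode = sum(no_bc))
  reads <- reads[!(no_bc | low_mq)]
  if (dedup) reads <- unique(reads, by = c("read_id", "chrom", "pos"))
  if (is.unsorted(order(reads$chrom, reads$pos)))  # cannot happen post-check
    stop("internal: unsorted alignments")
  setattr(reads, "excluded", excluded)
  reads[]
}

read_alignments_tsv <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != length(ALIGNMENT_COLUMNS))
  if (length(bad))
    stop("malformed alignment row at line ", bad[1L], " of ", path,
         " (expected ", length(ALIGNMENT_COLUMNS), " tab-separated fields)")
  dt <- suppressWarnings(
    fread(path, sep = "\t", header = TRUE,
          colClasses = list(character = c(1, 2, 5, 7, 8, 10),
                            numeric = c(3, 4, 9), integer = 6,
                            logical = 11)))
  for (col in c("pos", "end", "mate_pos"))
    if (!is.numeric(dt[[col]]))
      dt[, (col) := suppressWarnings(as.numeric(get(col)))]
  if (!is.integer(dt$mapq))
    dt[, mapq := suppressWarnings(as.integer(mapq))]
  if (!identical(names(dt), ALIGNMENT_COLUMNS))
    stop("alignment TSV header does not match the expected dialect: ",
         paste(names(dt), collapse = ", "))
  bad_row <- which(is.na(dt$pos) | is.na(dt$end) | is.na(dt$mapq) |
                     dt$pos >= dt$end | !(dt$strand %in% c("+", "-")))
  if (length(bad_row))
    stop("malformed alignment row at line ", bad_row[1L] + 1L, " of ", path)
  if (is.unsorted(order(dt$chrom, dt$pos)) ||
      dt[, any(diff(pos) < 0), by = chrom][, any(V1)])
    stop("alignment TSV is not sorted by (chrom, pos): ", path)
  dt
}

read_alignments_bam <- function(path) {
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "rname", "pos", "strand", "mapq", "flag",
             "mrnm", "mpos", "cigar", "qwidth"),
    tag = "BX")
  b <- Rsamtools::scanBam(path, param = param)[[1L]]
  ref_width <- cigar_reference_width(b$cigar, b$qwidth)
  mate_rev <- bitwAnd(b$flag, 0x20L) != 0L
  dt <- data.table(
    read_id = b$qname,
    chrom = as.character(b$rname),
    pos = as.numeric(b$pos) - 1,            # BAM is 1-based
    end = as.numeric(b$pos) - 1 + ref_width,
    strand = as.character(b$strand),
    mapq = as.integer(b$mapq),
    barcode = if (is.null(b$tag$BX)) NA_character_ else as.character(b$tag$BX),
    mate_chrom = as.character(b$mrnm),
    mate_pos = as.numeric(b$mpos) - 1,
    mate_strand = ifelse(mate_rev, "-", "+"),
    proper_pair = bitwAnd(b$flag, 0x2L) != 0L)
  if (is.unsorted(order(dt$chrom, dt$pos)))
    stop("BAM is not coordinate-sorted: ", path)
  dt
}

## reference-space alignment width from CIGAR (M/D/N/=/X consume reference)
cigar_reference_width <- function(cigar, qwidth) {
  w <- vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_real_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    lens <- as.numeric(sub("[MIDNSHP=X]", "", ops))
    sum(lens[grepl("[MDN=X]", ops)])
  }, numeric(1L), USE.NAMES = FALSE)
  ifelse(is.na(w), qwidth, w)
}

#' Write barcoded alignments in the package TSV dialect
#' @param reads alignment table (extra columns are dropped).
#' @param path output file.
#' @export
write_alignments_tsv <- function(reads, path) {
  dt <- as_reads_table(reads)[, ALIGNMENT_COLUMNS, with = FALSE]
  fwrite(dt, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Write / read structural variant calls as BEDPE
#'
#' Columns: `chrom1, start1, end1, chrom2, start2, end2, name,
#' score` (split-molecule support)`, strand1, strand2, svtype, d_params`
#' (comma-joined)`, barcodes` (semicolon-joined). Coordinates are 0-based
#' half-open; each breakend is a 1 bp interval. The pair round-trips
#' losslessly.
#'
#' @param calls an [sv_call_set] (see [call_svs()]).
#' @param path output file.
#' @export
write_sv_bedpe <- function(calls, path) {
  header <- paste(c("#chrom1", "start1", "end1", "chrom2", "start2", "end2",
                    "name", "score", "strand1", "strand2", "svtype",
                    "d_params", "barcodes"), collapse = "\t")
  lines <- header
  if (nrow(calls)) {
    body <- vapply(seq_len(nrow(calls)), function(i) {
      paste(c(calls$chrom1[i], calls$pos1[i], calls$pos1[i] + 1,
              calls$chrom2[i], calls$pos2[i], calls$pos2[i] + 1,
              calls$name[i], calls$split_molecule_count[i],
              calls$orient1[i], calls$orient2[i], calls$svtype[i],
              paste(calls$d_params[[i]], collapse = ","),
              paste(calls$support_barcodes[[i]], collapse = ";")),
            collapse = "\t")
    }, character(1L))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sv_bedpe
#' @export
read_sv_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(empty_sv_call_set())
  f <- strsplit(lines, "\t", fixed = TRUE)
  stopifnot(all(lengths(f) == 13L))
  g <- function(i) vapply(f, `[[`, "", i)
  calls <- data.table(
    name = g(7), chrom1 = g(1), pos1 = as.numeric(g(2)), orient1 = g(9),
    chrom2 = g(4), pos2 = as.numeric(g(5)), orient2 = g(10), svtype = g(11),
    split_molecule_count = as.integer(g(8)),
    support_barcodes = lapply(strsplit(g(13), ";", fixed = TRUE),
                              function(x) x[nzchar(x)]),
    d_params = lapply(strsplit(g(12), ",", fixed = TRUE), as.numeric))
  as_sv_call_set(calls)
}

#' Write simulation truth junctions as BEDPE
#' @param truth `truth_junctions` table of a [simulate_linked_reads()] result.
#' @param path output file.
#' @export
write_truth_bedpe <- function(truth, path) {
  header <- paste(c("#chrom1", "start1", "end1", "chrom2", "start2", "end2",
                    "name", "svtype", "strand1", "strand2"), collapse = "\t")
  lines <- header
  if (nrow(truth))
    lines <- c(lines, do.call(paste, c(truth[c(
      "chrom1", "start1", "end1", "chrom2", "start2", "end2", "name",
      "svtype", "orient1", "orient2")], sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a target/control panel BED
#'
#' Five tab-separated columns without header: `chrom, start, end, label,
#' role` with role in `{target, control}`. Regions must not overlap within
#' a role.
#'
#' @param path BED file.
#' @return data.frame with those five columns.
#' @export
read_target_bed <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE,
              col.names = c("chrom", "start", "end", "label", "role"),
              colClasses = list(character = c(1, 4, 5), numeric = c(2, 3)))
  if (!all(dt$role %in% c("target", "control")))
    stop("target BED roles must be 'target' or 'control'")
  if (any(dt$start >= dt$end)) stop("target BED has start >= end")
  for (r in unique(dt$role)) {
    sub <- dt[dt$role == r][order(chrom, start)]
    ov <- sub[, any(head(end, -1) > tail(start, -1)), by = chrom][, any(V1)]
    if (isTRUE(ov)) stop("overlapping regions within role '", r, "'")
  }
  as.data.frame(dt)
}

#' Write reconstructed molecules as TSV
#' @param molecules result of [reconstruct_molecules()].
#' @param path output file.
#' @export
write_molecules_tsv <- function(molecules, path) {
  cols <- c("barcode", "chrom", "start", "end", "n_reads", "d_used")
  fwrite(as.data.table(molecules)[, cols, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Write copy-number estimates as TSV
#' @param cn a [cn_estimate] or data.frame with columns incl. region and cn.
#' @param path output file.
#' @export
write_cn_tsv <- function(cn, path) {
  if (inherits(cn, "cn_estimate")) cn <- as.data.frame(cn)
  fwrite(as.data.table(cn), path, sep = "\t")
  invisible(path)
}

#' Read SNV calls from a VCF
#'
#' Parses a (plain or gzipped) VCF via \pkg{vcfR} and extracts the fields
#' this pipeline uses: `RO`/`AO` INFO counts (freebayes convention),
#' `GENE` and `PCHANGE` INFO annotations, and the FILTER status. The
#' variant allele fraction is recomputed as `AO / (RO + AO)`.
#'
#' @param path VCF file.
#' @return data.frame of SNV calls (`chrom, pos, ref, alt, filter_status,
#'   ref_count, alt_count, vaf, gene, protein_change`); `pos` is 1-based.
#' @export
read_snv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix))
    return(data.frame(chrom = character(), pos = numeric(), ref = character(),
                      alt = character(), filter_status = character(),
                      ref_count = numeric(), alt_count = numeric(),
                      vaf = numeric(), gene = character(),
                      protein_change = character()))
  info_num <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = key)))
  info_chr <- function(key) as.character(vcfR::extract.info(v, element = key))
  ro <- info_num("RO"); ao <- info_num("AO")
  out <- data.frame(
    chrom = fix$CHROM, pos = as.numeric(fix$POS), ref = fix$REF,
    alt = fix$ALT, filter_status = fix$FILTER,
    ref_count = ro, alt_count = ao,
    vaf = ifelse(!is.na(ro) & !is.na(ao) & (ro + ao) > 0, ao / (ro + ao), NA),
    gene = info_chr("GENE"), protein_change = info_chr("PCHANGE"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write SNV calls as a minimal plain-text VCF
#' @param calls data.frame as returned by [read_snv_vcf()] /
#'   [filter_snvs()].
#' @param path output file.
#' @export
write_snv_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=linkphase",
    "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"Reference allele read count\">",
    "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alternate allele read count\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(calls)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t%s\tRO=%d;AO=%d;GENE=%s;PCHANGE=%s",
    calls$chrom, as.integer(calls$pos), calls$ref, calls$alt,
    calls$filter_status, as.integer(calls$ref_count),
    as.integer(calls$alt_count), calls$gene, calls$protein_change)
  else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an oncogenicity annotation table
#'
#' Flat snapshot mapping `(gene, alteration)` to an oncogenicity class
#' (e.g. `Oncogenic`, `Likely Oncogenic`), consumed instead of a live
#' annotation service. Tab-separated with header
#' `gene  alteration  oncogenicity`.
#'
#' @param path TSV file.
#' @return data.frame with columns gene, alteration, oncogenicity.
#' @export
read_annotation_tsv <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  need <- c("gene", "alteration", "oncogenicity")
  if (!all(need %in% names(dt)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  as.data.frame(dt[, need, with = FALSE])
}

#' Write a phase network as JSON
#' @param network a [phase_network] (see [phase_svs()]).
#' @param path output file.
#' @export
write_phase_network_json <- function(network, path) {
  stopifnot(inherits(network, "phase_network"))
  nodes <- network$nodes
  obj <- list(
    nodes = lapply(seq_len(nrow(nodes)), function(i) list(
      id = nodes$id[i], svtype = nodes$svtype[i],
      be1 = list(chrom = nodes$chrom1[i], pos = nodes$pos1[i],
                 orient = nodes$orient1[i]),
      be2 = list(chrom = nodes$chrom2[i], pos = nodes$pos2[i],
                 orient = nodes$orient2[i]),
      support = nodes$support[i], component = nodes$component[i],
      unlinked = nodes$unlinked[i])),
    edges = lapply(seq_len(nrow(network$edges)), function(i) list(
      a = network$edges$a[i], b = network$edges$b[i],
      n_shared = network$edges$n_shared[i],
      shared = network$edges$shared[[i]])),
    components = network$components,
    min_shared = network$min_shared)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a pipeline run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [run_config()] defaults.
#' @param path YAML file.
#' @return a [run_config] list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
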