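## fixture builders and independent oracles shared across test files

## a read-pair builder: returns the two alignment records of one pair
mk_pair <- function(id, barcode, chrom1, pos1, strand1, chrom2, pos2,
                    strand2, rl = 150, mapq = 60) {
  span <- if (chrom1 == chrom2) abs(pos2 - pos1) + rl else Inf
  proper <- chrom1 == chrom2 && strand1 != strand2 && span <= 1000 &&
    (if (pos1 <= pos2) strand1 == "+" else strand2 == "+")
  data.frame(
    read_id = id,
    chrom = c(chrom1, chrom2), pos = c(pos1, pos2),
    end = c(pos1 + rl, pos2 + rl), strand = c(strand1, strand2),
    mapq = mapq, barcode = barcode,
    mate_chrom = c(chrom2, chrom1), mate_pos = c(pos2, pos1),
    mate_strand = c(strand2, strand1), proper_pair = proper,
    stringsAsFactors = FALSE)
}

sort_reads <- function(df) {
  df <- df[order(df$chrom, df$pos, df$end, df$read_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## reads giving one reconstructed molecule per (barcode, cluster): each
## cluster is a run of overlapping-ish reads
mk_molecule_reads <- function(barcode, chrom, positions, rl = 150,
                              prefix = barcode) {
  data.frame(
    read_id = sprintf("%s_r%03d", prefix, seq_along(positions)),
    chrom = chrom, pos = positions, end = positions + rl, strand = "+",
    mapq = 60, barcode = barcode,
    mate_chrom = NA_character_, mate_pos = NA_real_,
    mate_strand = NA_character_, proper_pair = TRUE,
    stringsAsFactors = FALSE)
}

## the deletion-junction fixture with an exact number of junction-spanning
## barcodes: breakends ~ (chr1, 10000, +) / (chr1, 60000, -)
mk_boundary_fixture <- function(n_barcodes) {
  rows <- list()
  for (i in seq_len(n_barcodes)) {
    bc <- sprintf("BC%02d", i)
    rows[[length(rows) + 1L]] <-
      mk_pair(paste0(bc, "_p1"), bc, "chr1", 9500, "+", "chr1", 9800, "-")
    rows[[length(rows) + 1L]] <-
      mk_pair(paste0(bc, "_p2"), bc, "chr1", 60050, "+", "chr1", 60400, "-")
    ## junction-spanning (discordant) pair
    rows[[length(rows) + 1L]] <-
      mk_pair(paste0(bc, "_pd"), bc, "chr1", 9780, "+", "chr1", 60080, "-")
  }
  sort_reads(do.call(rbind, rows))
}

## standard simulation geometry used in recovery tests: a 200 kb toy chrX
sim_ref <- function() c(chrXsim = 200000)

## circular 3-junction ecDNA-like derivative (DEL-, INV-, INV-type
## adjacencies), segments spaced > max(d) so fragments never merge
ecdna_derivative <- function(copy_number = 8) {
  derivative_structure("ecdna1", data.frame(
    chrom = "chrXsim", start = c(20000, 60000, 100000),
    end = c(30000, 70000, 110000), orient = c("+", "+", "-")),
    circular = TRUE, copy_number = copy_number)
}

## independent single-junction circle (tandem-duplication-type adjacency)
dup_derivative <- function(copy_number = 8) {
  derivative_structure("dup1", data.frame(
    chrom = "chrXsim", start = 140000, end = 180000, orient = "+"),
    circular = TRUE, copy_number = copy_number)
}

## linear amplified segment for copy-number recovery (total copies =
## copy_number + background ploidy)
amp_derivative <- function(copy_number = 7) {
  derivative_structure("amp", data.frame(
    chrom = "chrXsim", start = 20000, end = 30000, orient = "+"),
    circular = FALSE, copy_number = copy_number)
}

cn_control_regions <- function() {
  data.frame(chrom = "chrXsim", start = c(60000, 120000),
             end = c(110000, 170000))
}

call_svs_quiet <- function(...) suppressMessages(call_svs(...))

## match calls to truth junctions within a breakend tolerance; returns
## per-call index into truth (NA = false positive)
match_calls_to_truth <- function(calls, truth, tol = 1000) {
  vapply(seq_len(nrow(calls)), function(i) {
    hit <- which(
      truth$chrom1 == calls$chrom1[i] & truth$chrom2 == calls$chrom2[i] &
        abs(truth$start1 - calls$pos1[i]) <= tol &
        abs(truth$start2 - calls$pos2[i]) <= tol)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1L))
}

## ---- independent oracles ----

## exhaustive fixed-margin enumeration of the two-sided Fisher p-value,
## point probabilities from the combinatorial formula via lchoose()
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  a_values <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, a_values) + lchoose(r2, c1 - a_values) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[a_values == tab[1, 1]]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

## brute-force molecule partition: plain sequential scan per barcode/chrom
molecule_oracle <- function(reads, d, min_reads = 2L) {
  reads <- reads[order(reads$barcode, reads$chrom, reads$pos, reads$end), ]
  out <- list()
  for (bc in unique(reads$barcode)) {
    for (ch in unique(reads$chrom[reads$barcode == bc])) {
      sub <- reads[reads$barcode == bc & reads$chrom == ch, ]
      cur_start <- sub$pos[1]; cur_end <- sub$end[1]; cur_n <- 1L
      flush <- function() {
        if (cur_n >= min_reads)
          out[[length(out) + 1L]] <<- data.frame(
            barcode = bc, chrom = ch, start = cur_start, end = cur_end,
            n_reads = cur_n, stringsAsFactors = FALSE)
      }
      if (nrow(sub) > 1L) for (i in 2:nrow(sub)) {
        if (sub$pos[i] - cur_end > d) {
          flush()
          cur_start <- sub$pos[i]; cur_end <- sub$end[i]; cur_n <- 1L
        } else {
          cur_end <- max(cur_end, sub$end[i]); cur_n <- cur_n + 1L
        }
      }
      flush()
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(barcode = character(), chrom = character(), start = numeric(),
               end = numeric(), n_reads = integer(), stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start, res$barcode), ]
  rownames(res) <- NULL
  res
}

## random alignment tables for round-trip / oracle property tests
random_reads <- function(n, n_barcodes = 10, seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(100000, n, replace = TRUE))
  df <- data.frame(
    read_id = sprintf("r%05d", seq_len(n)),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = pos, end = pos + sample(50:200, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    mapq = sample(0:60, n, replace = TRUE),
    barcode = sprintf("BX%03d", sample.int(n_barcodes, n, replace = TRUE)),
    mate_chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    mate_pos = sample.int(100000, n, replace = TRUE),
    mate_strand = sample(c("+", "-"), n, replace = TRUE),
    proper_pair = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
  sort_reads(df)
}

## canonical comparable form of a molecule table
mol_key <- function(m) {
  m <- as.data.frame(m)[, c("barcode", "chrom", "start", "end", "n_reads")]
  m <- m[order(m$barcode, m$chrom, m$start), ]
  rownames(m) <- NULL
  m
}
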