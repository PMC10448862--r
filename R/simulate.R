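#' Generate deterministic synthetic reference sequences
#'
#' Builds pseudo-random DNA sequences (uniform base composition) for use as
#' simulation references. Each record is generated from its own seed so the
#' result is reproducible per sequence.
#'
#' @param spec data.frame with columns `name` and `length` (bp), and
#'   optionally `seed` (one integer per record; defaults to `seed + record
#'   index`).
#' @param seed base integer seed used when `spec$seed` is absent.
#' @return A [Biostrings::DNAStringSet] named by `spec$name`; write with
#'   [Biostrings::writeXStringSet()].
#' @examples
#' ref <- make_reference(data.frame(name = "chrXtoy", length = 2000), seed = 7)
#' Biostrings::width(ref)
#' @export
make_reference <- function(spec, seed = 1L) {
  spec <- as.data.frame(spec)
  if (!all(c("name", "length") %in% names(spec)))
    stop("spec must have columns name and length")
  if (anyDuplicated(spec$name))
    stop("duplicate reference sequence name(s): ",
         paste(unique(spec$name[duplicated(spec$name)]), collapse = ", "))
  if (any(spec$length < 1000))
    stop("reference sequences must be at least 1 kb")
  seeds <- if ("seed" %in% names(spec)) spec$seed else seed + seq_len(nrow(spec))
  seqs <- vapply(seq_len(nrow(spec)), function(i) {
    with_seed(seeds[i], paste(sample(c("A", "C", "G", "T"),
                                     spec$length[i], replace = TRUE),
                              collapse = ""))
  }, character(1L))
  Biostrings::DNAStringSet(setNames(seqs, spec$name))
}

#' Define a derivative (rearranged) structure
#'
#' A derivative structure is an ordered walk of oriented reference segments,
#' optionally circular (the ecDNA model), present at `copy_number` copies on
#' top of the unrearranged background genome.
#'
#' @param id character label.
#' @param segments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open bp) and `orient` (`"+"` or `"-"`).
#' @param circular logical; `TRUE` models a circular molecule (ecDNA).
#' @param copy_number positive integer number of copies of this structure.
#' @return An object of class `derivative_structure`.
#' @examples
#' ecdna <- derivative_structure("ecdna1",
#'   data.frame(chrom = "chrX", start = c(0, 20000), end = c(10000, 30000),
#'              orient = c("+", "-")),
#'   circular = TRUE, copy_number = 8)
#' truth_junctions(ecdna)
#' @export
derivative_structure <- function(id, segments, circular = FALSE,
                                 copy_number = 1L) {
  segments <- as.data.frame(segments)
  if (!all(c("chrom", "start", "end", "orient") %in% names(segments)))
    stop("segments must have columns chrom, start, end, orient")
  if (nrow(segments) < 1L) stop("a derivative needs at least one segment")
  if (!all(segments$start < segments$end))
    stop("segment start must be < end")
  if (!all(segments$orient %in% c("+", "-")))
    stop("segment orient must be '+' or '-'")
  if (!(is.numeric(copy_number) && length(copy_number) == 1L &&
        copy_number >= 1 && copy_number == round(copy_number)))
    stop("copy_number must be a positive integer")
  segments$chrom <- as.character(segments$chrom)
  structure(list(id = as.character(id), segments = segments,
                 circular = isTRUE(circular),
                 copy_number = as.integer(copy_number)),
            class = "derivative_structure")
}

#' @export
print.derivative_structure <- function(x, ...) {
  cat(sprintf("Derivative structure '%s': %d segment(s), %s, copy number %d\n",
              x$id, nrow(x$segments),
              if (x$circular) "circular (ecDNA-like)" else "linear",
              x$copy_number))
  seg <- x$segments
  cat(paste0(sprintf("  [%s]%s:%d-%d", seg$orient, seg$chrom,
                     as.integer(seg$start), as.integer(seg$end)),
             collapse = " -> "), if (x$circular) "-> (wrap)\n" else "\n")
  invisible(x)
}

## breakend contributed by one side of a segment.
## '+' orientation at a breakend means the retained segment extends toward
## lower coordinates (breakpoint at the segment's reference right end);
## '-' means it extends toward higher coordinates (breakpoint at the left).
segment_breakend <- function(seg, side = c("3p", "5p")) {
  side <- match.arg(side)
  fwd <- seg$orient == "+"
  if ((side == "3p") == fwd)
    list(chrom = seg$chrom, pos = seg$end, orient = "+")
  else
    list(chrom = seg$chrom, pos = seg$start, orient = "-")
}

## TRUE when two consecutive derivative segments are reference-adjacent
## with compatible orientation (no novel adjacency is formed)
is_trivial_adjacency <- function(a, b) {
  if (a$chrom != b$chrom || a$orient != b$orient) return(FALSE)
  if (a$orient == "+") a$end == b$start else a$start == b$end
}

#' Enumerate the novel adjacencies (truth junctions) of a derivative
#'
#' Each pair of consecutive segments (plus the wrap-around pair for a
#' circular derivative) creates one junction, unless the two segments are
#' reference-adjacent with compatible orientation (in which case the walk
#' simply continues along the reference and no novel adjacency exists).
#'
#' @param d a [derivative_structure()].
#' @return data.frame with one row per junction: `chrom1, pos1, orient1,
#'   chrom2, pos2, orient2, svtype, name`, breakends canonically ordered.
#' @export
truth_junctions <- function(d) {
  stopifnot(inherits(d, "derivative_structure"))
  segs <- split(d$segments, seq_len(nrow(d$segments)))
  segs <- lapply(segs, as.list)
  n <- length(segs)
  pairs <- if (n > 1L) Map(c, seq_len(n - 1L), seq(2L, n)) else list()
  if (d$circular) pairs <- c(pairs, list(c(n, 1L)))
  rows <- list()
  for (p in pairs) {
    a <- segs[[p[1L]]]; b <- segs[[p[2L]]]
    if (is_trivial_adjacency(a, b)) next
    be1 <- segment_breakend(a, "3p")
    be2 <- segment_breakend(b, "5p")
    cb <- canonical_breakends(be1, be2)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom1 = cb$be1$chrom, pos1 = cb$be1$pos, orient1 = cb$be1$orient,
      chrom2 = cb$be2$chrom, pos2 = cb$be2$pos, orient2 = cb$be2$orient,
      svtype = classify_sv_type(cb$be1, cb$be2),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom1 = character(), pos1 = numeric(), orient1 = character(),
               chrom2 = character(), pos2 = numeric(), orient2 = character(),
               svtype = character(), stringsAsFactors = FALSE)
  if (nrow(out)) out <- unique(out)
  out$name <- if (nrow(out)) sprintf("%s_j%d", d$id, seq_len(nrow(out))) else
    character()
  rownames(out) <- NULL
  out
}

#' Simulation parameters
#'
#' Parameters of the droplet-partitioned linked-read generator. Defaults
#' emulate a deep targeted assay: 50 kb HMW molecules, a median of ~30
#' linked reads per molecule (within the 15-148 band typical of targeted
#' linked-read data), 2 x 150 bp pairs at ~400 bp inserts, 60-fold per-copy
#' depth, and no barcode collisions.
#'
#' @param molecule_length_mean mean HMW molecule length (bp); lengths are
#'   log-normal with this mean.
#' @param molecule_length_sdlog log-scale standard deviation of molecule
#'   length.
#' @param reads_per_molecule_median target median number of linked reads per
#'   molecule (read pairs are Poisson, scaled by molecule length).
#' @param read_length read length (bp).
#' @param insert_mean,insert_sd fragment (insert) size distribution (bp).
#' @param target_coverage per-copy fold depth: each copy of each simulated
#'   structure receives this read depth over its span, so a region at total
#'   copy number k is sequenced at ~`k * target_coverage`.
#' @param barcode_collision_lambda expected number of *extra* molecules
#'   sharing one droplet barcode (Poisson); 0 gives one molecule per barcode.
#' @param background_ploidy copies of the unrearranged background genome
#'   co-simulated for every reference sequence (1 = haploid, as for chrX in
#'   a male genome).
#' @param seed integer seed; identical seeds give identical output.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(molecule_length_mean = 50000,
                       molecule_length_sdlog = 0.4,
                       reads_per_molecule_median = 30,
                       read_length = 150,
                       insert_mean = 400, insert_sd = 50,
                       target_coverage = 60,
                       barcode_collision_lambda = 0,
                       background_ploidy = 1L,
                       seed = 1L) {
  p <- list(molecule_length_mean = molecule_length_mean,
            molecule_length_sdlog = molecule_length_sdlog,
            reads_per_molecule_median = reads_per_molecule_median,
            read_length = read_length,
            insert_mean = insert_mean, insert_sd = insert_sd,
            target_coverage = target_coverage,
            barcode_collision_lambda = barcode_collision_lambda,
            background_ploidy = as.integer(background_ploidy),
            seed = as.integer(seed))
  pos_fields <- c("molecule_length_mean", "molecule_length_sdlog",
                  "reads_per_molecule_median", "read_length", "insert_mean",
                  "insert_sd", "target_coverage", "background_ploidy")
  for (f in pos_fields)
    if (!(is.numeric(p[[f]]) && length(p[[f]]) == 1L && p[[f]] > 0))
      stop("sim_params field '", f, "' must be a positive number")
  if (barcode_collision_lambda < 0)
    stop("barcode_collision_lambda must be >= 0")
  structure(p, class = "sim_params")
}

## reference sequence lengths from a DNAStringSet or named numeric vector
ref_lengths <- function(ref) {
  if (inherits(ref, "DNAStringSet"))
    return(setNames(Biostrings::width(ref), names(ref)))
  if (is.numeric(ref) && !is.null(names(ref))) return(ref)
  stop("ref must be a DNAStringSet or a named numeric vector of lengths")
}

## derivative-coordinate segment map: offsets of each segment within the
## concatenated derivative walk
segment_map <- function(segments) {
  widths <- segments$end - segments$start
  data.frame(segments, width = widths,
             offset = cumsum(c(0, widths[-length(widths)])))
}

#' Simulate droplet-partitioned linked reads from derivative structures
#'
#' Samples HMW molecules along each derivative's coordinate walk (and along
#' an always-co-simulated unrearranged background at
#' `params$background_ploidy`), places paired reads on each molecule, and
#' maps read coordinates back to the reference through the segment map.
#' Reads overlapping a junction point are dropped (downstream evidence is
#' discordant pairs and split molecules, not split reads), so a molecule
#' spanning a junction yields two or more reference fragments sharing one
#' barcode. Extra molecules per barcode follow
#' Poisson(`barcode_collision_lambda`).
#'
#' @param ref reference as returned by [make_reference()], or a named
#'   numeric vector of sequence lengths (no base-level sequence is emitted).
#' @param derivatives list of [derivative_structure()] objects (may be
#'   empty for a background-only simulation).
#' @param params a [sim_params()] object.
#' @return list of class `linked_sim`:
#' \describe{
#'   \item{reads}{alignment table in the package dialect (`read_id, chrom,
#'     pos, end, strand, mapq, barcode, mate_chrom, mate_pos, mate_strand,
#'     proper_pair`) plus provenance columns `molecule_id` and `source`,
#'     sorted by (chrom, pos).}
#'   \item{truth_junctions}{BEDPE-style truth table of novel adjacencies.}
#'   \item{truth_cn}{per-region total copy number (background ploidy plus
#'     derivative copies).}
#'   \item{molecules}{per-molecule truth (barcode, source structure,
#'     derivative-space coordinates).}
#' }
#' @export
simulate_linked_reads <- function(ref, derivatives = list(), params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (inherits(derivatives, "derivative_structure"))
    derivatives <- list(derivatives)
  rl <- ref_lengths(ref)
  for (d in derivatives) {
    stopifnot(inherits(d, "derivative_structure"))
    bad <- !(d$segments$chrom %in% names(rl)) |
      d$segments$end > rl[d$segments$chrom] | d$segments$start < 0
    if (any(bad))
      stop("derivative '", d$id, "' has segment(s) outside the reference")
  }
  if (anyDuplicated(vapply(derivatives, `[[`, "", "id")))
    stop("derivative ids must be unique")

  ## background = identity walk over each reference sequence
  units <- lapply(names(rl), function(chr) {
    list(id = paste0("background:", chr),
         segments = data.frame(chrom = chr, start = 0, end = rl[[chr]],
                               orient = "+", stringsAsFactors = FALSE),
         circular = FALSE, copies = params$background_ploidy)
  })
  units <- c(units, lapply(derivatives, function(d) {
    list(id = d$id, segments = d$segments, circular = d$circular,
         copies = d$copy_number)
  }))

  with_seed(params$seed, {
    mol_tabs <- lapply(units, simulate_unit_molecules, params = params)
    mols <- rbindlist(mol_tabs)
    mols[, molecule_id := sprintf("mol%07d", .I)]
    ## barcode assignment with optional collisions
    mols <- assign_barcodes(mols, params$barcode_collision_lambda)
    seg_maps <- setNames(lapply(units, function(u) segment_map(u$segments)),
                         vapply(units, `[[`, "", "id"))
    reads <- emit_reads(mols, seg_maps, params)
  })

  tj <- rbindlist(lapply(derivatives, truth_junctions), fill = TRUE)
  truth_bedpe <- if (nrow(tj)) data.frame(
    chrom1 = tj$chrom1, start1 = tj$pos1, end1 = tj$pos1 + 1,
    chrom2 = tj$chrom2, start2 = tj$pos2, end2 = tj$pos2 + 1,
    name = tj$name, svtype = tj$svtype,
    orient1 = tj$orient1, orient2 = tj$orient2,
    stringsAsFactors = FALSE) else data.frame(
    chrom1 = character(), start1 = numeric(), end1 = numeric(),
    chrom2 = character(), start2 = numeric(), end2 = numeric(),
    name = character(), svtype = character(),
    orient1 = character(), orient2 = character(), stringsAsFactors = FALSE)

  truth_cn <- truth_cn_table(rl, derivatives, params$background_ploidy)

  structure(list(reads = reads[], truth_junctions = truth_bedpe,
                 truth_cn = truth_cn, molecules = mols[],
                 params = params, ref_lengths = rl),
            class = "linked_sim")
}

#' @export
print.linked_sim <- function(x, ...) {
  cat(sprintf(
    "Linked-read simulation: %d reads, %d molecules, %d barcodes\n",
    nrow(x$reads), nrow(x$molecules), length(unique(x$molecules$barcode))))
  cat(sprintf("  truth junctions: %d; seed %d\n",
              nrow(x$truth_junctions), x$params$seed))
  invisible(x)
}

## molecules for one simulated unit (derivative or background walk).
## Molecules are drawn until the unit's read-pair budget (copies x
## target_coverage over its length) is met, with each molecule's expected
## pair count proportional to its own (clipped) length, so emitted depth
## tracks copy number even when molecule lengths are capped by a short
## derivative. Linear units use overhang-and-clip placement for uniform
## edge coverage; circular units wrap.
simulate_unit_molecules <- function(unit, params) {
  L <- sum(unit$segments$end - unit$segments$start)
  rl <- params$read_length
  lambda_pairs <- params$reads_per_molecule_median / 2
  needed_pairs <- unit$copies * params$target_coverage * L / (2 * rl)
  meanlog <- log(params$molecule_length_mean) -
    params$molecule_length_sdlog^2 / 2
  starts <- numeric(0); lens <- numeric(0)
  got <- 0
  chunk <- max(64L, ceiling(needed_pairs / lambda_pairs))
  while (got < needed_pairs) {
    len <- pmin(rlnorm(chunk, meanlog, params$molecule_length_sdlog), L)
    if (unit$circular) {
      s <- runif(chunk, 0, L)
    } else {
      s <- runif(chunk, -len, L)
      hi <- pmin(s + len, L)
      s <- pmax(s, 0)
      len <- hi - s
    }
    keep <- len >= 2 * rl
    s <- s[keep]; len <- len[keep]
    starts <- c(starts, s); lens <- c(lens, len)
    got <- got + sum(lambda_pairs * len / params$molecule_length_mean)
    chunk <- max(64L, ceiling((needed_pairs - got) /
                                lambda_pairs * 1.1))
  }
  cum <- cumsum(lambda_pairs * lens / params$molecule_length_mean)
  n <- which(cum >= needed_pairs)[1L]
  if (is.na(n)) n <- length(lens)
  data.table(source = unit$id, mol_start = floor(starts[seq_len(n)]),
             mol_len = floor(lens[seq_len(n)]), circular = unit$circular,
             unit_len = L)
}

assign_barcodes <- function(mols, lambda) {
  n <- nrow(mols)
  if (lambda <= 0) {
    mols[, barcode := sprintf("BX%07d-1", sample(n))]
    return(mols)
  }
  ord <- sample(n)  # random grouping of molecules into droplets
  sizes <- integer(0)
  total <- 0L
  while (total < n) {
    batch <- 1L + rpois(256L, lambda)
    sizes <- c(sizes, batch)
    total <- total + sum(batch)
  }
  sizes <- sizes[cumsum(sizes) - sizes < n]
  bc_idx <- rep(seq_along(sizes), sizes)[seq_len(n)]
  mols[ord, barcode := sprintf("BX%07d-1", bc_idx)]
  mols
}

## place read pairs on molecules and map derivative coordinates back to the
## reference; reads crossing a segment boundary (junction point) are dropped
emit_reads <- function(mols, seg_maps, params) {
  rl <- params$read_length
  lambda_pairs <- params$reads_per_molecule_median / 2
  n_pairs <- rpois(nrow(mols), lambda_pairs * mols$mol_len /
                     params$molecule_length_mean)
  mi <- rep(seq_len(nrow(mols)), n_pairs)
  if (!length(mi))
    return(empty_reads_table())
  frag <- pmax(round(rnorm(length(mi), params$insert_mean, params$insert_sd)),
               2 * rl)
  mstart <- mols$mol_start[mi]
  mlen <- mols$mol_len[mi]
  frag <- pmin(frag, mlen)
  fstart <- mstart + floor(runif(length(mi), 0, pmax(mlen - frag, 1e-9)))

  pairs <- data.table(
    mi = mi, source = mols$source[mi], barcode = mols$barcode[mi],
    molecule_id = mols$molecule_id[mi], circular = mols$circular[mi],
    unit_len = mols$unit_len[mi],
    a1 = fstart, b1 = fstart + rl, s1 = "+",
    a2 = fstart + frag - rl, b2 = fstart + frag, s2 = "-")
  pairs[, pair_id := sprintf("%s_p%06d", molecule_id, seq_len(.N)), by = mi]

  m1 <- map_to_reference(pairs$source, pairs$a1, pairs$b1, pairs$s1,
                         pairs$circular, pairs$unit_len, seg_maps)
  m2 <- map_to_reference(pairs$source, pairs$a2, pairs$b2, pairs$s2,
                         pairs$circular, pairs$unit_len, seg_maps)
  ok <- m1$ok & m2$ok
  if (!any(ok)) return(empty_reads_table())
  pairs <- pairs[ok]
  m1 <- lapply(m1, `[`, ok); m2 <- lapply(m2, `[`, ok)

  proper <- m1$chrom == m2$chrom & m1$strand != m2$strand &
    (pmax(m1$end, m2$end) - pmin(m1$pos, m2$pos)) <=
      params$insert_mean + 4 * params$insert_sd &
    ifelse(m1$pos <= m2$pos, m1$strand == "+", m2$strand == "+")

  half <- function(self, mate) data.table(
    read_id = pairs$pair_id, chrom = self$chrom, pos = self$pos,
    end = self$end, strand = self$strand, mapq = 60L,
    barcode = pairs$barcode, mate_chrom = mate$chrom, mate_pos = mate$pos,
    mate_strand = mate$strand, proper_pair = proper,
    molecule_id = pairs$molecule_id, source = pairs$source)
  reads <- rbind(half(m1, m2), half(m2, m1))
  setorder(reads, chrom, pos, end, read_id)
  reads
}

empty_reads_table <- function() {
  data.table(read_id = character(), chrom = character(), pos = numeric(),
             end = numeric(), strand = character(), mapq = integer(),
             barcode = character(), mate_chrom = character(),
             mate_pos = numeric(), mate_strand = character(),
             proper_pair = logical(), molecule_id = character(),
             source = character())
}

## vectorised mapping of derivative-space intervals [a,b) to reference
## coordinates; intervals spanning a segment boundary or the circular wrap
## point are flagged not-ok (junction-overlapping reads are dropped)
map_to_reference <- function(source, a, b, strand, circular, unit_len,
                             seg_maps) {
  n <- length(a)
  out <- list(chrom = character(n), pos = numeric(n), end = numeric(n),
              strand = character(n), ok = logical(n))
  wrap_cross <- circular & (floor(a / unit_len) != floor((b - 1) / unit_len))
  am <- ifelse(circular, a %% unit_len, a)
  for (src in unique(source)) {
    idx <- which(source == src & !wrap_cross)
    if (!length(idx)) next
    sm <- seg_maps[[src]]
    bounds <- c(sm$offset, sm$offset[nrow(sm)] + sm$width[nrow(sm)])
    seg <- findInterval(am[idx], bounds, rightmost.closed = FALSE)
    inside <- seg >= 1 & seg <= nrow(sm) &
      (am[idx] + (b[idx] - a[idx])) <= bounds[pmin(seg + 1L, length(bounds))]
    keep <- idx[inside]; segk <- seg[inside]
    if (!length(keep)) next
    rel_a <- am[keep] - sm$offset[segk]
    width <- b[keep] - a[keep]
    fwd <- sm$orient[segk] == "+"
    out$chrom[keep] <- sm$chrom[segk]
    out$pos[keep] <- ifelse(fwd, sm$start[segk] + rel_a,
                            sm$end[segk] - rel_a - width)
    out$end[keep] <- out$pos[keep] + width
    out$strand[keep] <- ifelse(fwd, strand[keep],
                               ifelse(strand[keep] == "+", "-", "+"))
    out$ok[keep] <- TRUE
  }
  out
}

## total copies per region: background ploidy everywhere, plus copy_number
## for each derivative segment footprint (multiplicity-aware)
truth_cn_table <- function(rl, derivatives, ploidy) {
  rows <- lapply(names(rl), function(chr) data.frame(
    region = sprintf("%s:0-%d", chr, rl[[chr]]), chrom = chr, start = 0,
    end = unname(rl[[chr]]), cn = ploidy, source = "background",
    stringsAsFactors = FALSE))
  for (d in derivatives) {
    seg <- unique(d$segments[c("chrom", "start", "end")])
    mult <- vapply(seq_len(nrow(seg)), function(i) {
      sum(d$segments$chrom == seg$chrom[i] & d$segments$start == seg$start[i] &
            d$segments$end == seg$end[i])
    }, integer(1L))
    rows[[length(rows) + 1L]] <- data.frame(
      region = sprintf("%s:%d-%d", seg$chrom, as.integer(seg$start),
                       as.integer(seg$end)),
      chrom = seg$chrom, start = seg$start, end = seg$end,
      cn = ploidy + d$copy_number * mult, source = d$id,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
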