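#' Breakend helpers and SV type classification
#'
#' A breakend is `(chrom, pos, orient)`: orientation `"+"` means the
#' retained segment extends toward lower coordinates (the breakpoint sits
#' at the segment's right end); `"-"` means it extends toward higher
#' coordinates. After canonical ordering (lower chrom/pos first) the
#' orientation pair determines the SV class: different chromosomes give a
#' translocation (TRA); `(+,-)` a deletion-type adjacency (DEL); `(-,+)` a
#' tandem-duplication-type adjacency (DUP); `(+,+)` or `(-,-)` an
#' inversion-type adjacency (INV).
#'
#' @param be1,be2 breakends as lists with `chrom`, `pos`, `orient`.
#' @return `classify_sv_type()`: one of `"DEL"`, `"DUP"`, `"INV"`, `"TRA"`.
#'   `canonical_breakends()`: `list(be1, be2)` in canonical order.
#' @examples
#' classify_sv_type(list(chrom = "chr1", pos = 10000, orient = "+"),
#'                  list(chrom = "chr1", pos = 20000, orient = "-"))
#' @export
classify_sv_type <- function(be1, be2) {
  if (be1$chrom != be2$chrom) return("TRA")
  key <- paste0(be1$orient, be2$orient)
  switch(key, "+-" = "DEL", "-+" = "DUP", "++" = "INV", "--" = "INV",
         stop("invalid breakend orientations: ", key))
}

#' @rdname classify_sv_type
#' @export
canonical_breakends <- function(be1, be2) {
  swap <- (be2$chrom < be1$chrom) ||
    (be2$chrom == be1$chrom && be2$pos < be1$pos)
  if (swap) list(be1 = be2, be2 = be1) else list(be1 = be1, be2 = be2)
}

#' Seed breakend candidates from discordant read pairs
#'
#' A pair is discordant when its mates map to different chromosomes, their
#' same-chromosome span exceeds `max_insert`, or their orientations violate
#' the forward-reverse (FR) convention. Each discordant pair contributes a
#' breakend signature: a read on the `+` strand points at a junction to its
#' right (breakend orientation `+`), a `-`-strand read at a junction to its
#' left (orientation `-`). Pairs with matching signature whose two sides
#' each fall within `cluster_tol` are clustered; clusters with at least
#' `min_pairs` pairs become candidates, positioned at the outermost read
#' ends toward the junction.
#'
#' @param reads alignment table carrying mate columns.
#' @param max_insert maximum proper-pair span (bp).
#' @param cluster_tol clustering tolerance (bp).
#' @param min_pairs minimum discordant pairs per candidate (default 2).
#' @return data.frame of candidates: `chrom1, pos1, orient1, chrom2, pos2,
#'   orient2, n_pairs`, breakends canonically ordered.
#' @export
find_discordant_candidates <- function(reads, max_insert = 2000,
                                       cluster_tol = 500, min_pairs = 2L) {
  dt <- as_reads_table(reads)
  empty <- data.frame(chrom1 = character(), pos1 = numeric(),
                      orient1 = character(), chrom2 = character(),
                      pos2 = numeric(), orient2 = character(),
                      n_pairs = integer(), stringsAsFactors = FALSE)
  need <- c("mate_chrom", "mate_pos", "mate_strand")
  if (!all(need %in% names(dt))) stop("reads lack mate information columns")
  dt <- dt[!is.na(mate_chrom) & !is.na(mate_pos)]
  if (!nrow(dt)) return(empty)
  ## keep one record per pair: the side that sorts lower
  lower <- dt$chrom < dt$mate_chrom |
    (dt$chrom == dt$mate_chrom &
       (dt$pos < dt$mate_pos |
          (dt$pos == dt$mate_pos & dt$strand == "+")))
  dt <- unique(dt[lower], by = "read_id")
  if (!nrow(dt)) return(empty)

  rlen <- dt$end - dt$pos
  span <- pmax(dt$mate_pos + rlen, dt$end) - dt$pos
  fr_ok <- dt$chrom == dt$mate_chrom & dt$strand == "+" &
    dt$mate_strand == "-"
  disc <- dt$chrom != dt$mate_chrom | span > max_insert | !fr_ok
  dd <- dt[disc]
  if (!nrow(dd)) return(empty)

  dd[, `:=`(orient1 = strand, orient2 = mate_strand,
            mate_end = mate_pos + (end - pos))]
  setorder(dd, chrom, mate_chrom, orient1, orient2, pos, mate_pos)
  dd[, sig := paste(chrom, mate_chrom, orient1, orient2, sep = "|")]
  dd[, cluster := {
    jump1 <- c(TRUE, diff(pos) > cluster_tol)
    jump2 <- c(TRUE, abs(diff(mate_pos)) > cluster_tol)
    cumsum(jump1 | jump2)
  }, by = sig]

  cand <- dd[, .(
    chrom1 = chrom[1L],
    pos1 = if (orient1[1L] == "+") max(end) else min(pos),
    orient1 = orient1[1L],
    chrom2 = mate_chrom[1L],
    pos2 = if (orient2[1L] == "+") max(mate_end) else min(mate_pos),
    orient2 = orient2[1L],
    n_pairs = .N), by = .(sig, cluster)]
  cand <- cand[n_pairs >= min_pairs]
  if (!nrow(cand)) return(empty)
  ## canonical ordering of the two breakends
  swap <- cand$chrom2 < cand$chrom1 |
    (cand$chrom2 == cand$chrom1 & cand$pos2 < cand$pos1)
  if (any(swap)) {
    tmp <- cand[swap, .(chrom1, pos1, orient1)]
    cand[swap, `:=`(chrom1 = chrom2, pos1 = pos2, orient1 = orient2)]
    cand[swap, `:=`(chrom2 = tmp$chrom1, pos2 = tmp$pos1,
                    orient2 = tmp$orient1)]
  }
  out <- as.data.frame(cand[, .(chrom1, pos1, orient1, chrom2, pos2,
                                orient2, n_pairs)])
  out[order(out$chrom1, out$pos1, out$chrom2, out$pos2), , drop = FALSE]
}

#' Collect barcoded split molecules supporting a candidate junction
#'
#' A split molecule is a pair of same-barcode reconstructed molecules whose
#' qualifying ends flank the candidate breakends: for a `+` breakend the
#' molecule's right end must lie within `w` of the breakend position, for a
#' `-` breakend its left end. One link is emitted per barcode per
#' candidate (barcodes, not fragments, are the unit of support).
#'
#' @param molecules a `molecule_set` (see [reconstruct_molecules()]).
#' @param candidate one candidate: list or single-row data.frame with
#'   `chrom1, pos1, orient1, chrom2, pos2, orient2`.
#' @param w matching window (bp); by convention defaults to the gap
#'   parameter `d` used to build the molecules.
#' @param guard terminality guard (bp), `NULL` for the default described
#'   below: a fragment only qualifies when its barcode has no other
#'   fragment just beyond the breakend (within `guard` on the junction
#'   side). A molecule that was merely fractured by a within-molecule read
#'   gap continues past the breakend and is rejected; a molecule that
#'   truly ends at the junction does not. By default the guard reaches
#'   `max(2w, 20 kb)` but never closer than `w` to the partner breakend,
#'   so junctions spanning less than about `2w` are left unguarded (and
#'   are better recovered at a smaller `d`).
#' @return data.frame with one row per supporting barcode: `barcode, mol1,
#'   mol2`.
#' @export
collect_split_molecules <- function(molecules, candidate, w, guard = NULL) {
  if (!(is.numeric(w) && length(w) == 1L && w > 0))
    stop("w must be a single positive number")
  cand <- as.list(as.data.frame(candidate)[1L, ])
  mols <- as.data.table(molecules)
  same_chrom <- cand$chrom1 == cand$chrom2
  span <- if (same_chrom) abs(cand$pos2 - cand$pos1) else Inf
  if (is.null(guard)) {
    guard <- max(2 * w, min(20000, span / 2))
    guard <- max(min(guard, span - w), 0)
  }
  side <- function(chrom_c, pos_c, orient_c) {
    on_chrom <- mols$chrom == chrom_c
    qual <- if (orient_c == "+") mols$end else mols$start
    hit <- on_chrom & abs(qual - pos_c) <= w
    ## barcodes whose coverage continues past the breakend on the junction
    ## side cannot have had a molecule terminating there: reject fragments
    ## starting inside the guard zone or extending through it
    beyond <- if (orient_c == "+")
      on_chrom & ((mols$start > pos_c & mols$start <= pos_c + guard) |
                    (mols$end > pos_c + w & mols$start <= pos_c + guard))
    else
      on_chrom & ((mols$end < pos_c & mols$end >= pos_c - guard) |
                    (mols$start < pos_c - w & mols$end >= pos_c - guard))
    list(hits = mols[hit, .(barcode, molecule)],
         bad = unique(mols$barcode[beyond]))
  }
  s1 <- side(cand$chrom1, cand$pos1, cand$orient1)
  s2 <- side(cand$chrom2, cand$pos2, cand$orient2)
  t1 <- s1$hits[!barcode %in% union(s1$bad, s2$bad)]
  t2 <- s2$hits[!barcode %in% union(s1$bad, s2$bad)]
  setnames(t1, "molecule", "mol1"); setnames(t2, "molecule", "mol2")
  if (!nrow(t1) || !nrow(t2))
    return(data.frame(barcode = character(), mol1 = character(),
                      mol2 = character(), stringsAsFactors = FALSE))
  links <- merge(t1, t2, by = "barcode", allow.cartesian = TRUE)
  links <- links[mol1 != mol2]
  links <- links[, .SD[1L], by = barcode]  # one link per barcode
  as.data.frame(links[order(barcode)])
}

#' Call structural variants from barcoded linked reads
#'
#' For each gap parameter in `d_values`: reconstruct molecules, seed
#' candidates from discordant read pairs, count barcoded split molecules
#' within window `w` of each candidate's breakends, and keep candidates
#' with at least `min_support` split molecules. Per-d call sets are then
#' unified with [merge_calls_across_d()]. The split-molecule support rule
#' (default: at least 5) is the final inclusion filter.
#'
#' @inheritParams find_discordant_candidates
#' @param d_values gap parameters (bp) to run; default `c(1000, 5000,
#'   10000)`.
#' @param w split-molecule matching window; `NULL` (default) uses each `d`.
#' @param min_support minimum barcoded split molecules per call (default 5).
#' @param merge_tol breakend tolerance (bp) when unifying calls across
#'   `d_values` (default 1000).
#' @param min_reads_per_molecule passed to [reconstruct_molecules()].
#' @return an `sv_call_set`: data.table with one row per call (`name,
#'   chrom1, pos1, orient1, chrom2, pos2, orient2, svtype,
#'   split_molecule_count`, list-columns `support_barcodes`, `d_params`).
#' @export
call_svs <- function(reads, d_values = c(1000, 5000, 10000), w = NULL,
                     min_support = 5L, max_insert = 2000, cluster_tol = 500,
                     min_pairs = 2L, merge_tol = 1000,
                     min_reads_per_molecule = 2L) {
  if (!length(d_values)) stop("d_values must be non-empty")
  dt <- as_reads_table(reads)
  candidates <- find_discordant_candidates(dt, max_insert = max_insert,
                                           cluster_tol = cluster_tol,
                                           min_pairs = min_pairs)
  per_d <- lapply(d_values, function(d) {
    mols <- reconstruct_molecules(dt, d = d,
                                  min_reads_per_molecule = min_reads_per_molecule)
    calls_for_d(mols, candidates, w %||% d, min_support, d)
  })
  merged <- merge_calls_across_d(per_d, tol = merge_tol)
  merged
}

calls_for_d <- function(mols, candidates, w, min_support, d) {
  if (!nrow(candidates)) return(empty_sv_call_set())
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, , drop = FALSE]
    links <- collect_split_molecules(mols, cand, w)
    n <- length(unique(links$barcode))
    if (n < min_support) return(NULL)
    be1 <- list(chrom = cand$chrom1, pos = cand$pos1, orient = cand$orient1)
    be2 <- list(chrom = cand$chrom2, pos = cand$pos2, orient = cand$orient2)
    data.table(chrom1 = cand$chrom1, pos1 = cand$pos1, orient1 = cand$orient1,
               chrom2 = cand$chrom2, pos2 = cand$pos2, orient2 = cand$orient2,
               svtype = classify_sv_type(be1, be2),
               split_molecule_count = n,
               support_barcodes = list(sort(unique(links$barcode))),
               d_params = list(d))
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(empty_sv_call_set())
  as_sv_call_set(rbindlist(rows))
}

#' Merge SV calls across gap parameters
#'
#' Calls with identical SV type and chromosomes whose breakends fall
#' within `tol` are unified by transitive closure. Merged breakend
#' positions are support-weighted medians (ties resolved toward the lower
#' coordinate); supporting barcode sets and the d-parameter provenance are
#' unioned, so support never decreases under merging.
#'
#' @param call_sets list of `sv_call_set` objects (one per d).
#' @param tol breakend tolerance in bp (default 1000).
#' @return a single merged `sv_call_set`.
#' @export
merge_calls_across_d <- function(call_sets, tol = 1000) {
  if (inherits(call_sets, "sv_call_set")) call_sets <- list(call_sets)
  all_calls <- rbindlist(lapply(call_sets, as.data.table), fill = TRUE)
  if (!nrow(all_calls)) return(empty_sv_call_set())
  if ("name" %in% names(all_calls)) all_calls[, name := NULL]
  key <- paste(all_calls$svtype, all_calls$chrom1, all_calls$chrom2,
               all_calls$orient1, all_calls$orient2, sep = "|")
  groups <- split(seq_len(nrow(all_calls)), key)
  merged <- list()
  for (idx in groups) {
    sub <- all_calls[idx]
    comp <- transitive_clusters(sub$pos1, sub$pos2, tol)
    for (cid in unique(comp)) {
      s <- sub[comp == cid]
      w <- s$split_molecule_count
      barcodes <- sort(unique(unlist(s$support_barcodes)))
      merged[[length(merged) + 1L]] <- data.table(
        chrom1 = s$chrom1[1L],
        pos1 = weighted_median_low(s$pos1, w),
        orient1 = s$orient1[1L],
        chrom2 = s$chrom2[1L],
        pos2 = weighted_median_low(s$pos2, w),
        orient2 = s$orient2[1L],
        svtype = s$svtype[1L],
        split_molecule_count = length(barcodes),
        support_barcodes = list(barcodes),
        d_params = list(sort(unique(unlist(s$d_params)))))
    }
  }
  out <- rbindlist(merged)
  setorder(out, chrom1, pos1, chrom2, pos2, svtype)
  as_sv_call_set(out)
}

## transitive closure over pairs with both coordinates within tol
transitive_clusters <- function(pos1, pos2, tol) {
  n <- length(pos1)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (abs(pos1[i] - pos1[j]) <= tol && abs(pos2[i] - pos2[j]) <= tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1L))
}

empty_sv_call_set <- function() {
  as_sv_call_set(data.table(
    chrom1 = character(), pos1 = numeric(), orient1 = character(),
    chrom2 = character(), pos2 = numeric(), orient2 = character(),
    svtype = character(), split_molecule_count = integer(),
    support_barcodes = list(), d_params = list()))
}

as_sv_call_set <- function(dt) {
  dt <- as.data.table(dt)
  if (!"name" %in% names(dt))
    dt[, name := if (.N) sprintf("sv%03d", seq_len(.N)) else character()]
  setcolorder(dt, c("name", "chrom1", "pos1", "orient1", "chrom2", "pos2",
                    "orient2", "svtype", "split_molecule_count",
                    "support_barcodes", "d_params"))
  if (!inherits(dt, "sv_call_set"))
    setattr(dt, "class", c("sv_call_set", class(dt)))
  dt[]
}

#' @export
print.sv_call_set <- function(x, ...) {
  cat(sprintf("SV call set: %d call(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- as.data.table(x)[, .(
      name, svtype,
      be1 = sprintf("%s:%d(%s)", chrom1, as.integer(pos1), orient1),
      be2 = sprintf("%s:%d(%s)", chrom2, as.integer(pos2), orient2),
      split_molecules = split_molecule_count,
      d = vapply(d_params, function(d) paste(d, collapse = ","), ""))]
    print(show, nrows = 20)
  }
  invisible(x)
}

#' @export
summary.sv_call_set <- function(object, ...) {
  tab <- table(factor(object$svtype, levels = c("DEL", "DUP", "INV", "TRA")))
  structure(list(n_calls = nrow(object), by_type = tab,
                 support = if (nrow(object))
                   summary(object$split_molecule_count) else NULL),
            class = "summary.sv_call_set")
}

#' @export
print.summary.sv_call_set <- function(x, ...) {
  cat(sprintf("%d SV call(s): %s\n", x$n_calls,
              paste(sprintf("%s=%d", names(x$by_type), x$by_type),
                    collapse = " ")))
  if (!is.null(x$support)) {
    cat("split-molecule support:\n")
    print(x$support)
  }
  invisible(x)
}
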