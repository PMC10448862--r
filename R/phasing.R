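#' Phase SV calls into shared-barcode networks
#'
#' Two SV calls are phased when their supporting split molecules share at
#' least `min_shared` barcodes: the shared barcode implies both novel
#' adjacencies were spanned by molecules from one droplet, i.e. they
#' co-reside on one HMW DNA molecule (for example one ecDNA amplicon).
#' The phase network has one node per call, an edge wherever the barcode
#' intersection reaches `min_shared`, and connected components as the
#' phased groups; singleton components are flagged `unlinked`.
#'
#' @param calls an `sv_call_set` (see [call_svs()]), or any data.frame with
#'   columns `name`, `svtype` and list-column `support_barcodes`.
#' @param min_shared minimum shared barcodes per edge (default 1, matching
#'   the "at least one other split molecule with the same barcode"
#'   criterion; raise when barcode collisions are a concern).
#' @return object of class `phase_network`: list with `nodes` (data.frame
#'   incl. `component` and `unlinked`), `edges` (data.frame `a, b,
#'   n_shared` and list-column `shared`), `components` (list of node-id
#'   vectors) and `min_shared`.
#' @export
phase_svs <- function(calls, min_shared = 1L) {
  calls <- as.data.table(calls)
  n <- nrow(calls)
  edges <- data.frame(a = character(), b = character(),
                      n_shared = integer(), stringsAsFactors = FALSE)
  edges$shared <- list()
  if (n > 1L) {
    rows <- list()
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        shared <- intersect(calls$support_barcodes[[i]],
                            calls$support_barcodes[[j]])
        if (length(shared) >= min_shared) {
          rows[[length(rows) + 1L]] <- list(a = calls$name[i],
                                            b = calls$name[j],
                                            n_shared = length(shared),
                                            shared = list(shared))
        }
      }
    }
    if (length(rows)) {
      edges <- data.frame(a = vapply(rows, `[[`, "", "a"),
                          b = vapply(rows, `[[`, "", "b"),
                          n_shared = vapply(rows, `[[`, 0L, "n_shared"),
                          stringsAsFactors = FALSE)
      edges$shared <- lapply(rows, function(r) r$shared[[1L]])
    }
  }
  g <- igraph::graph_from_data_frame(edges[c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = calls$name))
  comp <- igraph::components(g)
  membership <- comp$membership[calls$name]
  components <- split(calls$name, membership)
  names(components) <- NULL
  components <- components[order(-lengths(components))]
  comp_map <- setNames(rep(seq_along(components), lengths(components)),
                       unlist(components))
  comp_rank <- unname(comp_map[calls$name])
  nodes <- data.frame(
    id = calls$name, svtype = calls$svtype,
    chrom1 = calls$chrom1, pos1 = calls$pos1, orient1 = calls$orient1,
    chrom2 = calls$chrom2, pos2 = calls$pos2, orient2 = calls$orient2,
    support = calls$split_molecule_count,
    component = if (n) comp_rank else integer(),
    stringsAsFactors = FALSE)
  nodes$unlinked <- if (n) lengths(components)[nodes$component] == 1L else
    logical()
  structure(list(nodes = nodes, edges = edges, components = components,
                 min_shared = as.integer(min_shared)),
            class = "phase_network")
}

#' @export
print.phase_network <- function(x, ...) {
  sizes <- lengths(x$components)
  cat(sprintf(
    "Phase network: %d SV call(s), %d edge(s), %d component(s)%s\n",
    nrow(x$nodes), nrow(x$edges), length(x$components),
    if (length(sizes)) paste0(" (sizes ",
                              paste(sort(sizes, decreasing = TRUE),
                                    collapse = ", "), ")") else ""))
  n_unlinked <- sum(x$nodes$unlinked)
  if (n_unlinked) cat(sprintf("  %d unlinked call(s)\n", n_unlinked))
  invisible(x)
}

#' @export
summary.phase_network <- function(object, ...) {
  summarize_phasing(object)
}

#' @export
plot.phase_network <- function(x, ...) {
  g <- igraph::graph_from_data_frame(
    x$edges[c("a", "b")], directed = FALSE,
    vertices = data.frame(name = x$nodes$id, svtype = x$nodes$svtype))
  pal <- c(DEL = "#D55E00", DUP = "#0072B2", INV = "#009E73",
           TRA = "#CC79A7")
  igraph::plot.igraph(
    g, vertex.color = pal[x$nodes$svtype],
    vertex.label = x$nodes$id,
    edge.label = if (nrow(x$edges)) x$edges$n_shared else NULL, ...)
  invisible(x)
}

#' Barcode overlap between SNV-supporting reads and an SV call
#'
#' Returns the barcodes present both among the reads supporting an SNV and
#' in the SV call's split-molecule support set. An empty result is the
#' meaningful "zero overlap" outcome: the SNV-bearing molecules and the
#' rearranged molecules were partitioned in different droplets, i.e. there
#' is no evidence they co-reside.
#'
#' @param snv_supporting_reads alignment table (or character vector of
#'   barcodes) for the reads carrying the alternate allele.
#' @param call a single SV call (one row of an `sv_call_set`).
#' @return character vector of shared barcodes (possibly empty).
#' @export
snv_sv_barcode_overlap <- function(snv_supporting_reads, call) {
  bcs <- if (is.character(snv_supporting_reads)) snv_supporting_reads
  else as_reads_table(snv_supporting_reads)$barcode
  call <- as.data.table(call)
  support <- unlist(call$support_barcodes)
  sort(intersect(unique(bcs), support))
}

#' Per-sample phasing flags
#'
#' Reduces a phase network (plus optionally a copy-number estimate) to the
#' per-sample flags consumed by the cohort-level association tests.
#'
#' @param network a [phase_network].
#' @param cn_table optional [cn_estimate] or data.frame with columns `cn`
#'   and `high_cn`; copied into the flags when given.
#' @return list with `has_sv`, `has_phased_sv`, `n_svs`, `n_phased`,
#'   `max_component`, and when `cn_table` is given also `cn`, `high_cn`.
#' @export
summarize_phasing <- function(network, cn_table = NULL) {
  stopifnot(inherits(network, "phase_network"))
  sizes <- lengths(network$components)
  out <- list(
    has_sv = nrow(network$nodes) > 0L,
    has_phased_sv = any(sizes >= 2L),
    n_svs = nrow(network$nodes),
    n_phased = sum(sizes[sizes >= 2L]),
    max_component = if (length(sizes)) max(sizes) else 0L)
  if (!is.null(cn_table)) {
    cn_table <- as.list(as.data.frame(cn_table)[1L, , drop = FALSE])
    out$cn <- cn_table$cn
    out$high_cn <- isTRUE(cn_table$high_cn)
  }
  out
}
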