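test_that("breakend orientation pairs map to SV classes", {
  be <- function(chrom, pos, orient) list(chrom = chrom, pos = pos,
                                          orient = orient)
  expect_equal(classify_sv_type(be("chr1", 10000, "+"),
                                be("chr1", 20000, "-")), "DEL")
  expect_equal(classify_sv_type(be("chr1", 10000, "-"),
                                be("chr1", 20000, "+")), "DUP")
  expect_equal(classify_sv_type(be("chr1", 10000, "+"),
                                be("chr1", 20000, "+")), "INV")
  expect_equal(classify_sv_type(be("chr1", 10000, "-"),
                                be("chr1", 20000, "-")), "INV")
  expect_equal(classify_sv_type(be("chr1", 10000, "+"),
                                be("chr2", 500, "-")), "TRA")
  cb <- canonical_breakends(be("chr2", 500, "-"), be("chr1", 10000, "+"))
  expect_equal(cb$be1$chrom, "chr1")
  cb <- canonical_breakends(be("chr1", 9000, "+"), be("chr1", 2000, "-"))
  expect_equal(cb$be1$pos, 2000)
})

test_that("discordant pairs seed clustered breakend candidates", {
  ## textbook deletion signature: three +/- pairs ~50 kb apart
  rows <- do.call(rbind, lapply(1:3, function(i)
    mk_pair(sprintf("p%d", i), sprintf("BX%d", i), "chr1", 9700 + 20 * i,
            "+", "chr1", 60000 + 15 * i, "-")))
  cand <- find_discordant_candidates(sort_reads(rows), max_insert = 2000)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$orient1, "+"); expect_equal(cand$orient2, "-")
  expect_lt(abs(cand$pos1 - 10000), 500)
  expect_lt(abs(cand$pos2 - 60000), 500)
  expect_equal(cand$n_pairs, 3L)
  ## proper pairs only: empty candidate set
  proper <- sort_reads(rbind(
    mk_pair("q1", "BXa", "chr1", 1000, "+", "chr1", 1400, "-"),
    mk_pair("q2", "BXb", "chr1", 3000, "+", "chr1", 3350, "-")))
  expect_equal(nrow(find_discordant_candidates(proper)), 0L)
})

test_that("a simulated deletion yields one candidate at the truth breakends", {
  del <- derivative_structure("del8", data.frame(
    chrom = "chrXsim", start = c(0, 20000), end = c(10000, 30000),
    orient = c("+", "+")), copy_number = 8)
  sim <- simulate_linked_reads(sim_ref(), list(del), sim_params(seed = 17))
  cand <- find_discordant_candidates(sim$reads, max_insert = 2000,
                                     cluster_tol = 500, min_pairs = 2)
  expect_equal(nrow(cand), 1L)
  expect_lt(abs(cand$pos1 - 10000), 500)
  expect_lt(abs(cand$pos2 - 20000), 500)
})

test_that("split-molecule links require flanking molecule ends within w", {
  mols <- reconstruct_molecules(sort_reads(rbind(
    mk_molecule_reads("BXs", "chr1", c(9000, 9750), prefix = "a"),
    mk_molecule_reads("BXs", "chr1", c(20050, 20500), prefix = "b"),
    mk_molecule_reads("BXfar", "chr1", c(9100, 9750), prefix = "c"),
    mk_molecule_reads("BXfar", "chr1", c(35000, 35400), prefix = "d"))),
    d = 5000)
  cand <- data.frame(chrom1 = "chr1", pos1 = 10000, orient1 = "+",
                     chrom2 = "chr1", pos2 = 20000, orient2 = "-",
                     stringsAsFactors = FALSE)
  links <- collect_split_molecules(mols, cand, w = 1000)
  expect_equal(links$barcode, "BXs")  # BXfar's second molecule is 15 kb off
  expect_error(collect_split_molecules(mols, cand, w = 0), "positive")
})

test_that("the five-split-molecule support rule is a sharp boundary", {
  ## 4 junction-spanning barcodes: no call
  calls4 <- call_svs_quiet(mk_boundary_fixture(4), min_support = 5)
  expect_equal(nrow(calls4), 0L)
  ## 5 junction-spanning barcodes: exactly one deletion call
  calls5 <- call_svs_quiet(mk_boundary_fixture(5), min_support = 5)
  expect_equal(nrow(calls5), 1L)
  expect_equal(calls5$svtype, "DEL")
  expect_equal(calls5$split_molecule_count, 5L)
  expect_equal(sort(unlist(calls5$d_params)), c(1000, 5000, 10000))
  ## an unrearranged read set yields nothing
  quiet <- sort_reads(rbind(
    mk_pair("q1", "BXa", "chr1", 1000, "+", "chr1", 1400, "-"),
    mk_pair("q2", "BXa", "chr1", 2000, "+", "chr1", 2350, "-")))
  expect_equal(nrow(call_svs_quiet(quiet)), 0L)
  expect_error(call_svs_quiet(quiet, d_values = numeric()), "d_values")
})

test_that("calls are invariant to input read order", {
  fix <- mk_boundary_fixture(6)
  shuffled <- fix[sample.int(nrow(fix)), ]
  a <- call_svs_quiet(fix)
  b <- call_svs_quiet(shuffled)
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
})

test_that("cross-d merging unions support and matches a closure oracle", {
  mk_call <- function(pos1, pos2, svtype, support, d) {
    data.table::data.table(
      chrom1 = "chr1", pos1 = pos1, orient1 = "+", chrom2 = "chr1",
      pos2 = pos2, orient2 = "-", svtype = svtype,
      split_molecule_count = length(support),
      support_barcodes = list(support), d_params = list(d))
  }
  ## identical call from three d values collapses to one
  sets <- lapply(c(1000, 5000, 10000), function(d)
    linkphase:::as_sv_call_set(mk_call(10000, 20000, "DEL",
                                       c("b1", "b2", "b3", "b4", "b5"), d)))
  m <- merge_calls_across_d(sets, tol = 1000)
  expect_equal(nrow(m), 1L)
  expect_equal(m$d_params[[1]], c(1000, 5000, 10000))
  expect_equal(m$split_molecule_count, 5L)
  ## two deletions 50 kb apart stay separate
  two <- linkphase:::as_sv_call_set(rbind(
    mk_call(10000, 20000, "DEL", c("b1", "b2"), 1000),
    mk_call(60000, 70000, "DEL", c("b3"), 1000)))
  expect_equal(nrow(merge_calls_across_d(list(two), tol = 1000)), 2L)
  ## support never decreases under merging (union of barcode sets)
  partial <- list(
    linkphase:::as_sv_call_set(mk_call(10000, 20000, "DEL",
                                       c("b1", "b2"), 1000)),
    linkphase:::as_sv_call_set(mk_call(10400, 20300, "DEL",
                                       c("b2", "b3", "b4"), 5000)))
  mm <- merge_calls_across_d(partial, tol = 1000)
  expect_equal(nrow(mm), 1L)
  expect_equal(mm$split_molecule_count, 4L)
  expect_setequal(mm$support_barcodes[[1]], c("b1", "b2", "b3", "b4"))

  ## 100 random jittered duplicates: merged set equals brute-force
  ## transitive-closure clustering
  set.seed(42)
  centers <- data.frame(p1 = sample.int(1e6, 12), p2 = sample.int(1e6, 12))
  n <- 100
  pick <- sample.int(12, n, replace = TRUE)
  jit <- function(x) x + sample(-600:600, n, replace = TRUE)
  calls <- linkphase:::as_sv_call_set(data.table::rbindlist(
    lapply(seq_len(n), function(i) mk_call(
      jit(centers$p1[pick])[i], jit(centers$p2[pick])[i], "DEL",
      sprintf("bc%03d", i), 1000))))
  got <- merge_calls_across_d(list(calls), tol = 1000)
  ## oracle: BFS over the full pairwise adjacency
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    abs(calls$pos1[i] - calls$pos1[j]) <= 1000 &
      abs(calls$pos2[i] - calls$pos2[j]) <= 1000)
  comp <- rep(NA_integer_, n); k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  expect_equal(nrow(got), length(unique(comp)))
  ## every merged call's support is exactly one oracle component
  oracle_sets <- lapply(split(seq_len(n), comp), function(ix)
    sort(sprintf("bc%03d", ix)))
  got_sets <- lapply(got$support_barcodes, sort)
  expect_setequal(
    vapply(got_sets, paste, "", collapse = ","),
    vapply(oracle_sets, paste, "", collapse = ","))
})

test_that("simulated multi-junction derivatives are recovered exactly", {
  sim <- simulate_linked_reads(sim_ref(), list(ecdna_derivative()),
                               sim_params(seed = 23))
  calls <- call_svs_quiet(sim$reads)
  truth <- sim$truth_junctions
  expect_equal(nrow(calls), 3L)
  hits <- match_calls_to_truth(calls, truth, tol = 1000)
  expect_true(all(!is.na(hits)))
  expect_equal(sort(hits), 1:3)
  expect_equal(calls$svtype, truth$svtype[hits])
})

test_that("lower copy number lowers split-molecule support in expectation", {
  support_at <- function(cn, seed) {
    sim <- simulate_linked_reads(
      sim_ref(), list(ecdna_derivative(copy_number = cn)),
      sim_params(seed = seed))
    calls <- call_svs_quiet(sim$reads, d_values = 10000)
    mean(calls$split_molecule_count)
  }
  hi <- mean(vapply(1:3, function(s) support_at(8, s), numeric(1L)))
  lo <- mean(vapply(1:3, function(s) support_at(3, s), numeric(1L)))
  expect_gt(hi, lo)
})
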