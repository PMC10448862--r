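test_that("reference generation is deterministic and validated", {
  spec <- data.frame(name = "chrXtoy", length = 5000, seed = 7)
  a <- make_reference(spec)
  b <- make_reference(spec)
  expect_identical(as.character(a), as.character(b))
  expect_named(a, "chrXtoy")
  two <- make_reference(data.frame(name = c("a", "b"),
                                   length = c(10000, 20000)))
  expect_equal(unname(Biostrings::width(two)), c(10000, 20000))
  expect_error(make_reference(data.frame(name = c("a", "a"),
                                         length = c(10000, 20000))),
               "duplicate")
  expect_error(make_reference(data.frame(name = "tiny", length = 500)),
               "1 kb")
})

test_that("derivative structures are validated", {
  expect_error(derivative_structure("x", data.frame(
    chrom = "c", start = 10, end = 5, orient = "+")), "start")
  expect_error(derivative_structure("x", data.frame(
    chrom = "c", start = 0, end = 5, orient = "*")), "orient")
  expect_error(derivative_structure("x", data.frame(
    chrom = "c", start = 0, end = 5, orient = "+"), copy_number = 0),
    "copy_number")
})

test_that("truth junctions encode the breakend orientation conventions", {
  ## skipped middle segment: deletion-type adjacency
  del <- derivative_structure("d", data.frame(
    chrom = "chr1", start = c(0, 20000), end = c(10000, 30000),
    orient = c("+", "+")))
  j <- truth_junctions(del)
  expect_equal(nrow(j), 1L)
  expect_equal(j$pos1, 10000); expect_equal(j$orient1, "+")
  expect_equal(j$pos2, 20000); expect_equal(j$orient2, "-")
  expect_equal(j$svtype, "DEL")

  ## head-to-head: inversion-type adjacency
  inv <- derivative_structure("i", data.frame(
    chrom = "chr1", start = c(0, 10000), end = c(10000, 20000),
    orient = c("+", "-")))
  j <- truth_junctions(inv)
  expect_equal(nrow(j), 1L)
  expect_equal(j$pos1, 10000); expect_equal(j$orient1, "+")
  expect_equal(j$pos2, 20000); expect_equal(j$orient2, "+")
  expect_equal(j$svtype, "INV")

  ## single-segment circle wrap: tandem-duplication-type adjacency
  circ <- derivative_structure("c", data.frame(
    chrom = "chr1", start = 0, end = 10000, orient = "+"), circular = TRUE)
  j <- truth_junctions(circ)
  expect_equal(nrow(j), 1L)
  expect_equal(j$pos1, 0); expect_equal(j$orient1, "-")
  expect_equal(j$pos2, 10000); expect_equal(j$orient2, "+")
  expect_equal(j$svtype, "DUP")
})

test_that("reference-adjacent compatible segments yield no junction", {
  ident <- derivative_structure("id", data.frame(
    chrom = "chr1", start = c(0, 10000, 20000),
    end = c(10000, 20000, 30000), orient = "+"))
  expect_equal(nrow(truth_junctions(ident)), 0L)
  ## junction count: |segments| - 1 (+1 if circular) minus trivial ones
  mixed <- derivative_structure("m", data.frame(
    chrom = "chr1", start = c(0, 10000, 50000),
    end = c(10000, 20000, 60000), orient = "+"), circular = TRUE)
  expect_equal(nrow(truth_junctions(mixed)), 2L)  # one trivial adjacency
})

test_that("an unrearranged simulation has no junctions and one molecule per barcode", {
  sim <- simulate_linked_reads(c(chr1 = 100000), list(),
                               sim_params(seed = 11, target_coverage = 20))
  expect_equal(nrow(sim$truth_junctions), 0L)
  ## collision_lambda = 0: all reads of a barcode come from one molecule
  per_bc <- tapply(sim$reads$molecule_id, sim$reads$barcode,
                   function(x) length(unique(x)))
  expect_true(all(per_bc == 1L))
  ## reproducibility: identical seeds give byte-identical output
  sim2 <- simulate_linked_reads(c(chr1 = 100000), list(),
                                sim_params(seed = 11, target_coverage = 20))
  expect_identical(sim$reads, sim2$reads)
  tsv1 <- tempfile(); tsv2 <- tempfile()
  write_alignments_tsv(sim$reads, tsv1)
  write_alignments_tsv(sim2$reads, tsv2)
  expect_identical(readLines(tsv1), readLines(tsv2))
})

test_that("emitted depth scales with copy number and discordant pairs mark the junction", {
  ## 10 kb deletion derivative [A+, C+] at copy number 8 over background
  del <- derivative_structure("del8", data.frame(
    chrom = "chrXsim", start = c(0, 20000), end = c(10000, 30000),
    orient = c("+", "+")), copy_number = 8)
  ctl <- derivative_structure("ctl2", data.frame(
    chrom = "chrXsim", start = 100000, end = 130000, orient = "+"),
    copy_number = 2)
  sim <- simulate_linked_reads(sim_ref(), list(del, ctl),
                               sim_params(seed = 5))
  rd <- sim$reads
  depth_over <- function(s, e)
    sum(pmax(0, pmin(rd$end, e) - pmax(rd$pos, s))) / (e - s)
  ## total copies 9 vs 3 -> 3x depth ratio, within 10%
  ratio <- depth_over(0, 10000) / depth_over(100000, 130000)
  expect_lt(abs(ratio - 3), 0.3)
  ## discordant pairs cluster at the deletion breakends (10000,+)/(20000,-)
  disc <- rd[!rd$proper_pair & rd$strand == "+" & rd$chrom == rd$mate_chrom &
               rd$mate_pos - rd$pos > 5000, ]
  expect_gt(nrow(disc), 10)
  expect_true(all(abs(disc$end - 10000) < 1000))
  expect_true(all(abs(disc$mate_pos - 20000) < 1000))
})

test_that("split-molecule fraction matches a Monte-Carlo re-derivation", {
  set.seed(99)
  sim <- simulate_linked_reads(sim_ref(), list(ecdna_derivative()),
                               sim_params(seed = 21))
  expect_equal(nrow(sim$truth_junctions), 3L)
  rd <- data.table::as.data.table(sim$reads)
  mols <- data.table::as.data.table(sim$molecules)[source == "ecdna1"]
  ## observed: fraction of read-bearing ecDNA molecules whose reads occupy
  ## >= 2 of the three reference segments (i.e. the molecule crossed a
  ## junction and left fragments on both sides)
  seg_of <- findInterval(rd[source == "ecdna1"]$pos, c(20000, 60000, 100000))
  occ <- rd[source == "ecdna1"][, seg := seg_of][,
    .(nseg = data.table::uniqueN(seg)), by = molecule_id]
  observed <- mean(occ$nseg >= 2L)
  ## oracle: re-place reads independently along each molecule (Poisson
  ## count, uniform positions along the circle arc) and ask whether >= 2
  ## of the three 10 kb derivative segments receive a read
  L <- 30000; bounds <- c(0, 10000, 20000, 30000)
  p <- sim$params
  hit2 <- vapply(seq_len(nrow(mols)), function(i) {
    s <- mols$mol_start[i]; len <- mols$mol_len[i]
    n <- stats::rpois(1, p$reads_per_molecule_median * len /
                        p$molecule_length_mean)
    if (n < 1) return(NA)
    x <- (s + stats::runif(n, 0, len)) %% L
    length(unique(findInterval(x, bounds))) >= 2
  }, logical(1L))
  expect_lt(abs(observed - mean(hit2, na.rm = TRUE)), 0.05)
})

test_that("simulation rejects derivatives outside the reference", {
  bad <- derivative_structure("bad", data.frame(
    chrom = "chrXsim", start = 190000, end = 210000, orient = "+"))
  expect_error(simulate_linked_reads(sim_ref(), list(bad), sim_params()),
               "outside")
  missing_chrom <- derivative_structure("m", data.frame(
    chrom = "chrNope", start = 0, end = 10000, orient = "+"))
  expect_error(simulate_linked_reads(sim_ref(), list(missing_chrom),
                                     sim_params()), "outside")
})

test_that("barcode collisions follow the configured Poisson rate", {
  sim <- simulate_linked_reads(c(chr1 = 150000), list(),
                               sim_params(seed = 31, target_coverage = 30,
                                          barcode_collision_lambda = 2))
  per_bc <- tapply(sim$molecules$molecule_id, sim$molecules$barcode, length)
  ## mean molecules per barcode ~ 1 + lambda
  expect_lt(abs(mean(per_bc) - 3), 0.4)
  expect_gt(max(per_bc), 1)
})
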