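mk_snv <- function(filter = "PASS", vaf = 0.25, gene = "AR",
                   pchange = "T878A", pos = 66943592) {
  alt <- round(vaf * 40); ref <- 40 - alt
  data.frame(chrom = "chrX", pos = pos, ref = "A", alt = "G",
             filter_status = filter, ref_count = ref, alt_count = alt,
             vaf = vaf, gene = gene, protein_change = pchange,
             stringsAsFactors = FALSE)
}

annotation <- data.frame(
  gene = c("AR", "AR", "TP53", "AR"),
  alteration = c("T878A", "H875Y", "R175H", "Q58L"),
  oncogenicity = c("Oncogenic", "Likely Oncogenic", "Oncogenic", "Unknown"),
  stringsAsFactors = FALSE)

test_that("SNVs are filtered by PASS, allele fraction and oncogenicity", {
  kept <- filter_snvs(mk_snv(), annotation)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$oncogenicity, "Oncogenic")
  ## a clone that fell below the 10% allele fraction is excluded
  expect_equal(nrow(filter_snvs(mk_snv(vaf = 0.05), annotation)), 0L)
  ## exactly at the threshold passes (exclusion is only below it)
  expect_equal(nrow(filter_snvs(mk_snv(vaf = 0.10), annotation)), 1L)
  ## non-PASS is excluded while require_pass is on
  expect_equal(nrow(filter_snvs(mk_snv(filter = "q10", vaf = 0.4),
                                annotation)), 0L)
  expect_equal(nrow(filter_snvs(mk_snv(filter = "q10", vaf = 0.4),
                                annotation, require_pass = FALSE)), 1L)
  ## unannotated or non-oncogenic alterations are excluded
  expect_equal(nrow(filter_snvs(mk_snv(pchange = "Q58L"), annotation)), 0L)
  expect_equal(nrow(filter_snvs(mk_snv(gene = "KRAS"), annotation)), 0L)
  ## likely oncogenic is retained
  expect_equal(nrow(filter_snvs(mk_snv(pchange = "H875Y"), annotation)), 1L)
})

test_that("filtering is idempotent and the vaf filter is monotone", {
  calls <- rbind(mk_snv(), mk_snv(vaf = 0.05, pos = 1),
                 mk_snv(filter = "q10", pos = 2),
                 mk_snv(pchange = "H875Y", vaf = 0.5, pos = 3))
  once <- filter_snvs(calls, annotation)
  twice <- filter_snvs(once, annotation)
  expect_equal(once, twice)
  ## dropping the vaf filter yields a superset
  loose <- filter_snvs(calls, annotation, min_vaf = 0)
  expect_true(all(once$pos %in% loose$pos))
  expect_gte(nrow(loose), nrow(once))
  ## stored vaf always matches the count ratio
  expect_equal(loose$vaf,
               loose$alt_count / (loose$ref_count + loose$alt_count))
})

test_that("allele support counts carrier reads at the locus with barcodes", {
  reads <- sort_reads(rbind(
    mk_molecule_reads("BX1", "chrX", c(900, 1100), prefix = "a"),
    mk_molecule_reads("BX2", "chrX", c(950, 2000), prefix = "b"),
    mk_molecule_reads("BX3", "chrX", 5000, prefix = "c")))
  ## locus at 1-based 1001 = 0-based 1000: overlapped by a_r001 (900-1050),
  ## b_r001 (950-1100)
  sup <- count_allele_support(reads, "chrX", 1001,
                              c("a_r001", "b_r001", "c_r001"))
  expect_equal(sup$count, 2L)
  expect_equal(sup$barcodes, c("BX1", "BX2"))
  none <- count_allele_support(reads, "chrX", 1001, character())
  expect_equal(none$count, 0L)
  expect_equal(none$barcodes, character())
})

test_that("carrier fraction reflects amplicon copy number", {
  ## SNV on an 8-copies-total amplified segment vs 1-copy background:
  ## carrier fraction at the locus ~ 7/8 within binomial error
  sim <- simulate_linked_reads(sim_ref(), list(amp_derivative(7)),
                               sim_params(seed = 37))
  rd <- sim$reads
  at_locus <- rd[rd$pos <= 24999 & rd$end > 24999, ]
  carriers <- at_locus$read_id[at_locus$source == "amp"]
  sup <- count_allele_support(rd, "chrXsim", 25000, carriers)
  frac <- sup$count / nrow(at_locus)
  p <- 7 / 8
  se <- sqrt(p * (1 - p) / nrow(at_locus))
  expect_lt(abs(frac - p), 4 * se + 0.01)
})
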