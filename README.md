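# linkphase

Linked-read analysis of structurally complex, highly amplified oncogene
loci — molecule reconstruction, split-molecule structural variant (SV)
calling, barcode phasing of SVs into networks, targeted copy-number
estimation, oncogenic SNV filtering, and cohort-level enrichment tests.

## The problem

In droplet-partitioned linked-read DNA sequencing, all short reads derived
from one high-molecular-weight (HMW) DNA molecule (tens of kb) carry the
same droplet barcode (`BX` tag). Reconstructing those molecules in silico
restores long-range information that short reads lack. This matters for
loci like the androgen receptor (*AR*) gene in castration-resistant
prostate cancer, where amplification and structural rearrangement
co-occur: only molecule-level evidence can say whether multiple
rearrangements live on *different* tumor cells' DNA or on the *same*
molecule — for instance one extrachromosomal circular DNA (ecDNA) amplicon
carrying several rearrangements at once.

`linkphase` is aimed at method developers and computational biologists who
want a transparent, fully testable version of that analysis:

* **Molecule reconstruction.** Same-barcode, same-chromosome reads are
  greedily grouped left to right; a new molecule starts when the gap to the
  previous read exceeds the gap parameter *d* (run at *d* = 1000, 5000 and
  10 000 bp).
* **Split-molecule SV calling.** A breakend is `(chrom, pos, orient)` where
  `+` means the retained segment extends to lower coordinates and `-` to
  higher ones; after canonical ordering, `(+,-) → DEL`, `(-,+) → DUP`,
  `(+,+)/(-,-) → INV`, different chromosomes `→ TRA`. Candidates are seeded
  from discordant read-pair clusters, then scored by *barcoded split
  molecules*: same-barcode molecule pairs whose ends flank the two
  breakends. A call requires at least 5 split molecules; per-*d* call sets
  are unified across *d* (union with support-weighted-median breakends).
* **Phasing.** Two SV calls sharing at least one supporting barcode are
  linked; connected components of that graph are groups of rearrangements
  co-resident on one DNA molecule. Barcode overlap between SNV-supporting
  reads and SV split molecules asks the same question for point mutations.
* **Copy number.** `cn = ploidy_control × depth(target) / depth(controls)`,
  with high-level amplification flagged at `cn ≥ 8` (inclusive).
* **Cohort statistics.** Two-sided Fisher's exact tests of SV / phased-SV
  presence against high-level amplification, plus alteration frequencies.
* **Simulation.** A linked-read generator for multiply-rearranged,
  optionally circular (ecDNA-like) derivative structures over synthetic
  references, with machine-readable truth (junction BEDPE, copy-number
  table, per-molecule provenance), so every stage is testable without
  controlled-access patient data.

## Worked example

Simulate a circular, 8-copy, three-segment ecDNA-like amplicon over a
200 kb toy chromosome, call SVs, phase them, and estimate copy number:

```r
library(linkphase)

ref <- c(chrXsim = 200000)
ecdna <- derivative_structure("ecdna1", data.frame(
  chrom = "chrXsim", start = c(20000, 60000, 100000),
  end   = c(30000, 70000, 110000), orient = c("+", "+", "-")),
  circular = TRUE, copy_number = 8)

sim   <- simulate_linked_reads(ref, ecdna, sim_params(seed = 1))
calls <- call_svs(sim$reads)                 # d = 1000, 5000, 10000
net   <- phase_svs(calls)
cn    <- estimate_copy_number(sim$reads, "chrXsim:20000-30000",
           data.frame(chrom = "chrXsim", start = c(40000, 120000),
                      end = c(55000, 170000)))
```

Printed output:

```
Linked-read simulation: 173612 reads, 8892 molecules, 8892 barcodes
  truth junctions: 3; seed 1
SV call set: 3 call(s)
     name svtype              be1               be2 split_molecules               d
1:  sv001    INV chrXsim:20002(-) chrXsim:100000(-)            4743 1000,5000,10000
2:  sv002    DEL chrXsim:30000(+)  chrXsim:60001(-)            4764 1000,5000,10000
3:  sv003    INV chrXsim:70000(+) chrXsim:110000(+)            4737 1000,5000,10000
Phase network: 3 SV call(s), 3 edge(s), 1 component(s) (sizes 3)
Copy number of chrXsim:20000-30000: 8.73 (target depth 526.7x / control depth 60.3x, ploidy 1)
  high-level amplification (cn >= 8): TRUE
```

Reading this: the three novel adjacencies of the circle are recovered as a
deletion-type and two inversion-type breakend pairs, each within a few bp
of the truth and supported by thousands of barcoded split molecules. All
three calls fall in **one** phase component — the barcode evidence says
they co-reside on one molecule, which is exactly how the amplicon was
simulated. The target region sits at ~8.7 copies (8 ecDNA copies plus the
haploid chromosomal background) and is flagged as high-level
amplification.

`run_sample()` orchestrates the same stages from files (alignment TSV/BAM,
target BED, SNV VCF + oncogenicity table) and writes BEDPE / JSON / TSV /
VCF artifacts; `run_cohort()` aggregates per-sample summaries into
oncoprint-style tables and the Fisher tests. A thin command-line wrapper
lives in `inst/scripts/linkphase.R`.

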