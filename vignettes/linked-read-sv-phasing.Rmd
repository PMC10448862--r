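---
title: "Methods: split-molecule SV discovery and barcode phasing of amplified loci"
author: "linkphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-molecule SV discovery and barcode phasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkphase)
```

## The measurement model

Droplet-partitioned linked-read sequencing tags every short read derived
from one high-molecular-weight (HMW) DNA fragment with a shared droplet
barcode. Three consequences drive everything in this package:

1. **Molecules are recoverable.** Reads with one barcode on one chromosome,
   separated by gaps no larger than a parameter $d$, almost surely came
   from one physical fragment. `reconstruct_molecules()` makes this
   operational as a greedy left-to-right partition: scanning
   position-sorted reads per (barcode, chromosome), a new molecule starts
   whenever the gap from the running maximum end to the next read start
   exceeds $d$; a gap exactly equal to $d$ stays in the molecule (the
   tie-break is inclusive so the parameter reads as "maximum allowed
   gap"). Molecules with fewer than `min_reads_per_molecule` (default 2)
   reads are discarded.

2. **Rearrangements split molecules.** A fragment that physically spanned
   a novel adjacency maps back to the reference as two (or more) molecule
   fragments sharing a barcode, whose facing ends flank the two breakends.
   These *split molecules* are the quantitative unit of SV support.

3. **Barcodes phase.** If split molecules supporting two *different*
   junctions share a barcode, both junctions were (with collision caveats,
   below) on one physical fragment — e.g. one ecDNA amplicon carrying
   several rearrangements.

### Breakend conventions

A breakend is $(\mathrm{chrom}, \mathrm{pos}, \mathrm{orient})$ with
0-based half-open coordinates internally (BEDPE output is 0-based, VCF
1-based). Orientation `+` means the retained segment extends toward lower
coordinates (breakpoint at its right end); `-` toward higher coordinates.
After canonical ordering (lower chromosome/position first):

| orientation pair | class |
|---|---|
| `(+,-)` | DEL-type adjacency |
| `(-,+)` | DUP-type adjacency |
| `(+,+)` or `(-,-)` | INV-type adjacency |
| different chromosomes | TRA |

These are adjacency classes, not rearrangement mechanisms: a circular
amplicon's wrap-around junction has a DUP-type signature without any
tandem duplication having occurred.

## The caller

`call_svs()` runs, for each $d \in \{1000, 5000, 10000\}$ (defaults):

1. **Candidate seeding** from discordant read pairs
   (`find_discordant_candidates()`). A pair is discordant if its mates map
   to different chromosomes, span more than `max_insert` (default
   2000 bp), or violate FR orientation. Pairs with the same breakend
   signature clustering within `cluster_tol` (default 500 bp) on both
   sides, with at least `min_pairs` (default 2) members, become
   candidates positioned at the outermost read ends toward the junction.
   Seeding from discordant pairs rather than exhaustive molecule-pair
   search keeps the caller near-linear; both evidence classes are still
   required for a call.

2. **Split-molecule support** (`collect_split_molecules()`). For each
   candidate, a barcode supports the junction when one of its molecules
   has its qualifying end (right end for a `+` breakend, left end for
   `-`) within window $w$ of breakend 1 and a *different* molecule
   likewise at breakend 2. $w$ defaults to the current $d$: a fragment
   end cannot sit further from the junction than the read gap that
   defines molecule continuity. Support is counted in *barcodes*, one
   link per barcode per candidate, because the physical evidence unit is
   the droplet, not the fragment.

   **Terminality guard.** At small $d$ (1 kb) ordinary within-molecule
   read gaps exceed $d$ regularly, so unrearranged molecules fracture
   into fragments whose ends land anywhere — including inside breakend
   windows. What distinguishes a true junction fragment is that it is
   *terminal*: its barcode has no coverage just beyond the breakend on
   the junction side, whereas a fractured molecule continues right after
   the gap. A qualifying fragment is therefore rejected when its barcode
   has another fragment starting (or substantially extending) within a
   guard zone beyond the breakend. The zone reaches
   $\max(2w, 20\,\mathrm{kb})$ but always stops $w$ short of the partner
   breakend so the partner fragment itself is never penalised.
   Consequences: junctions spanning less than about $2w$ are effectively
   unguarded and are better recovered at a smaller $d$; heavy barcode
   collisions can suppress true support (a co-partitioned background
   molecule may sit in the zone), which is the conservative direction.

3. **Thresholding.** Candidates with at least `min_support = 5` split
   molecules become calls — the support rule applied per $d$ and
   preserved by merging.

4. **Cross-$d$ merging** (`merge_calls_across_d()`). Calls with the same
   SV class, chromosomes and orientations whose breakends agree within
   `merge_tol` (default 1000 bp) are unified by transitive closure;
   merged breakends are support-weighted medians with ties resolved
   toward the lower coordinate; barcode sets and $d$ provenance are
   unioned, so support never decreases. Whether runs at several $d$
   values should be unioned or intersected was genuinely open; union was
   chosen because each $d$ trades fragmentation against molecule
   chimerism differently, and a junction cleanly resolved at any $d$ is
   real evidence. No likelihood score is computed; the BEDPE score column
   is the split-molecule count.

## Phasing

`phase_svs()` computes all pairwise intersections of support-barcode sets
and draws an edge at `min_shared` ≥ 1 shared barcodes (default 1,
mirroring the "at least one other split molecule with the same barcode"
criterion). Connected components are the phased groups; singletons are
flagged *unlinked*. With barcode collisions (several molecules per
droplet) a single shared barcode can be coincidental, which is why
`min_shared` is exposed; the default simulation emits collision-free
barcodes, and a $\lambda = 2$ collision setting is exercised in tests to
document the degradation rather than to assert a threshold.
`snv_sv_barcode_overlap()` applies the same logic between the reads
supporting a point mutation and a call's split molecules; an empty
intersection is the meaningful "zero overlap" outcome (mutation and
rearrangement on different molecules).

## Copy number

`estimate_copy_number()` is a deliberate, transparent ratio estimator:
$\mathrm{cn} = \mathrm{ploidy}_{\mathrm{control}} \times
\overline{\mathrm{depth}}_{\mathrm{target}} /
\overline{\mathrm{depth}}_{\mathrm{controls}}$, with pooled per-base mean
depth over disjoint control regions and an error on zero control depth.
It is invariant to uniform depth rescaling, assumes composition-uniform
references (no GC correction — the synthetic references are uniform) and
pure tumor (no purity correction). Control ploidy defaults to 1, the male
chrX case. High-level amplification is flagged at $\mathrm{cn} \ge 8$,
inclusive: a tumor at exactly eight copies counts as high.

## SNV filtering

`filter_snvs()` keeps calls that are FILTER `PASS`, have variant allele
fraction $\ge$ `min_vaf` (default 0.10 — the comparison is inclusive so a
call *at* 10% passes; exclusion applies strictly below), and are
annotated `Oncogenic` or `Likely Oncogenic` in a flat annotation snapshot
(`inst/extdata/oncogenicity_synthetic.tsv` is a small synthetic stand-in
for such a table; no network lookups). Allele counts follow the
freebayes-style `RO`/`AO` convention and the VAF is recomputed from
counts. Sequence-level realignment is out of scope, so
`count_allele_support()` identifies alternate-allele reads by id (from
simulation truth or manual inspection) and returns their count and
barcode set.

## The simulator

`simulate_linked_reads()` emulates the assay around a
`derivative_structure`: an ordered walk of oriented reference segments,
optionally circular (the ecDNA model), at an integer `copy_number`. An
unrearranged background at `background_ploidy` (default 1, haploid chrX)
is always co-simulated so copy-number estimation has a denominator.
Machine-readable truth (junction BEDPE via `truth_junctions()`, a
copy-number table, and per-molecule provenance) accompanies every run.

Parameter defaults (`sim_params()`) encode deep targeted linked-read
conditions: log-normal molecule lengths with 50 kb mean (sdlog 0.4),
a median of ~30 linked reads per molecule — inside the 15–148 band seen
in deep targeted data — 2×150 bp pairs at 400 ± 50 bp inserts, 60-fold
per-copy coverage, and collision-free barcodes
(`barcode_collision_lambda = 0`; collisions are Poisson-distributed extra
molecules per droplet when enabled). Reads per molecule scale with
molecule length, and the number of molecules is driven by the unit's
read-pair budget computed from each molecule's actual (clipped) length,
so emitted depth tracks `copy_number` linearly even when a short
derivative caps molecule lengths. Linear units place molecules with
overhang-and-clip so coverage is uniform to the chromosome ends.

`copy_number` counts derivative copies *added on top of* the background,
and the truth table reports total copies (background + derivative) per
footprint — the quantity depth or FISH would measure. The "eight-copy
amplicon" study condition is therefore simulated as seven derivative
copies over the haploid background.

Reads overlapping a junction point are dropped rather than soft-clipped:
the caller's evidence classes are discordant pairs and split molecules,
not split reads, and emitting alignments directly (no base-level
sequences, no sequencing-error model) keeps the generator exact and fast.
What the simulator deliberately does **not** model: mappability and
repeat structure (LINEs at real breakpoints), GC bias, duplicates,
chimeric molecules, phase blocks, and tumor purity. Passing recovery
tests therefore demonstrate algorithmic correctness under clean
conditions, not robustness to alignment artifacts of real data.

## Numerical and degenerate-input choices

* Coordinates 0-based half-open internally; BEDPE 0-based, VCF 1-based.
* Weighted medians take the lowest value reaching half the total weight
  (deterministic tie-break toward lower coordinates).
* Percentages round half-away-from-zero to integers for reporting;
  exact fractions are always carried alongside.
* Fisher's exact test delegates to `stats::fisher.test` (two-sided =
  sum of hypergeometric point probabilities not exceeding the observed
  table's); all-zero tables, negative or non-integer entries error.
* Empty call sets, empty barcode sets, unknown barcodes (zero coverage
  rows) and feature-absent cohorts are all defined results, not errors;
  empty cohorts, zero control depth, non-positive $d$ or $w$, and
  overlapping target/control regions are errors.
* Every stochastic step runs under a caller-restored private RNG seeded
  from `sim_params(seed=)`, so identical seeds give byte-identical
  artifacts.

## Problem sizes used in the tests

The recovery suites use a 200 kb synthetic chromosome with a 30 kb
circular three-junction amplicon (segments ≥ 30 kb apart so fragments
never re-merge at any $d$), an independent 40 kb single-junction circle,
and a 10 kb linear amplified segment; 10 seeds for SV and phasing
recovery, 20 for copy number, 100 random instances for the molecule
oracle and 500 fixed-margin tables for the Fisher oracle. These sizes
give stable results (recall and precision 1.0, copy number within a few
percent) while keeping the full suite under a couple of minutes.

## Known limitations

* Junctions spanning less than roughly $2d$ for every configured $d$ are
  hard to support with split molecules (window and guard geometry); such
  events are better served by split-read callers.
* Support counting is conservative under heavy barcode collisions.
* The caller has no probabilistic model: no per-call likelihood, no
  explicit FDR. The five-split-molecule rule is the operating point.
* The ratio copy-number estimator ignores purity, GC and segmentation;
  it answers "how amplified is this targeted region relative to
  controls", nothing more.
* Phasing is a co-residence graph; it does not order junctions along the
  amplicon or reconstruct its full structure (optical-mapping territory).
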