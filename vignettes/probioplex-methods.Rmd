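---
title: "Multiplex genotyping and label-claim auditing of probiotic products: methods"
author: "probioplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex genotyping and label-claim auditing of probiotic products: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probioplex)
```

## The problem

Commercial probiotic products print two auditable claims on the label: which
bacterial species (and sometimes sub-species or strains) are inside, and how
many viable cells per gram. Verifying the first claim is hard with the usual
16S rRNA survey tools because the lactobacilli and bifidobacteria that
dominate these blends are often nearly identical over 16S. A single-copy
housekeeping gene such as *glucose-6-phosphate isomerase* (*pgi*) diverges
faster between species and so supports species- and sub-species-level PCR
assays. `probioplex` implements the full computational side of such an assay
system:

1. **Panel building** — group marker-gene sequences by taxon, align them,
   and build a degenerate IUPAC consensus per taxon
   (`read_marker_fasta()`, `align_marker_set()`, `build_consensus()`,
   `identity_matrix()`).
2. **Primer design** — enumerate fully conserved candidate windows, screen
   them for GC, melting temperature and secondary structure, score
   discrimination against every non-target taxon by exhaustive scanning,
   and emit one primer pair plus expected amplicon length per taxon
   (`design_assay()`, `design_panel_assays()`).
3. **In-silico PCR** — IUPAC-aware binding-site location and amplicon
   prediction, and panel-wide cross-reactivity matrices
   (`find_binding_sites()`, `predict_amplicons()`, `cross_reactivity()`).
4. **Multiplexing** — partition assays into k-plex reactions whose expected
   band lengths are mutually resolvable on a gel (`partition_assays()`).
5. **Genotyping and auditing** — run the virtual panel on a sample, call
   presence per taxon by exact band-length matching, and classify each
   (product, taxon) pair as claimed/unclaimed x present/absent
   (`virtual_gel()`, `call_presence()`, `audit_against_label()`).
6. **16S V4 profiling** — merge read pairs, quality-filter, dereplicate at
   100% identity, assign OTUs to type-strain groups, and summarize relative
   abundance (`profile_amplicons()` and friends).
7. **Enumeration auditing** — pour-plate arithmetic and log-scale
   comparison of measured to claimed CFU (`cfu_from_plates()`,
   `compare_claim()`, `potency_basis_test()`).
8. **Synthetic data** — seeded generators for panels, mock communities,
   amplicon reads and mislabeled products, so the whole system is testable
   without any external download (`generate_panel()`, `simulate_reads()`,
   `generate_product_fixture()`).

## Alignment and consensus model

Within-taxon marker sequences are near-identical, so a simple exact strategy
suffices: pairwise Needleman–Wunsch with match +2, mismatch −1, gap −2 and
free terminal gaps, extended to more than two sequences by center-star
progressive alignment (the center maximizes summed pairwise score; merges
follow the once-a-gap-always-a-gap rule). These scores are conventional
choices, fixed for reproducibility; they are not tuned to reproduce any
particular aligner's output bit for bit.

Percent identity between two sequences is matches divided by alignment
columns, with gap columns counting as non-matches. For identity we use
strict end-to-end alignment (terminal gaps penalized): under free end gaps
the optimum for near-identical sequences offset by one base slides into a
shorter overlap and deflates identity (e.g. `AAAA` vs `AAAT` would score 3
matches over 5 columns instead of 3 over 4). Both choices use the same
substitution scores.

The per-taxon consensus records, at every column, the unique IUPAC code
whose expansion equals exactly the set of bases observed — full conservation
stays a plain base, any polymorphism becomes a degenerate code. Columns
gapped in at least one sequence keep a `-` marker and are excluded from
primer-eligible regions: indels inside a priming site are rare in these
genes and excluding them is the conservative choice.

## Primer design choices

Candidate windows must be entirely degeneracy-free: a primer must bind every
strain of its taxon, and published assay panels of this kind use
fixed-sequence (non-degenerate) oligos. Screens and their defaults, all
exposed in `design_params()`:

* length 18–25 nt, GC 40–60%, Wallace Tm (2·AT + 4·GC) 50–70 °C. The
  Wallace rule is a deliberate screening stand-in for nearest-neighbor
  thermodynamics: deterministic, testable, and easily replaced.
* hairpin/self-dimer: the longest self-complementary run must stay below
  8 nt, and below 5 nt when anchored at the 3' terminus. Run lengths proxy
  for ΔG-based structure prediction, which is out of scope.

Discrimination is scored by exhaustively scanning every same-length window
of every non-target sequence on both strands (IUPAC-aware on the template
side) — the self-contained replacement for online BLAST searches. Pair
selection is a lexicographic maximization: (1) the worse primer's minimum
off-target mismatch count, (2) its minimum 3'-anchor mismatches, then among
pairs passing the cross-dimer screen, (3) product length closest to the
midpoint of the allowed 100–1000 bp range; ties break by leftmost forward
start, then shortest primers, making the design byte-deterministic. One hard
constraint is added: at least one primer of the selected pair must carry at
least one mismatch against every off-target, since a fully conserved pair
would co-amplify another panel member; a panel whose target and off-target
sequences are identical therefore fails with an explicit infeasibility
error. (Requiring *both* primers to mismatch would make short divergent
inserts undesignable at the minimum 100 bp product length; the optimizer
still prefers doubly discriminating pairs whenever they exist.)

## In-silico PCR and the virtual gel

Binding sites are all windows, on both strands, whose IUPAC-aware mismatch
count is within policy over the whole primer and within the 3'-terminal
anchor (defaults: zero mismatches anywhere, 3 nt anchor, products capped at
3000 bp). The strict default mirrors an exact band-length positivity rule;
both knobs can be relaxed, and relaxation can only add sites. Coordinates
are 0-based half-open on the plus strand throughout.

An amplicon is emitted for every forward site paired with a reverse site in
amplifiable orientation (reverse window end beyond the forward window end),
in both orientations, deduplicated. The cross-reactivity matrix runs every
assay against every taxon's sequences; a valid panel shows exactly its
expected length on the diagonal and empty off-diagonal cells. Off-target
products with lengths distinguishable from every expected band are not
suppressed here — the genotyper's exact length matching ignores them
downstream.

The gel model has two parameters: `min_separation` (default 50 bp — a
conservative resolvable difference on 2% agarose over the 100–1000 bp
range) and `length_tolerance` for band calling (default 0 = exact).
Partitioning sorts assays by expected length and deals them round-robin
across r reactions, with r the larger of ⌈n/plex⌉ and the largest set of
lengths mutually closer than `min_separation`. Because same-reaction assays
sit r apart in the sorted order, any violation would imply a conflict
clique larger than r, so this canonical scheme is always feasible and uses
the provably minimal number of reactions; the test suite still verifies
optimality against exhaustive set-partition enumeration for n ≤ 8.

## Presence calls and the audit matrix

A taxon is called present iff some band in its reaction is within
`length_tolerance` of its expected length; each band is assigned to at most
one assay (nearest expected length, ties to the lower length, flagged
ambiguous). Per product and panel taxon the audit records one of four
categories — claimed_present, claimed_absent, unclaimed_present,
unclaimed_absent — plus confirmed/mismatched/unresolvable for strain-level
claims (unresolvable when no strain assay exists). Claimed taxa outside the
panel are recorded as not_testable and excluded from discrepancy counts,
while cohort percentages keep the full product count as denominator, so both
views are available. A product is discrepant when it has at least one
claimed_absent or unclaimed_present call.

## The 16S V4 profiler

Mate pairs merge at the highest-scoring overlap (matches minus mismatches)
of at least 20 nt with at most a 10% mismatch fraction; disagreeing overlap
bases take the higher-quality base, ties the forward base. Reads with any
ambiguous base or any position below Phred 30 are removed (a read exactly at
Q30 everywhere survives: the rule removes < 30). Dereplication collapses
identical sequences — de novo clustering at 100% identity — and each OTU is
assigned the taxon group of its best global-alignment identity reference;
exact ties yield the union group, flagged ambiguous. Reference taxa whose V4
regions are identical are collapsed into one group up front, which is how
closely related species pairs (e.g. *B. longum*/*B. infantis*,
*L. casei*/*L. paracasei*, *L. acidophilus*/*L. helveticus*) behave in this
amplicon.

The minor-OTU filter keeps OTUs strictly above 0.1% of the grand total
across all samples (per the "more than 0.1% of total reads" convention; a
per-sample variant is exposed). Note that after filtering, relative
abundances renormalize over the retained reads, so in a 1000:1 spiked mock
the dominant group's share reflects the dropped minor mass; recovery checks
therefore run with the filter disabled (`min_frac = 0`). Samples are
excluded from abundance reporting when they fall below `min_reads`; the
default is 0 (only empty samples drop) so small examples behave intuitively,
and 10,000 reads is the documented survey-scale choice for excluding
low-coverage samples.

Two summary regressions are provided. `cfu_read_regression()` fits percent
reads on log10 CFU by ordinary least squares — this orientation (reads on
CFU) is fixed and documented, and the fit is on raw percents, not
log-transformed ones. `rank_abundance_fit()` fits mean abundance on ln(rank);
blends formulated around a few dominant strains give a negative slope.

## Enumeration audit

CFU/g is the mean of the three dilution-scaled plate counts with their
sample standard deviation; all-zero triplicates flag below-detection. Claim
comparison works on log10(measured) − log10(claimed); measured exactly equal
to the claim counts as *above* (the product meets its claim — the boundary
convention is documented because the dichotomy leaves it open), and an
excess beyond one log is flagged. The potency-basis comparison uses a Welch
two-sample t-test on log10 CFU by default — the variance assumption and
scale are not derivable from "2-Sample t-Test" alone, so the defensible
default is unequal variances on the log scale, with pooled-variance and
raw-scale variants exposed. The DNA-yield cell equivalence scales a target
concentration through the calibration `cells_in / dna_conc_out`; with the
1.2 × 10^10 cells → 51.8 ng/µL calibration, 1 pg/µL corresponds to
2.3 × 10^5 cells (2 significant figures).

## What the synthetic generators emulate

`generate_panel()` evolves every taxon from one ancestral sequence per locus
by substitutions only, with the per-lineage substitution probability solved
from the target expected pairwise identity t:
p = (3/4)(1 − √(1 − (4/3)(1 − t))) (substitutions uniform over the three
other bases; feasible down to the 25% random floor). Strains mutate from the
taxon base sequence the same way. Defaults mirror the study conditions:
20 taxa (the default roster of common probiotic species and sub-species,
including the three historically confusable pairs), pgi-like between-taxon
identity 85% vs 16S-like 97–98%, within-taxon identity 99.5%, two strains
per taxon, 600–800 bp genes. The substitution-only model keeps alignments
exact and oracles simple; it does not emulate indels, rearrangements,
horizontal transfer, or real gel artifacts (smearing, faint non-specific
bands), so passing recovery tests demonstrate algorithmic correctness on
clean divergence, not robustness to structural variation.

`generate_mock_community()` reproduces the standard designs: even (all
members at 1 × 10^8 CFU/mL, or 100 pg/µL in DNA units), reaction-subset
(only one reaction's taxa), and spiked (key targets at 1 × 10^8 CFU/mL
against 1 × 10^5 for the other members, or 1 ng/µL vs 1 pg/µL).
`simulate_reads()` draws each read pair's source taxon proportional to
abundance (one marker copy per cell — real 16S copy-number heterogeneity is
deliberately not modeled and is exposed as a caveat), slices the two ends of
the member's V4 reference, applies per-base substitution errors, and writes
constant-quality Phred scores with optional planted sub-threshold bases.
`generate_product_fixture()` injects labeling errors — species swaps
restricted to the related pairs, omissions, additions — such that the claim
plus the recorded errors reconstruct the true content exactly.

## Problem sizes and numerical choices

The shipped checks run at desk scale, chosen to exercise every code path
with comfortable statistical margins: full 20-taxon panels with 600–800 bp
genes for design and genotyping; 200 seeded products for recovery;
50,000-read spiked mocks (3-binomial-SD abundance bounds); a 7-point
dilution ladder at 20,000 reads per standard, built so the target's design
percent is exactly linear in log10 CFU — the regression then isolates
sampling noise, which is the property under test; 1000-replicate null
simulation for the t-test calibration at the survey's 24 vs 28 group split;
and exhaustive-oracle cross-checks at small n (alignments to length 8,
partitions to 8 assays, fuzzed scans to 10 kb templates). Generator
parameters and seeds are fixed in the test code; every generator is
deterministic given its seed.

Degenerate and edge inputs are handled explicitly: empty FASTA files,
records with invalid symbols, all-gap alignment columns, assays that fail
their own target (a validation error, not a silent cell), bands equidistant
between two assays (lower length wins, flagged), samples with zero retained
reads (excluded with a warning), zero-variance regression predictors
(error), and all-zero plate counts (below-detection flag).

## Known limitations

* Thermodynamics are screening-grade (Wallace Tm, run-length structure
  proxies), not nearest-neighbor ΔG models.
* PCR kinetics, amplification efficiency, preferential amplification in
  unequal mixtures, and chimera formation are not modeled; the in-silico
  panel validates specificity, not sensitivity under competition.
* The read simulator uses substitution-only errors at constant quality;
  real MiSeq error profiles (3' quality decay, indels) are out of scope.
* Assay behavior on genomes outside the panel is whatever the exhaustive
  scan yields; no curated database of near-neighbor species is bundled.
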