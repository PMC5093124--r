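# probioplex

Multiplex PCR genotyping and label-claim auditing of probiotic products.

Commercial probiotic blends print two verifiable claims: which bacterial
species and sub-species are inside, and how many colony-forming units per
gram. Checking the species claim is hard with 16S rRNA alone — the
lactobacilli and bifidobacteria used in these products are often nearly
identical over 16S — so species-resolved testing leans on a faster-evolving
single-copy gene such as *glucose-6-phosphate isomerase* (*pgi*).
`probioplex` implements the complete computational side of such an assay
system for QC labs, method developers and bioinformaticians:

* **Panel building** — per-taxon degenerate IUPAC consensus sequences from
  marker-gene alignments, and cross-taxon percent-identity matrices.
* **Primer design** — deterministic, screened (length, GC, Wallace Tm
  2·(A+T)+4·(G+C), hairpin/dimer run-length limits) and scored for
  discrimination by exhaustively scanning all non-target sequences,
  IUPAC-aware, on both strands.
* **In-silico multiplex PCR** — binding-site location under an explicit
  mismatch policy, amplicon prediction, cross-reactivity matrices, and
  partitioning of assays into gel-resolvable k-plex reactions (pentaplexes
  by default).
* **Genotyping & audit** — virtual gels, exact band-length presence calls,
  and per-product claimed/unclaimed × present/absent audit matrices with
  strain-level confirmed/mismatched/unresolvable calls.
* **16S V4 profiling** — read-pair merging, Phred ≥ 30 / no-N filtering,
  100%-identity dereplication, type-strain assignment with collapsing of
  V4-indistinguishable species groups, >0.1% minor-OTU filtering, relative
  abundance, and the two summary regressions (percent reads on log10 CFU;
  mean abundance on ln rank).
* **Enumeration audit** — triplicate pour-plate arithmetic, log10-scale
  claim comparison, Welch t-test between potency-basis groups, and
  DNA-yield cell-equivalence (limit-of-detection bookkeeping).
* **Synthetic data** — seeded generators for marker panels with 16S-like
  vs pgi-like conservation, mock-community standards (even /
  reaction-subset / 1000:1 spiked), paired amplicon reads, and mislabeled
  product fixtures (species swaps, omissions, additions).

## Worked example

Design a panel on a synthetic six-taxon *pgi*-like marker set, multiplex
it, and audit a product whose label claims *B. longum* while the capsule
actually contains *B. infantis* — the classic sub-species swap:

```r
library(probioplex)

spec <- panel_spec(n_taxa = 6, strains_per_taxon = 2, gene_length = 500,
                   between_taxon_identity = c(pgi = 85), seed = 101)
panel <- generate_panel(spec)$pgi
panel
#> marker_panel: 6 taxa, 12 sequences, locus pgi

assays <- design_panel_assays(panel)
assays[["Bifidobacterium longum infantis"]]
#> assay_definition: Bifidobacterium longum infantis (species_level)
#>   F: TTGCTAGCTTGATAAGCGTGGAC
#>   R: CTATTAGTTCCACCTCCCAACTTTT
#>   expected amplicon: 206 bp

cross_reactivity(assays, panel)
#> cross_reactivity: 6 assays x 6 taxa; 0 non-empty off-diagonal cells

scheme <- partition_assays(assays, plex_size = 3)
scheme
#> multiplex_scheme: 4 reactions
#>   rxnA: 166 bp (Bifidobacterium longum longum), 235 bp (Bifidobacterium animalis lactis)
#>   rxnB: 203 bp (Bifidobacterium bifidum), 258 bp (Bifidobacterium breve)
#>   rxnC: 206 bp (Bifidobacterium longum infantis)
#>   rxnD: 225 bp (Bifidobacterium animalis animalis)

fx <- generate_product_fixture(panel, n_claimed = 3,
                               error_menu = "swap_related", seed = 42)
fx$claim$claimed_taxa
#> "Bifidobacterium longum longum" "Bifidobacterium animalis lactis"
#> "Bifidobacterium animalis animalis"

calls <- genotype_sample(fx$sequences, scheme)
row <- audit_against_label(calls, fx$claim)
subset(row$species, category != "unclaimed_absent")
#>                               taxon          category
#> 1     Bifidobacterium longum longum    claimed_absent
#> 2   Bifidobacterium animalis lactis   claimed_present
#> 5   Bifidobacterium longum infantis unclaimed_present
#> 6 Bifidobacterium animalis animalis   claimed_present
```

Every non-target lane stays empty (no cross-amplification), the claimed
*B. longum* band is missing, and an unclaimed *B. infantis* band appears at
its expected 206 bp — the audit classifies the swap as one `claimed_absent`
plus one `unclaimed_present`.

The enumeration side is plain arithmetic with explicit conventions:

```r
cells_per_concentration(1, cells_in = 1.2e10, dna_conc_out_ng = 51.8)
#> 230000           # cells at the 1 pg/uL limit of detection
cfu_from_plates(c(100, 110, 120), 1e8)$cfu_per_g
#> 1.1e10
compare_claim(4e11, label_claim("p1", "Lactobacillus acidophilus", 1e10))$status
#> "above"
```

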