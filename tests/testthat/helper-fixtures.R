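# Shared fixtures, built once per test run and cached. Small panels keep
# the unit suite fast; the acceptance file builds its own full-size panel.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 6-taxon pgi-like panel, divergent enough for assay design to succeed
small_pgi_panel <- function() {
  cached("small_pgi", function() {
    spec <- panel_spec(n_taxa = 6, strains_per_taxon = 2, gene_length = 500,
                      within_taxon_identity = 99.5,
                      between_taxon_identity = c(pgi = 85), seed = 101)
    generate_panel(spec)$pgi
  })
}

small_assays <- function() {
  cached("small_assays", function() design_panel_assays(small_pgi_panel()))
}

small_scheme <- function() {
  cached("small_scheme", function() {
    partition_assays(small_assays(), plex_size = 3, gel = gel_model(50))
  })
}

# 12-taxon 16S-like panel and V4 references (collapsed related pairs)
small_16s_refs <- function() {
  cached("small_16s_refs", function() {
    spec <- panel_spec(n_taxa = 12, strains_per_taxon = 1, gene_length = 700,
                      within_taxon_identity = 99.5,
                      between_taxon_identity = c("16S" = 97), seed = 202)
    panel <- generate_panel(spec)[["16S"]]
    list(panel = panel,
         refs = v4_reference_set(panel, v4_start = 150, v4_len = 250))
  })
}

# hand-made two-assay scheme with known primers planted on tiny templates
toy_assay <- function(taxon, fwd, rev, expected_length) {
  fcand <- data.frame(sequence = fwd, strand = "+", start = 0L,
                      length = nchar(fwd), tm = tm_wallace(fwd),
                      gc = gc_percent(fwd), stringsAsFactors = FALSE)
  rcand <- data.frame(sequence = rev, strand = "-", start = 0L,
                      length = nchar(rev), tm = tm_wallace(rev),
                      gc = gc_percent(rev), stringsAsFactors = FALSE)
  assay_definition(taxon, fcand, rcand, expected_length)
}

# template of `total` bp that carries fwd at the start and the reverse
# primer's binding site at the end, so the assay yields one product of
# length `total`
planted_template <- function(fwd, rev, total, seed = 1) {
  set.seed(seed)
  filler <- random_dna(total - nchar(fwd) - nchar(rev))
  paste0(fwd, filler, revcomp(rev))
}
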