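test_that("Wallace Tm matches hand arithmetic and is GC-monotone", {
  expect_equal(tm_wallace("AATT"), 8)
  expect_equal(tm_wallace("GGCC"), 16)
  expect_equal(tm_wallace("ACGT"), 12)
  expect_error(tm_wallace("ACGW"), "non-degenerate")
  set.seed(21)
  for (i in 1:20) {
    s <- random_dna(sample(10:25, 1))
    chars <- strsplit(s, "")[[1]]
    at <- which(chars %in% c("A", "T"))
    if (!length(at)) next
    pos <- sample(at, 1)
    chars[pos] <- sample(c("G", "C"), 1)
    expect_gt(tm_wallace(paste(chars, collapse = "")), tm_wallace(s))
  }
})

test_that("complementarity runs follow the antiparallel duplex geometry", {
  expect_equal(complementarity_run("AAAA", "TTTT")$max_run, 4)
  expect_equal(complementarity_run("ACGT", "ACGT")$max_run, 4)
  expect_equal(complementarity_run("AAAA", "AAAA")$max_run, 0)
  # 3' run requires the run to touch a's last base
  r <- complementarity_run("TTTTGG", "AAAA")
  expect_equal(r$max_run, 4)
  expect_equal(r$three_prime_run_a, 0)
  r2 <- complementarity_run("GGTTTT", "AAAA")
  expect_equal(r2$three_prime_run_a, 4)
})

test_that("candidate enumeration respects degeneracy, GC and Tm screens", {
  params <- design_params(primer_len_range = c(18, 20))
  # a W in the middle of an otherwise eligible region blocks spanning windows
  set.seed(31)
  left <- random_dna(40)
  right <- random_dna(40)
  cons <- paste0(left, "W", right)
  cands <- enumerate_candidates(build_consensus(cons), params)
  if (nrow(cands)) {
    w_pos <- nchar(left) # 0-based position of the W
    expect_true(all(cands$start > w_pos | cands$start + cands$length <= w_pos))
  }
  # all-A consensus: GC 0%, outside range
  cands_a <- enumerate_candidates(build_consensus(strrep("A", 100)), params)
  expect_equal(nrow(cands_a), 0)
})

test_that("every enumerated candidate passes its own screens (idempotence)", {
  set.seed(32)
  cons <- random_dna(400)
  params <- design_params()
  cands <- enumerate_candidates(build_consensus(cons), params)
  expect_gt(nrow(cands), 0)
  for (i in seq_len(nrow(cands))) {
    s <- cands$sequence[i]
    expect_true(nchar(s) >= params$primer_len_range[1] &&
                nchar(s) <= params$primer_len_range[2])
    expect_true(cands$gc[i] >= params$gc_range[1] &&
                cands$gc[i] <= params$gc_range[2])
    expect_equal(cands$tm[i], tm_wallace(s))
    hp <- complementarity_run(s, s)
    expect_lt(hp$max_run, params$max_self_comp_run)
    expect_lt(hp$three_prime_run_a, params$max_3prime_comp_run)
  }
  # deterministic ordering: position then length
  expect_true(!is.unsorted(cands$start))
})

test_that("specificity profile handles identity and strand symmetry", {
  panel <- marker_panel(data.frame(
    taxon = c("Escherichia coli", "Salmonella enterica"),
    genus = c("Escherichia", "Salmonella"),
    species = c("coli", "enterica"), subspecies = NA, strain = NA,
    sequence = c("TTTTACGTACGTACGTTTTT", "TTTTTTT"),
    source_id = c("e1", "s1"), stringsAsFactors = FALSE), "other")
  prof <- specificity_profile("ACGTACGTACGT", panel)
  ec <- prof[prof$taxon == "Escherichia coli", ]
  expect_equal(ec$min_mismatches, 0)
  expect_equal(ec$three_prime_mismatches, 0)
  # AAAA has no plus-strand match in TTTTTTT but a perfect minus-strand one
  prof2 <- specificity_profile("AAAA", panel)
  se <- prof2[prof2$taxon == "Salmonella enterica", ]
  expect_equal(se$min_mismatches, 0)
})

test_that("specificity profile equals the brute-force oracle", {
  set.seed(41)
  for (rep in 1:25) {
    primer <- random_dna(sample(8:15, 1))
    seqs <- replicate(2, random_dna(sample(40:120, 1)))
    panel <- marker_panel(data.frame(
      taxon = "Synthetica spA", genus = "Synthetica", species = "spA",
      subspecies = NA, strain = NA, sequence = seqs,
      source_id = c("a", "b"), stringsAsFactors = FALSE), "other")
    got <- specificity_profile(primer, panel, anchor_len = 3)
    want <- oracle_specificity(primer, seqs, anchor = 3)
    expect_equal(got$min_mismatches, want[1])
    expect_equal(got$three_prime_mismatches, want[2])
  }
})

test_that("assay design discriminates a divergent two-taxon panel", {
  set.seed(51)
  target <- random_dna(500)
  # off-target: same backbone with a heavily mutated middle
  chars <- strsplit(target, "")[[1]]
  idx <- 150:320
  chars[idx] <- vapply(chars[idx], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, "")
  offtarget <- paste(chars, collapse = "")
  panel <- marker_panel(data.frame(
    taxon = rep(c("Lactobacillus casei", "Lactobacillus paracasei"),
                each = 1),
    genus = "Lactobacillus", species = c("casei", "paracasei"),
    subspecies = NA, strain = NA,
    sequence = c(target, offtarget),
    source_id = c("t1", "o1"), stringsAsFactors = FALSE), "pgi")
  assay <- design_assay("Lactobacillus casei", panel)
  offt <- marker_panel(panel$entries[2, ], "pgi")
  for (p in c(assay$forward$sequence, assay$reverse$sequence)) {
    prof <- specificity_profile(p, offt)
    expect_gte(prof$min_mismatches, 1)
  }
  # closure: the assay amplifies its own template at the expected length
  amp <- predict_amplicons(assay, target)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, assay$expected_length)
})

test_that("design fails cleanly on impossible panels", {
  set.seed(52)
  s <- random_dna(300)
  panel <- marker_panel(data.frame(
    taxon = c("Lactobacillus casei", "Lactobacillus paracasei"),
    genus = "Lactobacillus", species = c("casei", "paracasei"),
    subspecies = NA, strain = NA, sequence = c(s, s),
    source_id = c("a", "b"), stringsAsFactors = FALSE), "pgi")
  expect_error(design_assay("Lactobacillus casei", panel), "infeasible")
  single <- marker_panel(panel$entries[1, ], "pgi")
  expect_error(design_assay("Lactobacillus casei", single), "off-target")
  expect_error(design_assay("Lactobacillus gasseri", panel), "not in panel")
})

test_that("assay design is deterministic", {
  panel <- small_pgi_panel()
  tx <- panel_taxa(panel)[1]
  a1 <- design_assay(tx, panel)
  a2 <- design_assay(tx, panel)
  expect_identical(a1, a2)
})

test_that("designed panels pass their own cross-reactivity validation", {
  panel <- small_pgi_panel()
  assays <- small_assays()
  xr <- cross_reactivity(assays, panel)
  for (i in seq_along(xr$assays)) {
    for (j in seq_along(xr$taxa)) {
      cell <- xr$cells[[i, j]]
      if (xr$assays[i] == xr$taxa[j]) {
        expect_true(assays[[i]]$expected_length %in% cell)
      } else {
        expect_length(cell, 0)
      }
    }
  }
})

test_that("assay tables and primer FASTA round-trip", {
  assays <- small_assays()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assay_table(assays, path)
  back <- read_assay_table(path)
  expect_equal(length(back), length(assays))
  for (tx in names(assays)) {
    expect_identical(back[[tx]]$forward$sequence, assays[[tx]]$forward$sequence)
    expect_identical(back[[tx]]$reverse$sequence, assays[[tx]]$reverse$sequence)
    expect_equal(back[[tx]]$expected_length, assays[[tx]]$expected_length)
  }
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_primer_fasta(assays, fa)
  expect_equal(sum(startsWith(readLines(fa), ">")), 2 * length(assays))
})
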