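const_qual <- function(n, q = 35L) strrep(intToUtf8(q + 33L), n)

test_that("pair merging joins exact overlaps with the right arithmetic", {
  set.seed(81)
  amplicon <- random_dna(120)
  f <- substr(amplicon, 1, 70)             # 70 nt forward
  r <- revcomp(substr(amplicon, 51, 120))  # 70 nt reverse, 20 nt overlap
  fs <- read_set("s", f, const_qual(70))
  rs <- read_set("s", r, const_qual(70))
  merged <- merge_pairs(fs, rs, min_overlap = 20)
  expect_equal(n_reads(merged), 1)
  expect_equal(attr(merged, "n_dropped"), 0)
  expect_equal(nchar(merged$sequences), 70 + 70 - 20)
  expect_identical(merged$sequences, amplicon)
})

test_that("unmergeable pairs are dropped and counted", {
  set.seed(82)
  fs <- read_set("s", random_dna(60), const_qual(60))
  rs <- read_set("s", random_dna(60), const_qual(60))
  merged <- merge_pairs(fs, rs, min_overlap = 30,
                        max_overlap_mismatch_frac = 0)
  expect_equal(n_reads(merged), 0)
  expect_equal(attr(merged, "n_dropped"), 1)
  expect_error(merge_pairs(fs, read_set("s", character(0), character(0))),
               "differ in length")
})

test_that("planted overlaps reconstruct the designed amplicon length", {
  set.seed(83)
  for (rep in 1:15) {
    total <- sample(150:260, 1)
    rl <- sample(100:140, 1)
    if (2 * rl - total < 25) next  # ensure a comfortable overlap
    amplicon <- random_dna(total)
    f <- substr(amplicon, 1, rl)
    r <- revcomp(substr(amplicon, total - rl + 1, total))
    merged <- merge_pairs(read_set("s", f, const_qual(rl)),
                          read_set("s", r, const_qual(rl)),
                          min_overlap = 20)
    expect_equal(nchar(merged$sequences), total)
    expect_identical(merged$sequences, amplicon)
  }
})

test_that("overlap disagreements take the higher-quality base", {
  set.seed(87)
  amplicon <- random_dna(60)
  fchars <- strsplit(substr(amplicon, 1, 40), "")[[1]]
  # plant a low-quality miscall inside the overlap (positions 21-40)
  fchars[31] <- setdiff(c("A", "C", "G", "T"), fchars[31])[1]
  f <- paste(fchars, collapse = "")
  r <- revcomp(substr(amplicon, 21, 60))  # clean, high-quality reverse
  fq <- paste0(const_qual(30, 35), intToUtf8(20 + 33), const_qual(9, 35))
  merged <- merge_pairs(read_set("s", f, fq),
                        read_set("s", r, const_qual(40, 35)),
                        min_overlap = 15)
  expect_identical(merged$sequences, amplicon)
  # and the reverse preference: make the forward base the trusted one
  merged2 <- merge_pairs(read_set("s", f, const_qual(40, 38)),
                         read_set("s", r, const_qual(40, 35)),
                         min_overlap = 15)
  expect_identical(merged2$sequences, paste0(f, substr(amplicon, 41, 60)))
})

test_that("quality filtering removes ambiguous and sub-threshold reads", {
  reads <- read_set("s",
                    c("ACGT", "ACNT", "ACGG"),
                    c(const_qual(4, 30), const_qual(4, 40),
                      paste0(const_qual(3, 40), intToUtf8(29 + 33))))
  out <- quality_filter(reads, min_q = 30)
  # all-Q30 read retained (rule removes < 30), N removed, Q29 removed
  expect_equal(out$sequences, "ACGT")
  expect_equal(attr(out, "n_removed"), 2)
})

test_that("a planted low-quality base count is recovered exactly", {
  refs <- small_16s_refs()$refs
  comm <- generate_mock_community("even",
                                  unlist(refs$entries$member_taxa))
  sim <- simulate_reads(comm, refs, n_reads = 1000, error_rate = 0,
                        quality_q = 35, seed = 84, read_len = 150,
                        n_lowq = 100, lowq_score = 29)
  out <- quality_filter(sim$forward, min_q = 30)
  expect_equal(n_reads(out), 900)
  expect_equal(attr(out, "n_removed"), 100)
})

test_that("dereplication collapses identical sequences and keeps counts", {
  reads <- read_set("s", c(rep("ACGTACGT", 10), "ACGTACGA"),
                    rep(const_qual(8), 11))
  tab <- dereplicate(reads)
  expect_equal(nrow(tab$otus), 2)
  expect_equal(sort(tab$otus$s, decreasing = TRUE), c(10, 1))
  expect_equal(sum(otu_counts(tab)), 11)
  # one-base difference keeps OTUs separate (100% identity rule)
  expect_equal(nrow(dereplicate(read_set("s", c("AAAA", "AAAT"),
                                         rep(const_qual(4), 2)))$otus), 2)
})

test_that("reference building collapses identical V4 sequences", {
  refs <- build_reference_set(
    c("Bifidobacterium breve", "Bifidobacterium longum longum",
      "Lactobacillus gasseri"),
    c("ACGTACGTAA", "ACGTACGTAA", "TTGGCCAATT"))
  expect_equal(nrow(refs$entries), 2)
  grp <- taxon_group_of(refs, "Bifidobacterium longum longum")
  expect_identical(grp, "Bifidobacterium breve|Bifidobacterium longum longum")
  expect_identical(taxon_group_of(refs, "Bifidobacterium breve"), grp)
})

test_that("taxonomy assignment picks the closest group and flags ties", {
  refs <- build_reference_set(c("A a", "B b"),
                              c("ACGTACGTACGTACGTACGT",
                                "TTTTTTTTTTGGGGGGGGGG"))
  reads <- read_set("s", c("ACGTACGTACGTACGTACGT"), const_qual(20))
  tab <- assign_taxonomy(dereplicate(reads), refs)
  expect_identical(tab$otus$taxon_group, "A a")
  expect_equal(tab$otus$identity, 100)
  expect_false(tab$otus$ambiguous)
  # equidistant OTU: union group, flagged
  refs2 <- build_reference_set(c("A a", "B b"), c("AAAAAAAA", "AAAATTTT"))
  tab2 <- assign_taxonomy(dereplicate(read_set("s", "AAAAAATT",
                                               const_qual(8))), refs2)
  expect_true(tab2$otus$ambiguous)
  expect_identical(tab2$otus$taxon_group, "A a|B b")
})

test_that("minor-OTU filtering is strict and conserves read mass", {
  reads <- read_set("s", c(rep("AAAA", 998), "CCCC", "GGGG"),
                    rep(const_qual(4), 1000))
  tab <- assign_taxonomy(dereplicate(reads),
                         build_reference_set(c("A a", "C c", "G g"),
                                             c("AAAA", "CCCC", "GGGG")))
  # 1/1000 = exactly 0.1%: removed under the strict > rule
  out <- filter_minor(tab, min_frac = 0.001)
  expect_equal(nrow(out$otus), 1)
  expect_equal(attr(out, "n_removed_reads"), 2)
  expect_equal(sum(otu_counts(out)) + attr(out, "n_removed_reads"),
               sum(otu_counts(tab)))
  # 0.2% survives
  out2 <- filter_minor(tab, min_frac = 0.0005)
  expect_equal(nrow(out2$otus), 3)
})

test_that("relative abundance sums to 100 and excludes empty samples", {
  refs <- build_reference_set(c("A a", "B b"), c("AAAA", "CCCC"))
  r1 <- read_set("s1", c(rep("AAAA", 75), rep("CCCC", 25)),
                 rep(const_qual(4), 100))
  r2 <- read_set("s2", character(0), character(0))
  tab <- assign_taxonomy(dereplicate(list(r1, r2)), refs)
  expect_warning(ab <- relative_abundance(tab), "insufficient")
  expect_setequal(ab$sample, "s1")
  expect_equal(sum(ab$percent), 100, tolerance = 1e-9)
  expect_equal(ab$percent[ab$taxon_group == "A a"], 75)
  expect_equal(ab$percent[ab$taxon_group == "B b"], 25)
})

test_that("read counts are conserved through every pipeline stage", {
  fixtures <- small_16s_refs()
  refs <- fixtures$refs
  comm <- generate_mock_community("even", unlist(refs$entries$member_taxa))
  sim <- simulate_reads(comm, refs, n_reads = 3000, error_rate = 0.002,
                        quality_q = 35, seed = 85, read_len = 150,
                        n_lowq = 30)
  res <- profile_amplicons(list(sim$forward), list(sim$reverse), refs,
                           min_frac = 0)
  acct <- res$accounting
  expect_equal(acct$n_merged + acct$n_dropped_merge, acct$n_pairs)
  expect_equal(acct$n_filtered + acct$n_removed_quality, acct$n_merged)
  expect_equal(sum(otu_counts(res$table)), acct$n_filtered)
  expect_equal(sum(res$abundance$percent), 100, tolerance = 1e-9)
})

test_that("regression on a perfect dilution line gives unit R-squared", {
  res <- cfu_read_regression(c(5, 6, 7, 8), c(1, 11, 21, 31))
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, 10)
  expect_error(cfu_read_regression(c(5, 5, 5), c(1, 2, 3)), "zero variance")
})

test_that("rank-abundance log fit recovers slope and handles flat input", {
  ranks <- 1:10
  ab <- 40 - 8 * log(ranks)
  res <- rank_abundance_fit(ab)
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, -8)
  flat <- rank_abundance_fit(rep(5, 6))
  expect_equal(flat$slope, 0)
})

test_that("FASTQ writing and reading round-trips a read set", {
  set.seed(86)
  reads <- read_set("mysample", replicate(5, random_dna(50)),
                    replicate(5, const_qual(50, sample(20:40, 1))))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path, "mysample")
  expect_identical(back$sequences, reads$sequences)
  expect_identical(back$qualities, reads$qualities)
})
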