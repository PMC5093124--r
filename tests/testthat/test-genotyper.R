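test_that("virtual gel shows exactly the planted taxa's bands", {
  panel <- small_pgi_panel()
  scheme <- small_scheme()
  taxa <- panel_taxa(panel)
  # sample holding only the first taxon's marker
  sample_seqs <- panel_sequences(panel, taxa[1])
  pattern <- virtual_gel(sample_seqs, scheme)
  assays <- small_assays()
  expected <- assays[[taxa[1]]]$expected_length
  in_rxn <- vapply(scheme$reactions,
                   function(rxn) any(vapply(rxn, function(a) a$taxon, "") ==
                                       taxa[1]), TRUE)
  expect_equal(pattern[[which(in_rxn)]], expected)
  expect_true(all(lengths(pattern[!in_rxn]) == 0))
  # empty sample: all reactions empty
  empty <- virtual_gel(character(0), scheme)
  expect_true(all(lengths(empty) == 0))
})

test_that("two taxa sharing a reaction give two bands", {
  panel <- small_pgi_panel()
  scheme <- small_scheme()
  sizes <- lengths(scheme$reactions)
  expect_true(any(sizes >= 2))
  ri <- which(sizes >= 2)[1]
  rxn <- scheme$reactions[[ri]]
  tx <- vapply(rxn[1:2], function(a) a$taxon, "")
  seqs <- c(panel_sequences(panel, tx[1]), panel_sequences(panel, tx[2]))
  pattern <- virtual_gel(seqs, scheme)
  expect_length(pattern[[ri]], 2)
})

test_that("presence calling is exact at zero tolerance", {
  a300 <- toy_assay("Lactobacillus casei", "ACGTACGTACGTACGTAC",
                    "GGATCCGGATCCGGATCC", 300)
  a400 <- toy_assay("Lactobacillus rhamnosus", "ACGTACGTACGTACGTAC",
                    "GGATCCGGATCCGGATCC", 400)
  scheme <- structure(list(reactions = list(list(a300, a400)),
                           gel = gel_model(50, length_tolerance = 0)),
                      class = "multiplex_scheme")
  pat <- structure(list(rxnA = 300L), class = "band_pattern")
  calls <- call_presence(pat, scheme)
  expect_true(calls$detected[calls$taxon == "Lactobacillus casei"])
  expect_equal(calls$matched_length[calls$taxon == "Lactobacillus casei"],
               300L)
  pat310 <- structure(list(rxnA = 310L), class = "band_pattern")
  calls310 <- call_presence(pat310, scheme)
  expect_false(any(calls310$detected))
  # with tolerance the nearest assay picks it up
  scheme_tol <- scheme
  scheme_tol$gel <- gel_model(50, length_tolerance = 15)
  calls_tol <- call_presence(pat310, scheme_tol)
  expect_true(calls_tol$detected[calls_tol$taxon == "Lactobacillus casei"])
  expect_false(calls_tol$detected[calls_tol$taxon == "Lactobacillus rhamnosus"])
})

test_that("audit categories follow the four-way rule", {
  calls <- data.frame(
    taxon = c("A a", "B b", "C c"),
    detected = c(TRUE, FALSE, TRUE),
    matched_length = c(300L, NA, 500L), ambiguous = FALSE,
    stringsAsFactors = FALSE)
  claim <- label_claim("p1", c("A a", "B b"), 1e10)
  row <- audit_against_label(calls, claim)
  cat_of <- function(tx) row$species$category[row$species$taxon == tx]
  expect_equal(cat_of("A a"), "claimed_present")
  expect_equal(cat_of("B b"), "claimed_absent")
  expect_equal(cat_of("C c"), "unclaimed_present")
  # claimed taxon outside the panel: not testable
  claim2 <- label_claim("p2", c("A a", "Z z"), 1e10)
  row2 <- audit_against_label(calls, claim2)
  expect_equal(row2$species$category[row2$species$taxon == "Z z"],
               "not_testable")
})

test_that("strain claims resolve to confirmed, mismatched or unresolvable", {
  calls <- data.frame(taxon = "A a", detected = TRUE, matched_length = 300L,
                      ambiguous = FALSE, stringsAsFactors = FALSE)
  strain_calls <- data.frame(
    taxon = c("A a strain1", "A a strain2"),
    detected = c(TRUE, FALSE), matched_length = c(120L, NA),
    ambiguous = FALSE, stringsAsFactors = FALSE)
  claim <- label_claim("p", "A a", 1e10,
                       claimed_strains = c("A a strain1", "A a strain2",
                                           "A a strain3"))
  row <- audit_against_label(calls, claim, strain_calls)
  expect_equal(row$strains$category,
               c("confirmed", "mismatched", "unresolvable"))
})

test_that("audit summaries reproduce the printed-count arithmetic", {
  # survey shares recomputed from their printed integer counts
  expect_equal(percent_of_products(22, 52), 42.3)
  expect_equal(percent_of_products(18, 52), 34.6)
  expect_equal(percent_of_products(35, 52), 67.3)
  # an all-correct cohort summarizes to zero discrepancy
  calls <- data.frame(taxon = c("A a", "B b"), detected = c(TRUE, TRUE),
                      matched_length = c(1L, 2L), ambiguous = FALSE,
                      stringsAsFactors = FALSE)
  rows <- lapply(1:4, function(i) {
    audit_against_label(calls, label_claim(paste0("p", i), c("A a", "B b"),
                                           1e9))
  })
  s <- summarize_audit(audit_matrix(rows))
  expect_equal(s$n_products, 4)
  expect_equal(s$n_discrepant, 0)
  expect_equal(s$pct_discrepant, 0)
})

test_that("audit categories partition the product-by-taxon space", {
  panel <- small_pgi_panel()
  scheme <- small_scheme()
  n_taxa <- length(panel_taxa(panel))
  rows <- lapply(1:6, function(s) {
    fx <- generate_product_fixture(panel, n_claimed = 2,
                                   error_menu = if (s %% 2) "omit" else character(0),
                                   seed = s)
    audit_against_label(genotype_sample(fx$sequences, scheme), fx$claim)
  })
  counts <- vapply(rows, function(r) {
    sum(r$species$category %in% c("claimed_present", "claimed_absent",
                                  "unclaimed_present", "unclaimed_absent"))
  }, 0L)
  expect_true(all(counts == n_taxa))
})

test_that("mislabel fixtures land in their intended categories", {
  panel <- small_pgi_panel()
  scheme <- small_scheme()
  # swap: one claimed_absent plus one unclaimed_present
  fx <- generate_product_fixture(panel, n_claimed = 3,
                                 error_menu = "swap_related", seed = 9,
                                 related_pairs = list(panel_taxa(panel)[1:2]))
  row <- audit_against_label(genotype_sample(fx$sequences, scheme), fx$claim)
  tab <- table(row$species$category)
  expect_equal(unname(tab["claimed_absent"]), 1)
  expect_equal(unname(tab["unclaimed_present"]), 1)
  # omit: exactly one claimed_absent
  fx2 <- generate_product_fixture(panel, n_claimed = 3, error_menu = "omit",
                                  seed = 10)
  row2 <- audit_against_label(genotype_sample(fx2$sequences, scheme),
                              fx2$claim)
  expect_equal(sum(row2$species$category == "claimed_absent"), 1)
  expect_equal(sum(row2$species$category == "unclaimed_present"), 0)
})

test_that("claims and audit matrices survive their table round-trips", {
  claims <- list(
    label_claim("p1", c("Lactobacillus casei", "Bifidobacterium breve"),
                5e9, potency_basis = "time_of_manufacture",
                months_to_expiration = 6,
                claimed_strains = "Lactobacillus acidophilus NCFM"),
    label_claim("p2", "Lactobacillus gasseri", 2e10))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_label_claims(claims, path)
  back <- read_label_claims(path)
  expect_equal(back[[1]]$claimed_taxa, claims[[1]]$claimed_taxa)
  expect_equal(back[[1]]$claimed_strains, claims[[1]]$claimed_strains)
  expect_equal(back[[2]]$claimed_cfu_per_g, 2e10)
  # a cohort with no strain claims at all still round-trips
  no_strains <- list(label_claim("q1", "A a", 1e9),
                     label_claim("q2", "B b", 1e9))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_label_claims(no_strains, path2)
  back2 <- read_label_claims(path2)
  expect_length(back2[[1]]$claimed_strains, 0)

  calls <- data.frame(taxon = c("A a", "B b"), detected = c(TRUE, FALSE),
                      matched_length = c(1L, NA), ambiguous = FALSE,
                      stringsAsFactors = FALSE)
  rows <- list(audit_against_label(calls, label_claim("p1", "A a", 1e9)),
               audit_against_label(calls, label_claim("p2", "B b", 1e9)))
  mat_path <- withr::local_tempfile(fileext = ".tsv")
  write_audit_matrix(audit_matrix(rows), mat_path)
  df <- read.delim(mat_path, check.names = FALSE)
  expect_equal(df$product_id, c("p1", "p2"))
  expect_equal(df[["A a"]], c("claimed_present", "unclaimed_present"))
  expect_equal(df[["B b"]], c("unclaimed_absent", "claimed_absent"))
})
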