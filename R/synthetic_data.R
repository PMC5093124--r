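# Seeded generators: marker panels with locus-specific conservation
# (16S-like high, pgi-like lower), mock community standards (even /
# reaction-subset / spiked designs), paired amplicon reads, and mislabeled
# product fixtures with species swaps, omissions and additions.

# run expr under a temporary RNG state; restores the caller's stream
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# per-lineage substitution probability giving expected pairwise identity t
# between two lineages mutated independently from a common ancestor
# (substitutions uniform over the three other bases):
# P(match) = (1-p)^2 + p^2/3 = t  =>  p = (3/4) (1 - sqrt(1 - (4/3)(1-t)))
.divergence_rate <- function(identity_pct) {
  t <- identity_pct / 100
  arg <- 1 - (4 / 3) * (1 - t)
  if (arg < 0) {
    stop("target identity ", identity_pct,
         "% is below the random-sequence floor (25%)")
  }
  (3 / 4) * (1 - sqrt(arg))
}

.mutate <- function(chars, p) {
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
    idx <- which(hit)
    repl <- vapply(chars[idx], function(b) sample(alts[[b]], 1L), "")
    chars[idx] <- repl
  }
  chars
}

#' Synthetic panel specification
#'
#' @param n_taxa number of taxa (default 20; the default roster is used for
#'   up to 20, synthetic binomials beyond that).
#' @param strains_per_taxon sequences per taxon.
#' @param gene_length marker gene length (bp).
#' @param within_taxon_identity expected percent identity between strains of
#'   one taxon.
#' @param between_taxon_identity named numeric vector of expected
#'   between-taxon identity per locus, e.g. `c("16S" = 98, pgi = 85)` —
#'   16S-like conservation must exceed pgi-like.
#' @param seed RNG seed.
#' @return object of class `panel_spec`.
#' @export
panel_spec <- function(n_taxa = 20L, strains_per_taxon = 2L,
                       gene_length = 600L,
                       within_taxon_identity = 99.5,
                       between_taxon_identity = c("16S" = 98, pgi = 85),
                       seed = 1L) {
  stopifnot(n_taxa >= 1L, strains_per_taxon >= 1L, gene_length >= 50L,
            all(between_taxon_identity > 0),
            all(between_taxon_identity <= 100),
            within_taxon_identity > max(between_taxon_identity))
  if (is.null(names(between_taxon_identity))) {
    stop("between_taxon_identity must be named by locus")
  }
  structure(list(n_taxa = as.integer(n_taxa),
                 strains_per_taxon = as.integer(strains_per_taxon),
                 gene_length = as.integer(gene_length),
                 within_taxon_identity = within_taxon_identity,
                 between_taxon_identity = between_taxon_identity,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

.spec_taxa <- function(n_taxa) {
  roster <- default_taxon_roster()
  if (n_taxa <= length(roster)) {
    roster[seq_len(n_taxa)]
  } else {
    c(roster, sprintf("Synthetica sp%d",
                      seq_len(n_taxa - length(roster))))
  }
}

#' Generate marker panels from a specification
#'
#' One ancestral sequence per locus; each taxon's base sequence is derived
#' by seeded substitutions calibrated to hit the locus's between-taxon
#' identity in expectation, and strains by within-taxon substitutions.
#' Substitution-only evolution (no indels) keeps alignments exact.
#'
#' @param spec a `panel_spec`.
#' @return named list of `marker_panel` objects, one per locus named in
#'   `spec$between_taxon_identity`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  taxa <- .spec_taxa(spec$n_taxa)
  q_within <- .divergence_rate(spec$within_taxon_identity)
  .with_seed(spec$seed, {
    out <- lapply(seq_along(spec$between_taxon_identity), function(li) {
      locus_name <- names(spec$between_taxon_identity)[li]
      p_between <- .divergence_rate(spec$between_taxon_identity[[li]])
      ancestor <- sample(c("A", "C", "G", "T"), spec$gene_length,
                         replace = TRUE)
      rows <- list()
      for (ti in seq_along(taxa)) {
        base <- .mutate(ancestor, p_between)
        for (si in seq_len(spec$strains_per_taxon)) {
          strain_chars <- if (si == 1L) base else .mutate(base, q_within)
          tx <- parse_taxon(taxa[ti])
          rows[[length(rows) + 1L]] <- data.frame(
            taxon = taxa[ti], genus = tx$genus, species = tx$species,
            subspecies = tx$subspecies, strain = tx$strain,
            sequence = paste(strain_chars, collapse = ""),
            source_id = sprintf("syn_%s_t%02d_s%d", locus_name, ti, si),
            stringsAsFactors = FALSE)
        }
      }
      locus_kind <- if (locus_name %in% c("pgi", "16S")) locus_name else "other"
      marker_panel(do.call(rbind, rows), locus = locus_kind)
    })
    names(out) <- names(spec$between_taxon_identity)
    out
  })
}

#' Slice V4-like reference sequences from a 16S panel
#'
#' Takes each taxon's representative sequence and extracts a hypervariable
#' window; optionally forces listed related pairs to share an identical V4
#' (emulating species indistinguishable by the amplicon, which then collapse
#' into one reference group).
#'
#' @param panel_16s a 16S-like `marker_panel`.
#' @param v4_start 1-based window start on the gene (default 200).
#' @param v4_len window length (default 250).
#' @param collapse_pairs list of length-2 taxon label vectors whose V4
#'   regions are made identical (default [related_taxon_pairs()],
#'   intersected with the panel).
#' @return a `reference_set`.
#' @export
v4_reference_set <- function(panel_16s, v4_start = 200L, v4_len = 250L,
                             collapse_pairs = related_taxon_pairs()) {
  taxa <- panel_taxa(panel_16s)
  reps <- vapply(taxa, function(tx) panel_sequences(panel_16s, tx)[1], "")
  if (v4_start + v4_len - 1L > min(nchar(reps))) {
    stop("V4 window extends past the gene end")
  }
  v4 <- substr(reps, v4_start, v4_start + v4_len - 1L)
  names(v4) <- taxa
  for (pair in collapse_pairs) {
    if (all(pair %in% taxa)) v4[pair[2]] <- v4[pair[1]]
  }
  build_reference_set(taxa, unname(v4))
}

#' Generate a mock community design
#'
#' The three standard designs: `even` (all members at the same level),
#' `reaction_subset` (only the taxa of one multiplex reaction), and
#' `spiked` (key targets high, all other members three orders of magnitude
#' lower: 1e8 vs 1e5 CFU/mL, or 1 ng/uL vs 1 pg/uL in DNA units).
#'
#' @param design_kind `"even"`, `"reaction_subset"` or `"spiked"`.
#' @param taxa full panel taxon labels.
#' @param key_taxa key targets (spiked) or the reaction's taxa
#'   (reaction_subset).
#' @param units `"cfu"` (CFU/mL) or `"dna"` (pg/uL).
#' @return object of class `community_design`: data.frame `members`
#'   (taxon, abundance), design_kind, units.
#' @export
generate_mock_community <- function(design_kind, taxa, key_taxa = NULL,
                                    units = c("cfu", "dna")) {
  units <- match.arg(units)
  if (!design_kind %in% c("even", "reaction_subset", "spiked")) {
    stop("unknown design_kind: ", design_kind)
  }
  high <- if (units == "cfu") 1e8 else 1000   # 1 ng/uL = 1000 pg/uL
  low <- if (units == "cfu") 1e5 else 1
  even_level <- if (units == "cfu") 1e8 else 100
  members <- switch(design_kind,
    even = data.frame(taxon = taxa, abundance = even_level,
                      stringsAsFactors = FALSE),
    reaction_subset = {
      if (is.null(key_taxa) || !all(key_taxa %in% taxa)) {
        stop("reaction_subset needs key_taxa drawn from the panel taxa")
      }
      data.frame(taxon = key_taxa, abundance = high,
                 stringsAsFactors = FALSE)
    },
    spiked = {
      if (is.null(key_taxa) || !all(key_taxa %in% taxa)) {
        stop("spiked design needs key_taxa drawn from the panel taxa")
      }
      data.frame(taxon = taxa,
                 abundance = ifelse(taxa %in% key_taxa, high, low),
                 stringsAsFactors = FALSE)
    })
  structure(list(members = members, design_kind = design_kind,
                 units = units),
            class = "community_design")
}

#' Simulate paired amplicon reads from a community
#'
#' Per-read source taxa are drawn proportional to abundance (one marker
#' copy per cell); the read pair covers the two ends of the member's V4
#' reference with an overlap set by the read length. Substitution errors
#' are applied per read at `error_rate`; qualities are constant at
#' `quality_q` except for optional planted low-quality bases.
#'
#' @param community a `community_design`.
#' @param refs a `reference_set` covering every community member.
#' @param n_reads number of read pairs.
#' @param error_rate per-base substitution probability.
#' @param quality_q constant Phred score of the simulated bases.
#' @param seed RNG seed.
#' @param read_len length of each mate (must be > half the V4 length for
#'   the pair to overlap).
#' @param n_lowq number of forward reads given one planted base at
#'   `lowq_score`.
#' @param lowq_score the planted low quality score (default 29).
#' @param sample_id sample identifier.
#' @return list: `forward` and `reverse` `read_set` objects plus `truth`
#'   (drawn read counts per taxon group).
#' @export
simulate_reads <- function(community, refs, n_reads, error_rate = 0,
                           quality_q = 35L, seed = 1L, read_len = 150L,
                           n_lowq = 0L, lowq_score = 29L,
                           sample_id = "sample") {
  members <- community$members
  groups <- vapply(members$taxon, function(tx) taxon_group_of(refs, tx), "")
  templates <- refs$entries$v4_sequence[match(groups,
                                              refs$entries$taxon_group)]
  stopifnot(read_len <= min(nchar(templates)))
  if (n_reads == 0L) {
    return(list(forward = read_set(sample_id, character(0), character(0)),
                reverse = read_set(sample_id, character(0), character(0)),
                truth = setNames(integer(0), character(0))))
  }
  .with_seed(seed, {
    src <- sample.int(nrow(members), n_reads, replace = TRUE,
                      prob = members$abundance)
    fwd <- substr(templates[src], 1L, read_len)
    rev_tmpl <- templates[src]
    rlen <- nchar(rev_tmpl)
    rev <- vapply(substr(rev_tmpl, rlen - read_len + 1L, rlen), revcomp, "",
                  USE.NAMES = FALSE)
    apply_errors <- function(reads) {
      if (error_rate <= 0) return(reads)
      n_err <- stats::rbinom(length(reads), read_len, error_rate)
      for (i in which(n_err > 0L)) {
        chars <- strsplit(reads[i], "")[[1]]
        pos <- sample.int(read_len, n_err[i])
        chars[pos] <- .mutate(chars[pos], 1)
        reads[i] <- paste(chars, collapse = "")
      }
      reads
    }
    fwd <- apply_errors(fwd)
    rev <- apply_errors(rev)
    qual <- strrep(intToUtf8(quality_q + 33L), read_len)
    fqual <- rep(qual, n_reads)
    if (n_lowq > 0L) {
      idx <- sample.int(n_reads, min(n_lowq, n_reads))
      for (i in idx) {
        pos <- sample.int(read_len, 1L)
        substr(fqual[i], pos, pos) <- intToUtf8(lowq_score + 33L)
      }
    }
    truth <- table(factor(groups[src], levels = unique(groups)))
    list(forward = read_set(sample_id, fwd, fqual),
         reverse = read_set(sample_id, rev, rep(qual, n_reads)),
         truth = setNames(as.integer(truth), names(truth)))
  })
}

#' Generate a (possibly mislabeled) product fixture
#'
#' Starts from a claimed taxon set drawn from the panel and injects labeling
#' errors: `swap_related` replaces a claimed species by its closely related
#' partner in the actual content (one claimed organism absent, one
#' unclaimed present), `omit` drops a claimed organism from the content,
#' `add` puts an unclaimed organism in. The claim plus the injected errors
#' reconstruct the true content exactly.
#'
#' @param panel a `marker_panel`.
#' @param n_claimed number of claimed taxa.
#' @param error_menu character vector drawn from
#'   `c("swap_related", "omit", "add")`; one error of each listed kind is
#'   injected (empty = correctly labeled product).
#' @param seed RNG seed.
#' @param related_pairs swap partners (default [related_taxon_pairs()]).
#' @param product_id product identifier.
#' @param claimed_cfu_per_g claimed potency.
#' @param potency_basis potency wording on the label.
#' @param months_to_expiration months remaining.
#' @return object of class `product_fixture`: `claim` (a `label_claim`),
#'   `true_taxa`, `injected_errors` (data.frame kind/from/to), and
#'   `sequences` (marker sequences of the true content).
#' @export
generate_product_fixture <- function(panel, n_claimed = 3L,
                                     error_menu = character(0), seed = 1L,
                                     related_pairs = related_taxon_pairs(),
                                     product_id = "product",
                                     claimed_cfu_per_g = 1e10,
                                     potency_basis = "through_expiration",
                                     months_to_expiration = 12) {
  taxa <- panel_taxa(panel)
  stopifnot(n_claimed >= 1L, n_claimed <= length(taxa))
  bad <- setdiff(error_menu, c("swap_related", "omit", "add"))
  if (length(bad)) stop("unknown error kind(s): ", paste(bad, collapse = ", "))
  .with_seed(seed, {
    errors <- data.frame(kind = character(0), from = character(0),
                         to = character(0), stringsAsFactors = FALSE)
    if ("swap_related" %in% error_menu) {
      usable <- Filter(function(p) all(p %in% taxa), related_pairs)
      if (!length(usable)) stop("no related pair is fully inside the panel")
      pair <- usable[[sample.int(length(usable), 1L)]]
      pair <- sample(pair)  # random direction
      claimed <- unique(c(pair[1],
                          sample(setdiff(taxa, pair), n_claimed - 1L)))
      truth <- union(setdiff(claimed, pair[1]), pair[2])
      errors <- rbind(errors, data.frame(kind = "swap_related",
                                         from = pair[1], to = pair[2],
                                         stringsAsFactors = FALSE))
    } else {
      claimed <- sample(taxa, n_claimed)
      truth <- claimed
    }
    if ("omit" %in% error_menu) {
      omittable <- intersect(claimed, truth)
      if (!length(omittable)) stop("no claimed taxon left to omit")
      victim <- omittable[sample.int(length(omittable), 1L)]
      truth <- setdiff(truth, victim)
      errors <- rbind(errors, data.frame(kind = "omit", from = victim,
                                         to = NA_character_,
                                         stringsAsFactors = FALSE))
    }
    if ("add" %in% error_menu) {
      pool <- setdiff(taxa, union(claimed, truth))
      if (!length(pool)) stop("no unclaimed taxon available to add")
      extra <- pool[sample.int(length(pool), 1L)]
      truth <- union(truth, extra)
      errors <- rbind(errors, data.frame(kind = "add", from = NA_character_,
                                         to = extra, stringsAsFactors = FALSE))
    }
    sequences <- unlist(lapply(truth, function(tx) panel_sequences(panel, tx)))
    claim <- label_claim(product_id, claimed, claimed_cfu_per_g,
                         potency_basis = potency_basis,
                         months_to_expiration = months_to_expiration)
    structure(list(claim = claim, true_taxa = truth,
                   injected_errors = errors,
                   sequences = unname(sequences)),
              class = "product_fixture")
  })
}
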