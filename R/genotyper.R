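# Run a virtual multiplex panel on a sample's sequences, call per-taxon
# presence by exact band-length matching against the expected ladder, and
# audit calls against label claims using the four-category semantics:
# claimed_present / claimed_absent / unclaimed_present / unclaimed_absent.

.rxn_id <- function(i) {
  if (i <= 26L) paste0("rxn", LETTERS[i]) else paste0("rxn", i)
}

#' Build a label claim record
#'
#' @param product_id product identifier.
#' @param claimed_taxa character vector of claimed taxon labels (non-empty).
#' @param claimed_cfu_per_g claimed potency (CFU/g, > 0).
#' @param potency_basis `"time_of_manufacture"` or `"through_expiration"`.
#' @param months_to_expiration months remaining at testing time.
#' @param claimed_strains optional character vector of strain-level labels.
#' @return object of class `label_claim`.
#' @export
label_claim <- function(product_id, claimed_taxa, claimed_cfu_per_g,
                        potency_basis = c("through_expiration",
                                          "time_of_manufacture"),
                        months_to_expiration = NA_real_,
                        claimed_strains = character(0)) {
  potency_basis <- match.arg(potency_basis)
  stopifnot(length(claimed_taxa) >= 1L, claimed_cfu_per_g > 0)
  structure(list(product_id = product_id,
                 claimed_taxa = unique(claimed_taxa),
                 claimed_strains = claimed_strains,
                 claimed_cfu_per_g = claimed_cfu_per_g,
                 potency_basis = potency_basis,
                 months_to_expiration = months_to_expiration),
            class = "label_claim")
}

#' Read label claims from a tab-separated table
#'
#' Columns: product_id, claimed_taxa (semicolon-separated labels),
#' claimed_cfu_per_g, potency_basis, months_to_expiration, and optionally
#' claimed_strains (semicolon-separated).
#'
#' @param path input file.
#' @return list of `label_claim` objects.
#' @export
read_label_claims <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("product_id", "claimed_taxa", "claimed_cfu_per_g",
              "potency_basis", "months_to_expiration")
  if (!all(needed %in% names(df))) {
    stop("claim table must have columns: ", paste(needed, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    strain_field <- if ("claimed_strains" %in% names(df)) {
      df$claimed_strains[i]
    } else NA
    strains <- if (is.character(strain_field) && !is.na(strain_field) &&
                   nzchar(strain_field)) {
      trimws(strsplit(strain_field, ";")[[1]])
    } else character(0)
    label_claim(df$product_id[i],
                trimws(strsplit(df$claimed_taxa[i], ";")[[1]]),
                df$claimed_cfu_per_g[i],
                potency_basis = df$potency_basis[i],
                months_to_expiration = df$months_to_expiration[i],
                claimed_strains = strains)
  })
}

#' Write label claims to a tab-separated table
#' @param claims list of `label_claim` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_label_claims <- function(claims, path) {
  df <- do.call(rbind, lapply(claims, function(cl) {
    data.frame(product_id = cl$product_id,
               claimed_taxa = paste(cl$claimed_taxa, collapse = ";"),
               claimed_cfu_per_g = cl$claimed_cfu_per_g,
               potency_basis = cl$potency_basis,
               months_to_expiration = cl$months_to_expiration,
               claimed_strains = paste(cl$claimed_strains, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Virtual gel of a sample under a multiplex scheme
#'
#' Per reaction, the union of predicted amplicon lengths of that reaction's
#' assays over all sample sequences, deduplicated and sorted — the band
#' pattern an agarose gel of the multiplex would show.
#'
#' @param sample_sequences character vector of DNA strings.
#' @param scheme a `multiplex_scheme`.
#' @param policy a `mismatch_policy`.
#' @return object of class `band_pattern`: named list (rxnA, rxnB, ...) of
#'   sorted band length vectors.
#' @export
virtual_gel <- function(sample_sequences, scheme,
                        policy = mismatch_policy()) {
  bands <- lapply(seq_along(scheme$reactions), function(i) {
    lens <- integer(0)
    for (a in scheme$reactions[[i]]) {
      for (s in sample_sequences) {
        amp <- predict_amplicons(a, s, policy)
        lens <- c(lens, amp$length)
      }
    }
    sort(unique(lens))
  })
  names(bands) <- vapply(seq_along(bands), .rxn_id, "")
  structure(bands, class = "band_pattern")
}

#' Call per-taxon presence from a band pattern
#'
#' A taxon is detected iff some band in its reaction lies within the gel's
#' length tolerance (default 0 = exact) of its expected length. Each band is
#' assigned to at most one assay — the nearest expected length, ties to the
#' lower expected length (flagged ambiguous).
#'
#' @param pattern a `band_pattern` aligned with `scheme` reactions.
#' @param scheme a `multiplex_scheme`.
#' @return data.frame: taxon, detected, matched_length (NA when absent),
#'   ambiguous.
#' @export
call_presence <- function(pattern, scheme) {
  if (length(pattern) != length(scheme$reactions)) {
    stop("band pattern has ", length(pattern), " reactions; scheme has ",
         length(scheme$reactions))
  }
  tol <- scheme$gel$length_tolerance
  rows <- list()
  for (i in seq_along(scheme$reactions)) {
    rxn <- scheme$reactions[[i]]
    exp_len <- vapply(rxn, function(a) a$expected_length, 0L)
    bands <- pattern[[i]]
    matched <- rep(NA_integer_, length(rxn))
    ambiguous <- rep(FALSE, length(rxn))
    for (b in bands) {
      d <- abs(exp_len - b)
      if (!any(d <= tol)) next
      hits <- which(d == min(d))
      if (length(hits) > 1L) {
        # equidistant expected lengths: lower length wins, flagged
        hits <- hits[which.min(exp_len[hits])]
        ambiguous[hits] <- TRUE
      }
      if (min(d) == 0 && sum(exp_len == b) > 1L) {
        stop("scheme integrity violated: band ", b,
             " exactly matches two assays in reaction ", .rxn_id(i))
      }
      if (is.na(matched[hits])) matched[hits] <- b
    }
    for (k in seq_along(rxn)) {
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = rxn[[k]]$taxon, detected = !is.na(matched[k]),
        matched_length = matched[k], ambiguous = ambiguous[k],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genotype one sample end to end
#'
#' Convenience wrapper: virtual gel then presence calls.
#'
#' @param sample_sequences character vector of DNA strings.
#' @param scheme a `multiplex_scheme`.
#' @param policy a `mismatch_policy`.
#' @return presence-call data.frame (see [call_presence()]).
#' @export
genotype_sample <- function(sample_sequences, scheme,
                            policy = mismatch_policy()) {
  call_presence(virtual_gel(sample_sequences, scheme, policy), scheme)
}

#' Audit presence calls against a label claim
#'
#' Four-way category per panel taxon: claimed_present, claimed_absent,
#' unclaimed_present, unclaimed_absent. Claimed taxa outside the panel are
#' recorded as not_testable and excluded from discrepancy counting.
#' Strain-level calls (when strain assays are supplied) yield confirmed /
#' mismatched / unresolvable.
#'
#' @param calls presence-call data.frame covering the panel's taxa.
#' @param claim a `label_claim`.
#' @param strain_calls optional presence-call data.frame from strain-level
#'   assays (taxon column holds strain labels).
#' @return object of class `audit_row`: data.frames `species` (taxon,
#'   category) and `strains` (strain, category), plus the product id.
#' @export
audit_against_label <- function(calls, claim, strain_calls = NULL) {
  panel_tx <- calls$taxon
  claimed <- intersect(claim$claimed_taxa, panel_tx)
  not_testable <- setdiff(claim$claimed_taxa, panel_tx)
  category <- ifelse(panel_tx %in% claimed,
                     ifelse(calls$detected, "claimed_present", "claimed_absent"),
                     ifelse(calls$detected, "unclaimed_present", "unclaimed_absent"))
  species <- data.frame(taxon = panel_tx, category = category,
                        stringsAsFactors = FALSE)
  if (length(not_testable)) {
    species <- rbind(species,
                     data.frame(taxon = not_testable,
                                category = "not_testable",
                                stringsAsFactors = FALSE))
  }
  strains <- data.frame(strain = character(0), category = character(0))
  if (length(claim$claimed_strains)) {
    strain_cat <- vapply(claim$claimed_strains, function(st) {
      if (is.null(strain_calls) || !st %in% strain_calls$taxon) {
        "unresolvable"
      } else if (strain_calls$detected[match(st, strain_calls$taxon)]) {
        "confirmed"
      } else {
        "mismatched"
      }
    }, "")
    strains <- data.frame(strain = claim$claimed_strains,
                          category = unname(strain_cat),
                          stringsAsFactors = FALSE)
  }
  structure(list(product_id = claim$product_id, species = species,
                 strains = strains),
            class = "audit_row")
}

#' Assemble audit rows into a product x taxon audit matrix
#' @param rows list of `audit_row` objects.
#' @return object of class `audit_matrix` (list of rows plus the taxon set).
#' @export
audit_matrix <- function(rows) {
  taxa <- unique(unlist(lapply(rows, function(r) r$species$taxon)))
  structure(list(rows = rows, taxa = taxa), class = "audit_matrix")
}

#' Summarize an audit matrix
#'
#' A product is discrepant when it has at least one claimed_absent or one
#' unclaimed_present category. Percentages are over all products, rounded
#' to one decimal.
#'
#' @param matrix an `audit_matrix`.
#' @return list: n_products, n_with_missing_claimed, n_with_unclaimed,
#'   n_discrepant, pct_with_missing_claimed, pct_with_unclaimed,
#'   pct_discrepant.
#' @export
summarize_audit <- function(matrix) {
  rows <- matrix$rows
  stopifnot(length(rows) >= 1L)
  miss <- vapply(rows, function(r) any(r$species$category == "claimed_absent"),
                 TRUE)
  unclaimed <- vapply(rows,
                      function(r) any(r$species$category == "unclaimed_present"),
                      TRUE)
  n <- length(rows)
  list(n_products = n,
       n_with_missing_claimed = sum(miss),
       n_with_unclaimed = sum(unclaimed),
       n_discrepant = sum(miss | unclaimed),
       pct_with_missing_claimed = round(100 * sum(miss) / n, 1),
       pct_with_unclaimed = round(100 * sum(unclaimed) / n, 1),
       pct_discrepant = round(100 * sum(miss | unclaimed) / n, 1))
}

#' Share of products with a property, as the survey prints it
#'
#' Worked-example arithmetic on printed survey counts: `100 * count / n`
#' rounded to one decimal (e.g. 35 of 52 -> 67.3).
#'
#' @param count numerator.
#' @param n denominator (> 0).
#' @return percentage rounded to one decimal.
#' @export
percent_of_products <- function(count, n) {
  stopifnot(n > 0, count >= 0, count <= n)
  round(100 * count / n, 1)
}

#' Export an audit matrix as a tab-separated category table
#'
#' One row per product, one column per taxon, categories as text tokens.
#'
#' @param matrix an `audit_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_audit_matrix <- function(matrix, path) {
  taxa <- matrix$taxa
  rows <- lapply(matrix$rows, function(r) {
    cats <- setNames(rep("unclaimed_absent", length(taxa)), taxa)
    cats[r$species$taxon] <- r$species$category
    data.frame(product_id = r$product_id, t(cats), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
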