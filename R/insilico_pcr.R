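# Virtual amplification: exhaustive IUPAC-aware binding-site location on
# both strands, amplicon prediction from compatible site pairs, and
# panel-wide cross-reactivity matrices. Coordinates are 0-based half-open
# intervals on the plus strand (the template as given).

#' Primer-binding mismatch policy
#'
#' The default is the strictest setting — perfect match over the whole
#' primer — mirroring an exact band-length positivity rule; both knobs can
#' be relaxed to explore tolerant binding.
#'
#' @param max_total_mismatches allowed mismatches over the whole primer.
#' @param anchor_len length of the 3'-terminal anchor (nt).
#' @param max_anchor_mismatches allowed mismatches within the anchor.
#' @param max_product_len longest product considered amplifiable (bp).
#' @return object of class `mismatch_policy`.
#' @export
mismatch_policy <- function(max_total_mismatches = 0L, anchor_len = 3L,
                            max_anchor_mismatches = 0L,
                            max_product_len = 3000L) {
  stopifnot(anchor_len >= 0L,
            max_anchor_mismatches <= max_total_mismatches ||
              max_anchor_mismatches == 0L)
  structure(list(max_total_mismatches = as.integer(max_total_mismatches),
                 anchor_len = as.integer(anchor_len),
                 max_anchor_mismatches = as.integer(max_anchor_mismatches),
                 max_product_len = as.integer(max_product_len)),
            class = "mismatch_policy")
}

#' Locate primer binding sites on a template
#'
#' Scans every same-length window on both strands. A template symbol matches
#' a primer base iff their IUPAC expansions intersect. A window is a site
#' when total mismatches and 3'-anchor mismatches are within policy. On the
#' minus strand the primer's 3' terminus points at the window start.
#'
#' @param primer DNA string (5'->3').
#' @param template DNA string (IUPAC allowed).
#' @param policy a `mismatch_policy`.
#' @param template_id identifier recorded on the sites.
#' @return data.frame: template_id, strand, start, end (0-based half-open on
#'   the plus strand), mismatches; sorted by start.
#' @export
find_binding_sites <- function(primer, template, policy = mismatch_policy(),
                               template_id = "template") {
  pe <- iupac_encode(primer)
  te <- iupac_encode(template)
  if (length(pe) > length(te)) stop("primer longer than template")
  k <- length(pe)
  empty <- data.frame(template_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0))
  collect <- function(sc, strand) {
    if (!nrow(sc)) return(empty)
    keep <- sc[, 1] <= policy$max_total_mismatches &
      sc[, 2] <= policy$max_anchor_mismatches
    if (!any(keep)) return(empty)
    starts <- which(keep) - 1L
    data.frame(template_id = template_id, strand = strand, start = starts,
               end = starts + k, mismatches = sc[keep, 1],
               stringsAsFactors = FALSE)
  }
  plus <- collect(scan_mm_cpp(pe, te, policy$anchor_len, TRUE,
                              policy$max_total_mismatches), "+")
  minus <- collect(scan_mm_cpp(iupac_encode(revcomp(primer)), te,
                               policy$anchor_len, FALSE,
                               policy$max_total_mismatches), "-")
  out <- rbind(plus, minus)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict amplicons of an assay on a template
#'
#' Pairs every forward site on one strand with every reverse site on the
#' other strand in amplifiable orientation (reverse window end beyond the
#' forward window end, product no longer than the policy cap). Both
#' orientations are considered; duplicate intervals are removed.
#'
#' @param assay an `assay_definition`.
#' @param template DNA string, or a list with `sequence`/`source_id` fields.
#' @param policy a `mismatch_policy`.
#' @param template_id identifier recorded on the amplicons.
#' @return data.frame: template_id, start, end, length, taxon; sorted by
#'   start, then end.
#' @export
predict_amplicons <- function(assay, template, policy = mismatch_policy(),
                              template_id = "template") {
  if (is.list(template)) {
    if (!is.null(template$source_id)) template_id <- template$source_id
    template <- template$sequence
  }
  stopifnot(nzchar(template))
  empty <- data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      taxon = character(0))
  if (nchar(template) < min(assay$forward$length, assay$reverse$length)) {
    return(empty)
  }
  safe_sites <- function(primer) {
    if (nchar(primer) > nchar(template)) return(NULL)
    find_binding_sites(primer, template, policy, template_id)
  }
  fs <- safe_sites(assay$forward$sequence)
  rs <- safe_sites(assay$reverse$sequence)
  if (is.null(fs) || is.null(rs) || !nrow(fs) || !nrow(rs)) return(empty)
  pairs <- list()
  emit <- function(left, right) {
    # left primes rightward from + strand, right primes leftward from -
    if (!nrow(left) || !nrow(right)) return()
    for (i in seq_len(nrow(left))) {
      for (j in seq_len(nrow(right))) {
        if (right$end[j] > left$end[i]) {
          len <- right$end[j] - left$start[i]
          if (len <= policy$max_product_len) {
            pairs[[length(pairs) + 1L]] <<- c(left$start[i], right$end[j])
          }
        }
      }
    }
  }
  emit(fs[fs$strand == "+", , drop = FALSE], rs[rs$strand == "-", , drop = FALSE])
  emit(rs[rs$strand == "+", , drop = FALSE], fs[fs$strand == "-", , drop = FALSE])
  if (!length(pairs)) return(empty)
  m <- unique(do.call(rbind, pairs))
  out <- data.frame(template_id = template_id, start = m[, 1], end = m[, 2],
                    length = m[, 2] - m[, 1], taxon = assay$taxon,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Panel-wide cross-reactivity matrix
#'
#' Runs every assay against every sequence of every taxon in the panel. A
#' validated panel has exactly its expected length on the diagonal and empty
#' off-diagonal cells (or lengths distinguishable from every expected band).
#'
#' @param assays list of `assay_definition` objects.
#' @param panel a `marker_panel` covering every assay taxon.
#' @param policy a `mismatch_policy`.
#' @param require_diagonal error when an assay fails to amplify its own
#'   taxon at its expected length (default TRUE).
#' @return object of class `cross_reactivity` wrapping a list-matrix of
#'   sorted amplicon length vectors (assays x taxa).
#' @export
cross_reactivity <- function(assays, panel, policy = mismatch_policy(),
                             require_diagonal = TRUE) {
  taxa <- panel_taxa(panel)
  assay_taxa <- vapply(assays, function(a) a$taxon, "")
  missing_taxa <- setdiff(assay_taxa, taxa)
  if (length(missing_taxa)) {
    stop("panel does not cover assay taxa: ",
         paste(missing_taxa, collapse = ", "))
  }
  cells <- matrix(vector("list", length(assays) * length(taxa)),
                  nrow = length(assays),
                  dimnames = list(assay_taxa, taxa))
  for (i in seq_along(assays)) {
    for (j in seq_along(taxa)) {
      lens <- integer(0)
      for (s in panel_sequences(panel, taxa[j])) {
        amp <- predict_amplicons(assays[[i]], s, policy)
        lens <- c(lens, amp$length)
      }
      cells[[i, j]] <- sort(unique(lens))
    }
  }
  if (require_diagonal) {
    for (i in seq_along(assays)) {
      own <- cells[[i, match(assay_taxa[i], taxa)]]
      if (!assays[[i]]$expected_length %in% own) {
        stop("assay fails own target: ", assay_taxa[i],
             " (expected ", assays[[i]]$expected_length, " bp, got ",
             if (length(own)) paste(own, collapse = ",") else "none", ")")
      }
    }
  }
  structure(list(cells = cells, assays = assay_taxa, taxa = taxa,
                 policy = policy),
            class = "cross_reactivity")
}

#' @export
print.cross_reactivity <- function(x, ...) {
  off <- 0L
  for (i in seq_along(x$assays)) {
    for (j in seq_along(x$taxa)) {
      if (x$assays[i] != x$taxa[j] && length(x$cells[[i, j]])) off <- off + 1L
    }
  }
  cat("cross_reactivity:", length(x$assays), "assays x", length(x$taxa),
      "taxa;", off, "non-empty off-diagonal cells\n")
  invisible(x)
}

#' Export a cross-reactivity matrix as a tab-separated table
#'
#' Cells hold comma-joined amplicon lengths, `-` when empty.
#'
#' @param x a `cross_reactivity`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cross_reactivity <- function(x, path) {
  chr <- matrix("-", nrow = length(x$assays), ncol = length(x$taxa),
                dimnames = list(x$assays, x$taxa))
  for (i in seq_along(x$assays)) {
    for (j in seq_along(x$taxa)) {
      if (length(x$cells[[i, j]])) {
        chr[i, j] <- paste(x$cells[[i, j]], collapse = ",")
      }
    }
  }
  df <- data.frame(assay = rownames(chr), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
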