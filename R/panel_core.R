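# Marker panels: per-taxon collections of marker-gene sequences (pgi-like or
# 16S-like loci), the substrate from which consensus sequences, identity
# matrices and primer assays are built.

#' Construct a marker panel
#'
#' @param entries data.frame with columns `taxon`, `genus`, `species`,
#'   `subspecies`, `strain`, `sequence`, `source_id`.
#' @param locus one of `"pgi"`, `"16S"`, `"other"` — the single locus all
#'   entries share.
#' @return an object of class `marker_panel`.
#' @export
marker_panel <- function(entries, locus = c("pgi", "16S", "other")) {
  locus <- match.arg(locus)
  stopifnot(is.data.frame(entries), nrow(entries) >= 1L)
  needed <- c("taxon", "genus", "species", "subspecies", "strain",
              "sequence", "source_id")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols)) {
    stop("entries is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- !grepl("^[ACGTN]+$", entries$sequence)
  if (any(bad)) {
    stop("sequence alphabet must be A/C/G/T/N; offending record(s): ",
         paste(entries$source_id[bad], collapse = ", "))
  }
  structure(list(entries = entries[needed], locus = locus),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker_panel:", length(panel_taxa(x)), "taxa,",
      nrow(x$entries), "sequences, locus", x$locus, "\n")
  invisible(x)
}

#' Taxa present in a panel
#' @param panel a `marker_panel`.
#' @return character vector of unique taxon labels, in first-seen order.
#' @export
panel_taxa <- function(panel) unique(panel$entries$taxon)

#' Sequences of one taxon
#' @param panel a `marker_panel`.
#' @param taxon a taxon label present in the panel.
#' @return character vector of sequences.
#' @export
panel_sequences <- function(panel, taxon) {
  out <- panel$entries$sequence[panel$entries$taxon == taxon]
  if (!length(out)) stop("taxon not in panel: ", taxon)
  out
}

#' Read a marker-gene FASTA into a panel
#'
#' Headers must follow the `Genus species [subsp] [strain]|source_id`
#' dialect (see [parse_taxon()]). Sequences are upper-cased and U is mapped
#' to T; the alphabet is then restricted to A/C/G/T/N.
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @param locus locus shared by all records.
#' @return a `marker_panel`.
#' @export
read_marker_fasta <- function(path, locus = c("pgi", "16S", "other")) {
  locus <- match.arg(locus)
  if (!file.exists(path)) stop("file does not exist: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA: ", path)
  headers <- names(set)
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  rows <- lapply(seq_along(headers), function(i) {
    tx <- tryCatch(parse_taxon(headers[i]),
                   error = function(e) stop("record ", i, " ('", headers[i],
                                            "'): ", conditionMessage(e)))
    if (!nzchar(seqs[i])) stop("record '", headers[i], "' has empty sequence")
    if (!grepl("^[ACGTN]+$", seqs[i])) {
      bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]), c("A", "C", "G", "T", "N"))
      stop("record '", headers[i], "' contains invalid symbol(s): ",
           paste(bad, collapse = ", "))
    }
    data.frame(taxon = tx$label, genus = tx$genus, species = tx$species,
               subspecies = tx$subspecies, strain = tx$strain,
               sequence = seqs[i],
               source_id = if (is.na(tx$source_id)) headers[i] else tx$source_id,
               stringsAsFactors = FALSE)
  })
  marker_panel(do.call(rbind, rows), locus = locus)
}

#' Write a panel to FASTA
#' @param panel a `marker_panel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_marker_fasta <- function(panel, path) {
  set <- Biostrings::DNAStringSet(panel$entries$sequence)
  names(set) <- paste0(panel$entries$taxon, "|", panel$entries$source_id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# alignment score under the design scoring scheme; terminal gap runs in
# either row are free
.align_score <- function(ga, gb, match = 2, mismatch = -1, gap = -2) {
  a <- strsplit(ga, "")[[1]]; b <- strsplit(gb, "")[[1]]
  n <- length(a)
  interior <- function(ch) {
    g <- ch == "-"
    if (!any(g)) return(rep(FALSE, length(ch)))
    lead <- cumsum(!g) == 0
    trail <- rev(cumsum(rev(!g)) == 0)
    g & !(lead | trail)
  }
  gap_a <- a == "-"; gap_b <- b == "-"
  pen_a <- interior(a); pen_b <- interior(b)
  s <- 0
  for (i in seq_len(n)) {
    if (gap_a[i] || gap_b[i]) {
      if (pen_a[i] || pen_b[i]) s <- s + gap
    } else {
      s <- s + if (a[i] == b[i]) match else mismatch
    }
  }
  s
}

#' Globally align a set of marker sequences
#'
#' Pairwise Needleman-Wunsch (match +2, mismatch -1, gap -2, terminal gaps
#' free); for more than two sequences a center-star progressive strategy is
#' used: the center is the sequence with the highest summed pairwise score,
#' and the remaining sequences are merged into its master alignment under the
#' once-a-gap-always-a-gap rule.
#'
#' @param sequences character vector (>= 1) of non-empty DNA strings.
#' @return character vector of equal-length gapped strings; removing gaps
#'   from element i reproduces `sequences[i]`.
#' @export
align_marker_set <- function(sequences) {
  stopifnot(length(sequences) >= 1L, all(nzchar(sequences)))
  sequences <- toupper(sequences)
  n <- length(sequences)
  if (n == 1L) return(sequences)
  if (n == 2L) {
    al <- nw_align_cpp(sequences[1], sequences[2], 2, -1, -2, TRUE)
    return(c(al[1], al[2]))
  }
  # center-star: all pairwise alignments, center maximizes total score
  score <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      al <- nw_align_cpp(sequences[i], sequences[j], 2, -1, -2, TRUE)
      score[i, j] <- score[j, i] <- .align_score(al[1], al[2])
    }
  }
  center <- which.max(rowSums(score))
  others <- setdiff(seq_len(n), center)
  # master alignment as a list of character vectors, first row = center
  master <- list(strsplit(sequences[center], "")[[1]])
  order_rows <- center
  for (j in others) {
    al <- nw_align_cpp(sequences[center], sequences[j], 2, -1, -2, TRUE)
    gc <- strsplit(al[1], "")[[1]]
    gs <- strsplit(al[2], "")[[1]]
    # merge gc (center with new gaps) into master (center with old gaps)
    mc <- master[[1]]
    mi <- 1L; ci <- 1L
    new_master <- vector("list", length(master))
    for (k in seq_along(new_master)) new_master[[k]] <- character(0)
    new_row <- character(0)
    while (mi <= length(mc) || ci <= length(gc)) {
      m_gap <- mi <= length(mc) && mc[mi] == "-"
      c_gap <- ci <= length(gc) && gc[ci] == "-"
      m_done <- mi > length(mc); c_done <- ci > length(gc)
      if (!m_done && (m_gap) && (c_done || !c_gap)) {
        # master has a gap column the pairwise alignment lacks
        for (k in seq_along(master)) {
          new_master[[k]] <- c(new_master[[k]], master[[k]][mi])
        }
        new_row <- c(new_row, "-")
        mi <- mi + 1L
      } else if (!c_done && c_gap && (m_done || !m_gap)) {
        # pairwise alignment opened a new gap in the center
        for (k in seq_along(master)) {
          new_master[[k]] <- c(new_master[[k]], "-")
        }
        new_row <- c(new_row, gs[ci])
        ci <- ci + 1L
      } else {
        # both aligned on the same center base (or both gap)
        for (k in seq_along(master)) {
          new_master[[k]] <- c(new_master[[k]], master[[k]][mi])
        }
        new_row <- c(new_row, gs[ci])
        mi <- mi + 1L; ci <- ci + 1L
      }
    }
    master <- c(new_master, list(new_row))
    order_rows <- c(order_rows, j)
  }
  out <- vapply(master, paste, "", collapse = "")
  out[order(order_rows)]
}

#' Build a degenerate consensus profile for one taxon
#'
#' Each column's consensus symbol is the unique IUPAC code whose expansion
#' equals exactly the set of non-gap bases observed (100% identity is kept as
#' a plain base, polymorphism as a degenerate code). Columns gapped in at
#' least one sequence keep a `-` marker and are excluded from primer-eligible
#' regions.
#'
#' @param aligned equal-length gapped strings (from [align_marker_set()]).
#' @param taxon taxon label the profile describes.
#' @return object of class `consensus_profile` with fields `taxon`,
#'   `consensus` (IUPAC string with `-` markers) and `column_support`
#'   (contributing sequences per column).
#' @export
build_consensus <- function(aligned, taxon = "taxon") {
  stopifnot(length(aligned) >= 1L)
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L) stop("sequences are not aligned (unequal lengths)")
  mat <- do.call(rbind, lapply(aligned, function(s) iupac_encode(s)))
  support <- colSums(mat != 0L)
  if (any(support == 0L)) {
    stop("alignment column(s) ", paste(which(support == 0L), collapse = ", "),
         " contain only gaps")
  }
  any_gap <- colSums(mat == 0L) > 0L
  union_mask <- integer(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    union_mask[j] <- Reduce(bitwOr, mat[mat[, j] != 0L, j])
  }
  cons <- .MASK_CODE[union_mask + 1L]
  cons[any_gap] <- "-"
  structure(list(taxon = taxon,
                 consensus = paste(cons, collapse = ""),
                 column_support = as.integer(support)),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  n_deg <- sum(!strsplit(x$consensus, "")[[1]] %in% c("A", "C", "G", "T", "-"))
  cat("consensus_profile:", x$taxon, "-", nchar(x$consensus), "columns,",
      n_deg, "degenerate\n")
  invisible(x)
}

#' Consensus profiles for every taxon of a panel
#' @param panel a `marker_panel`.
#' @return named list of `consensus_profile` objects, one per taxon.
#' @export
panel_consensus <- function(panel) {
  taxa <- panel_taxa(panel)
  out <- lapply(taxa, function(tx) {
    build_consensus(align_marker_set(panel_sequences(panel, tx)), taxon = tx)
  })
  names(out) <- taxa
  out
}

#' Percent identity of two sequences under global alignment
#'
#' matches / alignment columns x 100; gap columns count as non-matches.
#' Terminal gaps are penalized here (strict end-to-end alignment), so two
#' sequences shifted by one base lose identity at both ends rather than
#' sliding into a shorter overlap.
#'
#' @param a,b DNA strings.
#' @return percent identity in `[0, 100]`.
#' @export
pair_identity <- function(a, b) {
  al <- nw_align_cpp(toupper(a), toupper(b), 2, -1, -2, FALSE)
  x <- strsplit(al[1], "")[[1]]; y <- strsplit(al[2], "")[[1]]
  100 * sum(x == y & x != "-") / length(x)
}

#' Cross-taxon percent-identity matrix
#'
#' One representative per taxon (its first panel sequence) is globally
#' aligned against every other representative; identity is
#' matches / alignment columns over the pairwise alignment.
#'
#' @param panel a `marker_panel` with >= 2 taxa.
#' @return symmetric matrix of class `identity_matrix` (diagonal 100) with
#'   taxon labels as dimnames and the locus as an attribute.
#' @export
identity_matrix <- function(panel) {
  taxa <- panel_taxa(panel)
  if (length(taxa) < 2L) stop("identity matrix needs >= 2 taxa")
  reps <- vapply(taxa, function(tx) panel_sequences(panel, tx)[1], "")
  n <- length(taxa)
  m <- matrix(100, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      m[i, j] <- m[j, i] <- pair_identity(reps[i], reps[j])
    }
  }
  structure(m, class = c("identity_matrix", "matrix"), locus = panel$locus)
}

#' Mean off-diagonal percent identity
#' @param m an `identity_matrix`.
#' @return scalar mean of the off-diagonal entries.
#' @export
mean_offdiag_identity <- function(m) {
  mean(m[row(m) != col(m)])
}

#' Export an identity matrix as a tab-separated table
#' @param m an `identity_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_identity_matrix <- function(m, path) {
  df <- data.frame(taxon = rownames(m), as.data.frame(unclass(m),
                                                      check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export consensus profiles as IUPAC FASTA
#' @param profiles list of `consensus_profile` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(profiles, path) {
  lines <- unlist(lapply(profiles, function(p) {
    c(paste0(">", p$taxon), p$consensus)
  }))
  writeLines(lines, path)
  invisible(path)
}
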