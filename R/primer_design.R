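# Discriminative primer design against a taxon's degenerate consensus:
# candidate enumeration within conserved (degeneracy-free) windows,
# Wallace-rule Tm and GC screens, hairpin/dimer run-length screens, and an
# exhaustive in-panel specificity scan replacing online BLAST queries.

#' Primer design parameters
#'
#' @param primer_len_range min/max primer length (nt).
#' @param gc_range allowed GC percentage range.
#' @param tm_range allowed Wallace Tm range (degrees C).
#' @param amplicon_len_range allowed product length range (bp).
#' @param max_self_comp_run a candidate fails the hairpin/self-dimer screen
#'   when its longest self-complementary run reaches this many nt.
#' @param max_3prime_comp_run fail threshold for complementary runs anchored
#'   at the 3' terminus.
#' @param three_prime_anchor length (nt) of the 3'-terminal anchor used for
#'   specificity scoring.
#' @return object of class `design_params`.
#' @export
design_params <- function(primer_len_range = c(18L, 25L),
                          gc_range = c(40, 60),
                          tm_range = c(50, 70),
                          amplicon_len_range = c(100L, 1000L),
                          max_self_comp_run = 8L,
                          max_3prime_comp_run = 5L,
                          three_prime_anchor = 3L) {
  stopifnot(length(primer_len_range) == 2L,
            primer_len_range[1] <= primer_len_range[2],
            gc_range[1] <= gc_range[2], tm_range[1] <= tm_range[2],
            amplicon_len_range[1] <= amplicon_len_range[2],
            three_prime_anchor <= primer_len_range[1])
  structure(list(primer_len_range = as.integer(primer_len_range),
                 gc_range = gc_range, tm_range = tm_range,
                 amplicon_len_range = as.integer(amplicon_len_range),
                 max_self_comp_run = as.integer(max_self_comp_run),
                 max_3prime_comp_run = as.integer(max_3prime_comp_run),
                 three_prime_anchor = as.integer(three_prime_anchor)),
            class = "design_params")
}

#' Wallace-rule melting temperature
#'
#' Tm = 2(A+T) + 4(G+C), the classic screening estimate for short oligos.
#'
#' @param sequence non-degenerate DNA string.
#' @return Tm in degrees C.
#' @export
#' @examples
#' tm_wallace("ACGT") # 12
tm_wallace <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!length(chars)) stop("sequence must be non-empty")
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("tm_wallace requires a non-degenerate A/C/G/T sequence")
  }
  2 * sum(chars %in% c("A", "T")) + 4 * sum(chars %in% c("G", "C"))
}

#' GC percentage of a primer
#' @param sequence non-degenerate DNA string.
#' @return percent GC.
#' @export
gc_percent <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Longest Watson-Crick complementary run between two oligos
#'
#' Slides `a` (5'->3') against `b` (3'->5') over every ungapped offset and
#' reports the longest contiguous complementary stretch, plus the longest
#' stretch that includes a's 3'-terminal base. `complementarity_run(a, a)`
#' is the hairpin/self-dimer screen.
#'
#' @param a,b DNA strings.
#' @return list with `max_run` and `three_prime_run_a` (nt).
#' @export
#' @examples
#' complementarity_run("AAAA", "TTTT")$max_run # 4
complementarity_run <- function(a, b) {
  ea <- iupac_encode(a)
  eb_rc <- iupac_encode(revcomp(b))
  runs <- max_common_run_cpp(ea, eb_rc)
  list(max_run = runs[1], three_prime_run_a = runs[2])
}

.hairpin_ok <- function(seq, params) {
  r <- complementarity_run(seq, seq)
  r$max_run < params$max_self_comp_run &&
    r$three_prime_run_a < params$max_3prime_comp_run
}

#' Enumerate primer candidates on a consensus profile
#'
#' Windows must be free of degenerate and gap symbols (fully conserved within
#' the taxon), satisfy the length/GC/Tm ranges and pass the hairpin screen.
#' Both strands are enumerated; minus-strand candidates are the reverse
#' complement of the window, with `start` still the window start on the
#' consensus. Ordering is deterministic: by start position, then length,
#' plus strand before minus.
#'
#' @param profile a `consensus_profile`.
#' @param params a `design_params`.
#' @return data.frame of candidates: sequence, strand, start (0-based),
#'   length, tm, gc. May have zero rows.
#' @export
enumerate_candidates <- function(profile, params = design_params()) {
  cons <- profile$consensus
  chars <- strsplit(cons, "")[[1]]
  L <- length(chars)
  plain <- chars %in% c("A", "C", "G", "T")
  is_gc <- chars %in% c("G", "C")
  is_at <- chars %in% c("A", "T")
  cum_plain <- cumsum(plain)
  cum_gc <- cumsum(is_gc)
  cum_at <- cumsum(is_at)
  rows <- list()
  for (len in seq(params$primer_len_range[1], params$primer_len_range[2])) {
    if (len > L) next
    starts <- seq_len(L - len + 1L)
    n_plain <- cum_plain[starts + len - 1L] - c(0, cum_plain)[starts]
    ok <- n_plain == len
    if (!any(ok)) next
    n_gc <- cum_gc[starts + len - 1L] - c(0, cum_gc)[starts]
    n_at <- cum_at[starts + len - 1L] - c(0, cum_at)[starts]
    gc <- 100 * n_gc / len
    tm <- 2 * n_at + 4 * n_gc
    ok <- ok & gc >= params$gc_range[1] & gc <= params$gc_range[2] &
      tm >= params$tm_range[1] & tm <= params$tm_range[2]
    if (!any(ok)) next
    s_ok <- starts[ok]
    wins <- substring(cons, s_ok, s_ok + len - 1L)
    revs <- vapply(wins, revcomp, "", USE.NAMES = FALSE)
    keep_f <- vapply(wins, .hairpin_ok, TRUE, params = params,
                     USE.NAMES = FALSE)
    keep_r <- vapply(revs, .hairpin_ok, TRUE, params = params,
                     USE.NAMES = FALSE)
    if (any(keep_f)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = wins[keep_f], strand = "+", start = s_ok[keep_f] - 1L,
        length = len, tm = tm[ok][keep_f], gc = gc[ok][keep_f],
        stringsAsFactors = FALSE)
    }
    if (any(keep_r)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = revs[keep_r], strand = "-", start = s_ok[keep_r] - 1L,
        length = len, tm = tm[ok][keep_r], gc = gc[ok][keep_r],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence = character(0), strand = character(0),
                      start = integer(0), length = integer(0),
                      tm = numeric(0), gc = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$length, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Specificity profile of one primer against off-target taxa
#'
#' For each off-target taxon, scans every same-length window of every
#' sequence on both strands (IUPAC-aware on the template side) and reports
#' the minimum Hamming mismatch count, together with the mismatch count
#' inside the primer's 3'-terminal anchor at that best window (the smallest
#' anchor count among windows achieving the minimum).
#'
#' @param primer non-degenerate DNA string (5'->3').
#' @param offtargets a `marker_panel` of non-target taxa.
#' @param anchor_len 3'-anchor length (nt).
#' @return data.frame: taxon, min_mismatches, three_prime_mismatches.
#' @export
specificity_profile <- function(primer, offtargets, anchor_len = 3L) {
  pe <- iupac_encode(primer)
  pe_rc <- iupac_encode(revcomp(primer))
  k <- length(pe)
  taxa <- panel_taxa(offtargets)
  res <- lapply(taxa, function(tx) {
    best <- c(k + 1L, k + 1L)
    for (s in panel_sequences(offtargets, tx)) {
      te <- iupac_encode(s)
      if (length(te) < k) next
      best <- scan_best_cpp(pe, te, anchor_len, TRUE, best[1], best[2])
      best <- scan_best_cpp(pe_rc, te, anchor_len, FALSE, best[1], best[2])
    }
    data.frame(taxon = tx, min_mismatches = best[1],
               three_prime_mismatches = best[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Build one assay definition
#' @param taxon taxon label.
#' @param forward,reverse single-row candidate data.frames.
#' @param expected_length product length (bp).
#' @param kind `"species_level"` or `"strain_level"`.
#' @return object of class `assay_definition`.
#' @export
assay_definition <- function(taxon, forward, reverse, expected_length,
                             kind = c("species_level", "strain_level")) {
  kind <- match.arg(kind)
  stopifnot(forward$strand == "+", reverse$strand == "-",
            expected_length > 0)
  structure(list(taxon = taxon, forward = as.list(forward),
                 reverse = as.list(reverse),
                 expected_length = as.integer(expected_length), kind = kind),
            class = "assay_definition")
}

#' @export
print.assay_definition <- function(x, ...) {
  cat("assay_definition:", x$taxon, sprintf("(%s)", x$kind), "\n",
      " F:", x$forward$sequence, "\n",
      " R:", x$reverse$sequence, "\n",
      " expected amplicon:", x$expected_length, "bp\n")
  invisible(x)
}

# worse-primer specificity score of a candidate against pre-encoded
# off-target templates: min over taxa of (min_mismatches, anchor_mismatches)
.candidate_offtarget_score <- function(cand_seq, enc_templates, anchor_len) {
  pe <- iupac_encode(cand_seq)
  pe_rc <- iupac_encode(revcomp(cand_seq))
  k <- length(pe)
  best <- c(k + 1L, k + 1L)
  for (te in enc_templates) {
    if (length(te) < k) next
    best <- scan_best_cpp(pe, te, anchor_len, TRUE, best[1], best[2])
    best <- scan_best_cpp(pe_rc, te, anchor_len, FALSE, best[1], best[2])
  }
  c(mm = best[1], amm = best[2])
}

#' Design a discriminative assay for one taxon
#'
#' Builds the taxon consensus, enumerates candidates, scores each candidate's
#' off-target specificity by exhaustive in-panel scanning, and selects the
#' forward/reverse pair by an ordered objective: (1) maximize the worse
#' primer's minimum off-target mismatch count, (2) maximize its minimum
#' off-target 3'-anchor mismatches, then among pairs passing the cross-dimer
#' screen (a hard requirement), (3) minimize the distance of the product
#' length from the midpoint of the allowed amplicon range. Ties break by
#' leftmost forward start, then shortest primer.
#'
#' @param taxon target taxon label (must be in `panel`).
#' @param panel a `marker_panel` containing the target and >= 1 off-target
#'   taxon.
#' @param params a `design_params`.
#' @return an `assay_definition`, or an error if no pair passes every screen.
#' @export
design_assay <- function(taxon, panel, params = design_params()) {
  taxa <- panel_taxa(panel)
  if (!taxon %in% taxa) stop("taxon not in panel: ", taxon)
  if (length(taxa) < 2L) stop("panel must contain at least one off-target taxon")
  offtargets <- marker_panel(panel$entries[panel$entries$taxon != taxon, ,
                                           drop = FALSE], panel$locus)
  profile <- build_consensus(align_marker_set(panel_sequences(panel, taxon)),
                             taxon = taxon)
  cands <- enumerate_candidates(profile, params)
  if (!nrow(cands)) stop("design infeasible for taxon ", taxon,
                         ": no candidate windows pass the screens")
  enc_templates <- lapply(offtargets$entries$sequence, iupac_encode)
  scores <- score_candidates_cpp(lapply(cands$sequence, iupac_encode),
                                 lapply(cands$sequence,
                                        function(s) iupac_encode(revcomp(s))),
                                 enc_templates,
                                 params$three_prime_anchor)
  cands$off_mm <- scores[, 1]
  cands$off_amm <- scores[, 2]

  fw <- cands[cands$strand == "+", , drop = FALSE]
  rv <- cands[cands$strand == "-", , drop = FALSE]
  if (!nrow(fw) || !nrow(rv)) {
    stop("design infeasible for taxon ", taxon, ": missing strand candidates")
  }
  mid <- mean(params$amplicon_len_range)
  # pair score = worse primer's (mm, amm); enumerate score levels descending
  pair_mm <- outer(fw$off_mm, rv$off_mm, pmin)
  pair_amm <- outer(fw$off_amm, rv$off_amm, pmin)
  # amplicon spans forward window start to reverse window end
  len <- outer(fw$start, rv$start + rv$length, function(a, b) b - a)
  feasible <- len >= params$amplicon_len_range[1] &
    len <= params$amplicon_len_range[2]
  # at least one primer of the pair must mismatch every off-target (a
  # non-discriminating pair would co-amplify another panel member)
  feasible <- feasible & outer(fw$off_mm, rv$off_mm, pmax) >= 1
  if (!any(feasible)) {
    stop("design infeasible for taxon ", taxon,
         ": no discriminating primer pair yields an in-range amplicon")
  }
  ord <- order(-pair_mm[feasible], -pair_amm[feasible],
               abs(len[feasible] - mid),
               fw$start[row(len)[feasible]],
               fw$length[row(len)[feasible]] + rv$length[col(len)[feasible]])
  idx_f <- row(len)[feasible][ord]
  idx_r <- col(len)[feasible][ord]
  for (k in seq_along(idx_f)) {
    f <- fw[idx_f[k], ]; r <- rv[idx_r[k], ]
    cd <- complementarity_run(f$sequence, r$sequence)
    if (cd$max_run >= params$max_self_comp_run) next
    if (cd$three_prime_run_a >= params$max_3prime_comp_run) next
    cd_rev <- complementarity_run(r$sequence, f$sequence)
    if (cd_rev$three_prime_run_a >= params$max_3prime_comp_run) next
    return(assay_definition(taxon, f[, 1:6], r[, 1:6],
                            expected_length = len[idx_f[k], idx_r[k]],
                            kind = "species_level"))
  }
  stop("design infeasible for taxon ", taxon,
       ": all candidate pairs fail the cross-dimer screen")
}

#' Design assays for every taxon of a panel
#' @param panel a `marker_panel` with >= 2 taxa.
#' @param params a `design_params`.
#' @return named list of `assay_definition` objects.
#' @export
design_panel_assays <- function(panel, params = design_params()) {
  taxa <- panel_taxa(panel)
  out <- lapply(taxa, design_assay, panel = panel, params = params)
  names(out) <- taxa
  out
}

#' Export an assay set as a tab-separated table
#' @param assays list of `assay_definition` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(assays, path) {
  df <- do.call(rbind, lapply(assays, function(a) {
    data.frame(taxon = a$taxon, forward = a$forward$sequence,
               reverse = a$reverse$sequence,
               expected_length = a$expected_length, kind = a$kind,
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import an assay set from a tab-separated table
#'
#' Positional information is not stored in the table, so re-imported assays
#' carry placeholder coordinates; Tm and GC are recomputed.
#'
#' @param path file written by [write_assay_table()].
#' @return named list of `assay_definition` objects.
#' @export
read_assay_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("taxon", "forward", "reverse", "expected_length", "kind")
  if (!all(needed %in% names(df))) {
    stop("assay table must have columns: ", paste(needed, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    fcand <- data.frame(sequence = df$forward[i], strand = "+", start = NA_integer_,
                        length = nchar(df$forward[i]),
                        tm = tm_wallace(df$forward[i]),
                        gc = gc_percent(df$forward[i]), stringsAsFactors = FALSE)
    rcand <- data.frame(sequence = df$reverse[i], strand = "-", start = NA_integer_,
                        length = nchar(df$reverse[i]),
                        tm = tm_wallace(df$reverse[i]),
                        gc = gc_percent(df$reverse[i]), stringsAsFactors = FALSE)
    assay_definition(df$taxon[i], fcand, rcand, df$expected_length[i],
                     kind = df$kind[i])
  })
  names(out) <- df$taxon
  out
}

#' Export primers as FASTA
#' @param assays list of `assay_definition` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_primer_fasta <- function(assays, path) {
  lines <- unlist(lapply(assays, function(a) {
    c(paste0(">", a$taxon, "_F"), a$forward$sequence,
      paste0(">", a$taxon, "_R"), a$reverse$sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}
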