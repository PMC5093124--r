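# 16S rRNA V4 relative-abundance pipeline: overlap-based pair merging,
# Phred/ambiguity filtering, 100%-identity dereplication into OTUs,
# type-strain assignment with collapsing of indistinguishable reference
# groups, minor-OTU filtering, per-sample abundance summaries, and the two
# summary regressions (percent reads on log10 CFU; mean abundance on
# log rank).

#' Construct a read set
#'
#' @param sample_id sample identifier.
#' @param sequences character vector of DNA strings (may contain N).
#' @param qualities character vector of Phred+33 quality strings, same
#'   lengths as `sequences`.
#' @return object of class `read_set`.
#' @export
read_set <- function(sample_id, sequences, qualities) {
  stopifnot(length(sequences) == length(qualities),
            all(nchar(sequences) == nchar(qualities)))
  if (length(qualities)) {
    qr <- range(utf8ToInt(paste(qualities, collapse = ""))) - 33L
    if (qr[1] < 0L || qr[2] > 60L) {
      stop("Phred scores must lie in [0, 60] (Phred+33 encoding)")
    }
  }
  structure(list(sample_id = sample_id,
                 sequences = toupper(sequences),
                 qualities = qualities),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", x$sample_id, "-", length(x$sequences), "reads\n")
  invisible(x)
}

#' Number of reads in a read set
#' @param reads a `read_set`.
#' @return integer count.
#' @export
n_reads <- function(reads) length(reads$sequences)

#' Read a FASTQ file (Phred+33) into a read set
#' @param path FASTQ file.
#' @param sample_id sample identifier (defaults to the file name).
#' @return a `read_set`.
#' @export
read_fastq <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  }
  # Biostrings warns that FASTQ id metadata is dropped on conversion; ids
  # are regenerated on write, so the warning is noise here
  set <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  read_set(sample_id,
           unname(as.character(set)),
           unname(as.character(Biostrings::quality(set))))
}

#' Write a read set as FASTQ (Phred+33)
#' @param reads a `read_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  n <- n_reads(reads)
  ids <- sprintf("%s_read%d", reads$sample_id, seq_len(n))
  lines <- character(4L * n)
  if (n) {
    lines[seq(1L, 4L * n, by = 4L)] <- paste0("@", ids)
    lines[seq(2L, 4L * n, by = 4L)] <- reads$sequences
    lines[seq(3L, 4L * n, by = 4L)] <- "+"
    lines[seq(4L, 4L * n, by = 4L)] <- reads$qualities
  }
  writeLines(lines, path)
  invisible(path)
}

# merge one unique pair; returns list(sequence, quality) or NULL
.merge_one <- function(fseq, rseq, fqual, rqual, min_overlap, max_mm_frac) {
  f <- strsplit(fseq, "")[[1]]
  rc <- strsplit(revcomp(rseq), "")[[1]]
  fq <- utf8ToInt(fqual) - 33L
  rq <- rev(utf8ToInt(rqual) - 33L)
  lf <- length(f); lr <- length(rc)
  if (min(lf, lr) < min_overlap) return(NULL)
  best <- NULL; best_score <- -Inf
  for (ov in seq(min(lf, lr), min_overlap)) {
    ftail <- f[(lf - ov + 1L):lf]
    rhead <- rc[seq_len(ov)]
    mm <- sum(ftail != rhead)
    if (mm / ov > max_mm_frac) next
    score <- (ov - mm) - mm
    if (score > best_score) {
      best_score <- score
      best <- ov
    }
  }
  if (is.null(best)) return(NULL)
  ov <- best
  fi <- (lf - ov + 1L):lf
  ri <- seq_len(ov)
  ftail <- f[fi]; rhead <- rc[ri]
  fq_ov <- fq[fi]; rq_ov <- rq[ri]
  take_r <- rq_ov > fq_ov
  merged_ov <- ifelse(ftail == rhead, ftail, ifelse(take_r, rhead, ftail))
  qual_ov <- pmax(fq_ov, rq_ov)
  seq_out <- paste(c(f[seq_len(lf - ov)], merged_ov, rc[-ri]), collapse = "")
  qual_out <- intToUtf8(c(fq[seq_len(lf - ov)], qual_ov, rq[-ri]) + 33L)
  list(sequence = seq_out, quality = qual_out)
}

#' Merge paired-end reads by best overlap
#'
#' For each mate pair, the reverse read is reverse-complemented and slid
#' against the forward read; the highest-scoring overlap of at least
#' `min_overlap` nt with a mismatch fraction at or below the threshold is
#' accepted (matches minus mismatches scoring; ties resolved toward the
#' longer overlap). Disagreeing overlap bases take the higher-quality base.
#' Pairs with no acceptable overlap are dropped and counted.
#'
#' @param forward,reverse `read_set` objects of equal length and order.
#' @param min_overlap minimum overlap (nt).
#' @param max_overlap_mismatch_frac maximum mismatch fraction in the overlap.
#' @return a merged `read_set`; the number of dropped pairs is available as
#'   `attr(, "n_dropped")`.
#' @export
merge_pairs <- function(forward, reverse, min_overlap = 20L,
                        max_overlap_mismatch_frac = 0.1) {
  if (n_reads(forward) != n_reads(reverse)) {
    stop("mate lists differ in length: ", n_reads(forward), " vs ",
         n_reads(reverse))
  }
  n <- n_reads(forward)
  if (!n) {
    out <- read_set(forward$sample_id, character(0), character(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  key <- paste(forward$sequences, reverse$sequences,
               forward$qualities, reverse$qualities, sep = "\r")
  uk <- !duplicated(key)
  merged_by_key <- new.env(parent = emptyenv())
  for (i in which(uk)) {
    merged_by_key[[key[i]]] <- .merge_one(
      forward$sequences[i], reverse$sequences[i],
      forward$qualities[i], reverse$qualities[i],
      min_overlap, max_overlap_mismatch_frac)
  }
  res <- lapply(key, function(k) merged_by_key[[k]])
  ok <- !vapply(res, is.null, TRUE)
  out <- read_set(forward$sample_id,
                  vapply(res[ok], `[[`, "", "sequence"),
                  vapply(res[ok], `[[`, "", "quality"))
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Quality-filter a read set
#'
#' Retains reads with no ambiguous base (N) and every base at Phred quality
#' `min_q` or better (the removal rule is quality < `min_q`).
#'
#' @param reads a `read_set`.
#' @param min_q minimum per-base Phred score (default 30).
#' @return filtered `read_set`; removals in `attr(, "n_removed")`.
#' @export
quality_filter <- function(reads, min_q = 30L) {
  n <- n_reads(reads)
  if (!n) {
    out <- reads
    attr(out, "n_removed") <- 0L
    return(out)
  }
  has_n <- grepl("N", reads$sequences, fixed = TRUE)
  min_qual <- vapply(reads$qualities,
                     function(q) min(as.integer(charToRaw(q))) - 33L,
                     0L, USE.NAMES = FALSE)
  keep <- !has_n & min_qual >= min_q
  out <- read_set(reads$sample_id, reads$sequences[keep],
                  reads$qualities[keep])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Dereplicate reads into 100%-identity OTUs
#'
#' Identical sequences collapse into one OTU; counts are preserved per
#' sample. This is de novo clustering at 100% identity.
#'
#' @param reads a `read_set` or a list of `read_set` objects (one per
#'   sample).
#' @return object of class `otu_table`: data.frame `otus` (otu_id, sequence,
#'   taxon_group, identity, ambiguous, one count column per sample) plus
#'   `samples`.
#' @export
dereplicate <- function(reads) {
  if (inherits(reads, "read_set")) reads <- list(reads)
  samples <- vapply(reads, function(r) r$sample_id, "")
  if (anyDuplicated(samples)) stop("duplicate sample ids in read sets")
  seqs <- unique(unlist(lapply(reads, `[[`, "sequences")))
  counts <- vapply(reads, function(r) {
    tab <- table(factor(r$sequences, levels = seqs))
    as.integer(tab)
  }, integer(length(seqs)))
  counts <- matrix(counts, nrow = length(seqs),
                   dimnames = list(NULL, samples))
  total <- rowSums(counts)
  ord <- order(-total, seqs)
  otus <- data.frame(otu_id = sprintf("otu_%d", seq_along(seqs)),
                     sequence = seqs[ord],
                     taxon_group = NA_character_,
                     identity = NA_real_,
                     ambiguous = FALSE,
                     stringsAsFactors = FALSE)
  otus <- cbind(otus, as.data.frame(counts[ord, , drop = FALSE]))
  rownames(otus) <- NULL
  structure(list(otus = otus, samples = samples), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", nrow(x$otus), "OTUs x", length(x$samples), "samples;",
      sum(otu_counts(x)), "reads\n")
  invisible(x)
}

#' Count matrix of an OTU table
#' @param table an `otu_table`.
#' @return integer matrix (OTUs x samples).
#' @export
otu_counts <- function(table) {
  m <- as.matrix(table$otus[, table$samples, drop = FALSE])
  rownames(m) <- table$otus$otu_id
  m
}

#' Build a type-strain reference set, collapsing indistinguishable taxa
#'
#' Taxa whose V4 region is identical cannot be told apart by the amplicon
#' and are collapsed into one group (e.g. a group holding both members of a
#' closely related species pair); the group is named by its sorted members
#' joined with `|`.
#'
#' @param taxa character vector of taxon labels.
#' @param v4_sequences character vector of the taxa's V4 region sequences.
#' @return object of class `reference_set`: data.frame with taxon_group,
#'   member_taxa (list column), v4_sequence.
#' @export
build_reference_set <- function(taxa, v4_sequences) {
  stopifnot(length(taxa) == length(v4_sequences), length(taxa) >= 1L)
  v4 <- toupper(v4_sequences)
  groups <- split(taxa, v4)
  entries <- data.frame(
    taxon_group = vapply(groups, function(g) paste(sort(g), collapse = "|"), ""),
    v4_sequence = names(groups),
    stringsAsFactors = FALSE)
  entries$member_taxa <- unname(lapply(groups, sort))
  entries <- entries[order(entries$taxon_group), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries), class = "reference_set")
}

#' Read a V4 reference FASTA into a reference set
#' @param path FASTA with taxon labels as headers.
#' @return a `reference_set` (identical V4 sequences collapsed).
#' @export
read_reference_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (!length(set)) stop("empty reference FASTA: ", path)
  build_reference_set(names(set), toupper(as.character(set)))
}

#' Group membership lookup
#' @param refs a `reference_set`.
#' @param taxon a member taxon label.
#' @return the taxon_group containing `taxon`.
#' @export
taxon_group_of <- function(refs, taxon) {
  hit <- vapply(refs$entries$member_taxa, function(m) taxon %in% m, TRUE)
  if (!any(hit)) stop("taxon not in reference set: ", taxon)
  refs$entries$taxon_group[which(hit)[1]]
}

#' Assign OTUs to their closest type-strain group
#'
#' Each OTU receives the taxon group of its best global-alignment percent
#' identity reference; exact ties across groups yield the union group
#' (members joined with `|`) flagged ambiguous.
#'
#' @param table an `otu_table`.
#' @param refs a `reference_set`.
#' @return the `otu_table` with taxon_group, identity and ambiguous filled.
#' @export
assign_taxonomy <- function(table, refs) {
  stopifnot(nrow(refs$entries) >= 1L)
  for (i in seq_len(nrow(table$otus))) {
    ids <- vapply(refs$entries$v4_sequence, pair_identity,
                  0, b = table$otus$sequence[i], USE.NAMES = FALSE)
    best <- max(ids)
    hits <- which(ids == best)
    if (length(hits) == 1L) {
      table$otus$taxon_group[i] <- refs$entries$taxon_group[hits]
      table$otus$ambiguous[i] <- FALSE
    } else {
      members <- sort(unique(unlist(refs$entries$member_taxa[hits])))
      table$otus$taxon_group[i] <- paste(members, collapse = "|")
      table$otus$ambiguous[i] <- TRUE
    }
    table$otus$identity[i] <- best
  }
  table
}

#' Remove minor OTUs
#'
#' Retains OTUs whose total count across all samples is strictly more than
#' `min_frac` of the grand total (the "more than 0.1% of total reads" rule);
#' a per-sample variant is available.
#'
#' @param table an `otu_table`.
#' @param min_frac abundance threshold (default 0.001 = 0.1%).
#' @param per_sample when TRUE an OTU is kept if it exceeds the threshold in
#'   any single sample.
#' @return filtered `otu_table`; removed read mass in
#'   `attr(, "n_removed_reads")`.
#' @export
filter_minor <- function(table, min_frac = 0.001, per_sample = FALSE) {
  counts <- otu_counts(table)
  if (per_sample) {
    totals <- colSums(counts)
    frac <- sweep(counts, 2, pmax(totals, 1L), "/")
    keep <- apply(frac, 1, max) > min_frac
  } else {
    grand <- sum(counts)
    keep <- rowSums(counts) / max(grand, 1L) > min_frac
  }
  removed <- sum(counts[!keep, , drop = FALSE])
  out <- table
  out$otus <- table$otus[keep, , drop = FALSE]
  rownames(out$otus) <- NULL
  attr(out, "n_removed_reads") <- removed
  out
}

#' Per-sample relative abundance by taxon group
#'
#' @param table an assigned (and typically minor-filtered) `otu_table`.
#' @param min_reads samples with fewer retained reads are excluded with a
#'   warning (0 keeps every sample with at least one read; 10000 reproduces
#'   a low-coverage exclusion rule).
#' @return data.frame: sample, taxon_group, percent; percents sum to 100
#'   per retained sample.
#' @export
relative_abundance <- function(table, min_reads = 0L) {
  counts <- otu_counts(table)
  groups <- table$otus$taxon_group
  if (anyNA(groups)) stop("assign_taxonomy must run before relative_abundance")
  totals <- colSums(counts)
  drop <- totals == 0L | totals < min_reads
  if (any(drop)) {
    warning("excluding sample(s) with insufficient reads: ",
            paste(table$samples[drop], collapse = ", "))
  }
  rows <- list()
  for (s in table$samples[!drop]) {
    by_group <- tapply(counts[, s], groups, sum)
    pct <- 100 * by_group / totals[s]
    rows[[s]] <- data.frame(sample = s, taxon_group = names(pct),
                            percent = as.numeric(pct),
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(sample = character(0), taxon_group = character(0),
                      percent = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# R^2 = 1 - SSres/SStot; a zero-variance response fitted exactly counts as 1
.r_squared <- function(fit, response) {
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((response - mean(response))^2)
  if (ss_tot > 0) 1 - ss_res / ss_tot else 1
}

#' Regression of percent reads on log10 CFU
#'
#' Ordinary least squares of observed percent reads on the log10 CFU of the
#' corresponding standards; used to check that read abundance tracks input
#' dilution.
#'
#' @param log10_cfu numeric predictor (log10 CFU of each standard).
#' @param percent_reads numeric response.
#' @return object of class `regression_result`: slope, intercept, r_squared,
#'   n.
#' @export
cfu_read_regression <- function(log10_cfu, percent_reads) {
  stopifnot(length(log10_cfu) == length(percent_reads),
            length(log10_cfu) >= 3L)
  if (isTRUE(all.equal(stats::var(log10_cfu), 0)) ||
      stats::var(log10_cfu) == 0) {
    stop("predictor has zero variance")
  }
  fit <- lm(percent_reads ~ log10_cfu)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = .r_squared(fit, percent_reads),
                 n = length(log10_cfu)),
            class = "regression_result")
}

#' Logarithmic fit to a rank-abundance profile
#'
#' Least squares of mean abundance on ln(rank); products formulated with a
#' few dominant organisms show a decreasing logarithmic curve (negative
#' slope).
#'
#' @param mean_abundance mean percent abundance at ranks 1..m (m >= 3).
#' @return a `regression_result` (slope is the ln-rank coefficient).
#' @export
rank_abundance_fit <- function(mean_abundance) {
  m <- length(mean_abundance)
  stopifnot(m >= 3L)
  lr <- log(seq_len(m))
  fit <- lm(mean_abundance ~ lr)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = .r_squared(fit, mean_abundance),
                 n = m),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("regression_result: slope %.4g, intercept %.4g, R^2 %.4f, n %d\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Run the full amplicon profiling pipeline
#'
#' merge -> quality filter -> dereplicate -> assign -> minor filter ->
#' relative abundance, with per-stage read accounting.
#'
#' @param forward_sets,reverse_sets lists of paired `read_set` objects.
#' @param refs a `reference_set`.
#' @param min_overlap,max_overlap_mismatch_frac see [merge_pairs()].
#' @param min_q see [quality_filter()].
#' @param min_frac see [filter_minor()].
#' @param min_reads see [relative_abundance()].
#' @return list: `abundance` (data.frame), `table` (filtered `otu_table`),
#'   `accounting` (per-sample read counts through the stages).
#' @export
profile_amplicons <- function(forward_sets, reverse_sets, refs,
                              min_overlap = 20L,
                              max_overlap_mismatch_frac = 0.1,
                              min_q = 30L, min_frac = 0.001,
                              min_reads = 0L) {
  stopifnot(length(forward_sets) == length(reverse_sets))
  filtered <- vector("list", length(forward_sets))
  acct <- list()
  for (i in seq_along(forward_sets)) {
    merged <- merge_pairs(forward_sets[[i]], reverse_sets[[i]],
                          min_overlap, max_overlap_mismatch_frac)
    qf <- quality_filter(merged, min_q)
    filtered[[i]] <- qf
    acct[[i]] <- data.frame(sample = forward_sets[[i]]$sample_id,
                            n_pairs = n_reads(forward_sets[[i]]),
                            n_merged = n_reads(merged),
                            n_dropped_merge = attr(merged, "n_dropped"),
                            n_filtered = n_reads(qf),
                            n_removed_quality = attr(qf, "n_removed"),
                            stringsAsFactors = FALSE)
  }
  table <- assign_taxonomy(dereplicate(filtered), refs)
  table <- filter_minor(table, min_frac)
  list(abundance = relative_abundance(table, min_reads),
       table = table,
       accounting = do.call(rbind, acct))
}

#' Export an OTU table as a tab-separated matrix
#' @param table an `otu_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  write.table(table$otus, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
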