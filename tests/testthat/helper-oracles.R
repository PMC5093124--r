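# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no nw_align_cpp, no scan_mm_cpp): plain R loops and
# exhaustive enumeration, so agreement is evidence rather than tautology.

ORACLE_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L,
                 W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L, V = 7L,
                 N = 15L, `-` = 0L)

oracle_encode <- function(x) unname(ORACLE_MASK[strsplit(toupper(x), "")[[1]]])

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# every plus-strand window's mismatch count (single explicit loop)
oracle_window_mm <- function(primer, template) {
  pe <- oracle_encode(primer)
  te <- oracle_encode(template)
  k <- length(pe)
  noff <- length(te) - k + 1L
  if (noff < 1L) return(integer(0))
  vapply(seq_len(noff), function(s) {
    sum(bitwAnd(pe, te[s:(s + k - 1L)]) == 0L)
  }, 0L)
}

# mismatches inside the last `anchor` primer positions, per window
oracle_window_anchor_mm <- function(primer, template, anchor) {
  pe <- oracle_encode(primer)
  te <- oracle_encode(template)
  k <- length(pe)
  noff <- length(te) - k + 1L
  apos <- (k - anchor + 1L):k
  vapply(seq_len(noff), function(s) {
    win <- te[s:(s + k - 1L)]
    sum(bitwAnd(pe[apos], win[apos]) == 0L)
  }, 0L)
}

# all binding sites by the definition: plus-strand windows of the primer,
# plus minus-strand sites obtained by scanning the reverse-complemented
# TEMPLATE (a different route than the implementation, which scans the
# reverse-complemented primer)
oracle_binding_sites <- function(primer, template, max_mm, anchor,
                                 max_anchor_mm) {
  k <- nchar(primer)
  L <- nchar(template)
  plus_mm <- oracle_window_mm(primer, template)
  plus_amm <- oracle_window_anchor_mm(primer, template, anchor)
  keep <- which(plus_mm <= max_mm & plus_amm <= max_anchor_mm)
  plus <- data.frame(strand = rep("+", length(keep)), start = keep - 1L,
                     mismatches = plus_mm[keep], stringsAsFactors = FALSE)
  rc_t <- oracle_revcomp(template)
  minus_mm <- oracle_window_mm(primer, rc_t)
  minus_amm <- oracle_window_anchor_mm(primer, rc_t, anchor)
  keepm <- which(minus_mm <= max_mm & minus_amm <= max_anchor_mm)
  # window [s, s+k) on revcomp(T) maps to [L-s-k, L-s) on T
  minus <- data.frame(strand = rep("-", length(keepm)),
                      start = L - (keepm - 1L) - k,
                      mismatches = minus_mm[keepm], stringsAsFactors = FALSE)
  out <- rbind(plus, minus)
  out[order(out$start, out$strand), , drop = FALSE]
}

# per-taxon minimum (mismatches, anchor mismatches at the best window)
oracle_specificity <- function(primer, sequences, anchor) {
  best <- c(Inf, Inf)
  for (s in sequences) {
    for (tmpl in c(s, oracle_revcomp(s))) {
      if (nchar(tmpl) < nchar(primer)) next
      mm <- oracle_window_mm(primer, tmpl)
      if (!length(mm)) next
      amm <- oracle_window_anchor_mm(primer, tmpl, anchor)
      m <- min(mm)
      a <- min(amm[mm == m])
      if (m < best[1] || (m == best[1] && a < best[2])) best <- c(m, a)
    }
  }
  best
}

# brute-force amplicons: double loop over all forward/reverse site pairs
oracle_amplicons <- function(fwd, rev, template, max_mm, anchor,
                             max_anchor_mm, max_len) {
  fs <- oracle_binding_sites(fwd, template, max_mm, anchor, max_anchor_mm)
  rs <- oracle_binding_sites(rev, template, max_mm, anchor, max_anchor_mm)
  out <- NULL
  grab <- function(left, right, kl, kr) {
    for (i in seq_len(nrow(left))) {
      for (j in seq_len(nrow(right))) {
        le <- left$start[i] + kl
        re <- right$start[j] + kr
        if (re > le && re - left$start[i] <= max_len) {
          out <<- rbind(out, c(left$start[i], re))
        }
      }
    }
  }
  grab(fs[fs$strand == "+", , drop = FALSE],
       rs[rs$strand == "-", , drop = FALSE], nchar(fwd), nchar(rev))
  grab(rs[rs$strand == "+", , drop = FALSE],
       fs[fs$strand == "-", , drop = FALSE], nchar(rev), nchar(fwd))
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  out <- unique(as.data.frame(out))
  names(out) <- c("start", "end")
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive alignment enumeration: every monotone path, scored with
# match +2 / mismatch -1 / gap -2 and terminal gap runs free
oracle_best_alignment_score <- function(a, b) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  score_alignment <- function(cols) oracle_alignment_score(
    paste(cols[1, ], collapse = ""), paste(cols[2, ], collapse = ""))
  best <- -Inf
  rec <- function(i, j, top, bottom) {
    if (i > length(ac) && j > length(bc)) {
      sc <- score_alignment(rbind(top, bottom))
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= length(ac) && j <= length(bc)) {
      rec(i + 1L, j + 1L, c(top, ac[i]), c(bottom, bc[j]))
    }
    if (i <= length(ac)) rec(i + 1L, j, c(top, ac[i]), c(bottom, "-"))
    if (j <= length(bc)) rec(i, j + 1L, c(top, "-"), c(bottom, bc[j]))
    invisible()
  }
  rec(1L, 1L, character(0), character(0))
  best
}

# score an alignment: match +2, mismatch -1, gap -2, except that the gap
# runs at the start and end of EACH ROW (sequence overhangs) cost nothing
oracle_alignment_score <- function(ga, gb) {
  a <- strsplit(ga, "")[[1]]
  b <- strsplit(gb, "")[[1]]
  k <- length(a)
  row_interior_gap <- function(ch) {
    g <- ch == "-"
    lead <- cumsum(!g) == 0
    trail <- rev(cumsum(rev(!g)) == 0)
    g & !lead & !trail
  }
  ia <- row_interior_gap(a)
  ib <- row_interior_gap(b)
  s <- 0
  for (i in seq_len(k)) {
    if (a[i] == "-" || b[i] == "-") {
      if (ia[i] || ib[i]) s <- s - 2
    } else {
      s <- s + if (a[i] == b[i]) 2 else -1
    }
  }
  s
}

# minimum number of reactions over all set partitions (exhaustive, n <= 8)
oracle_min_reactions <- function(lengths, plex_size, min_sep) {
  n <- length(lengths)
  best <- n
  assign_next <- function(i, blocks) {
    if (length(blocks) >= best) return(invisible())
    if (i > n) {
      best <<- min(best, length(blocks))
      return(invisible())
    }
    for (bi in seq_along(blocks)) {
      blk <- blocks[[bi]]
      if (length(blk) < plex_size &&
          all(abs(blk - lengths[i]) >= min_sep)) {
        nb <- blocks
        nb[[bi]] <- c(blk, lengths[i])
        assign_next(i + 1L, nb)
      }
    }
    assign_next(i + 1L, c(blocks, list(lengths[i])))
    invisible()
  }
  assign_next(2L, list(lengths[1]))
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
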