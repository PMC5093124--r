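# Partition assays into k-plex reactions whose expected amplicon lengths are
# mutually resolvable on a gel. Two assays conflict when their expected
# lengths differ by less than the gel's minimum separation; the conflict
# graph on sorted lengths is a unit-interval graph, so sorting by length and
# dealing round-robin across r reactions is an optimal colouring whenever
# r >= max(ceiling(n / plex_size), largest conflict clique).

#' Gel resolution model
#'
#' @param min_separation smallest length difference (bp) two bands in one
#'   reaction may have and still be resolved.
#' @param length_tolerance band-calling tolerance (bp); 0 = exact match.
#' @return object of class `gel_model`.
#' @export
gel_model <- function(min_separation = 50L, length_tolerance = 0L) {
  stopifnot(min_separation > 0L, length_tolerance >= 0L)
  structure(list(min_separation = as.integer(min_separation),
                 length_tolerance = as.integer(length_tolerance)),
            class = "gel_model")
}

# largest number of lengths inside any open window of width min_separation
.max_conflict_clique <- function(lengths, min_separation) {
  x <- sort(lengths)
  best <- 1L
  j <- 1L
  for (i in seq_along(x)) {
    while (x[i] - x[j] >= min_separation) j <- j + 1L
    best <- max(best, i - j + 1L)
  }
  best
}

#' Partition assays into gel-resolvable multiplex reactions
#'
#' Uses the minimum feasible number of reactions subject to the plex-size
#' cap and the pairwise separation constraint, and returns the deterministic
#' canonical solution: assays sorted by expected length (ties by taxon) are
#' dealt round-robin across the reactions.
#'
#' @param assays list of `assay_definition` objects with distinct taxa.
#' @param plex_size maximum assays per reaction (5 = pentaplex).
#' @param gel a `gel_model`.
#' @param max_reactions optional cap; an error is raised when the minimum
#'   feasible reaction count exceeds it.
#' @return object of class `multiplex_scheme`: list of reactions (each an
#'   ordered list of assays) plus the gel model.
#' @export
partition_assays <- function(assays, plex_size = 5L, gel = gel_model(),
                             max_reactions = NULL) {
  stopifnot(plex_size >= 1L, length(assays) >= 1L)
  taxa <- vapply(assays, function(a) a$taxon, "")
  if (anyDuplicated(taxa)) stop("assays must have distinct taxa")
  lens <- vapply(assays, function(a) a$expected_length, 0L)
  n <- length(assays)
  r <- max(ceiling(n / plex_size),
           .max_conflict_clique(lens, gel$min_separation))
  if (!is.null(max_reactions) && r > max_reactions) {
    stop("assays cannot be partitioned within ", max_reactions,
         " reactions (minimum feasible is ", r, ")")
  }
  ord <- order(lens, taxa)
  reactions <- vector("list", r)
  for (k in seq_along(ord)) {
    slot <- ((k - 1L) %% r) + 1L
    reactions[[slot]] <- c(reactions[[slot]], list(assays[[ord[k]]]))
  }
  scheme <- structure(list(reactions = reactions, gel = gel),
                      class = "multiplex_scheme")
  stopifnot(validate_scheme(scheme, plex_size))
  scheme
}

#' Check a scheme's size and separation constraints
#' @param scheme a `multiplex_scheme`.
#' @param plex_size maximum reaction size to check against.
#' @return TRUE if valid, otherwise FALSE.
#' @export
validate_scheme <- function(scheme, plex_size = Inf) {
  for (rxn in scheme$reactions) {
    if (length(rxn) > plex_size) return(FALSE)
    lens <- vapply(rxn, function(a) a$expected_length, 0L)
    if (length(lens) > 1L) {
      d <- diff(sort(lens))
      if (any(d < scheme$gel$min_separation)) return(FALSE)
    }
  }
  TRUE
}

#' Number of reactions in a scheme
#' @param scheme a `multiplex_scheme`.
#' @return integer count.
#' @export
n_reactions <- function(scheme) length(scheme$reactions)

#' Taxa covered by a scheme
#' @param scheme a `multiplex_scheme`.
#' @return character vector of taxon labels, reaction by reaction.
#' @export
scheme_taxa <- function(scheme) {
  unlist(lapply(scheme$reactions,
                function(rxn) vapply(rxn, function(a) a$taxon, "")))
}

#' @export
print.multiplex_scheme <- function(x, ...) {
  cat("multiplex_scheme:", n_reactions(x), "reactions\n")
  lad <- render_ladder(x)
  for (i in seq_along(lad)) {
    cat(sprintf("  rxn%s: %s\n", LETTERS[i],
                paste(sprintf("%d bp (%s)", lad[[i]]$length, lad[[i]]$taxon),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Expected band ladder per reaction
#'
#' @param scheme a `multiplex_scheme`.
#' @return list (one element per reaction) of data.frames with ascending
#'   `length` and `taxon` columns — the positive-control ladder a gel of
#'   that reaction should show.
#' @export
render_ladder <- function(scheme) {
  lapply(scheme$reactions, function(rxn) {
    if (!length(rxn)) {
      return(data.frame(length = integer(0), taxon = character(0)))
    }
    df <- data.frame(length = vapply(rxn, function(a) a$expected_length, 0L),
                     taxon = vapply(rxn, function(a) a$taxon, ""),
                     stringsAsFactors = FALSE)
    df <- df[order(df$length), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

#' Export a scheme as a tab-separated table
#' @param scheme a `multiplex_scheme`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  rows <- list()
  for (i in seq_along(scheme$reactions)) {
    for (a in scheme$reactions[[i]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        reaction_id = paste0("rxn", LETTERS[i]), taxon = a$taxon,
        forward = a$forward$sequence, reverse = a$reverse$sequence,
        expected_length = a$expected_length, kind = a$kind,
        stringsAsFactors = FALSE)
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Import a scheme from a tab-separated table
#' @param path file written by [write_scheme()].
#' @param gel a `gel_model`.
#' @return a `multiplex_scheme`.
#' @export
read_scheme <- function(path, gel = gel_model()) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ids <- unique(df$reaction_id)
  reactions <- lapply(ids, function(id) {
    sub <- df[df$reaction_id == id, , drop = FALSE]
    lapply(seq_len(nrow(sub)), function(i) {
      fcand <- data.frame(sequence = sub$forward[i], strand = "+",
                          start = NA_integer_, length = nchar(sub$forward[i]),
                          tm = tm_wallace(sub$forward[i]),
                          gc = gc_percent(sub$forward[i]),
                          stringsAsFactors = FALSE)
      rcand <- data.frame(sequence = sub$reverse[i], strand = "-",
                          start = NA_integer_, length = nchar(sub$reverse[i]),
                          tm = tm_wallace(sub$reverse[i]),
                          gc = gc_percent(sub$reverse[i]),
                          stringsAsFactors = FALSE)
      assay_definition(sub$taxon[i], fcand, rcand, sub$expected_length[i],
                       kind = sub$kind[i])
    })
  })
  structure(list(reactions = reactions, gel = gel),
            class = "multiplex_scheme")
}
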