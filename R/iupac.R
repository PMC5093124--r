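# IUPAC nucleotide codes as bitmasks over {A=1, C=2, G=4, T=8}.
# Unions give the 11 ambiguity codes; N covers all four. The gap marker "-"
# maps to 0 and intersects nothing.

.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L,
  `-` = 0L
)

.MASK_CODE <- character(16L)
.MASK_CODE[1L + c(1L, 2L, 4L, 8L, 5L, 10L, 6L, 9L, 12L, 3L, 14L, 13L, 11L, 7L, 15L)] <-
  c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

.COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
)

#' Encode a DNA string as an IUPAC bitmask vector
#'
#' Each symbol maps to the union-of-bases bitmask (A=1, C=2, G=4, T=8); the
#' gap symbol maps to 0. Two symbols are compatible iff their masks intersect.
#'
#' @param x a single DNA string (IUPAC alphabet, optionally with `-`).
#' @return integer vector of per-position masks.
#' @keywords internal
iupac_encode <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  m <- .IUPAC_MASK[chars]
  if (anyNA(m)) {
    bad <- unique(chars[is.na(m)])
    stop("invalid nucleotide symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

#' Decode a bitmask vector back to IUPAC symbols
#' @param m integer vector of masks in 0..15 (0 renders as `-`).
#' @return a single string.
#' @keywords internal
iupac_decode <- function(m) {
  out <- .MASK_CODE[m + 1L]
  out[m == 0L] <- "-"
  paste(out, collapse = "")
}

#' Expand an IUPAC symbol to its base set
#' @param sym single IUPAC character.
#' @return character vector of plain bases.
#' @export
#' @examples
#' iupac_expand("W") # A T
iupac_expand <- function(sym) {
  m <- .IUPAC_MASK[toupper(sym)]
  if (is.na(m)) stop("unknown IUPAC symbol: ", sym)
  c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
}

#' Smallest IUPAC code covering a set of bases
#' @param bases character vector over A/C/G/T.
#' @return single IUPAC character.
#' @export
iupac_code <- function(bases) {
  m <- sum(.IUPAC_MASK[unique(toupper(bases))])
  if (is.na(m) || m < 1L || m > 15L) stop("bases must be drawn from A, C, G, T")
  .MASK_CODE[m + 1L]
}

#' Reverse complement of a DNA string (IUPAC-aware)
#' @param x a single DNA string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  comp <- .COMPLEMENT[chars]
  if (anyNA(comp)) stop("invalid symbol in sequence")
  paste(rev(unname(comp)), collapse = "")
}
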