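# Taxon labels are canonical strings "Genus species [subspecies] [strain]".
# The FASTA header dialect is "Genus species [subspecies] [strain]|source_id":
# a third token in lowercase letters is read as a subspecies, any other third
# token (digits or capitals, e.g. "NCFM", "La-14") as a strain designation.

#' Build a canonical taxon label
#'
#' @param genus,species non-empty character scalars.
#' @param subspecies,strain optional character scalars (`NA` to omit).
#' @return a character scalar; rendering is stable and unique per
#'   (genus, species, subspecies, strain) tuple.
#' @export
#' @examples
#' taxon_label("Lactobacillus", "acidophilus", strain = "NCFM")
taxon_label <- function(genus, species, subspecies = NA_character_,
                        strain = NA_character_) {
  if (!nzchar(genus) || !nzchar(species)) {
    stop("genus and species must be non-empty")
  }
  parts <- c(genus, species,
             if (!is.na(subspecies) && nzchar(subspecies)) subspecies,
             if (!is.na(strain) && nzchar(strain)) strain)
  paste(parts, collapse = " ")
}

#' Parse a taxon annotation from header text
#'
#' @param x header text, either `Genus species [subsp] [strain]` or the
#'   full `...|source_id` form.
#' @return list with genus, species, subspecies, strain, label, source_id.
#' @export
parse_taxon <- function(x) {
  x <- trimws(x)
  source_id <- NA_character_
  if (grepl("|", x, fixed = TRUE)) {
    halves <- strsplit(x, "|", fixed = TRUE)[[1]]
    if (length(halves) != 2L || !nzchar(trimws(halves[2]))) {
      stop("malformed taxon header (expected 'Genus species [subsp] [strain]|id'): ", x)
    }
    source_id <- trimws(halves[2])
    x <- trimws(halves[1])
  }
  toks <- strsplit(x, "[[:space:]]+")[[1]]
  if (length(toks) < 2L || length(toks) > 4L) {
    stop("taxon annotation must have 2-4 tokens: ", x)
  }
  genus <- toks[1]; species <- toks[2]
  subspecies <- NA_character_; strain <- NA_character_
  is_subsp <- function(tok) grepl("^[a-z]+$", tok)
  if (length(toks) == 3L) {
    if (is_subsp(toks[3])) subspecies <- toks[3] else strain <- toks[3]
  } else if (length(toks) == 4L) {
    if (!is_subsp(toks[3])) {
      stop("third token must be a lowercase subspecies when four tokens are given: ", x)
    }
    subspecies <- toks[3]; strain <- toks[4]
  }
  list(genus = genus, species = species, subspecies = subspecies,
       strain = strain,
       label = taxon_label(genus, species, subspecies, strain),
       source_id = source_id)
}

#' The default 20-taxon probiotic assay roster
#'
#' The species and sub-species commonly blended into commercial probiotic
#' products, at the resolution a pgi-based multiplex panel targets. This is
#' a synthetic reconstruction of a typical 20-organism roster of lactobacilli,
#' bifidobacteria and dairy starters; it drives the synthetic panel
#' generators and the worked examples.
#'
#' @return character vector of 20 canonical taxon labels.
#' @export
default_taxon_roster <- function() {
  c(
    "Bifidobacterium animalis lactis",
    "Bifidobacterium animalis animalis",
    "Bifidobacterium longum longum",
    "Bifidobacterium longum infantis",
    "Bifidobacterium breve",
    "Bifidobacterium bifidum",
    "Bifidobacterium adolescentis",
    "Lactobacillus acidophilus",
    "Lactobacillus helveticus",
    "Lactobacillus casei",
    "Lactobacillus paracasei",
    "Lactobacillus rhamnosus",
    "Lactobacillus plantarum",
    "Lactobacillus gasseri",
    "Lactobacillus reuteri",
    "Lactobacillus salivarius",
    "Lactobacillus delbrueckii bulgaricus",
    "Lactobacillus fermentum",
    "Lactococcus lactis",
    "Streptococcus thermophilus"
  )
}

#' Closely related species pairs prone to label swaps
#'
#' Pairs that have historically been mislabeled for one another in commercial
#' products; the mislabeled-product generator restricts species swaps to
#' these by default.
#'
#' @return list of length-2 character vectors of taxon labels.
#' @export
related_taxon_pairs <- function() {
  list(
    c("Bifidobacterium longum longum", "Bifidobacterium longum infantis"),
    c("Lactobacillus casei", "Lactobacillus paracasei"),
    c("Lactobacillus acidophilus", "Lactobacillus helveticus")
  )
}
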