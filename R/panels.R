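#' Construct a species panel
#'
#' @param samples data.frame with columns `sample_id`, `species_id`.
#' @param focal character vector of focal species ids.
#' @param background background species ids; defaults to every non-focal
#'   species present in `samples`.
#' @return A [SpeciesPanel-class].
#' @examples
#' speciesPanel(data.frame(sample_id = c("bd1", "cf1"),
#'                         species_id = c("bush_dog", "crab_eating_fox")),
#'              focal = "bush_dog")
#' @export
speciesPanel <- function(samples, focal = character(), background = NULL) {
  samples$sample_id <- as.character(samples$sample_id)
  samples$species_id <- as.character(samples$species_id)
  if (is.null(background))
    background <- setdiff(unique(samples$species_id), focal)
  new("SpeciesPanel", samples = samples[, c("sample_id", "species_id")],
      focal = as.character(focal), background = as.character(background))
}

#' Read a species panel from a two-column TSV
#'
#' The file must have two tab-separated columns, `sample_id` and
#' `species_id`; a header line is optional and detected by name.
#'
#' @param path path to the TSV.
#' @inheritParams speciesPanel
#' @return A [SpeciesPanel-class].
#' @export
readSpeciesPanel <- function(path, focal = character(), background = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("sample_id", first, fixed = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!has_header) names(df)[1:2] <- c("sample_id", "species_id")
  speciesPanel(df, focal = focal, background = background)
}

#' @describeIn speciesPanel sample ids of a panel (or of a
#'   [VariantPanel-class]).
#' @param x a SpeciesPanel or VariantPanel.
#' @export
sampleIds <- function(x) {
  if (is(x, "VariantPanel")) x <- x@panel
  x@samples$sample_id
}

#' @describeIn speciesPanel species ids present in the panel.
#' @export
speciesIds <- function(x) {
  if (is(x, "VariantPanel")) x <- x@panel
  unique(x@samples$species_id)
}

#' @describeIn speciesPanel focal species ids.
#' @export
focalSpecies <- function(x) {
  if (is(x, "VariantPanel")) x <- x@panel
  x@focal
}

#' @describeIn speciesPanel background species ids.
#' @export
backgroundSpecies <- function(x) {
  if (is(x, "VariantPanel")) x <- x@panel
  x@background
}

#' @describeIn speciesPanel sample ids belonging to one or more species.
#' @param species character vector of species ids.
#' @export
samplesOfSpecies <- function(x, species) {
  if (is(x, "VariantPanel")) x <- x@panel
  x@samples$sample_id[x@samples$species_id %in% species]
}

setMethod("show", "SpeciesPanel", function(object) {
  cat("SpeciesPanel:", nrow(object@samples), "samples,",
      length(unique(object@samples$species_id)), "species\n")
  cat("  focal:", paste(object@focal, collapse = ", "), "\n")
  cat("  background:", paste(object@background, collapse = ", "), "\n")
})

## ---- genome layout (Seqinfo) ----------------------------------------------

#' Build a genome layout
#'
#' The layout is a `GenomeInfoDb::Seqinfo`; chromosome names must be unique
#' and lengths strictly positive.
#'
#' @param chrom character vector of chromosome names.
#' @param length integer vector of chromosome lengths in bp.
#' @return A `Seqinfo`.
#' @examples
#' genomeLayout(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genomeLayout <- function(chrom, length) {
  if (any(length <= 0)) stop("chromosome lengths must be strictly positive")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  GenomeInfoDb::Seqinfo(seqnames = as.character(chrom),
                        seqlengths = as.integer(length))
}

#' Read a genome layout from a two-column chromosome-length TSV
#'
#' @param path TSV with columns chromosome name and length in bp. Lines
#'   starting with `#` are ignored.
#' @return A `Seqinfo`.
#' @export
readGenomeLayout <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  genomeLayout(df[[1]], df[[2]])
}

#' Total genome length of a layout
#'
#' @param layout a `Seqinfo` (or an object with one, e.g. a
#'   [VariantPanel-class]).
#' @return Total length in bp, the denominator of genome-fraction summaries.
#' @export
genomeSize <- function(layout) {
  if (is(layout, "VariantPanel"))
    layout <- GenomeInfoDb::seqinfo(layout@sites)
  sum(as.numeric(GenomeInfoDb::seqlengths(layout)))
}

#' Write a genome layout to a chromosome-length TSV
#'
#' @param layout a `Seqinfo`.
#' @param path output path.
#' @export
writeGenomeLayout <- function(layout, path) {
  writeLines(paste(GenomeInfoDb::seqnames(layout),
                   GenomeInfoDb::seqlengths(layout), sep = "\t"), path)
}
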