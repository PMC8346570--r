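#' Bundled GRCh37 autosome lengths
#'
#' Chromosome lengths (bp) of the 22 human autosomes on the GRCh37
#' assembly, used as the denominator for genome-fraction computations and
#' as the coordinate space of the synthetic-data generator.
#'
#' @return A data frame with columns `chrom` (character, `"1"`–`"22"`) and
#'   `length` (integer bp).
#' @export
autosome_lengths <- function() {
  tab <- read.delim(bilinevo_extdata("grch37_autosomes.tsv"),
                    colClasses = c("character", "numeric"))
  tab
}

#' Load a 96 x 30 mutational-signature catalog
#'
#' Reads a signature catalog TSV (first column `context`, then one column
#' per signature) and validates that it is column-stochastic.  The package
#' ships a deterministic *synthetic* stand-in catalog
#' (`signature_catalog_v2_synthetic.tsv`) with the structure of the classic
#' 30-signature SBS reference — a CpG C>T aging-like column (`Sig1`),
#' APOBEC-like TpC columns (`Sig2`, `Sig13`), and so on — because the
#' published probabilities are not redistributable.  Any catalog with the
#' same layout (e.g. the real COSMIC v2 or v3 file) can be supplied
#' instead; the catalog file is the single source of truth for the channel
#' order.
#'
#' @param path Path to a catalog TSV. Defaults to the bundled synthetic
#'   catalog.
#' @return A numeric matrix, contexts in rows (rownames are channel labels
#'   such as `"A[C>T]G"`), signatures in columns.
#' @export
load_signature_catalog <- function(path = NULL) {
  path <- path %||% bilinevo_extdata("signature_catalog_v2_synthetic.tsv")
  tab <- read.delim(path, check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  if (nrow(mat) != 96) stop("signature catalog must have 96 context rows")
  if (any(mat < 0)) stop("signature catalog entries must be non-negative")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-6))
    stop("signature catalog columns must each sum to 1")
  mat
}

#' Load the signature-to-etiology map
#'
#' @param path Path to a two-column TSV (`signature`, `etiology`). Defaults
#'   to the bundled map covering all 30 signatures (Sig1 = aging,
#'   Sig2/Sig13 = APOBEC, Sig7 = UV, Sig10 = POLE, ...).
#' @return Named character vector: etiology label per signature.
#' @export
load_etiology_map <- function(path = NULL) {
  path <- path %||% bilinevo_extdata("signature_etiology.tsv")
  tab <- read.delim(path, colClasses = "character")
  setNames(tab$etiology, tab$signature)
}

#' Load the driver-gene list
#'
#' A bundled list of recurrently mutated cancer driver genes (pan-cancer
#' consensus style) used to restrict driver tabulation.
#'
#' @param path Optional path to a one-column TSV with header `gene`.
#' @return Character vector of gene symbols.
#' @export
load_driver_genes <- function(path = NULL) {
  path <- path %||% bilinevo_extdata("driver_genes.tsv")
  read.delim(path, colClasses = "character")$gene
}
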