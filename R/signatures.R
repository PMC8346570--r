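# Mutational-signature decomposition: 96-channel spectrum counting and
# non-negative least-squares fitting against a signature catalog.

#' Canonical SBS96 channel labels
#'
#' The 96 pyrimidine-centered single-base-substitution channels in the
#' conventional order: substitutions C>A, C>G, C>T, T>A, T>C, T>G, and
#' within each substitution the 16 flanking-base combinations with the 5'
#' base varying slowest (A, C, G, T).
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    out <- character(0)
    for (f5 in bases) for (f3 in bases)
      out <- c(out, paste0(f5, "[", s, "]", f3))
    out
  }))
}

revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, ""), function(b) paste(rev(b), collapse = ""),
         character(1))
}

#' Map SNVs to SBS96 channels
#'
#' Collapses each substitution to the pyrimidine strand: a purine
#' reference (A or G) is reverse-complemented together with its
#' trinucleotide context, so e.g. a G>A call in context `TGC` lands in the
#' `G[C>T]A` channel.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param context Trinucleotide reference-strand context with the mutated
#'   base in the middle (e.g. `"ACA"`).
#' @return Character vector of channel labels.
#' @export
snv_channel <- function(ref, alt, context) {
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  bad <- !grepl("^[ACGT]{3}$", context) | substr(context, 2, 2) != ref |
    nchar(ref) != 1 | nchar(alt) != 1 | ref == alt
  if (any(bad))
    stop("malformed SNV context at rows: ",
         paste(head(which(bad), 5), collapse = ", "))
  flip <- ref %in% c("A", "G")
  ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  context[flip] <- revcomp(context[flip])
  paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
         substr(context, 3, 3))
}

#' Tally the 96-channel mutation spectrum of a set of SNVs
#'
#' @param snvs Data frame with columns `ref`, `alt`, `context`
#'   (trinucleotide, reference strand).
#' @return Named integer vector of length 96 summing to `nrow(snvs)`.
#' @export
count_spectrum <- function(snvs) {
  channels <- sbs96_channels()
  spec <- setNames(integer(96), channels)
  if (nrow(snvs) == 0) return(spec)
  ch <- snv_channel(snvs$ref, snvs$alt, snvs$context)
  tab <- table(factor(ch, levels = channels))
  spec[] <- as.integer(tab)
  spec
}

#' Decompose a mutation spectrum into signature exposures
#'
#' Fits the normalized 96-channel spectrum as a non-negative linear
#' combination of catalog signatures (non-negative least squares), prunes
#' signatures contributing less than `min_contribution` of the total
#' exposure, re-fits on the retained set until stable, and renormalizes
#' the retained exposures to sum to 1.  The 6% default pruning cutoff
#' mirrors the cutoff conventionally used for this style of refitting.
#'
#' @param spectrum Non-negative 96-vector of channel counts (names are
#'   matched against the catalog rownames when present).
#' @param catalog Signature catalog matrix from [load_signature_catalog()].
#' @param min_contribution Minimum retained relative contribution.
#' @return List with `exposures` (named 30-vector summing to 1, zeros for
#'   pruned signatures), `error` (L2 norm of the residual between the
#'   normalized spectrum and its reconstruction), and `retained`.
#' @export
decompose_signatures <- function(spectrum, catalog = load_signature_catalog(),
                                 min_contribution = 0.06) {
  if (length(spectrum) != nrow(catalog))
    stop("spectrum length must match catalog rows")
  if (any(spectrum < 0)) stop("spectrum must be non-negative")
  if (sum(spectrum) <= 0) stop("cannot decompose an all-zero spectrum")
  if (!is.null(names(spectrum)))
    spectrum <- spectrum[rownames(catalog)]
  target <- spectrum / sum(spectrum)

  keep <- seq_len(ncol(catalog))
  repeat {
    fit <- pracma::lsqnonneg(catalog[, keep, drop = FALSE], target)
    w <- fit$x
    if (sum(w) <= 0) stop("degenerate non-negative fit")
    rel <- w / sum(w)
    ok <- rel >= min_contribution
    if (all(ok) || sum(ok) == 0) {
      if (sum(ok) == 0) { # keep the single largest contributor
        ok <- seq_along(rel) == which.max(rel)
        keep <- keep[ok]
        fit <- pracma::lsqnonneg(catalog[, keep, drop = FALSE], target)
        w <- fit$x
      } else {
        keep <- keep[ok]
        w <- w[ok]
      }
      break
    }
    keep <- keep[ok]
  }

  recon <- catalog[, keep, drop = FALSE] %*% cbind(w)
  err <- sqrt(sum((target - recon)^2))
  exposures <- setNames(numeric(ncol(catalog)), colnames(catalog))
  exposures[keep] <- w / sum(w)
  list(exposures = exposures, error = err,
       retained = colnames(catalog)[keep])
}

#' Aggregate signature exposures by etiology
#'
#' @param exposures Named exposure vector (as returned in
#'   `decompose_signatures()$exposures`).
#' @param etiology_map Named character vector mapping every signature to an
#'   etiology label; see [load_etiology_map()].
#' @return Named numeric vector of per-etiology contribution sums (same
#'   total as `sum(exposures)`).
#' @export
aggregate_by_etiology <- function(exposures, etiology_map = load_etiology_map()) {
  unmapped <- setdiff(names(exposures), names(etiology_map))
  if (length(unmapped) > 0)
    stop("signatures missing from etiology map: ",
         paste(unmapped, collapse = ", "))
  grp <- etiology_map[names(exposures)]
  out <- tapply(exposures, grp, sum)
  sort(setNames(as.numeric(out), names(out)), decreasing = TRUE)
}
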