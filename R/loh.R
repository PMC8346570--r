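# LOH interval analysis on allele-specific copy-number segments.
# Coordinates are 1-based inclusive (SEG dialect); lengths are
# end - start + 1.  A segment is under LOH when its minor copy number is
# zero (copy-neutral LOH, deletion LOH and homozygous deletion all
# qualify).  Interval arithmetic is done with GenomicRanges/IRanges.

segments_to_granges <- function(seg) {
  GenomicRanges::GRanges(as.character(seg$chrom),
                         IRanges::IRanges(seg$start, seg$end))
}

# intersect with harmonized seqlevels (profiles need not mention every
# chromosome)
gr_intersect <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  GenomicRanges::intersect(a, b, ignore.strand = TRUE)
}

granges_to_segments <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr))
}

#' Read a SEG-like allele-specific copy-number table
#'
#' Tab-separated columns: `sample_id`, `chrom`, `start`, `end` (1-based
#' inclusive), `cn_total`, `cn_minor`.
#'
#' @param path Path to the TSV.
#' @return Data frame of segments with a derived logical `loh` column.
#' @export
read_seg <- function(path) {
  seg <- read.delim(path, stringsAsFactors = FALSE)
  seg$chrom <- as.character(seg$chrom)
  validate_segments(seg)
}

validate_segments <- function(seg) {
  if (any(seg$start > seg$end)) stop("segment with start > end")
  if (any(seg$cn_minor > seg$cn_total - seg$cn_minor))
    stop("cn_minor exceeds the major copy number")
  seg$loh <- seg$cn_minor == 0
  seg
}

#' Per-sample segment profile
#'
#' Validates and orders one sample's segments (sorted, non-overlapping
#' within chromosome) and records the covered (segmented) genome length.
#'
#' @param seg Segment data frame of a single sample (see [read_seg()]).
#' @return A `segment_profile`: list with `sample_id`, `segments`,
#'   `covered_length`.
#' @export
segment_profile <- function(seg) {
  seg <- validate_segments(seg)
  ord <- order(seg$chrom, seg$start)
  seg <- seg[ord, , drop = FALSE]
  by_chr <- split(seg, seg$chrom)
  for (s in by_chr) {
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping segments within a chromosome")
  }
  structure(list(sample_id = unique(seg$sample_id) %||% NA_character_,
                 segments = seg,
                 covered_length = sum(seg$end - seg$start + 1)),
            class = "segment_profile")
}

loh_segments_of <- function(profile) {
  profile$segments[profile$segments$loh, , drop = FALSE]
}

#' Genome fraction under LOH
#'
#' @param profile A `segment_profile`.
#' @param denominator `"covered"` (segmented length; default) or
#'   `"autosome_total"` (the bundled GRCh37 autosome total).
#' @return Fraction in \[0, 1\].
#' @export
loh_fraction <- function(profile,
                         denominator = c("covered", "autosome_total")) {
  denominator <- match.arg(denominator)
  loh <- loh_segments_of(profile)
  loh_len <- sum(loh$end - loh$start + 1)
  denom <- switch(denominator,
                  covered = profile$covered_length,
                  autosome_total = sum(autosome_lengths()$length))
  if (denom <= 0) stop("empty profile: covered length is zero")
  loh_len / denom
}

#' Shared (ancestral) LOH across the three tumors
#'
#' Base-pair three-way intersection of the LOH intervals of the GBC, LG
#' and HG profiles, attributed to their common ancestor.  The fraction
#' uses the same denominator semantics as [loh_fraction()]; for
#' `"covered"` the denominator is the three-way intersection of the
#' covered regions.
#'
#' @param gbc,lg,hg `segment_profile`s of one patient's three tumors.
#' @param denominator As in [loh_fraction()].
#' @return List with `segments` (the intersected LOH intervals, 1-based
#'   inclusive) and `fraction`.
#' @export
shared_loh <- function(gbc, lg, hg,
                       denominator = c("covered", "autosome_total")) {
  denominator <- match.arg(denominator)
  profs <- list(gbc, lg, hg)
  loh_gr <- lapply(profs, function(p) {
    loh <- loh_segments_of(p)
    if (nrow(loh) == 0)
      GenomicRanges::GRanges()
    else segments_to_granges(loh)
  })
  inter <- Reduce(gr_intersect, loh_gr)
  seg <- granges_to_segments(inter)
  inter_len <- sum(seg$end - seg$start + 1)
  denom <- if (denominator == "covered") {
    cov <- Reduce(gr_intersect,
                  lapply(profs, function(p) segments_to_granges(p$segments)))
    sum(GenomicRanges::width(cov))
  } else {
    sum(autosome_lengths()$length)
  }
  if (denom <= 0) stop("empty covered intersection")
  list(segments = seg, fraction = inter_len / denom)
}

#' Per-chromosome LOH fractions
#'
#' Fraction of each autosome (chr1-22, bundled GRCh37 lengths as the
#' denominator) under LOH.
#'
#' @param segments Data frame of LOH segments (`chrom`, `start`, `end`),
#'   or a `segment_profile` whose LOH segments are used.
#' @return Named numeric vector of 22 fractions.
#' @export
chromosome_loh_profile <- function(segments) {
  if (inherits(segments, "segment_profile"))
    segments <- loh_segments_of(segments)
  genome <- autosome_lengths()
  out <- setNames(numeric(nrow(genome)), genome$chrom)
  if (nrow(segments) > 0) {
    unknown <- setdiff(unique(segments$chrom), genome$chrom)
    if (length(unknown) > 0)
      stop("unknown chromosome label(s): ", paste(unknown, collapse = ", "))
    lens <- tapply(segments$end - segments$start + 1, segments$chrom, sum)
    out[names(lens)] <- as.numeric(lens)
  }
  out / genome$length
}

#' Binned LOH status matrix for tree building
#'
#' Splits the autosomes into fixed-size bins (default 10 Mb, the
#' operational definition of "large-scale") and flags a bin in a sample
#' when at least `min_overlap_frac` of it is under LOH.
#'
#' @param profiles Named list of `segment_profile`s (names = sample roles).
#' @param bin_size Bin width in bp.
#' @param min_overlap_frac Minimum LOH-covered fraction of a bin.
#' @return Binary matrix, bins in rows, samples in columns.
#' @export
loh_bin_matrix <- function(profiles, bin_size = 1e7,
                           min_overlap_frac = 0.5) {
  genome <- autosome_lengths()
  bins <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(1, genome$length[i], by = bin_size)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + bin_size - 1, genome$length[i]))
  }))
  gr_bins <- segments_to_granges(bins)
  mat <- sapply(profiles, function(p) {
    loh <- loh_segments_of(p)
    if (nrow(loh) == 0) return(integer(length(gr_bins)))
    cov <- gr_intersect(gr_bins, segments_to_granges(loh))
    hits <- GenomicRanges::findOverlaps(gr_bins, cov)
    w <- GenomicRanges::width(IRanges::pintersect(
      gr_bins[S4Vectors::queryHits(hits)],
      cov[S4Vectors::subjectHits(hits)]))
    covered <- numeric(length(gr_bins))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(agg))] <- agg
    as.integer(covered / GenomicRanges::width(gr_bins) >= min_overlap_frac)
  })
  rownames(mat) <- paste0(bins$chrom, ":", bins$start, "-", bins$end)
  mat
}

#' Hierarchical clustering of chromosome-level LOH profiles
#'
#' Average-linkage clustering on Euclidean distances between
#' per-chromosome LOH fraction profiles, with a flat cut for group
#' labels; the input matrix is returned for heatmap export.
#'
#' @param profiles Numeric matrix, samples in rows, chromosomes in
#'   columns (as built from [chromosome_loh_profile()] vectors).
#' @param k Number of flat clusters to cut (default 2).
#' @return List with `hclust`, `labels` (named cluster memberships) and
#'   `matrix`.
#' @export
cluster_loh_profiles <- function(profiles, k = 2) {
  if (nrow(profiles) < 2) stop("need at least two samples to cluster")
  hc <- hclust(dist(profiles, method = "euclidean"), method = "average")
  k <- min(k, nrow(profiles))
  list(hclust = hc, labels = cutree(hc, k = k), matrix = profiles)
}
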