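# Evolutionary-path classification: BilIN-independent when the carcinoma
# lineage splits before the common ancestor of the two BilIN lesions,
# BilIN-dependent when it splits after (sister to LG- or HG-BilIN), with
# SCNA- and LOH-layer corroboration and a consensus vote.

#' Classify the evolutionary path from a tree topology
#'
#' `((LG,HG),GBC)` is BilIN-independent (the carcinoma split before the
#' common ancestor of the two BilIN lesions); a tree whose sister pair
#' contains GBC is BilIN-dependent, with the sublabel naming the BilIN
#' lesion GBC clusters with; a star is unresolved.
#'
#' @param tree A `lesion_tree`, a nested-list topology, or a topology
#'   label such as `"((GBC,HG),LG)"`.
#' @return One of `"BilIN_independent"`, `"BilIN_dependent_LG"`,
#'   `"BilIN_dependent_HG"`, `"unresolved"`.
#' @export
classify_topology <- function(tree) {
  sister <- if (inherits(tree, "lesion_tree")) {
    if (!tree$resolved) return("unresolved")
    tree$sister
  } else {
    top <- if (is.character(tree)) topology_from_label(tree) else tree
    if (!is.list(top) || length(top) != 2) return("unresolved")
    sister_of(top)
  }
  if (setequal(sister, c("LG", "HG"))) return("BilIN_independent")
  if (setequal(sister, c("GBC", "LG"))) return("BilIN_dependent_LG")
  if (setequal(sister, c("GBC", "HG"))) return("BilIN_dependent_HG")
  "unresolved"
}

#' Tree from gene-level copy-number values
#'
#' The sister pair is the tumor pair with the smallest Manhattan distance
#' between gene-level SCNA profiles; distance ties give a star.
#'
#' @param scna Numeric matrix, genes in rows, the three tumor samples in
#'   columns (the matched normal is the implicit all-zero profile).
#' @param distance `"manhattan"` (default) or `"euclidean"`.
#' @return A `lesion_tree` with method `"scna"`.
#' @export
build_scna_tree <- function(scna, distance = c("manhattan", "euclidean")) {
  distance <- match.arg(distance)
  if (!is.numeric(scna)) stop("SCNA matrix must be numeric")
  leaves <- colnames(scna)
  if (length(leaves) != 3) stop("expected three tumor columns")
  d <- as.matrix(dist(t(scna), method = distance))
  pairs <- list(c(leaves[1], leaves[2]), c(leaves[1], leaves[3]),
                c(leaves[2], leaves[3]))
  dd <- vapply(pairs, function(p) d[p[1], p[2]], numeric(1))
  best <- which(dd == min(dd))
  if (length(best) != 1)
    return(new_lesion_tree(star_topology(leaves), leaves, method = "scna",
                           tie = TRUE))
  sister <- pairs[[best]]
  top <- list(list(sister[1], sister[2]), setdiff(leaves, sister))
  new_lesion_tree(top, leaves, method = "scna")
}

#' Tree from binned LOH status
#'
#' Applies the same exhaustive maximum-parsimony machinery as the
#' mutation tree to a binary matrix of large-scale LOH status per genomic
#' bin (default binning is provided by [loh_bin_matrix()]).
#'
#' @param loh_bins Binary matrix, bins in rows, tumor samples in columns.
#' @return A `lesion_tree` with method `"loh"`.
#' @export
build_loh_tree <- function(loh_bins) {
  informative <- rowSums(loh_bins) > 0
  if (!any(informative)) {
    leaves <- colnames(loh_bins)
    return(new_lesion_tree(star_topology(leaves), leaves, method = "loh",
                           n_sites = 0L))
  }
  suppressWarnings(infer_tree(loh_bins[informative, , drop = FALSE],
                              method = "loh"))
}

#' Consensus path classification over evidence layers
#'
#' Majority vote over the resolved layers at the coarse independent vs
#' dependent level; ties (and the case where every layer is unresolved but
#' a mutation label exists) fall back to the mutation layer.  The
#' dependent sublabel is always taken from the mutation layer when it has
#' one, since the coarser layers need not resolve it.
#'
#' @param labels Named character vector (or list) of per-layer path
#'   labels; must contain a `mutation` entry, e.g.
#'   `c(mutation = ..., scna = ..., loh = ...)`.
#' @return List with `label` (the consensus path label), `group`
#'   (`"independent"`, `"dependent"` or `"unresolved"`), and `evidence`
#'   (the per-layer labels).
#' @export
consensus_classification <- function(labels) {
  labels <- unlist(labels)
  if (!"mutation" %in% names(labels))
    stop("a 'mutation' layer label is required")
  coarse <- function(l) {
    if (l == "BilIN_independent") "independent"
    else if (l %in% c("BilIN_dependent_LG", "BilIN_dependent_HG")) "dependent"
    else "unresolved"
  }
  votes <- vapply(labels, coarse, character(1))
  resolved <- votes[votes != "unresolved"]
  mut <- labels[["mutation"]]
  group <- if (length(resolved) == 0) {
    coarse(mut)
  } else {
    n_ind <- sum(resolved == "independent")
    n_dep <- sum(resolved == "dependent")
    if (n_ind > n_dep) "independent"
    else if (n_dep > n_ind) "dependent"
    else coarse(mut)  # tie -> mutation layer
  }
  label <- if (group == "independent") {
    "BilIN_independent"
  } else if (group == "dependent") {
    if (coarse(mut) == "dependent") mut else "BilIN_dependent"
  } else {
    "unresolved"
  }
  list(label = label, group = group, evidence = as.list(labels))
}
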