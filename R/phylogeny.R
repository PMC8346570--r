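# Rooted maximum-parsimony lesion phylogenies.  The root is the matched
# normal sample, fixed at the all-absent (0) state; minimum state changes
# per character are computed by unit-cost dynamic programming (Sankoff),
# which allows back-mutation, matching standard maximum-parsimony
# semantics.  With three tumor leaves the topology space (three resolved
# rooted trees plus the star) is scored exhaustively.

# A topology is a nested structure: a leaf is a character scalar, an
# internal node a list of child subtrees (two children when resolved; the
# 3-leaf star is a single internal node with three leaf children).

topology_leaves <- function(top) {
  if (is.character(top)) return(top)
  unlist(lapply(top, topology_leaves))
}

#' Enumerate rooted tree topologies
#'
#' Recursively enumerates all resolved rooted binary topologies over a
#' leaf set by inserting each leaf on every edge (including the root
#' edge), giving the classic (2n-3)!! count: 3 trees for 3 leaves, 15 for
#' 4.
#'
#' @param leaves Character vector of 2–6 leaf names.
#' @return List of nested-list topologies.
#' @export
enumerate_topologies <- function(leaves) {
  n <- length(leaves)
  if (n < 2) stop("need at least 2 leaves")
  if (n > 6) stop("exhaustive enumeration is limited to 6 leaves")
  trees <- list(leaves[1])
  for (k in 2:n) {
    new_trees <- list()
    for (tr in trees)
      new_trees <- c(new_trees, insert_leaf(tr, leaves[k]))
    trees <- new_trees
  }
  trees
}

# all ways to attach `leaf` on an edge of `tree`, plus above the root
insert_leaf <- function(tree, leaf) {
  out <- list(list(tree, leaf))            # new root above the old one
  if (is.list(tree)) {
    for (i in seq_along(tree)) {
      for (sub in insert_leaf(tree[[i]], leaf)) {
        mod <- tree
        mod[[i]] <- sub
        out <- c(out, list(mod))
      }
    }
  }
  out
}

star_topology <- function(leaves) as.list(leaves)

#' Canonical label of a topology
#'
#' @param top Nested-list topology.
#' @return A newick-like label, e.g. `"((LG,HG),GBC)"`; child order as
#'   stored.
#' @export
topology_label <- function(top) {
  if (is.character(top)) return(top)
  paste0("(", paste(vapply(top, topology_label, character(1)),
                    collapse = ","), ")")
}

#' Parse a 3-leaf topology label
#'
#' Accepts labels of the form `"((A,B),C)"` (whitespace ignored) or
#' `"star"` and returns the nested-list topology.
#'
#' @param label Character scalar.
#' @return Nested-list topology.
#' @export
topology_from_label <- function(label) {
  lab <- gsub("[[:space:]]", "", label)
  if (identical(lab, "star")) return(star_topology(tumor_roles()))
  m <- regmatches(lab, regexec("^\\(\\((\\w+),(\\w+)\\),(\\w+)\\)$", lab))[[1]]
  if (length(m) != 4) stop("unrecognized topology label: ", label)
  list(list(m[2], m[3]), m[4])
}

# unit-cost Sankoff: minimum number of 0<->1 changes on `top` for one
# row of leaf states, with the root (above `top`) fixed at state 0.
# Returns the per-row vector of minimal change counts.
sankoff_scores <- function(top, mat) {
  # cost(node) -> n x 2 matrix of min changes in the subtree given the
  # node's state is 0 (col 1) or 1 (col 2)
  node_cost <- function(node) {
    if (is.character(node)) {
      s <- mat[, node]
      cbind(ifelse(s == 0, 0, Inf), ifelse(s == 1, 0, Inf))
    } else {
      total <- 0
      for (child in node) {
        cc <- node_cost(child)
        # min over the child's state t of cost(child,t) + [s != t]
        total <- total + cbind(pmin(cc[, 1], cc[, 2] + 1),
                               pmin(cc[, 2], cc[, 1] + 1))
      }
      total
    }
  }
  cc <- node_cost(top)
  # stem edge from the fixed-0 root to the top node
  pmin(cc[, 1], cc[, 2] + 1)
}

#' Parsimony score of a topology for a binary mutation matrix
#'
#' Sum over matrix rows of the minimum number of 0/1 state changes on the
#' rooted tree, with the root (the matched normal) fixed at the all-zero
#' state.
#'
#' @param top Nested-list topology (or a label accepted by
#'   [topology_from_label()]).
#' @param mat Binary matrix from [build_binary_matrix()]; columns must
#'   cover the topology's leaves.
#' @return Integer score.
#' @export
parsimony_score <- function(top, mat) {
  if (is.character(top) && length(top) == 1 && !top %in% colnames(mat))
    top <- topology_from_label(top)
  leaves <- topology_leaves(top)
  if (!all(leaves %in% colnames(mat)))
    stop("matrix columns do not cover the topology leaves")
  if (nrow(mat) == 0) return(0L)
  if (any(rowSums(mat[, leaves, drop = FALSE]) == 0))
    stop("matrix contains all-zero rows")
  as.integer(sum(sankoff_scores(top, mat)))
}

# score all three resolved 3-leaf topologies + star from the 8 possible
# row patterns (fast path used by infer_tree and the bootstrap)
pattern_costs_3leaf <- function(leaves) {
  pats <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(pats) <- leaves
  tops <- c(enumerate_topologies(leaves), list(star_topology(leaves)))
  names(tops) <- vapply(tops, topology_label, character(1))
  costs <- sapply(tops, function(tp) sankoff_scores(tp, pats))
  list(patterns = pats, costs = costs, topologies = tops)
}

row_pattern_index <- function(mat, leaves) {
  1 + mat[, leaves[1]] + 2 * mat[, leaves[2]] + 4 * mat[, leaves[3]]
}

sister_of <- function(top) {
  # for a resolved 3-leaf topology, the cherry below the internal edge
  if (!is.list(top) || length(top) != 2) return(NULL)
  kids <- top
  inner <- kids[[which(vapply(kids, is.list, logical(1)))[1]]]
  sort(unlist(inner))
}

new_lesion_tree <- function(topology, leaves, scores = NULL,
                            branch_mutations = NULL, support = NA_real_,
                            n_sites = NA_integer_, method = "snv",
                            tie = FALSE) {
  resolved <- is.list(topology) && length(topology) == 2
  structure(list(
    topology = topology,
    label = if (resolved) topology_label(topology) else "star",
    resolved = resolved,
    sister = if (resolved) sister_of(topology) else NULL,
    outgroup = if (resolved)
      setdiff(leaves, sister_of(topology)) else NULL,
    leaves = leaves,
    scores = scores,
    parsimony_score = if (!is.null(scores))
      unname(scores[if (resolved) topology_label(topology) else
        topology_label(star_topology(leaves))]) else NA_integer_,
    branch_mutations = branch_mutations,
    branch_lengths = if (!is.null(branch_mutations))
      vapply(branch_mutations, length, integer(1)) else NULL,
    support = support,
    n_sites = n_sites,
    method = method,
    tie = tie
  ), class = "lesion_tree")
}

#' Infer the per-patient lesion tree by exhaustive maximum parsimony
#'
#' Scores every resolved rooted topology over the three tumor samples
#' (root fixed at the matched normal's all-absent state) and returns the
#' unique minimum-score topology.  If two or more resolved topologies tie
#' for the minimum, the star topology is returned with the tie recorded.
#'
#' @param mat Binary presence matrix (rows = SNVs, columns = GBC/LG/HG).
#' @param method Label recorded on the tree (`"snv"`, `"loh"`, ...).
#' @return A `lesion_tree` object with per-topology scores, branch
#'   mutation assignments and branch lengths.
#' @export
infer_tree <- function(mat, method = "snv") {
  leaves <- colnames(mat)
  if (is.null(leaves) || length(leaves) != 3)
    stop("expected a matrix with the three tumor-sample columns")
  mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  if (nrow(mat) == 0) {
    warning("no informative rows; returning star topology")
    tree <- new_lesion_tree(star_topology(leaves), leaves,
                            n_sites = 0L, method = method)
    tree$branch_mutations <- assign_branch_mutations(tree, mat)
    tree$branch_lengths <- lengths(tree$branch_mutations)
    return(tree)
  }
  pc <- pattern_costs_3leaf(leaves)
  counts <- tabulate(row_pattern_index(mat, leaves), nbins = 8)
  scores <- setNames(as.integer(colSums(pc$costs * counts)),
                     colnames(pc$costs))
  resolved_scores <- scores[seq_len(3)]
  best <- which(resolved_scores == min(resolved_scores))
  if (length(best) == 1) {
    top <- pc$topologies[[best]]
    tie <- FALSE
  } else {
    top <- star_topology(leaves)
    tie <- TRUE
  }
  tree <- new_lesion_tree(top, leaves, scores = scores,
                          n_sites = nrow(mat), method = method, tie = tie)
  tree$branch_mutations <- assign_branch_mutations(tree, mat)
  tree$branch_lengths <- lengths(tree$branch_mutations)
  tree
}

#' Bootstrap support for the inferred sister pair
#'
#' Resamples matrix rows with replacement and records, per replicate, the
#' best resolved topology (score ties broken uniformly at random).
#' Support is the fraction of replicates recovering the original tree's
#' sister pair.
#'
#' @param mat Binary presence matrix.
#' @param B Number of bootstrap replicates.
#' @param seed RNG seed.
#' @return List with `support` (fraction matching the observed sister
#'   pair; `NA` when the observed tree is a star), and `pair_support`, the
#'   per-sister-pair replicate fractions.
#' @export
bootstrap_support <- function(mat, B = 1000, seed = 1) {
  if (B < 1) stop("B must be at least 1")
  leaves <- colnames(mat)
  tree <- infer_tree(mat)
  pc <- pattern_costs_3leaf(leaves)
  counts <- tabulate(row_pattern_index(mat, leaves), nbins = 8)
  n <- sum(counts)
  if (n == 0)
    return(list(support = NA_real_,
                pair_support = setNames(rep(NA_real_, 3), c("", "", ""))))
  pairs <- t(vapply(pc$topologies[1:3], sister_of, character(2)))
  pair_id <- apply(pairs, 1, paste, collapse = "+")

  set.seed(seed)
  wins <- setNames(numeric(3), pair_id)
  for (b in seq_len(B)) {
    cb <- as.vector(rmultinom(1, n, counts / n))
    sc <- colSums(pc$costs[, 1:3, drop = FALSE] * cb)
    best <- which(sc == min(sc))
    pick <- if (length(best) == 1) best else sample(best, 1)
    wins[pick] <- wins[pick] + 1
  }
  pair_support <- wins / B
  support <- if (tree$resolved)
    unname(pair_support[paste(tree$sister, collapse = "+")]) else NA_real_
  list(support = support, pair_support = pair_support)
}

#' Assign mutations to tree branches
#'
#' Each matrix row is assigned to the branch whose subtended leaf set
#' equals the row's presence pattern: the trunk (all three tumors), the
#' internal branch above the sister pair, or a terminal branch.  Rows
#' whose pattern matches no branch of the tree (the off-tree tumor pair on
#' a resolved tree; any pair on a star) are collected in the `homoplasy`
#' bucket and excluded from branch lengths.
#'
#' @param tree A `lesion_tree`.
#' @param mat Binary presence matrix.
#' @return Named list of mutation-id vectors: `trunk`, `internal` (absent
#'   for a star tree), one per leaf, and `homoplasy`.
#' @export
assign_branch_mutations <- function(tree, mat) {
  leaves <- tree$leaves
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  pat <- apply(mat[, leaves, drop = FALSE] == 1, 1, function(z)
    paste(sort(leaves[z]), collapse = "+"))
  branches <- c(list(trunk = sort(leaves)),
                if (tree$resolved) list(internal = tree$sister),
                setNames(as.list(leaves), leaves))
  keys <- vapply(branches, function(b) paste(sort(b), collapse = "+"),
                 character(1))
  out <- lapply(keys, function(k) ids[pat == k])
  names(out) <- names(branches)
  out$homoplasy <- ids[!pat %in% keys]
  out
}

#' Count trunk mutations
#'
#' The number of SNVs present in all three tumor samples of a patient,
#' i.e. acquired in their common ancestor.
#'
#' @param presence Presence map from [rescue_across_samples()].
#' @return Integer count.
#' @export
count_trunk_mutations <- function(presence) {
  roles <- tumor_roles()
  snv <- presence[presence$variant_type == "SNV", , drop = FALSE]
  sum(Reduce(`&`, lapply(roles, function(r) snv[[r]])))
}

#' Re-infer the tree from mutations outside LOH regions
#'
#' Drops every matrix row whose genomic position falls inside a region
#' under LOH in any of the three tumor samples, then re-runs
#' [infer_tree()] — a robustness check that allele loss is not driving
#' the topology.
#'
#' @param mat Binary presence matrix.
#' @param positions Data frame aligned with `rownames(mat)`: columns
#'   `variant_id`, `chrom`, `pos`.
#' @param loh_segments Data frame of LOH segments of the three tumors
#'   (columns `chrom`, `start`, `end`; 1-based inclusive).
#' @return A `lesion_tree` (star with a warning when no rows remain).
#' @export
infer_tree_nonloh <- function(mat, positions, loh_segments) {
  pos <- positions[match(rownames(mat), positions$variant_id), ]
  in_loh <- rep(FALSE, nrow(mat))
  if (!is.null(loh_segments) && nrow(loh_segments) > 0) {
    gr_mut <- GenomicRanges::GRanges(pos$chrom,
                                     IRanges::IRanges(pos$pos, pos$pos))
    gr_loh <- GenomicRanges::GRanges(
      loh_segments$chrom,
      IRanges::IRanges(loh_segments$start, loh_segments$end))
    in_loh <- IRanges::overlapsAny(gr_mut, gr_loh)
  }
  infer_tree(mat[!in_loh, , drop = FALSE], method = "snv_nonloh")
}

#' @export
print.lesion_tree <- function(x, ...) {
  cat("Lesion tree (", x$method, " layer)\n", sep = "")
  cat("  topology: ", x$label,
      if (x$tie) "  [tie between resolved topologies]", "\n", sep = "")
  if (!is.null(x$scores)) {
    cat("  parsimony scores: ",
        paste(names(x$scores), x$scores, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$branch_lengths)) {
    bl <- x$branch_lengths
    cat("  branch mutations: ",
        paste(names(bl), bl, sep = "=", collapse = ", "), "\n", sep = "")
  }
  if (!is.na(x$support)) cat("  bootstrap support:", x$support, "\n")
  invisible(x)
}

#' Newick string for a lesion tree
#'
#' Branch lengths are mutation counts; the internal node carries the
#' bootstrap support (when available) as its label; the matched normal is
#' included as the zero-length root leaf.
#'
#' @param tree A `lesion_tree` with branch assignments.
#' @return Newick character scalar.
#' @export
as_newick <- function(tree) {
  bl <- tree$branch_lengths %||%
    setNames(numeric(length(tree$leaves) + 2),
             c("trunk", "internal", tree$leaves))
  leaf_str <- function(l) paste0(l, ":", bl[[l]] %||% 0)
  if (tree$resolved) {
    inner <- paste0("(", paste(vapply(tree$sister, leaf_str, character(1)),
                               collapse = ","), ")",
                    if (!is.na(tree$support)) tree$support else "",
                    ":", bl[["internal"]] %||% 0)
    core <- paste0("(", inner, ",", leaf_str(tree$outgroup), ")")
  } else {
    core <- paste0("(", paste(vapply(tree$leaves, leaf_str, character(1)),
                              collapse = ","), ")")
  }
  paste0("(", core, ":", bl[["trunk"]] %||% 0, ",normal:0);")
}

#' @export
plot.lesion_tree <- function(x, ...) {
  phy <- ape::read.tree(text = as_newick(x))
  plot(phy, ...)
  invisible(phy)
}
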