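# Independent oracles used against the package implementations.

# exhaustive small-parsimony oracle: minimum 0/1 state changes on a
# rooted topology (root fixed at 0) by enumerating every assignment of
# states to internal nodes
n_internal_nodes <- function(node) {
  if (is.character(node)) return(0L)
  1L + sum(vapply(node, n_internal_nodes, integer(1)))
}

oracle_row_score <- function(top, row) {
  k <- n_internal_nodes(top)
  combos <- as.matrix(expand.grid(rep(list(0:1), k)))
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    st <- combos[i, ]
    ptr <- 0L
    changes <- 0L
    walk <- function(node, parent_state) {
      if (is.character(node)) {
        changes <<- changes + as.integer(row[[node]] != parent_state)
        return(invisible(NULL))
      }
      ptr <<- ptr + 1L
      s <- st[[ptr]]
      changes <<- changes + as.integer(s != parent_state)
      for (ch in node) walk(ch, s)
    }
    walk(top, 0L)
    best <- min(best, changes)
  }
  best
}

oracle_parsimony <- function(top, mat) {
  sum(vapply(seq_len(nrow(mat)), function(i)
    oracle_row_score(top, as.list(mat[i, ])), numeric(1)))
}

# per-base membership oracle for interval intersections on a toy genome
perbase_mask <- function(intervals, len) {
  v <- logical(len)
  for (i in seq_len(nrow(intervals)))
    v[intervals$start[i]:intervals$end[i]] <- TRUE
  v
}

# random non-overlapping 1-based inclusive intervals on [1, len]
random_intervals <- function(len, n_max = 6) {
  n <- sample.int(n_max, 1)
  bounds <- sort(sample.int(len, 2 * n))
  data.frame(start = bounds[seq(1, 2 * n, by = 2)],
             end = bounds[seq(2, 2 * n, by = 2)])
}

# wrap LOH intervals on toy chromosome "1" as a segment_profile whose
# covered region is the whole toy genome
toy_profile <- function(intervals, len, sample_id = "S") {
  loh <- data.frame(chrom = rep("1", nrow(intervals)),
                    start = intervals$start, end = intervals$end,
                    cn_total = rep(2L, nrow(intervals)))
  seg <- bilinevo:::tile_with_loh(loh,
                                  data.frame(chrom = "1", length = len))
  seg$sample_id <- sample_id
  segment_profile(seg)
}

# shorthand builder for mutation-call rows
make_call <- function(patient_id = "P1", sample_role = "GBC",
                      chrom = "1", pos = 1000, ref = "C", alt = "T",
                      gene = "GENE1", effect_class = "missense",
                      context = "ACA", t_depth = 100, t_alt = 30,
                      n_depth = 80, caller_support = 3,
                      in_target = TRUE, protein_change = NA,
                      variant_type = "SNV") {
  data.frame(patient_id = patient_id,
             sample_id = paste0(patient_id, "_", sample_role),
             sample_role = sample_role, chrom = chrom, pos = pos,
             ref = ref, alt = alt, gene = gene,
             effect_class = effect_class, context = context,
             t_depth = t_depth, t_alt = t_alt, n_depth = n_depth,
             caller_support = caller_support, in_target = in_target,
             protein_change = protein_change,
             variant_type = variant_type, stringsAsFactors = FALSE)
}

# presence map for the three tumor roles from a named pattern list
make_presence <- function(patterns) {
  ids <- names(patterns)
  out <- data.frame(variant_id = ids, chrom = "1",
                    pos = seq_along(ids) * 100, ref = "C", alt = "T",
                    gene = "G", variant_type = "SNV",
                    stringsAsFactors = FALSE)
  roles <- c("GBC", "LG", "HG")
  for (i in seq_along(roles))
    out[[roles[i]]] <- vapply(patterns, function(p)
      as.logical(p[i]), logical(1))
  out
}

presence_matrix <- function(patterns) {
  build_binary_matrix(make_presence(patterns))
}

# clone_set stub for JSI formula checks
make_clone_set <- function(ccf_tab, sizes) {
  clusters <- data.frame(cluster = seq_len(nrow(ccf_tab)), size = sizes)
  for (r in colnames(ccf_tab))
    clusters[[paste0("ccf_", r)]] <- ccf_tab[, r]
  assignments <- rep(seq_len(nrow(ccf_tab)), sizes)
  names(assignments) <- paste0("M", seq_along(assignments))
  structure(list(clusters = clusters, assignments = assignments,
                 n_clones = sum(sizes >= 10), min_clone_size = 10,
                 K = nrow(clusters)),
            class = "clone_set")
}

catalog_cached <- local({
  cat <- NULL
  function() {
    if (is.null(cat)) cat <<- load_signature_catalog()
    cat
  }
})
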