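# Cohort orchestration: runs the full per-patient analysis and the
# between-group comparisons.

#' Two-group comparison
#'
#' Two-sided Student's t-test (equal variance, as in classical
#' figure-caption usage) or Wilcoxon rank-sum test; raw p-values, no
#' multiple-testing correction.  The rank-sum test is exact for combined
#' n of at most 20 without ties, otherwise a normal approximation with
#' continuity correction.
#'
#' @param values_by_group Named list of two numeric vectors.
#' @param test `"student_t"` or `"wilcoxon"`.
#' @return List with `statistic`, `p_value`, `means` (per group), `test`.
#' @export
group_compare <- function(values_by_group,
                          test = c("student_t", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(length(values_by_group) == 2)
  x <- values_by_group[[1]]; y <- values_by_group[[2]]
  means <- vapply(values_by_group, mean, numeric(1))
  if (test == "student_t") {
    if (length(x) < 2 || length(y) < 2)
      stop("t-test needs at least two values per group")
    if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
      warning("zero within-group variance; t-test undefined")
      return(list(statistic = NA_real_, p_value = NA_real_,
                  means = means, test = test))
    }
    ht <- t.test(x, y, var.equal = TRUE)
  } else {
    n <- length(x) + length(y)
    exact <- n <= 20 && !anyDuplicated(c(x, y))
    ht <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                       correct = TRUE))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       means = means, test = test)
}

sample_profiles <- function(segments) {
  lapply(split(segments, segments$sample_role),
         function(s) segment_profile(s))
}

#' Analyse one patient bundle
#'
#' Runs the per-patient chain: filter, cross-sample rescue, binary
#' matrix, mutation tree (plus the non-LOH robustness tree), LOH-layer
#' tree and consensus path classification, trunk count, per-sample and
#' shared LOH fractions, per-sample signature exposures, clone
#' clustering and pairwise JSI seeding calls.
#'
#' @param bundle Patient bundle (fields `patient_id`, `calls`,
#'   `segments`, `purity`), as from [simulate_patient()] or
#'   [read_patient_bundle()].
#' @param catalog Signature catalog.
#' @param min_depth,min_callers Primary filter thresholds.
#' @param seed Seed for clustering and bootstrap.
#' @param do_clonality Set `FALSE` to skip the (relatively expensive)
#'   clone clustering and seeding steps.
#' @param bootstrap_B Bootstrap replicates for the mutation tree (0 to
#'   skip).
#' @return List of per-patient results (see [run_pipeline()]).
#' @export
analyse_patient <- function(bundle, catalog = load_signature_catalog(),
                            min_depth = 10, min_callers = 2, seed = 1,
                            do_clonality = TRUE, bootstrap_B = 0) {
  roles <- tumor_roles()
  pass <- filter_calls(bundle$calls, min_depth = min_depth,
                       min_callers = min_callers)
  presence <- rescue_across_samples(bundle$calls, pass)
  mat <- build_binary_matrix(presence)
  tree <- suppressWarnings(infer_tree(mat))
  if (bootstrap_B > 0 && nrow(mat) > 0)
    tree$support <- bootstrap_support(mat, B = bootstrap_B,
                                      seed = seed)$support

  profiles <- sample_profiles(bundle$segments)[roles]
  loh_frac <- vapply(profiles, loh_fraction, numeric(1))
  shared <- shared_loh(profiles$GBC, profiles$LG, profiles$HG)
  loh_tree <- build_loh_tree(loh_bin_matrix(profiles))
  labels <- c(mutation = classify_topology(tree),
              loh = classify_topology(loh_tree))
  consensus <- consensus_classification(labels)

  loh_union <- do.call(rbind, lapply(profiles, function(p) {
    s <- loh_segments_of(p)
    s[, c("chrom", "start", "end")]
  }))
  positions <- data.frame(
    variant_id = presence$variant_id, chrom = presence$chrom,
    pos = presence$pos)
  tree_nonloh <- suppressWarnings(
    infer_tree_nonloh(mat, positions, loh_union))

  snv_pass <- pass[pass$variant_type == "SNV", , drop = FALSE]
  exposures <- lapply(roles, function(r) {
    snvs <- snv_pass[snv_pass$sample_role == r, , drop = FALSE]
    if (nrow(snvs) == 0) return(NULL)
    decompose_signatures(count_spectrum(snvs), catalog)
  })
  names(exposures) <- roles

  clones <- NULL; seeding <- NULL
  if (do_clonality && nrow(presence) > 0) {
    recs <- clonality_records(bundle, presence)
    if (nrow(recs) > 0) {
      clones <- cluster_ccfs(recs, seed = seed)
      pairs <- list(c("GBC", "LG"), c("GBC", "HG"), c("LG", "HG"))
      seeding <- lapply(pairs, function(p) {
        jsi <- compute_jsi(clones, p)
        list(pair = paste(p, collapse = "-"), jsi = jsi,
             call = classify_seeding(jsi))
      })
    }
  }

  list(patient_id = bundle$patient_id,
       n_pass = nrow(pass), n_snv = nrow(mat),
       tree = tree, tree_nonloh = tree_nonloh, loh_tree = loh_tree,
       classification = consensus,
       trunk_count = count_trunk_mutations(presence),
       loh_fraction = loh_frac, shared_loh_fraction = shared$fraction,
       shared_loh_segments = shared$segments,
       exposures = exposures, clones = clones,
       n_clones = if (!is.null(clones)) clones$n_clones else NA_integer_,
       seeding = seeding)
}

# assemble per-mutation per-sample read/copy-number records for
# clustering: present-anywhere SNVs, local CN looked up in the sample's
# segments, purity from the bundle's purity table
clonality_records <- function(bundle, presence) {
  roles <- tumor_roles()
  snv <- presence[presence$variant_type == "SNV", , drop = FALSE]
  if (nrow(snv) == 0) return(data.frame())
  calls <- bundle$calls
  calls$.key <- variant_key(calls)
  purity <- setNames(bundle$purity$purity,
                     bundle$purity$sample_role)
  out <- list()
  for (r in roles) {
    seg <- bundle$segments[bundle$segments$sample_role == r, ,
                           drop = FALSE]
    cr <- calls[calls$sample_role == r &
                  calls$.key %in% snv$variant_id, , drop = FALSE]
    cr <- cr[match(snv$variant_id, cr$.key), , drop = FALSE]
    cn_t <- rep(2L, nrow(snv)); cn_m <- rep(1L, nrow(snv))
    if (nrow(seg) > 0) {
      gr_mut <- GenomicRanges::GRanges(
        snv$chrom, IRanges::IRanges(snv$pos, snv$pos))
      gr_seg <- segments_to_granges(seg)
      hit <- GenomicRanges::findOverlaps(gr_mut, gr_seg, select = "first")
      has <- !is.na(hit)
      cn_t[has] <- seg$cn_total[hit[has]]
      cn_m[has] <- seg$cn_minor[hit[has]]
    }
    out[[r]] <- data.frame(
      mutation_id = snv$variant_id, sample_role = r,
      alt = ifelse(is.na(cr$t_alt), 0L, cr$t_alt),
      depth = ifelse(is.na(cr$t_depth), 0L, cr$t_depth),
      purity = purity[[r]], cn_total = cn_t, cn_minor = cn_m,
      stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, out)
  recs[recs$depth > 0, , drop = FALSE]
}

#' Run the full pipeline over a cohort
#'
#' Applies [analyse_patient()] to every bundle (per-patient failures are
#' caught, reported and skipped) and computes the between-group
#' comparisons: trunk mutation counts (Wilcoxon rank-sum, as used for
#' that comparison in the source analyses), per-sample and shared LOH
#' fractions, and counted clone numbers (Student's t).
#'
#' @param bundles List of patient bundles, or of `list(bundle, truth)`
#'   pairs as produced by [simulate_cohort()].
#' @param catalog Signature catalog.
#' @param seed Seed forwarded to per-patient analyses.
#' @param do_clonality Whether to run clone clustering per patient.
#' @param ... Forwarded to [analyse_patient()].
#' @return A `cohort_report`: list with `patients` (per-patient summary
#'   data frame), `group_stats` (comparison table), `details`
#'   (full per-patient results) and `failures`.
#' @export
run_pipeline <- function(bundles, catalog = load_signature_catalog(),
                         seed = 1, do_clonality = TRUE, ...) {
  bundles <- lapply(bundles, function(b)
    if (!is.null(b$bundle)) b$bundle else b)
  details <- list(); failures <- list()
  for (b in bundles) {
    res <- tryCatch(
      analyse_patient(b, catalog = catalog, seed = seed,
                      do_clonality = do_clonality, ...),
      error = function(e)
        structure(list(patient_id = b$patient_id,
                       message = conditionMessage(e)),
                  class = "patient_failure"))
    if (inherits(res, "patient_failure")) failures[[b$patient_id]] <- res
    else details[[res$patient_id]] <- res
  }

  patients <- do.call(rbind, lapply(details, function(d) {
    data.frame(
      patient_id = d$patient_id,
      label = d$classification$label,
      group = d$classification$group,
      trunk_count = d$trunk_count,
      loh_gbc = unname(d$loh_fraction[["GBC"]]),
      loh_lg = unname(d$loh_fraction[["LG"]]),
      loh_hg = unname(d$loh_fraction[["HG"]]),
      shared_loh = d$shared_loh_fraction,
      n_clones = d$n_clones,
      n_snv = d$n_snv, stringsAsFactors = FALSE)
  }))
  rownames(patients) <- NULL

  group_stats <- NULL
  if (!is.null(patients) &&
      all(c("independent", "dependent") %in% patients$group)) {
    ind <- patients[patients$group == "independent", ]
    dep <- patients[patients$group == "dependent", ]
    cmp <- function(col, test) {
      g <- list(independent = ind[[col]], dependent = dep[[col]])
      g <- lapply(g, function(v) v[!is.na(v)])
      res <- tryCatch(group_compare(g, test),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(quantity = col, test = test,
                 mean_independent = res$means[["independent"]],
                 mean_dependent = res$means[["dependent"]],
                 statistic = res$statistic %||% NA_real_,
                 p_value = res$p_value %||% NA_real_)
    }
    group_stats <- rbind(
      cmp("trunk_count", "wilcoxon"),
      cmp("loh_gbc", "student_t"),
      cmp("loh_lg", "student_t"),
      cmp("loh_hg", "student_t"),
      cmp("shared_loh", "student_t"),
      if (do_clonality) cmp("n_clones", "student_t"))
    rownames(group_stats) <- NULL
  }

  structure(list(patients = patients, group_stats = group_stats,
                 details = details, failures = failures),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  n <- if (is.null(x$patients)) 0 else nrow(x$patients)
  cat("Cohort report:", n, "patient(s)")
  if (length(x$failures) > 0)
    cat(",", length(x$failures), "failed")
  cat("\n")
  if (n > 0) {
    cat("\nPer-patient summary:\n")
    print(x$patients, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$group_stats)) {
    cat("\nGroup comparisons (independent vs dependent):\n")
    print(x$group_stats, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
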