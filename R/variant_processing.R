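# Somatic-call filtering, the cross-sample rescue rule, TMB, the binary
# presence matrix, and driver tabulation.

variant_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Read a MAF-like mutation table
#'
#' Expected tab-separated columns: `patient_id`, `sample_id`,
#' `sample_role` (normal/GBC/LG/HG), `chrom`, `pos` (1-based), `ref`,
#' `alt`, `gene`, `effect_class`, `context` (SNV trinucleotide, `NA` for
#' indels), `t_depth`, `t_alt`, `n_depth`, `caller_support`, `in_target`,
#' and optionally `protein_change` and `variant_type` (`SNV`/`indel`;
#' inferred from allele lengths when absent).
#'
#' @param path Path to the TSV.
#' @return Data frame of mutation calls.
#' @export
read_maf <- function(path) {
  calls <- read.delim(path, colClasses = NA, stringsAsFactors = FALSE)
  calls$chrom <- as.character(calls$chrom)
  if (is.null(calls$variant_type))
    calls$variant_type <- ifelse(nchar(calls$ref) == 1 & nchar(calls$alt) == 1,
                                 "SNV", "indel")
  calls$in_target <- as.logical(calls$in_target)
  calls
}

#' Filter somatic calls by depth, caller support and target status
#'
#' Keeps calls with tumor and normal site depth at least `min_depth`,
#' caller support of at least `min_callers`, and located inside the
#' targeted regions.  Records with negative depths are dropped with a
#' warning.
#'
#' @param calls Data frame of mutation calls for one patient (see
#'   [read_maf()] for the schema).
#' @param min_depth Minimum site depth required in both the tumor and the
#'   matched normal.
#' @param min_callers Minimum number of supporting callers.
#' @return The PASS subset of `calls`.
#' @export
filter_calls <- function(calls, min_depth = 10, min_callers = 2) {
  if (nrow(calls) == 0) return(calls)
  bad <- calls$t_depth < 0 | calls$n_depth < 0
  if (any(bad)) {
    warning(sum(bad), " call(s) with negative depth dropped")
    calls <- calls[!bad, , drop = FALSE]
  }
  keep <- calls$t_depth >= min_depth &
    calls$n_depth >= min_depth &
    calls$caller_support >= min_callers &
    calls$in_target
  calls[keep, , drop = FALSE]
}

#' Rescue mutations across samples of the same patient
#'
#' A variant that passes the primary filter in at least one tumor sample
#' of a patient is rescued in the patient's remaining tumor samples when
#' even a single caller supports it there (and the site is adequately
#' covered).  Returns the per-variant presence pattern over the three
#' tumor roles.
#'
#' @param calls All calls of one patient (one row per variant per sample
#'   in which any evidence was recorded).
#' @param pass_set Output of [filter_calls()] on `calls`.
#' @param min_support_rescue Minimum caller support for a rescue (default 1).
#' @param min_depth_rescue Minimum tumor depth required at the rescued
#'   site (default 10, symmetric with the primary filter).
#' @param rescue_min_alt Minimum number of alternate reads required for a
#'   rescue (default 0).
#' @return Data frame with one row per PASS variant: `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `variant_type`, and logical
#'   presence columns `GBC`, `LG`, `HG`.
#' @export
rescue_across_samples <- function(calls, pass_set,
                                  min_support_rescue = 1,
                                  min_depth_rescue = 10,
                                  rescue_min_alt = 0) {
  roles <- tumor_roles()
  if (any(pass_set$sample_role == "normal"))
    stop("variant passed filters in the normal sample: ",
         "possible germline contamination")
  empty <- data.frame(variant_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), gene = character(0),
                      variant_type = character(0))
  for (r in roles) empty[[r]] <- logical(0)
  if (nrow(pass_set) == 0) return(empty)

  calls$.key <- variant_key(calls)
  pass_set$.key <- variant_key(pass_set)
  pass_keys <- unique(pass_set$.key)

  # presence = PASS in that sample, or rescued there
  tumor <- calls[calls$sample_role %in% roles & calls$.key %in% pass_keys, ,
                 drop = FALSE]
  pass_id <- paste(pass_set$.key, pass_set$sample_role)
  is_pass <- paste(tumor$.key, tumor$sample_role) %in% pass_id
  rescued <- tumor$caller_support >= min_support_rescue &
    tumor$t_depth >= min_depth_rescue &
    tumor$t_alt >= rescue_min_alt
  present <- is_pass | rescued

  out <- tumor[!duplicated(tumor$.key),
               c("chrom", "pos", "ref", "alt", "gene", "variant_type")]
  out <- data.frame(variant_id = tumor$.key[!duplicated(tumor$.key)], out)
  for (r in roles) {
    idx <- tumor$sample_role == r & present
    out[[r]] <- out$variant_id %in% tumor$.key[idx]
  }
  rownames(out) <- NULL
  out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
}

#' Tumor mutation burden
#'
#' Counts missense, nonsense and ORF-shifting indel mutations and divides
#' by the targeted territory in megabases.
#'
#' @param pass_set Filtered calls of one sample.
#' @param target_size_mb Size of the targeted regions in Mb.
#' @return Mutations per megabase.
#' @export
compute_tmb <- function(pass_set, target_size_mb) {
  if (!is.numeric(target_size_mb) || target_size_mb <= 0)
    stop("target_size_mb must be positive")
  qualifying <- c("missense", "nonsense", "orf_shift_indel")
  sum(pass_set$effect_class %in% qualifying) / target_size_mb
}

#' Build the binary SNV presence matrix
#'
#' One row per distinct SNV after rescue, one column per tumor role;
#' entries are 1 when the variant is present in that sample.  The matched
#' normal is the implicit all-zero root state and is not a column.
#'
#' @param presence Presence map from [rescue_across_samples()].
#' @return Integer matrix with variant ids as rownames.
#' @export
build_binary_matrix <- function(presence) {
  roles <- tumor_roles()
  snv <- presence[presence$variant_type == "SNV", , drop = FALSE]
  mat <- matrix(0L, nrow = nrow(snv), ncol = length(roles),
                dimnames = list(snv$variant_id, roles))
  for (r in roles) mat[, r] <- as.integer(snv[[r]])
  mat[rowSums(mat) > 0, , drop = FALSE]
}

#' Tabulate driver-gene mutations
#'
#' Restricts a per-sample mutation table to listed driver genes and to
#' protein-affecting effect classes (missense, nonsense, splice site,
#' nonstop).
#'
#' @param mutations Data frame with columns `patient_id`, `gene`,
#'   `sample_role`, `protein_change`, `effect_class`.
#' @param driver_list Character vector of driver gene symbols.
#' @return The qualifying subset (the driver table).
#' @export
annotate_drivers <- function(mutations, driver_list = load_driver_genes()) {
  if (length(driver_list) == 0)
    return(mutations[0, , drop = FALSE])
  qualifying <- c("missense", "nonsense", "splice_site", "nonstop")
  keep <- mutations$gene %in% driver_list &
    mutations$effect_class %in% qualifying
  out <- mutations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count patients carrying a driver mutation in a gene
#'
#' @param driver_table Output of [annotate_drivers()].
#' @param gene Gene symbol.
#' @return Number of distinct patients with at least one qualifying
#'   mutation in `gene`.
#' @export
count_patients_with_driver <- function(driver_table, gene) {
  length(unique(driver_table$patient_id[driver_table$gene == gene]))
}
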