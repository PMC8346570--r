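# Seeded generator of synthetic patient bundles (somatic calls,
# allele-specific segments, purities) with ground truth, emulating the
# generative structure the analysis assumes: a rooted three-tumor clone
# tree per patient, trunk/internal/private mutation branches, signature-
# mixture trinucleotide contexts, lineage-inherited LOH segments, and
# binomial read support at realistic exome depths.

#' Configuration for one simulated patient
#'
#' Defaults are anchored to the study scale of the gallbladder cohort the
#' package models: mean sequencing depths of 107x (normal), 171x (GBC),
#' 188x (LG-BilIN) and 206x (HG-BilIN); per-sample SNV burdens around 214;
#' trunk burdens of 150 (BilIN-independent) versus 36 (BilIN-dependent);
#' ancestral LOH genome fractions of 13% versus 2% with additional
#' private LOH per lineage; and an aging-dominated signature mixture
#' (Signature 1 above 75%).
#'
#' @param mode `"independent"` (GBC splits first; sister pair LG+HG),
#'   `"dependent_LG"` (GBC sister to LG-BilIN) or `"dependent_HG"`.
#' @param n_trunk Expected (Poisson) trunk SNV count.
#' @param n_branch_pair Expected SNV count on the internal branch above
#'   the sister pair.
#' @param n_private Expected private SNV count per tumor.
#' @param loh_trunk_frac Genome fraction under trunk (ancestral) LOH.
#' @param loh_private_frac Additional private LOH fraction per tumor
#'   lineage.
#' @param loh_frac_cv Patient-level coefficient of variation applied to
#'   the LOH fraction targets (unit-mean gamma jitter).
#' @param purity_range Uniform sampling interval for tumor purities.
#' @param depth_mean Named expected depths per sample role.
#' @param signature_weights Non-negative 30-vector summing to 1.
#' @param rescue_miss_prob Probability that a truly present mutation gets
#'   caller support 1 in a sample (detectable only through rescue).
#' @param fn_prob Probability of caller support 0 despite presence.
#' @param seed Integer seed for the patient's RNG stream.
#' @return A `sim_patient_config` list.
#' @export
sim_patient_config <- function(mode = c("independent", "dependent_LG",
                                        "dependent_HG"),
                               n_trunk = NULL,
                               n_branch_pair = NULL,
                               n_private = NULL,
                               loh_trunk_frac = NULL,
                               loh_private_frac = NULL,
                               loh_frac_cv = 0.15,
                               purity_range = c(0.4, 0.8),
                               depth_mean = c(normal = 107, GBC = 171,
                                              LG = 188, HG = 206),
                               signature_weights = NULL,
                               rescue_miss_prob = 0.05,
                               fn_prob = 0.01,
                               seed = 1L) {
  mode <- match.arg(mode)
  indep <- mode == "independent"
  n_trunk <- n_trunk %||% if (indep) 150 else 36
  n_branch_pair <- n_branch_pair %||% if (indep) 25 else 100
  n_private <- n_private %||% if (indep) 40 else 70
  loh_trunk_frac <- loh_trunk_frac %||% if (indep) 0.13 else 0.02
  loh_private_frac <- loh_private_frac %||% if (indep) 0.07 else 0.03
  if (is.null(signature_weights)) {
    signature_weights <- setNames(numeric(30), paste0("Sig", 1:30))
    signature_weights[c("Sig1", "Sig2", "Sig5")] <- c(0.78, 0.10, 0.12)
  }
  cfg <- list(mode = mode, n_trunk = n_trunk,
              n_branch_pair = n_branch_pair, n_private = n_private,
              loh_trunk_frac = loh_trunk_frac,
              loh_private_frac = loh_private_frac,
              loh_frac_cv = loh_frac_cv,
              purity_range = purity_range, depth_mean = depth_mean,
              signature_weights = signature_weights,
              rescue_miss_prob = rescue_miss_prob, fn_prob = fn_prob,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_patient_config")
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$n_trunk, cfg$n_branch_pair, cfg$n_private,
             cfg$loh_trunk_frac, cfg$loh_private_frac,
             cfg$rescue_miss_prob, cfg$fn_prob)
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (any(cfg$depth_mean <= 0)) stop("depths must be positive")
  if (cfg$purity_range[1] <= 0 || cfg$purity_range[2] > 1 ||
      cfg$purity_range[1] > cfg$purity_range[2])
    stop("purity_range must be an interval within (0, 1]")
  w <- cfg$signature_weights
  if (length(w) != 30) stop("signature_weights must have length 30")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("signature_weights must be non-negative and sum to 1")
  if (cfg$loh_trunk_frac + cfg$loh_private_frac > 1)
    stop("LOH fractions sum to more than 1 per lineage")
  if (cfg$rescue_miss_prob + cfg$fn_prob > 1)
    stop("rescue_miss_prob + fn_prob must not exceed 1")
  invisible(cfg)
}

mode_sister <- function(mode) {
  switch(mode,
         independent = c("LG", "HG"),
         dependent_LG = c("GBC", "LG"),
         dependent_HG = c("GBC", "HG"))
}

# draw non-overlapping segments totalling `target_len` bp, avoiding
# `existing` (data.frame chrom/start/end); trims the last segment so the
# placed total hits the target exactly
place_loh_segments <- function(target_len, existing, genome,
                               size_range = c(5e6, 3e7)) {
  placed <- existing[0, c("chrom", "start", "end")]
  remaining <- target_len
  tries <- 0
  while (remaining > 0 && tries < 2000) {
    tries <- tries + 1
    size <- min(round(runif(1, size_range[1], size_range[2])), remaining)
    ci <- sample.int(nrow(genome), 1, prob = genome$length)
    chrom <- genome$chrom[ci]
    if (genome$length[ci] < size) next
    start <- floor(runif(1, 1, genome$length[ci] - size + 1))
    end <- start + size - 1
    blockers <- rbind(existing[existing$chrom == chrom,
                               c("chrom", "start", "end")],
                      placed[placed$chrom == chrom, , drop = FALSE])
    if (nrow(blockers) > 0 &&
        any(blockers$start <= end & blockers$end >= start)) next
    placed <- rbind(placed, data.frame(chrom = chrom, start = start,
                                       end = end))
    remaining <- remaining - size
  }
  placed
}

#' Simulate one patient bundle with ground truth
#'
#' Draws per-branch Poisson mutation counts on the clone tree implied by
#' the configured mode, assigns trinucleotide contexts from the signature
#' mixture, places lineage-inherited LOH segments on the GRCh37
#' autosomes, and emits per-sample read counts: alternate reads are
#' binomial at the expected VAF implied by purity, local copy number and
#' multiplicity (mutations at LOH sites are modelled on the retained
#' allele, so their multiplicity equals the local total copy number).
#' Caller support is 2–5 for cleanly detected mutations, 1 with
#' probability `rescue_miss_prob`, 0 with probability `fn_prob`; the
#' matched normal carries no somatic mutations.
#'
#' @param config A [sim_patient_config()].
#' @param patient_id Patient identifier written into the tables.
#' @param catalog Signature catalog (for context sampling).
#' @return List with `bundle` (fields `patient_id`, `calls`, `segments`,
#'   `purity`) and `truth` (mode, topology, per-branch mutation and LOH
#'   assignments, purities, per-mutation clone membership, indel count).
#' @export
simulate_patient <- function(config, patient_id = "SIM01",
                             catalog = load_signature_catalog()) {
  validate_sim_config(config)
  set.seed(config$seed)
  genome <- autosome_lengths()
  roles <- tumor_roles()
  sister <- mode_sister(config$mode)
  outgroup <- setdiff(roles, sister)
  topology <- list(list(sister[1], sister[2]), outgroup)

  branch_leaves <- c(list(trunk = roles, internal = sister),
                     setNames(lapply(roles, identity), roles))

  # ---- LOH events: trunk + per-tumor private, non-overlapping in lineage
  jitter <- function() {
    if (config$loh_frac_cv <= 0) return(1)
    shape <- 1 / config$loh_frac_cv^2
    rgamma(1, shape = shape, rate = shape)
  }
  genome_len <- sum(genome$length)
  none <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0))
  trunk_target <- config$loh_trunk_frac * jitter() * genome_len
  loh_events <- list(trunk = place_loh_segments(round(trunk_target),
                                                none, genome))
  for (r in roles) {
    tgt <- config$loh_private_frac * jitter() * genome_len
    loh_events[[r]] <- place_loh_segments(round(tgt), loh_events$trunk,
                                          genome)
  }
  # copy-number state per LOH event: deletion (1+0) or copy-neutral (2+0)
  for (b in names(loh_events)) {
    ev <- loh_events[[b]]
    ev$cn_total <- if (nrow(ev) > 0)
      sample(c(1L, 2L), nrow(ev), replace = TRUE) else integer(0)
    loh_events[[b]] <- ev
  }

  sample_loh <- function(role) {
    ev <- rbind(loh_events$trunk, loh_events[[role]])
    ev[order(ev$chrom, ev$start), , drop = FALSE]
  }

  # ---- mutations per branch
  counts <- c(trunk = rpois(1, config$n_trunk),
              internal = rpois(1, config$n_branch_pair),
              setNames(rpois(length(roles), config$n_private), roles))
  n_mut <- sum(counts)
  branch_of <- rep(names(counts), counts)

  purity <- setNames(runif(length(roles), config$purity_range[1],
                           config$purity_range[2]), roles)

  calls <- empty_calls()
  ids <- character(0)
  muts <- data.frame(mutation_id = character(0), branch = character(0),
                     chrom = character(0), pos = numeric(0))
  if (n_mut > 0) {
    spec <- sample_contexts(config$signature_weights, catalog, n_mut)
    channels <- rep(names(spec), spec)[sample.int(n_mut)]
    ref <- sub("^.\\[(.)>.\\].$", "\\1", channels)
    alt <- sub("^.\\[.>(.)\\].$", "\\1", channels)
    context <- paste0(substr(channels, 1, 1), ref,
                      substr(channels, nchar(channels), nchar(channels)))
    # half the calls are reported on the purine strand
    flip <- runif(n_mut) < 0.5
    ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    context[flip] <- revcomp(context[flip])

    ci <- sample.int(nrow(genome), n_mut, replace = TRUE,
                     prob = genome$length)
    chrom <- genome$chrom[ci]
    pos <- floor(runif(n_mut, 1, genome$length[ci] + 1))
    while (anyDuplicated(paste(chrom, pos))) {  # loci must be unique
      dup <- duplicated(paste(chrom, pos))
      pos[dup] <- floor(runif(sum(dup), 1, genome$length[ci[dup]] + 1))
    }
    # mutation ids are the variant keys the pipeline uses downstream
    ids <- paste(chrom, pos, ref, alt, sep = ":")
    gene <- sprintf("GENE%04d", sample.int(5000, n_mut, replace = TRUE))
    effect <- sample(c("missense", "silent", "nonsense", "splice_site",
                       "other"), n_mut, replace = TRUE,
                     prob = c(0.55, 0.25, 0.05, 0.03, 0.12))
    n_depth <- rpois(n_mut, config$depth_mean[["normal"]])

    muts <- data.frame(mutation_id = ids, branch = branch_of,
                       chrom = chrom, pos = pos)

    rows <- vector("list", length(roles))
    for (r in roles) {
      present <- vapply(branch_of, function(b) r %in% branch_leaves[[b]],
                        logical(1))
      loh <- sample_loh(r)
      hit <- rep(0L, n_mut)  # 0 = no LOH; else event cn_total
      if (nrow(loh) > 0) {
        for (i in seq_len(nrow(loh)))
          hit[chrom == loh$chrom[i] & pos >= loh$start[i] &
                pos <= loh$end[i]] <- loh$cn_total[i]
      }
      cn_total <- ifelse(hit > 0, hit, 2L)
      mult <- ifelse(hit > 0, hit, 1L)
      rho <- purity[[r]]
      evaf <- ifelse(present,
                     rho * mult / (rho * cn_total + 2 * (1 - rho)), 0)
      depth <- rpois(n_mut, config$depth_mean[[r]])
      alt_count <- rbinom(n_mut, depth, evaf)
      u <- runif(n_mut)
      support <- ifelse(!present, 0L,
                        ifelse(u < config$fn_prob, 0L,
                               ifelse(u < config$fn_prob +
                                        config$rescue_miss_prob, 1L,
                                      sample(2:5, n_mut, replace = TRUE))))
      rows[[r]] <- data.frame(
        patient_id = patient_id,
        sample_id = paste0(patient_id, "_", r),
        sample_role = r, chrom = chrom, pos = pos, ref = ref, alt = alt,
        gene = gene, effect_class = effect, context = context,
        t_depth = depth, t_alt = alt_count, n_depth = n_depth,
        caller_support = as.integer(support), in_target = TRUE,
        protein_change = NA_character_, variant_type = "SNV",
        stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, rows)
    rownames(calls) <- NULL
  }

  # ---- per-sample segment profiles tiling the autosomes
  segments <- do.call(rbind, lapply(roles, function(r) {
    loh <- sample_loh(r)
    seg <- tile_with_loh(loh, genome)
    data.frame(sample_id = paste0(patient_id, "_", r),
               sample_role = r, seg, stringsAsFactors = FALSE)
  }))
  rownames(segments) <- NULL

  purity_tab <- data.frame(
    sample_id = paste0(patient_id, "_", c("normal", roles)),
    sample_role = c("normal", roles),
    purity = c(NA_real_, unname(purity)),
    ploidy = 2, stringsAsFactors = FALSE)

  branch_sets <- lapply(names(counts), function(b) ids[branch_of == b])
  names(branch_sets) <- names(counts)

  bundle <- list(patient_id = patient_id, calls = calls,
                 segments = segments, purity = purity_tab)
  truth <- list(mode = config$mode,
                topology = topology_label(topology),
                sister = sister,
                branch_mutations = branch_sets,
                branch_loh = loh_events,
                purity = purity,
                mutations = muts,
                n_indels = rpois(1, 9))
  list(bundle = bundle, truth = truth)
}

empty_calls <- function() {
  data.frame(patient_id = character(0), sample_id = character(0),
             sample_role = character(0), chrom = character(0),
             pos = numeric(0), ref = character(0), alt = character(0),
             gene = character(0), effect_class = character(0),
             context = character(0), t_depth = integer(0),
             t_alt = integer(0), n_depth = integer(0),
             caller_support = integer(0), in_target = logical(0),
             protein_change = character(0), variant_type = character(0),
             stringsAsFactors = FALSE)
}

# complement of the LOH events on each chromosome becomes diploid
# heterozygous segments, so profiles tile the full autosomes
tile_with_loh <- function(loh, genome) {
  out <- list()
  for (i in seq_len(nrow(genome))) {
    chrom <- genome$chrom[i]; len <- genome$length[i]
    ev <- loh[loh$chrom == chrom, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    cur <- 1
    for (j in seq_len(nrow(ev))) {
      if (ev$start[j] > cur)
        out <- c(out, list(data.frame(chrom = chrom, start = cur,
                                      end = ev$start[j] - 1,
                                      cn_total = 2L, cn_minor = 1L)))
      out <- c(out, list(data.frame(chrom = chrom, start = ev$start[j],
                                    end = ev$end[j],
                                    cn_total = ev$cn_total[j],
                                    cn_minor = 0L)))
      cur <- ev$end[j] + 1
    }
    if (cur <= len)
      out <- c(out, list(data.frame(chrom = chrom, start = cur, end = len,
                                    cn_total = 2L, cn_minor = 1L)))
  }
  do.call(rbind, out)
}

#' Sample trinucleotide-context counts from a signature mixture
#'
#' Multinomial draw of `n` contexts from the mixture spectrum
#' `catalog %*% weights`.
#'
#' @param signature_weights Non-negative 30-vector summing to 1.
#' @param catalog Signature catalog.
#' @param n Number of contexts to draw.
#' @param seed Optional seed.
#' @return Named count vector over the 96 channels, summing to `n`.
#' @export
sample_contexts <- function(signature_weights, catalog, n, seed = NULL) {
  if (length(signature_weights) != ncol(catalog))
    stop("signature weight vector length must match the catalog (",
         ncol(catalog), ")")
  if (n < 0) stop("n must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  mix <- as.vector(catalog %*% signature_weights)
  counts <- if (n == 0) integer(nrow(catalog))
  else as.vector(rmultinom(1, n, mix))
  setNames(counts, rownames(catalog))
}

#' Simulate a cohort of patients
#'
#' Generates `n_independent` BilIN-independent patients followed by
#' `n_dependent` BilIN-dependent ones, alternating between the
#' GBC+LG and GBC+HG sister-pair submodes.  Each patient gets its own
#' RNG stream keyed by the cohort seed and patient index.
#'
#' @param n_independent,n_dependent Patient counts per group.
#' @param base_config Optional named list of [sim_patient_config()]
#'   overrides applied to every patient; fields left unset take the
#'   per-mode defaults.
#' @param seed Cohort seed.
#' @param catalog Signature catalog.
#' @return List of `list(bundle, truth)` pairs, one per patient.
#' @export
simulate_cohort <- function(n_independent, n_dependent,
                            base_config = NULL, seed = 1,
                            catalog = load_signature_catalog()) {
  if (n_independent < 0 || n_dependent < 0)
    stop("patient counts must be non-negative")
  n <- n_independent + n_dependent
  if (n == 0) return(list())
  modes <- c(rep("independent", n_independent),
             rep(c("dependent_LG", "dependent_HG"),
                 length.out = n_dependent))
  set.seed(seed)
  pseeds <- sample.int(.Machine$integer.max - 1, n)
  lapply(seq_len(n), function(i) {
    args <- list(mode = modes[i], seed = pseeds[i])
    if (!is.null(base_config)) {
      keep <- setdiff(names(base_config), c("mode", "seed"))
      args <- c(args, base_config[keep])
    }
    cfg <- do.call(sim_patient_config, args)
    simulate_patient(cfg, patient_id = sprintf("SIM%02d", i),
                     catalog = catalog)
  })
}

#' Write a patient bundle to disk
#'
#' Emits the MAF-like mutation TSV, SEG-like segment TSV, purity TSV and
#' truth JSON of one simulated patient, in the same formats the pipeline
#' reads.
#'
#' @param sim A `list(bundle, truth)` pair from [simulate_patient()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_patient_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- sim$bundle$patient_id
  paths <- c(
    mutations = file.path(dir, paste0(id, "_mutations.tsv")),
    segments = file.path(dir, paste0(id, "_segments.tsv")),
    purity = file.path(dir, paste0(id, "_purity.tsv")),
    truth = file.path(dir, paste0(id, "_truth.json")))
  write.table(sim$bundle$calls, paths["mutations"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$bundle$segments, paths["segments"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$bundle$purity, paths["purity"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a patient bundle written by [write_patient_bundle()]
#'
#' @param dir Directory containing the bundle files.
#' @param patient_id Patient identifier (file prefix).
#' @return A `list(bundle, truth)` pair (truth `NULL` when the JSON is
#'   absent).
#' @export
read_patient_bundle <- function(dir, patient_id) {
  calls <- read_maf(file.path(dir, paste0(patient_id, "_mutations.tsv")))
  segments <- read.delim(file.path(dir, paste0(patient_id,
                                               "_segments.tsv")),
                         stringsAsFactors = FALSE)
  segments$chrom <- as.character(segments$chrom)
  purity <- read.delim(file.path(dir, paste0(patient_id, "_purity.tsv")),
                       stringsAsFactors = FALSE)
  truth_path <- file.path(dir, paste0(patient_id, "_truth.json"))
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  list(bundle = list(patient_id = patient_id, calls = calls,
                     segments = segments, purity = purity),
       truth = truth)
}
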