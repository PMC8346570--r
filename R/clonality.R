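# Cancer cell fractions, clone clustering across the three tumor
# samples, and Jaccard-similarity seeding classification.
#
# CCF model: a mutation with multiplicity m in a sample of purity rho and
# local total copy number c_t has expected VAF
#   E[VAF] = CCF * rho * m / (rho * c_t + 2 * (1 - rho)),
# so CCF = VAF / (rho * m) * (rho * c_t + 2 * (1 - rho)), capped at 1.
# Clone clustering fits a finite mixture with binomial read-count
# emissions around cluster-implied VAFs, selecting the number of clusters
# by BIC; clones are only *counted* when they contain at least 10
# mutations.

#' Cancer cell fraction of a mutation
#'
#' Estimates the multiplicity as
#' `m = round(vaf * (rho * cn_total + 2 * (1 - rho)) / rho)` clamped to
#' `[1, max(1, cn_total - cn_minor)]`, then converts VAF to CCF (capped
#' at 1, with the cap recorded).
#'
#' @param vaf Variant allele fraction(s) in \[0, 1\].
#' @param purity Sample purity in (0, 1\].
#' @param cn_total,cn_minor Local total and minor copy numbers.
#' @return Data frame with `ccf`, `multiplicity`, `capped`, and `defined`
#'   (`FALSE` where `cn_total` is 0, where the CCF is undefined).
#' @export
compute_ccf <- function(vaf, purity, cn_total, cn_minor) {
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  n <- max(length(vaf), length(purity), length(cn_total), length(cn_minor))
  vaf <- rep_len(vaf, n); purity <- rep_len(purity, n)
  cn_total <- rep_len(cn_total, n); cn_minor <- rep_len(cn_minor, n)
  defined <- cn_total >= 1
  denom <- purity * cn_total + 2 * (1 - purity)
  m_raw <- round(vaf * denom / purity)
  m <- pmin(pmax(m_raw, 1), pmax(1, cn_total - cn_minor))
  ccf_raw <- vaf / (purity * m) * denom
  ccf <- pmin(1, ccf_raw)
  ccf[!defined] <- NA_real_
  m[!defined] <- NA_integer_
  data.frame(ccf = ccf, multiplicity = as.integer(m),
             capped = defined & ccf_raw > 1, defined = defined)
}

# expected VAF per unit CCF for each mutation x sample
ccf_coefficient <- function(purity, cn_total, multiplicity) {
  purity * multiplicity / (purity * cn_total + 2 * (1 - purity))
}

binom_loglik <- function(alt, depth, p) {
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  alt * log(p) + (depth - alt) * log(1 - p)
}

# one EM fit at fixed K from an initial hard assignment
fit_mixture <- function(alt, depth, coef, K, init_cluster,
                        max_iter = 100, tol = 1e-5) {
  n <- nrow(alt); S <- ncol(alt)
  phi <- matrix(0.5, K, S)
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), init_cluster)] <- 1
  pi_k <- rep(1 / K, K)
  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    # M-step: per cluster/sample 1-D weighted binomial MLE on phi
    for (k in seq_len(K)) {
      w <- resp[, k]
      if (sum(w) < 1e-12) { pi_k[k] <- 1e-12; next }
      for (s in seq_len(S)) {
        obj <- function(ph)
          -sum(w * binom_loglik(alt[, s], depth[, s], coef[, s] * ph))
        phi[k, s] <- optimize(obj, c(0, 1), tol = 1e-4)$minimum
      }
    }
    pi_k <- colSums(resp) / n
    pi_k <- pmax(pi_k, 1e-12)
    # E-step
    ll_k <- sapply(seq_len(K), function(k) {
      p <- coef * matrix(phi[k, ], n, S, byrow = TRUE)
      rowSums(binom_loglik(alt, depth, p))
    })
    if (n == 1) ll_k <- matrix(ll_k, nrow = 1)
    ll_k <- sweep(ll_k, 2, log(pi_k), `+`)
    mx <- apply(ll_k, 1, max)
    lse <- mx + log(rowSums(exp(ll_k - mx)))
    resp <- exp(ll_k - lse)
    new_loglik <- sum(lse)
    if (is.finite(loglik) && abs(new_loglik - loglik) < tol * abs(loglik))
      { loglik <- new_loglik; break }
    loglik <- new_loglik
  }
  assignment <- max.col(resp, ties.method = "first")
  list(phi = phi, pi = pi_k, resp = resp, assignment = assignment,
       loglik = loglik, K = K)
}

#' Cluster mutations into clones across the three tumors
#'
#' Fits finite binomial-mixture models to per-mutation alternate read
#' counts in the three tumor samples: cluster `k` has a per-sample CCF
#' vector, each mutation's expected VAF in a sample is the cluster CCF
#' scaled by purity, local copy number and multiplicity, and read counts
#' are binomial.  The number of clusters is chosen by BIC over
#' `1..K_max` with multiple seeded restarts.  Following the counting
#' rule, only clusters with at least `min_clone_size` mutations are
#' counted as clones.
#'
#' @param records Data frame with one row per mutation per tumor sample:
#'   `mutation_id`, `sample_role`, `alt`, `depth`, `purity`, `cn_total`,
#'   `cn_minor`.  Mutations falling in `cn_total = 0` regions are
#'   excluded.
#' @param K_max Largest number of clusters tried.
#' @param seed RNG seed (restarts and initialisation).
#' @param min_clone_size Minimum cluster size for a *counted* clone
#'   (default 10).
#' @param n_restarts Random restarts per K in addition to the
#'   kmeans-based initialisation.
#' @return A `clone_set`: list with `clusters` (per-cluster size and
#'   per-sample mean CCF), `assignments`, `n_clones` (counted clones),
#'   `K`, `bic`, `mutation_ids`.
#' @export
cluster_ccfs <- function(records, K_max = 8, seed = 1,
                         min_clone_size = 10, n_restarts = 1) {
  roles <- tumor_roles()
  records <- records[records$sample_role %in% roles, , drop = FALSE]
  # wide matrices: mutations x samples
  ids <- unique(records$mutation_id)
  idx <- cbind(match(records$mutation_id, ids),
               match(records$sample_role, roles))
  build <- function(col, default = NA_real_) {
    m <- matrix(default, length(ids), length(roles),
                dimnames = list(ids, roles))
    m[idx] <- records[[col]]
    m
  }
  alt <- build("alt"); depth <- build("depth")
  purity <- build("purity"); cn_t <- build("cn_total")
  cn_m <- build("cn_minor")
  ok <- rowSums(is.na(depth)) == 0 & apply(cn_t >= 1, 1, all)
  if (!any(ok)) stop("no mutation with defined CCF in all samples")
  alt <- alt[ok, , drop = FALSE]; depth <- depth[ok, , drop = FALSE]
  purity <- purity[ok, , drop = FALSE]
  cn_t <- cn_t[ok, , drop = FALSE]; cn_m <- cn_m[ok, , drop = FALSE]
  ids <- ids[ok]
  n <- length(ids)

  vaf <- ifelse(depth > 0, alt / depth, 0)
  mult <- matrix(compute_ccf(as.vector(vaf), as.vector(purity),
                             as.vector(cn_t),
                             as.vector(cn_m))$multiplicity, n)
  coef <- ccf_coefficient(purity, cn_t, mult)
  ccf_naive <- matrix(pmin(1, vaf / coef), nrow = n,
                      dimnames = dimnames(vaf))

  # presence-pattern initialisation: multi-region clones differ mostly
  # by which samples carry them, so hard-assigning mutations by their
  # thresholded CCF pattern seeds EM close to the clone structure
  pattern_init <- function(K) {
    pat <- apply(ccf_naive > 0.25, 1, function(z)
      paste(as.integer(z), collapse = ""))
    tab <- sort(table(pat), decreasing = TRUE)
    top <- names(tab)[seq_len(min(K, length(tab)))]
    cl <- match(pat, top)
    cl[is.na(cl)] <- 1L
    cl
  }

  set.seed(seed)
  best <- NULL; best_bic <- Inf
  bics <- numeric(0)
  for (K in seq_len(min(K_max, n))) {
    inits <- list()
    if (K == 1) {
      inits <- list(rep(1L, n))
    } else {
      inits <- list(pattern_init(K))
      km <- tryCatch(kmeans(ccf_naive, centers = K, nstart = 5),
                     error = function(e) NULL)
      if (!is.null(km)) inits <- c(inits, list(km$cluster))
      for (r in seq_len(n_restarts))
        inits <- c(inits, list(sample.int(K, n, replace = TRUE)))
    }
    fit_K <- NULL
    for (init in inits) {
      f <- fit_mixture(alt, depth, coef, K, init)
      if (is.null(fit_K) || f$loglik > fit_K$loglik) fit_K <- f
    }
    n_par <- K * ncol(alt) + (K - 1)
    bic <- -2 * fit_K$loglik + n_par * log(n)
    bics[K] <- bic
    if (bic < best_bic) { best_bic <- bic; best <- fit_K }
    # stop expanding K once BIC has worsened twice in a row
    if (K >= 3 && bics[K] > bics[K - 1] && bics[K - 1] > bics[K - 2]) break
  }

  assignment <- best$assignment
  sizes <- tabulate(assignment, nbins = best$K)
  keep <- which(sizes > 0)
  clusters <- data.frame(cluster = seq_along(keep),
                         size = sizes[keep])
  for (s in seq_along(roles))
    clusters[[paste0("ccf_", roles[s])]] <- best$phi[keep, s]
  relabel <- match(assignment, keep)
  structure(list(clusters = clusters,
                 assignments = setNames(relabel, ids),
                 n_clones = sum(clusters$size >= min_clone_size),
                 min_clone_size = min_clone_size,
                 K = nrow(clusters), bic = best_bic,
                 mutation_ids = ids),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat("Clone set:", nrow(x$clusters), "cluster(s),",
      x$n_clones, "counted clone(s) (>=", x$min_clone_size,
      "mutations)\n")
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Jaccard similarity index between a sample pair
#'
#' Each clustered mutation is graded in each sample from its cluster's
#' mean CCF there: absent (CCF below `absent_cutoff`), subclonal, or
#' clonal (CCF at least `clonal_cutoff`).  With `s` the mutations
#' subclonal in both samples and `pA`/`pB` those present in exactly one,
#' `JSI = s / (pA + pB + s)`; mutations clonal in both samples are
#' excluded (shared trunk gives no seeding information).
#'
#' @param clone_set A `clone_set` from [cluster_ccfs()].
#' @param pair Character 2-vector of tumor roles, e.g. `c("GBC", "LG")`.
#' @param clonal_cutoff CCF at or above which a mutation is clonal.
#' @param absent_cutoff CCF below which a mutation is absent.
#' @return JSI in \[0, 1\], or `NA` when no informative mutations remain.
#' @export
compute_jsi <- function(clone_set, pair, clonal_cutoff = 0.6,
                        absent_cutoff = 0.05) {
  stopifnot(length(pair) == 2)
  cl <- clone_set$clusters
  grade <- function(ccf)
    ifelse(ccf < absent_cutoff, "absent",
           ifelse(ccf >= clonal_cutoff, "clonal", "subclonal"))
  ga <- grade(cl[[paste0("ccf_", pair[1])]])[clone_set$assignments]
  gb <- grade(cl[[paste0("ccf_", pair[2])]])[clone_set$assignments]
  s <- sum(ga == "subclonal" & gb == "subclonal")
  pa <- sum(ga != "absent" & gb == "absent")
  pb <- sum(ga == "absent" & gb != "absent")
  if (s + pa + pb == 0) return(NA_real_)
  s / (pa + pb + s)
}

#' Classify seeding from a JSI value
#'
#' @param jsi JSI in \[0, 1\] or `NA`.
#' @param cutoff Decision threshold (default 0.3): values at or above the
#'   cutoff are polyclonal seeding, below it monoclonal.
#' @return `"polyclonal"`, `"monoclonal"`, or `NA`.
#' @export
classify_seeding <- function(jsi, cutoff = 0.3) {
  if (is.na(jsi)) return(NA_character_)
  if (jsi >= cutoff) "polyclonal" else "monoclonal"
}
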