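test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_patient_config(depth_mean = c(normal = 0, GBC = 100,
                                                 LG = 100, HG = 100)),
               "depths")
  expect_error(sim_patient_config(purity_range = c(0, 0.5)), "purity")
  expect_error(sim_patient_config(loh_trunk_frac = 0.6,
                                  loh_private_frac = 0.5),
               "sum to more than 1")
  expect_error(sim_patient_config(signature_weights = rep(1 / 29, 29)),
               "length 30")
  expect_error(sim_patient_config(n_trunk = -1), "non-negative")
  # mode presets follow the study scale
  expect_equal(sim_patient_config("independent")$n_trunk, 150)
  expect_equal(sim_patient_config("dependent_LG")$n_trunk, 36)
})

test_that("zero-rate configuration yields an empty, well-formed bundle", {
  cfg <- sim_patient_config("independent", n_trunk = 0,
                            n_branch_pair = 0, n_private = 0, seed = 5)
  sim <- simulate_patient(cfg, "P00", catalog = catalog_cached())
  expect_equal(nrow(sim$bundle$calls), 0)
  expect_true(all(lengths(sim$truth$branch_mutations) == 0))
  # segments still tile the genome for all three tumors
  expect_setequal(unique(sim$bundle$segments$sample_role),
                  c("GBC", "LG", "HG"))
})

test_that("the generator is deterministic per seed", {
  cfg <- sim_patient_config("dependent_HG", seed = 77)
  a <- simulate_patient(cfg, "P01", catalog = catalog_cached())
  b <- simulate_patient(cfg, "P01", catalog = catalog_cached())
  expect_identical(a, b)
  cfg2 <- sim_patient_config("dependent_HG", seed = 78)
  c <- simulate_patient(cfg2, "P01", catalog = catalog_cached())
  expect_false(identical(a, c))
})

test_that("emitted mutations are conserved and patterns match the clone tree", {
  cfg <- sim_patient_config("dependent_LG", fn_prob = 0,
                            rescue_miss_prob = 0, seed = 13)
  sim <- simulate_patient(cfg, "P02", catalog = catalog_cached())
  truth <- sim$truth
  # conservation: every emitted mutation in exactly one branch set
  n_branch <- sum(lengths(truth$branch_mutations))
  expect_equal(nrow(truth$mutations), n_branch)
  expect_equal(anyDuplicated(unlist(truth$branch_mutations)), 0)
  expect_equal(nrow(sim$bundle$calls), 3 * n_branch)

  # with no caller noise the rescued presence pattern equals the leaf
  # set below each mutation's branch
  pass <- filter_calls(sim$bundle$calls)
  pres <- rescue_across_samples(sim$bundle$calls, pass)
  leafsets <- list(trunk = c("GBC", "LG", "HG"),
                   internal = truth$sister,
                   GBC = "GBC", LG = "LG", HG = "HG")
  for (b in names(truth$branch_mutations)) {
    ids <- truth$branch_mutations[[b]]
    for (r in c("GBC", "LG", "HG")) {
      got <- pres[[r]][match(ids, pres$variant_id)]
      expect_true(all(got == (r %in% leafsets[[b]])),
                  label = paste("branch", b, "role", r))
    }
  }
})

test_that("near-noiseless simulation is recovered end to end", {
  cfg <- sim_patient_config("independent", fn_prob = 0,
                            rescue_miss_prob = 0,
                            purity_range = c(1, 1),
                            depth_mean = c(normal = 10000, GBC = 10000,
                                           LG = 10000, HG = 10000),
                            seed = 101)
  sim <- simulate_patient(cfg, "P03", catalog = catalog_cached())
  pass <- filter_calls(sim$bundle$calls)
  pres <- rescue_across_samples(sim$bundle$calls, pass)
  tree <- infer_tree(build_binary_matrix(pres))
  expect_equal(classify_topology(tree), "BilIN_independent")
  expect_equal(sim$truth$mode, "independent")
  expect_equal(count_trunk_mutations(pres),
               length(sim$truth$branch_mutations$trunk))
})

test_that("cohorts split modes as configured, deterministically", {
  expect_length(simulate_cohort(0, 0, seed = 1), 0)

  light <- list(n_trunk = 5, n_branch_pair = 5, n_private = 2)
  cohort <- simulate_cohort(6, 5, base_config = light, seed = 3,
                            catalog = catalog_cached())
  expect_length(cohort, 11)
  modes <- vapply(cohort, function(x) x$truth$mode, character(1))
  expect_equal(sum(modes == "independent"), 6)
  expect_equal(unname(modes[7:11]),
               c("dependent_LG", "dependent_HG", "dependent_LG",
                 "dependent_HG", "dependent_LG"))

  again <- simulate_cohort(6, 5, base_config = light, seed = 3,
                           catalog = catalog_cached())
  expect_identical(cohort, again)
  expect_error(simulate_cohort(-1, 0), "non-negative")
})

test_that("context sampling is a faithful multinomial of the mixture", {
  catalog <- catalog_cached()
  w <- setNames(numeric(30), colnames(catalog)); w["Sig1"] <- 1

  zero <- sample_contexts(w, catalog, 0)
  expect_true(all(zero == 0) && length(zero) == 96)

  n <- 1e6
  draw <- sample_contexts(w, catalog, n, seed = 8)
  expect_equal(sum(draw), n)
  expect_lt(sum(abs(draw / n - catalog[, "Sig1"])), 0.01)

  for (k in c(10, 1000)) {
    expect_equal(sum(sample_contexts(w, catalog, k, seed = k)), k)
  }
  expect_error(sample_contexts(rep(1 / 29, 29), catalog, 10), "length")
})

test_that("bundles round-trip through the on-disk formats", {
  cfg <- sim_patient_config("independent", n_trunk = 10,
                            n_branch_pair = 5, n_private = 3, seed = 55)
  sim <- simulate_patient(cfg, "P04", catalog = catalog_cached())
  dir <- tempfile("bundle")
  write_patient_bundle(sim, dir)
  back <- read_patient_bundle(dir, "P04")
  expect_equal(back$bundle$calls$pos, sim$bundle$calls$pos)
  expect_equal(back$bundle$calls$caller_support,
               sim$bundle$calls$caller_support)
  expect_equal(back$bundle$segments$cn_minor,
               sim$bundle$segments$cn_minor)
  expect_equal(back$truth$mode, sim$truth$mode)
  expect_setequal(back$truth$branch_mutations$trunk,
                  sim$truth$branch_mutations$trunk)
  # identical pipeline result from disk and from memory
  p1 <- rescue_across_samples(sim$bundle$calls,
                              filter_calls(sim$bundle$calls))
  p2 <- rescue_across_samples(back$bundle$calls,
                              filter_calls(back$bundle$calls))
  expect_equal(p2, p1)
})
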