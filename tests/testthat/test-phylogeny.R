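leaves3 <- c("GBC", "LG", "HG")

test_that("topology enumeration follows the double-factorial count", {
  expect_length(enumerate_topologies(c("A", "B")), 1)
  expect_length(enumerate_topologies(leaves3), 3)
  expect_length(enumerate_topologies(c("A", "B", "C", "D")), 15)
  tops4 <- enumerate_topologies(c("A", "B", "C", "D"))
  labels <- vapply(tops4, topology_label, character(1))
  expect_equal(anyDuplicated(labels), 0)
  expect_error(enumerate_topologies(letters[1:7]), "6 leaves")
})

test_that("parsimony scores match hand-derived cases", {
  trunk_only <- presence_matrix(list(a = c(1, 1, 1), b = c(1, 1, 1),
                                     c = c(1, 1, 1), d = c(1, 1, 1)))
  for (top in c(enumerate_topologies(leaves3),
                list(bilinevo:::star_topology(leaves3))))
    expect_equal(parsimony_score(top, trunk_only), 4)

  pats <- c(rep(list(c(0, 1, 1)), 5), list(c(1, 0, 0)), list(c(0, 1, 0)))
  names(pats) <- paste0("m", seq_along(pats))
  m <- presence_matrix(pats)
  expect_equal(parsimony_score("((LG,HG),GBC)", m), 7)
  expect_equal(parsimony_score("((GBC,HG),LG)", m), 12)

  expect_error(
    parsimony_score("((LG,HG),GBC)",
                    matrix(0, 1, 3, dimnames = list("z", leaves3))),
    "all-zero")
})

test_that("parsimony agrees with exhaustive ancestral-state enumeration", {
  set.seed(42)
  tops <- c(enumerate_topologies(leaves3),
            list(bilinevo:::star_topology(leaves3)))
  for (trial in 1:100) {
    n <- sample.int(50, 1)
    m <- matrix(rbinom(3 * n, 1, runif(1, 0.2, 0.8)), ncol = 3,
                dimnames = list(paste0("m", 1:n), leaves3))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) == 0) next
    top <- tops[[sample.int(4, 1)]]
    expect_equal(parsimony_score(top, m), oracle_parsimony(top, m))
  }
})

test_that("tree inference picks the unique minimum and stars on ties", {
  pair_lg_hg <- presence_matrix(list(a = c(0, 1, 1), b = c(0, 1, 1),
                                     c = c(1, 1, 1)))
  tr <- infer_tree(pair_lg_hg)
  expect_true(tr$resolved)
  expect_equal(tr$sister, c("HG", "LG"))

  no_pairs <- presence_matrix(list(a = c(1, 1, 1), b = c(1, 0, 0),
                                   c = c(0, 1, 0), d = c(0, 0, 1)))
  tr2 <- infer_tree(no_pairs)
  expect_false(tr2$resolved)
  expect_true(tr2$tie)
  expect_equal(tr2$label, "star")

  single <- presence_matrix(list(a = c(1, 1, 0)))
  tr3 <- infer_tree(single)
  expect_equal(tr3$sister, c("GBC", "LG"))

  # star never beats the best resolved tree; ties exactly without pairs
  set.seed(9)
  for (trial in 1:40) {
    n <- sample.int(30, 1)
    m <- matrix(rbinom(3 * n, 1, 0.5), ncol = 3,
                dimnames = list(paste0("m", 1:n), leaves3))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) == 0) next
    tr <- suppressWarnings(infer_tree(m))
    star_lab <- topology_label(bilinevo:::star_topology(leaves3))
    best_resolved <- min(tr$scores[setdiff(names(tr$scores), star_lab)])
    expect_gte(tr$scores[[star_lab]], best_resolved)
    has_pair <- any(rowSums(m) == 2)
    expect_equal(tr$scores[[star_lab]] == best_resolved, !has_pair)
  }
})

test_that("bootstrap support reflects conflict and is seed-stable", {
  clean <- presence_matrix(setNames(rep(list(c(0, 1, 1)), 100),
                                    paste0("m", 1:100)))
  expect_equal(bootstrap_support(clean, B = 200, seed = 5)$support, 1.0)

  conflict <- presence_matrix(c(
    setNames(rep(list(c(0, 1, 1)), 20), paste0("a", 1:20)),
    setNames(rep(list(c(1, 1, 0)), 20), paste0("b", 1:20))))
  bs <- suppressWarnings(bootstrap_support(conflict, B = 1000, seed = 5))
  ps <- bs$pair_support
  expect_lt(abs(ps[["HG+LG"]] - 0.5), 0.08)
  expect_lt(abs(ps[["GBC+LG"]] - 0.5), 0.08)

  again <- suppressWarnings(bootstrap_support(conflict, B = 1000, seed = 5))
  expect_identical(bs, again)
})

test_that("branch assignment separates compatible rows from homoplasy", {
  m <- presence_matrix(list(t1 = c(1, 1, 1), p1 = c(0, 1, 1),
                            p2 = c(0, 1, 1), g1 = c(1, 0, 0),
                            x1 = c(1, 0, 1)))
  tr <- infer_tree(m)
  expect_equal(tr$sister, c("HG", "LG"))
  ba <- tr$branch_mutations
  expect_equal(ba$trunk, "t1")
  expect_equal(ba$internal, c("p1", "p2"))
  expect_equal(ba$GBC, "g1")
  expect_equal(ba$homoplasy, "x1")
  # conservation: branch lengths + homoplasy = rows
  expect_equal(sum(lengths(ba)), nrow(m))
})

test_that("trunk mutation counting is the three-way intersection", {
  all_shared <- make_presence(setNames(rep(list(c(1, 1, 1)), 10),
                                       paste0("m", 1:10)))
  expect_equal(count_trunk_mutations(all_shared), 10)

  none <- make_presence(list(a = c(1, 0, 0), b = c(0, 1, 0)))
  expect_equal(count_trunk_mutations(none), 0)

  mixed <- make_presence(c(
    setNames(rep(list(c(1, 1, 1)), 3), paste0("t", 1:3)),
    setNames(rep(list(c(0, 1, 1)), 2), paste0("p", 1:2)),
    setNames(rep(list(c(1, 0, 0)), 4), paste0("q", 1:4))))
  expect_equal(count_trunk_mutations(mixed), 3)
})

test_that("non-LOH re-inference drops rows inside LOH regions", {
  m <- presence_matrix(list(a = c(0, 1, 1), b = c(0, 1, 1),
                            c = c(1, 1, 1)))
  positions <- data.frame(variant_id = rownames(m), chrom = "1",
                          pos = c(100, 200, 5000))
  no_loh <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0))
  t_all <- infer_tree(m)
  t_same <- infer_tree_nonloh(m, positions, no_loh)
  expect_equal(t_same$label, t_all$label)
  expect_equal(t_same$scores, t_all$scores)

  everywhere <- data.frame(chrom = "1", start = 1, end = 1e6)
  expect_warning(t_star <- infer_tree_nonloh(m, positions, everywhere),
                 "no informative rows")
  expect_equal(t_star$label, "star")

  # dropping only the LOH-resident rows keeps the informative signal
  loh_tail <- data.frame(chrom = "1", start = 4000, end = 6000)
  t_drop <- infer_tree_nonloh(m, positions, loh_tail)
  expect_equal(t_drop$sister, c("HG", "LG"))
  expect_equal(t_drop$n_sites, 2L)
})

test_that("newick export round-trips through ape", {
  m <- presence_matrix(list(a = c(0, 1, 1), b = c(0, 1, 1),
                            c = c(1, 1, 1), d = c(1, 0, 0)))
  tr <- infer_tree(m)
  tr$support <- 0.97
  nwk <- as_newick(tr)
  phy <- ape::read.tree(text = nwk)
  expect_s3_class(phy, "phylo")
  expect_setequal(phy$tip.label, c("GBC", "LG", "HG", "normal"))
})
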