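test_that("truncated geometric sizes follow the renormalized law", {
  # closed form at p = 0.5, max 3: (4/7, 2/7, 1/7)
  set.seed(7)
  draws <- sample_event_size(0.5, 3L, n = 4000L)
  freq <- tabulate(draws, 3) / 4000
  expected <- c(4, 2, 1) / 7
  se <- sqrt(expected * (1 - expected) / 4000)
  expect_true(all(abs(freq - expected) < 3 * se))
  # degenerate truncation
  expect_true(all(sample_event_size(0.5, 1L, n = 50L) == 1L))
  expect_error(sample_event_size(0.5, 0L))
  expect_error(sample_event_size(1.2, 3L))
})

test_that("the fixed-size design yields 3dn+1 genes per extant genome", {
  for (leaves in c(2L, 4L)) {
    d <- log2(leaves) + 1L     # branches crossed from the origin to a leaf
    for (n in 1:2) {
      sim <- simulate_history(named_design("fig5", leaves = leaves, n = n),
                              seed = 100 + n)
      sizes <- vapply(sim$leaf_orders, function(o) length(o$ids), integer(1))
      expect_true(all(sizes == 3 * d * n + 1))
    }
  }
})

test_that("per-branch budgets are honored exactly", {
  sim <- simulate_history(named_design("fig7", leaves = 2), seed = 21)
  counts <- table(sim$truth$branch[sim$truth$type != "SPEC"],
                  sim$truth$type[sim$truth$type != "SPEC"])
  # every branch: 4 DUP, 1 INV_DUP, 1 INV, 1 DEL
  expect_true(all(counts[, "DUP"] == 4))
  expect_true(all(counts[, "INV_DUP"] == 1))
  expect_true(all(counts[, "INV"] == 1))
  expect_true(all(counts[, "DEL"] == 1))
  expect_true(all(sim$truth$size[sim$truth$type == "DEL"] %in% 1:2))

  # fig6 splits duplications evenly with the requested inversions
  sim6 <- simulate_history(named_design("fig6", leaves = 2, x = 4,
                                        inversion_fraction = 1 / 2), seed = 8)
  expect_identical(sum(sim6$truth$type %in% c("DUP", "INV_DUP")), 4L)
  expect_identical(sum(sim6$truth$type == "INV"), 4L)
  sim0 <- simulate_history(named_design("fig6", leaves = 2, x = 4,
                                        inversion_fraction = 0), seed = 8)
  expect_identical(sum(sim0$truth$type == "INV"), 0L)
})

test_that("zero budget leaves single-gene genomes and a single cherry", {
  cfg <- simulation_config(balanced_species_tree(2), list())
  sim <- simulate_history(cfg, seed = 1)
  expect_true(all(vapply(sim$leaf_orders, length, integer(1)) == 1L))
  expect_identical(length(multidiltag:::tree_leaves(sim$gene_tree)), 2L)
})

test_that("every simulated history validates against its own output", {
  for (seed in c(3, 17, 23)) {
    sim <- simulate_history(named_design("fig7", leaves = 2), seed = seed)
    expect_true(validate_history(sim$history, sim$leaf_orders, sim$gene_tree)$ok)
  }
})

test_that("simulation is a pure function of (config, seed)", {
  a <- simulate_history(named_design("fig7", leaves = 2), seed = 12)
  b <- simulate_history(named_design("fig7", leaves = 2), seed = 12)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$leaf_orders, unclass), lapply(b$leaf_orders, unclass))
  c <- simulate_history(named_design("fig7", leaves = 2), seed = 13)
  expect_false(identical(a$truth, c$truth))
})

test_that("deletion-free histories create exactly the sampled gene counts", {
  cfg <- named_design("fig6", leaves = 2, x = 4, inversion_fraction = 0)
  sim <- simulate_history(cfg, seed = 31)
  dup_sizes <- sim$truth$size[sim$truth$type %in% c("DUP", "INV_DUP")]
  # genes at the leaves: each lineage holds 1 + sizes of the events on its
  # root-to-leaf path of branches
  stree <- cfg$species_tree
  snames <- multidiltag:::species_vertex_names(stree)
  for (leaf in multidiltag:::tree_leaves(stree)) {
    path <- leaf
    v <- leaf
    while (stree$parent[v] != 0L) { v <- stree$parent[v]; path <- c(path, v) }
    on_path <- sim$truth$branch %in% snames[path] &
      sim$truth$type %in% c("DUP", "INV_DUP")
    expect_identical(length(sim$leaf_orders[[snames[leaf]]]$ids),
                     1L + sum(sim$truth$size[on_path]))
  }
})
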