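st3 <- function() read_newick_tree("((1,2)A,3)B;", "species")

test_that("LCA mapping handles congruent, nested and loss-implying trees", {
  # congruent cherry: no duplications, no losses
  r1 <- lca_reconcile(read_newick_tree("(1|g1,2|g2);", "gene"),
                      read_newick_tree("(1,2)A;", "species"))
  expect_identical(r1$n_dup, 0L)
  expect_identical(r1$n_loss, 0L)
  expect_identical(ancestral_gene_count(r1, "A"), 1L)

  # fully congruent 3-species tree
  r2 <- lca_reconcile(read_newick_tree("((1|g1,2|g2),3|g3);", "gene"), st3())
  expect_identical(r2$n_dup, 0L)
  expect_identical(r2$n_loss, 0L)
  rep2 <- reconciliation_report(r2)
  expect_true(all(rep2$n_genes == 1L))
  expect_identical(losses_on_branch(r2, "A", "1"), character(0))

  # cherry (g1, g3): an implied speciation at A with a loss toward genome 2
  r3 <- lca_reconcile(read_newick_tree("(1|g1,3|g3);", "gene"), st3())
  expect_identical(r3$n_dup, 0L)
  expect_identical(r3$n_loss, 1L)
  expect_length(losses_on_branch(r3, "A", "2"), 1L)
  A <- match("A", r3$species_names)
  two <- match("2", r3$species_names)
  expect_identical(length(r3$PG[[two]]), 0L)
  expect_identical(length(r3$G[[A]]), 1L)
})

test_that("genome and pre-speciation sets match the worked 3-species instance", {
  # two root lineages a, b; b duplicates into d, e on the branch to A;
  # a's copy c is lost toward genome 2
  gt <- read_newick_tree(
    "((1|c1,3|a3),(((1|d1,2|d2),(1|e1,2|e2)),3|b3));", "gene")
  rec <- lca_reconcile(gt, st3())
  expect_identical(ancestral_gene_count(rec, "A"), 3L)
  expect_identical(ancestral_gene_count(rec, "B"), 2L)
  expect_identical(rec$n_loss, 1L)
  expect_length(losses_on_branch(rec, "A", "2"), 1L)
  A <- match("A", rec$species_names)
  expect_identical(length(rec$PG[[A]]), 2L)            # PG(A) = G(B)
  expect_identical(length(rec$PG[[match("1", rec$species_names)]]), 3L)
  expect_identical(length(rec$PG[[match("2", rec$species_names)]]), 2L)
  expect_identical(length(rec$PG[[match("3", rec$species_names)]]), 2L)
})

test_that("branch forests have one top per pre-speciation gene", {
  gt <- read_newick_tree(
    "((1|c1,3|a3),(((1|d1,2|d2),(1|e1,2|e2)),3|b3));", "gene")
  rec <- lca_reconcile(gt, st3())
  sroot <- rec$species_tree$root
  for (A in seq_along(rec$forests)) {
    f <- rec$forests[[A]]
    expect_setequal(f$leaf_keys, rec$G[[A]])
    if (A != sroot) {
      expect_setequal(unname(f$top_relabel), rec$PG[[A]])
    } else {
      expect_identical(unname(f$top_relabel), "origin")
    }
  }
})

test_that("rejects a gene whose genome is not in the species tree", {
  gt <- read_newick_tree("(1|g1,9|g9);", "gene")
  expect_error(lca_reconcile(gt, st3()), class = "multidiltag_bad_reconciliation")
})

test_that("LCA reconciliation attains the brute-force duplication+loss minimum", {
  set.seed(19)
  species <- list("((1,2),3);", "((1,2),(3,4));", "(1,(2,(3,4)));")
  for (i in 1:25) {
    stxt <- sample(species, 1)[[1]]
    stree <- read_newick_tree(stxt, "species")
    genomes <- multidiltag:::tree_leaf_labels(stree)
    # random gene tree over 3-5 genes in random genomes
    ng <- sample(3:5, 1)
    gs <- paste0("x", seq_len(ng))
    gen <- sample(genomes, ng, replace = TRUE)
    labs <- paste0(gen, "|", gs)
    while (length(labs) > 1) {
      i2 <- sample(length(labs), 2)
      labs <- c(labs[-i2], paste0("(", labs[i2[1]], ",", labs[i2[2]], ")"))
    }
    gt <- read_newick_tree(paste0(labs, ";"), "gene")
    rec <- lca_reconcile(gt, stree)
    oracle <- oracle_min_dup_loss(gt, stree, attr(gt, "leaf_genome"))
    expect_identical(rec$n_dup + rec$n_loss, as.integer(oracle))
  }
})

test_that("deletion-free simulations reconcile without losses at the true counts", {
  cfg <- named_design("fig6", leaves = 4, x = 4, inversion_fraction = 0)
  sim <- simulate_history(cfg, seed = 77)
  rec <- lca_reconcile(sim$gene_tree, cfg$species_tree)
  expect_identical(rec$n_loss, 0L)
  # gene count at the root equals 1 + sizes of pre-root duplications
  snames <- rec$species_names
  sroot <- rec$species_tree$root
  pre <- sim$truth$type %in% c("DUP", "INV_DUP") &
    sim$truth$branch == snames[sroot]
  expect_identical(length(rec$G[[sroot]]), 1L + sum(sim$truth$size[pre]))
})
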