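test_that("Newick parsing enforces rooted binary trees and label conventions", {
  gt <- read_newick_tree("((1|a,2|a2),(1|b,2|b2));", "gene")
  expect_setequal(multidiltag:::tree_leaf_labels(gt), c("a", "a2", "b", "b2"))
  expect_identical(unname(attr(gt, "leaf_genome")[c("a", "b2")]), c("1", "2"))

  st <- read_newick_tree("((1,2)A,3)B;", "species")
  expect_identical(sort(multidiltag:::tree_leaf_labels(st)), c("1", "2", "3"))
  expect_true("A" %in% st$label)

  expect_error(read_newick_tree("(a,b,c);", "species"),
               class = "multidiltag_bad_tree")
  expect_error(suppressWarnings(read_newick_tree("((1|a,(1|b,1|c));", "gene")))
  expect_error(read_newick_tree("(a,b);", "gene"),
               class = "multidiltag_bad_tree")  # labels lack genome part
})

test_that("Newick round trip preserves topology and labels", {
  txt <- "((1|a,2|a2),(1|b,2|b2));"
  gt <- read_newick_tree(txt, "gene")
  back <- write_newick_tree(gt, leaf_genome = attr(gt, "leaf_genome"))
  gt2 <- read_newick_tree(back, "gene")
  expect_identical(multidiltag:::tree_canon(gt), multidiltag:::tree_canon(gt2))
  # single-leaf trees write too
  expect_identical(write_newick_tree(multidiltag:::tree_single("x")), "x;")
})

test_that("orders files round trip; malformed input is rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  orders <- list(gene_order("1", c("a", "b"), c(1L, -1L)),
                 gene_order("2", c("c"), 1L))
  write_orders(orders, f)
  back <- read_orders(f)
  expect_identical(back[["1"]]$ids, c("a", "b"))
  expect_identical(back[["1"]]$signs, c(1L, -1L))
  # byte-identical round trip for canonical files
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_orders(back, f2)
  expect_identical(readLines(f), readLines(f2))

  writeLines(c("1\t+a b"), f)
  expect_error(read_orders(f), class = "multidiltag_bad_orders")
  writeLines(c("1\t+a", "1\t+b"), f)
  expect_error(read_orders(f), class = "multidiltag_bad_orders")
  writeLines(c("1\t+a", "2\t"), f)
  expect_warning(read_orders(f), "empty order")
  # cross-check against the gene-tree universe
  writeLines(c("1\t+a", "2\t+zzz"), f)
  gt <- read_newick_tree("(1|a,2|b);", "gene")
  expect_error(suppressWarnings(read_orders(f, gene_tree = gt)),
               class = "multidiltag_bad_orders")
})

test_that("simulation outputs are written as plain text files", {
  sim <- simulate_history(named_design("fig5", leaves = 2, n = 1), seed = 5)
  prefix <- file.path(withr::local_tempdir(), "sim")
  paths <- write_simulation(sim, prefix)
  expect_true(all(file.exists(paths)))
  gt <- read_newick_tree(paths[["gene_tree"]], "gene")
  orders <- read_orders(paths[["orders"]], gene_tree = gt)
  expect_identical(sort(names(orders)), c("1", "2"))
  truth <- utils::read.delim(paths[["truth"]])
  expect_true(all(c("branch", "type", "size") %in% names(truth)))
})

test_that("the command line surface runs and reports failures", {
  td <- withr::local_tempdir()
  out <- file.path(td, "sim")
  expect_identical(cli_main(c("simulate", "--design", "fig5", "--leaves", "2",
                              "--n", "1", "--seed", "3", "--out", out)), 0L)
  expect_true(file.exists(paste0(out, ".orders.tsv")))
  fit_out <- file.path(td, "fit")
  expect_identical(
    cli_main(c("infer", "--gene-tree", paste0(out, ".genetree.nwk"),
               "--species-tree", paste0(out, ".speciestree.nwk"),
               "--orders", paste0(out, ".orders.tsv"), "--out", fit_out)), 0L)
  expect_true(file.exists(paste0(fit_out, ".branch_events.tsv")))
  # simulate without --seed fails with nonzero status
  expect_identical(suppressMessages(cli_main(c("simulate", "--design", "fig5"))), 1L)
  # disabling every event type leaves no predecessors
  expect_identical(suppressMessages(
    cli_main(c("infer", "--gene-tree", paste0(out, ".genetree.nwk"),
               "--species-tree", paste0(out, ".speciestree.nwk"),
               "--orders", paste0(out, ".orders.tsv"),
               "--disable-events", "dup,inv_dup,inv,del"))), 1L)
})
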