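st2 <- function() read_newick_tree("(1,2)A;", "species")

test_that("loss reinsertion enumerates the full combinatorial closure", {
  e1 <- extend_with_losses(gene_order("g", "a", 1L), "b")
  expect_length(e1, 4L)
  strs <- sort(vapply(e1, function(o) multidiltag:::order_string(o$ids, o$signs),
                      character(1)))
  expect_identical(strs, sort(c("+b +a", "-b +a", "+a +b", "+a -b")))

  expect_length(extend_with_losses(gene_order("g", c("a", "c"), 1L), "b"), 6L)
  e0 <- extend_with_losses(gene_order("g", "a", 1L), character(0))
  expect_length(e0, 1L)
  # two lost genes into one: 2(n+1) * 2(n+2) = 2*2*2*3 = 24, all distinct
  e2 <- extend_with_losses(gene_order("g", "a", 1L), c("b", "c"))
  expect_length(e2, 24L)
  expect_identical(anyDuplicated(vapply(e2, function(o)
    multidiltag:::order_sig(o$ids, o$signs), character(1))), 0L)
  # explosion guard
  expect_error(extend_with_losses(gene_order("g", letters[1:4], 1L),
                                  paste0("L", 1:4), cap = 100L),
               class = "multidiltag_loss_explosion")
})

test_that("two congruent two-gene clusters cost one duplication", {
  gt <- read_newick_tree("((1|a1,2|a2),(1|b1,2|b2));", "gene")
  orders <- list(gene_order("1", c("a1", "b1"), 1L),
                 gene_order("2", c("a2", "b2"), 1L))
  fit <- multi_diltag(gt, orders, st2())
  expect_equal(fit$total_cost, 101)
  expect_true(fit$valid$ok)
  ss <- solution_set(fit, "A")
  expect_identical(nrow(ss), 1L)
  rep <- branch_event_report(fit)
  expect_identical(sum(rep$n_dup), 1L)
  expect_identical(sum(rep$n_inv_dup) + sum(rep$n_inv) + sum(rep$n_del), 0L)
  g <- glance(fit)
  expect_identical(g$n_events, 1L)
  expect_true(g$valid)
})

test_that("a gene lost on one branch is reinserted and charged as reported", {
  gt <- read_newick_tree("((1|a1,2|a2),2|b2);", "gene")
  orders <- list(gene_order("1", "a1", 1L),
                 gene_order("2", c("a2", "b2"), 1L))
  # plain-count speciation-edge labels: the total is the one duplication
  fit <- multi_diltag(gt, orders, st2(), id_label_costs = FALSE)
  expect_equal(fit$total_cost, 101)
  expect_true(fit$valid$ok)
  # the loss-extended solution set at A holds 4 reinsertions (one merged
  # with the right branch's own ancestral order)
  ss <- solution_set(fit, "A")
  expect_identical(nrow(ss), 4L)
  # the chosen edge toward the right child matches its origin exactly
  ed <- fit$speciation_edges
  expect_true(any(ed$to_vertex == "2" & ed$id_label == 0))
  # with cost-converted labels the implied deletion on branch 1 is charged
  fit2 <- multi_diltag(gt, orders, st2(), id_label_costs = TRUE)
  expect_equal(fit2$total_cost, 101 + 501)
  expect_true(fit2$valid$ok)
  # the replayed history must contain that deletion either way
  rep <- branch_event_report(fit)
  expect_identical(sum(rep$n_del), 1L)
  expect_identical(sum(rep$n_losses), 1L)
})

test_that("deletion-free simulated instances are recovered at the true cost", {
  cm <- cost_model()
  for (seed in c(5, 9)) {
    cfg <- named_design("fig6", leaves = 2, x = 4, inversion_fraction = 0)
    sim <- simulate_history(cfg, seed = seed)
    fit <- multi_diltag(sim$gene_tree, sim$leaf_orders, cfg$species_tree)
    expect_true(fit$valid$ok)
    true_cost <- sum(vapply(sim$history$events, event_cost, numeric(1),
                            costs = cm))
    expect_lte(fit$total_cost, true_cost)
  }
})

test_that("traceback falls back to the next-best root candidate", {
  gt <- read_newick_tree("((1|a1,2|a2),2|b2);", "gene")
  orders <- list(gene_order("1", "a1", 1L),
                 gene_order("2", c("a2", "b2"), 1L))
  fit <- multi_diltag(gt, orders, st2())
  best <- fit$root_candidates[[1]]
  tb2 <- traceback_history(fit, exclude_root = best$elem_index)
  expect_gte(tb2$total_cost, fit$total_cost)
  v <- validate_history(tb2$history, orders, gt)
  expect_true(v$ok)
  all_idx <- unique(vapply(fit$root_candidates, `[[`, integer(1), "elem_index"))
  expect_error(traceback_history(fit, exclude_root = all_idx), "excluded")
})

test_that("branch reports follow the loss counting convention", {
  # hand-built history: one size-2 deletion = 1 deletion, 2 gene losses
  init <- initial_state("u", "G")
  ev <- list(tag_event("DUP", "G", c(1, 1)),
             tag_event("DUP", "G", c(1, 2)),
             tag_event("DEL", "G", c(2, 3)))
  h <- tag_history(init, ev)
  rep <- branch_event_report(h)
  expect_identical(rep$n_dup, 2L)
  expect_identical(rep$n_del, 1L)
  expect_identical(rep$n_losses, 2L)
  # compound events count one duplication and one deletion
  ev2 <- list(tag_event("DUP", "G", c(1, 1)),
              tag_event("DUP", "G", c(1, 2), deleted_subspan = c(3, 3)))
  rep2 <- branch_event_report(tag_history(init, ev2))
  expect_identical(rep2$n_dup, 2L)
  expect_identical(rep2$n_del, 1L)
  expect_identical(rep2$n_losses, 1L)
  expect_identical(sort(unlist(rep2$dup_sizes)), c(1L, 2L))
})

test_that("fits on four species traverse nested branches consistently", {
  cfg <- named_design("fig6", leaves = 4, x = 4, inversion_fraction = 0)
  sim <- simulate_history(cfg, seed = 15)
  fit <- multi_diltag(sim$gene_tree, sim$leaf_orders, cfg$species_tree)
  expect_true(fit$valid$ok)
  rep <- branch_event_report(fit)
  expect_identical(sum(rep$n_dup) + sum(rep$n_inv_dup),
                   sum(sim$truth$type %in% c("DUP", "INV_DUP")))
})
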