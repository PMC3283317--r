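test_that("forward event semantics follow the evolutionary model", {
  s3 <- mk_state("((g|a,g|b),g|c);", c("a", "b", "c"), 1L)

  # multiple tandem duplication replaces the span by l-block then r-block
  d <- apply_event(s3, tag_event("DUP", "g", c(1, 2)))
  expect_identical(d$orders[["g"]]$ids, c("a.1", "b.1", "a.2", "b.2", "c"))
  expect_identical(d$orders[["g"]]$signs, rep(1L, 5))
  # each duplicated gene became a cherry
  P <- multidiltag:::forest_from_gene_tree(d$tree)$parent
  expect_identical(unname(P["a.1"]), unname(P["a.2"]))
  expect_identical(unname(P["b.1"]), unname(P["b.2"]))

  # the two inverted-duplication placements
  s1 <- initial_state("a", "g")
  l <- apply_event(s1, tag_event("INV_DUP", "g", c(1, 1), variant = "left"))
  r <- apply_event(s1, tag_event("INV_DUP", "g", c(1, 1), variant = "right"))
  expect_identical(l$orders[["g"]]$signs, c(-1L, 1L))
  expect_identical(r$orders[["g"]]$signs, c(1L, -1L))

  # inversion reverses and negates the span, tree untouched
  si <- mk_state("((g|a,g|b),g|c);", c("a", "b", "c"), c(1L, -1L, 1L))
  v <- apply_event(si, tag_event("INV", "g", c(1, 2)))
  expect_identical(v$orders[["g"]]$ids, c("b", "a", "c"))
  expect_identical(v$orders[["g"]]$signs, c(1L, -1L, 1L))
  expect_identical(canon_state(si)
                   , canon_state(apply_event(v, tag_event("INV", "g", c(1, 2)))))

  # deletion removes genes from order and tree (degree-2 suppression)
  dl <- apply_event(s3, tag_event("DEL", "g", c(2, 2)))
  expect_identical(dl$orders[["g"]]$ids, c("a", "c"))
  expect_setequal(multidiltag:::tree_leaf_labels(dl$tree), c("a", "c"))

  # speciation copies the whole order into two genomes
  sp <- apply_event(si, tag_event("SPEC", "g", new_genomes = c("g1", "g2")))
  expect_setequal(names(sp$orders), c("g1", "g2"))
  expect_identical(sp$orders[["g1"]]$signs, si$orders[["g"]]$signs)
  expect_identical(sp$orders[["g2"]]$signs, si$orders[["g"]]$signs)

  # errors: unknown genome, span out of range, emptying deletion
  expect_error(apply_event(s3, tag_event("DUP", "nope", c(1, 1))),
               class = "multidiltag_bad_event")
  expect_error(apply_event(s3, tag_event("INV", "g", c(2, 5))),
               class = "multidiltag_bad_event")
  expect_error(apply_event(s3, tag_event("DEL", "g", c(1, 3))),
               class = "multidiltag_empty_genome")
  # with a second genome present the tree survives an emptied order
  sp2 <- apply_event(s3, tag_event("SPEC", "g", new_genomes = c("gA", "gB")))
  emptied <- apply_event(sp2, tag_event("DEL", "gA", c(1, 3)),
                         allow_empty_genome = TRUE)
  expect_length(emptied$orders[["gA"]]$ids, 0L)
  expect_length(emptied$orders[["gB"]]$ids, 3L)
})

test_that("event costs are alpha + m * beta, compounds add the deletion", {
  cm <- cost_model()
  expect_equal(event_cost(tag_event("DUP", "g", c(1, 1)), cm), 101)
  expect_equal(event_cost(tag_event("DEL", "g", c(1, 2)), cm), 502)
  expect_equal(event_cost(tag_event("INV", "g", c(2, 4)), cm), 503)
  expect_equal(event_cost(tag_event("INV_DUP", "g", c(1, 2), variant = "left"), cm), 102)
  # compound: dup size 2 + deletion of one copy
  expect_equal(event_cost(tag_event("DUP", "g", c(1, 2),
                                    deleted_subspan = c(3, 3)), cm), 102 + 501)
  # zero-size events are invalid
  expect_error(tag_event("DUP", "g", c(2, 1)))
  # disabled types cost Inf
  cm2 <- cost_model(enabled = c("dup", "del"))
  expect_identical(event_cost(tag_event("INV", "g", c(1, 1)), cm2), Inf)
})

test_that("gene-count bookkeeping and sign conservation hold under random events", {
  set.seed(42)
  state <- initial_state("g1", "G")
  for (i in 1:40) {
    o <- state$orders[["G"]]
    n <- length(o$ids)
    nt <- length(multidiltag:::tree_leaves(state$tree))
    expect_identical(n, nt)
    type <- sample(c("DUP", "INV_DUP", "INV", "DEL"), 1,
                   prob = c(.4, .2, .2, if (n > 3) .2 else 0))
    m <- sample(seq_len(min(n, 3)), 1)
    p <- sample(n - m + 1L, 1)
    ev <- switch(type,
      DUP = tag_event("DUP", "G", c(p, p + m - 1L)),
      INV_DUP = tag_event("INV_DUP", "G", c(p, p + m - 1L),
                          variant = sample(c("left", "right"), 1)),
      INV = tag_event("INV", "G", c(p, p + m - 1L)),
      DEL = tag_event("DEL", "G", c(p, p + m - 1L)))
    s2 <- apply_event(state, ev)
    n2 <- length(s2$orders[["G"]]$ids)
    if (type %in% c("DUP", "INV_DUP")) expect_identical(n2, n + m)
    if (type == "INV") expect_identical(n2, n)
    if (type == "DEL") expect_identical(n2, n - m)
    if (type == "DUP") {
      expect_identical(s2$orders[["G"]]$signs[p:(p + 2 * m - 1)],
                       rep(o$signs[p:(p + m - 1)], 2))
    }
    state <- s2
  }
})

test_that("histories replay and validate; a flipped sign is caught", {
  cfg <- named_design("fig5", leaves = 2, n = 1)
  sim <- simulate_history(cfg, seed = 99)
  v <- validate_history(sim$history, sim$leaf_orders, sim$gene_tree)
  expect_true(v$ok)

  bad <- sim$leaf_orders
  bad[[1]]$signs[1] <- -bad[[1]]$signs[1]
  v2 <- validate_history(sim$history, bad, sim$gene_tree)
  expect_false(v2$ok)
  expect_match(v2$divergence, "signs")

  # wrong topology is caught too
  n <- length(sim$leaf_orders)
  gt2 <- sim$gene_tree
  v3 <- validate_history(sim$history, sim$leaf_orders[c(2, 1)], sim$gene_tree)
  expect_true(v3$ok)  # order of the list does not matter, genomes are named
})
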