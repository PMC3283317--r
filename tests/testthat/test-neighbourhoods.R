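Pmap <- function(newick) multidiltag:::forest_from_gene_tree(
  read_newick_tree(newick, "gene"))$parent

test_that("duplication undo collapses sign-consistent cherry patterns", {
  P <- Pmap("(g|a,g|b);")
  p <- run_operator("DUP", c("a", "b"), c(1L, 1L), P)
  expect_length(p, 1L)
  expect_identical(p[[1]]$signs, 1L)
  expect_identical(p[[1]]$event$span, c(1L, 1L))
  # sign mismatch: no duplication predecessor
  expect_length(run_operator("DUP", c("a", "b"), c(1L, -1L), P), 0L)

  # size-2 pattern (l1 l2 r1 r2) over two cherries
  P4 <- Pmap("((g|a,g|a2),(g|b,g|b2));")
  p4 <- run_operator("DUP", c("a", "b", "a2", "b2"), rep(1L, 4), P4)
  spans <- vapply(p4, function(x) paste(x$event$span, collapse = ","), character(1))
  expect_true("1,2" %in% spans)
  big <- p4[[which(spans == "1,2")]]
  expect_length(big$ids, 2L)
  # non-cherry arrangement (a b a2 b2 with cherries (a,b),(a2,b2)) fails
  Px <- Pmap("((g|a,g|b),(g|a2,g|b2));")
  px <- run_operator("DUP", c("a", "b", "a2", "b2"), rep(1L, 4), Px)
  expect_false("1,2" %in% vapply(px, function(x)
    paste(x$event$span, collapse = ","), character(1)))
})

test_that("inverted-duplication undo detects both placements", {
  P <- Pmap("(g|a,g|b);")
  pl <- run_operator("INV_DUP", c("a", "b"), c(-1L, 1L), P)
  expect_length(pl, 2L)   # left variant giving +u, right variant giving -u
  vs <- vapply(pl, function(x) x$event$variant, character(1))
  expect_setequal(vs, c("left", "right"))
  sl <- pl[[which(vs == "left")]]
  expect_identical(sl$signs, 1L)
  # all-positive cherry is not an inverted duplication
  expect_length(run_operator("INV_DUP", c("a", "b"), c(1L, 1L), P), 0L)
  # embedded pattern (+x, -c, +b) with cherry (b, c)
  P3 <- Pmap("(g|x,(g|b,g|c));")
  p3 <- run_operator("INV_DUP", c("x", "c", "b"), c(1L, -1L, 1L), P3)
  expect_true(any(vapply(p3, function(x) length(x$ids) == 2L &&
                           x$ids[1] == "x", logical(1))))
})

test_that("inversion undo enumerates exactly n(n+1)/2 spans and is an involution", {
  P <- Pmap("(g|a,g|b);")
  p <- run_operator("INV", c("a", "b"), c(1L, -1L), P)
  expect_length(p, 3L)
  sigs <- vapply(p, function(x) multidiltag:::order_sig(x$ids, x$signs), character(1))
  expect_setequal(sigs, c(multidiltag:::order_sig(c("a", "b"), c(-1L, -1L)),
                          multidiltag:::order_sig(c("a", "b"), c(1L, 1L)),
                          multidiltag:::order_sig(c("b", "a"), c(1L, -1L))))
  # single gene: one span
  P1 <- multidiltag:::forest_from_gene_tree(multidiltag:::tree_single("a"))$parent
  expect_length(run_operator("INV", "a", 1L, P1), 1L)
  # involution: undoing the same span twice returns the original
  x <- p[[1]]
  back <- run_operator("INV", x$ids, x$signs, P)
  expect_true(any(vapply(back, function(y)
    identical(y$ids, c("a", "b")) && identical(y$signs, c(1L, -1L)), logical(1))))
})

test_that("duplication-with-deletion undo anchors on a surviving cherry", {
  # ((a,b),c): dup of (u,v) with one copy of v deleted explains (a,b,c)
  P <- Pmap("((g|a,g|b),g|c);")
  p <- run_operator("CDUP", c("a", "b", "c"), rep(1L, 3), P)
  expect_length(p, 1L)
  expect_identical(p[[1]]$event$type, "DUP")
  expect_identical(p[[1]]$event$span, c(1L, 2L))
  expect_length(p[[1]]$ids, 2L)
  expect_equal(event_cost(p[[1]]$event, cost_model()), 603)  # 102 + 501
  # a bare deletion is never proposed: single gene has no compound undo
  P1 <- multidiltag:::forest_from_gene_tree(multidiltag:::tree_single("a"))$parent
  expect_length(run_operator("CDUP", "a", 1L, P1), 0L)
})

test_that("all neighbourhood proposals replay forward to the state they undo", {
  # ancestors: everything reachable by <= 1 event from a single gene, plus a
  # couple of deeper states; children: every forward event applied to them
  set.seed(11)
  ancestors <- list(initial_state("u", "g"))
  for (ev in enumerate_forward_events(ancestors[[1]], "g", with_compounds = FALSE)) {
    ancestors <- c(ancestors, list(apply_event(ancestors[[1]], ev)))
  }
  a2 <- apply_event(ancestors[[2]], tag_event("DUP", "g", c(1, 2)))
  a3 <- apply_event(ancestors[[3]], tag_event("INV", "g", c(1, 1)))
  ancestors <- c(ancestors, list(a2, a3))

  n_checked <- 0L
  for (anc in ancestors) {
    if (length(anc$orders[["g"]]$ids) > 4L) next
    for (ev in enumerate_forward_events(anc, "g")) {
      child <- apply_event(anc, ev)
      P <- multidiltag:::forest_from_gene_tree(child$tree)$parent
      o <- child$orders[["g"]]
      type <- if (!is.null(ev$deleted_subspan)) "CDUP" else ev$type
      preds <- run_operator(type, o$ids, o$signs, P)
      # soundness: every proposal replays to the child exactly
      for (pr in preds) {
        ps <- build_pred_state(child, pr$ids, pr$signs, pr$event)
        replayed <- apply_event(ps, pr$event)
        expect_true(states_equal(replayed, child))
      }
      # completeness: the event we applied is among the undos
      hit <- FALSE
      for (pr in preds) {
        if (event_key(pr$event) != event_key(ev)) next
        ps <- build_pred_state(child, pr$ids, pr$signs, pr$event)
        if (states_equal(ps, anc)) { hit <- TRUE; break }
      }
      expect_true(hit)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 100L)
})

test_that("neighbourhood sizes respect the published complexity bounds", {
  set.seed(13)
  for (i in 1:10) {
    cfg <- named_design("fig7", leaves = 2)
    sim <- simulate_history(cfg, seed = 500 + i)
    o <- sim$leaf_orders[[1]]
    n <- length(o$ids)
    if (n > 12L) next
    P <- multidiltag:::forest_from_gene_tree(sim$gene_tree)$parent
    nd <- length(run_operator("DUP", o$ids, o$signs, P)) +
      length(run_operator("INV_DUP", o$ids, o$signs, P))
    expect_lte(nd, 4L * n)
    expect_identical(length(run_operator("INV", o$ids, o$signs, P)),
                     as.integer(n * (n + 1) / 2))
    expect_lte(length(run_operator("CDUP", o$ids, o$signs, P)), 8L * n^2)
  }
})
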