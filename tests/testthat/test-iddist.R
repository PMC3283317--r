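go <- function(ids, signs) gene_order("g", ids, signs)

test_that("ID distance handles identity, single deletions and single inversions", {
  x <- go(c("a", "b", "c"), c(1L, -1L, 1L))
  expect_identical(id_distance(x, x)$distance, 0L)

  d1 <- id_distance(go(c("a", "b"), c(1L, 1L)), go("a", 1L))
  expect_identical(d1$distance, 1L)
  expect_identical(d1$events[[1]]$type, "DEL")

  d2 <- id_distance(x, go(c("a", "b", "c"), c(1L, 1L, 1L)))
  expect_identical(d2$distance, 1L)
  expect_identical(d2$events[[1]]$type, "INV")

  expect_error(id_distance(go("a", 1L), go("z", 1L)),
               class = "multidiltag_bad_iddist")
})

test_that("realizing event lists replay the source order into the target", {
  set.seed(23)
  for (i in 1:60) {
    n <- sample(2:7, 1)
    x <- go(letters[1:n], sample(c(-1L, 1L), n, TRUE))
    keep <- sort(sample(n, sample(seq_len(n), 1)))
    y <- go(letters[keep][sample(length(keep))],
            sample(c(-1L, 1L), length(keep), TRUE))
    d <- id_distance(x, y)
    cur <- list(ids = x$ids, signs = x$signs)
    for (ev in d$events) {
      cur <- multidiltag:::id_apply_op(cur$ids, cur$signs,
                                       list(op = ev$type, span = ev$span))
    }
    expect_identical(cur$ids, y$ids)
    expect_identical(cur$signs, y$signs)
  }
})

test_that("exact distances agree with an independent iterative-deepening oracle", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(2:5, 1)
    x <- go(letters[1:n], sample(c(-1L, 1L), n, TRUE))
    # derive y by a few random ops so true distances stay small
    cur <- list(ids = x$ids, signs = x$signs)
    for (k in seq_len(sample(0:3, 1))) {
      nn <- length(cur$ids)
      if (nn > 1 && runif(1) < 0.3) {
        p <- sample(nn - 1L, 1)
        cur <- multidiltag:::id_apply_op(cur$ids, cur$signs,
                                         list(op = "DEL", span = c(p, p)))
      } else {
        p <- sample(nn, 1); q <- sample(p:nn, 1)
        cur <- multidiltag:::id_apply_op(cur$ids, cur$signs,
                                         list(op = "INV", span = c(p, q)))
      }
    }
    y <- go(cur$ids, cur$signs)
    got <- id_distance(x, y)
    expect_true(got$exact)
    expect_identical(got$distance, as.integer(oracle_id_distance(x, y)))
  }
})

test_that("above the exact bound the value is an upper bound, never below", {
  set.seed(37)
  for (i in 1:25) {
    n <- 9L   # above the default exact bound of 8
    x <- go(letters[1:n], sample(c(-1L, 1L), n, TRUE))
    cur <- list(ids = x$ids, signs = x$signs)
    for (k in 1:2) {
      nn <- length(cur$ids)
      p <- sample(nn, 1); q <- sample(p:nn, 1)
      cur <- multidiltag:::id_apply_op(cur$ids, cur$signs,
                                       list(op = "INV", span = c(p, q)))
    }
    y <- go(cur$ids, cur$signs)
    heur <- id_distance(x, y)             # heuristic path (length 9 > 8)
    exact <- id_distance(x, y, exact_bound = 12L)
    expect_gte(heur$distance, exact$distance)
    expect_true(exact$exact)
    expect_lte(exact$distance, 2L)
  }
})
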