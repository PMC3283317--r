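# Inversions+Deletions (ID) distance ---------------------------------------
#
# The minimum number of inversions plus deletions transforming a signed
# gene order x into a signed gene order y whose gene content is a subset of
# x's.  Speciation edges of the multi-species solution graph are labelled
# with this distance.
#
# Strategy: an upper-bound schedule is built first (delete each maximal run
# of genes absent from y, then sort the remainder into y by a greedy
# signed-reversal schedule).  For orders up to `exact_bound` genes a
# breadth-first search over signed orders then looks for anything shorter;
# since the BFS is complete up to one level below the upper bound, the
# returned distance is exact whenever the search was not truncated by the
# state cap.  Beyond the bound the upper-bound schedule is reported as a
# documented heuristic.

#' Inversions+deletions distance between two signed orders
#'
#' @param x,y [gene_order()] objects, or lists with `ids` and `signs`.
#'   `y`'s genes must all be present in `x`.
#' @param exact_bound maximum length of `x` for which the exact BFS is run;
#'   longer instances report an upper bound (`exact = FALSE`).
#' @param max_states safety cap on BFS states explored.
#' @param with_events also return one realizing event list (INV/DEL
#'   [tag_event()]s with genome taken from `x`).
#' @return list with `distance`, `exact` (logical), and (if requested)
#'   `events`, applied left to right.
#' @examples
#' x <- gene_order("g", c("a", "b"), c(1L, 1L))
#' y <- gene_order("g", "a", 1L)
#' id_distance(x, y)$distance  # 1 (one deletion)
#' @export
id_distance <- function(x, y, exact_bound = 8L, max_states = 2e5,
                        with_events = TRUE) {
  gx <- if (inherits(x, "gene_order")) x$genome else "x"
  if (!all(y$ids %in% x$ids)) {
    abort("y contains a gene absent from x", class = "multidiltag_bad_iddist")
  }
  up <- id_heuristic(x$ids, x$signs, y$ids, y$signs)
  out <- list(distance = up$distance, exact = TRUE, ops = up$ops)
  if (up$distance > 0L) {
    if (length(x$ids) <= exact_bound) {
      bfs <- id_search(x$ids, x$signs, y$ids, y$signs,
                      max_depth = up$distance - 1L, max_states = max_states)
      if (!is.null(bfs$found)) {
        out <- list(distance = bfs$found$distance, exact = TRUE,
                    ops = bfs$found$ops)
      } else if (bfs$truncated) {
        out$exact <- FALSE    # state cap hit: upper bound not certified
      }
    } else {
      out$exact <- FALSE
    }
  }
  list(distance = out$distance, exact = out$exact,
       events = if (with_events) id_ops_to_events(out$ops, gx))
}

# ops are lists: list(op = "INV"/"DEL", span = c(p, q)), applied sequentially.
id_ops_to_events <- function(ops, genome) {
  lapply(ops, function(o) tag_event(o$op, genome, span = o$span))
}

id_apply_op <- function(ids, signs, op) {
  p <- op$span[1]; q <- op$span[2]
  if (op$op == "INV") {
    ids[p:q] <- rev(ids[p:q])
    signs[p:q] <- rev(-signs[p:q])
  } else {
    ids <- ids[-(p:q)]
    signs <- signs[-(p:q)]
  }
  list(ids = ids, signs = signs)
}

# Exact search front end: bidirectional meet-in-the-middle when few genes
# are absent from the target (the usual speciation-edge case), otherwise a
# plain forward BFS.  Both are complete up to max_depth.
id_search <- function(xi, xs, yi, ys, max_depth, max_states) {
  if (length(setdiff(xi, yi)) <= 3L) {
    id_mitm(xi, xs, yi, ys, max_depth, max_states)
  } else {
    id_bfs(xi, xs, yi, ys, max_depth, max_states)
  }
}

# Bidirectional breadth-first search.  The forward side applies inversions
# and deletions of runs of absent genes; the backward side (from y) applies
# inversions and reinsertions of absent runs (the preimages of deletions).
# Frontiers are expanded level by level, balanced by depth, so every path
# of length <= depthF + depthB has been detected once those depths are
# reached.
id_mitm <- function(xi, xs, yi, ys, max_depth, max_states) {
  nx <- length(xi)
  code <- setNames(seq_len(nx), xi)
  sig_of <- function(v) if (length(v)) intToUtf8(v + nx + 1L) else ""
  start <- unname(code[xi] * xs)
  target <- unname(code[yi] * ys)
  if (identical(start, target)) {
    return(list(found = list(distance = 0L, ops = list()), truncated = FALSE))
  }
  if (max_depth < 1L) return(list(found = NULL, truncated = FALSE))
  absent <- setdiff(seq_len(nx), unname(code[yi]))

  # node stores: v, parent index (own side), op
  nodesF <- list(list(v = start, parent = 0L, op = NULL, depth = 0L))
  nodesB <- list(list(v = target, parent = 0L, op = NULL, depth = 0L))
  seenF <- new.env(parent = emptyenv()); assign(sig_of(start), 1L, envir = seenF)
  seenB <- new.env(parent = emptyenv()); assign(sig_of(target), 1L, envir = seenB)
  frontF <- 1L; frontB <- 1L
  depthF <- 0L; depthB <- 0L
  best <- NULL   # list(total, fi, bi)
  nseen <- 2L; truncated <- FALSE

  moves_forward <- function(v) {
    n <- length(v)
    out <- list()
    for (p in seq_len(n)) {
      for (q in p:n) {
        w <- v; w[p:q] <- -w[q:p]
        out[[length(out) + 1L]] <- list(w = w, op = list(op = "INV", span = c(p, q)))
      }
    }
    is_abs <- abs(v) %in% absent
    if (any(is_abs)) {
      for (p in seq_len(n)) {
        if (!is_abs[p]) next
        q <- p
        while (q <= n && is_abs[q]) {
          if (q - p + 1L < n || !length(target)) {
            out[[length(out) + 1L]] <-
              list(w = v[-(p:q)], op = list(op = "DEL", span = c(p, q)))
          }
          q <- q + 1L
        }
      }
    }
    out
  }

  insertable <- function(v) absent[!absent %in% abs(v)]

  moves_backward <- function(v) {
    # preimages: u such that one op on u yields v
    n <- length(v)
    out <- list()
    for (p in seq_len(n)) {
      for (q in p:n) {
        w <- v; w[p:q] <- -w[q:p]
        out[[length(out) + 1L]] <- list(w = w, op = list(op = "INV", span = c(p, q)))
      }
    }
    miss <- insertable(v)
    if (length(miss)) {
      blocks <- list()
      for (g in miss) blocks <- c(blocks, list(g), list(-g))
      if (length(miss) >= 2L) {
        for (g1 in miss) for (g2 in setdiff(miss, g1)) {
          for (s1 in c(1L, -1L)) for (s2 in c(1L, -1L)) {
            blocks <- c(blocks, list(c(g1 * s1, g2 * s2)))
          }
        }
      }
      if (length(miss) >= 3L) {
        perms3 <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
        for (pp in perms3) {
          gs <- miss[pp]
          for (s1 in c(1L,-1L)) for (s2 in c(1L,-1L)) for (s3 in c(1L,-1L)) {
            blocks <- c(blocks, list(gs * c(s1, s2, s3)))
          }
        }
      }
      for (bl in blocks) {
        r <- length(bl)
        for (pos in 0:n) {
          w <- append(v, bl, after = pos)
          out[[length(out) + 1L]] <-
            list(w = w, op = list(op = "DEL", span = c(pos + 1L, pos + r)))
        }
      }
    }
    out
  }

  expand <- function(side) {
    if (side == "F") {
      nodes <- nodesF; seen <- seenF; front <- frontF; other <- seenB
      mk <- moves_forward; depth <- depthF + 1L
    } else {
      nodes <- nodesB; seen <- seenB; front <- frontB; other <- seenF
      mk <- moves_backward; depth <- depthB + 1L
    }
    newfront <- integer(0)
    for (i in front) {
      for (mv in mk(nodes[[i]]$v)) {
        sig <- sig_of(mv$w)
        if (exists(sig, envir = seen, inherits = FALSE)) next
        nodes[[length(nodes) + 1L]] <-
          list(v = mv$w, parent = i, op = mv$op, depth = depth)
        idx <- length(nodes)
        assign(sig, idx, envir = seen)
        newfront <- c(newfront, idx)
        nseen <<- nseen + 1L
        if (nseen > max_states) {
          truncated <<- TRUE
        } else if (exists(sig, envir = other, inherits = FALSE)) {
          oidx <- get(sig, envir = other)
          ototal <- if (side == "F") depth + nodesB[[oidx]]$depth else
            nodesF[[oidx]]$depth + depth
          cand <- if (side == "F") list(total = ototal, fi = idx, bi = oidx) else
            list(total = ototal, fi = oidx, bi = idx)
          if (is.null(best) || cand$total < best$total) best <<- cand
        }
        if (truncated) break
      }
      if (truncated) break
    }
    if (side == "F") {
      nodesF <<- nodes; frontF <<- newfront; depthF <<- depth
    } else {
      nodesB <<- nodes; frontB <<- newfront; depthB <<- depth
    }
  }

  while (!truncated) {
    t <- depthF + depthB
    if (!is.null(best) && best$total <= t) break
    if (t >= max_depth) break
    if (!length(frontF) && !length(frontB)) break
    side <- if (!length(frontB)) "F" else if (!length(frontF)) "B" else
      if (depthF <= depthB) "F" else "B"
    if (side == "F" && !length(frontF)) break
    if (side == "B" && !length(frontB)) break
    expand(side)
  }
  # A meet at total t is certified minimal once depthF+depthB >= t (or one
  # side is fully explored); a truncated search certifies nothing.
  if (!truncated && !is.null(best) && best$total <= max_depth &&
      (best$total <= depthF + depthB || !length(frontF) || !length(frontB))) {
    opsF <- list()
    i <- best$fi
    while (nodesF[[i]]$depth > 0L) {
      opsF <- c(list(nodesF[[i]]$op), opsF)
      i <- nodesF[[i]]$parent
    }
    opsB <- list()
    i <- best$bi
    while (nodesB[[i]]$depth > 0L) {
      opsB <- c(opsB, list(nodesB[[i]]$op))
      i <- nodesB[[i]]$parent
    }
    return(list(found = list(distance = best$total, ops = c(opsF, opsB)),
                truncated = FALSE))
  }
  list(found = NULL, truncated = truncated)
}

# Complete BFS up to max_depth over integer-encoded signed orders.
# Returns list(found = NULL or list(distance, ops), truncated = logical).
# States are byte-encoded (one UTF-8 code point per signed gene) and path
# reconstruction uses per-level parent pointers.
id_bfs <- function(xi, xs, yi, ys, max_depth, max_states) {
  nx <- length(xi)
  code <- setNames(seq_len(nx), xi)
  start <- unname(code[xi] * xs)
  sig_of <- function(v) if (length(v)) intToUtf8(v + nx + 1L) else ""
  target <- sig_of(unname(code[yi] * ys))
  absent <- setdiff(seq_len(nx), unname(code[yi]))
  if (identical(sig_of(start), target)) {
    return(list(found = list(distance = 0L, ops = list()), truncated = FALSE))
  }
  if (max_depth < 1L) return(list(found = NULL, truncated = FALSE))
  seen <- new.env(parent = emptyenv())
  assign(sig_of(start), TRUE, envir = seen)
  levels <- list(list(states = list(start), parent = 0L, op = list()))
  frontier <- list(start)
  fr_parent <- integer(0)
  fr_op <- list()
  nseen <- 1L
  truncated <- FALSE

  reconstruct <- function(depth, parent, op) {
    ops <- list(op)
    d <- depth - 1L
    while (d >= 1L) {
      lv <- levels[[d + 1L]]
      ops <- c(list(lv$op[[parent]]), ops)
      parent <- lv$parent[parent]
      d <- d - 1L
    }
    ops
  }

  for (depth in seq_len(max_depth)) {
    nxt <- list(); nxt_parent <- integer(0); nxt_op <- list()
    for (si in seq_along(frontier)) {
      v <- frontier[[si]]
      n <- length(v)
      is_abs <- abs(v) %in% absent
      moves <- vector("list", 0L)
      for (p in seq_len(n)) {
        for (q in p:n) {
          w <- v
          w[p:q] <- -w[q:p]
          moves[[length(moves) + 1L]] <- list(w = w, op = list(op = "INV", span = c(p, q)))
        }
      }
      if (any(is_abs)) {
        for (p in seq_len(n)) {
          if (!is_abs[p]) next
          q <- p
          while (q <= n && is_abs[q]) {
            if (q - p + 1L < n || !length(yi)) {
              moves[[length(moves) + 1L]] <-
                list(w = v[-(p:q)], op = list(op = "DEL", span = c(p, q)))
            }
            q <- q + 1L
          }
        }
      }
      for (mv in moves) {
        sig <- sig_of(mv$w)
        if (identical(sig, target)) {
          return(list(found = list(distance = depth,
                                   ops = reconstruct(depth, si, mv$op)),
                      truncated = FALSE))
        }
        if (!exists(sig, envir = seen, inherits = FALSE)) {
          assign(sig, TRUE, envir = seen)
          nseen <- nseen + 1L
          if (nseen > max_states) return(list(found = NULL, truncated = TRUE))
          nxt[[length(nxt) + 1L]] <- mv$w
          nxt_parent <- c(nxt_parent, si)
          nxt_op[[length(nxt_op) + 1L]] <- mv$op
        }
      }
    }
    if (!length(nxt)) break
    levels[[depth + 1L]] <- list(states = nxt, parent = nxt_parent, op = nxt_op)
    frontier <- nxt
    fr_parent <- nxt_parent
    fr_op <- nxt_op
  }
  list(found = NULL, truncated = FALSE)
}

# Upper-bound schedule: delete maximal runs of absent genes in place, then
# sort the remainder into y by signed reversals.  Two reversal schedules are
# tried - a breakpoint-descent (apply the reversal that removes the most
# breakpoints while it keeps making progress) and a positional greedy
# fallback - and the shorter one is kept.  Never below the exact distance.
id_heuristic <- function(xi, xs, yi, ys) {
  ops <- list()
  is_abs <- !(xi %in% yi)
  runs <- rle(is_abs)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  del <- which(runs$values)
  for (i in rev(del)) {     # right-to-left so earlier spans stay valid
    ops[[length(ops) + 1L]] <- list(op = "DEL", span = c(starts[i], ends[i]))
  }
  v <- encode_signed(xi[!is_abs], xs[!is_abs], yi)
  w <- encode_signed(yi, ys, yi)
  inv1 <- reversal_descent_schedule(v, w)
  inv2 <- reversal_positional_schedule(v, w)
  inv <- if (length(inv1) <= length(inv2)) inv1 else inv2
  c(ops, inv) -> ops
  list(distance = length(ops), ops = ops)
}

encode_signed <- function(ids, signs, ref) {
  unname(match(ids, ref) * signs)
}

# breakpoint machinery on integer-coded signed orders; sentinels are
# m+1 (start) and m+2 (end) where m = length of the target
bp_good_env <- function(w) {
  m <- length(w)
  ww <- c(m + 1L, w, m + 2L)
  good <- new.env(parent = emptyenv())
  for (j in seq_len(m + 1L)) {
    assign(paste(ww[j], ww[j + 1L]), TRUE, envir = good)
    assign(paste(-ww[j + 1L], -ww[j]), TRUE, envir = good)
  }
  good
}

# Schedule A: steepest-descent on breakpoints; stops when no reversal
# removes a breakpoint, finishing with the positional schedule if needed.
reversal_descent_schedule <- function(v, w) {
  m <- length(w)
  good <- bp_good_env(w)
  attr(good, "start") <- m + 1L
  attr(good, "end") <- m + 2L
  is_good <- function(a, b) exists(paste(a, b), envir = good, inherits = FALSE)
  ops <- list()
  guard <- 0L
  while (!identical(v, w)) {
    guard <- guard + 1L
    if (guard > 3L * m + 6L) break
    n <- length(v)
    vv <- c(m + 1L, v, m + 2L)
    best <- NULL; best_delta <- 0L
    for (p in seq_len(n)) {
      for (q in p:n) {
        old <- is_good(vv[p], vv[p + 1L]) + is_good(vv[q + 1L], vv[q + 2L])
        new <- is_good(vv[p], -vv[q + 1L]) + is_good(-vv[p + 1L], vv[q + 2L])
        delta <- new - old
        if (delta > best_delta) { best_delta <- delta; best <- c(p, q) }
      }
    }
    if (is.null(best)) break
    p <- best[1]; q <- best[2]
    v[p:q] <- -v[q:p]
    ops[[length(ops) + 1L]] <- list(op = "INV", span = c(p, q))
  }
  if (!identical(v, w)) {
    ops <- c(ops, reversal_positional_schedule(v, w))
  }
  ops
}

# Schedule B: positional greedy - bring the target's i-th gene into place,
# then fix its sign; at most two reversals per position.
reversal_positional_schedule <- function(v, w) {
  ops <- list()
  for (i in seq_along(w)) {
    j <- match(abs(w[i]), abs(v))
    if (j != i) {
      ops[[length(ops) + 1L]] <- list(op = "INV", span = c(i, j))
      v[i:j] <- -v[j:i]
    }
    if (v[i] != w[i]) {
      ops[[length(ops) + 1L]] <- list(op = "INV", span = c(i, i))
      v[i] <- -v[i]
    }
  }
  ops
}
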