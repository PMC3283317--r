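# Independent oracles used to cross-check the package's algorithms.  These
# reimplement the forward model, reconciliation scoring and ID distance
# from first principles on small instances; they share no machinery with
# the package's search code.

# --- forward-search oracle (minimum history cost) ---------------------------
#
# States carry a signed order of node ids plus a parent vector describing
# the gene tree grown so far.  Events are applied forward from the single
# ancestral gene; a Dijkstra over canonical state fingerprints returns the
# cheapest cost at which the target ordered gene tree is reached.

omk_start <- function(sign = 1L) {
  list(order = 1L, signs = sign, parent = c(0L), nextid = 2L)
}

ocanon <- function(st) {
  kids <- split(seq_along(st$parent), st$parent)
  posof <- integer(length(st$parent))
  posof[st$order] <- seq_along(st$order)
  ser <- function(v) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) return(as.character(posof[v]))
    paste0("(", paste(sort(vapply(ch, ser, character(1))), collapse = ","), ")")
  }
  roots <- which(st$parent == 0L)
  paste(paste(st$signs, collapse = ","), ser(roots[1]), sep = "|")
}

oapply <- function(st, type, p, q, variant = NULL, del = NULL) {
  m <- q - p + 1L
  anc <- st$order[p:q]
  l <- st$nextid + seq_len(m) - 1L
  r <- st$nextid + m + seq_len(m) - 1L
  if (type == "INV") {
    st$order[p:q] <- rev(st$order[p:q])
    st$signs[p:q] <- rev(-st$signs[p:q])
    return(st)
  }
  st$nextid <- st$nextid + 2L * m
  st$parent <- c(st$parent, rep(0L, 2L * m))
  st$parent[l] <- anc
  st$parent[r] <- anc
  s <- st$signs[p:q]
  if (type == "DUP") {
    seg_o <- c(l, r); seg_s <- c(s, s)
  } else if (variant == "left") {
    seg_o <- c(rev(l), r); seg_s <- c(rev(-s), s)
  } else {
    seg_o <- c(l, rev(r)); seg_s <- c(s, rev(-s))
  }
  st$order <- append(st$order[-(p:q)], seg_o, after = p - 1L)
  st$signs <- append(st$signs[-(p:q)], seg_s, after = p - 1L)
  if (!is.null(del)) {
    for (pos in del[2]:del[1]) {     # right to left
      leaf <- st$order[pos]
      par <- st$parent[leaf]
      sib <- setdiff(which(st$parent == par), leaf)
      st$parent[sib] <- st$parent[par]
      st$parent[c(leaf, par)] <- -1L  # detached
      st$order <- st$order[-pos]
      st$signs <- st$signs[-pos]
    }
  }
  st
}

# All forward moves with their costs (duplication repertoire + compounds).
omoves <- function(st, costs, with_compounds = TRUE) {
  n <- length(st$order)
  al <- costs$alpha; be <- costs$beta
  out <- list()
  add <- function(st2, cost) out[[length(out) + 1L]] <<- list(st = st2, cost = cost)
  for (p in seq_len(n)) {
    for (q in p:n) {
      m <- q - p + 1L
      add(oapply(st, "DUP", p, q), al[["dup"]] + m * be[["dup"]])
      add(oapply(st, "INV_DUP", p, q, "left"), al[["inv_dup"]] + m * be[["inv_dup"]])
      add(oapply(st, "INV_DUP", p, q, "right"), al[["inv_dup"]] + m * be[["inv_dup"]])
      add(oapply(st, "INV", p, q), al[["inv"]] + m * be[["inv"]])
      if (with_compounds && m >= 2L) {
        for (off in c(p - 1L, p - 1L + m)) {
          for (s in seq_len(m)) {
            for (e in s:m) {
              k <- e - s + 1L
              if (k >= m) next
              cost <- al[["dup"]] + m * be[["dup"]] + al[["del"]] + k * be[["del"]]
              add(oapply(st, "DUP", p, q, del = c(off + s, off + e)), cost)
              costi <- al[["inv_dup"]] + m * be[["inv_dup"]] + al[["del"]] + k * be[["del"]]
              add(oapply(st, "INV_DUP", p, q, "left", del = c(off + s, off + e)), costi)
              add(oapply(st, "INV_DUP", p, q, "right", del = c(off + s, off + e)), costi)
            }
          }
        }
      }
    }
  }
  out
}

# Canonical fingerprint of a package single-genome state, in the oracle's
# format, so oracle states can be compared against the target.
ocanon_of_state <- function(state, genome) {
  o <- state$orders[[genome]]
  tree <- state$tree
  posof <- setNames(seq_along(o$ids), o$ids)
  ser <- function(v) {
    ch <- tree$children[[v]]
    if (!length(ch)) return(as.character(unname(posof[tree$label[v]])))
    paste0("(", paste(sort(vapply(ch, ser, character(1))), collapse = ","), ")")
  }
  paste(paste(o$signs, collapse = ","), ser(tree$root), sep = "|")
}

# Dijkstra from the single ancestral gene to the target state.
# The ancestral single gene may have either orientation; take the best.
oracle_min_cost <- function(target_state, genome, costs, bound,
                            with_compounds = TRUE) {
  min(oracle_min_cost_signed(target_state, genome, costs, bound, 1L,
                             with_compounds),
      oracle_min_cost_signed(target_state, genome, costs, bound, -1L,
                             with_compounds))
}

oracle_min_cost_signed <- function(target_state, genome, costs, bound, sign,
                                   with_compounds = TRUE) {
  target <- ocanon_of_state(target_state, genome)
  ntarget <- length(target_state$orders[[genome]]$ids)
  start <- omk_start(sign)
  seen <- new.env(parent = emptyenv())
  frontier <- list(list(st = start, cost = 0))
  assign(ocanon(start), 0, envir = seen)
  while (length(frontier)) {
    cst <- vapply(frontier, `[[`, numeric(1), "cost")
    i <- which.min(cst)
    cur <- frontier[[i]]
    frontier <- frontier[-i]
    key <- ocanon(cur$st)
    if (get(key, envir = seen) < cur$cost) next
    if (identical(key, target)) return(cur$cost)
    if (cur$cost >= bound) next
    for (mv in omoves(cur$st, costs, with_compounds)) {
      if (length(mv$st$order) > ntarget) next   # orders never shrink forward
      c2 <- cur$cost + mv$cost
      if (c2 > bound) next
      k2 <- ocanon(mv$st)
      old <- if (exists(k2, envir = seen, inherits = FALSE)) get(k2, envir = seen) else Inf
      if (c2 < old) {
        assign(k2, c2, envir = seen)
        frontier[[length(frontier) + 1L]] <- list(st = mv$st, cost = c2)
      }
    }
  }
  Inf
}

# --- brute-force reconciliation oracle --------------------------------------
#
# Enumerates every valid mapping of gene-tree internal vertices into the
# species tree (each vertex at or above the LCA of its children's images)
# and scores duplications + losses directly from the embedding.

oracle_min_dup_loss <- function(gene_tree, species_tree, leaf_genome) {
  sleaf <- setNames(multidiltag:::tree_leaves(species_tree),
                    multidiltag:::tree_leaf_labels(species_tree))
  sdepth <- multidiltag:::tree_depths(species_tree)
  nT <- multidiltag:::tree_n_vertices(gene_tree)
  glv <- multidiltag:::tree_leaves(gene_tree)
  internal <- setdiff(seq_len(nT), glv)
  fixed <- integer(nT)
  fixed[glv] <- sleaf[leaf_genome[gene_tree$label[glv]]]
  ancestors <- function(v) {
    out <- v
    while (species_tree$parent[v] != 0L) { v <- species_tree$parent[v]; out <- c(out, v) }
    out
  }
  post <- multidiltag:::tree_postorder(gene_tree)
  post_int <- post[post %in% internal]
  sdist <- function(a, b) abs(sdepth[a] - sdepth[b])
  in_subtree <- function(anc, v) multidiltag:::tree_is_ancestor(species_tree, anc, v)

  best <- Inf
  assignv <- integer(nT); assignv[glv] <- fixed[glv]
  recur <- function(i) {
    if (i > length(post_int)) {
      score <- 0L
      for (v in post_int) {
        ch <- gene_tree$children[[v]]
        a <- assignv[ch[1]]; b <- assignv[ch[2]]
        sv <- assignv[v]
        schild <- species_tree$children[[sv]]
        spec <- length(schild) == 2L &&
          ((in_subtree(schild[1], a) && in_subtree(schild[2], b)) ||
           (in_subtree(schild[2], a) && in_subtree(schild[1], b)))
        dup <- !spec
        score <- score + dup
        for (c in ch) {
          score <- score + sdist(sv, assignv[c]) - 1L + dup
        }
      }
      best <<- min(best, score)
      return(invisible())
    }
    v <- post_int[i]
    ch <- gene_tree$children[[v]]
    lca <- multidiltag:::tree_lca(species_tree, assignv[ch[1]], assignv[ch[2]],
                                  depths = sdepth)
    for (img in ancestors(lca)) {
      assignv[v] <<- img
      recur(i + 1L)
    }
    invisible()
  }
  recur(1L)
  best
}

# --- ID-distance oracle -----------------------------------------------------
#
# Plain iterative-deepening DFS over inversions and deletions of runs of
# genes absent from the target.  Exponential but fine at toy sizes.

oracle_id_distance <- function(x, y, max_d = 8L) {
  absent <- setdiff(x$ids, y$ids)
  tgt <- paste(ifelse(y$signs > 0, y$ids, paste0("-", y$ids)), collapse = " ")
  keyof <- function(ids, signs) {
    paste(ifelse(signs > 0, ids, paste0("-", ids)), collapse = " ")
  }
  dfs <- function(ids, signs, depth) {
    if (identical(keyof(ids, signs), tgt)) return(TRUE)
    if (depth == 0L) return(FALSE)
    n <- length(ids)
    for (p in seq_len(n)) {
      for (q in p:n) {
        i2 <- ids; s2 <- signs
        i2[p:q] <- rev(i2[p:q]); s2[p:q] <- rev(-s2[p:q])
        if (dfs(i2, s2, depth - 1L)) return(TRUE)
      }
    }
    isabs <- ids %in% absent
    for (p in seq_len(n)) {
      if (!isabs[p]) next
      q <- p
      while (q <= n && isabs[q]) {
        if (q - p + 1L < n || !length(y$ids)) {
          if (dfs(ids[-(p:q)], signs[-(p:q)], depth - 1L)) return(TRUE)
        }
        q <- q + 1L
      }
    }
    FALSE
  }
  for (d in 0:max_d) {
    if (dfs(x$ids, x$signs, d)) return(d)
  }
  Inf
}
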