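# Shared fixtures and state utilities (built in code; no stored data).

gt3 <- function() read_newick_tree("(g|a,(g|b,g|c));", "gene")

mk_state <- function(newick, ids, signs, genome = "g") {
  tag_state(read_newick_tree(newick, "gene"),
            gene_order(genome, ids, signs))
}

rename_leaf <- function(tree, from, to) {
  if (from == to) return(tree)
  v <- multidiltag:::tree_find_leaf(tree, from)
  tree$label[v] <- to
  tree
}

# Canonical fingerprint of a state: per-genome sign strings plus the gene
# tree topology with leaves renamed to "<genome>#<position>".
canon_state <- function(state) {
  gs <- sort(names(state$orders))
  map <- character(0)
  parts <- character(0)
  for (g in gs) {
    o <- state$orders[[g]]
    if (length(o$ids)) map[o$ids] <- paste0(g, "#", seq_along(o$ids))
    parts <- c(parts, paste0(g, ":", paste(o$signs, collapse = ",")))
  }
  paste(paste(parts, collapse = ";"),
        multidiltag:::tree_canon(state$tree,
                                 relabel = function(x) unname(map[x])),
        sep = "|")
}

states_equal <- function(a, b) identical(canon_state(a), canon_state(b))

# Rebuild the predecessor ordered gene tree implied by an undo proposal
# (predecessor order + forward event), starting from the child state.  Used
# to replay-validate every neighbourhood proposal.
build_pred_state <- function(child, pred_ids, pred_signs, event) {
  tree <- child$tree
  genome <- event$genome
  if (event$type %in% c("DUP", "INV_DUP")) {
    cl <- event$child_labels
    p <- event$span[1]
    for (x in seq_along(cl$left)) {
      l <- cl$left[x]; r <- cl$right[x]
      anc <- pred_ids[p + x - 1]
      ldel <- grepl(":del$", l); rdel <- grepl(":del$", r)
      if (!ldel && !rdel) {
        tree <- multidiltag:::tree_drop_leaves(tree, r)
        tree <- rename_leaf(tree, l, anc)
      } else if (ldel) {
        tree <- rename_leaf(tree, r, anc)
      } else {
        tree <- rename_leaf(tree, l, anc)
      }
    }
  }
  orders <- child$orders
  orders[[genome]] <- gene_order(genome, pred_ids, pred_signs)
  tag_state(tree, orders)
}

# Every forward event applicable to one genome of a state, in the search's
# event repertoire: duplications, inverted duplications, inversions, and
# duplication-with-deletion compounds (run inside one copy block).
enumerate_forward_events <- function(state, genome, with_compounds = TRUE) {
  n <- length(state$orders[[genome]]$ids)
  evs <- list()
  add <- function(e) evs[[length(evs) + 1L]] <<- e
  for (p in seq_len(n)) {
    for (q in p:n) {
      m <- q - p + 1L
      add(tag_event("DUP", genome, c(p, q)))
      add(tag_event("INV_DUP", genome, c(p, q), variant = "left"))
      add(tag_event("INV_DUP", genome, c(p, q), variant = "right"))
      add(tag_event("INV", genome, c(p, q)))
      if (with_compounds && m >= 2L) {
        for (off in c(p - 1L, p - 1L + m)) {          # block A / block B
          for (s in seq_len(m)) {
            for (e in s:m) {
              if (e - s + 1L >= m) next               # keep one survivor
              add(tag_event("DUP", genome, c(p, q),
                            deleted_subspan = c(off + s, off + e)))
              add(tag_event("INV_DUP", genome, c(p, q), variant = "left",
                            deleted_subspan = c(off + s, off + e)))
              add(tag_event("INV_DUP", genome, c(p, q), variant = "right",
                            deleted_subspan = c(off + s, off + e)))
            }
          }
        }
      }
    }
  }
  evs
}

# Key used to match a forward event with an undone event proposal.
event_key <- function(e) {
  paste(e$type, e$span[1], e$span[2], e$variant %||% ".",
        if (is.null(e$deleted_subspan)) "." else
          paste(e$deleted_subspan, collapse = ":"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_operator <- function(type, ids, signs, P, genome = "g") {
  switch(type,
    DUP = multidiltag:::duplication_predecessors(ids, signs, P, genome),
    INV_DUP = multidiltag:::inverted_duplication_predecessors(ids, signs, P, genome),
    INV = multidiltag:::inversion_predecessors(ids, signs, P, genome),
    CDUP = multidiltag:::duplication_with_deletion_predecessors(ids, signs, P, genome)
  )
}
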