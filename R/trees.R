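#' @importFrom rlang abort warn .data %||%
#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

# Internal rooted-binary-tree container -----------------------------------
#
# Gene trees evolve by replacing leaves with cherries and by dropping leaves
# (with suppression of the resulting degree-2 vertices), operations that
# ape's edge-matrix representation is awkward to mutate through.  Trees are
# therefore held in an indexed form: parallel vectors over vertex indices,
# with `parent` (0 at the root), a `children` list (integer pairs, or
# integer(0) at leaves) and a `label` vector.  Leaf labels are the gene (or
# genome) identifiers and must be unique; internal labels are optional.

new_tag_tree <- function(parent, children, label, root) {
  structure(
    list(parent = as.integer(parent), children = children,
         label = as.character(label), root = as.integer(root)),
    class = "tag_tree"
  )
}

#' Single-leaf tree
#' @param label leaf label.
#' @return a `tag_tree` with one vertex.
#' @keywords internal
tree_single <- function(label) {
  new_tag_tree(0L, list(integer(0)), label, 1L)
}

tree_is_leaf <- function(tree, v) lengths(tree$children)[v] == 0L

tree_n_vertices <- function(tree) length(tree$parent)

tree_leaves <- function(tree) which(lengths(tree$children) == 0L)

tree_leaf_labels <- function(tree) tree$label[tree_leaves(tree)]

tree_find_leaf <- function(tree, label) {
  v <- which(tree$label == label & lengths(tree$children) == 0L)
  if (length(v) != 1L) {
    abort(sprintf("leaf '%s' not found (or not unique) in tree", label))
  }
  v
}

#' Post-order vertex sequence (children before parents)
#' @keywords internal
tree_postorder <- function(tree) {
  # iterative DFS; reversing the visit order puts children before parents
  visit <- integer(0)
  stack <- tree$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, v)
    stack <- c(stack, tree$children[[v]])
  }
  rev(visit)
}

tree_depths <- function(tree) {
  n <- tree_n_vertices(tree)
  d <- integer(n)
  for (v in rev(tree_postorder(tree))) {  # preorder
    p <- tree$parent[v]
    d[v] <- if (p == 0L) 0L else d[p] + 1L
  }
  d
}

#' Lowest common ancestor of two vertices
#' @keywords internal
tree_lca <- function(tree, a, b, depths = tree_depths(tree)) {
  while (a != b) {
    if (depths[a] >= depths[b]) a <- tree$parent[a] else b <- tree$parent[b]
  }
  a
}

tree_is_ancestor <- function(tree, anc, v) {
  # TRUE iff anc is v or an ancestor of v
  while (v != 0L) {
    if (v == anc) return(TRUE)
    v <- tree$parent[v]
  }
  FALSE
}

#' Replace a leaf by a cherry of two new leaves
#' @keywords internal
tree_replace_leaf_by_cherry <- function(tree, leaf_label, left_label, right_label) {
  v <- tree_find_leaf(tree, leaf_label)
  n <- tree_n_vertices(tree)
  l <- n + 1L; r <- n + 2L
  tree$parent <- c(tree$parent, v, v)
  tree$children <- c(tree$children, list(integer(0)), list(integer(0)))
  tree$children[[v]] <- c(l, r)
  tree$label <- c(tree$label, left_label, right_label)
  tree
}

#' Drop leaves by label, suppressing degree-2 vertices
#' @keywords internal
tree_drop_leaves <- function(tree, labels) {
  for (lab in labels) {
    v <- tree_find_leaf(tree, lab)
    p <- tree$parent[v]
    if (p == 0L) abort("cannot delete the last gene of the tree")
    sib <- setdiff(tree$children[[p]], v)
    gp <- tree$parent[p]
    # splice sibling into grandparent position (suppress p)
    tree$parent[sib] <- gp
    if (gp == 0L) {
      tree$root <- sib
    } else {
      tree$children[[gp]][tree$children[[gp]] == p] <- sib
    }
    # mark v and p dead
    tree$parent[c(v, p)] <- NA_integer_
    tree$children[[v]] <- integer(0)
    tree$children[[p]] <- integer(0)
    tree$label[c(v, p)] <- NA_character_
  }
  tree_compact(tree)
}

tree_compact <- function(tree) {
  keep <- which(!is.na(tree$parent) | seq_along(tree$parent) == tree$root)
  keep <- sort(unique(c(keep, tree$root)))
  old2new <- rep(NA_integer_, tree_n_vertices(tree))
  old2new[keep] <- seq_along(keep)
  parent <- tree$parent[keep]
  parent[!is.na(parent) & parent != 0L] <-
    old2new[parent[!is.na(parent) & parent != 0L]]
  parent[is.na(parent)] <- 0L
  children <- lapply(tree$children[keep], function(ch) old2new[ch])
  new_tag_tree(parent, children, tree$label[keep], old2new[tree$root])
}

# Canonical serialization -------------------------------------------------

#' Serialize a tree with an explicit leaf relabeling, order-preserving
#'
#' Children are sorted by their serialized form so that the string is a
#' canonical topology invariant given the leaf labels.
#' @keywords internal
tree_canon <- function(tree, relabel = identity) {
  ser <- function(v) {
    ch <- tree$children[[v]]
    if (!length(ch)) return(relabel(tree$label[v]))
    parts <- sort(vapply(ch, ser, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  ser(tree$root)
}

#' Test isomorphism of two trees under a leaf-label bijection
#'
#' @param map named character vector mapping leaf labels of `t1` to leaf
#'   labels of `t2`.
#' @keywords internal
tree_iso_mapped <- function(t1, t2, map) {
  l1 <- tree_leaf_labels(t1)
  l2 <- tree_leaf_labels(t2)
  if (length(l1) != length(l2)) return(FALSE)
  if (!all(l1 %in% names(map))) return(FALSE)
  if (!setequal(unname(map[l1]), l2)) return(FALSE)
  identical(tree_canon(t1, relabel = function(x) unname(map[x])),
            tree_canon(t2))
}

# Conversion to and from ape ----------------------------------------------

tag_tree_from_phylo <- function(phy) {
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  ntot <- nt + nn
  parent <- integer(ntot)
  children <- rep(list(integer(0)), ntot)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; c <- phy$edge[i, 2]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  if (any(lengths(children) > 0L & lengths(children) != 2L)) {
    abort("tree is not binary", class = "multidiltag_bad_tree")
  }
  label <- character(ntot)
  label[seq_len(nt)] <- phy$tip.label
  if (!is.null(phy$node.label)) label[nt + seq_len(nn)] <- phy$node.label
  root <- which(parent == 0L)
  if (length(root) != 1L) abort("tree is not rooted", class = "multidiltag_bad_tree")
  new_tag_tree(parent, children, label, root)
}

tag_tree_to_phylo <- function(tree) {
  leaves <- tree_leaves(tree)
  internal <- setdiff(seq_len(tree_n_vertices(tree)), leaves)
  old2new <- integer(tree_n_vertices(tree))
  old2new[leaves] <- seq_along(leaves)
  # ape wants the root first among internal vertices
  internal <- c(tree$root, setdiff(internal, tree$root))
  old2new[internal] <- length(leaves) + seq_along(internal)
  edges <- cbind(old2new[tree$parent[tree$parent != 0L]],
                 old2new[which(tree$parent != 0L)])
  phy <- list(edge = edges, tip.label = tree$label[leaves],
              Nnode = length(internal),
              node.label = tree$label[internal])
  class(phy) <- "phylo"
  phy
}
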