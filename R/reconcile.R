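# LCA reconciliation of a gene tree into a species tree ---------------------
#
# The reconciliation embeds the gene tree T into the species tree S: each
# internal gene vertex maps to the LCA of its children's images and is a
# duplication iff its image equals a child's image.  From the embedding we
# derive, for every species vertex A:
#
#   * the genome set G(A): the ancestral gene copies present at the moment
#     of speciation A.  A copy is either a speciation vertex of T mapping to
#     A, or a T-edge whose lineage crosses A (the copy speciates at A but
#     survives in only one descendant lineage - the other side is a loss);
#   * the pre-speciation set PG(A) (A below B): the members of G(B) whose
#     lineage continues into the branch (B, A);
#   * per-branch loss records: G(B) \ PG(A);
#   * the branch forest: a forest whose leaves are the units of G(A), whose
#     internal vertices are the duplication vertices of T assigned to the
#     branch above A, and whose roots correspond one-to-one to PG(A).  This
#     forest is the static cherry structure that the backward DILTAG search
#     on the branch works against.
#
# Unit keys: extant genes keep their gene id; a speciation vertex v at
# species vertex A is keyed "s<v>@<A>"; a crossing edge with lower endpoint
# v is keyed "x<v>@<A>".  Duplication vertices appear in forests as "d<v>".

species_vertex_names <- function(stree) {
  labs <- stree$label
  idx <- seq_along(labs)
  ifelse(is.na(labs) | labs == "", paste0("S", idx), labs)
}

#' LCA reconciliation
#'
#' @param gene_tree a `tag_tree` with a `leaf_genome` attribute (see
#'   [read_newick_tree()]), or with leaf labels that are themselves genome
#'   ids of a one-gene-per-genome family.
#' @param species_tree a `tag_tree` whose leaf labels are genome ids.
#' @param leaf_genome optional named vector gene id -> genome overriding the
#'   attribute.
#' @return an object of class `reconciliation` with the mapping, genome
#'   sets `G`, pre-speciation sets `PG`, loss records and branch forests.
#' @examples
#' gt <- read_newick_tree("((1|a,2|b),3|c);", "gene")
#' st <- read_newick_tree("((1,2)A,3)B;", "species")
#' rec <- lca_reconcile(gt, st)
#' rec$n_dup
#' @export
lca_reconcile <- function(gene_tree, species_tree, leaf_genome = NULL) {
  leaf_genome <- leaf_genome %||% attr(gene_tree, "leaf_genome")
  if (is.null(leaf_genome)) {
    abort("gene_tree carries no leaf -> genome map")
  }
  sleaf <- setNames(tree_leaves(species_tree),
                    tree_leaf_labels(species_tree))
  glv <- tree_leaves(gene_tree)
  genomes <- leaf_genome[gene_tree$label[glv]]
  if (anyNA(genomes) || !all(genomes %in% names(sleaf))) {
    abort("a gene maps to a genome absent from the species tree",
          class = "multidiltag_bad_reconciliation")
  }

  nT <- tree_n_vertices(gene_tree)
  sdepth <- tree_depths(species_tree)
  M <- integer(nT)
  M[glv] <- sleaf[genomes]
  post <- tree_postorder(gene_tree)
  is_dup <- logical(nT)
  for (v in post) {
    ch <- gene_tree$children[[v]]
    if (!length(ch)) next
    M[v] <- tree_lca(species_tree, M[ch[1]], M[ch[2]], depths = sdepth)
    is_dup[v] <- M[v] == M[ch[1]] || M[v] == M[ch[2]]
  }

  unit_key <- function(v, A) {
    if (tree_is_leaf(gene_tree, v) && M[v] == A) return(gene_tree$label[v])
    if (!tree_is_leaf(gene_tree, v) && !is_dup[v] && M[v] == A) {
      return(paste0("s", v, "@", A))
    }
    paste0("x", v, "@", A)
  }

  nS <- tree_n_vertices(species_tree)
  units <- vector("list", nS)          # per species vertex: tibble rows
  add_unit <- function(A, v, kind) {
    units[[A]][[length(units[[A]]) + 1L]] <<-
      list(key = unit_key(v, A), tvertex = v, kind = kind)
  }
  for (A in seq_len(nS)) units[[A]] <- list()

  for (v in seq_len(nT)) {
    if (tree_is_leaf(gene_tree, v)) {
      add_unit(M[v], v, "leaf")
    } else if (!is_dup[v]) {
      add_unit(M[v], v, "spec")
    }
  }
  # crossing units: edge (parent(v), v) present at every species vertex
  # strictly between the images, plus the parent's image itself when the
  # parent is a duplication (the duplication sits above that speciation)
  for (v in seq_len(nT)) {
    u <- gene_tree$parent[v]
    if (u == 0L) next
    X <- tree_lca  # placate lints; real loop below
    A <- species_tree$parent[M[v]]
    while (A != 0L && sdepth[A] > sdepth[M[u]]) {
      add_unit(A, v, "crossing")
      A <- species_tree$parent[A]
    }
    if (A == M[u] && A != 0L && is_dup[u] && M[v] != M[u]) {
      add_unit(A, v, "crossing")
    }
  }

  unit_tb <- dplyr::bind_rows(lapply(seq_len(nS), function(A) {
    if (!length(units[[A]])) return(NULL)
    tibble::tibble(
      key = vapply(units[[A]], `[[`, character(1), "key"),
      tvertex = vapply(units[[A]], `[[`, integer(1), "tvertex"),
      kind = vapply(units[[A]], `[[`, character(1), "kind"),
      species = A
    )
  }))

  svertex_of <- setNames(unit_tb$species, unit_tb$key)
  tvertex_of <- setNames(unit_tb$tvertex, unit_tb$key)
  G <- lapply(seq_len(nS), function(A) sort(unit_tb$key[unit_tb$species == A]))

  # PG sets and losses
  PG <- rep(list(character(0)), nS)
  losses <- list()
  for (B in seq_len(nS)) {
    chS <- species_tree$children[[B]]
    if (!length(chS)) next
    for (key in G[[B]]) {
      v <- tvertex_of[[key]]
      kind <- unit_tb$kind[unit_tb$key == key]
      if (kind == "spec") {
        for (A in chS) PG[[A]] <- c(PG[[A]], key)
      } else {
        # crossing: continues toward M(v)
        side <- chS[vapply(chS, function(A) tree_is_ancestor(species_tree, A, M[v]),
                           logical(1))]
        other <- setdiff(chS, side)
        PG[[side]] <- c(PG[[side]], key)
        losses[[length(losses) + 1L]] <-
          list(parent = B, child = other, key = key)
      }
    }
  }
  PG <- lapply(PG, sort)
  loss_tb <- if (length(losses)) {
    tibble::tibble(parent = vapply(losses, `[[`, integer(1), "parent"),
                   child = vapply(losses, `[[`, integer(1), "child"),
                   key = vapply(losses, `[[`, character(1), "key"))
  } else {
    tibble::tibble(parent = integer(0), child = integer(0), key = character(0))
  }

  # Branch forests (branch above each species vertex; the species root's
  # branch is the pre-root lineage back to the single ancestral gene).
  forests <- vector("list", nS)
  sroot <- species_tree$root
  for (A in seq_len(nS)) {
    leaf_keys <- G[[A]]
    dup_vs <- which(is_dup & M == A & !tree_is_leaf_vec(gene_tree))
    nodes <- c(leaf_keys, paste0("d", dup_vs, recycle0 = TRUE))
    parent <- setNames(rep(NA_character_, length(nodes)), nodes)
    top_relabel <- character(0)
    climb <- function(node_key, v) {
      u <- gene_tree$parent[v]
      if (u != 0L && is_dup[u] && M[u] == A) {
        parent[[node_key]] <<- paste0("d", u)
      } else {
        # top of the branch forest: name the unit of the parent genome set
        # this subtree descends from
        B <- if (A == sroot) 0L else species_tree$parent[A]
        root_key <- if (u == 0L || B == 0L) {
          "origin"
        } else if (!is_dup[u] && M[u] == B && !tree_is_leaf(gene_tree, u)) {
          unit_key(u, B)
        } else {
          unit_key(v, B)
        }
        top_relabel[[node_key]] <<- root_key
      }
    }
    for (key in leaf_keys) climb(key, tvertex_of[[key]])
    for (v in dup_vs) climb(paste0("d", v), v)
    children <- split(names(parent)[!is.na(parent)], parent[!is.na(parent)])
    forests[[A]] <- list(
      nodes = nodes, parent = parent, children = children,
      leaf_keys = leaf_keys, tops = names(top_relabel),
      top_relabel = top_relabel
    )
  }

  structure(list(
    gene_tree = gene_tree, species_tree = species_tree,
    leaf_genome = leaf_genome,
    M = M, is_dup = is_dup, units = unit_tb,
    G = G, PG = PG, losses = loss_tb, forests = forests,
    species_names = species_vertex_names(species_tree),
    n_dup = sum(is_dup), n_loss = nrow(loss_tb)
  ), class = "reconciliation")
}

tree_is_leaf_vec <- function(tree) lengths(tree$children) == 0L

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation: %d duplications, %d losses>\n", x$n_dup, x$n_loss))
  invisible(x)
}

#' Number of ancestral genes at a species vertex
#'
#' The size of the genome set G(A): the gene count the multi-species search
#' targets at A.  For a species leaf this equals the observed order length.
#'
#' @param rec a [lca_reconcile()] result.
#' @param vertex species vertex name (internal label, `"S<i>"`, or leaf
#'   genome id).
#' @export
ancestral_gene_count <- function(rec, vertex) {
  A <- species_vertex_index(rec, vertex)
  length(rec$G[[A]])
}

species_vertex_index <- function(rec, vertex) {
  A <- match(vertex, rec$species_names)
  if (is.na(A)) abort(sprintf("unknown species vertex '%s'", vertex))
  A
}

#' Ancestral genes lost on a species-tree branch
#'
#' Returns the unit keys of `G(parent)` lost on the branch to `child` -
#' exactly the genes the multi-species algorithm reinserts when extending
#' that branch's solution set.
#'
#' @param rec a [lca_reconcile()] result.
#' @param parent,child species vertex names of the branch.
#' @return character vector of lost unit keys.
#' @export
losses_on_branch <- function(rec, parent, child) {
  B <- species_vertex_index(rec, parent)
  A <- species_vertex_index(rec, child)
  if (!A %in% rec$species_tree$children[[B]]) {
    abort(sprintf("(%s, %s) is not a species-tree branch", parent, child))
  }
  sort(rec$losses$key[rec$losses$parent == B & rec$losses$child == A])
}

#' Per-vertex reconciliation report
#'
#' @param rec a [lca_reconcile()] result.
#' @return a tibble with one row per species vertex: its name, |G(A)|,
#'   |PG(A)| and the number of genes lost on the branch above it.
#' @export
reconciliation_report <- function(rec) {
  nS <- tree_n_vertices(rec$species_tree)
  sroot <- rec$species_tree$root
  tibble::tibble(
    vertex = rec$species_names,
    is_leaf = tree_is_leaf_vec(rec$species_tree),
    n_genes = lengths(rec$G),
    n_pre_speciation = ifelse(seq_len(nS) == sroot, NA_integer_, lengths(rec$PG)),
    n_lost_above = vapply(seq_len(nS), function(A) {
      sum(rec$losses$child == A)
    }, integer(1))
  )
}
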