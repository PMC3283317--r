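# File formats: Newick trees and signed gene-order tables -------------------

#' Read a rooted binary tree from Newick
#'
#' Gene trees must label leaves as `"<genome><sep><gene>"` (default
#' separator `"|"`); the genome part must be a leaf of the species tree.
#' Species trees carry genome identifiers at the leaves and optional names
#' at internal vertices.
#'
#' @param path path to a Newick file, or a Newick string ending in `";"`.
#' @param kind `"gene"` or `"species"`.
#' @param sep separator between genome and gene in gene-tree leaf labels.
#' @return a `tag_tree`; gene trees carry a `leaf_genome` attribute (named
#'   character vector gene id -> genome).
#' @export
read_newick_tree <- function(path, kind = c("gene", "species"), sep = "|") {
  kind <- match.arg(kind)
  text <- if (grepl(";\\s*$", path[1]) && !file.exists(path[1])) path else {
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) abort("malformed Newick input", class = "multidiltag_bad_tree")
  tree <- tag_tree_from_phylo(phy)
  if (kind == "species") {
    if (anyDuplicated(tree_leaf_labels(tree))) {
      abort("duplicate genome labels in species tree", class = "multidiltag_bad_tree")
    }
    return(tree)
  }
  labs <- tree_leaf_labels(tree)
  parts <- strsplit(labs, sep, fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    abort(sprintf("gene tree leaf labels must be '<genome>%s<gene>'", sep),
          class = "multidiltag_bad_tree")
  }
  genome <- vapply(parts, `[[`, character(1), 1L)
  gene <- vapply(parts, `[[`, character(1), 2L)
  if (anyDuplicated(gene)) {
    abort("gene ids must be unique across genomes", class = "multidiltag_bad_tree")
  }
  leaves <- tree_leaves(tree)
  tree$label[leaves] <- gene
  attr(tree, "leaf_genome") <- setNames(genome, gene)
  tree
}

#' Write a `tag_tree` to Newick
#' @param tree a `tag_tree`.
#' @param path output file; if `NULL`, the Newick string is returned.
#' @param leaf_genome optional named vector gene -> genome; when given,
#'   leaves are written as `"<genome><sep><gene>"`.
#' @param sep label separator, as in [read_newick_tree()].
#' @export
write_newick_tree <- function(tree, path = NULL, leaf_genome = NULL, sep = "|") {
  out <- tree
  if (!is.null(leaf_genome)) {
    lv <- tree_leaves(out)
    out$label[lv] <- paste0(leaf_genome[out$label[lv]], sep, out$label[lv])
  }
  lv <- tree_leaves(out)
  nwk <- if (length(lv) == 1L) {
    paste0(out$label[lv], ";")
  } else {
    ape::write.tree(tag_tree_to_phylo(out))
  }
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(path)
}

#' Read signed gene orders from a TSV file
#'
#' One line per genome: the genome id, a tab, then space-separated signed
#' gene tokens such as `"+a -b +c"`.  An empty order (a genome whose copies
#' were all lost) is accepted with a warning.
#'
#' @param path input file.
#' @param gene_tree optional gene tree; when given, order contents are
#'   cross-checked against the tree's leaf universe.
#' @return named list of [gene_order()].
#' @export
read_orders <- function(path, gene_tree = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) | grepl("\t", lines)]
  orders <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    genome <- trimws(parts[1])
    body <- if (length(parts) >= 2L) parts[2] else ""
    tok <- parse_signed_tokens(body)
    if (!length(tok$ids)) {
      warn(sprintf("genome '%s' has an empty order (all copies lost?)", genome))
    }
    if (genome %in% names(orders)) {
      abort(sprintf("duplicate genome '%s' in orders file", genome),
            class = "multidiltag_bad_orders")
    }
    orders[[genome]] <- gene_order(genome, tok$ids, tok$signs)
  }
  if (!is.null(gene_tree)) {
    ids <- unlist(lapply(orders, function(o) o$ids), use.names = FALSE)
    if (anyDuplicated(ids)) {
      abort("gene id appears in two orders", class = "multidiltag_bad_orders")
    }
    if (!setequal(ids, tree_leaf_labels(gene_tree))) {
      abort("orders and gene tree disagree on the gene universe",
            class = "multidiltag_bad_orders")
    }
  }
  orders
}

#' Write gene orders to TSV (inverse of [read_orders()])
#' @param orders list of [gene_order()].
#' @param path output file.
#' @export
write_orders <- function(orders, path) {
  if (inherits(orders, "gene_order")) orders <- list(orders)
  lines <- vapply(orders, function(o) {
    body <- if (length(o$ids)) {
      paste(paste0(ifelse(o$signs > 0, "+", "-"), o$ids), collapse = " ")
    } else ""
    paste0(o$genome, "\t", body)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a history's events to TSV
#'
#' One row per event: genome (branch), type, span start/end, size, variant,
#' deleted subspan.
#' @param history a [tag_history()] or a list of [tag_event()].
#' @param path output file; if `NULL`, the tibble is returned.
#' @export
write_events <- function(history, path = NULL) {
  events <- if (inherits(history, "tag_history")) history$events else history
  tb <- events_tibble(events)
  if (is.null(path)) return(tb)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

events_tibble <- function(events) {
  tibble::tibble(
    genome = vapply(events, function(e) e$genome, character(1)),
    type = vapply(events, function(e) e$type, character(1)),
    start = vapply(events, function(e) if (is.null(e$span)) NA_integer_ else e$span[1], integer(1)),
    end = vapply(events, function(e) if (is.null(e$span)) NA_integer_ else e$span[2], integer(1)),
    size = vapply(events, function(e) as.integer(event_size(e)), integer(1)),
    variant = vapply(events, function(e) e$variant %||% NA_character_, character(1)),
    del_start = vapply(events, function(e) if (is.null(e$deleted_subspan)) NA_integer_ else e$deleted_subspan[1], integer(1)),
    del_end = vapply(events, function(e) if (is.null(e$deleted_subspan)) NA_integer_ else e$deleted_subspan[2], integer(1))
  )
}
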