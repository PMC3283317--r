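# Evolutionary model: states, events, costs, forward semantics -------------

#' Create an ordered-gene-tree state
#'
#' The evolving state of the model: one rooted binary gene tree whose leaves
#' are all current genes, plus one signed gene order per current genome.
#'
#' @param tree a `tag_tree` whose leaf labels are gene ids.
#' @param orders list of [gene_order()] objects, one per genome.
#' @return an object of class `tag_state`.
#' @export
tag_state <- function(tree, orders) {
  if (inherits(orders, "gene_order")) orders <- list(orders)
  names(orders) <- vapply(orders, function(o) o$genome, character(1))
  if (anyDuplicated(names(orders))) abort("duplicate genome in orders")
  state <- structure(list(tree = tree, orders = orders), class = "tag_state")
  check_state(state)
  state
}

check_state <- function(state) {
  in_orders <- unlist(lapply(state$orders, function(o) o$ids), use.names = FALSE)
  leaves <- tree_leaf_labels(state$tree)
  if (anyDuplicated(in_orders)) abort("gene id present in two orders")
  if (!setequal(in_orders, leaves)) {
    abort("gene tree leaves and order contents disagree",
          class = "multidiltag_bad_state")
  }
  invisible(state)
}

#' Initial single-gene state
#' @param gene label of the ancestral gene.
#' @param genome genome identifier.
#' @param sign orientation of the ancestral gene.
#' @export
initial_state <- function(gene = "g", genome = "root", sign = 1L) {
  tag_state(tree_single(gene), gene_order(genome, gene, sign))
}

#' @export
print.tag_state <- function(x, ...) {
  cat(sprintf("<tag_state: %d genes in %d genome(s)>\n",
              length(tree_leaves(x$tree)), length(x$orders)))
  for (o in x$orders) cat(" ", format(o), "\n")
  invisible(x)
}

# Events --------------------------------------------------------------------

EVENT_TYPES <- c("DUP", "INV_DUP", "INV", "DEL", "SPEC")

#' Create an evolutionary event
#'
#' @param type one of `"DUP"`, `"INV_DUP"`, `"INV"`, `"DEL"`, `"SPEC"`.
#' @param genome genome the event acts on.
#' @param span 1-based inclusive positions `c(p, q)` in that genome's order
#'   (ignored for `SPEC`).
#' @param variant for `INV_DUP`: `"left"` if the left copy block is the
#'   inverted one, `"right"` otherwise.
#' @param deleted_subspan optional `c(p, q)` of copies removed immediately
#'   after a duplication, in post-duplication coordinates; only valid with
#'   `DUP`/`INV_DUP` (a duplication-with-deletion compound).
#' @param new_genomes for `SPEC`: the two genome identifiers created.
#' @param child_labels optional list with elements `left` and `right`:
#'   explicit labels for the copies created by `DUP`/`INV_DUP`/`SPEC`
#'   (otherwise a label factory names them).
#' @return an object of class `tag_event`.
#' @export
tag_event <- function(type, genome, span = NULL, variant = NULL,
                      deleted_subspan = NULL, new_genomes = NULL,
                      child_labels = NULL) {
  type <- match.arg(type, EVENT_TYPES)
  if (type == "SPEC") {
    if (is.null(new_genomes) || length(new_genomes) != 2L) {
      abort("SPEC requires two new_genomes")
    }
    span <- NULL
  } else {
    span <- as.integer(span)
    if (length(span) != 2L || span[1] < 1L || span[2] < span[1]) {
      abort("span must be c(p, q) with 1 <= p <= q")
    }
  }
  if (!is.null(deleted_subspan)) {
    if (!type %in% c("DUP", "INV_DUP")) {
      abort("deleted_subspan is only valid with DUP or INV_DUP")
    }
    deleted_subspan <- as.integer(deleted_subspan)
  }
  if (type == "INV_DUP") variant <- match.arg(variant, c("left", "right"))
  structure(list(type = type, genome = as.character(genome), span = span,
                 variant = variant, deleted_subspan = deleted_subspan,
                 new_genomes = new_genomes, child_labels = child_labels),
            class = "tag_event")
}

# Internal fast path used by the search operators: skips validation.
new_event <- function(type, genome, span = NULL, variant = NULL,
                      deleted_subspan = NULL, new_genomes = NULL,
                      child_labels = NULL) {
  structure(list(type = type, genome = genome, span = span,
                 variant = variant, deleted_subspan = deleted_subspan,
                 new_genomes = new_genomes, child_labels = child_labels),
            class = "tag_event")
}

event_size <- function(event) {
  if (event$type == "SPEC") return(NA_integer_)
  event$span[2] - event$span[1] + 1L
}

#' @export
format.tag_event <- function(x, ...) {
  if (x$type == "SPEC") {
    sprintf("SPEC %s -> {%s, %s}", x$genome, x$new_genomes[1], x$new_genomes[2])
  } else {
    extra <- ""
    if (!is.null(x$variant)) extra <- paste0(" ", x$variant)
    if (!is.null(x$deleted_subspan)) {
      extra <- paste0(extra, sprintf(" -del(%d,%d)", x$deleted_subspan[1],
                                     x$deleted_subspan[2]))
    }
    sprintf("%s %s (%d,%d)%s", x$type, x$genome, x$span[1], x$span[2], extra)
  }
}

#' @export
print.tag_event <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Cost model ----------------------------------------------------------------

#' Event cost model
#'
#' The cost of an event of size m (acting on m genes) is `alpha_e + m *
#' beta_e`, where `alpha_e` is the opening cost and `beta_e` the extension
#' cost of event type e.  Speciations cost 0.  Defaults follow the standard
#' calibration used with the DILTAG search: duplications (direct or
#' inverted) open at 100, deletions and inversions at 500, extension 1 for
#' all types.
#'
#' @param alpha named numeric: opening cost per event type
#'   (`dup`, `inv_dup`, `del`, `inv`).
#' @param beta named numeric: extension cost per event type.
#' @param enabled character vector of enabled event types; disabled types
#'   carry infinite cost and are skipped during neighbourhood generation.
#' @return an object of class `cost_model`.
#' @examples
#' cm <- cost_model()
#' event_cost(tag_event("DUP", "g1", c(1, 1)), cm)  # 101
#' @export
cost_model <- function(alpha = c(dup = 100, inv_dup = 100, del = 500, inv = 500),
                       beta  = c(dup = 1,   inv_dup = 1,   del = 1,   inv = 1),
                       enabled = c("dup", "inv_dup", "del", "inv")) {
  need <- c("dup", "inv_dup", "del", "inv")
  alpha <- alpha[need]; beta <- beta[need]
  if (anyNA(alpha) || anyNA(beta)) abort("alpha and beta must name all event types")
  if (any(alpha < 0) || any(beta < 0)) abort("costs must be nonnegative")
  if (any(alpha + beta <= 0)) abort("enabled events must have strictly positive cost")
  enabled <- match.arg(enabled, need, several.ok = TRUE)
  structure(list(alpha = alpha, beta = beta, enabled = enabled),
            class = "cost_model")
}

cost_key <- function(type) {
  switch(type, DUP = "dup", INV_DUP = "inv_dup", INV = "inv", DEL = "del",
         abort(sprintf("no cost for event type %s", type)))
}

#' Cost of an event under a cost model
#'
#' A duplication-with-deletion compound costs the duplication (at its full
#' size) plus the deletion of the removed copies.
#'
#' @param event a [tag_event()].
#' @param costs a [cost_model()].
#' @return a nonnegative number (`Inf` for a disabled event type).
#' @export
event_cost <- function(event, costs) {
  if (event$type == "SPEC") return(0)
  m <- event_size(event)
  if (is.na(m) || m < 1L) abort("events act on at least one gene")
  key <- cost_key(event$type)
  if (!key %in% costs$enabled) return(Inf)
  cost <- costs$alpha[[key]] + m * costs$beta[[key]]
  if (!is.null(event$deleted_subspan)) {
    if (!"del" %in% costs$enabled) return(Inf)
    k <- event$deleted_subspan[2] - event$deleted_subspan[1] + 1L
    cost <- cost + costs$alpha[["del"]] + k * costs$beta[["del"]]
  }
  cost
}

# Forward semantics ---------------------------------------------------------

default_label_factory <- function(parent_label, which) {
  paste0(parent_label, ".", which)
}

#' Apply an event to a state
#'
#' Implements the forward semantics of the five event types.  Duplications
#' (direct or inverted) replace each affected gene `u` by a cherry `(l, r)`
#' in the tree and splice the copy blocks into the order; inversions reverse
#' and negate a span; deletions remove genes from order and tree; a
#' speciation copies a whole genome into two new genomes, replacing every
#' gene by a cherry.
#'
#' @param state a [tag_state()].
#' @param event a [tag_event()].
#' @param label_factory function `(parent_label, which)` naming the two
#'   copies created for a gene; `which` is `1` (left) or `2` (right).
#'   Ignored where `event$child_labels` supplies labels explicitly.
#' @param allow_empty_genome allow a deletion to remove a genome's last
#'   genes (degenerate histories); off by default.
#' @return the successor `tag_state`.
#' @examples
#' s <- initial_state("u", "g1")
#' s2 <- apply_event(s, tag_event("DUP", "g1", c(1, 1)))
#' s2$orders[["g1"]]$ids  # "u.1" "u.2"
#' @export
apply_event <- function(state, event, label_factory = default_label_factory,
                        allow_empty_genome = FALSE) {
  ord <- state$orders[[event$genome]]
  if (is.null(ord)) {
    abort(sprintf("unknown genome '%s'", event$genome),
          class = "multidiltag_bad_event")
  }
  n <- length(ord$ids)
  if (event$type != "SPEC") {
    p <- event$span[1]; q <- event$span[2]
    if (q > n) abort("span out of range", class = "multidiltag_bad_event")
  }
  tree <- state$tree
  orders <- state$orders

  make_copies <- function(ids, which) {
    cl <- event$child_labels
    if (!is.null(cl)) {
      lab <- if (which == 1L) cl$left else cl$right
      if (length(lab) != length(ids)) abort("child_labels length mismatch")
      lab
    } else {
      vapply(ids, label_factory, character(1), which = which)
    }
  }

  if (event$type %in% c("DUP", "INV_DUP")) {
    seg_ids <- ord$ids[p:q]; seg_signs <- ord$signs[p:q]
    l_ids <- make_copies(seg_ids, 1L)
    r_ids <- make_copies(seg_ids, 2L)
    for (x in seq_along(seg_ids)) {
      tree <- tree_replace_leaf_by_cherry(tree, seg_ids[x], l_ids[x], r_ids[x])
    }
    if (event$type == "DUP") {
      new_ids <- c(l_ids, r_ids)
      new_signs <- c(seg_signs, seg_signs)
    } else if (event$variant == "left") {
      new_ids <- c(rev(l_ids), r_ids)
      new_signs <- c(rev(-seg_signs), seg_signs)
    } else {
      new_ids <- c(l_ids, rev(r_ids))
      new_signs <- c(seg_signs, rev(-seg_signs))
    }
    ids <- append(ord$ids[-(p:q)], new_ids, after = p - 1L)
    signs <- append(ord$signs[-(p:q)], new_signs, after = p - 1L)
    orders[[event$genome]] <- gene_order(ord$genome, ids, signs)
    state2 <- structure(list(tree = tree, orders = orders), class = "tag_state")
    if (!is.null(event$deleted_subspan)) {
      d <- event$deleted_subspan
      if (d[1] < p || d[2] > p + 2L * length(seg_ids) - 1L) {
        abort("deleted_subspan outside the duplicated block",
              class = "multidiltag_bad_event")
      }
      state2 <- apply_event(state2,
                            tag_event("DEL", event$genome, span = d),
                            allow_empty_genome = allow_empty_genome)
    }
    return(state2)
  }

  if (event$type == "INV") {
    ids <- ord$ids; signs <- ord$signs
    ids[p:q] <- rev(ids[p:q])
    signs[p:q] <- rev(-signs[p:q])
    orders[[event$genome]] <- gene_order(ord$genome, ids, signs)
    return(structure(list(tree = tree, orders = orders), class = "tag_state"))
  }

  if (event$type == "DEL") {
    if (q - p + 1L >= n && !allow_empty_genome) {
      abort("deletion would empty the genome (set allow_empty_genome to permit)",
            class = "multidiltag_empty_genome")
    }
    gone <- ord$ids[p:q]
    tree <- tree_drop_leaves(tree, gone)
    orders[[event$genome]] <- gene_order(ord$genome, ord$ids[-(p:q)],
                                         ord$signs[-(p:q)])
    return(structure(list(tree = tree, orders = orders), class = "tag_state"))
  }

  # SPEC
  l_ids <- make_copies(ord$ids, 1L)
  r_ids <- make_copies(ord$ids, 2L)
  for (x in seq_along(ord$ids)) {
    tree <- tree_replace_leaf_by_cherry(tree, ord$ids[x], l_ids[x], r_ids[x])
  }
  orders[[event$genome]] <- NULL
  orders[[event$new_genomes[1]]] <- gene_order(event$new_genomes[1], l_ids, ord$signs)
  orders[[event$new_genomes[2]]] <- gene_order(event$new_genomes[2], r_ids, ord$signs)
  structure(list(tree = tree, orders = orders), class = "tag_state")
}

# Histories ------------------------------------------------------------------

#' Create an evolutionary history
#'
#' A history is an initial single-gene state plus the forward sequence of
#' events that produced the observed clusters.  States along the way are
#' recovered by replay.
#'
#' @param initial the starting `tag_state` (normally [initial_state()]).
#' @param events list of [tag_event()] in application order.
#' @param species_tree optional `tag_tree` of the genomes (induced by the
#'   SPEC events).
#' @export
tag_history <- function(initial, events, species_tree = NULL) {
  structure(list(initial = initial, events = events, species_tree = species_tree),
            class = "tag_history")
}

#' @export
print.tag_history <- function(x, ...) {
  cat(sprintf("<tag_history: %d events>\n", length(x$events)))
  invisible(x)
}

#' Replay a history's events from its initial state
#'
#' @param history a [tag_history()].
#' @param keep_states return all intermediate states (otherwise only final).
#' @return the final `tag_state`, or a list of states if `keep_states`.
#' @export
replay_history <- function(history, keep_states = FALSE) {
  state <- history$initial
  states <- if (keep_states) vector("list", length(history$events) + 1L)
  if (keep_states) states[[1L]] <- state
  for (i in seq_along(history$events)) {
    state <- apply_event(state, history$events[[i]], allow_empty_genome = TRUE)
    if (keep_states) states[[i + 1L]] <- state
  }
  if (keep_states) states else state
}

#' Validate a history against observed data
#'
#' Replays the history forward and checks that it reproduces the observed
#' signed gene orders and a gene tree isomorphic to the observed gene tree.
#' Orders are compared genome by genome, position by position (signs
#' included); the position-wise identification of replayed with observed
#' genes must extend to a tree isomorphism.
#'
#' @param history a [tag_history()].
#' @param observed list of [gene_order()] (one per extant genome).
#' @param gene_tree the observed gene tree (`tag_tree`).
#' @return a list with elements `ok` (logical) and `divergence`
#'   (`NULL`, or a message describing the first mismatch found).
#' @export
validate_history <- function(history, observed, gene_tree) {
  if (inherits(observed, "gene_order")) observed <- list(observed)
  names(observed) <- vapply(observed, function(o) o$genome, character(1))
  final <- tryCatch(replay_history(history), error = function(e) e)
  if (inherits(final, "error")) {
    return(list(ok = FALSE, divergence = paste("replay failed:",
                                               conditionMessage(final))))
  }
  if (!setequal(names(final$orders), names(observed))) {
    return(list(ok = FALSE, divergence = "genome sets differ"))
  }
  map <- character(0)
  for (g in names(observed)) {
    got <- final$orders[[g]]; want <- observed[[g]]
    if (length(got$ids) != length(want$ids)) {
      return(list(ok = FALSE,
                  divergence = sprintf("genome %s: %d genes, expected %d",
                                       g, length(got$ids), length(want$ids))))
    }
    if (!identical(got$signs, want$signs)) {
      return(list(ok = FALSE, divergence = sprintf("genome %s: signs differ", g)))
    }
    map[got$ids] <- want$ids
  }
  if (anyDuplicated(unname(map))) {
    return(list(ok = FALSE, divergence = "replayed-to-observed gene map not a bijection"))
  }
  if (!tree_iso_mapped(final$tree, gene_tree, map)) {
    return(list(ok = FALSE, divergence = "gene tree topology differs"))
  }
  list(ok = TRUE, divergence = NULL)
}
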