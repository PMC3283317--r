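# Forward simulator of evolutionary histories --------------------------------

#' Sample an event size from a truncated geometric distribution
#'
#' Sizes follow `P(k) proportional to (1-p)^(k-1) p` for `k = 1..max_size`
#' (renormalized): smaller events are more frequent, and an event can never
#' span more genes than the cluster currently holds.
#'
#' @param p geometric parameter in (0, 1).
#' @param max_size truncation point (the current cluster size).
#' @param n number of draws.
#' @return integer vector of sizes in `[1, max_size]`.
#' @examples
#' set.seed(1); table(sample_event_size(0.5, 3, 1000))
#' @export
sample_event_size <- function(p, max_size, n = 1L) {
  if (max_size < 1L) abort("max_size must be >= 1")
  if (p <= 0 || p >= 1) abort("p must be in (0, 1)")
  k <- seq_len(max_size)
  w <- (1 - p)^(k - 1) * p
  sample.int(max_size, n, replace = TRUE, prob = w / sum(w))
}

#' Balanced species tree with 2^d leaves
#' @param leaves number of leaves (a power of two).
#' @return a `tag_tree` with leaves labelled `"1".."leaves"`.
#' @export
balanced_species_tree <- function(leaves) {
  if (leaves < 1L || bitwAnd(leaves, leaves - 1L) != 0L) {
    abort("leaves must be a power of two")
  }
  if (leaves == 1L) return(tree_single("1"))
  build <- function(lo, hi) {
    if (lo == hi) return(as.character(lo))
    mid <- (lo + hi) %/% 2L
    paste0("(", build(lo, mid), ",", build(mid + 1L, hi), ")")
  }
  read_newick_tree(paste0(build(1L, leaves), ";"), "species")
}

#' Simulation configuration
#'
#' @param species_tree a `tag_tree`.
#' @param branch_events named list: for every species vertex name (the
#'   branch above that vertex; the root name stands for the pre-root
#'   lineage), a list of event specs `list(type=, size=, cap=)` where
#'   `size = NA` means "sample from the truncated geometric" and `cap`
#'   optionally truncates the sampled size further.
#' @param p geometric size parameter.
#' @param shuffle draw the within-branch event order uniformly at random
#'   (the default); otherwise apply events as listed.
#' @export
simulation_config <- function(species_tree, branch_events, p = 0.5,
                              shuffle = TRUE) {
  snames <- species_vertex_names(species_tree)
  unknown <- setdiff(names(branch_events), snames)
  if (length(unknown)) {
    abort(sprintf("branch_events names not in the species tree: %s",
                  paste(unknown, collapse = ", ")))
  }
  structure(list(species_tree = species_tree, branch_events = branch_events,
                 p = p, shuffle = shuffle),
            class = "simulation_config")
}

event_spec <- function(type, size = NA_integer_, cap = NA_integer_) {
  list(type = type, size = size, cap = cap)
}

#' Named experimental designs
#'
#' * `"fig5"`: on every branch, `n` simple and `n` double tandem
#'   duplications (fixed sizes 1 and 2) plus 2 inversions, so every extant
#'   genome holds exactly `3*d*n + 1` genes at depth `d`.
#' * `"fig6"`: a total of `x` duplications (half direct, half inverted)
#'   plus `0`, `x/2` or `x` inversions (`inversion_fraction` 0, 1/3 or
#'   1/2), distributed evenly over the branches (round-robin remainder).
#' * `"fig7"`: on every branch, 4 tandem duplications, 1 inverted
#'   duplication, 1 inversion and 1 deletion of size 1 or 2.
#'
#' Event sizes are sampled from the truncated geometric distribution unless
#' the design fixes them.
#'
#' @param name one of `"fig5"`, `"fig6"`, `"fig7"`.
#' @param leaves number of extant genomes (power of two).
#' @param n per-branch duplication multiplier (fig5).
#' @param x total number of duplications (fig6).
#' @param inversion_fraction 0, 1/3 or 1/2 (fig6).
#' @param p geometric size parameter.
#' @return a [simulation_config()].
#' @export
named_design <- function(name = c("fig5", "fig6", "fig7"), leaves = 2L,
                         n = 1L, x = NULL, inversion_fraction = 0, p = 0.5) {
  name <- match.arg(name)
  stree <- balanced_species_tree(leaves)
  snames <- species_vertex_names(stree)
  branch_names <- snames[order(tree_depths(stree), seq_along(snames))]
  be <- setNames(rep(list(list()), length(branch_names)), branch_names)
  if (name == "fig5") {
    for (b in branch_names) {
      be[[b]] <- c(replicate(n, event_spec("DUP", size = 1L), simplify = FALSE),
                   replicate(n, event_spec("DUP", size = 2L), simplify = FALSE),
                   replicate(2L, event_spec("INV"), simplify = FALSE))
    }
  } else if (name == "fig6") {
    if (is.null(x)) abort("fig6 needs x (total number of duplications)")
    if (!isTRUE(all.equal(inversion_fraction, 0)) &&
        !isTRUE(all.equal(inversion_fraction, 1 / 3)) &&
        !isTRUE(all.equal(inversion_fraction, 1 / 2))) {
      abort("inversion_fraction must be 0, 1/3 or 1/2")
    }
    n_inv <- if (isTRUE(all.equal(inversion_fraction, 0))) 0L else {
      if (isTRUE(all.equal(inversion_fraction, 1 / 3))) as.integer(x / 2) else
        as.integer(x)
    }
    dups <- rep(c("DUP", "INV_DUP"), length.out = x)
    nb <- length(branch_names)
    for (i in seq_along(dups)) {
      b <- branch_names[((i - 1L) %% nb) + 1L]
      be[[b]] <- c(be[[b]], list(event_spec(dups[i])))
    }
    for (i in seq_len(n_inv)) {
      b <- branch_names[((i - 1L) %% nb) + 1L]
      be[[b]] <- c(be[[b]], list(event_spec("INV")))
    }
  } else {
    for (b in branch_names) {
      be[[b]] <- c(replicate(4L, event_spec("DUP"), simplify = FALSE),
                   list(event_spec("INV_DUP"), event_spec("INV"),
                        event_spec("DEL", cap = 2L)))
    }
  }
  simulation_config(stree, be, p = p)
}

#' Simulate an evolutionary history consistent with a species tree
#'
#' Starts from a single positive ancestral gene, traverses the species tree
#' root to leaves, applies each branch's events (sizes sampled where not
#' fixed, spans uniform over valid starts, inverted-duplication variants
#' uniform) and a speciation at every internal vertex.
#'
#' @param config a [simulation_config()] (or [named_design()] output).
#' @param seed integer seed; the simulation is a pure function of
#'   `(config, seed)`.
#' @param del_retries redraws allowed when a sampled deletion would empty a
#'   genome.
#' @return an object of class `tag_simulation`: the true `history`, the
#'   final `state`, the extant `gene_tree` (with `leaf_genome` attribute),
#'   the `leaf_orders`, and a `truth` tibble of the events performed.
#' @export
simulate_history <- function(config, seed, del_retries = 50L) {
  if (missing(seed)) abort("simulate_history requires a seed")
  set.seed(seed)
  stree <- config$species_tree
  snames <- species_vertex_names(stree)
  state <- initial_state(gene = "g1", genome = snames[stree$root])
  truth <- list()
  events <- list()

  emit <- function(ev, size) {
    state <<- apply_event(state, ev)
    events[[length(events) + 1L]] <<- ev
    truth[[length(truth) + 1L]] <<- tibble::tibble(
      branch = ev$genome, type = ev$type,
      size = as.integer(size),
      start = if (is.null(ev$span)) NA_integer_ else ev$span[1],
      variant = ev$variant %||% NA_character_
    )
  }

  preorder <- rev(tree_postorder(stree))
  for (v in preorder) {
    genome <- snames[v]
    specs <- config$branch_events[[genome]] %||% list()
    if (length(specs) && isTRUE(config$shuffle)) {
      specs <- specs[sample.int(length(specs))]
    }
    queue <- specs
    defers <- 0L
    while (length(queue)) {
      sp <- queue[[1]]
      queue <- queue[-1]
      len <- length(state$orders[[genome]]$ids)
      if (sp$type == "DEL") {
        maxs <- min(len - 1L, if (is.na(sp$cap)) len - 1L else sp$cap)
        if (maxs < 1L) {
          # cannot delete without emptying the genome: defer the deletion
          # to the end of the branch (later duplications restore room)
          defers <- defers + 1L
          if (defers > del_retries || !length(queue)) {
            abort("deletion would empty the genome; reduce the budget")
          }
          queue <- c(queue, list(sp))
          next
        }
        tries <- 0L
        repeat {
          size <- if (!is.na(sp$size)) sp$size else sample_event_size(config$p, maxs)
          if (size <= maxs) break
          tries <- tries + 1L
          if (tries > del_retries) abort("could not draw a feasible deletion size")
        }
      } else {
        maxs <- min(len, if (is.na(sp$cap)) len else sp$cap)
        if (!is.na(sp$size) && sp$size > maxs) {
          # a fixed-size event wider than the current cluster is deferred
          # to the end of the branch until duplications make room for it
          defers <- defers + 1L
          if (defers > del_retries || !length(queue)) {
            abort(sprintf("a size-%d %s does not fit the cluster; reduce the budget",
                          sp$size, sp$type))
          }
          queue <- c(queue, list(sp))
          next
        }
        size <- if (!is.na(sp$size)) sp$size else
          sample_event_size(config$p, maxs)
      }
      start <- sample.int(len - size + 1L, 1L)
      ev <- switch(sp$type,
        DUP = tag_event("DUP", genome, span = c(start, start + size - 1L)),
        INV_DUP = tag_event("INV_DUP", genome, span = c(start, start + size - 1L),
                            variant = sample(c("left", "right"), 1L)),
        INV = tag_event("INV", genome, span = c(start, start + size - 1L)),
        DEL = tag_event("DEL", genome, span = c(start, start + size - 1L)),
        abort(sprintf("unknown simulated event type '%s'", sp$type))
      )
      emit(ev, size)
    }
    ch <- stree$children[[v]]
    if (length(ch)) {
      ev <- tag_event("SPEC", genome, new_genomes = snames[ch])
      emit(ev, NA_integer_)
    }
  }

  leaf_orders <- state$orders[snames[tree_leaves(stree)]]
  leaf_genome <- setNames(
    rep(vapply(leaf_orders, function(o) o$genome, character(1)),
        vapply(leaf_orders, function(o) length(o$ids), integer(1))),
    unlist(lapply(leaf_orders, function(o) o$ids), use.names = FALSE)
  )
  gene_tree <- state$tree
  attr(gene_tree, "leaf_genome") <- leaf_genome
  structure(list(
    history = tag_history(initial_state(gene = "g1", genome = snames[stree$root]),
                          events, species_tree = stree),
    state = state, gene_tree = gene_tree, leaf_orders = leaf_orders,
    truth = if (length(truth)) dplyr::bind_rows(truth) else
      tibble::tibble(branch = character(0), type = character(0),
                     size = integer(0), start = integer(0),
                     variant = character(0)),
    config = config, seed = seed
  ), class = "tag_simulation")
}

#' @export
print.tag_simulation <- function(x, ...) {
  cat(sprintf("<tag_simulation: %d events, %d extant genome(s), seed %s>\n",
              length(x$history$events), length(x$leaf_orders), format(x$seed)))
  invisible(x)
}

#' Write a simulation's inputs and truth to files
#'
#' Emits the gene tree and species tree (Newick), the leaf orders (TSV) and
#' the true event list (TSV) under a common file prefix.
#' @param sim a [simulate_history()] result.
#' @param prefix path prefix for the four output files.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, prefix) {
  paths <- c(gene_tree = paste0(prefix, ".genetree.nwk"),
             species_tree = paste0(prefix, ".speciestree.nwk"),
             orders = paste0(prefix, ".orders.tsv"),
             truth = paste0(prefix, ".truth.tsv"))
  write_newick_tree(sim$gene_tree, paths["gene_tree"],
                    leaf_genome = attr(sim$gene_tree, "leaf_genome"))
  write_newick_tree(sim$config$species_tree, paths["species_tree"])
  write_orders(sim$leaf_orders, paths["orders"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
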