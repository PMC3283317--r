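# DILTAG: backward best-first search over the history graph -----------------

#' Search parameters
#'
#' @param capacity number of partial histories retained in the greedy queue.
#' @param depth expansion horizon per round (1 = pure best-first).
#' @param max_solutions cap on the solution-set size collected at minimum
#'   cost.
#' @param max_expansions total work budget of one branch search (number of
#'   partial histories expanded); past it the best solutions found so far
#'   are returned.
#' @param loss_cap cap on the number of loss-extended orders per branch
#'   (the combinatorial reinsertion of lost genes is exponential).
#' @param id_bound maximum order length for the exact ID-distance BFS.
#' @param id_max_states state cap for the ID-distance BFS.
#' @export
search_params <- function(capacity = 1000L, depth = 1L, max_solutions = 1000L,
                          max_expansions = 2000L, loss_cap = 10000L,
                          id_bound = 8L, id_max_states = 2e5) {
  if (capacity < 1L || depth < 1L) abort("capacity and depth must be >= 1")
  structure(list(capacity = as.integer(capacity), depth = as.integer(depth),
                 max_solutions = as.integer(max_solutions),
                 max_expansions = as.integer(max_expansions),
                 loss_cap = as.integer(loss_cap), id_bound = as.integer(id_bound),
                 id_max_states = id_max_states),
            class = "search_params")
}

# One representative minimum-cost path from an ancestral solution state
# down to a source: the forward event sequence replaying the branch, plus
# the source id reached.
engine_path <- function(res, sig) {
  events <- list()
  cur <- sig
  repeat {
    rec <- get(cur, envir = res$nodes)
    if (!length(rec$down)) {
      return(list(events = events, source = rec$src[1], source_sig = cur))
    }
    link <- rec$down[[1]]
    events <- c(events, list(link$event))
    cur <- link$sig
  }
}

# Representative minimum-cost path from a solution state down to one
# specific source (depth-first through the optimal links).
engine_path_to <- function(res, sig, source_id) {
  walk <- function(s, acc) {
    rec <- get(s, envir = res$nodes)
    if (!length(rec$down)) {
      if (source_id %in% rec$src) {
        return(list(events = acc, source = source_id, source_sig = s))
      }
      return(NULL)
    }
    for (l in rec$down) {
      got <- walk(l$sig, c(acc, list(l$event)))
      if (!is.null(got)) return(got)
    }
    NULL
  }
  walk(sig, list())
}

# All source ids reachable from a solution through optimal links.
engine_sources <- function(res, sig) {
  seen <- new.env(parent = emptyenv())
  srcs <- character(0)
  walk <- function(s) {
    if (exists(s, envir = seen, inherits = FALSE)) return(invisible())
    assign(s, TRUE, envir = seen)
    rec <- get(s, envir = res$nodes)
    if (!length(rec$down)) {
      srcs <<- c(srcs, rec$src)
    } else {
      for (l in rec$down) walk(l$sig)
    }
    invisible()
  }
  walk(sig)
  unique(srcs)
}

forest_from_gene_tree <- function(tree) {
  n <- tree_n_vertices(tree)
  key <- ifelse(tree_is_leaf_vec(tree), tree$label, paste0("n", seq_len(n)))
  parent <- setNames(ifelse(tree$parent == 0L, NA_character_, key[pmax(tree$parent, 1L)]),
                     key)
  list(parent = parent, nodes = key,
       leaf_keys = key[tree_is_leaf_vec(tree)],
       tops = key[tree$parent == 0L],
       top_relabel = setNames(key[tree$parent == 0L], key[tree$parent == 0L]))
}

#' Single-cluster backward search (DILTAG)
#'
#' Searches backwards from an ordered gene tree to an ancestral gene order
#' with exactly `g` genes, by best-first exploration of the four backward
#' neighbourhoods (duplication, inverted duplication, inversion,
#' duplication-with-deletion), keeping a greedy queue of the most promising
#' partial histories.
#'
#' @param gene_tree a `tag_tree` whose leaves are the cluster's genes.
#' @param order a [gene_order()] over the tree's leaves.
#' @param g target number of ancestral genes (`1 <= g <= n`).
#' @param costs a [cost_model()].
#' @param params a [search_params()].
#' @return an object of class `diltag_result`: `min_cost`, a tibble
#'   `solution_set` of ancestral orders attained at minimum cost, and the
#'   solution graph of optimal backward paths.
#' @examples
#' gt <- read_newick_tree("((g|a,g|b),g|c);", "gene")
#' o <- gene_order("g", c("a", "b", "c"), 1L)
#' diltag(gt, o, g = 1)$min_cost  # 202: two simple duplications
#' @export
diltag <- function(gene_tree, order, g, costs = cost_model(),
                   params = search_params()) {
  n <- length(order$ids)
  if (g < 1L || g > n) abort("g must satisfy 1 <= g <= number of genes")
  if (!setequal(order$ids, tree_leaf_labels(gene_tree))) {
    abort("order and gene tree disagree on the gene set")
  }
  forest <- forest_from_gene_tree(gene_tree)
  sources <- list(list(ids = order$ids, signs = order$signs, source = "input"))
  res <- diltag_engine(forest, sources, g, costs, params, genome = order$genome)
  if (!is.finite(res$min_cost)) {
    warn("no ancestral order with g genes reachable (event types disabled?)")
  }
  sols <- lapply(res$solutions, function(s) get(s, envir = res$nodes))
  structure(list(
    min_cost = res$min_cost,
    solution_set = tibble::tibble(
      order = vapply(sols, function(x) order_string(x$ids, x$signs), character(1)),
      ids = lapply(sols, `[[`, "ids"),
      signs = lapply(sols, `[[`, "signs"),
      n_events = vapply(sols, function(x) x$nev, integer(1))
    ),
    g = g, engine = res, forest = forest, input = order, costs = costs,
    params = params
  ), class = "diltag_result")
}

#' @export
print.diltag_result <- function(x, ...) {
  cat(sprintf("<diltag_result: MIN = %s, %d ancestral order(s) with %d gene(s)>\n",
              format(x$min_cost), nrow(x$solution_set), x$g))
  invisible(x)
}
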