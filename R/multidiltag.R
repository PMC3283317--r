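# Multi-species gluing of per-branch backward searches ----------------------

#' All extensions of a gene order by reinserting lost genes
#'
#' Every lost gene is inserted at every position with either sign; for k
#' lost genes into a length-n order the full combinatorial closure has
#' `2^k (n+1)(n+2)...(n+k)` elements.  A configurable cap guards against
#' the exponential blow-up.
#'
#' @param order a [gene_order()].
#' @param lost_genes character vector of gene ids to reinsert (disjoint from
#'   the order's genes).
#' @param cap maximum closure size before aborting with class
#'   `multidiltag_loss_explosion`.
#' @return list of [gene_order()] objects.
#' @examples
#' length(extend_with_losses(gene_order("g", "a", 1L), "b"))  # 4
#' @export
extend_with_losses <- function(order, lost_genes, cap = 10000L) {
  lost_genes <- as.character(lost_genes)
  if (any(lost_genes %in% order$ids)) abort("lost genes must be disjoint from the order")
  n <- length(order$ids); k <- length(lost_genes)
  if (k) {
    predicted <- prod(2 * (n + seq_len(k)))
    if (predicted > cap) {
      abort(sprintf("loss reinsertion would enumerate %.0f orders (cap %d)",
                    predicted, cap),
            class = "multidiltag_loss_explosion")
    }
  }
  sets <- list(list(ids = order$ids, signs = order$signs))
  for (gene in lost_genes) {
    nxt <- vector("list", 0L)
    for (st in sets) {
      len <- length(st$ids)
      for (pos in 0:len) {
        for (sg in c(1L, -1L)) {
          nxt[[length(nxt) + 1L]] <- list(
            ids = append(st$ids, gene, after = pos),
            signs = append(st$signs, sg, after = pos)
          )
        }
      }
    }
    sets <- nxt
  }
  lapply(sets, function(st) gene_order(order$genome, st$ids, st$signs))
}

# Internal element record of a solution set E(A): a candidate ancestral
# signed order plus, per originating side, the branch-layer order it was
# extended from.
new_elem <- function(ids, signs) {
  list(ids = ids, signs = signs, sig = order_sig(ids, signs), prov = list())
}

#' Infer a most-parsimonious multi-species history (Multi-DILTAG)
#'
#' Traverses the species tree bottom-up.  At each internal vertex A the
#' backward search is run on both child branches from every element of the
#' child's solution set, stopping at |PG(child)| genes; only minimum-cost
#' ancestral orders are kept, genes lost on the branch are reinserted in
#' every possible way, and the union over the two branches forms the
#' solution set E(A).  Speciation edges are labelled with the minimum
#' inversions+deletions (ID) distance.  Above the species root the search
#' continues down to a single ancestral gene.  One minimum-cost history is
#' traced back and validated by forward replay.
#'
#' @param gene_tree a `tag_tree` with a `leaf_genome` attribute.
#' @param leaf_orders list of [gene_order()], one per species leaf.
#' @param species_tree a `tag_tree` of the genomes.
#' @param costs a [cost_model()].
#' @param params a [search_params()].
#' @param reconciliation optional precomputed [lca_reconcile()] result.
#' @param id_label_costs convert speciation-edge ID labels into event costs
#'   (inversion/deletion costs of the realizing events) when summing the
#'   total history cost; edge *selection* always uses plain event counts.
#' @return an object of class `multi_diltag`.
#' @export
multi_diltag <- function(gene_tree, leaf_orders, species_tree,
                         costs = cost_model(), params = search_params(),
                         reconciliation = NULL, id_label_costs = TRUE) {
  rec <- reconciliation %||% lca_reconcile(gene_tree, species_tree)
  stree <- rec$species_tree
  snames <- rec$species_names
  nS <- tree_n_vertices(stree)
  if (inherits(leaf_orders, "gene_order")) leaf_orders <- list(leaf_orders)
  names(leaf_orders) <- vapply(leaf_orders, function(o) o$genome, character(1))

  E <- vector("list", nS)       # solution sets per species vertex
  dp <- vector("list", nS)      # per element: accumulated subtree cost
  choice <- vector("list", nS)  # per element, per side: traceback choices
  layer <- vector("list", nS)   # per child vertex: branch-layer records
  branch_min <- rep(NA_real_, nS)
  edges <- list()               # speciation-edge table rows

  post <- tree_postorder(stree)
  for (A in post) {
    chS <- stree$children[[A]]
    if (!length(chS)) {
      o <- leaf_orders[[snames[A]]]
      if (is.null(o)) abort(sprintf("no order supplied for genome '%s'", snames[A]))
      if (!setequal(o$ids, rec$G[[A]])) {
        abort(sprintf("order for genome '%s' does not match its genes in the tree",
                      snames[A]))
      }
      E[[A]] <- list(new_elem(o$ids, o$signs))
      dp[[A]] <- 0
      next
    }
    acc <- list()
    for (cS in chS) {
      lay <- run_branch(rec, cS, E[[cS]], costs, params)
      branch_min[cS] <- lay$min_cost
      layer[[cS]] <- lay
      lost <- sort(rec$losses$key[rec$losses$parent == A & rec$losses$child == cS])
      for (yi in seq_along(lay$orders)) {
        y <- lay$orders[[yi]]
        exts <- extend_with_losses(gene_order(snames[A], y$ids, y$signs),
                                   lost, cap = params$loss_cap)
        for (ex in exts) {
          sig <- order_sig(ex$ids, ex$signs)
          if (is.null(acc[[sig]])) acc[[sig]] <- new_elem(ex$ids, ex$signs)
          acc[[sig]]$prov[[length(acc[[sig]]$prov) + 1L]] <-
            list(side = cS, layer_index = yi)
        }
      }
    }
    acc <- acc[sort(names(acc))]
    E[[A]] <- unname(acc)
    # accumulated cost + traceback choice per element
    dp[[A]] <- numeric(length(E[[A]]))
    choice[[A]] <- vector("list", length(E[[A]]))
    for (ei in seq_along(E[[A]])) {
      elem <- E[[A]][[ei]]
      best_total <- Inf; best_choice <- NULL
      own_sides <- unique(vapply(elem$prov, `[[`, integer(1), "side"))
      for (own in own_sides) {
        tot <- 0; ch <- list()
        ok <- TRUE
        for (cS in chS) {
          use_own <- cS == own
          sel <- select_side(elem, cS, use_own, lay = layer[[cS]],
                             E_child = E[[cS]], dp_child = dp[[cS]],
                             costs = costs, params = params,
                             id_label_costs = id_label_costs)
          if (is.null(sel)) { ok <- FALSE; break }
          tot <- tot + sel$cost
          ch[[as.character(cS)]] <- sel
        }
        if (ok && tot < best_total) { best_total <- tot; best_choice <- ch }
      }
      dp[[A]][ei] <- best_total
      choice[[A]][[ei]] <- best_choice
      for (cS in chS) {
        sel <- best_choice[[as.character(cS)]]
        edges[[length(edges) + 1L]] <- tibble::tibble(
          from_vertex = snames[A], from_order = order_string(elem$ids, elem$signs),
          to_vertex = snames[cS],
          to_order = order_string(layer[[cS]]$orders[[sel$layer_index]]$ids,
                                  layer[[cS]]$orders[[sel$layer_index]]$signs),
          id_label = sel$id_count, own_side = sel$own
        )
      }
    }
  }

  # pre-root lineage: continue the search down to a single ancestral gene
  # (one multi-source search from the whole root solution set, as on the
  # branches; only minimum-cost sources remain candidates)
  sroot <- stree$root
  root_forest <- rec$forests[[sroot]]
  pre_sources <- lapply(seq_along(E[[sroot]]), function(ei) {
    list(ids = E[[sroot]][[ei]]$ids, signs = E[[sroot]][[ei]]$signs,
         source = as.character(ei))
  })
  pre <- diltag_engine(root_forest, pre_sources, g = length(root_forest$tops),
                       costs, params, genome = snames[sroot])
  if (!is.finite(pre$min_cost) || !length(pre$solutions)) {
    abort("no root candidate admits a history down to a single ancestral gene",
          class = "multidiltag_search_failed")
  }
  cand <- list()
  for (sol in pre$solutions) {
    for (src in engine_sources(pre, sol)) {
      ei <- as.integer(src)
      cand[[length(cand) + 1L]] <- list(
        elem_index = ei, solution = sol, pre_cost = pre$min_cost,
        total = pre$min_cost + dp[[sroot]][ei]
      )
    }
  }
  ord <- order(vapply(cand, `[[`, numeric(1), "total"),
               vapply(cand, `[[`, integer(1), "elem_index"))
  cand <- cand[ord]

  result <- structure(list(
    reconciliation = rec, costs = costs, params = params,
    E = E, dp = dp, choice = choice, layer = layer,
    branch_min = branch_min, root_candidates = cand, preroot_engine = pre,
    speciation_edges = if (length(edges)) dplyr::bind_rows(edges) else NULL,
    leaf_orders = leaf_orders, gene_tree = rec$gene_tree,
    species_tree = stree, species_names = snames,
    id_label_costs = id_label_costs
  ), class = "multi_diltag")

  tb <- traceback_history(result)
  result$history <- tb$history
  result$total_cost <- tb$total_cost
  result$root_order <- tb$root_order
  result$valid <- validate_history(tb$history, leaf_orders, rec$gene_tree)
  if (!result$valid$ok) {
    warn(paste("traced-back history failed validation:", result$valid$divergence))
  }
  result
}

# Run the backward search on the branch above species vertex cS from every
# element of E(cS), stop at |PG(cS)| genes, keep minimum-cost ancestral
# orders, relabel the attained forest roots to their pre-speciation unit
# keys.
run_branch <- function(rec, cS, E_child, costs, params) {
  forest <- rec$forests[[cS]]
  g <- length(forest$tops)
  sources <- lapply(seq_along(E_child), function(i) {
    list(ids = E_child[[i]]$ids, signs = E_child[[i]]$signs,
         source = as.character(i))
  })
  res <- diltag_engine(forest, sources, g, costs, params,
                       genome = rec$species_names[cS])
  if (!is.finite(res$min_cost) || !length(res$solutions)) {
    abort(sprintf("branch search above '%s' found no ancestral order with %d genes",
                  rec$species_names[cS], g),
          class = "multidiltag_search_failed")
  }
  orders <- lapply(res$solutions, function(sig) {
    nrec <- get(sig, envir = res$nodes)
    path <- engine_path(res, sig)
    list(ids = unname(forest$top_relabel[nrec$ids]), signs = nrec$signs,
         raw_ids = nrec$ids,
         sources = engine_sources(res, sig),
         path_events = path$events, path_source = path$source)
  })
  list(min_cost = res$min_cost, orders = orders, engine = res, vertex = cS)
}

# Choose, for element `elem` of E(A) and one child side, the branch-layer
# order to connect to: its own originating order when `use_own`, otherwise
# the layer order(s) minimizing the ID event count; ties are broken toward
# the cheapest realizing cost, then deterministically.
#
# Distances are certified lazily: every candidate gets the cheap
# upper-bound schedule first, and the exact BFS only runs deep enough to
# either beat the best distance certified so far or prove it cannot.
select_side <- function(elem, cS, use_own, lay, E_child, dp_child, costs,
                        params, id_label_costs) {
  idx <- if (use_own) {
    vapply(Filter(function(p) p$side == cS, elem$prov), `[[`, integer(1),
           "layer_index")
  } else {
    seq_along(lay$orders)
  }
  idx <- unique(idx)
  if (!length(idx)) return(NULL)
  ups <- lapply(idx, function(yi) {
    y <- lay$orders[[yi]]
    id_heuristic(elem$ids, elem$signs, y$ids, y$signs)
  })
  hvals <- vapply(ups, `[[`, numeric(1), "distance")
  ord <- order(hvals, idx)
  best_d <- Inf
  cands <- list()
  for (j in ord) {
    yi <- idx[j]; y <- lay$orders[[yi]]
    h <- as.integer(hvals[j])
    exact <- TRUE
    if (h == 0L) {
      d <- 0L; ops <- list()
    } else if (length(elem$ids) > params$id_bound) {
      d <- h; ops <- ups[[j]]$ops; exact <- FALSE
      if (d > best_d) next
    } else {
      cap <- min(h - 1L, if (is.finite(best_d)) as.integer(best_d) else h - 1L)
      bfs <- id_search(elem$ids, elem$signs, y$ids, y$signs,
                       max_depth = cap, max_states = params$id_max_states)
      if (!is.null(bfs$found)) {
        d <- bfs$found$distance; ops <- bfs$found$ops
      } else if (bfs$truncated) {
        d <- h; ops <- ups[[j]]$ops; exact <- FALSE
        if (d > best_d) next
      } else if (cap >= h - 1L) {
        d <- h; ops <- ups[[j]]$ops
        if (d > best_d) next
      } else {
        next  # proven worse than the best certified candidate
      }
    }
    if (d < best_d) best_d <- d
    cands[[length(cands) + 1L]] <- list(yi = yi, d = d, ops = ops, exact = exact)
  }
  cands <- Filter(function(cd) cd$d == best_d, cands)
  best <- NULL
  for (cd in cands) {
    y <- lay$orders[[cd$yi]]
    ev <- id_ops_to_events(cd$ops, "x")
    ev_cost <- sum(vapply(ev, event_cost, numeric(1), costs = costs))
    down <- min(dp_child[as.integer(y$sources)])
    src <- y$sources[which.min(dp_child[as.integer(y$sources)])]
    total <- (if (id_label_costs) ev_cost else 0) + lay$min_cost + down
    if (is.null(best) || total < best$cost ||
        (total == best$cost && cd$yi < best$layer_index)) {
      best <- list(layer_index = cd$yi, id_count = cd$d, id_events = ev,
                   source_index = as.integer(src), own = use_own, cost = total)
    }
  }
  best
}

#' Trace one minimum-cost history out of a fitted result
#'
#' Selects the best root candidate (optionally excluding some), converts the
#' chosen speciation-edge ID labels into explicit inversion/deletion events,
#' and emits a complete forward history that replays to the observed data.
#'
#' @param result a [multi_diltag()] result.
#' @param exclude_root integer indices of root candidates to skip (useful to
#'   inspect alternative optima).
#' @return list with `history` (a [tag_history()]), `total_cost`, and
#'   `root_order` (the ancestral order at the species root).
#' @export
traceback_history <- function(result, exclude_root = integer(0)) {
  rec <- result$reconciliation
  stree <- result$species_tree
  snames <- result$species_names
  sroot <- stree$root
  cand <- result$root_candidates
  keep <- !vapply(cand, function(cd) cd$elem_index %in% exclude_root, logical(1))
  cand <- cand[keep]
  if (!length(cand)) abort("all root candidates excluded")
  cd <- cand[[1]]                        # candidates are sorted by total cost

  # pre-root: forward events from the single ancestral gene down to the
  # chosen root solution-set element
  pre <- engine_path_to(result$preroot_engine, cd$solution,
                        as.character(cd$elem_index))
  anc <- get(cd$solution, envir = result$preroot_engine$nodes)
  init <- initial_state(gene = anc$ids[1], genome = snames[sroot],
                        sign = anc$signs[1])
  events <- strip_labels(pre$events)

  recurse <- function(A, ei) {
    elem <- result$E[[A]][[ei]]
    chS <- stree$children[[A]]
    if (!length(chS)) return(list())
    ev <- list(tag_event("SPEC", snames[A],
                         new_genomes = c(snames[chS[1]], snames[chS[2]])))
    for (cS in chS) {
      sel <- result$choice[[A]][[ei]][[as.character(cS)]]
      y <- result$layer[[cS]]$orders[[sel$layer_index]]
      id_ev <- lapply(sel$id_events, function(e) {
        e$genome <- snames[cS]; e
      })
      branch_ev <- strip_labels(y$path_events)
      branch_ev <- lapply(branch_ev, function(e) { e$genome <- snames[cS]; e })
      ev <- c(ev, id_ev, branch_ev, recurse(cS, sel$source_index))
    }
    ev
  }
  events <- c(events, recurse(sroot, cd$elem_index))
  root_elem <- result$E[[sroot]][[cd$elem_index]]
  list(history = tag_history(init, events, species_tree = stree),
       total_cost = cd$total,
       root_order = order_string(root_elem$ids, root_elem$signs))
}

# Child labels recorded during the search refer to forest vertex keys which
# collide across genomes after speciations; replay names copies through the
# default label factory instead.
strip_labels <- function(events) {
  lapply(events, function(e) { e$child_labels <- NULL; e })
}

#' Per-branch event report of the traced-back history
#'
#' Counts, for every species-tree branch (identified by its child vertex;
#' the species root stands for the pre-root lineage), the inferred events by
#' type, the gene losses (a deletion of size m causes m losses) and the
#' duplication sizes.
#'
#' @param result a [multi_diltag()] result, or a [tag_history()].
#' @return a tibble with one row per branch.
#' @export
branch_event_report <- function(result) {
  history <- if (inherits(result, "multi_diltag")) result$history else result
  ev <- history$events
  rows <- lapply(ev, function(e) {
    if (e$type == "SPEC") return(NULL)
    k_del <- if (!is.null(e$deleted_subspan)) {
      e$deleted_subspan[2] - e$deleted_subspan[1] + 1L
    } else 0L
    tibble::tibble(
      branch = e$genome, type = e$type, size = event_size(e),
      n_dup = as.integer(e$type == "DUP"),
      n_inv_dup = as.integer(e$type == "INV_DUP"),
      n_inv = as.integer(e$type == "INV"),
      n_del = as.integer(e$type == "DEL" || k_del > 0L),
      n_losses = if (e$type == "DEL") event_size(e) else k_del
    )
  })
  rows <- dplyr::bind_rows(rows)
  if (!nrow(rows)) {
    return(tibble::tibble(branch = character(0), n_dup = integer(0),
                          n_inv_dup = integer(0), n_inv = integer(0),
                          n_del = integer(0), n_losses = integer(0),
                          dup_sizes = list()))
  }
  rows |>
    dplyr::group_by(.data$branch) |>
    dplyr::summarise(
      n_dup = sum(.data$n_dup), n_inv_dup = sum(.data$n_inv_dup),
      n_inv = sum(.data$n_inv), n_del = sum(.data$n_del),
      n_losses = sum(.data$n_losses),
      dup_sizes = list(.data$size[.data$type %in% c("DUP", "INV_DUP")]),
      .groups = "drop"
    )
}

#' @export
print.multi_diltag <- function(x, ...) {
  cat(sprintf("<multi_diltag: total cost %s, root order %s, %s>\n",
              format(x$total_cost), x$root_order,
              if (isTRUE(x$valid$ok)) "history validated" else "INVALID"))
  invisible(x)
}

#' Candidate ancestral orders at a species vertex
#' @param result a [multi_diltag()] result.
#' @param vertex species vertex name.
#' @return tibble of the solution set E(vertex).
#' @export
solution_set <- function(result, vertex) {
  A <- species_vertex_index(result$reconciliation, vertex)
  tibble::tibble(
    vertex = vertex,
    order = vapply(result$E[[A]], function(e) order_string(e$ids, e$signs),
                   character(1)),
    subtree_cost = result$dp[[A]]
  )
}
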