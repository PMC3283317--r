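# Core backward search engine ----------------------------------------------
#
# Best-first exploration ranked by accumulated cost plus an admissible
# completion bound, seeded with a constructive rollout upper bound and
# capped in total work (the greedy queue of the published heuristic).
# `forest` carries at least `parent` (named character, NA at roots);
# `sources` is a list of list(ids, signs, source = <id>).  Returns MIN, the
# solution states of exactly `g` genes at cost MIN, and the optimal-path
# graph (an environment of node records with `down` links toward the
# sources).

diltag_engine <- function(forest, sources, g, costs, params, genome = "genome") {
  P <- forest$parent
  nodes <- new.env(parent = emptyenv())
  # byte-encoded state signature over the fixed forest-node universe
  code <- setNames(seq_along(P), names(P))
  K <- length(P)
  esig <- function(ids, signs) intToUtf8(unname(code[ids]) * signs + K + 1L)

  # Admissible completion bound: an undone duplication collapses an
  # antichain of forest vertices, so it lowers the deepest remaining chain
  # of uncollapsed duplication vertices by at most one level - at least
  # max-depth more duplication events (opening cost alpha each) and
  # surplus-many removed genes (extension cost beta each) are still needed.
  dup_types <- intersect(costs$enabled, c("dup", "inv_dup"))
  alpha_min <- if (length(dup_types)) min(costs$alpha[dup_types]) else Inf
  beta_min <- if (length(dup_types)) min(costs$beta[dup_types]) else Inf
  depth_code <- local({
    d <- integer(K)
    for (i in seq_len(K)) {
      v <- names(P)[i]; n <- 0L
      while (!is.na(P[[v]])) { v <- P[[v]]; n <- n + 1L }
      d[i] <- n
    }
    d
  })
  # the depth argument is only valid when the search runs all the way to
  # the forest roots; for intermediate targets fall back to one opening
  use_depth <- g == sum(is.na(P))
  promise_floor <- function(ids) {
    nids <- length(ids)
    if (nids == g) return(0)
    lev <- if (use_depth) max(depth_code[code[ids]]) else 1L
    alpha_min * lev + beta_min * (nids - g)
  }
  promise <- function(cost, ids) cost + promise_floor(ids)

  MIN <- Inf
  solutions <- character(0)
  fr_sig <- character(0); fr_f <- numeric(0); fr_cost <- numeric(0)
  fr_nev <- integer(0)

  for (s in sources) {
    sig <- esig(s$ids, s$signs)
    rec <- if (exists(sig, envir = nodes, inherits = FALSE)) get(sig, envir = nodes)
    if (is.null(rec)) {
      if (length(s$ids) < g) {
        warn("a source holds fewer genes than the target; it is ignored")
        next
      }
      rec <- list(ids = s$ids, signs = s$signs, cost = 0, nev = 0L,
                  down = list(), src = s$source)
      assign(sig, rec, envir = nodes)
      if (length(s$ids) == g) {
        MIN <- 0
        solutions <- c(solutions, sig)
      } else {
        fr_sig <- c(fr_sig, sig); fr_f <- c(fr_f, promise(0, s$ids))
        fr_cost <- c(fr_cost, 0); fr_nev <- c(fr_nev, 0L)
      }
    } else {
      rec$src <- unique(c(rec$src, s$source))
      assign(sig, rec, envir = nodes)
    }
  }

  # Constructive upper bound: collapse the deepest available cherry, paying
  # one inversion whenever no pattern is adjacent.  Its cost seeds MIN so
  # pruning is active from the first expansion, and its path is kept as a
  # fallback should the capped greedy search lose every solution.
  rollout <- NULL
  if (length(fr_sig) && is.infinite(MIN) && length(dup_types)) {
    for (s in sources) {
      if (length(s$ids) <= g) next
      ro <- engine_rollout(s$ids, s$signs, P, g, costs, genome)
      if (!is.null(ro) && ro$cost < (rollout$cost %||% Inf)) {
        rollout <- ro
        rollout$source <- s$source
      }
    }
    if (!is.null(rollout)) MIN <- min(MIN, rollout$cost)
  }

  budget <- params$max_expansions
  pops <- 0L
  while (length(fr_sig) && pops < budget) {
    # deterministic pop: most promising first, then the deepest partial
    # history (closest to an ancestor), then lexicographic on the order
    cand <- which(fr_f == min(fr_f))
    if (length(cand) > 1L) cand <- cand[fr_nev[cand] == max(fr_nev[cand])]
    i <- if (length(cand) > 1L) cand[order(fr_sig[cand])[1L]] else cand[1L]
    sig <- fr_sig[i]; f <- fr_f[i]; cost <- fr_cost[i]; nev <- fr_nev[i]
    fr_sig <- fr_sig[-i]; fr_f <- fr_f[-i]; fr_cost <- fr_cost[-i]
    fr_nev <- fr_nev[-i]
    rec <- get(sig, envir = nodes)
    if (cost > rec$cost) next            # stale entry
    if (f > MIN) break                   # nothing left can reach MIN
    pops <- pops + 1L
    # an inversion undo raises the ranking value by at least its own cost
    # (the completion bound is unchanged); a compound's deletion part does
    # the same, so both families are skippable near the bound
    preds <- all_predecessors(
      rec$ids, rec$signs, P, genome, costs,
      include_inv = f + costs$alpha[["inv"]] + costs$beta[["inv"]] <= MIN,
      include_cmp = f + costs$alpha[["del"]] + costs$beta[["del"]] <= MIN
    )
    np_sig <- character(0); np_f <- numeric(0); np_cost <- numeric(0)
    for (pr in preds) {
      ev <- pr$event
      ekey <- if (ev$type == "DUP") "dup" else
        if (ev$type == "INV_DUP") "inv_dup" else "inv"
      c2 <- cost + costs$alpha[[ekey]] +
        (ev$span[2] - ev$span[1] + 1L) * costs$beta[[ekey]]
      if (!is.null(ev$deleted_subspan)) {
        c2 <- c2 + costs$alpha[["del"]] +
          (ev$deleted_subspan[2] - ev$deleted_subspan[1] + 1L) * costs$beta[["del"]]
      }
      f2 <- promise(c2, pr$ids)
      if (f2 > MIN) next
      psig <- esig(pr$ids, pr$signs)
      link <- list(sig = sig, event = ev)
      old <- if (exists(psig, envir = nodes, inherits = FALSE)) {
        get(psig, envir = nodes)
      }
      if (is.null(old) || c2 < old$cost) {
        assign(psig, list(ids = pr$ids, signs = pr$signs, cost = c2,
                          nev = nev + 1L, down = list(link), src = NULL),
               envir = nodes)
        if (length(pr$ids) == g) {
          if (c2 < MIN) MIN <- c2
          solutions <- c(solutions, psig)
        } else {
          np_sig <- c(np_sig, psig); np_f <- c(np_f, f2); np_cost <- c(np_cost, c2)
        }
      } else if (c2 == old$cost && length(old$down) < 32L) {
        old$down <- c(old$down, list(link))
        assign(psig, old, envir = nodes)
      }
    }
    if (length(np_sig)) {
      fr_sig <- c(fr_sig, np_sig); fr_f <- c(fr_f, np_f)
      fr_cost <- c(fr_cost, np_cost)
      fr_nev <- c(fr_nev, rep.int(nev + 1L, length(np_sig)))
    }
    # greedy queue truncation: keep the most promising partial histories
    # (amortized: the frontier may overshoot to twice the capacity)
    if (length(fr_sig) > 2L * params$capacity) {
      o <- order(fr_f, -fr_nev, fr_sig)
      keep <- o[seq_len(params$capacity)]
      fr_sig <- fr_sig[keep]; fr_f <- fr_f[keep]; fr_cost <- fr_cost[keep]
      fr_nev <- fr_nev[keep]
    }
  }

  solutions <- solutions[vapply(solutions, function(s)
    get(s, envir = nodes)$cost == MIN, logical(1))]
  solutions <- sort(unique(solutions))
  if (length(solutions) > params$max_solutions) {
    solutions <- solutions[seq_len(params$max_solutions)]
  }
  if (!length(solutions) && !is.null(rollout)) {
    # install the rollout chain as the (single) solution path
    MIN <- rollout$cost
    cur_sig <- esig(rollout$chain[[1]]$ids, rollout$chain[[1]]$signs)
    # chain runs observed -> ancestor; rebuild down links ancestor-ward
    below <- cur_sig
    for (j in seq_along(rollout$chain)[-1]) {
      st <- rollout$chain[[j]]
      sg <- esig(st$ids, st$signs)
      assign(sg, list(ids = st$ids, signs = st$signs, cost = st$cost,
                      nev = j - 1L, down = list(list(sig = below, event = st$event)),
                      src = NULL), envir = nodes)
      below <- sg
    }
    solutions <- below
  }
  list(min_cost = MIN, solutions = solutions, nodes = nodes, g = g)
}

# Deterministic constructive schedule from one state up to g genes: always
# collapse the largest available duplication pattern; when none is
# adjacent, pay one inversion to bring the deepest remaining cherry
# together.  Returns the chain of states (observed first) with the forward
# event and accumulated cost at each step.
engine_rollout <- function(ids, signs, P, g, costs, genome) {
  chain <- list(list(ids = ids, signs = signs, cost = 0, event = NULL))
  cost <- 0
  guard <- 0L
  cur_ids <- ids; cur_signs <- signs
  while (length(cur_ids) > g) {
    guard <- guard + 1L
    if (guard > 4L * length(ids) + 8L) return(NULL)
    preds <- c(
      if ("dup" %in% costs$enabled)
        duplication_predecessors(cur_ids, cur_signs, P, genome),
      if ("inv_dup" %in% costs$enabled)
        inverted_duplication_predecessors(cur_ids, cur_signs, P, genome)
    )
    if (length(preds)) {
      m <- vapply(preds, function(p) p$event$span[2] - p$event$span[1] + 1L,
                  integer(1))
      pick <- which(m == max(m))[1]
      pr <- preds[[pick]]
      ev <- pr$event
      ekey <- if (ev$type == "DUP") "dup" else "inv_dup"
      cost <- cost + costs$alpha[[ekey]] +
        (ev$span[2] - ev$span[1] + 1L) * costs$beta[[ekey]]
      cur_ids <- pr$ids; cur_signs <- pr$signs
      chain[[length(chain) + 1L]] <-
        list(ids = cur_ids, signs = cur_signs, cost = cost, event = ev)
      next
    }
    if (!"inv" %in% costs$enabled) return(NULL)
    # no pattern is adjacent: bring the closest sibling pair together
    par <- unname(P[cur_ids])
    pp <- which(!is.na(par))
    tab <- split(pp, par[pp])
    pairs <- Filter(function(x) length(x) == 2L, tab)
    if (!length(pairs)) return(NULL)    # cannot happen above the roots
    gaps <- vapply(pairs, function(x) x[2] - x[1], integer(1))
    pair <- pairs[[which(gaps == min(gaps))[1]]]
    i <- pair[1]; j <- pair[2]
    span <- c(i + 1L, j)
    cur_ids[span[1]:span[2]] <- cur_ids[span[2]:span[1]]
    cur_signs[span[1]:span[2]] <- -cur_signs[span[2]:span[1]]
    ev <- new_event("INV", genome, span = span)
    cost <- cost + costs$alpha[["inv"]] +
      (span[2] - span[1] + 1L) * costs$beta[["inv"]]
    chain[[length(chain) + 1L]] <-
      list(ids = cur_ids, signs = cur_signs, cost = cost, event = ev)
  }
  list(cost = cost, chain = chain)
}
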