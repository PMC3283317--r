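# Backward (predecessor) neighbourhoods ------------------------------------
#
# The history graph is explored backwards from the observed ordered gene
# tree.  Within a branch search the working gene tree is fully determined by
# the static branch forest (from the reconciliation, or the input gene tree
# itself for a single-cluster search) plus the set of gene ids currently in
# the order: a state is just a signed order over forest vertices, and
# undoing a duplication replaces a cherry (two current ids sharing a forest
# parent) by that parent.  Each operator returns every predecessor state
# together with the forward event (in predecessor coordinates) that maps it
# back to the argument state.
#
# Deletions appear only in combination with duplications (a compound event:
# duplicate m genes, then delete a contiguous run inside one copy block),
# which keeps the history graph finite.  In a compound undo the copies that
# were deleted are represented by their surviving partner, which simply
# keeps its id in the predecessor (it stands for the ancestral gene).

pred_state <- function(ids, signs, event) list(ids = ids, signs = signs, event = event)

#' Predecessors by undoing a direct tandem duplication
#'
#' Finds every pattern `(l_p..l_q, r_p..r_q)` of 2m contiguous genes where
#' each `(l_x, r_x)` is a cherry of the forest and signs match, and collapses
#' it to the ancestral segment.
#'
#' @param ids,signs the current signed order.
#' @param P named character parent map of the branch forest (`NA` at roots).
#' @param genome genome id recorded on the undone event.
#' @return list of `list(ids, signs, event)`.
#' @keywords internal
duplication_predecessors <- function(ids, signs, P, genome) {
  n <- length(ids)
  out <- list()
  par <- unname(P[ids])
  if (!any(duplicated(par[!is.na(par)]))) return(out)  # no cherry anywhere
  for (m in seq_len(n %/% 2L)) {
    # pair_ok[i]: positions (i, i+m) are a sign-consistent cherry
    i <- seq_len(n - m)
    pair_ok <- !is.na(par[i]) & !is.na(par[i + m]) &
      par[i] == par[i + m] & signs[i] == signs[i + m]
    if (!any(pair_ok)) next
    # a window (a, m) matches iff pair_ok[a .. a+m-1] are all TRUE
    bad <- cumsum(c(0L, !pair_ok))
    for (a in seq_len(n - 2L * m + 1L)) {
      if (bad[a + m] - bad[a] > 0L) next
      L <- a:(a + m - 1L); R <- (a + m):(a + 2L * m - 1L)
      new_ids <- append(ids[-c(L, R)], par[L], after = a - 1L)
      new_signs <- append(signs[-c(L, R)], signs[L], after = a - 1L)
      ev <- new_event("DUP", genome, span = c(a, a + m - 1L),
                      child_labels = list(left = ids[L], right = ids[R]))
      out[[length(out) + 1L]] <- pred_state(new_ids, new_signs, ev)
    }
  }
  out
}

#' Predecessors by undoing an inverted duplication
#'
#' Both placements are detected: the left copy block reversed and negated
#' (`variant = "left"`), or the right one (`variant = "right"`).
#' @inheritParams duplication_predecessors
#' @keywords internal
inverted_duplication_predecessors <- function(ids, signs, P, genome) {
  n <- length(ids)
  out <- list()
  par <- unname(P[ids])
  if (!any(duplicated(par[!is.na(par)]))) return(out)  # no cherry anywhere
  # both placements pair the window positions mirrored around the gap
  # c-1 | c with opposite signs; scan each gap's palindromic cherry radius
  for (cgap in 2:max(2L, n)) {
    if (cgap > n) break
    r <- 0L
    while (cgap - 1L - r >= 1L && cgap + r <= n) {
      i <- cgap - 1L - r; j <- cgap + r
      if (is.na(par[i]) || is.na(par[j]) || par[i] != par[j] ||
          signs[i] != -signs[j]) break
      r <- r + 1L
    }
    if (r == 0L) next
    for (m in seq_len(r)) {
      a <- cgap - m
      L <- a:(a + m - 1L); R <- (a + m):(a + 2L * m - 1L)
      rest_ids <- ids[-c(L, R)]; rest_signs <- signs[-c(L, R)]
      # variant "left": window = (-l_q .. -l_p, r_p .. r_q)
      new_ids <- append(rest_ids, par[rev(L)], after = a - 1L)
      new_signs <- append(rest_signs, signs[R], after = a - 1L)
      ev <- new_event("INV_DUP", genome, span = c(a, a + m - 1L),
                      variant = "left",
                      child_labels = list(left = rev(ids[L]), right = ids[R]))
      out[[length(out) + 1L]] <- pred_state(new_ids, new_signs, ev)
      # variant "right": window = (l_p .. l_q, -r_q .. -r_p)
      new_ids2 <- append(rest_ids, par[L], after = a - 1L)
      new_signs2 <- append(rest_signs, signs[L], after = a - 1L)
      ev2 <- new_event("INV_DUP", genome, span = c(a, a + m - 1L),
                       variant = "right",
                       child_labels = list(left = ids[L], right = rev(ids[R])))
      out[[length(out) + 1L]] <- pred_state(new_ids2, new_signs2, ev2)
    }
  }
  out
}

#' Predecessors by undoing an inversion
#'
#' One predecessor per contiguous span: reverse and negate it; the tree is
#' untouched.  Exactly n(n+1)/2 predecessors.
#' @inheritParams duplication_predecessors
#' @keywords internal
inversion_predecessors <- function(ids, signs, P, genome) {
  n <- length(ids)
  out <- vector("list", n * (n + 1L) / 2L)
  k <- 0L
  for (p in seq_len(n)) {
    for (q in p:n) {
      new_ids <- ids; new_signs <- signs
      new_ids[p:q] <- rev(new_ids[p:q])
      new_signs[p:q] <- rev(-new_signs[p:q])
      k <- k + 1L
      out[[k]] <- pred_state(new_ids, new_signs,
                             new_event("INV", genome, span = c(p, q)))
    }
  }
  out
}

#' Predecessors by undoing a duplication-with-deletion compound
#'
#' Patterns where a duplication of m contiguous genes was followed by the
#' deletion of a contiguous run of k copies (1 <= k < m) inside one copy
#' block.  Copies present in both blocks must form sign-consistent
#' cherries; a copy whose partner was deleted keeps its id (it represents
#' the ancestral gene).  Both direct and inverted duplications are handled.
#' @inheritParams duplication_predecessors
#' @keywords internal
duplication_with_deletion_predecessors <- function(ids, signs, P, genome) {
  n <- length(ids)
  out <- list()
  if (n < 1L) return(out)
  par <- unname(P[ids])
  # block descriptors: sigA/sigB = sign factor, revA/revB = display reversal
  variants <- list(
    list(type = "DUP", variant = NULL, sigA = 1L, sigB = 1L,
         revA = FALSE, revB = FALSE),
    list(type = "INV_DUP", variant = "left", sigA = -1L, sigB = 1L,
         revA = TRUE, revB = FALSE),
    list(type = "INV_DUP", variant = "right", sigA = 1L, sigB = -1L,
         revA = FALSE, revB = TRUE)
  )
  if (!any(duplicated(par[!is.na(par)]))) return(out)  # no cherry anywhere
  for (vi in seq_along(variants)) {
    vr <- variants[[vi]]
    for (partial in c("A", "B")) {
      tb <- compound_gate_table(n, vi, vr, partial)
      if (!nrow(tb)) next
      # one vectorized gate on the first and last survivor pairs of every
      # candidate (variant, window, deletion run) before full matching
      ok <- !is.na(par[tb$ia]) & !is.na(par[tb$ib]) &
        par[tb$ia] == par[tb$ib] &
        signs[tb$ia] * vr$sigA == signs[tb$ib] * vr$sigB &
        !is.na(par[tb$ja]) & !is.na(par[tb$jb]) &
        par[tb$ja] == par[tb$jb] &
        signs[tb$ja] * vr$sigA == signs[tb$jb] * vr$sigB
      for (j in which(ok)) {
        a <- tb$a[j]; m <- tb$m[j]
        cand <- compound_match(ids, signs, par, a, m, tb$k[j], tb$d[j],
                               partial, vr)
        if (!is.null(cand)) {
          ev <- new_event(vr$type, genome, span = c(a, a + m - 1L),
                          variant = vr$variant,
                          deleted_subspan = cand$del_span,
                          child_labels = cand$child_labels)
          out[[length(out) + 1L]] <- pred_state(cand$ids, cand$signs, ev)
        }
      }
    }
  }
  out
}

# Candidate (window start, ancestor size, deletion run) table for the
# compound gate, with the first-survivor-pair positions precomputed; pure
# geometry, so cached per (order length, variant, partial block).
.gate_cache <- new.env(parent = emptyenv())

compound_gate_table <- function(n, vi, vr, partial) {
  key <- paste0(n, ":", vi, ":", partial)
  hit <- .gate_cache[[key]]
  if (!is.null(hit)) return(hit)
  rows_m <- integer(0); rows_k <- integer(0); rows_d <- integer(0)
  rows_a <- integer(0); rows_ia <- integer(0); rows_ib <- integer(0)
  rows_ja <- integer(0); rows_jb <- integer(0)
  pos_in <- function(x, rank, len, rev) if (rev) len - rank + 1L else rank
  if (n >= 3L) {
    for (m in 2:n) {
      for (k in seq_len(m - 1L)) {
        w <- 2L * m - k
        if (w > n) next
        lenA <- if (partial == "A") m - k else m
        lenB <- if (partial == "B") m - k else m
        av <- seq_len(n - w + 1L)
        for (d in seq_len(m - k + 1L)) {
          x1 <- if (d == 1L) k + 1L else 1L      # first surviving copy
          xl <- if (d + k - 1L == m) d - 1L else m  # last surviving copy
          rl <- m - k                             # its rank among survivors
          pA1 <- if (partial == "A") pos_in(x1, 1L, lenA, vr$revA) else
            pos_in(x1, x1, m, vr$revA)
          pB1 <- if (partial == "B") pos_in(x1, 1L, lenB, vr$revB) else
            pos_in(x1, x1, m, vr$revB)
          pAl <- if (partial == "A") pos_in(xl, rl, lenA, vr$revA) else
            pos_in(xl, xl, m, vr$revA)
          pBl <- if (partial == "B") pos_in(xl, rl, lenB, vr$revB) else
            pos_in(xl, xl, m, vr$revB)
          rows_m <- c(rows_m, rep.int(m, length(av)))
          rows_k <- c(rows_k, rep.int(k, length(av)))
          rows_d <- c(rows_d, rep.int(d, length(av)))
          rows_a <- c(rows_a, av)
          rows_ia <- c(rows_ia, av - 1L + pA1)
          rows_ib <- c(rows_ib, av - 1L + lenA + pB1)
          rows_ja <- c(rows_ja, av - 1L + pAl)
          rows_jb <- c(rows_jb, av - 1L + lenA + pBl)
        }
      }
    }
  }
  tb <- list(m = rows_m, k = rows_k, d = rows_d, a = rows_a,
             ia = rows_ia, ib = rows_ib, ja = rows_ja, jb = rows_jb)
  tb <- structure(tb, class = "data.frame",
                  row.names = seq_along(rows_m))
  .gate_cache[[key]] <- tb
  tb
}

# Attempt to read a compound pattern at window start `a`: ancestor size m,
# deleted x-run d..d+k-1 missing from the `partial` block.  Returns NULL or
# the predecessor plus event pieces.
compound_match <- function(ids, signs, par, a, m, k, d, partial, vr) {
  surv <- setdiff(seq_len(m), d:(d + k - 1L))
  lenA <- if (partial == "A") m - k else m
  lenB <- if (partial == "B") m - k else m
  offA <- a - 1L
  offB <- a - 1L + lenA
  # display positions of every ancestor index x in each block (NA if absent)
  rankA <- if (partial == "A") match(seq_len(m), surv) else seq_len(m)
  rankB <- if (partial == "B") match(seq_len(m), surv) else seq_len(m)
  posA <- if (vr$revA) lenA - rankA + 1L else rankA
  posB <- if (vr$revB) lenB - rankB + 1L else rankB
  ia <- offA + posA[surv]; ib <- offB + posB[surv]
  pA <- par[ia]; pB <- par[ib]
  if (anyNA(pA) || anyNA(pB) || any(pA != pB)) return(NULL)
  sA <- signs[ia] * vr$sigA; sB <- signs[ib] * vr$sigB
  if (any(sA != sB)) return(NULL)
  anc_ids <- character(m); anc_signs <- integer(m)
  l_ids <- character(m); r_ids <- character(m)
  anc_ids[surv] <- pA; anc_signs[surv] <- sA
  l_ids[surv] <- ids[ia]; r_ids[surv] <- ids[ib]
  gone <- setdiff(seq_len(m), surv)
  if (partial == "A") {
    jb <- offB + posB[gone]
    anc_ids[gone] <- ids[jb]; anc_signs[gone] <- signs[jb] * vr$sigB
    l_ids[gone] <- paste0(ids[jb], ":del"); r_ids[gone] <- ids[jb]
  } else {
    ja <- offA + posA[gone]
    anc_ids[gone] <- ids[ja]; anc_signs[gone] <- signs[ja] * vr$sigA
    l_ids[gone] <- ids[ja]; r_ids[gone] <- paste0(ids[ja], ":del")
  }
  w <- 2L * m - k
  win <- a:(a + w - 1L)
  new_ids <- append(ids[-win], anc_ids, after = a - 1L)
  if (anyDuplicated(new_ids)) return(NULL)
  new_signs <- append(signs[-win], anc_signs, after = a - 1L)
  # deleted run in post-duplication display coordinates
  full_posA <- function(x) if (vr$revA) m - x + 1L else x
  full_posB <- function(x) if (vr$revB) m - x + 1L else x
  dr <- d:(d + k - 1L)
  disp <- if (partial == "A") {
    (a - 1L) + vapply(dr, full_posA, integer(1))
  } else {
    (a - 1L + m) + vapply(dr, full_posB, integer(1))
  }
  list(ids = new_ids, signs = new_signs,
       del_span = c(min(disp), max(disp)),
       child_labels = list(left = l_ids, right = r_ids))
}

#' All enabled predecessor moves of a state
#'
#' `include_inv` / `include_cmp` let the search skip whole operator
#' families when no inversion or compound undo can still lead to a
#' minimum-cost solution (their cost exceeds any possible drop of the
#' completion bound).
#' @keywords internal
all_predecessors <- function(ids, signs, P, genome, costs,
                             include_inv = TRUE, include_cmp = TRUE) {
  en <- costs$enabled
  out <- list()
  if ("dup" %in% en) {
    out <- c(out, duplication_predecessors(ids, signs, P, genome))
  }
  if ("inv_dup" %in% en) {
    out <- c(out, inverted_duplication_predecessors(ids, signs, P, genome))
  }
  if ("inv" %in% en && include_inv) {
    out <- c(out, inversion_predecessors(ids, signs, P, genome))
  }
  if ("del" %in% en && include_cmp) {
    if ("dup" %in% en || "inv_dup" %in% en) {
      cmp <- duplication_with_deletion_predecessors(ids, signs, P, genome)
      if (!"dup" %in% en) {
        cmp <- Filter(function(p) p$event$type != "DUP", cmp)
      }
      if (!"inv_dup" %in% en) {
        cmp <- Filter(function(p) p$event$type != "INV_DUP", cmp)
      }
      out <- c(out, cmp)
    }
  }
  out
}
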