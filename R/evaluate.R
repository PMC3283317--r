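# Simulation experiments: duplication-count and size-distribution accuracy --

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483587)
}

#' Duplication-count recovery experiment
#'
#' For each total duplication count `x` and each replicate: simulate a
#' history with `x` duplications (half direct, half inverted) plus the
#' requested fraction of inversions, run the multi-species inference, and
#' compare the number of inferred duplications (direct + inverted) in the
#' traced-back history with the truth.
#'
#' @param x_values totals of simulated duplications to sweep.
#' @param inversion_fraction 0, 1/3 or 1/2.
#' @param replicates replicates per `x`.
#' @param seed master seed; replicate seeds derive deterministically.
#' @param leaves number of extant genomes.
#' @param costs,params forwarded to [multi_diltag()].
#' @return an object of class `dup_count_experiment`: a per-replicate
#'   tibble plus aggregate means.
#' @export
run_duplication_count_experiment <- function(x_values = c(2L, 4L, 6L),
                                             inversion_fraction = 0,
                                             replicates = 20L, seed = 1L,
                                             leaves = 2L,
                                             costs = cost_model(),
                                             params = search_params()) {
  rows <- list()
  i <- 0L
  for (x in x_values) {
    for (r in seq_len(replicates)) {
      i <- i + 1L
      rs <- derive_seed(seed, i)
      design <- named_design("fig6", leaves = leaves, x = x,
                             inversion_fraction = inversion_fraction)
      sim <- simulate_history(design, seed = rs)
      fit <- multi_diltag(sim$gene_tree, sim$leaf_orders,
                          design$species_tree, costs = costs, params = params)
      rep_tb <- branch_event_report(fit)
      rows[[i]] <- tibble::tibble(
        x = x, replicate = r, seed = rs,
        true_dups = sum(sim$truth$type %in% c("DUP", "INV_DUP")),
        inferred_dups = sum(rep_tb$n_dup) + sum(rep_tb$n_inv_dup),
        valid = isTRUE(fit$valid$ok), total_cost = fit$total_cost
      )
    }
  }
  rows <- dplyr::bind_rows(rows)
  agg <- rows |>
    dplyr::group_by(x) |>
    dplyr::summarise(mean_true = mean(true_dups),
                     mean_inferred = mean(inferred_dups),
                     mean_rel_error = mean(abs(inferred_dups - true_dups) /
                                             pmax(true_dups, 1L)),
                     all_valid = all(valid), .groups = "drop")
  structure(list(replicates = rows, summary = agg,
                 inversion_fraction = inversion_fraction, seed = seed,
                 leaves = leaves),
            class = "dup_count_experiment")
}

#' @export
print.dup_count_experiment <- function(x, ...) {
  cat(sprintf("<dup_count_experiment: %d%% inversions>\n",
              round(100 * x$inversion_fraction)))
  print(x$summary)
  invisible(x)
}

#' Duplication-size-distribution recovery experiment
#'
#' Simulates the per-branch design "4 tandem duplications, 1 inverted
#' duplication, 1 inversion, 1 deletion of size 1 or 2", infers histories,
#' and compares the inferred duplication-size distribution with the truth:
#' total-variation distance plus the size-1 and size-2 biases
#' (inferred minus true frequency).
#'
#' @param replicates number of replicates.
#' @param seed master seed.
#' @param leaves number of extant genomes.
#' @param costs,params forwarded to [multi_diltag()].
#' @return an object of class `size_dist_experiment`.
#' @export
run_size_distribution_experiment <- function(replicates = 20L, seed = 1L,
                                             leaves = 2L,
                                             costs = cost_model(),
                                             params = search_params()) {
  rows <- list()
  true_sizes <- integer(0)
  inf_sizes <- integer(0)
  for (r in seq_len(replicates)) {
    rs <- derive_seed(seed, r + 131L)
    design <- named_design("fig7", leaves = leaves)
    sim <- simulate_history(design, seed = rs)
    fit <- multi_diltag(sim$gene_tree, sim$leaf_orders, design$species_tree,
                        costs = costs, params = params)
    rep_tb <- branch_event_report(fit)
    ts <- sim$truth$size[sim$truth$type %in% c("DUP", "INV_DUP")]
    is <- unlist(rep_tb$dup_sizes)
    true_sizes <- c(true_sizes, ts)
    inf_sizes <- c(inf_sizes, is)
    rows[[r]] <- tibble::tibble(replicate = r, seed = rs,
                                n_true = length(ts), n_inferred = length(is),
                                valid = isTRUE(fit$valid$ok),
                                total_cost = fit$total_cost)
  }
  sizes <- seq_len(max(c(true_sizes, inf_sizes, 1L)))
  p_true <- tabulate(true_sizes, nbins = max(sizes)) / max(length(true_sizes), 1L)
  p_inf <- tabulate(inf_sizes, nbins = max(sizes)) / max(length(inf_sizes), 1L)
  structure(list(
    replicates = dplyr::bind_rows(rows),
    distribution = tibble::tibble(size = sizes, true_freq = p_true,
                                  inferred_freq = p_inf),
    tv_distance = sum(abs(p_true - p_inf)) / 2,
    size1_bias = p_inf[1] - p_true[1],
    size2_bias = if (length(p_true) >= 2L) p_inf[2] - p_true[2] else 0,
    seed = seed, leaves = leaves
  ), class = "size_dist_experiment")
}

#' @export
print.size_dist_experiment <- function(x, ...) {
  cat(sprintf("<size_dist_experiment: TV = %.3f, size-1 bias = %+.3f, size-2 bias = %+.3f>\n",
              x$tv_distance, x$size1_bias, x$size2_bias))
  invisible(x)
}
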