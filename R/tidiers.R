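# broom-style tidiers --------------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn branch_event_report `tidy()` method: the per-branch event table.
#' @param x a `multi_diltag` object.
#' @param ... unused.
#' @method tidy multi_diltag
#' @export
tidy.multi_diltag <- function(x, ...) branch_event_report(x)

#' One-row summary of a multi-species fit
#' @param x a `multi_diltag` object.
#' @param ... unused.
#' @method glance multi_diltag
#' @export
glance.multi_diltag <- function(x, ...) {
  tibble::tibble(
    total_cost = x$total_cost,
    n_species = length(x$leaf_orders),
    n_genes = length(tree_leaves(x$gene_tree)),
    n_events = sum(vapply(x$history$events, function(e) e$type != "SPEC",
                          logical(1))),
    n_root_candidates = length(x$root_candidates),
    valid = isTRUE(x$valid$ok),
    root_order = x$root_order
  )
}

#' @describeIn diltag `tidy()` method: the solution set as a tibble.
#' @param x a `diltag_result` object.
#' @param ... unused.
#' @method tidy diltag_result
#' @export
tidy.diltag_result <- function(x, ...) x$solution_set

#' One-row summary of a single-cluster search
#' @param x a `diltag_result` object.
#' @param ... unused.
#' @method glance diltag_result
#' @export
glance.diltag_result <- function(x, ...) {
  tibble::tibble(min_cost = x$min_cost, g = x$g,
                 n_solutions = nrow(x$solution_set))
}

#' @describeIn run_duplication_count_experiment `tidy()` method: per-x means.
#' @param x a `dup_count_experiment` object.
#' @param ... unused.
#' @method tidy dup_count_experiment
#' @export
tidy.dup_count_experiment <- function(x, ...) x$summary

#' @describeIn run_duplication_count_experiment `glance()` method.
#' @method glance dup_count_experiment
#' @export
glance.dup_count_experiment <- function(x, ...) {
  tibble::tibble(inversion_fraction = x$inversion_fraction,
                 leaves = x$leaves,
                 mean_rel_error = mean(x$summary$mean_rel_error),
                 overestimation = mean(x$summary$mean_inferred -
                                         x$summary$mean_true),
                 all_valid = all(x$replicates$valid))
}

#' @describeIn run_size_distribution_experiment `tidy()` method: the size
#'   distribution table.
#' @param x a `size_dist_experiment` object.
#' @param ... unused.
#' @method tidy size_dist_experiment
#' @export
tidy.size_dist_experiment <- function(x, ...) x$distribution

#' @describeIn run_size_distribution_experiment `glance()` method.
#' @method glance size_dist_experiment
#' @export
glance.size_dist_experiment <- function(x, ...) {
  tibble::tibble(tv_distance = x$tv_distance, size1_bias = x$size1_bias,
                 size2_bias = x$size2_bias,
                 all_valid = all(x$replicates$valid))
}
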