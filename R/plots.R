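# ggplot2 displays -----------------------------------------------------------

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_abline labs position_dodge theme_minimal
#' @export
ggplot2::autoplot

#' Plot inferred versus true duplication counts
#' @param object a [run_duplication_count_experiment()] result.
#' @param ... unused.
#' @method autoplot dup_count_experiment
#' @export
autoplot.dup_count_experiment <- function(object, ...) {
  ggplot(object$summary, aes(x = .data$mean_true, y = .data$mean_inferred)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_line() +
    geom_point() +
    labs(x = "simulated duplications",
         y = "inferred duplications (direct + inverted)",
         title = sprintf("Duplication-count recovery (%d%% inversions)",
                         round(100 * object$inversion_fraction))) +
    theme_minimal()
}

#' Plot true versus inferred duplication-size distributions
#' @param object a [run_size_distribution_experiment()] result.
#' @param ... unused.
#' @method autoplot size_dist_experiment
#' @export
autoplot.size_dist_experiment <- function(object, ...) {
  d <- tidyr::pivot_longer(object$distribution, c("true_freq", "inferred_freq"),
                           names_to = "which", values_to = "freq")
  d$which <- ifelse(d$which == "true_freq", "true", "inferred")
  ggplot(d, aes(x = factor(.data$size), y = .data$freq, fill = .data$which)) +
    geom_col(position = position_dodge()) +
    labs(x = "duplication size (genes)", y = "frequency", fill = NULL,
         title = sprintf("Duplication-size distribution (TV = %.3f)",
                         object$tv_distance)) +
    theme_minimal()
}

#' Plot per-branch inferred event counts
#' @param object a [multi_diltag()] result.
#' @param ... unused.
#' @method autoplot multi_diltag
#' @export
autoplot.multi_diltag <- function(object, ...) {
  tb <- branch_event_report(object)
  d <- tidyr::pivot_longer(tb[, c("branch", "n_dup", "n_inv_dup", "n_inv", "n_del")],
                           -"branch", names_to = "event", values_to = "count")
  d$event <- sub("^n_", "", d$event)
  ggplot(d, aes(x = .data$branch, y = .data$count, fill = .data$event)) +
    geom_col(position = position_dodge()) +
    labs(x = "species-tree branch (child vertex)", y = "inferred events",
         fill = NULL) +
    theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
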