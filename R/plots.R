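#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_step labs facet_wrap position_dodge theme_minimal
#' @export
ggplot2::autoplot

#' Plot a property-distribution comparison
#'
#' Side-by-side histograms of one physico-chemical property for two
#' datasets, annotated with the Wasserstein-1 distance.
#'
#' @param object a `property_comparison` from [compare_distributions()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.property_comparison <- function(object, ...) {
  ggplot(object$histogram,
         aes(x = .data$mid, y = .data$density, fill = .data$dataset)) +
    geom_col(position = position_dodge(), alpha = 0.8) +
    labs(x = object$property, y = "relative frequency",
         title = sprintf("%s distribution (Wasserstein-1 = %.3g)",
                         object$property, object$distance)) +
    theme_minimal()
}

#' Plot a hyperparameter-optimization trace
#'
#' Per-trial objective (mean cross-validated MCC) with the running best.
#'
#' @param object an `hpo_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hpo_result <- function(object, ...) {
  tr <- object$trace
  tr$best_so_far <- cummax(tr$score)
  ggplot(tr, aes(x = .data$trial)) +
    geom_point(aes(y = .data$score), alpha = 0.6) +
    geom_step(aes(y = .data$best_so_far), colour = "firebrick") +
    labs(y = "mean CV MCC",
         title = sprintf("HPO trace: %s (best %.3f)", object$algo,
                         object$best_score)) +
    theme_minimal()
}

#' Plot train/test length distributions of a split
#'
#' @param object a `dataset_split`.
#' @param data the peptide tibble the split was made from.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dataset_split <- function(object, data, ...) {
  d <- tidy(object) |>
    left_join(data[, c("id", "sequence")], by = "id") |>
    mutate(length = nchar(.data$sequence))
  ggplot(d, aes(x = .data$length, fill = .data$set)) +
    ggplot2::geom_histogram(binwidth = 5, boundary = 0,
                            position = "identity", alpha = 0.6) +
    labs(x = "peptide length (residues)", y = "count",
         title = sprintf("%s split: %d train / %d test", object$method,
                         length(object$train_ids),
                         length(object$test_ids))) +
    theme_minimal()
}

#' Plot member scores behind an ensemble prediction
#'
#' Ranked ensemble scores with per-peptide uncertainty bars (member-score
#' standard deviation).
#'
#' @param object a prediction tibble from [predict_peptides()] or
#'   [predict.peptide_ensemble()].
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_predictions <- function(object, ...) {
  d <- object |> arrange(dplyr::desc(.data$score)) |>
    mutate(rank = dplyr::row_number())
  ggplot(d, aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_ribbon(aes(ymin = pmax(0, .data$score - .data$uncertainty),
                             ymax = pmin(1, .data$score + .data$uncertainty)),
                         alpha = 0.3) +
    geom_line() +
    labs(x = "rank", y = "ensemble score",
         title = "Predicted bioactivity (band: member-score SD)") +
    theme_minimal()
}
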