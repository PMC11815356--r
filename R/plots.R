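#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot LOO-CV AUC by model and species
#'
#' @param object A `colonization_analysis`.
#' @param ... Unused.
#' @return A ggplot: one panel per species, models on the y axis, a dashed
#'   line at AUC 0.5 (random) and a dotted line at the environment-only AUC.
#' @export
autoplot.colonization_analysis <- function(object, ...) {
  tab <- dplyr::mutate(object$auc_table,
                       model = factor(.data$model_id, levels = 10:1))
  env <- dplyr::filter(tab, .data$model_id == 1)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$auc, y = .data$model)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_vline(data = env,
                        ggplot2::aes(xintercept = .data$auc),
                        linetype = "dotted") +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = "LOO-CV AUC", y = "model id") +
    ggplot2::theme_minimal()
}

#' Plot a colonization prevalence report
#'
#' @param object A `prevalence_report`.
#' @param ... Unused.
#' @return A ggplot of per-species detection prevalence by year.
#' @export
autoplot.prevalence_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$species, y = .data$prevalence,
                               fill = .data$year)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "proportion of target logs occupied") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot variance-partition shares
#'
#' @param object A `variance_partition` (optionally with a `species`
#'   column).
#' @param ... Unused.
#' @return A stacked-bar ggplot of the shares.
#' @export
autoplot.variance_partition <- function(object, ...) {
  if (!"species" %in% names(object)) object$species <- "model"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$species, y = .data$share,
                               fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "share of explained variance") +
    ggplot2::theme_minimal()
}

#' Plot ordination scores
#'
#' @param object An `ordination_fit`.
#' @param ... Unused.
#' @return A ggplot scatter of the first two latent-variable scores.
#' @export
autoplot.ordination_fit <- function(object, ...) {
  sc <- tibble::as_tibble(object$scores, rownames = "id")
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$LV1, y = .data$LV2)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(title = sprintf("model-based ordination (%s)",
                                  object$family)) +
    ggplot2::theme_minimal()
}

#' Plot posterior coefficient intervals
#'
#' @param object A `probit_fit`.
#' @param ... Passed to [posterior_summary()].
#' @return A ggplot of posterior means and credible intervals per predictor,
#'   coloured by predictor group.
#' @export
autoplot.probit_fit <- function(object, ...) {
  s <- posterior_summary(object, ...)
  s$term <- factor(s$term, levels = rev(s$term))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$estimate, y = .data$term,
                                  colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "posterior coefficient", y = NULL) +
    ggplot2::theme_minimal()
}
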