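#' Plot TM-score comparison records
#'
#' Jittered TM-scores by comparison mode with the similarity-band thresholds
#' (0.17 random-like, 0.3 significant, 0.5 same fold) as horizontal lines.
#'
#' @param records A comparison-record tibble (columns `mode`, `tm`).
#' @return A ggplot object.
#' @export
plot_comparisons <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$mode, y = .data$tm)) +
    ggplot2::geom_hline(yintercept = c(0.17, 0.3, 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "TM-score") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.classification_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$fold),
                                  y = .data$misclassification)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$mean_misclassification,
                        linetype = "dashed") +
    ggplot2::labs(x = "fold", y = "misclassification rate") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.feature_mode_comparison <- function(object, ...) {
  d <- tidy(object)
  d$fold <- factor(d$fold)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature_mode,
                                  y = .data$misclassification,
                                  group = .data$fold)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "misclassification rate",
                  title = "static vs dynamic PSN features (paired folds)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dynamic_psn <- function(object, ...) {
  d <- purrr::map_dfr(seq_along(object$snapshots), function(t) {
    gv <- count_graphlets(object$snapshots[[t]])
    tibble::tibble(snapshot = t, graphlet = names(gv$counts),
                   count = as.numeric(gv$counts))
  })
  d$graphlet <- factor(d$graphlet, levels = graphlet_classes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$snapshot, y = .data$count,
                                  colour = .data$graphlet)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "snapshot", y = "graphlet count") +
    ggplot2::theme_minimal()
}
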