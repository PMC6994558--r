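#' Plot projection scores
#'
#' Bar chart of projection scores per query sample, one facet per sample,
#' with the significance threshold drawn when a calibration is supplied.
#'
#' @param scores Tibble from [project_onto_basis()] (optionally through
#'   [classify_significant()]).
#' @param calibration Optional `null_calibration`; draws dashed lines at
#'   +/- threshold.
#' @return A ggplot object.
#' @export
plot_projection_scores <- function(scores, calibration = NULL) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(
    x = .data$cell_type, y = .data$score,
    fill = if ("significant" %in% names(scores)) .data$significant else NULL)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = NULL, y = "projection score", fill = "significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(calibration)) {
    p <- p + ggplot2::geom_hline(
      yintercept = c(-1, 1) * calibration$threshold, linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname calibrate_null
#' @param object A `null_calibration` built with `keep_scores = TRUE`.
#' @exportS3Method ggplot2::autoplot
autoplot.null_calibration <- function(object, ...) {
  if (is.null(object$scores)) {
    stop("calibration was built with keep_scores = FALSE", call. = FALSE)
  }
  ggplot2::ggplot(tibble::tibble(score = as.vector(object$scores)),
                  ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 80) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "null projection score", y = "count",
                  title = sprintf("random-profile null (R = %d, sd = %.4f)",
                                  object$R, object$sd)) +
    ggplot2::theme_minimal()
}

#' Plot enrichment scores
#'
#' Heat-style tile plot of the condition x sample enrichment-score table.
#'
#' @param es Tibble from [score_signatures()].
#' @return A ggplot object.
#' @export
plot_enrichment_scores <- function(es) {
  ggplot2::ggplot(es, ggplot2::aes(x = .data$sample_id, y = .data$condition,
                                   fill = .data$es)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL, fill = "ES") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
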