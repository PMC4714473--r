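#' Plot a dominance tournament
#'
#' Bar chart of normalized tournament weights with the beta threshold drawn
#' as a dashed line; dominant molecules are filled.
#'
#' @param object A `litfun_dominance` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot litfun_dominance
#' @export
autoplot.litfun_dominance <- function(object, ...) {
  df <- mutate(object$scores,
               molecule = stats::reorder(.data$molecule, -.data$weight))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$molecule, y = .data$weight,
                                   fill = .data$dominant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$beta, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey25",
                                          `FALSE` = "grey75"),
                               name = "dominant") +
    ggplot2::labs(x = NULL, y = "normalized tournament weight",
                  subtitle = sprintf("beta = %.3f", object$beta)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a protein-centric precision-recall curve
#'
#' @param object A `litfun_pr_curve` tibble from [cafa_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot litfun_pr_curve
#' @export
autoplot.litfun_pr_curve <- function(object, ...) {
  df <- filter(as_tibble(object), !is.na(.data$pr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rc, y = .data$pr)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}

#' Heatmap of a per-abstract weight table
#'
#' @param weights Long weight tibble (`molecule`, `abstract_id`, `weight`).
#' @return A ggplot object.
#' @export
plot_weight_matrix <- function(weights) {
  ggplot2::ggplot(weights, ggplot2::aes(x = .data$molecule,
                                        y = .data$abstract_id,
                                        fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey20") +
    ggplot2::labs(x = NULL, y = NULL, fill = "w") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
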