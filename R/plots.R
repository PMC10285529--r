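#' Plot a processed image
#'
#' `type = "counts"` shows the per-class object counts; `type = "labels"`
#' shows the classified ROIs as coloured tiles over the image canvas
#' (background blank).
#'
#' @param object An `nq_result`.
#' @param type `"counts"` or `"labels"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nq_result <- function(object, type = c("counts", "labels"), ...) {
  type <- match.arg(type)
  if (type == "counts") {
    cls <- c("PMN", "RND", "RUP", "PER", "BACTERIA", "NET", "EXTRA_ARTIFACT",
             "UNKNOWN_INTRACELLULAR")
    df <- tibble::tibble(
      class = factor(cls, levels = cls),
      count = unlist(object$summary[cls])
    )
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$count)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::labs(
          title = object$source_id,
          subtitle = sprintf("Q = %.1f%%, NET area %.2f%%",
                             object$summary$quality_score,
                             object$summary$net_area_fraction),
          x = NULL, y = "objects") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
    )
  }
  px <- tidyr::unnest(
    dplyr::transmute(
      object$rois, label = .data$label,
      coords = purrr::map(.data$pixels, ~ tibble::as_tibble(.x))),
    "coords")
  ggplot2::ggplot(px, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(limits = c(object$dim[1], 1)) +
    ggplot2::xlim(1, object$dim[2]) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$source_id, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the partial score function
#'
#' Visualizes the smooth interval-membership score for one feature range:
#' flat top on `[l, u]`, half-sine ramps over the adaptive margins.
#'
#' @param l,u Acceptance bounds.
#' @param s Margin factor(s); several values may be given for comparison.
#' @return A ggplot.
#' @export
plot_partial_score <- function(l, u, s = c(0.2, 0.5, 1)) {
  m <- score_margins(l, u, max(s))
  xs <- seq(l - 1.3 * max(m$dl, (u - l) / 10),
            u + 1.3 * max(m$du, (u - l) / 10), length.out = 512)
  df <- purrr::map_dfr(s, function(si) {
    tibble::tibble(x = xs, s = sprintf("s = %g", si),
                   score = partial_score(xs, l, u, si))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$score,
                                   colour = .data$s)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(l, u), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "feature value", y = "partial score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
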