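# Presentation helpers: polar fingerprint profiles and similarity heatmaps.

#' Polar plot of one or more fingerprints
#'
#' Draws each material's 16 attribute values on a polar axis ordered by the
#' schema's attribute clusters, the conventional way to show a visual
#' fingerprint: high values towards the boundary, low values towards the
#' centre.
#'
#' @param fps Fingerprint set.
#' @param material_ids Materials to draw (default: all, capped at 8).
#' @return A ggplot object.
#' @export
plot_fingerprint <- function(fps, material_ids = NULL) {
  fps <- validate_fingerprint_set(fps)
  if (is.null(material_ids)) {
    material_ids <- utils::head(fps$material_id, 8)
  }
  schema <- attribute_schema()
  ord <- order(schema$cluster, schema$id)
  long <- fps[fps$material_id %in% material_ids, , drop = FALSE] |>
    tidyr::pivot_longer(dplyr::all_of(fp_cols()), names_to = "attr",
                        values_to = "value") |>
    dplyr::mutate(id = as.integer(sub("attr", "", .data$attr)),
                  name = factor(schema$name[.data$id],
                                levels = schema$name[ord]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$name, y = .data$value,
                                     group = .data$material_id,
                                     colour = .data$material_id)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = NULL, colour = "material") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 7))
}

#' Polar plot of a category's median profile
#'
#' The contour ribbon spans plus/minus one standard error around the median.
#'
#' @param fps Fingerprint set with categories.
#' @param category Category to profile.
#' @return A ggplot object.
#' @export
plot_category_profile <- function(fps, category) {
  prof <- category_profile(fps, category)
  schema <- attribute_schema()
  ord <- order(schema$cluster, schema$id)
  prof$name <- factor(prof$name, levels = schema$name[ord])
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$name, y = .data$median,
                                     group = 1)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$median - .data$stderr,
                                      ymax = .data$median + .data$stderr),
                         alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_polygon(fill = NA, colour = "steelblue", linewidth = 0.8) +
    ggplot2::coord_polar() +
    ggplot2::labs(title = category, x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 7))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a similarity matrix
#'
#' @param object An `fp_similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fp_similarity_matrix <- function(object, ...) {
  ids <- rownames(object)
  df <- tibble::as_tibble(as.data.frame(unclass(object)),
                          rownames = "from") |>
    tidyr::pivot_longer(-"from", names_to = "to", values_to = "similarity") |>
    dplyr::mutate(from = factor(.data$from, levels = ids),
                  to = factor(.data$to, levels = rev(ids)))
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Bar chart of per-attribute evaluation statistics
#'
#' @param object An `fp_eval` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fp_eval <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$name, .data$id),
                                     y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~.data$metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1,
                                                       size = 7))
}
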