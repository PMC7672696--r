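#' Plot a competency report
#'
#' Tile plot of competency questions against matched entity classes, one
#' facet per model, coloured by whether the computed set equals the
#' model-expected set.
#'
#' @param object A `competency_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot competency_report
#' @export
autoplot.competency_report <- function(object, ...) {
  long <- tidy(object) |>
    dplyr::filter(!is.na(.data$entity_id)) |>
    dplyr::mutate(
      cq = factor(.data$cq),
      model = toupper(.data$model)
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$entity_id, y = .data$cq, fill = .data$matches_model
    )
  ) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::facet_wrap(ggplot2::vars(.data$model), ncol = 1) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d95f0e"),
      name = "matches model expectation"
    ) +
    ggplot2::labs(
      x = "matched entity class", y = "competency question",
      title = "Competency-question matches by homology model"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a homology query result
#'
#' Bar chart of matched annotations per entity class, contradicted matches
#' highlighted.
#'
#' @param object A `homology_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot homology_result
#' @export
autoplot.homology_result <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::count(.data$entity_id, .data$contradicted)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$entity_id, y = .data$n, fill = .data$contradicted)
  ) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "#31a354", `TRUE` = "#de2d26"),
      name = "contradicted"
    ) +
    ggplot2::labs(
      x = "entity class", y = "matched annotations",
      title = sprintf(
        "%s homologs of %s (%s)",
        attr(object, "kind"), attr(object, "query_entity"),
        toupper(attr(object, "model"))
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
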