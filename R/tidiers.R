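#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a homology query result
#'
#' @param x A `homology_result`.
#' @param labels Optional id-to-label map to attach display labels.
#' @param ... Unused.
#' @return A plain tibble of matches, one row per (annotation,
#'   justification) pair.
#' @method tidy homology_result
#' @export
tidy.homology_result <- function(x, labels = NULL, ...) {
  out <- tibble::as_tibble(x)
  if (!is.null(labels)) {
    lab <- function(id) {
      res <- unname(labels[id])
      ifelse(is.na(res), id, res)
    }
    out <- dplyr::mutate(
      out,
      entity_label = lab(.data$entity_id),
      taxon_label = lab(.data$taxon_id),
      .after = "entity_id"
    )
  }
  out
}

#' One-row summary of a homology query result
#'
#' @param x A `homology_result`.
#' @param ... Unused.
#' @return A one-row tibble: query term, kind, model, scope, match and
#'   entity-class counts, and whether any match is contradicted.
#' @method glance homology_result
#' @export
glance.homology_result <- function(x, ...) {
  tibble::tibble(
    query_entity = attr(x, "query_entity"),
    kind = attr(x, "kind"),
    model = attr(x, "model"),
    query_scope = attr(x, "query_scope"),
    n_matches = nrow(x),
    n_entity_classes = length(unique(x$entity_id)),
    any_contradicted = any(x$contradicted)
  )
}

#' Tidy a competency report
#'
#' @param x A `competency_report`.
#' @param ... Unused.
#' @return A long tibble with one row per question, model, and matched
#'   entity class.
#' @method tidy competency_report
#' @export
tidy.competency_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select(
      "cq", "model", "query_label", "kind", "entity_classes",
      "matches_model", "matches_user", "contains_user"
    ) |>
    tidyr::unnest_longer("entity_classes", values_to = "entity_id", keep_empty = TRUE)
}

#' Per-model summary of a competency report
#'
#' @param x A `competency_report`.
#' @param ... Unused.
#' @return One row per model: how many of the questions matched the
#'   model-expected set, matched the user expectation exactly, and
#'   contained the user expectation.
#' @method glance competency_report
#' @export
glance.competency_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n_questions = dplyr::n(),
      n_matches_model = sum(.data$matches_model),
      n_matches_user = sum(.data$matches_user),
      n_contains_user = sum(.data$contains_user),
      .groups = "drop"
    )
}
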