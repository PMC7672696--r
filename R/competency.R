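#' Run the competency-question harness over a fixture
#'
#' Executes each of the fixture's competency questions under the requested
#' models and compares the computed match set (annotation keys,
#' entity|taxon) against two references: the set the model is expected to
#' entail (`matches_model`) and the expert-user expectation column
#' (`matches_user` for exact equality, `contains_user` for the weaker
#' "returned everything the user expected, possibly more" reading that the
#' all-all AVA semantics satisfy).
#'
#' @param fixture A `homology_fixture` whose `expectations` element is
#'   non-`NULL` (see [build_demo()]).
#' @param models Character subset of `c("rea", "ava")`.
#' @return A `competency_report`: a tibble with one row per question and
#'   model, holding the query, the computed and expected sets
#'   (list-columns), the comparison booleans, and the computed entity
#'   classes.
#' @export
run_competency <- function(fixture, models = c("rea", "ava")) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(fixture$expectations)) {
    stop("fixture carries no competency expectations", call. = FALSE)
  }
  ex <- fixture$expectations
  queries <- dplyr::distinct(
    ex, .data$cq, .data$query_id, .data$query_label, .data$kind
  )
  expected_for <- function(cq, column) {
    rows <- ex[ex$cq == cq & ex$column == column, , drop = FALSE]
    if (nrow(rows) == 0) character() else sort(rows$keys[[1]])
  }

  # compile ancestral groups once; every AVA query shares them
  ava_groups <- if ("ava" %in% models) {
    compile_model(fixture$assertions, "ava", fixture$labels)$groups
  }

  rows <- purrr::map(models, function(model) {
    purrr::pmap(queries, function(cq, query_id, query_label, kind) {
      res <- if (model == "rea") {
        rea_query(
          fixture$annotations, fixture$assertions, fixture$anatomy,
          fixture$taxonomy, query_id, kind
        )
      } else {
        ava_query(
          fixture$annotations, ava_groups, fixture$anatomy, fixture$taxonomy,
          query_id, kind,
          assertions = fixture$assertions
        )
      }
      computed <- sort(unique(res$ann_key))
      expected_model <- expected_for(cq, model)
      expected_user <- expected_for(cq, "user")
      matches_model <- setequal(computed, expected_model)
      matches_user <- setequal(computed, expected_user)
      contains_user <- all(expected_user %in% computed)
      tibble::tibble(
        cq = cq, model = model,
        query_id = query_id, query_label = query_label, kind = kind,
        n_matches = nrow(res),
        computed = list(computed),
        entity_classes = list(entity_classes(res)),
        expected_model = list(expected_model),
        expected_user = list(expected_user),
        matches_model = matches_model,
        matches_user = matches_user,
        contains_user = contains_user
      )
    }) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$cq, .data$model)

  structure(
    rows,
    class = c("competency_report", class(tibble::tibble()))
  )
}

#' @export
print.competency_report <- function(x, ...) {
  cat("<competency_report>\n")
  show <- dplyr::mutate(
    tibble::as_tibble(x),
    computed = vapply(.data$entity_classes, length, integer(1))
  )
  print(show[, c(
    "cq", "model", "query_label", "kind", "n_matches",
    "matches_model", "matches_user", "contains_user"
  )], n = Inf)
  invisible(x)
}
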