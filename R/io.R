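# Tab-delimited fixture interchange: terms.tsv (id, label, namespace),
# edges.tsv (child_id, relation, parent_id), assertions.tsv (curated-table
# schema), annotations.tsv, expectations.json.

#' Write a fixture to a directory of TSV files
#'
#' @param fixture A `homology_fixture`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  terms <- dplyr::bind_rows(fixture$anatomy$terms, fixture$taxonomy$terms)
  edges <- dplyr::bind_rows(fixture$anatomy$edges, fixture$taxonomy$edges)
  readr::write_tsv(terms, file.path(dir, "terms.tsv"))
  readr::write_tsv(edges, file.path(dir, "edges.tsv"))
  readr::write_tsv(
    serialize_assertions(fixture$assertions),
    file.path(dir, "assertions.tsv")
  )
  readr::write_tsv(fixture$annotations, file.path(dir, "annotations.tsv"))
  if (!is.null(fixture$expectations)) {
    jsonlite::write_json(
      fixture$expectations,
      file.path(dir, "expectations.json"),
      dataframe = "rows", auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(dir)
}

#' Render a parsed assertion collection back to the curated-table schema
#'
#' Inverse of [parse_assertions()]: re-parsing the serialized table yields
#' the same collection.
#'
#' @param assertions An assertion tibble.
#' @return A tibble in the assertion-TSV schema.
#' @export
serialize_assertions <- function(assertions) {
  rel <- ifelse(assertions$kind == "serial", "serially_homologous_to", "homologous_to")
  rel <- ifelse(assertions$negated, paste0("not_", rel), rel)
  join <- function(x) vapply(x, paste, character(1), collapse = ";")
  tibble::tibble(
    entity1_id = assertions$entity1_id,
    taxon1_id = assertions$taxon1_id,
    relationship = rel,
    entity2_id = assertions$entity2_id,
    taxon2_id = assertions$taxon2_id,
    evidence_eco_ids = join(assertions$evidence),
    attribution = join(assertions$attribution)
  )
}

#' Read a fixture from a directory of TSV files
#'
#' @param dir Directory produced by [write_fixture()] (or hand-authored in
#'   the same schema).
#' @return A `homology_fixture`.
#' @export
read_fixture <- function(dir) {
  tsv <- function(name) {
    readr::read_tsv(
      file.path(dir, name),
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }
  terms <- tsv("terms.tsv")
  edges <- tsv("edges.tsv")
  ns <- stats::setNames(terms$namespace, terms$id)
  edge_ns <- ns[edges$child_id]
  split_graph <- function(which_ns) {
    load_ontology(
      terms[terms$namespace == which_ns, , drop = FALSE],
      edges[!is.na(edge_ns) & edge_ns == which_ns, , drop = FALSE]
    )
  }
  anatomy <- split_graph("anatomy")
  taxonomy <- split_graph("taxonomy")
  assertions <- parse_assertions(tsv("assertions.tsv"), anatomy, taxonomy)
  annotations <- tsv("annotations.tsv")

  expectations <- NULL
  exp_path <- file.path(dir, "expectations.json")
  if (file.exists(exp_path)) {
    raw <- jsonlite::fromJSON(exp_path, simplifyVector = TRUE)
    expectations <- tibble::as_tibble(raw) |>
      dplyr::mutate(
        cq = as.integer(.data$cq),
        keys = lapply(.data$keys, as.character)
      )
  }

  structure(
    list(
      anatomy = anatomy, taxonomy = taxonomy,
      assertions = assertions, annotations = annotations,
      expectations = expectations,
      labels = term_labels(anatomy, taxonomy)
    ),
    class = "homology_fixture"
  )
}

#' Read a minimal OBO flat-file subset
#'
#' Supports `[Term]` stanzas with `id:`, `name:`, `is_a:`, and
#' `relationship: part_of` / `relationship: develops_from` tags. Every
#' other stanza type or tag is ignored with a single logged warning per
#' tag.
#'
#' @param path Path to an OBO flat file.
#' @param namespace Namespace assigned to the loaded terms.
#' @return An `onto_graph`.
#' @export
read_obo <- function(path, namespace = "anatomy") {
  lines <- trimws(sub("!.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[lines != ""]

  stanza_starts <- grep("^\\[", lines)
  bounds <- c(stanza_starts, length(lines) + 1)

  terms <- list()
  edges <- list()
  ignored <- character()
  note_ignored <- function(what) {
    if (!what %in% ignored) {
      warning("read_obo: ignoring ", what, call. = FALSE)
      ignored <<- c(ignored, what)
    }
  }

  for (s in seq_along(stanza_starts)) {
    head_line <- lines[bounds[s]]
    body <- lines[seq(bounds[s] + 1, bounds[s + 1] - 1)]
    if (bounds[s] + 1 > bounds[s + 1] - 1) body <- character()
    if (head_line != "[Term]") {
      note_ignored(paste("stanza", head_line))
      next
    }
    tags <- sub(":.*$", "", body)
    values <- trimws(sub("^[^:]+:", "", body))
    id <- values[tags == "id"][1]
    if (is.na(id)) next
    name <- values[tags == "name"][1]
    terms[[length(terms) + 1]] <- tibble::tibble(
      id = id, label = if (is.na(name)) id else name, namespace = namespace
    )
    for (j in seq_along(tags)) {
      if (tags[j] %in% c("id", "name")) next
      if (tags[j] == "is_a") {
        edges[[length(edges) + 1]] <- tibble::tibble(
          child_id = id, relation = "is_a",
          parent_id = sub("\\s.*$", "", values[j])
        )
      } else if (tags[j] == "relationship") {
        parts <- strsplit(values[j], "\\s+")[[1]]
        if (length(parts) >= 2 && parts[1] %in% c("part_of", "develops_from")) {
          edges[[length(edges) + 1]] <- tibble::tibble(
            child_id = id, relation = parts[1], parent_id = parts[2]
          )
        } else {
          note_ignored(paste("relationship type", parts[1]))
        }
      } else {
        note_ignored(paste("tag", tags[j]))
      }
    }
  }

  edge_tab <- if (length(edges) > 0) {
    dplyr::bind_rows(edges)
  } else {
    tibble::tibble(
      child_id = character(), relation = character(), parent_id = character()
    )
  }
  load_ontology(dplyr::bind_rows(terms), edge_tab)
}

#' Render query-result matches as the interchange TSV schema
#'
#' @param result A `homology_result`.
#' @param labels Optional id-to-label map.
#' @return A tibble with columns `entity_id`, `entity_label`, `quality`,
#'   `taxon_id`, `taxon_label`, `justification`, `contradicted`.
#' @export
result_table <- function(result, labels = NULL) {
  lab <- function(id) {
    if (is.null(labels)) {
      return(id)
    }
    out <- unname(labels[id])
    ifelse(is.na(out), id, out)
  }
  tibble::tibble(
    entity_id = result$entity_id,
    entity_label = lab(result$entity_id),
    quality = result$quality,
    taxon_id = result$taxon_id,
    taxon_label = lab(result$taxon_id),
    justification = result$justification,
    contradicted = result$contradicted
  )
}
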