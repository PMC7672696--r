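#' Load and validate an ontology graph
#'
#' Builds an immutable ontology graph from a table of terms and a table of
#' typed edges, and eagerly precomputes the reflexive-transitive closure of
#' the `is_a` relation. Only `is_a` edges contribute to subsumption;
#' `part_of` and `develops_from` edges are carried for navigation and
#' serialization but never propagate homology (homology reasoning is
#' restricted to subsumption).
#'
#' @param term_table A data frame with columns `id`, `label`, `namespace`.
#'   Ids are CURIEs (`prefix:local`); namespace is one of `anatomy`,
#'   `taxonomy`, `evidence`, `relation`.
#' @param edge_table A data frame with columns `child_id`, `relation`,
#'   `parent_id`; `relation` is one of `is_a`, `part_of`, `develops_from`.
#'   May have zero rows.
#' @return An object of class `onto_graph`: a list with tibbles `terms` and
#'   `edges` plus `closure`, a named list mapping each term id to the sorted
#'   character vector of its `is_a` ancestors (including itself).
#' @examples
#' terms <- tibble::tibble(
#'   id = c("A:1", "A:2"), label = c("fin", "paired fin"),
#'   namespace = "anatomy"
#' )
#' edges <- tibble::tibble(child_id = "A:1", relation = "is_a", parent_id = "A:2")
#' g <- load_ontology(terms, edges)
#' subsumes(g, "A:1", "A:2")
#' @export
load_ontology <- function(term_table, edge_table) {
  terms <- tibble::as_tibble(term_table)
  edges <- tibble::as_tibble(edge_table)
  need_t <- c("id", "label", "namespace")
  if (!all(need_t %in% names(terms))) {
    stop("format error: term table must have columns ", paste(need_t, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(
      child_id = character(), relation = character(), parent_id = character()
    )
  }
  need_e <- c("child_id", "relation", "parent_id")
  if (!all(need_e %in% names(edges))) {
    stop("format error: edge table must have columns ", paste(need_e, collapse = ", "),
      call. = FALSE
    )
  }
  terms <- dplyr::select(terms, dplyr::all_of(need_t))
  edges <- dplyr::select(edges, dplyr::all_of(need_e))

  bad_curie <- terms$id[!grepl("^[^:[:space:]]+:[^[:space:]]+$", terms$id)]
  if (length(bad_curie) > 0) {
    stop("format error: term ids are not CURIEs: ", paste(bad_curie, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(terms$id)) {
    stop("format error: duplicated term ids: ",
      paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(is.na(terms$label) | terms$label == "")) {
    stop("format error: empty labels for: ",
      paste(terms$id[is.na(terms$label) | terms$label == ""], collapse = ", "),
      call. = FALSE
    )
  }
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of", "develops_from"))
  if (length(bad_rel) > 0) {
    stop("format error: unknown edge relation(s): ", paste(bad_rel, collapse = ", "),
      call. = FALSE
    )
  }
  dangling <- setdiff(c(edges$child_id, edges$parent_id), terms$id)
  if (length(dangling) > 0) {
    stop("reference error: edge endpoints not declared as terms: ",
      paste(sort(dangling), collapse = ", "),
      call. = FALSE
    )
  }

  # order-insensitive internal representation; duplicates are kept (and
  # surfaced by validate_graph), they are harmless to the closure
  terms <- dplyr::arrange(terms, .data$id)
  edges <- dplyr::arrange(edges, .data$relation, .data$child_id, .data$parent_id)

  closure <- isa_closure(terms$id, edges)

  structure(
    list(terms = terms, edges = edges, closure = closure),
    class = "onto_graph"
  )
}

# Reflexive-transitive closure of is_a edges; errors on cycles, naming one.
isa_closure <- function(ids, edges) {
  isa <- edges[edges$relation == "is_a", , drop = FALSE]
  if (nrow(isa) == 0) {
    cl <- lapply(ids, function(i) i)
    names(cl) <- ids
    return(cl)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = isa$child_id, to = isa$parent_id),
    directed = TRUE,
    vertices = data.frame(name = ids)
  )
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, cyc[1])
    # walk the cycle through the offending edge for a readable message
    path <- igraph::shortest_paths(g, from = ends[2], to = ends[1])$vpath[[1]]
    stop("cycle error: is_a cycle involving ",
      paste(c(names(path), ends[2]), collapse = " -> "),
      call. = FALSE
    )
  }
  cl <- lapply(igraph::V(g), function(v) {
    sort(names(igraph::subcomponent(g, v, mode = "out")))
  })
  names(cl) <- names(igraph::V(g))
  cl[ids]
}

#' @export
print.onto_graph <- function(x, ...) {
  ns <- table(x$terms$namespace)
  rel <- table(x$edges$relation)
  cat("<onto_graph> ", nrow(x$terms), " terms (",
    paste(sprintf("%s: %d", names(ns), ns), collapse = ", "), "); ",
    nrow(x$edges), " edges (",
    paste(sprintf("%s: %d", names(rel), rel), collapse = ", "), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Test is_a subsumption between terms
#'
#' `subsumes(g, sub, super)` is `TRUE` iff `super` lies in the
#' reflexive-transitive `is_a` closure of `sub` (so every term subsumes under
#' itself). Vectorized over `sub`/`super`, recycling length-1 arguments.
#'
#' @param g An `onto_graph`.
#' @param sub,super Character vectors of term ids declared in `g`.
#' @return Logical vector.
#' @export
subsumes <- function(g, sub, super) {
  stopifnot(inherits(g, "onto_graph"))
  n <- max(length(sub), length(super))
  sub <- rep_len(sub, n)
  super <- rep_len(super, n)
  undeclared <- setdiff(unique(c(sub, super)), names(g$closure))
  if (length(undeclared) > 0) {
    stop("reference error: term(s) not declared in graph: ",
      paste(sort(undeclared), collapse = ", "),
      call. = FALSE
    )
  }
  vapply(
    seq_len(n),
    function(i) super[i] %in% g$closure[[sub[i]]],
    logical(1)
  )
}

#' Ancestors of a term under is_a
#'
#' @param g An `onto_graph`.
#' @param id A single term id.
#' @return Sorted character vector of `is_a` ancestors, including `id`.
#' @export
ancestors <- function(g, id) {
  stopifnot(inherits(g, "onto_graph"))
  if (!id %in% names(g$closure)) {
    stop("reference error: term not declared in graph: ", id, call. = FALSE)
  }
  g$closure[[id]]
}

#' Test membership of a taxon in a taxon scope
#'
#' A taxon scope is either a taxonomy term id or `NA`, the unrestricted
#' scope (no `in_taxon` restriction). A taxon is in scope iff the scope is
#' unrestricted or the taxon is subsumed by the scope taxon.
#'
#' @param g_tax The taxonomy `onto_graph`.
#' @param taxon Character vector of taxonomy term ids.
#' @param scope Character vector of scope taxon ids, `NA` for unrestricted.
#' @return Logical vector.
#' @export
in_scope <- function(g_tax, taxon, scope) {
  n <- max(length(taxon), length(scope))
  taxon <- rep_len(taxon, n)
  scope <- rep_len(scope, n)
  out <- rep(TRUE, n)
  restricted <- !is.na(scope)
  if (any(restricted)) {
    out[restricted] <- subsumes(g_tax, taxon[restricted], scope[restricted])
  }
  out
}

#' Validate an ontology graph
#'
#' Reports (rather than raises) structural blemishes that loading tolerates:
#' orphan terms touching no edge, duplicated edges, and edges whose two
#' endpoints live in different namespaces. A clean graph yields a zero-row
#' report.
#'
#' @param g An `onto_graph`.
#' @param extra_edges Optional additional edge tibble to audit against `g`'s
#'   terms (same columns as the edge table), e.g. a not-yet-loaded overlay.
#' @return A tibble with columns `check`, `item`, `message`; zero rows iff
#'   the graph passes all checks.
#' @export
validate_graph <- function(g, extra_edges = NULL) {
  stopifnot(inherits(g, "onto_graph"))
  edges <- g$edges
  if (!is.null(extra_edges)) {
    edges <- dplyr::bind_rows(edges, tibble::as_tibble(extra_edges))
  }
  report <- list()

  touched <- unique(c(edges$child_id, edges$parent_id))
  orphans <- setdiff(g$terms$id, touched)
  if (length(orphans) > 0 && nrow(g$terms) > 1) {
    report$orphans <- tibble::tibble(
      check = "orphan_term", item = sort(orphans),
      message = "term participates in no edge"
    )
  }

  key <- paste(edges$child_id, edges$relation, edges$parent_id)
  dup <- sort(unique(key[duplicated(key)]))
  if (length(dup) > 0) {
    report$dup <- tibble::tibble(
      check = "duplicate_edge", item = dup,
      message = "edge appears more than once"
    )
  }

  ns <- stats::setNames(g$terms$namespace, g$terms$id)
  mixed <- ns[edges$child_id] != ns[edges$parent_id]
  mixed[is.na(mixed)] <- FALSE
  if (any(mixed)) {
    report$ns <- tibble::tibble(
      check = "namespace_mixing",
      item = paste(edges$child_id[mixed], edges$relation[mixed],
        edges$parent_id[mixed]
      ),
      message = "edge endpoints belong to different namespaces"
    )
  }

  out <- dplyr::bind_rows(report)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      check = character(), item = character(), message = character()
    )
  }
  out
}
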