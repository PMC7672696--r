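#' Match phenotype annotations against a taxon-scoped class expression
#'
#' An annotation falls in a side of a homology assertion iff its anatomical
#' entity is subsumed by the side's base class and its organism taxon is in
#' the side's taxon scope. The annotation's quality is inert: it never
#' affects homology reasoning.
#'
#' @param annotations A phenotype-annotation tibble (columns `entity_id`,
#'   `taxon_id`, and optionally `quality`, `related_entity`, `source`).
#' @param g_anat,g_tax Anatomy and taxonomy `onto_graph`s.
#' @param side_base Anatomy term id (the class expression's base).
#' @param side_scope Taxonomy term id or `NA` (unrestricted).
#' @return Logical vector, one element per annotation row.
#' @export
annotation_in_side <- function(annotations, g_anat, g_tax, side_base,
                               side_scope = NA_character_) {
  if (nrow(annotations) == 0) {
    return(logical())
  }
  subsumes(g_anat, annotations$entity_id, side_base) &
    in_scope(g_tax, annotations$taxon_id, side_scope)
}

ann_keys <- function(annotations) {
  paste(annotations$entity_id, annotations$taxon_id, sep = "|")
}

new_homology_result <- function(matches, query_entity, kind, model,
                                query_scope = NA_character_) {
  structure(
    matches,
    query_entity = query_entity, kind = kind, model = model,
    query_scope = query_scope,
    class = c("homology_result", class(tibble::tibble()))
  )
}

empty_matches <- function(model) {
  tibble::tibble(
    entity_id = character(), quality = character(),
    related_entity = character(), taxon_id = character(),
    source = character(), ann_key = character(),
    justification = character(), matched_side = character(),
    witness_key = character(), contradicted = logical()
  )
}

sort_matches <- function(m) {
  m[order(m$entity_id, m$taxon_id, m$source, m$justification), , drop = FALSE]
}

ann_cols <- function(annotations) {
  ann <- tibble::as_tibble(annotations)
  for (col in c("quality", "related_entity", "source")) {
    if (!col %in% names(ann)) ann[[col]] <- NA_character_
  }
  ann$ann_key <- ann_keys(ann)
  ann[, c(
    "entity_id", "quality", "related_entity", "taxon_id", "source", "ann_key"
  )]
}

#' Homology query under the reciprocal-existential (REA) model
#'
#' An annotation matches iff some positive assertion of the requested kind
#' has an orientation (match side, target side) such that the annotation
#' falls in the match side and the target side's base class is subsumed by
#' the query entity (and, when the query is taxon-scoped, the target side's
#' scope is within the query scope). All-some semantics: annotations on the
#' query term itself are not returned unless licensed by such an assertion,
#' and subclasses of the target filler are never inferred to be the filler.
#'
#' @param annotations Phenotype-annotation tibble.
#' @param assertions Assertion tibble (may include negated rows: they never
#'   license matches but drive the `contradicted` flag).
#' @param g_anat,g_tax Anatomy and taxonomy `onto_graph`s.
#' @param query_entity Anatomy term id being queried.
#' @param kind `"historical"` or `"serial"`.
#' @param query_scope Optional taxonomy term id restricting the query.
#' @return A `homology_result`: the matched annotations with one row per
#'   (annotation, licensing assertion) pair, columns `justification`
#'   (assertion id), `matched_side`, and `contradicted`.
#' @export
rea_query <- function(annotations, assertions, g_anat, g_tax,
                      query_entity, kind = c("historical", "serial"),
                      query_scope = NA_character_) {
  kind <- match.arg(kind)
  if (!query_entity %in% g_anat$terms$id) {
    stop("reference error: query entity not declared: ", query_entity,
      call. = FALSE
    )
  }
  contradicted_keys <- contradicted_pair_keys(assertions)
  pos <- dplyr::filter(assertions, !.data$negated, .data$kind == !!kind)
  ann <- ann_cols(annotations)
  if (nrow(pos) == 0 || nrow(ann) == 0) {
    return(new_homology_result(
      empty_matches("rea"), query_entity, kind, "rea", query_scope
    ))
  }

  sides <- dplyr::bind_rows(
    tibble::tibble(
      assertion_id = pos$assertion_id, pair_key = pos$pair_key,
      match_base = pos$entity2_id, match_scope = pos$taxon2_id,
      target_base = pos$entity1_id, target_scope = pos$taxon1_id,
      matched_side = "entity2"
    ),
    tibble::tibble(
      assertion_id = pos$assertion_id, pair_key = pos$pair_key,
      match_base = pos$entity1_id, match_scope = pos$taxon1_id,
      target_base = pos$entity2_id, target_scope = pos$taxon2_id,
      matched_side = "entity1"
    )
  )
  target_ok <- subsumes(g_anat, sides$target_base, query_entity)
  if (!is.na(query_scope)) {
    scope_ok <- !is.na(sides$target_scope) &
      subsumes(g_tax, sides$target_scope, query_scope)
    target_ok <- target_ok & scope_ok
  }
  sides <- sides[target_ok, , drop = FALSE]

  matches <- purrr::pmap(
    sides,
    function(assertion_id, pair_key, match_base, match_scope, ...) {
      hit <- annotation_in_side(ann, g_anat, g_tax, match_base, match_scope)
      if (!any(hit)) {
        return(NULL)
      }
      out <- ann[hit, , drop = FALSE]
      out$justification <- assertion_id
      out$matched_side <- list(...)$matched_side
      out$witness_key <- NA_character_
      out$contradicted <- pair_key %in% contradicted_keys
      out
    }
  ) |>
    purrr::compact() |>
    dplyr::bind_rows()
  if (nrow(matches) == 0) matches <- empty_matches("rea")
  new_homology_result(
    sort_matches(matches), query_entity, kind, "rea", query_scope
  )
}

#' Homology query under the ancestral-value (AVA) model
#'
#' Membership semantics over ancestral groups: an annotation is a member of
#' a group iff it falls in either of the group's two taxon-scoped sides. An
#' annotation matches the query iff it shares a group (of the requested
#' kind) with a witness annotation whose entity is subsumed by the query
#' entity (the witness may be the annotation itself). All-all semantics:
#' the query term's own annotations, subtypes, and any asserted superclass
#' side come back, as entailed by the property chain over the ancestral
#' individual.
#'
#' @inheritParams rea_query
#' @param groups Ancestral-group tibble from [compile_model()] /
#'   [ava_axioms()].
#' @param assertions Optional full assertion tibble used solely to flag
#'   contradicted licensing pairs.
#' @return A `homology_result` with one row per (annotation, group) match;
#'   `justification` holds the ancestral individual id, `witness_key` the
#'   witness annotation.
#' @export
ava_query <- function(annotations, groups, g_anat, g_tax,
                      query_entity, kind = c("historical", "serial"),
                      query_scope = NA_character_, assertions = NULL) {
  kind <- match.arg(kind)
  if (!query_entity %in% g_anat$terms$id) {
    stop("reference error: query entity not declared: ", query_entity,
      call. = FALSE
    )
  }
  contradicted_keys <- if (is.null(assertions)) {
    character()
  } else {
    contradicted_pair_keys(assertions)
  }
  gr <- dplyr::filter(groups, .data$kind == !!kind)
  ann <- ann_cols(annotations)
  if (nrow(gr) == 0 || nrow(ann) == 0) {
    return(new_homology_result(
      empty_matches("ava"), query_entity, kind, "ava", query_scope
    ))
  }

  membership <- ava_membership(ann, gr, g_anat, g_tax)
  if (nrow(membership) == 0) {
    return(new_homology_result(
      empty_matches("ava"), query_entity, kind, "ava", query_scope
    ))
  }

  witness_ok <- subsumes(g_anat, membership$entity_id, query_entity)
  if (!is.na(query_scope)) {
    witness_ok <- witness_ok & in_scope(g_tax, membership$taxon_id, query_scope)
  }
  witnesses <- membership[witness_ok, , drop = FALSE]
  witnesses <- witnesses[order(witnesses$entity_id, witnesses$taxon_id), ,
    drop = FALSE
  ]
  witnesses <- witnesses[!duplicated(witnesses$individual_id), , drop = FALSE]
  if (nrow(witnesses) == 0) {
    return(new_homology_result(
      empty_matches("ava"), query_entity, kind, "ava", query_scope
    ))
  }

  matches <- membership |>
    dplyr::inner_join(
      dplyr::select(witnesses, "individual_id", witness_key = "ann_key"),
      by = "individual_id"
    ) |>
    dplyr::rename(justification = "individual_id") |>
    dplyr::mutate(contradicted = .data$pair_key %in% contradicted_keys) |>
    dplyr::select(-"pair_key")
  new_homology_result(
    sort_matches(matches), query_entity, kind, "ava", query_scope
  )
}

# one row per (annotation, group, first matching side)
ava_membership <- function(ann, gr, g_anat, g_tax) {
  purrr::pmap(
    gr[, c(
      "individual_id", "entity1_id", "taxon1_id", "entity2_id", "taxon2_id",
      "pair_key"
    )],
    function(individual_id, entity1_id, taxon1_id, entity2_id, taxon2_id,
             pair_key) {
      in1 <- annotation_in_side(ann, g_anat, g_tax, entity1_id, taxon1_id)
      in2 <- annotation_in_side(ann, g_anat, g_tax, entity2_id, taxon2_id)
      hit <- in1 | in2
      if (!any(hit)) {
        return(NULL)
      }
      out <- ann[hit, , drop = FALSE]
      out$individual_id <- individual_id
      out$matched_side <- ifelse(in1[hit], "entity1", "entity2")
      out$pair_key <- pair_key
      out
    }
  ) |>
    purrr::compact() |>
    dplyr::bind_rows()
}

#' Are two annotated structures homologous at the instance level?
#'
#' Defined for the AVA model only: two phenotype instances are inferred
#' homologous iff they are members of a common ancestral group of the
#' requested kind (the property chain through the shared ancestral
#' individual entails `homologous_to` between them). Symmetric, and
#' reflexive for any member of at least one group. The REA model makes no
#' instance-level homology entailments ("all-some"), so requesting it is an
#' error.
#'
#' @param a,b One-row annotation tibbles (or rows of one).
#' @param kind `"historical"` or `"serial"`.
#' @param groups Ancestral-group tibble.
#' @param g_anat,g_tax Ontology graphs.
#' @param model Must be `"ava"`.
#' @return Logical scalar.
#' @export
pairwise_homologous <- function(a, b, kind, groups, g_anat, g_tax,
                                model = c("ava", "rea")) {
  model <- match.arg(model)
  if (model == "rea") {
    stop(
      "unsupported operation: the REA model does not entail homology ",
      "between individuals (all-some semantics)",
      call. = FALSE
    )
  }
  gr <- dplyr::filter(groups, .data$kind == !!kind)
  if (nrow(gr) == 0) {
    return(FALSE)
  }
  mem <- function(x) {
    m <- ava_membership(ann_cols(x), gr, g_anat, g_tax)
    unique(m$individual_id)
  }
  length(intersect(mem(a), mem(b))) > 0
}

#' Expand or exclude a set of entities by their homologs
#'
#' A positive filter (`expand`) unions the input entity set with the entity
#' classes returned by a homology query for each reference entity; a
#' negative filter (`exclude`) removes from the input any entity returned
#' by a homology query for some reference entity. Useful e.g. for widening
#' a search to homologous structures, or for screening out historical
#' homologs when hunting for deep (non-homologous) similarity.
#'
#' @param fixture A homology fixture (see [build_demo()]).
#' @param entities Character vector of anatomy term ids to filter.
#' @param mode `"expand"` or `"exclude"`.
#' @param kind,model Query kind and model.
#' @param reference Entities whose homologs drive the filter; defaults to
#'   `entities`.
#' @return Sorted character vector of entity ids.
#' @export
homology_filter <- function(fixture, entities, mode = c("expand", "exclude"),
                            kind = c("historical", "serial"),
                            model = c("rea", "ava"), reference = entities) {
  mode <- match.arg(mode)
  kind <- match.arg(kind)
  model <- match.arg(model)
  undeclared <- setdiff(c(entities, reference), fixture$anatomy$terms$id)
  if (length(undeclared) > 0) {
    stop("reference error: entities not declared: ",
      paste(sort(undeclared), collapse = ", "),
      call. = FALSE
    )
  }
  hom <- unique(unlist(lapply(reference, function(e) {
    entity_classes(query_homologs(fixture, e, kind = kind, model = model))
  })))
  if (mode == "expand") {
    sort(union(entities, hom))
  } else {
    sort(setdiff(entities, hom))
  }
}

#' Run a homology query against a fixture
#'
#' Convenience wrapper compiling the fixture's positive assertions under
#' the requested model and dispatching to [rea_query()] or [ava_query()].
#'
#' @param fixture A homology fixture (see [build_demo()]).
#' @param query_entity Anatomy term id.
#' @param kind,model Query kind and homology model.
#' @param query_scope Optional taxonomy term id.
#' @param prototype Materialize one synthetic annotation per anatomy class
#'   (taxon = taxonomy root) instead of using the fixture's annotation set,
#'   for ABox-free exploration. Taxon-scoped assertions do not fire on
#'   prototypes unless the root itself is in scope.
#' @return A `homology_result`.
#' @export
query_homologs <- function(fixture, query_entity,
                           kind = c("historical", "serial"),
                           model = c("rea", "ava"),
                           query_scope = NA_character_, prototype = FALSE) {
  kind <- match.arg(kind)
  model <- match.arg(model)
  ann <- if (prototype) prototype_annotations(fixture) else fixture$annotations
  if (model == "rea") {
    rea_query(
      ann, fixture$assertions, fixture$anatomy, fixture$taxonomy,
      query_entity, kind, query_scope
    )
  } else {
    compiled <- compile_model(fixture$assertions, "ava", fixture$labels)
    ava_query(
      ann, compiled$groups, fixture$anatomy, fixture$taxonomy,
      query_entity, kind, query_scope,
      assertions = fixture$assertions
    )
  }
}

prototype_annotations <- function(fixture) {
  tax <- fixture$taxonomy
  isa <- tax$edges[tax$edges$relation == "is_a", , drop = FALSE]
  roots <- sort(setdiff(tax$terms$id, isa$child_id))
  root <- roots[1]
  tibble::tibble(
    entity_id = sort(fixture$anatomy$terms$id),
    quality = "prototype",
    related_entity = NA_character_,
    taxon_id = root,
    source = "prototype"
  )
}

#' Distinct anatomical entity classes among a query's matches
#'
#' @param result A `homology_result`.
#' @return Sorted character vector of entity ids (the projection of the
#'   matches onto their entity class).
#' @export
entity_classes <- function(result) {
  stopifnot(inherits(result, "homology_result"))
  sort(unique(result$entity_id))
}

#' @export
print.homology_result <- function(x, ...) {
  cat(sprintf(
    "<homology_result> %s homologs of %s under %s%s: %d match(es), %d entity class(es)\n",
    attr(x, "kind"), attr(x, "query_entity"), toupper(attr(x, "model")),
    if (!is.na(attr(x, "query_scope"))) {
      paste0(" in ", attr(x, "query_scope"))
    } else {
      ""
    },
    nrow(x), length(unique(x$entity_id))
  ))
  NextMethod()
}
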