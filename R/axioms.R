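#' @keywords internal
iri <- function(id) sprintf("<urn:curie:%s>", id)

ind_iri <- function(id) sprintf("<urn:ind:%s>", id)

# Render a (possibly taxon-scoped) class expression: the bare class when the
# scope is unrestricted, otherwise "base and in_taxon some scope".
render_cexpr <- function(base, scope) {
  if (is.na(scope)) {
    iri(base)
  } else {
    sprintf(
      "ObjectIntersectionOf(%s ObjectSomeValuesFrom(%s %s))",
      iri(base), iri(IN_TAXON), iri(scope)
    )
  }
}

empty_axioms <- function() {
  tibble::tibble(
    form = character(),
    subject_base = character(), subject_scope = character(),
    property = character(),
    filler_base = character(), filler_scope = character(),
    filler_individual = character(),
    chain = list(),
    rendered = character()
  )
}

axiom_row <- function(form, subject_base = NA_character_,
                      subject_scope = NA_character_, property = NA_character_,
                      filler_base = NA_character_, filler_scope = NA_character_,
                      filler_individual = NA_character_, chain = NULL) {
  rendered <- switch(form,
    subclass_of_existential = sprintf(
      "SubClassOf(%s ObjectSomeValuesFrom(%s %s))",
      render_cexpr(subject_base, subject_scope), iri(property),
      render_cexpr(filler_base, filler_scope)
    ),
    subclass_of_hasvalue = sprintf(
      "SubClassOf(%s ObjectHasValue(%s %s))",
      render_cexpr(subject_base, subject_scope), iri(property),
      ind_iri(filler_individual)
    ),
    inverse_properties = sprintf(
      "InverseObjectProperties(%s %s)",
      iri(chain[1]), iri(chain[2])
    ),
    property_chain = sprintf(
      "SubObjectPropertyOf(ObjectPropertyChain(%s %s) %s)",
      iri(chain[1]), iri(chain[2]), iri(property)
    ),
    stop("unknown axiom form: ", form, call. = FALSE)
  )
  tibble::tibble(
    form = form, subject_base = subject_base, subject_scope = subject_scope,
    property = property, filler_base = filler_base,
    filler_scope = filler_scope, filler_individual = filler_individual,
    chain = list(chain %||% character()), rendered = rendered
  )
}

reject_negated <- function(a) {
  if (any(a$negated)) {
    stop(
      "rejection error: negated assertions are metadata only and are never ",
      "compiled into axioms (rows: ",
      paste(a$assertion_id[a$negated], collapse = ", "), ")",
      call. = FALSE
    )
  }
}

#' Reciprocal existential axioms (REA) for one assertion
#'
#' Translates a positive homology assertion into the reciprocal pair of
#' existential-restriction axioms: each taxon-scoped side is subclassed
#' under `assertion_property some` the other side. This "all-some" pattern
#' stays inside the OWL EL profile.
#'
#' @param a A one-row (or n-row, processed row-wise) assertion tibble; all
#'   rows must be positive.
#' @param vocab A [relation_vocabulary()] row matching the assertion's kind.
#' @return An axiom tibble with exactly two `subclass_of_existential` rows
#'   per assertion.
#' @export
rea_axioms <- function(a, vocab) {
  reject_negated(a)
  stopifnot(all(a$kind == vocab$kind))
  purrr::pmap(
    list(a$entity1_id, a$taxon1_id, a$entity2_id, a$taxon2_id),
    function(e1, t1, e2, t2) {
      dplyr::bind_rows(
        axiom_row("subclass_of_existential",
          subject_base = e1, subject_scope = t1,
          property = vocab$assertion_property,
          filler_base = e2, filler_scope = t2
        ),
        axiom_row("subclass_of_existential",
          subject_base = e2, subject_scope = t2,
          property = vocab$assertion_property,
          filler_base = e1, filler_scope = t1
        )
      )
    }
  ) |>
    dplyr::bind_rows()
}

slug <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

side_slug <- function(entity, scope, labels) {
  lab <- function(id) {
    if (!is.null(labels) && id %in% names(labels)) labels[[id]] else id
  }
  s <- slug(lab(entity))
  if (!is.na(scope)) s <- paste0(s, "_", slug(lab(scope)))
  s
}

#' Deterministic id of the ancestral individual for an assertion
#'
#' The AVA model generates one OWL individual per assertion, standing for
#' the ancestral structure from which all instances of the two homologous
#' classes descend. Its id is a pure function of the homology kind and the
#' two taxon-scoped sides in canonical (lexicographically sorted) order:
#' lowercased labels with non-alphanumeric runs collapsed to underscores,
#' scope label appended when restricted, suffixed `_ancestor` (historical)
#' or `_serial_ancestor` (serial).
#'
#' @param entity1,taxon1,entity2,taxon2 The two sides (taxa may be `NA`).
#' @param kind `"historical"` or `"serial"`.
#' @param labels Optional named character vector mapping term ids to display
#'   labels; ids are used where no label is known.
#' @return A character scalar.
#' @export
ancestor_individual_id <- function(entity1, taxon1, entity2, taxon2, kind,
                                   labels = NULL) {
  sides <- sort(c(
    side_slug(entity1, taxon1, labels),
    side_slug(entity2, taxon2, labels)
  ))
  suffix <- if (kind == "serial") "_serial_ancestor" else "_ancestor"
  paste0(paste(sides, collapse = "_"), suffix)
}

#' Ancestral value axioms (AVA) for one assertion
#'
#' Translates a positive homology assertion into the AVA pattern: a
#' generated ancestral individual, with each taxon-scoped side subclassed
#' under a `hasValue` restriction on the kind's membership property with
#' that individual. Together with the per-kind [property_axioms()] this
#' yields "all-all" semantics: every instance of either side is homologous
#' to every instance of both sides.
#'
#' @inheritParams rea_axioms
#' @param labels Optional id-to-label map used for individual naming.
#' @return A list with `axioms` (two `subclass_of_hasvalue` rows per
#'   assertion) and `groups` (one row per assertion: `individual_id`,
#'   `kind`, the two sides, `assertion_id`, `pair_key`), the ancestral
#'   groups consumed by the entailment engine.
#' @export
ava_axioms <- function(a, vocab, labels = NULL) {
  reject_negated(a)
  stopifnot(all(a$kind == vocab$kind))
  groups <- a |>
    dplyr::mutate(
      individual_id = purrr::pmap_chr(
        list(.data$entity1_id, .data$taxon1_id, .data$entity2_id, .data$taxon2_id),
        function(e1, t1, e2, t2) {
          ancestor_individual_id(e1, t1, e2, t2, vocab$kind, labels)
        }
      )
    ) |>
    dplyr::select(
      "individual_id", "kind", "entity1_id", "taxon1_id",
      "entity2_id", "taxon2_id", "assertion_id", "pair_key"
    )
  axioms <- purrr::pmap(
    list(
      a$entity1_id, a$taxon1_id, a$entity2_id, a$taxon2_id,
      groups$individual_id
    ),
    function(e1, t1, e2, t2, ind) {
      dplyr::bind_rows(
        axiom_row("subclass_of_hasvalue",
          subject_base = e1, subject_scope = t1,
          property = vocab$member_of_property, filler_individual = ind
        ),
        axiom_row("subclass_of_hasvalue",
          subject_base = e2, subject_scope = t2,
          property = vocab$member_of_property, filler_individual = ind
        )
      )
    }
  ) |>
    dplyr::bind_rows()
  list(axioms = axioms, groups = groups)
}

#' Per-kind property axioms for the AVA model
#'
#' Emits, once per homology kind, the inverse-properties axiom relating the
#' membership property to its has-member inverse, and the property chain
#' `member_of o has_member SubPropertyOf assertion_property` through which
#' the homology relation is inferred between co-members of an ancestral
#' individual.
#'
#' @param vocab A [relation_vocabulary()] row.
#' @return An axiom tibble with exactly two rows (`inverse_properties`,
#'   `property_chain`).
#' @export
property_axioms <- function(vocab) {
  dplyr::bind_rows(
    axiom_row("inverse_properties",
      chain = c(vocab$member_of_property, vocab$has_member_property)
    ),
    axiom_row("property_chain",
      property = vocab$assertion_property,
      chain = c(vocab$member_of_property, vocab$has_member_property)
    )
  )
}

#' Compile an assertion collection under one homology model
#'
#' Drops negated assertions (metadata only), dispatches each positive
#' assertion to [rea_axioms()] or [ava_axioms()] with the vocabulary of its
#' kind, and, for AVA, appends the per-kind [property_axioms()] for each
#' kind in use.
#'
#' @param assertions An assertion tibble from [parse_assertions()].
#' @param model `"rea"` or `"ava"`.
#' @param labels Optional id-to-label map (e.g. from a fixture's graphs).
#' @return A list with `axioms` (tibble) and `groups` (tibble; zero rows
#'   under REA).
#' @export
compile_model <- function(assertions, model = c("rea", "ava"), labels = NULL) {
  model <- match.arg(model)
  pos <- dplyr::filter(assertions, !.data$negated)
  kinds <- sort(unique(pos$kind))
  axioms <- empty_axioms()
  groups <- tibble::tibble(
    individual_id = character(), kind = character(),
    entity1_id = character(), taxon1_id = character(),
    entity2_id = character(), taxon2_id = character(),
    assertion_id = character(), pair_key = character()
  )
  for (k in kinds) {
    vocab <- relation_vocabulary(k)
    sub <- dplyr::filter(pos, .data$kind == k)
    if (model == "rea") {
      axioms <- dplyr::bind_rows(axioms, rea_axioms(sub, vocab))
    } else {
      out <- ava_axioms(sub, vocab, labels)
      axioms <- dplyr::bind_rows(axioms, out$axioms, property_axioms(vocab))
      groups <- dplyr::bind_rows(groups, out$groups)
    }
  }
  list(axioms = axioms, groups = groups)
}

#' Id-to-label map from one or more ontology graphs
#'
#' @param ... `onto_graph` objects.
#' @return A named character vector mapping term ids to labels.
#' @export
term_labels <- function(...) {
  terms <- dplyr::bind_rows(lapply(list(...), function(g) g$terms))
  stats::setNames(terms$label, terms$id)
}
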