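# Deterministic OWL functional-style serialization of a fixture plus a
# compiled axiom set, and a parser for the limited grammar we emit. Every
# term id is rendered as an <urn:curie:...> IRI (demo ids contain a second
# colon and so cannot be abbreviated IRIs); generated individuals as
# <urn:ind:...>. part_of / develops_from ontology edges are rendered in the
# usual anatomy-ontology encoding, as existential restrictions on
# BFO:0000050 / RO:0002202.

PART_OF <- "BFO:0000050"
DEVELOPS_FROM <- "RO:0002202"
NOT_HOM_META <- "local:negated_homology_assertion"

edge_axiom <- function(child, relation, parent) {
  if (relation == "is_a") {
    sprintf("SubClassOf(%s %s)", iri(child), iri(parent))
  } else {
    prop <- if (relation == "part_of") PART_OF else DEVELOPS_FROM
    sprintf(
      "SubClassOf(%s ObjectSomeValuesFrom(%s %s))",
      iri(child), iri(prop), iri(parent)
    )
  }
}

#' Serialize graphs, axioms, and annotations as OWL functional syntax
#'
#' Produces a deterministic functional-style document: declarations first,
#' then logical axioms (ontology edges and compiled homology axioms), then
#' phenotype-annotation instances, then negated-assertion metadata, each
#' block sorted lexicographically by rendered text. Byte-identical output
#' for identical inputs regardless of input row order.
#'
#' @param g_anat,g_tax Anatomy and taxonomy `onto_graph`s.
#' @param axioms An axiom tibble (e.g. from [compile_model()]); its `groups`
#'   individuals are declared via `individuals`.
#' @param annotations Optional phenotype-annotation tibble (columns
#'   `entity_id`, `taxon_id`, ...); each row becomes a named individual
#'   typed by the entity intersected with an `in_taxon` existential.
#' @param negated Optional tibble of negated assertions (metadata only);
#'   rendered as annotation assertions, never as logical axioms.
#' @param individuals Character vector of ancestral individual ids to
#'   declare.
#' @param ontology_iri IRI name of the ontology.
#' @return A single character scalar (the document, lines joined by
#'   newline).
#' @export
serialize_ontology <- function(g_anat, g_tax, axioms,
                               annotations = NULL, negated = NULL,
                               individuals = character(),
                               ontology_iri = "urn:homora:demo") {
  referenced <- c(
    axioms$subject_base, axioms$subject_scope, axioms$filler_base,
    axioms$filler_scope, axioms$property, unlist(axioms$chain)
  )
  referenced <- unique(referenced[!is.na(referenced)])
  declared <- c(g_anat$terms$id, g_tax$terms$id)
  props <- sort(unique(c(
    IN_TAXON, PART_OF, DEVELOPS_FROM,
    axioms$property[!is.na(axioms$property)], unlist(axioms$chain)
  )))
  dangling <- setdiff(referenced, c(declared, props))
  if (length(dangling) > 0) {
    stop("reference error: axiom references undeclared terms: ",
      paste(sort(dangling), collapse = ", "),
      call. = FALSE
    )
  }

  decl <- c(
    sprintf("Declaration(Class(%s))", iri(sort(declared))),
    sprintf("Declaration(ObjectProperty(%s))", iri(props))
  )

  ann_lines <- character()
  if (!is.null(annotations) && nrow(annotations) > 0) {
    annotations <- dplyr::arrange(
      tibble::as_tibble(annotations),
      dplyr::across(dplyr::any_of(c("entity_id", "taxon_id", "quality", "source")))
    )
    undeclared_e <- setdiff(annotations$entity_id, g_anat$terms$id)
    undeclared_t <- setdiff(annotations$taxon_id, g_tax$terms$id)
    if (length(c(undeclared_e, undeclared_t)) > 0) {
      stop("reference error: annotation references undeclared terms: ",
        paste(sort(c(undeclared_e, undeclared_t)), collapse = ", "),
        call. = FALSE
      )
    }
    ann_ids <- sprintf(
      "phenotype_%s", slug(paste(annotations$entity_id, annotations$taxon_id,
        seq_len(nrow(annotations))
      ))
    )
    ann_lines <- sprintf(
      "ClassAssertion(ObjectIntersectionOf(%s ObjectSomeValuesFrom(%s %s)) %s)",
      iri(annotations$entity_id), iri(IN_TAXON), iri(annotations$taxon_id),
      ind_iri(ann_ids)
    )
    decl <- c(decl, sprintf("Declaration(NamedIndividual(%s))", ind_iri(ann_ids)))
  }
  if (length(individuals) > 0) {
    decl <- c(decl, sprintf(
      "Declaration(NamedIndividual(%s))", ind_iri(sort(unique(individuals)))
    ))
  }

  edges <- dplyr::bind_rows(g_anat$edges, g_tax$edges)
  edge_lines <- if (nrow(edges) > 0) {
    mapply(edge_axiom, edges$child_id, edges$relation, edges$parent_id,
      USE.NAMES = FALSE
    )
  } else {
    character()
  }

  meta_lines <- character()
  if (!is.null(negated) && nrow(negated) > 0) {
    tag <- function(e, t) paste0(e, "@", ifelse(is.na(t), "*", t))
    meta_lines <- sprintf(
      'AnnotationAssertion(%s %s "%s")',
      iri(NOT_HOM_META), iri(negated$entity1_id),
      paste(negated$kind, tag(negated$entity1_id, negated$taxon1_id),
        tag(negated$entity2_id, negated$taxon2_id),
        sep = "|"
      )
    )
  }

  lines <- c(
    sprintf("Ontology(<%s>", ontology_iri),
    sort(decl),
    sort(c(edge_lines, axioms$rendered)),
    sort(ann_lines),
    sort(meta_lines),
    ")"
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

# --- parser ----------------------------------------------------------------

ofn_tokenize <- function(text) {
  pattern <- '<[^>]+>|[A-Za-z][A-Za-z0-9]*\\(|\\)|"[^"]*"'
  m <- gregexpr(pattern, text)
  regmatches(text, m)[[1]]
}

# recursive descent over the emitted grammar; returns list(node, next_pos)
ofn_parse_node <- function(tokens, pos) {
  tok <- tokens[pos]
  if (startsWith(tok, "<")) {
    return(list(node = list(type = "atom", id = ofn_strip_iri(tok)), pos = pos + 1))
  }
  if (startsWith(tok, "\"")) {
    return(list(
      node = list(type = "literal", value = gsub('^"|"$', "", tok)),
      pos = pos + 1
    ))
  }
  if (!endsWith(tok, "(")) {
    stop("parse error: unexpected token ", tok, call. = FALSE)
  }
  fun <- sub("\\($", "", tok)
  pos <- pos + 1
  args <- list()
  while (tokens[pos] != ")") {
    res <- ofn_parse_node(tokens, pos)
    args <- c(args, list(res$node))
    pos <- res$pos
    if (pos > length(tokens)) stop("parse error: unbalanced parentheses", call. = FALSE)
  }
  list(node = list(type = fun, args = args), pos = pos + 1)
}

ofn_strip_iri <- function(tok) {
  inner <- sub("^<", "", sub(">$", "", tok))
  sub("^urn:(curie|ind):", "", inner)
}

is_ind_iri <- function(tok) startsWith(tok, "<urn:ind:")

# decompose a parsed class expression into (base, scope)
ofn_cexpr <- function(node) {
  if (node$type == "atom") {
    return(list(base = node$id, scope = NA_character_))
  }
  if (node$type == "ObjectIntersectionOf" && length(node$args) == 2 &&
    node$args[[1]]$type == "atom" &&
    node$args[[2]]$type == "ObjectSomeValuesFrom" &&
    node$args[[2]]$args[[1]]$id == IN_TAXON) {
    return(list(
      base = node$args[[1]]$id,
      scope = node$args[[2]]$args[[2]]$id
    ))
  }
  stop("parse error: unsupported class expression", call. = FALSE)
}

#' Parse one rendered axiom back into structured form
#'
#' Inverse of the axiom renderer: re-parsing the `rendered` text of an
#' axiom reproduces its structured fields.
#'
#' @param line A rendered axiom string.
#' @return A one-row structured axiom tibble (same columns as the compiler
#'   emits), or `NULL` for non-axiom lines (declarations, class assertions,
#'   annotation assertions, document delimiters).
#' @export
parse_axiom <- function(line) {
  line <- trimws(line)
  if (line == "" || startsWith(line, "Ontology(") || line == ")" ||
    startsWith(line, "Declaration(") || startsWith(line, "ClassAssertion(") ||
    startsWith(line, "AnnotationAssertion(")) {
    return(NULL)
  }
  tokens <- ofn_tokenize(line)
  node <- ofn_parse_node(tokens, 1)$node
  if (node$type == "InverseObjectProperties") {
    return(axiom_row("inverse_properties",
      chain = c(node$args[[1]]$id, node$args[[2]]$id)
    ))
  }
  if (node$type == "SubObjectPropertyOf") {
    ch <- node$args[[1]]
    stopifnot(ch$type == "ObjectPropertyChain")
    return(axiom_row("property_chain",
      property = node$args[[2]]$id,
      chain = c(ch$args[[1]]$id, ch$args[[2]]$id)
    ))
  }
  if (node$type == "SubClassOf") {
    subj <- ofn_cexpr(node$args[[1]])
    obj <- node$args[[2]]
    if (obj$type == "ObjectSomeValuesFrom") {
      fill <- ofn_cexpr(obj$args[[2]])
      return(axiom_row("subclass_of_existential",
        subject_base = subj$base, subject_scope = subj$scope,
        property = obj$args[[1]]$id,
        filler_base = fill$base, filler_scope = fill$scope
      ))
    }
    if (obj$type == "ObjectHasValue") {
      return(axiom_row("subclass_of_hasvalue",
        subject_base = subj$base, subject_scope = subj$scope,
        property = obj$args[[1]]$id,
        filler_individual = obj$args[[2]]$id
      ))
    }
    # plain is_a edge axiom
    fill <- ofn_cexpr(obj)
    return(axiom_row("subclass_of_existential",
      subject_base = subj$base, subject_scope = subj$scope,
      property = NA_character_,
      filler_base = fill$base, filler_scope = fill$scope
    ))
  }
  stop("parse error: unsupported axiom: ", line, call. = FALSE)
}

#' Parse an OWL functional-syntax document emitted by this package
#'
#' @param text The document (character scalar or lines).
#' @return A structured axiom tibble containing every logical axiom in the
#'   document. Plain `SubClassOf` between named classes (is_a edges) come
#'   back with `property = NA`; homology axioms can be selected by their
#'   properties or forms.
#' @export
parse_ofn <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rows <- purrr::compact(lapply(lines, parse_axiom))
  if (length(rows) == 0) {
    return(empty_axioms())
  }
  dplyr::bind_rows(rows)
}

#' Select the homology axioms from a parsed document
#'
#' @param axioms A structured axiom tibble from [parse_ofn()].
#' @return The rows that belong to a homology model: existential or
#'   hasValue restrictions on homology/membership properties, inverse
#'   property axioms, and property chains.
#' @export
homology_axioms <- function(axioms) {
  hom_props <- c(
    relation_vocabulary("historical")[, c(
      "assertion_property", "member_of_property", "has_member_property"
    )],
    relation_vocabulary("serial")[, c(
      "assertion_property", "member_of_property", "has_member_property"
    )]
  )
  hom_props <- unique(unlist(hom_props, use.names = FALSE))
  dplyr::filter(
    axioms,
    .data$form %in% c("inverse_properties", "property_chain") |
      (!is.na(.data$property) & .data$property %in% hom_props)
  )
}
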