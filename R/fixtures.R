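# Regenerates the fin/limb demonstration data set: a small anatomy graph and
# vertebrate taxonomy, the curated homology assertion table (11 rows, 2
# negative), the 23 entity-quality phenotype annotations, and the expected
# answer sets of the seven competency questions under both homology models
# and under the expert-user expectation.

demo_anatomy_terms <- function() {
  tibble::tribble(
    ~id, ~label,
    "UBERON:demo:appendage", "paired appendage structure",
    "UBERON:demo:paired_fin", "paired fin",
    "UBERON:demo:limb", "limb",
    "UBERON:demo:paired_fin_bud", "paired fin bud",
    "UBERON:demo:limb_bud", "limb bud",
    "UBERON:0000151", "pectoral fin",
    "UBERON:0000152", "pelvic fin",
    "UBERON:4200003", "archipterygial fin",
    "UBERON:0002102", "forelimb",
    "UBERON:0002103", "hindlimb",
    "UBERON:0000024", "forelimb wing",
    "UBERON:4300239", "hind flipper",
    "UBERON:4300172", "pectoral fin bud",
    "UBERON:demo:pelvic_fin_bud", "pelvic fin bud",
    "UBERON:0005417", "forelimb bud",
    "UBERON:0005418", "hindlimb bud",
    "UBERON:4300230", "forelimb wing bud",
    "UBERON:0000976", "humerus",
    "UBERON:0000981", "femur",
    "UBERON:demo:pectoral_fin_ray", "pectoral fin ray",
    "UBERON:demo:forelimb_bud_mesenchyme", "forelimb bud mesenchyme",
    "UBERON:0003631", "pedal digit 1",
    "UBERON:0012136", "prehallux",
    "UBERON:demo:manual_digit_1", "manual digit 1",
    "UBERON:demo:manus", "manus",
    "UBERON:demo:phalanx", "phalanx"
  ) |>
    dplyr::mutate(namespace = "anatomy")
}

demo_anatomy_edges <- function() {
  tibble::tribble(
    ~child, ~relation, ~parent,
    # subsumption backbone
    "paired fin", "is_a", "paired appendage structure",
    "limb", "is_a", "paired appendage structure",
    "paired fin bud", "is_a", "paired appendage structure",
    "limb bud", "is_a", "paired appendage structure",
    "prehallux", "is_a", "paired appendage structure",
    "pectoral fin", "is_a", "paired fin",
    "pelvic fin", "is_a", "paired fin",
    "archipterygial fin", "is_a", "pectoral fin",
    "forelimb", "is_a", "limb",
    "hindlimb", "is_a", "limb",
    "forelimb wing", "is_a", "forelimb",
    "hind flipper", "is_a", "hindlimb",
    "pectoral fin bud", "is_a", "paired fin bud",
    "pelvic fin bud", "is_a", "paired fin bud",
    "forelimb bud", "is_a", "limb bud",
    "hindlimb bud", "is_a", "limb bud",
    "forelimb wing bud", "is_a", "forelimb bud",
    # parthood (never propagates homology)
    "humerus", "part_of", "forelimb",
    "femur", "part_of", "hindlimb",
    "pectoral fin ray", "part_of", "pectoral fin",
    "forelimb bud mesenchyme", "part_of", "forelimb bud",
    "pedal digit 1", "part_of", "hindlimb",
    "manual digit 1", "part_of", "forelimb",
    "manus", "part_of", "forelimb",
    "phalanx", "part_of", "manus",
    # development (never propagates homology)
    "forelimb", "develops_from", "forelimb bud",
    "forelimb wing", "develops_from", "forelimb wing bud",
    "hindlimb", "develops_from", "hindlimb bud",
    "pectoral fin", "develops_from", "pectoral fin bud",
    "pelvic fin", "develops_from", "pelvic fin bud"
  )
}

# Uberon-style homology grouping classes: high-level classes of
# near-certain homology. Off by default; enabling them must not change any
# query answer (they only add shared superclasses, never new asserted
# sides).
demo_overlay_terms <- function() {
  tibble::tribble(
    ~id, ~label,
    "UBERON:0004708", "paired limb/fin",
    "UBERON:0004710", "pectoral appendage",
    "UBERON:demo:pelvic_appendage", "pelvic appendage",
    "UBERON:demo:paired_limb_fin_bud", "paired limb/fin bud"
  ) |>
    dplyr::mutate(namespace = "anatomy")
}

demo_overlay_edges <- function() {
  tibble::tribble(
    ~child, ~relation, ~parent,
    "paired limb/fin", "is_a", "paired appendage structure",
    "paired limb/fin bud", "is_a", "paired appendage structure",
    "paired fin", "is_a", "paired limb/fin",
    "limb", "is_a", "paired limb/fin",
    "pectoral fin", "is_a", "pectoral appendage",
    "forelimb", "is_a", "pectoral appendage",
    "pelvic fin", "is_a", "pelvic appendage",
    "hindlimb", "is_a", "pelvic appendage",
    "pectoral appendage", "is_a", "paired limb/fin",
    "pelvic appendage", "is_a", "paired limb/fin",
    "paired fin bud", "is_a", "paired limb/fin bud",
    "limb bud", "is_a", "paired limb/fin bud"
  )
}

demo_taxonomy_terms <- function() {
  higher <- c(
    "Vertebrata", "Actinopterygii", "Sarcopterygii", "Tetrapoda",
    "Amphibia", "Mammalia", "Aves", "Anura", "Dicynodontia"
  )
  species <- c(
    "Glyptolepis", "Acanthostega gunnari", "Eoraptor lunensis",
    "Triadobatrachus massinoti", "Callobatrachus sanyanensis",
    "Xenophrys aceras", "Myotis lucifugus", "Callorhinus ursinus",
    "Pteropus giganteus", "Mus musculus", "Hippopotamus amphibius",
    "Dasypus novemcinctus", "Gallus gallus domesticus", "Danio rerio",
    "Acestrorhynchus pantaneiro", "Colossoma macropomum",
    "Adrianichthys oophorus"
  )
  labels <- c(higher, species)
  tibble::tibble(
    id = paste0("VTO:demo:", vapply(labels, slug, character(1))),
    label = labels,
    namespace = "taxonomy"
  )
}

demo_taxonomy_edges <- function() {
  tibble::tribble(
    ~child, ~parent,
    "Actinopterygii", "Vertebrata",
    "Sarcopterygii", "Vertebrata",
    "Glyptolepis", "Sarcopterygii",
    "Tetrapoda", "Sarcopterygii",
    "Amphibia", "Tetrapoda",
    "Mammalia", "Tetrapoda",
    "Aves", "Tetrapoda",
    "Acanthostega gunnari", "Tetrapoda",
    "Eoraptor lunensis", "Tetrapoda",
    "Dicynodontia", "Tetrapoda",
    "Anura", "Amphibia",
    "Triadobatrachus massinoti", "Amphibia",
    "Callobatrachus sanyanensis", "Anura",
    "Xenophrys aceras", "Anura",
    "Myotis lucifugus", "Mammalia",
    "Callorhinus ursinus", "Mammalia",
    "Pteropus giganteus", "Mammalia",
    "Mus musculus", "Mammalia",
    "Hippopotamus amphibius", "Mammalia",
    "Dasypus novemcinctus", "Mammalia",
    "Gallus gallus domesticus", "Aves",
    "Danio rerio", "Actinopterygii",
    "Acestrorhynchus pantaneiro", "Actinopterygii",
    "Colossoma macropomum", "Actinopterygii",
    "Adrianichthys oophorus", "Actinopterygii"
  ) |>
    dplyr::mutate(relation = "is_a") |>
    dplyr::select("child", "relation", "parent")
}

# The 11 curated fin/limb homology assertion rows; evidence by ECO code:
# positional 0000060, gene expression 0000075, developmental 0000067,
# non-traceable author statement 0000034.
demo_assertion_rows <- function() {
  tibble::tribble(
    ~entity1, ~taxon1, ~relationship, ~entity2, ~taxon2, ~evidence, ~attribution,
    "forelimb", "Tetrapoda", "serially_homologous_to", "hindlimb", "Tetrapoda", "ECO:0000060", "B63",
    "forelimb bud", "Tetrapoda", "serially_homologous_to", "hindlimb bud", "Tetrapoda", "ECO:0000075", "B69;B29",
    "humerus", "Tetrapoda", "serially_homologous_to", "femur", "Tetrapoda", "ECO:0000075", "B49",
    "pectoral fin", "Vertebrata", "homologous_to", "forelimb", "Tetrapoda", "ECO:0000034", "B23",
    "pectoral fin", "Vertebrata", "serially_homologous_to", "pelvic fin", "Vertebrata", "ECO:0000075", "B69;B29",
    "pectoral fin bud", "Vertebrata", "homologous_to", "forelimb bud", "Tetrapoda", "ECO:0000067", "B19;B29",
    "pelvic fin bud", "Vertebrata", "homologous_to", "hindlimb bud", "Tetrapoda", "ECO:0000067", "B19;B29",
    "pelvic fin", "Vertebrata", "homologous_to", "hindlimb", "Tetrapoda", "ECO:0000034", "B23",
    "prehallux", "Anura", "homologous_to", "pedal digit 1", "Tetrapoda", "ECO:0000067", "B20",
    "prehallux", "Anura", "not_homologous_to", "pedal digit 1", "Tetrapoda", "ECO:0000067", "B16",
    "prehallux", "Anura", "not_homologous_to", "pedal digit 1", "Tetrapoda", "ECO:0000067", "B20"
  )
}

# The 23 entity-quality phenotype annotations. Two near-duplicate mouse
# rows ("Forelimb bud / Small" and "Small forelimb buds") are deliberately
# both present: pre- and post-composed forms of the same phenotype.
demo_annotation_rows <- function() {
  tibble::tribble(
    ~entity, ~quality, ~related_entity, ~species, ~source,
    "archipterygial fin", "present", NA, "Glyptolepis", "phenoscape-kb",
    "forelimb", "length", "hindlimb", "Eoraptor lunensis", "phenoscape-kb",
    "forelimb bud", "small", NA, "Mus musculus", "phenoscape-kb",
    "forelimb bud mesenchyme", "present", NA, "Mus musculus", "added-for-testing",
    "forelimb wing", "structure", NA, "Pteropus giganteus", "phenoscape-kb",
    "forelimb wing bud", "present", NA, "Gallus gallus domesticus", "added-for-testing",
    "hind flipper", "present", NA, "Callorhinus ursinus", "phenoscape-kb",
    "hindlimb", "decreased length", NA, "Triadobatrachus massinoti", "phenoscape-kb",
    "humerus", "decreased length", "trunk vertebra", "Acanthostega gunnari", "phenoscape-kb",
    "limb", "decreased length", NA, "Dicynodontia", "phenoscape-kb",
    "manual digit 1", "torsioned", NA, "Xenophrys aceras", "phenoscape-kb",
    "manus", "has extra parts of type", "phalanx", "Hippopotamus amphibius", "phenoscape-kb",
    "paired fin bud", "hypoplastic", NA, "Danio rerio", "phenoscape-kb",
    "pectoral fin", "position", "cleithrum", "Acestrorhynchus pantaneiro", "phenoscape-kb",
    "pectoral fin bud", "aplastic", NA, "Danio rerio", "phenoscape-kb",
    "pectoral fin ray", "bifurcated", NA, "Colossoma macropomum", "phenoscape-kb",
    "pedal digit 1", "decreased length", "pedal digit 2", "Dasypus novemcinctus", "phenoscape-kb",
    "pelvic fin", "located in", "posterior region of body", "Adrianichthys oophorus", "phenoscape-kb",
    "prehallux", "present", NA, "Myotis lucifugus", "phenoscape-kb",
    "prehallux", "present", NA, "Callobatrachus sanyanensis", "phenoscape-kb",
    "forelimb bud", "small forelimb buds", NA, "Mus musculus", "phenoscape-kb",
    "hindlimb bud", "small hindlimb buds", NA, "Mus musculus", "phenoscape-kb",
    "limb bud", "small limb buds", NA, "Mus musculus", "phenoscape-kb"
  )
}

# Competency questions and, per question, the expected annotation sets
# (entity@species label pairs) under the expert-user expectation and under
# the entailments of each model.
demo_expectation_spec <- function() {
  cq_user <- list(
    `1` = c("forelimb|Eoraptor lunensis", "forelimb wing|Pteropus giganteus"),
    `2` = c(
      "forelimb|Eoraptor lunensis", "pectoral fin|Acestrorhynchus pantaneiro",
      "archipterygial fin|Glyptolepis"
    ),
    `3` = c(
      "forelimb bud|Mus musculus", "forelimb wing bud|Gallus gallus domesticus"
    ),
    `4` = "prehallux|Callobatrachus sanyanensis",
    `5` = c("forelimb|Eoraptor lunensis", "forelimb wing|Pteropus giganteus"),
    `6` = c(
      "forelimb bud|Mus musculus", "forelimb wing bud|Gallus gallus domesticus"
    ),
    `7` = c("forelimb|Eoraptor lunensis", "forelimb wing|Pteropus giganteus")
  )
  cq_rea <- cq_user
  cq_rea$`2` <- character()
  cq_rea$`7` <- character()
  cq_ava <- cq_user
  cq_ava$`1` <- c(cq_user$`1`, "pectoral fin|Acestrorhynchus pantaneiro",
    "archipterygial fin|Glyptolepis"
  )
  cq_ava$`2` <- c(cq_user$`2`, "forelimb wing|Pteropus giganteus")
  cq_ava$`3` <- c(cq_user$`3`, "pectoral fin bud|Danio rerio")
  cq_ava$`4` <- c(cq_user$`4`, "pedal digit 1|Dasypus novemcinctus")
  cq_ava$`5` <- c(cq_user$`5`, "hindlimb|Triadobatrachus massinoti",
    "hind flipper|Callorhinus ursinus"
  )
  cq_ava$`6` <- c(cq_user$`6`, "hindlimb bud|Mus musculus")
  cq_ava$`7` <- c(cq_user$`7`, "hindlimb|Triadobatrachus massinoti",
    "hind flipper|Callorhinus ursinus"
  )
  list(
    queries = tibble::tibble(
      cq = 1:7,
      query_label = c(
        "pectoral fin", "forelimb wing", "pectoral fin bud", "pedal digit 1",
        "hindlimb", "hindlimb bud", "hind flipper"
      ),
      kind = c(rep("historical", 4), rep("serial", 3))
    ),
    user = cq_user, rea = cq_rea, ava = cq_ava
  )
}

#' Build the fin/limb demonstration fixture
#'
#' Deterministically regenerates the demonstration data set: the paired
#' fin/limb anatomy subgraph (is_a backbone plus part_of and develops_from
#' edges that must never propagate homology), a small vertebrate taxonomy,
#' the 11 curated homology assertions (2 of them negative), the 23
#' entity-quality phenotype annotations, and the expected answers of the
#' seven competency questions under the REA model, the AVA model, and the
#' expert-user expectation.
#'
#' @param include_grouping_overlay Also include the homology-driven
#'   grouping classes (e.g. "paired limb/fin", "pectoral appendage") as
#'   extra superclasses. They add subsumption structure only and must not
#'   change any query answer.
#' @return A `homology_fixture`: a list with `anatomy` and `taxonomy`
#'   graphs, `assertions`, `annotations`, `expectations`, and `labels`.
#' @export
build_demo <- function(include_grouping_overlay = FALSE) {
  anat_terms <- demo_anatomy_terms()
  anat_edges <- demo_anatomy_edges()
  if (include_grouping_overlay) {
    anat_terms <- dplyr::bind_rows(anat_terms, demo_overlay_terms())
    anat_edges <- dplyr::bind_rows(anat_edges, demo_overlay_edges())
  }
  tax_terms <- demo_taxonomy_terms()
  label_to_id <- stats::setNames(
    c(anat_terms$id, tax_terms$id), c(anat_terms$label, tax_terms$label)
  )
  to_id <- function(x) unname(label_to_id[x])

  anatomy <- load_ontology(
    anat_terms,
    tibble::tibble(
      child_id = to_id(anat_edges$child),
      relation = anat_edges$relation,
      parent_id = to_id(anat_edges$parent)
    )
  )
  tax_edges <- demo_taxonomy_edges()
  taxonomy <- load_ontology(
    tax_terms,
    tibble::tibble(
      child_id = to_id(tax_edges$child),
      relation = tax_edges$relation,
      parent_id = to_id(tax_edges$parent)
    )
  )

  arows <- demo_assertion_rows()
  assertion_table <- tibble::tibble(
    entity1_id = to_id(arows$entity1),
    taxon1_id = to_id(arows$taxon1),
    relationship = arows$relationship,
    entity2_id = to_id(arows$entity2),
    taxon2_id = to_id(arows$taxon2),
    evidence_eco_ids = arows$evidence,
    attribution = arows$attribution
  )
  assertions <- parse_assertions(assertion_table, anatomy, taxonomy)

  nrows <- demo_annotation_rows()
  annotations <- tibble::tibble(
    entity_id = to_id(nrows$entity),
    quality = nrows$quality,
    related_entity = nrows$related_entity,
    taxon_id = to_id(nrows$species),
    source = nrows$source
  )

  spec <- demo_expectation_spec()
  key_to_id <- function(keys) {
    if (length(keys) == 0) {
      return(character())
    }
    parts <- strsplit(keys, "|", fixed = TRUE)
    sort(vapply(
      parts,
      function(p) paste(to_id(p[1]), to_id(p[2]), sep = "|"),
      character(1)
    ))
  }
  expectations <- tidyr::crossing(
    spec$queries,
    column = c("rea", "ava", "user")
  ) |>
    dplyr::mutate(
      query_id = to_id(.data$query_label),
      keys = purrr::map2(
        .data$cq, .data$column,
        function(cq, column) key_to_id(spec[[column]][[as.character(cq)]])
      )
    ) |>
    dplyr::select("cq", "query_id", "query_label", "kind", "column", "keys") |>
    dplyr::arrange(.data$cq, .data$column)

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

#' Demonstration fixture plus an over-general homology assertion
#'
#' Adds the historical assertion "paired fin (in Vertebrata) homologous to
#' limb (in Tetrapoda)" to the demonstration fixture. Because the asserted
#' classes are general grouping terms, the all-all AVA semantics then
#' relate every paired fin to every limb: a query for homologs of
#' "pectoral fin" gains hindlimb (and other limb) entities. The all-some
#' REA semantics are unaffected: the pectoral fin query still returns only
#' forelimb and forelimb wing.
#'
#' @return A `homology_fixture` with the extra assertion and a
#'   `scenario` element naming it.
#' @export
build_general_scenario <- function() {
  fx <- build_demo()
  extra <- tibble::tibble(
    entity1_id = "UBERON:demo:paired_fin",
    taxon1_id = "VTO:demo:vertebrata",
    relationship = "homologous_to",
    entity2_id = "UBERON:demo:limb",
    taxon2_id = "VTO:demo:tetrapoda",
    evidence_eco_ids = "ECO:0000034",
    attribution = "B29"
  )
  parsed <- parse_assertions(extra, fx$anatomy, fx$taxonomy)
  parsed$assertion_id <- "ha:extra_paired_fin_limb"
  fx$assertions <- dplyr::bind_rows(fx$assertions, parsed)
  fx$scenario <- "general paired fin / limb assertion"
  fx
}

#' @export
print.homology_fixture <- function(x, ...) {
  cat(sprintf(
    "<homology_fixture> anatomy: %d terms; taxonomy: %d terms; %d assertions (%d negated); %d annotations%s\n",
    nrow(x$anatomy$terms), nrow(x$taxonomy$terms),
    nrow(x$assertions), sum(x$assertions$negated), nrow(x$annotations),
    if (!is.null(x$scenario)) paste0("; scenario: ", x$scenario) else ""
  ))
  invisible(x)
}

#' Random fixture generator for property tests
#'
#' Builds a seeded, reproducible fixture in the same shape as the
#' demonstration one: a random rooted anatomy DAG (every non-root term has
#' at least one is_a parent, plus scattered part_of / develops_from
#' edges), a random rooted taxonomy tree, random positive and negative
#' homology assertions with random taxon scopes, and random annotations.
#' No expectations are attached.
#'
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param n_terms Number of anatomy terms (the taxonomy gets roughly a
#'   third as many).
#' @param n_assertions,n_annotations Table sizes.
#' @return A `homology_fixture` (with `expectations = NULL`).
#' @export
build_random <- function(seed, n_terms = 30, n_assertions = 10,
                         n_annotations = 40) {
  stopifnot(n_terms >= 3, n_assertions >= 0, n_annotations >= 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  rooted_dag <- function(ids, namespace, extra_relations = FALSE) {
    n <- length(ids)
    terms <- tibble::tibble(
      id = ids, label = sub("^[^:]+:", "", ids), namespace = namespace
    )
    edges <- purrr::map(2:n, function(i) {
      k <- 1 + stats::rbinom(1, 1, 0.3)
      parents <- sample(seq_len(i - 1), min(k, i - 1))
      tibble::tibble(
        child_id = ids[i], relation = "is_a", parent_id = ids[parents]
      )
    }) |>
      dplyr::bind_rows()
    if (extra_relations) {
      n_extra <- max(1, n %/% 5)
      lo <- sample(2:n, n_extra, replace = TRUE)
      hi <- vapply(lo, function(i) sample(seq_len(i - 1), 1), integer(1))
      extra <- tibble::tibble(
        child_id = ids[lo],
        relation = sample(c("part_of", "develops_from"), n_extra, replace = TRUE),
        parent_id = ids[hi]
      )
      edges <- dplyr::bind_rows(edges, extra)
    }
    load_ontology(terms, dplyr::distinct(edges))
  }

  anat_ids <- sprintf("ANAT:%03d", seq_len(n_terms))
  n_taxa <- max(5, n_terms %/% 3)
  tax_ids <- sprintf("TAX:%03d", seq_len(n_taxa))
  anatomy <- rooted_dag(anat_ids, "anatomy", extra_relations = TRUE)
  taxonomy <- rooted_dag(tax_ids, "taxonomy")

  assertions <- empty_assertions()
  if (n_assertions > 0) {
    pick_scope <- function(n) {
      ifelse(stats::runif(n) < 0.3, NA_character_,
        sample(tax_ids, n, replace = TRUE)
      )
    }
    e1 <- sample(anat_ids, n_assertions, replace = TRUE)
    e2 <- vapply(
      e1,
      function(e) sample(setdiff(anat_ids, e), 1),
      character(1),
      USE.NAMES = FALSE
    )
    neg <- stats::runif(n_assertions) < 0.2
    raw <- tibble::tibble(
      entity1_id = e1,
      taxon1_id = pick_scope(n_assertions),
      relationship = paste0(
        ifelse(neg, "not_", ""),
        sample(c("homologous_to", "serially_homologous_to"),
          n_assertions,
          replace = TRUE
        )
      ),
      entity2_id = e2,
      taxon2_id = pick_scope(n_assertions),
      evidence_eco_ids = sample(eco_codes()$eco, n_assertions, replace = TRUE),
      attribution = sprintf("src%02d", sample(1:5, n_assertions, replace = TRUE))
    )
    assertions <- parse_assertions(raw, anatomy, taxonomy)
  }

  annotations <- tibble::tibble(
    entity_id = sample(anat_ids, n_annotations, replace = TRUE),
    quality = "present",
    related_entity = NA_character_,
    taxon_id = sample(tax_ids, n_annotations, replace = TRUE),
    source = sprintf("ann%03d", seq_len(n_annotations))
  )

  structure(
    list(
      anatomy = anatomy, taxonomy = taxonomy,
      assertions = assertions, annotations = annotations,
      expectations = NULL,
      labels = term_labels(anatomy, taxonomy)
    ),
    class = "homology_fixture"
  )
}
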