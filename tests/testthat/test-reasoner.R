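test_that("annotation-side matching combines entity subsumption and taxon scope", {
  fx <- build_demo()
  prehallux <- demo_id(fx, "prehallux")
  anura <- demo_id(fx, "Anura")
  ann <- fx$annotations[fx$annotations$entity_id == prehallux, ]
  frog <- ann[grepl("callobatrachus", ann$taxon_id), ]
  bat <- ann[grepl("myotis", ann$taxon_id), ]

  expect_true(annotation_in_side(frog, fx$anatomy, fx$taxonomy, prehallux, anura))
  expect_false(annotation_in_side(bat, fx$anatomy, fx$taxonomy, prehallux, anura))
  # unrestricted root side admits everything declared beneath it
  root <- demo_id(fx, "paired appendage structure")
  expect_true(all(annotation_in_side(
    fx$annotations[fx$annotations$entity_id != demo_id(fx, "humerus") &
      !fx$annotations$entity_id %in% c(
        demo_id(fx, "femur"), demo_id(fx, "pectoral fin ray"),
        demo_id(fx, "forelimb bud mesenchyme"), demo_id(fx, "pedal digit 1"),
        demo_id(fx, "manual digit 1"), demo_id(fx, "manus")
      ), ],
    fx$anatomy, fx$taxonomy, root, NA_character_
  )))
})

test_that("REA answers follow all-some semantics on the demonstration data", {
  fx <- build_demo()

  cq1 <- query_homologs(fx, demo_id(fx, "pectoral fin"), "historical", "rea")
  expect_equal(demo_entity_labels(fx, cq1), c("forelimb", "forelimb wing"))
  # the query term's own annotations are not licensed
  expect_false(demo_id(fx, "pectoral fin") %in% cq1$entity_id)

  # a subtype filler cannot be assumed: no homologs of forelimb wing
  cq2 <- query_homologs(fx, demo_id(fx, "forelimb wing"), "historical", "rea")
  expect_equal(nrow(cq2), 0)

  cq5 <- query_homologs(fx, demo_id(fx, "hindlimb"), "serial", "rea")
  expect_equal(demo_entity_labels(fx, cq5), c("forelimb", "forelimb wing"))
  expect_false(demo_id(fx, "hind flipper") %in% cq5$entity_id)
  expect_false(demo_id(fx, "pelvic fin") %in% cq5$entity_id)

  # no serial homologs of hind flipper under REA
  expect_equal(
    nrow(query_homologs(fx, demo_id(fx, "hind flipper"), "serial", "rea")), 0
  )
})

test_that("AVA answers follow all-all semantics with a witness annotation", {
  fx <- build_demo()

  cq2 <- query_homologs(fx, demo_id(fx, "forelimb wing"), "historical", "ava")
  expect_equal(
    demo_entity_labels(fx, cq2),
    sort(c("forelimb", "pectoral fin", "archipterygial fin", "forelimb wing"))
  )
  # every match carries the ancestral-group justification and a witness
  expect_true(all(grepl("_ancestor$", cq2$justification)))
  expect_true(all(!is.na(cq2$witness_key)))

  cq7 <- query_homologs(fx, demo_id(fx, "hind flipper"), "serial", "ava")
  expect_equal(
    demo_entity_labels(fx, cq7),
    sort(c("forelimb", "forelimb wing", "hindlimb", "hind flipper"))
  )
})

test_that("an over-general assertion widens AVA but not REA answers", {
  sc <- build_general_scenario()
  pf <- demo_id(sc, "pectoral fin")

  ava <- query_homologs(sc, pf, "historical", "ava")
  expect_true(demo_id(sc, "hindlimb") %in% ava$entity_id)
  expect_true(demo_id(sc, "forelimb") %in% ava$entity_id)

  rea <- query_homologs(sc, pf, "historical", "rea")
  expect_equal(demo_entity_labels(sc, rea), c("forelimb", "forelimb wing"))

  # removing the extra assertion restores the baseline everywhere
  sc$assertions <- dplyr::filter(sc$assertions, assertion_id != "ha:extra_paired_fin_limb")
  base <- run_competency(build_demo())
  again <- run_competency(sc)
  expect_identical(
    as.data.frame(again[, c("cq", "model", "computed")]),
    as.data.frame(base[, c("cq", "model", "computed")])
  )
})

test_that("taxon-scoped queries restrict matches to the requested clade", {
  fx <- build_demo()
  pd1 <- demo_id(fx, "pedal digit 1")
  # unscoped: the anuran prehallux annotation matches, the bat one does not
  res <- query_homologs(fx, pd1, "historical", "rea")
  expect_equal(
    res$ann_key,
    paste(demo_id(fx, "prehallux"), demo_id(fx, "Callobatrachus sanyanensis"),
      sep = "|"
    )
  )
  expect_true(all(res$contradicted))

  # scoping the query to Mammalia drops the Tetrapoda-scoped target side
  scoped <- query_homologs(fx, pd1, "historical", "rea",
    query_scope = demo_id(fx, "Mammalia")
  )
  expect_equal(nrow(scoped), 0)
  # a query scope containing the target side's scope still matches
  vert <- query_homologs(fx, pd1, "historical", "rea",
    query_scope = demo_id(fx, "Vertebrata")
  )
  expect_equal(nrow(vert), 1)
})

test_that("instance-level homology is AVA-only, symmetric, and group-scoped", {
  fx <- build_demo()
  cm <- compile_model(fx$assertions, "ava", fx$labels)
  pick <- function(entity, taxon_part) {
    rows <- fx$annotations[
      fx$annotations$entity_id == demo_id(fx, entity) &
        grepl(taxon_part, fx$annotations$taxon_id),
    ]
    rows[1, ]
  }
  forelimb <- pick("forelimb", "eoraptor")
  pectoral <- pick("pectoral fin", "acestrorhynchus")
  pelvic <- pick("pelvic fin", "adrianichthys")

  expect_true(pairwise_homologous(
    forelimb, pectoral, "historical", cm$groups, fx$anatomy, fx$taxonomy
  ))
  expect_true(pairwise_homologous(
    pectoral, forelimb, "historical", cm$groups, fx$anatomy, fx$taxonomy
  ))
  expect_false(pairwise_homologous(
    forelimb, pelvic, "historical", cm$groups, fx$anatomy, fx$taxonomy
  ))
  expect_true(pairwise_homologous(
    forelimb, forelimb, "historical", cm$groups, fx$anatomy, fx$taxonomy
  ))
  expect_error(
    pairwise_homologous(
      forelimb, pectoral, "historical", cm$groups, fx$anatomy, fx$taxonomy,
      model = "rea"
    ),
    "unsupported"
  )
})

test_that("homology filters expand or exclude by query results", {
  fx <- build_demo()
  pf <- demo_id(fx, "pectoral fin")
  fl <- demo_id(fx, "forelimb")
  hum <- demo_id(fx, "humerus")

  expanded <- homology_filter(fx, pf, "expand", "historical", "rea")
  expect_setequal(
    unname(fx$labels[expanded]),
    c("pectoral fin", "forelimb", "forelimb wing")
  )
  expect_equal(homology_filter(fx, character(), "expand", "historical", "rea"),
    character()
  )
  excluded <- homology_filter(
    fx, c(fl, hum), "exclude", "historical", "rea", reference = pf
  )
  expect_equal(excluded, hum)
  expect_error(
    homology_filter(fx, "UBERON:missing", "expand", "historical", "rea"),
    "reference error"
  )
})

test_that("prototype mode materializes one instance per anatomy class", {
  # unscoped mini-fixture: one historical assertion A1 <-> A2
  anatomy <- load_ontology(
    tibble::tibble(
      id = c("A:1", "A:2", "A:3"), label = c("one", "two", "three"),
      namespace = "anatomy"
    ),
    tibble::tibble(child_id = c("A:1", "A:2"), relation = "is_a", parent_id = "A:3")
  )
  taxonomy <- load_ontology(
    tibble::tibble(id = "T:1", label = "root taxon", namespace = "taxonomy"),
    NULL
  )
  assertions <- parse_assertions(
    tibble::tibble(
      entity1_id = "A:1", taxon1_id = NA_character_,
      relationship = "homologous_to",
      entity2_id = "A:2", taxon2_id = NA_character_,
      evidence_eco_ids = "", attribution = ""
    ),
    anatomy, taxonomy
  )
  fx <- make_fixture(anatomy, taxonomy, assertions, tibble::tibble(
    entity_id = character(), quality = character(),
    related_entity = character(), taxon_id = character(), source = character()
  ))

  # without annotations nothing matches
  expect_equal(nrow(query_homologs(fx, "A:1", "historical", "rea")), 0)
  # with prototypes, the asserted partner is returned
  proto <- query_homologs(fx, "A:1", "historical", "rea", prototype = TRUE)
  expect_equal(entity_classes(proto), "A:2")
  proto_ava <- query_homologs(fx, "A:1", "historical", "ava", prototype = TRUE)
  expect_setequal(entity_classes(proto_ava), c("A:1", "A:2"))
})
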