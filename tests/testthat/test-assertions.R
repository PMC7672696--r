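test_that("the curated fin/limb table parses to 11 assertions, 2 negative", {
  fx <- build_demo()
  a <- fx$assertions
  expect_equal(nrow(a), 11)
  expect_equal(sum(a$negated), 2)
  expect_equal(sum(a$kind == "serial"), 4)

  # first row: forelimb serially homologous to hindlimb within Tetrapoda
  expect_equal(fx$labels[[a$entity1_id[1]]], "forelimb")
  expect_equal(fx$labels[[a$entity2_id[1]]], "hindlimb")
  expect_equal(a$kind[1], "serial")
  expect_false(a$negated[1])
  expect_equal(a$evidence[[1]], "ECO:0000060")
  expect_equal(fx$labels[[a$taxon1_id[1]]], "Tetrapoda")

  # multi-valued attribution cells are split
  expect_equal(a$attribution[[2]], c("B69", "B29"))
})

test_that("parser rejects unknown keywords, dangling ids, and self-pairs", {
  fx <- build_demo()
  row <- tibble::tibble(
    entity1_id = demo_id(fx, "forelimb"), taxon1_id = NA_character_,
    relationship = "similar_to",
    entity2_id = demo_id(fx, "hindlimb"), taxon2_id = NA_character_,
    evidence_eco_ids = "", attribution = ""
  )
  expect_error(parse_assertions(row, fx$anatomy, fx$taxonomy), "format error")

  row$relationship <- "homologous_to"
  row$entity2_id <- "UBERON:does_not_exist"
  expect_error(
    parse_assertions(row, fx$anatomy, fx$taxonomy),
    "reference error.*row.*1"
  )

  row$entity2_id <- row$entity1_id
  expect_error(parse_assertions(row, fx$anatomy, fx$taxonomy), "self-homology")

  # blank taxon cell means unrestricted scope
  ok <- tibble::tibble(
    entity1_id = demo_id(fx, "forelimb"), taxon1_id = "",
    relationship = "Homologous_to",
    entity2_id = demo_id(fx, "hindlimb"), taxon2_id = NA_character_,
    evidence_eco_ids = "", attribution = ""
  )
  parsed <- parse_assertions(ok, fx$anatomy, fx$taxonomy)
  expect_true(is.na(parsed$taxon1_id))
  expect_true(is.na(parsed$taxon2_id))
  expect_equal(parsed$kind, "historical")
})

test_that("serialization round-trips the assertion collection", {
  for (fx in list(build_demo(), build_random(11, 20, 8, 5))) {
    reparsed <- parse_assertions(
      serialize_assertions(fx$assertions), fx$anatomy, fx$taxonomy
    )
    expect_equal(
      as.data.frame(reparsed[, -1]), as.data.frame(fx$assertions[, -1])
    )
  }
})

test_that("contradiction audit finds exactly the prehallux / pedal digit 1 pair", {
  fx <- build_demo()
  contra <- find_contradictions(fx$assertions)
  expect_equal(nrow(contra), 1)
  expect_setequal(
    unname(fx$labels[c(contra$entity1_id, contra$entity2_id)]),
    c("prehallux", "pedal digit 1")
  )
  expect_equal(contra$kind, "historical")
  expect_equal(contra$n_positive, 1)
  expect_equal(contra$n_negative, 2)
  expect_setequal(contra$negative_attribution[[1]], c("B16", "B20"))

  # no negatives, no contradictions
  expect_equal(nrow(find_contradictions(
    dplyr::filter(fx$assertions, !negated)
  )), 0)

  # an unopposed negative is not a contradiction but is listed separately
  lone <- tibble::tibble(
    entity1_id = demo_id(fx, "humerus"), taxon1_id = NA_character_,
    relationship = "not_serially_homologous_to",
    entity2_id = demo_id(fx, "femur"), taxon2_id = NA_character_,
    evidence_eco_ids = "ECO:0000071", attribution = "B99"
  )
  with_lone <- dplyr::bind_rows(
    dplyr::filter(fx$assertions, !negated),
    parse_assertions(lone, fx$anatomy, fx$taxonomy)
  )
  # scope differs from the positive humerus/femur row (Tetrapoda), so no
  # contradiction under identical-scope matching
  expect_equal(nrow(find_contradictions(with_lone)), 0)
  expect_equal(nrow(unopposed_negatives(with_lone)), 1)
})

test_that("evidence and kind filtering keeps exactly the matching subset", {
  fx <- build_demo()
  a <- fx$assertions

  gene_expr <- filter_assertions(a, evidence_classes = "ECO:0000075")
  expect_equal(nrow(gene_expr), 3)
  expect_true(all(gene_expr$kind == "serial"))

  # identity under empty filters with negatives kept
  expect_equal(filter_assertions(a, include_negated = TRUE), a)

  # an ECO id absent from every row matches nothing
  expect_equal(nrow(filter_assertions(a, evidence_classes = "ECO:9999999")), 0)

  # subset and idempotence
  f <- filter_assertions(a, kinds = "historical", evidence_classes = "ECO:0000067")
  expect_true(all(f$assertion_id %in% a$assertion_id))
  expect_equal(filter_assertions(f, kinds = "historical",
    evidence_classes = "ECO:0000067"
  ), f)

  # is_a descent matching through an evidence ontology
  eco_g <- load_ontology(
    tibble::tibble(
      id = c("ECO:0000041", "ECO:0000067"),
      label = c("similarity evidence", "developmental similarity evidence"),
      namespace = "evidence"
    ),
    tibble::tibble(
      child_id = "ECO:0000067", relation = "is_a", parent_id = "ECO:0000041"
    )
  )
  via_parent <- filter_assertions(
    a,
    evidence_classes = "ECO:0000041", evidence_graph = eco_g
  )
  expect_equal(nrow(via_parent), 3) # the three developmental-evidence rows
  expect_equal(
    nrow(filter_assertions(a, evidence_classes = "ECO:0000041")), 0
  )
})
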