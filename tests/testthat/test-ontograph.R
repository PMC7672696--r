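test_that("loading validates structure and computes subsumption closure", {
  fx <- build_demo()

  # the demo subsumption backbone is present
  expect_true(subsumes(
    fx$anatomy, demo_id(fx, "pectoral fin"), demo_id(fx, "paired fin")
  ))
  expect_true(subsumes(
    fx$anatomy, demo_id(fx, "archipterygial fin"), demo_id(fx, "pectoral fin")
  ))
  # reflexivity
  expect_true(subsumes(
    fx$anatomy, demo_id(fx, "pectoral fin"), demo_id(fx, "pectoral fin")
  ))
  # parthood never subsumes
  expect_false(subsumes(
    fx$anatomy, demo_id(fx, "humerus"), demo_id(fx, "forelimb")
  ))

  # empty tables load cleanly
  empty <- load_ontology(
    tibble::tibble(id = character(), label = character(), namespace = character()),
    tibble::tibble(
      child_id = character(), relation = character(), parent_id = character()
    )
  )
  expect_s3_class(empty, "onto_graph")
  expect_equal(nrow(empty$terms), 0)
})

test_that("malformed inputs raise typed load errors", {
  terms <- tibble::tibble(
    id = c("A:1", "A:2"), label = c("a", "b"), namespace = "anatomy"
  )
  edge <- function(c, r, p) {
    tibble::tibble(child_id = c, relation = r, parent_id = p)
  }
  expect_error(
    load_ontology(terms, edge(c("A:1", "A:2"), "is_a", c("A:2", "A:1"))),
    "cycle error"
  )
  expect_error(load_ontology(terms, edge("A:1", "sibling_of", "A:2")), "format error")
  expect_error(load_ontology(terms, edge("A:1", "is_a", "A:9")), "reference error")
  expect_error(
    load_ontology(dplyr::mutate(terms, id = c("A:1", "A:1")), edge("A:1", "is_a", "A:1")),
    "duplicated"
  )
  expect_error(
    load_ontology(dplyr::mutate(terms, label = c("a", "")), NULL),
    "format error"
  )
  expect_error(
    load_ontology(dplyr::mutate(terms, id = c("noprefix", "A:2")), NULL),
    "CURIE"
  )
  expect_error(subsumes(load_ontology(terms, NULL), "A:1", "A:9"), "reference error")
})

test_that("subsumes agrees with brute-force reachability on random DAGs", {
  for (seed in 1:3) {
    fx <- build_random(seed, n_terms = 30, n_assertions = 0, n_annotations = 1)
    ids <- fx$anatomy$terms$id
    grid <- expand.grid(sub = ids, super = ids, stringsAsFactors = FALSE)
    got <- subsumes(fx$anatomy, grid$sub, grid$super)
    want <- mapply(
      function(s, p) oracle_subsumes(fx$anatomy$edges, s, p),
      grid$sub, grid$super
    )
    expect_identical(got, unname(want))
  }
})

test_that("part_of and develops_from edges never change subsumption", {
  fx <- build_demo()
  stripped <- load_ontology(
    fx$anatomy$terms,
    dplyr::filter(fx$anatomy$edges, .data$relation == "is_a")
  )
  ids <- fx$anatomy$terms$id
  grid <- expand.grid(sub = ids, super = ids, stringsAsFactors = FALSE)
  expect_identical(
    subsumes(fx$anatomy, grid$sub, grid$super),
    subsumes(stripped, grid$sub, grid$super)
  )
})

test_that("taxon scope membership honours the taxonomy and the unrestricted scope", {
  fx <- build_demo()
  anura <- demo_id(fx, "Anura")
  expect_true(in_scope(
    fx$taxonomy, demo_id(fx, "Callobatrachus sanyanensis"), anura
  ))
  expect_false(in_scope(
    fx$taxonomy, demo_id(fx, "Myotis lucifugus"), anura
  ))
  expect_true(in_scope(
    fx$taxonomy, demo_id(fx, "Myotis lucifugus"), NA_character_
  ))
})

test_that("validate reports orphans, duplicate edges, and namespace mixing", {
  fx <- build_demo()
  expect_equal(nrow(validate_graph(fx$anatomy)), 0)
  expect_equal(nrow(validate_graph(fx$taxonomy)), 0)

  terms <- tibble::tibble(
    id = c("A:1", "A:2", "A:3", "T:1"),
    label = c("a", "b", "lonely", "taxon"),
    namespace = c("anatomy", "anatomy", "anatomy", "taxonomy")
  )
  edges <- tibble::tibble(
    child_id = c("A:1", "A:1", "T:1"),
    relation = c("is_a", "is_a", "is_a"),
    parent_id = c("A:2", "A:2", "A:2")
  )
  rep <- validate_graph(load_ontology(terms, edges))
  expect_setequal(
    unique(rep$check), c("orphan_term", "duplicate_edge", "namespace_mixing")
  )
  expect_true("A:3" %in% rep$item[rep$check == "orphan_term"])
  expect_true(any(grepl("A:1 is_a A:2", rep$item[rep$check == "duplicate_edge"])))
})

test_that("the minimal OBO reader loads terms and typed relationships", {
  obo <- c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: A:1",
    "name: paired fin",
    "xref: FOO:1",
    "",
    "[Term]",
    "id: A:2",
    "name: pectoral fin",
    "is_a: A:1 ! paired fin",
    "relationship: part_of A:1",
    "relationship: adjacent_to A:1",
    "",
    "[Typedef]",
    "id: part_of"
  )
  path <- withr::local_tempfile(lines = obo, fileext = ".obo")
  warnings <- capture_warnings(g <- read_obo(path))
  expect_true(all(grepl("ignoring", warnings)))
  expect_setequal(
    warnings,
    c(
      "read_obo: ignoring tag xref",
      "read_obo: ignoring relationship type adjacent_to",
      "read_obo: ignoring stanza [Typedef]"
    )
  )
  expect_equal(nrow(g$terms), 2)
  expect_true(subsumes(g, "A:2", "A:1"))
  expect_true(any(g$edges$relation == "part_of"))
  expect_false(any(g$edges$relation == "adjacent_to"))
})
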