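# Invariants of the two homology semantics, checked on the demonstration
# fixture and on seeded random fixtures.

cq_key_sets <- function(fx, model) {
  queries <- dplyr::distinct(fx$expectations, cq, query_id, kind)
  lapply(seq_len(nrow(queries)), function(i) {
    sort(unique(query_homologs(
      fx, queries$query_id[i], queries$kind[i], model
    )$ann_key))
  })
}

test_that("REA matches are contained in AVA matches for every competency query", {
  fx <- build_demo()
  rea <- cq_key_sets(fx, "rea")
  ava <- cq_key_sets(fx, "ava")
  for (i in seq_along(rea)) {
    expect_true(all(rea[[i]] %in% ava[[i]]))
  }
})

test_that("serial and historical reasoning never leak into each other", {
  fx <- build_demo()
  only <- function(keep_kind) {
    out <- fx
    out$assertions <- dplyr::filter(fx$assertions, kind == keep_kind)
    out
  }
  for (model in c("rea", "ava")) {
    full <- cq_key_sets(fx, model)
    queries <- dplyr::distinct(fx$expectations, cq, query_id, kind)
    for (i in seq_len(nrow(queries))) {
      reduced <- query_homologs(
        only(queries$kind[i]), queries$query_id[i], queries$kind[i], model
      )
      expect_identical(sort(unique(reduced$ann_key)), full[[i]])
    }
  }
})

test_that("negative assertions change flags only, never match sets", {
  fx <- build_demo()
  no_neg <- fx
  no_neg$assertions <- dplyr::filter(fx$assertions, !negated)
  for (model in c("rea", "ava")) {
    with_neg <- cq_key_sets(fx, model)
    without <- cq_key_sets(no_neg, model)
    expect_identical(with_neg, without)
  }
  # the flag itself is live: the pedal digit 1 query is marked contradicted
  flagged <- query_homologs(fx, demo_id(fx, "pedal digit 1"), "historical", "rea")
  unflagged <- query_homologs(
    no_neg, demo_id(fx, "pedal digit 1"), "historical", "rea"
  )
  expect_true(all(flagged$contradicted))
  expect_false(any(unflagged$contradicted))
})

test_that("removing part_of and develops_from edges changes no answer", {
  fx <- build_demo()
  stripped <- fx
  stripped$anatomy <- load_ontology(
    fx$anatomy$terms,
    dplyr::filter(fx$anatomy$edges, relation == "is_a")
  )
  for (model in c("rea", "ava")) {
    expect_identical(cq_key_sets(stripped, model), cq_key_sets(fx, model))
  }
})

test_that("widening an assertion's taxon scope never removes a match", {
  fx <- build_demo()
  root <- demo_id(fx, "Vertebrata")
  base <- list(rea = cq_key_sets(fx, "rea"), ava = cq_key_sets(fx, "ava"))
  for (i in which(!is.na(fx$assertions$taxon1_id) & !fx$assertions$negated)) {
    widened <- fx
    widened$assertions$taxon1_id[i] <- root
    widened$assertions$taxon2_id[i] <- root
    for (model in c("rea", "ava")) {
      new_sets <- cq_key_sets(widened, model)
      for (q in seq_along(new_sets)) {
        expect_true(all(base[[model]][[q]] %in% new_sets[[q]]))
      }
    }
  }
})

test_that("negated assertions never license a match on random fixtures", {
  for (seed in 1:5) {
    fx <- build_random(seed, 20, 10, 25)
    if (!any(fx$assertions$negated)) next
    no_neg <- fx
    no_neg$assertions <- dplyr::filter(fx$assertions, !negated)
    probes <- unique(c(
      fx$assertions$entity1_id, fx$assertions$entity2_id
    ))[1:4]
    probes <- probes[!is.na(probes)]
    for (q in probes) {
      for (kind in c("historical", "serial")) {
        expect_identical(engine_rea(fx, q, kind), engine_rea(no_neg, q, kind))
        expect_identical(engine_ava(fx, q, kind), engine_ava(no_neg, q, kind))
      }
    }
  }
})

test_that("both engines agree with their brute-force oracles on random fixtures", {
  for (seed in 1:10) {
    fx <- build_random(seed, 20, 8, 25)
    probes <- unique(c(
      fx$anatomy$terms$id[1:2],
      fx$assertions$entity1_id[1]
    ))
    probes <- probes[!is.na(probes)]
    for (q in probes) {
      for (kind in c("historical", "serial")) {
        expect_identical(engine_rea(fx, q, kind), oracle_rea(fx, q, kind))
        expect_identical(engine_ava(fx, q, kind), oracle_ava_query(fx, q, kind))
      }
    }
  }
})

test_that("AVA instance homology is symmetric and reflexive within groups", {
  fx <- build_random(17, 20, 8, 20)
  cm <- compile_model(fx$assertions, "ava", fx$labels)
  pairs <- oracle_ava_materialize(fx, "historical")
  set.seed(1)
  idx <- sample(nrow(fx$annotations))
  for (i in idx[1:8]) {
    for (j in idx[1:8]) {
      got <- pairwise_homologous(
        fx$annotations[i, ], fx$annotations[j, ], "historical",
        cm$groups, fx$anatomy, fx$taxonomy
      )
      # symmetric
      expect_identical(got, pairwise_homologous(
        fx$annotations[j, ], fx$annotations[i, ], "historical",
        cm$groups, fx$anatomy, fx$taxonomy
      ))
      # equal to the forward-chaining materialization
      expect_identical(
        got, any(pairs[, 1] == i & pairs[, 2] == j)
      )
    }
    # reflexive iff member of at least one group
    in_any <- any(pairs[, 1] == i)
    expect_identical(
      pairwise_homologous(
        fx$annotations[i, ], fx$annotations[i, ], "historical",
        cm$groups, fx$anatomy, fx$taxonomy
      ),
      in_any
    )
  }
})
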