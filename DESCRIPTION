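Package: homora
Title: Logical Models of Anatomical Homology over Anatomy Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles curated assertions of historical and serial homology
    between anatomical structures into two alternative OWL axiom patterns --
    reciprocal existential axioms (REA, "all-some" semantics) and ancestral
    value axioms (AVA, "all-all" semantics via a generated ancestral
    individual, inverse properties, and a property chain) -- and answers
    homology queries over an anatomy ontology, a taxonomy, and a set of
    entity-quality phenotype annotations with a bespoke entailment engine.
    Includes a deterministic OWL functional-syntax serializer, taxon-scoped
    class expressions, evidence-based assertion filtering, contradiction
    auditing of negative homology statements, a regenerated fin/limb
    demonstration fixture, and a competency-question harness comparing both
    models against expert expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
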