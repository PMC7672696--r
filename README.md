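# homora

Logical models of anatomical homology over anatomy ontologies, in R.

## The problem

Comparative anatomists record two kinds of homology between anatomical
structures: **historical homology** (similarity inherited from a common
ancestor — a fish's pectoral fin and a tetrapod's forelimb) and **serial
homology** (similarity between repeated structures within one body plan —
forelimb and hindlimb). Curated homology assertions are increasingly
attached to multispecies anatomy ontologies so that phenotype
knowledgebases can answer questions such as *"find every phenotype
annotated to a historical homolog of the pectoral fin"*. How an assertion
should propagate through the ontology graph — to subtypes, parts,
developmental precursors, taxon-restricted populations — is a modelling
decision with real consequences for what such queries return.

`homora` implements and contrasts the two standard OWL axiom patterns for
a positive assertion "A in taxon X is homologous to B in taxon Y":

* **REA — reciprocal existential axioms** ("all-some" semantics, OWL
  EL-compatible):

  ```
  (A and in_taxon some X) SubClassOf homologous_to some (B and in_taxon some Y)
  (B and in_taxon some Y) SubClassOf homologous_to some (A and in_taxon some X)
  ```

* **AVA — ancestral value axioms** ("all-all" semantics): a generated OWL
  individual stands for the ancestral structure, both sides are subclassed
  under a `hasValue` membership restriction on it, and an inverse-property
  axiom plus the property chain

  ```
  homology_member_of o has_homology_member SubPropertyOf homologous_to
  ```

  entail that *every* instance of A is homologous to *every* instance of B
  (and to every instance of A).

Rather than shipping a description-logic reasoner, the package answers
homology queries with a bespoke entailment engine that is exact for these
two axiom shapes: homology propagates through `is_a` subsumption only —
never through `part_of` or `develops_from`, never across homology kinds —
with taxon scopes resolved against a taxonomy graph. Negative assertions
(`not_homologous_to`) are metadata: they never enter reasoning, but
contradicted conclusions are flagged. A deterministic OWL functional-syntax
serializer exports each compiled model for inspection or external
cross-checking.

The package ships a regenerated fin/limb demonstration data set —
11 curated assertions (2 negative), 23 entity–quality phenotype
annotations across 17 vertebrate taxa — and a harness of seven competency
questions with the answer sets an expert comparative anatomist expects,
alongside the answer sets each model actually entails.

## Worked example

```r
library(homora)

fx <- build_demo()                 # the fin/limb demonstration fixture
res <- query_homologs(fx, "UBERON:0000151",   # pectoral fin
                      kind = "historical", model = "ava")
tidy(res, labels = fx$labels)[, c("entity_label", "quality", "taxon_label")]
#> # A tibble: 4 × 3
#>   entity_label       quality   taxon_label
#>   <chr>              <chr>     <chr>
#> 1 forelimb wing      structure Pteropus giganteus
#> 2 pectoral fin       position  Acestrorhynchus pantaneiro
#> 3 forelimb           length    Eoraptor lunensis
#> 4 archipterygial fin present   Glyptolepis
```

Under the all-all AVA semantics the query returns the asserted homolog
(`forelimb`, annotated in the dinosaur *Eoraptor*), its subtype
(`forelimb wing`, the bat wing), and — because every member of the
ancestral group is homologous to every other — the query term itself and
its subtype (`archipterygial fin`, in the lobe-finned fish *Glyptolepis*).
The same query under `model = "rea"` returns only `forelimb` and
`forelimb wing`: the existential pattern never entails homology back onto
the query class. Each match carries its justification (the licensing
assertion or ancestral individual, here
`forelimb_tetrapoda_pectoral_fin_vertebrata_ancestor`), the witness
annotation, and a contradiction flag.

The competency harness runs all seven questions under both models:

```r
glance(run_competency(fx))
#> # A tibble: 2 × 5
#>   model n_questions n_matches_model n_matches_user n_contains_user
#> 1 ava             7               7              0               7
#> 2 rea             7               7              5               5
```

Both models reproduce their expected answer sets on all 7 questions
(`n_matches_model`). Measured against what the expert user *wanted*, REA
agrees exactly on 5 of 7 (it returns nothing for homologs of a subtype
such as "forelimb wing", or serial homologs of "hind flipper"), while AVA
always returns a superset of the expectation (`n_contains_user = 7`) —
the extras being the query term itself, its subtypes, and any asserted
superclass.

A command-line wrapper covers the same ground:

```sh
exec/homora build-demo --out demo/
exec/homora run-competency --fixture demo/
exec/homora query --model rea --kind serial --term UBERON:4300239 --fixture demo/
exec/homora generate-axioms --model ava --assertions demo/assertions.tsv \
    --ontology demo/ --out annotations-ava.ofn
exec/homora check-contradictions --fixture demo/
```

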