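---
title: "Two logical models of anatomical homology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two logical models of anatomical homology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homora)
```

## The modelling problem

A curated homology assertion relates two anatomical classes, each
optionally restricted to a taxon: "pectoral fin in Vertebrata is
historically homologous to forelimb in Tetrapoda". Once such assertions
are attached to an anatomy ontology, a phenotype query such as *historical
homologs of the pectoral fin* should return annotations on the homolog and
its subtypes — and must not return annotations on parts
(`humerus`), developmental precursors (`forelimb bud`), or homologs of the
other kind (`hindlimb` via serial homology). Homology of a whole does not
imply homology of its parts, and homologous structures routinely develop
from non-homologous precursors; the engine therefore propagates homology
through `is_a` subsumption only. Historical and serial homology use
disjoint relation vocabularies and never feed each other.

Two axiom patterns translate an assertion into OWL, and they entail
different answers:

* **REA** (reciprocal existential axioms): each taxon-scoped side is
  subclassed under an existential restriction on the other
  (`pectoral fin SubClassOf homologous_to some forelimb`, and the
  reciprocal). Every instance of one class is homologous to *some*
  instance of the other. This stays in the OWL EL profile and scales, but
  it supports only class-expression queries: given a particular forelimb
  instance, nothing follows about which pectoral fin it is homologous to,
  and a query by a *subtype* of a filler (homologs of "forelimb wing")
  returns nothing, because the existential filler cannot be assumed to be
  that subtype.

* **AVA** (ancestral value axioms): each assertion generates one OWL
  individual standing for the ancestral structure; both sides are
  subclassed under `homology_member_of value ⟨ancestor⟩`, and the pair of
  property axioms `member_of InverseOf has_member` and
  `member_of o has_member SubPropertyOf homologous_to` then entails
  homology between *every* pair of member instances, including
  reflexively. Queries by subtype, the query term itself, and any
  asserted superclass all return results. The price is expressivity
  (inverses and chains leave OWL EL).

## The entailment engine

The engine answers queries directly over four inputs: the anatomy graph,
the taxonomy graph, the assertion table, and the phenotype-annotation
table (an ABox of entity–quality instances; the quality is inert for
homology). The `is_a` closure of each graph is precomputed eagerly at load
and graphs are treated as immutable thereafter; `part_of` and
`develops_from` edges are stored but never enter the closure, which makes
the no-leakage property structural rather than procedural.

An annotation *falls in* a taxon-scoped side `(B, Y)` iff its entity is
subsumed by `B` and its organism taxon by `Y` (an absent scope is
unrestricted). On top of that:

* **REA query** for term `Q`: an annotation matches iff some positive
  assertion of the requested kind, in one of its two orientations
  `(match side, target side)`, has the annotation falling in the match
  side and the target side's base subsumed by `Q`. If the query itself is
  taxon-scoped, the target side's scope must lie within the query scope;
  this containment check is syntactic (we do not attempt to detect
  vacuously empty intersections), which matches the reported entailments
  and keeps the engine a pure closure computation.

* **AVA query** for term `Q`: each positive assertion yields an ancestral
  group whose members are the annotations falling in either side. An
  annotation matches iff it shares a group with a *witness* annotation
  whose entity is subsumed by `Q` (the witness may be the annotation
  itself). This is the instance-based reading: like the original Protégé
  demonstration, the engine queries a populated ABox, so a class with no
  annotations cannot serve as evidence of membership. Whether the
  class-level entailment `C ⊑ ∃homologous_to.Q` should hold *without* any
  witness instance is subtle in OWL; we deliberately implement the
  witness-based reading and note that a `prototype = TRUE` mode
  materializes one synthetic annotation per anatomy class (placed at the
  taxonomy root) for ABox-free exploration — with the caveat that
  taxon-scoped assertions do not fire on root-level prototypes.

Two further semantic decisions: AVA reflexivity is *group-scoped* — a
structure that participates in no assertion is not returned for its own
query — and ancestral groups are never merged, so `A↔B` and `B↔C` do not
entail `A↔C` under either model (neither axiom pattern entails it).

Negative assertions (`not_homologous_to`) are parsed, audited, and carried
as metadata only. Compiling one into axioms is an error: adding them as
logical axioms would make the affected classes unsatisfiable. When a
positive assertion that licenses a match is opposed by a negative
assertion about the identical pair of taxon-scoped sides and the same
kind, the match is flagged `contradicted = TRUE`; the flag never vetoes
the match. Negatives whose sides overlap a positive pair without being
identical are not treated as contradictions (the curated examples all use
identical scopes); they surface via `unopposed_negatives()`.

## Tunable parameters

* `kind` (`historical` / `serial`): selects the relation vocabulary
  (`RO:HOM0000007` / `RO:HOM0000027`, plus locally defined membership
  properties for AVA, since the Relations Ontology does not define them).
* `model` (`rea` / `ava`): the axiom pattern and query semantics above.
* `query_scope`: optional taxon restriction on a query; default
  unrestricted.
* `evidence_classes` in `filter_assertions()`: keep only assertions backed
  by given ECO evidence classes (exact id match by default; `is_a`-descent
  match when an evidence graph is supplied). This supports
  "only homology supported by developmental similarity"-style reasoning
  switches.
* `include_grouping_overlay` in `build_demo()`: adds Uberon-style homology
  grouping classes ("paired limb/fin", "pectoral appendage", ...) as extra
  superclasses. Because they only add shared ancestors and never new
  asserted sides, enabling the overlay must not change any answer; the
  test suite enforces this as a regression property.

## Serialization

Each compiled model serializes to an OWL functional-syntax (`.ofn`)
document — declarations, then logical axioms, then annotation instances,
then negated-assertion metadata, each block sorted lexicographically, so
output is byte-identical across runs and row orders and diffs line by
line. Functional syntax was chosen over Manchester syntax precisely for
this line-oriented determinism. Term identifiers are CURIEs throughout the
package; demonstration ids deliberately carry a second colon
(`VTO:demo:anura`), which no OFN prefix abbreviation can express, so every
identifier is rendered uniformly as an IRI of the form
`<urn:curie:...>` (generated individuals as `<urn:ind:...>`). The limited
grammar we emit is re-parsed by `parse_ofn()`, and parse∘serialize is
tested to be the identity on the structured axiom set. `part_of` and
`develops_from` edges are rendered in the conventional anatomy-ontology
encoding (existential restrictions on `BFO:0000050` / `RO:0002202`).

One ambiguity is worth recording: we emit no symmetry declaration for the
homology relation itself. Reciprocity is explicit in the REA pair, and in
AVA symmetry of the entailed relation follows from the inverse and chain
axioms; declaring the property symmetric would be redundant at best and
masks modelling errors at worst.

The ancestral-individual id is a pure function of the homology kind and
the two taxon-scoped sides in lexicographically sorted order (lowercased
labels, non-alphanumeric runs collapsed to underscores, scope label
appended when restricted, suffix `_ancestor` or `_serial_ancestor`).
Including the scope and sorting the sides makes the scheme injective over
distinct scoped assertions and side-order-independent, at the cost of not
reproducing the shorter unsorted, unscoped example name sometimes used for
illustration.

## The demonstration fixture and what it does not show

`build_demo()` regenerates the fin/limb demonstration set in code: 26
anatomy terms (17 with published UBERON ids, the rest in a `UBERON:demo:`
namespace), a 26-term vertebrate taxonomy (`VTO:demo:` ids derived from
the printed species names), the 11 curated assertions, the 23 phenotype
annotations, and the expected answer sets of the seven competency
questions under three readings: the expert expectation, REA, and AVA.
Two annotation rows are deliberate near-duplicates (pre- and post-composed
"small forelimb bud" phenotypes on the same mouse); they are retained as
distinct matches and collapse in entity-class projections. Taxonomy
placements not fixed by the source material (*Triadobatrachus* within
Amphibia; *Acanthostega*, *Eoraptor*, and Dicynodontia directly within
Tetrapoda; a single Aves lineage for chicken) are the least-committal
placements that preserve every in/out decision the questions require, and
are documented constants in the fixture source.

Passing the competency harness on this fixture shows that the engine
realizes the intended semantics of the two axiom patterns on a curated,
fully annotated graph. It does not show robustness to the features of
production knowledgebases: sparsity of annotation is the practically
important one for AVA, since a group with no annotation under the query
term has no witness and contributes nothing (for example, a query for
serial homologs of "femur" finds annotations via the humerus side under
REA, but AVA returns nothing because no femur annotation exists in the
fixture — the REA⊆AVA containment property is therefore stated only for
queries whose relevant classes are annotated). Real ontologies also bring
scale, multiple inheritance tangles, and annotation noise that the
demonstration set does not exercise.

`build_random()` generates seeded property-test fixtures: a rooted random
`is_a` DAG (every non-root term has at least one parent, so validation
stays clean) with scattered `part_of`/`develops_from` edges, a random
rooted taxonomy, assertions with ~30% unrestricted scopes and ~20%
negatives, and uniformly scattered annotations. These sizes — 16–30 terms,
7–10 assertions, 16–40 annotations, 100 seeds in the acceptance battery —
were chosen to keep exhaustive brute-force oracles (path-search
subsumption, triple-loop REA matching, forward-chaining AVA
materialization to fixpoint) cheap enough to run over every seed while
still covering scope/negation/kind interactions.

## Numerical and ordering conventions

All matching is by term id; labels are display-only. Result collections
are sorted by (entity id, taxon id, source, justification); when an
annotation is a member of a witness group through both sides, the side
recorded is entity1. The witness recorded per group is the first in
(entity id, taxon id) order. `is_a` cycles are a load-time error naming a
cycle; dangling edge endpoints and unknown relation keywords likewise
fail fast, while duplicate edges, orphan terms, and cross-namespace edges
are reported by `validate_graph()` without raising. Empty inputs (no
assertions, no annotations) yield empty results rather than errors.

## Known limitations

* Not a general OWL-DL reasoner: only the two homology axiom shapes plus
  `is_a`/`in_taxon` structure are interpreted. The serialized `.ofn`
  artifacts exist so an external DL reasoner can be used as an
  independent cross-check where one is available.
* Negative assertions only flag; there is deliberately no veto semantics.
* Query-scope matching is syntactic containment of the target side's
  scope; a query scoped below an assertion's scope (e.g. querying within
  Mammalia against a Tetrapoda-scoped side) returns nothing rather than
  specializing the side.
* The OBO reader covers the minimal `[Term]`/`is_a`/`relationship`
  subset needed to ingest hand-maintained edge files, not full OBO.
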