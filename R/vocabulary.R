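#' Relation vocabulary for a homology kind
#'
#' Each kind of homology uses its own triple of object properties: the
#' assertion property that queries are phrased with (from the OBO Relations
#' Ontology), and a locally defined membership/has-member pair used by the
#' ancestral-value (AVA) model, related by an inverse axiom and a property
#' chain.
#'
#' @param kind `"historical"` or `"serial"`.
#' @return A one-row tibble with columns `kind`, `assertion_property`,
#'   `assertion_label`, `member_of_property`, `has_member_property`.
#' @export
relation_vocabulary <- function(kind = c("historical", "serial")) {
  kind <- match.arg(kind)
  if (kind == "historical") {
    tibble::tibble(
      kind = "historical",
      assertion_property = "RO:HOM0000007",
      assertion_label = "in historical homology relationship with",
      member_of_property = "local:historical_homology_member_of",
      has_member_property = "local:has_historical_homology_member"
    )
  } else {
    tibble::tibble(
      kind = "serial",
      assertion_property = "RO:HOM0000027",
      assertion_label = "in serial homology relationship with",
      member_of_property = "local:serial_homology_member_of",
      has_member_property = "local:has_serial_homology_member"
    )
  }
}

# in_taxon (RO:0002162), used for taxon-scoped class expressions
IN_TAXON <- "RO:0002162"

#' Evidence code shorthand used in the curated assertion tables
#'
#' Maps the free-text evidence labels used in the fin/limb assertion table to
#' Evidence & Conclusion Ontology (ECO) identifiers: the phenotypic
#' similarity evidence family plus the two author-statement codes.
#'
#' @return A tibble with columns `label` and `eco`.
#' @export
eco_codes <- function() {
  tibble::tribble(
    ~label, ~eco,
    "structural similarity evidence", "ECO:0000027",
    "positional similarity evidence", "ECO:0000060",
    "compositional similarity evidence", "ECO:0000063",
    "developmental similarity evidence", "ECO:0000067",
    "morphological similarity evidence", "ECO:0000071",
    "gene expression similarity evidence", "ECO:0000075",
    "traceable author statement", "ECO:0000033",
    "non-traceable author statement", "ECO:0000034"
  )
}
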