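#' Parse a curated homology assertion table
#'
#' Each row relates an anatomical entity in an (optional) taxon to a second
#' entity in an (optional) taxon as historically or serially homologous, or
#' explicitly not so. Negative rows (`not_` relationship keywords) are kept
#' as metadata: they are never compiled into axioms and never license a
#' query match, but they drive contradiction auditing.
#'
#' @param table A data frame with columns `entity1_id`, `taxon1_id`,
#'   `relationship`, `entity2_id`, `taxon2_id`, `evidence_eco_ids`,
#'   `attribution`. `relationship` is one of `homologous_to`,
#'   `serially_homologous_to`, `not_homologous_to`,
#'   `not_serially_homologous_to` (case-insensitive). Blank or `NA` taxon
#'   cells mean an unrestricted scope; `evidence_eco_ids` and `attribution`
#'   cells may hold several `;`-separated entries.
#' @param g_anat,g_tax Anatomy and taxonomy `onto_graph`s used to resolve
#'   entity and taxon ids.
#' @return A tibble of assertions with columns `assertion_id`, `entity1_id`,
#'   `taxon1_id`, `kind`, `negated`, `entity2_id`, `taxon2_id`, `pair_key`,
#'   and list-columns `evidence` and `attribution`.
#' @export
parse_assertions <- function(table, g_anat, g_tax) {
  tab <- tibble::as_tibble(table)
  need <- c(
    "entity1_id", "taxon1_id", "relationship", "entity2_id", "taxon2_id",
    "evidence_eco_ids", "attribution"
  )
  if (!all(need %in% names(tab))) {
    stop("format error: assertion table must have columns ",
      paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(tab) == 0) {
    return(empty_assertions())
  }

  rel <- tolower(trimws(tab$relationship))
  rel <- gsub("[[:space:]]+", "_", rel)
  known <- c(
    "homologous_to", "serially_homologous_to",
    "not_homologous_to", "not_serially_homologous_to"
  )
  bad <- which(!rel %in% known)
  if (length(bad) > 0) {
    stop("format error: unknown relationship keyword in row(s) ",
      paste(bad, collapse = ", "), ": ",
      paste(unique(tab$relationship[bad]), collapse = ", "),
      call. = FALSE
    )
  }

  blank_to_na <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & trimws(x) == ""] <- NA_character_
    trimws(x)
  }
  e1 <- trimws(tab$entity1_id)
  e2 <- trimws(tab$entity2_id)
  t1 <- blank_to_na(tab$taxon1_id)
  t2 <- blank_to_na(tab$taxon2_id)

  check_resolvable(e1, g_anat, "entity1_id")
  check_resolvable(e2, g_anat, "entity2_id")
  check_resolvable(t1[!is.na(t1)], g_tax, "taxon1_id", rows = which(!is.na(t1)))
  check_resolvable(t2[!is.na(t2)], g_tax, "taxon2_id", rows = which(!is.na(t2)))

  same_scope <- (is.na(t1) & is.na(t2)) | (!is.na(t1) & !is.na(t2) & t1 == t2)
  self_pair <- which(e1 == e2 & same_scope)
  if (length(self_pair) > 0) {
    stop("format error: self-homology pair(s) in row(s) ",
      paste(self_pair, collapse = ", "),
      call. = FALSE
    )
  }

  split_multi <- function(x) {
    lapply(as.character(x), function(cell) {
      if (is.na(cell) || trimws(cell) == "") {
        return(character())
      }
      out <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
      out[out != ""]
    })
  }

  negated <- startsWith(rel, "not_")
  kind <- ifelse(grepl("serially", rel), "serial", "historical")

  side_tag <- function(e, t) paste0(e, "@", ifelse(is.na(t), "*", t))
  s1 <- side_tag(e1, t1)
  s2 <- side_tag(e2, t2)
  pair_key <- paste(kind, pmin(s1, s2), pmax(s1, s2), sep = "|")

  tibble::tibble(
    assertion_id = sprintf("ha:%03d", seq_along(e1)),
    entity1_id = e1, taxon1_id = t1,
    kind = kind, negated = negated,
    entity2_id = e2, taxon2_id = t2,
    pair_key = pair_key,
    evidence = split_multi(tab$evidence_eco_ids),
    attribution = split_multi(tab$attribution)
  )
}

empty_assertions <- function() {
  tibble::tibble(
    assertion_id = character(), entity1_id = character(),
    taxon1_id = character(), kind = character(), negated = logical(),
    entity2_id = character(), taxon2_id = character(), pair_key = character(),
    evidence = list(), attribution = list()
  )
}

check_resolvable <- function(ids, g, col, rows = seq_along(ids)) {
  if (length(ids) == 0) {
    return(invisible())
  }
  miss <- !ids %in% g$terms$id
  if (any(miss)) {
    stop("reference error: unresolvable ", col, " in row(s) ",
      paste(rows[miss], collapse = ", "), ": ",
      paste(unique(ids[miss]), collapse = ", "),
      call. = FALSE
    )
  }
  invisible()
}

#' Find positive/negative contradictions among assertions
#'
#' A pair of anatomical sides (matched on identical entity ids and identical
#' taxon scopes, unordered) is contradicted when, for the same homology
#' kind, the table holds at least one positive and at least one negative
#' assertion about it. Contradictions are reported, never resolved: negative
#' assertions do not veto entailments, they only flag results.
#'
#' @param assertions An assertion tibble from [parse_assertions()].
#' @return A tibble with one row per contradicted pair: the two sides,
#'   `kind`, counts `n_positive`/`n_negative`, and list-columns of the
#'   positive and negative evidence and attributions.
#' @seealso [unopposed_negatives()] for negatives with no positive
#'   counterpart (not contradictions).
#' @export
find_contradictions <- function(assertions) {
  grouped <- assertions |>
    dplyr::group_by(.data$pair_key, .data$kind) |>
    dplyr::summarise(
      entity1_id = .data$entity1_id[1],
      taxon1_id = .data$taxon1_id[1],
      entity2_id = .data$entity2_id[1],
      taxon2_id = .data$taxon2_id[1],
      n_positive = sum(!.data$negated),
      n_negative = sum(.data$negated),
      positive_evidence = list(sort(unique(unlist(.data$evidence[!.data$negated])))),
      negative_evidence = list(sort(unique(unlist(.data$evidence[.data$negated])))),
      positive_attribution = list(sort(unique(unlist(.data$attribution[!.data$negated])))),
      negative_attribution = list(sort(unique(unlist(.data$attribution[.data$negated])))),
      .groups = "drop"
    )
  grouped |>
    dplyr::filter(.data$n_positive > 0, .data$n_negative > 0) |>
    dplyr::arrange(.data$pair_key)
}

# cheap projection used by the query engines to set the contradicted flag
contradicted_pair_keys <- function(assertions) {
  intersect(
    assertions$pair_key[assertions$negated],
    assertions$pair_key[!assertions$negated]
  )
}

#' Negative assertions with no positive counterpart
#'
#' @param assertions An assertion tibble from [parse_assertions()].
#' @return The subset of negated assertion rows whose (sides, kind) pair has
#'   no positive assertion; these are reported separately from
#'   contradictions.
#' @export
unopposed_negatives <- function(assertions) {
  pos_keys <- unique(assertions$pair_key[!assertions$negated])
  assertions |>
    dplyr::filter(.data$negated, !.data$pair_key %in% pos_keys)
}

#' Filter assertions by kind, evidence class, and polarity
#'
#' Supports evidence-based selection of homology assumptions: keep only
#' assertions backed by particular lines of evidence (ECO classes), and/or
#' of one homology kind. Matching is by exact ECO id, or by `is_a` descent
#' when an evidence `onto_graph` is supplied (so a request for a general
#' evidence class keeps assertions annotated with its subtypes).
#'
#' @param assertions An assertion tibble from [parse_assertions()].
#' @param kinds Optional character subset of `c("historical", "serial")`.
#' @param evidence_classes Optional character vector of ECO CURIEs; an
#'   assertion is kept if any of its evidence records matches any requested
#'   class.
#' @param include_negated Keep negated assertions (default `FALSE`).
#' @param evidence_graph Optional ECO `onto_graph` enabling `is_a`-descent
#'   matching.
#' @return The filtered assertion tibble (always a subset of the input).
#' @export
filter_assertions <- function(assertions, kinds = NULL, evidence_classes = NULL,
                              include_negated = FALSE, evidence_graph = NULL) {
  out <- assertions
  if (!include_negated) {
    out <- dplyr::filter(out, !.data$negated)
  }
  if (!is.null(kinds)) {
    out <- dplyr::filter(out, .data$kind %in% kinds)
  }
  if (!is.null(evidence_classes)) {
    matches_class <- function(eco_ids) {
      if (length(eco_ids) == 0) {
        return(FALSE)
      }
      if (is.null(evidence_graph)) {
        return(any(eco_ids %in% evidence_classes))
      }
      known <- eco_ids[eco_ids %in% names(evidence_graph$closure)]
      direct <- any(eco_ids %in% evidence_classes)
      direct || any(vapply(
        known,
        function(e) any(ancestors(evidence_graph, e) %in% evidence_classes),
        logical(1)
      ))
    }
    keep <- vapply(out$evidence, matches_class, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  out
}
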