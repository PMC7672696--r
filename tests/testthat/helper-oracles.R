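# Independent brute-force oracles, written against the raw edge tables only
# (no use of the package's precomputed closure or query engines).

# reachability over is_a edges by depth-first path search
oracle_subsumes <- function(edges, sub, super) {
  if (sub == super) {
    return(TRUE)
  }
  isa <- edges[edges$relation == "is_a", , drop = FALSE]
  seen <- character()
  frontier <- sub
  while (length(frontier) > 0) {
    cur <- frontier[1]
    frontier <- frontier[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    parents <- isa$parent_id[isa$child_id == cur]
    if (super %in% parents) {
      return(TRUE)
    }
    frontier <- c(frontier, parents)
  }
  FALSE
}

oracle_in_side <- function(fx, ann_row, base, scope) {
  ok_e <- oracle_subsumes(fx$anatomy$edges, ann_row$entity_id, base)
  ok_t <- is.na(scope) ||
    oracle_subsumes(fx$taxonomy$edges, ann_row$taxon_id, scope)
  ok_e && ok_t
}

# REA matcher: iterate all (annotation, positive assertion, orientation)
# triples; returns sorted unique annotation row indices
oracle_rea <- function(fx, query_entity, kind) {
  pos <- fx$assertions[!fx$assertions$negated & fx$assertions$kind == kind, ]
  hits <- integer()
  for (i in seq_len(nrow(fx$annotations))) {
    ann <- fx$annotations[i, ]
    for (j in seq_len(nrow(pos))) {
      a <- pos[j, ]
      orientations <- list(
        list(mb = a$entity2_id, ms = a$taxon2_id, tb = a$entity1_id),
        list(mb = a$entity1_id, ms = a$taxon1_id, tb = a$entity2_id)
      )
      for (o in orientations) {
        if (oracle_subsumes(fx$anatomy$edges, o$tb, query_entity) &&
          oracle_in_side(fx, ann, o$mb, o$ms)) {
          hits <- c(hits, i)
        }
      }
    }
  }
  sort(unique(hits))
}

# Naive AVA materializer: assert member_of triples per annotation x group
# side, apply the inverse rule then the property chain to fixpoint, read off
# homologous pairs of annotation row indices.
oracle_ava_materialize <- function(fx, kind) {
  pos <- fx$assertions[!fx$assertions$negated & fx$assertions$kind == kind, ]
  member_of <- list() # annotation index -> group ids
  for (i in seq_len(nrow(fx$annotations))) {
    ann <- fx$annotations[i, ]
    gs <- character()
    for (j in seq_len(nrow(pos))) {
      a <- pos[j, ]
      if (oracle_in_side(fx, ann, a$entity1_id, a$taxon1_id) ||
        oracle_in_side(fx, ann, a$entity2_id, a$taxon2_id)) {
        gs <- c(gs, a$assertion_id)
      }
    }
    member_of[[i]] <- gs
  }
  # inverse rule: member_of(a, g) => has_member(g, a)
  has_member <- list()
  repeat {
    new <- FALSE
    for (i in seq_along(member_of)) {
      for (g in member_of[[i]]) {
        if (!i %in% (has_member[[g]] %||% integer())) {
          has_member[[g]] <- c(has_member[[g]], i)
          new <- TRUE
        }
      }
    }
    if (!new) break
  }
  # chain rule: member_of(a, g) o has_member(g, b) => homologous(a, b)
  pairs <- matrix(integer(), ncol = 2)
  for (i in seq_along(member_of)) {
    for (g in member_of[[i]]) {
      for (b in has_member[[g]]) {
        pairs <- rbind(pairs, c(i, b))
      }
    }
  }
  unique(pairs)
}

oracle_ava_query <- function(fx, query_entity, kind) {
  pairs <- oracle_ava_materialize(fx, kind)
  if (nrow(pairs) == 0) {
    return(integer())
  }
  witness_ok <- vapply(
    seq_len(nrow(fx$annotations)),
    function(i) {
      oracle_subsumes(fx$anatomy$edges, fx$annotations$entity_id[i], query_entity)
    },
    logical(1)
  )
  hits <- pairs[witness_ok[pairs[, 2]], 1]
  sort(unique(hits))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# convenience: sorted unique annotation row indices matched by the engine
engine_rea <- function(fx, query_entity, kind) {
  res <- rea_query(
    fx$annotations, fx$assertions, fx$anatomy, fx$taxonomy, query_entity, kind
  )
  match_rows(fx, res)
}

engine_ava <- function(fx, query_entity, kind) {
  compiled <- compile_model(fx$assertions, "ava", fx$labels)
  res <- ava_query(
    fx$annotations, compiled$groups, fx$anatomy, fx$taxonomy, query_entity, kind
  )
  match_rows(fx, res)
}

# map matched (entity, taxon, source) back to annotation row indices
match_rows <- function(fx, res) {
  key <- function(df) paste(df$entity_id, df$taxon_id, df$source)
  sort(unique(which(key(fx$annotations) %in% key(res))))
}

make_fixture <- function(anatomy, taxonomy, assertions, annotations) {
  structure(
    list(
      anatomy = anatomy, taxonomy = taxonomy, assertions = assertions,
      annotations = annotations, expectations = NULL,
      labels = term_labels(anatomy, taxonomy)
    ),
    class = "homology_fixture"
  )
}

# label helpers for the demonstration fixture
demo_id <- function(fx, label) {
  id <- names(fx$labels)[match(label, fx$labels)]
  stopifnot(!is.na(id))
  id
}

demo_entity_labels <- function(fx, result) {
  sort(unname(fx$labels[entity_classes(result)]))
}
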