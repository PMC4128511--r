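# Independent oracles used across the suite. They deliberately avoid the
# package's graph machinery: closures are computed by naive edge relaxation
# to a fixpoint, profile scores by direct double loops over annotation
# pairs.

# Reachability closure by repeated relaxation until fixpoint.
# direction "positive": follow edges subject -> object;
# direction "negative": follow edges object -> subject.
oracle_scope <- function(ontology, term, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  edges <- ontology$edges
  members <- term
  repeat {
    new <- if (direction == "positive") {
      edges$object[edges$subject %in% members]
    } else {
      edges$subject[edges$object %in% members]
    }
    grown <- union(members, new)
    if (length(grown) == length(members)) break
    members <- grown
  }
  sort(members)
}

# Naive symmetric best-match average built from first principles: term
# similarity as max IC over the intersection of oracle scopes, weighted by
# a direct kappa lookup, combined by an explicit double loop.
oracle_bma <- function(p1, p2, ic, ontology, compat = default_compatibility()) {
  if (nrow(p1) == 0 || nrow(p2) == 0) return(0)
  icv <- stats::setNames(ic$ic_bits, ic$term_id)
  tsim <- function(a, b) {
    common <- intersect(oracle_scope(ontology, a), oracle_scope(ontology, b))
    if (length(common) == 0) 0 else max(icv[common])
  }
  one_way <- function(a, b) {
    mean(vapply(seq_len(nrow(a)), function(i) {
      max(vapply(seq_len(nrow(b)), function(j) {
        quality_compatibility(a$quality[[i]], b$quality[[j]], compat) *
          tsim(a$entity_id[[i]], b$entity_id[[j]])
      }, 0))
    }, 0))
  }
  (one_way(p1, p2) + one_way(p2, p1)) / 2
}

# simGIC by explicit set arithmetic over (entity, polarity) pairs.
oracle_simgic <- function(p1, p2, ic, qualities = default_qualities()) {
  icv <- stats::setNames(ic$ic_bits, ic$term_id)
  pol <- stats::setNames(qualities$polarity, qualities$quality)
  set1 <- unique(paste(p1$entity_id, pol[p1$quality]))
  set2 <- unique(paste(p2$entity_id, pol[p2$quality]))
  if (length(set1) == 0 || length(set2) == 0) return(0)
  ent <- function(k) sub(" .*$", "", k)
  den <- sum(icv[ent(union(set1, set2))])
  if (den == 0) return(if (setequal(set1, set2)) 1 else 0)
  sum(icv[ent(intersect(set1, set2))]) / den
}

expect_same_ontology <- function(a, b) {
  expect_identical(a$kind, b$kind)
  expect_identical(dplyr::arrange(a$terms, id), dplyr::arrange(b$terms, id))
  expect_identical(
    dplyr::arrange(a$edges, subject, relation, object),
    dplyr::arrange(b$edges, subject, relation, object))
}

# Annotation set of one profile as a sorted entity/quality key vector.
ann_set <- function(profiles, id) {
  p <- dplyr::filter(profiles, profile_id == id)
  sort(paste(p$entity_id, p$quality))
}
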