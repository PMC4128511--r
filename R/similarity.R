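# Information content and profile similarity.
#
# IC is computed from annotation frequencies in a propagated corpus:
# IC(t) = -log2(count(t)/N), count(t) = number of profiles carrying a
# positive-polarity annotation of t after propagation. Because positive
# annotations flow whole -> part, a part can only accumulate counts, so a
# whole process always has information content at least as high as each of
# its necessary parts.
#
# Term similarity is Resnik-style, but the "common subsumer" is a common
# positive-propagation target (a shared part or superclass) rather than a
# classic ancestor: that is the only direction consistent with the IC
# ordering above. Profile similarity combines term similarities by
# symmetric best-match averaging (BMA), weighted by quality compatibility;
# simGIC over (entity, polarity) sets is provided as a second measure.

#' Information content of ontology terms over a corpus
#'
#' Propagates the corpus (see [propagate_profiles()]) and computes, for
#' every term of the ontology, the number of profiles carrying a
#' positive-polarity annotation of it and the information content
#' `-log2(count/N)` in bits. Terms never annotated get the finite maximum
#' `-log2(1/N)` rather than infinity, keeping downstream scores finite
#' without smoothing the observed counts.
#'
#' @param profiles A non-empty corpus tibble, valid against `ontology`.
#' @param ontology A valid [ceq_ontology()].
#' @param mode Propagation mode, see [propagate_profiles()].
#' @param qualities Quality vocabulary.
#' @return A tibble with columns `term_id`, `count`, `ic_bits`, one row per
#'   ontology term; corpus size `N` and the propagation mode are stored in
#'   attributes `n_profiles` and `mode`.
#' @export
information_content <- function(profiles, ontology,
                                mode = c("sound", "heuristic"),
                                qualities = default_qualities()) {
  mode <- match.arg(mode)
  profiles <- check_profile_frame(profiles)
  n <- n_distinct(profiles$profile_id)
  if (n == 0) abort("cannot compute information content over an empty corpus")
  prop <- propagate_profiles(profiles, ontology, mode, qualities)
  pos <- qualities$quality[qualities$polarity == "positive"]
  counts <- prop |>
    filter(.data$quality %in% pos) |>
    distinct(.data$profile_id, .data$entity_id) |>
    count(.data$entity_id, name = "count")
  out <- tibble(term_id = sort(ontology$terms$id)) |>
    left_join(counts, by = c(term_id = "entity_id")) |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count),
           ic_bits = ifelse(.data$count == 0, log2(.env$n),
                            -log2(.data$count / .env$n)))
  attr(out, "n_profiles") <- n
  attr(out, "mode") <- mode
  out
}

ic_lookup <- function(ic) {
  stats::setNames(ic$ic_bits, ic$term_id)
}

#' Resnik-style similarity of two terms
#'
#' The maximum information content over the shared positive-propagation
#' targets of the two terms (their positive scopes, each including the
#' term itself); 0 when the scopes are disjoint. Symmetric, and
#' `term_similarity(t, t)` equals `IC(t)`.
#'
#' @param t1,t2 Term ids present in `ontology`.
#' @param ic An IC table from [information_content()].
#' @param ontology A valid [ceq_ontology()].
#' @return Similarity in bits (non-negative scalar).
#' @export
term_similarity <- function(t1, t2, ic, ontology) {
  assert_known_term(ontology, t1)
  assert_known_term(ontology, t2)
  common <- intersect(positive_scope(ontology, t1),
                      positive_scope(ontology, t2))
  if (length(common) == 0) return(0)
  max(ic_lookup(ic)[common])
}

# Precomputed engine for repeated profile comparisons.
sim_engine <- function(ic, ontology, compat = default_compatibility()) {
  list(scopes = scope_table(ontology, "out"),
       ic = ic_lookup(ic),
       kappa = compat_fun(compat))
}

engine_term_sim <- function(engine, e1, e2) {
  common <- intersect(engine$scopes[[e1]], engine$scopes[[e2]])
  if (length(common) == 0) 0 else max(engine$ic[common])
}

# Symmetric best-match average between two annotation tables
# (columns entity_id, quality). Profiles are scored as given; propagate
# first if inferred annotations should participate.
bma_score <- function(p1, p2, engine) {
  n1 <- nrow(p1); n2 <- nrow(p2)
  if (n1 == 0 || n2 == 0) return(0)
  ts <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      k <- engine$kappa(p1$quality[[i]], p2$quality[[j]])
      if (k > 0) {
        ts[i, j] <- k * engine_term_sim(engine, p1$entity_id[[i]],
                                        p2$entity_id[[j]])
      }
    }
  }
  (mean(apply(ts, 1, max)) + mean(apply(ts, 2, max))) / 2
}

simgic_score <- function(p1, p2, engine, qualities) {
  pol <- stats::setNames(qualities$polarity, qualities$quality)
  key <- function(p) unique(paste(p$entity_id, unname(pol[p$quality])))
  s1 <- key(p1); s2 <- key(p2)
  if (length(s1) == 0 || length(s2) == 0) return(0)
  ent <- function(keys) vapply(strsplit(keys, " "), `[[`, "", 1L)
  inter <- intersect(s1, s2)
  uni <- union(s1, s2)
  num <- sum(engine$ic[ent(inter)])
  den <- sum(engine$ic[ent(uni)])
  if (den == 0) {
    return(if (setequal(s1, s2)) 1 else 0)
  }
  num / den
}

#' Similarity of two annotation profiles
#'
#' Scores two profiles of the same kind against each other. `"bma"`
#' (default) is the symmetric best-match average: for each annotation of
#' one profile take the best `kappa(q1, q2) * term_similarity(e1, e2)`
#' match in the other, average within each direction, then average the two
#' directions. `"simgic"` is the ratio of summed IC over the intersection
#' versus the union of the two (entity, polarity) sets, in [0, 1].
#'
#' Profiles are scored exactly as given; run [propagate_profiles()] first
#' when inferred annotations should contribute (they sharpen similarity
#' between profiles curated at different granularities).
#'
#' @param p1,p2 Corpus tibbles each holding one profile's rows (same kind).
#' @param ic IC table from [information_content()].
#' @param ontology A valid [ceq_ontology()].
#' @param compat Quality-compatibility table, see [default_compatibility()].
#' @param method `"bma"` or `"simgic"`.
#' @param qualities Quality vocabulary.
#' @return A non-negative scalar score (bits for BMA, [0, 1] for simGIC);
#'   0 if either profile is empty.
#' @export
profile_similarity <- function(p1, p2, ic, ontology,
                               compat = default_compatibility(),
                               method = c("bma", "simgic"),
                               qualities = default_qualities()) {
  method <- match.arg(method)
  p1 <- check_profile_frame(p1); p2 <- check_profile_frame(p2)
  if (nrow(p1) > 0 && nrow(p2) > 0 &&
      !identical(unique(p1$kind), unique(p2$kind))) {
    abort("profiles of different kinds cannot be compared")
  }
  engine <- sim_engine(ic, ontology, compat)
  if (method == "bma") {
    bma_score(p1, p2, engine)
  } else {
    simgic_score(p1, p2, engine, qualities)
  }
}

#' Ranked similarity search over a profile corpus
#'
#' A BLAST-like search in annotation space: the query profile and the
#' corpus are propagated, every corpus profile is scored against the query
#' and the top `k` hits are returned in descending score order with a
#' deterministic tie-break by profile id.
#'
#' @param query A corpus tibble holding the query profile (same kind as
#'   the corpus).
#' @param profiles The corpus tibble to search.
#' @param ontology A valid [ceq_ontology()].
#' @param k Number of hits to return; `k = 0` gives an empty result, `k`
#'   larger than the corpus returns everything.
#' @param ic IC table; computed from `profiles` (propagated, `mode`) when
#'   `NULL`.
#' @param compat Quality-compatibility table.
#' @param method `"bma"` or `"simgic"`.
#' @param mode Propagation mode.
#' @param qualities Quality vocabulary.
#' @return A tibble with columns `rank`, `profile_id`, `score`.
#' @export
similarity_search <- function(query, profiles, ontology, k = 10,
                              ic = NULL,
                              compat = default_compatibility(),
                              method = c("bma", "simgic"),
                              mode = c("sound", "heuristic"),
                              qualities = default_qualities()) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  query <- check_profile_frame(query)
  profiles <- check_profile_frame(profiles)
  if (n_distinct(query$profile_id) > 1) {
    abort("`query` must hold a single profile")
  }
  if (nrow(query) > 0 && nrow(profiles) > 0 &&
      !identical(unique(query$kind), unique(profiles$kind))) {
    abort("query kind does not match corpus kind")
  }
  if (is.null(ic)) ic <- information_content(profiles, ontology, mode, qualities)
  qprop <- propagate_profiles(query, ontology, mode, qualities)
  cprop <- propagate_profiles(profiles, ontology, mode, qualities)
  engine <- sim_engine(ic, ontology, compat)
  members <- split_profiles(cprop)
  scores <- map_dbl(members, function(m) {
    if (method == "bma") bma_score(qprop, m, engine)
    else simgic_score(qprop, m, engine, qualities)
  })
  out <- tibble(profile_id = names(members), score = unname(scores)) |>
    arrange(dplyr::desc(.data$score), .data$profile_id) |>
    head(n = max(0L, as.integer(k))) |>
    mutate(rank = row_number()) |>
    select(all_of(c("rank", "profile_id", "score")))
  out
}
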