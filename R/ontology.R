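# Ontology container and closure computations.
#
# An ontology is a pair of tibbles: `terms` (id, label, category) and `edges`
# (subject, relation, object) restricted to the relations is_a and has_part.
# has_part carries all-some semantics: every instance of the subject has some
# instance of the object as a part. Both relation subgraphs must be acyclic.

#' Category vocabulary for the two ontology kinds
#'
#' Continuant categories describe the cell-part (phenotype) ontology;
#' occurrent categories describe the cell-mechanism ontology.
#'
#' @format A named list with elements `phenotype` and `mechanism`, each a
#'   character vector of admissible `category` values.
#' @export
ceq_categories <- list(
  phenotype = c("cell", "structure", "ultrastructure", "molecule"),
  mechanism = c("mechanism-network", "ultrastructural-event",
                "molecular-interaction")
)

ceq_relations <- c("is_a", "has_part")

#' Construct an ontology of cell parts or cell mechanisms
#'
#' Bundles a term table and an edge table into a `ceq_ontology`. Only
#' structural requirements (column names and types) are enforced here;
#' semantic invariants (unique ids, acyclic relations, category/kind
#' agreement) are checked by [validate_ontology()], which reports violations
#' as data rather than failing.
#'
#' @param terms A data frame with columns `id`, `label`, `category`. Ids are
#'   OBO-style CURIEs (e.g. `CPH:0001`); the bundled fixtures use the
#'   reserved prefixes `CPH` (cell parts) and `CMM` (cell mechanisms), but
#'   any prefix (e.g. real CL/GO ids) is passed through unchanged.
#' @param edges A data frame with columns `subject`, `relation`, `object`;
#'   `relation` must be `"is_a"` or `"has_part"`. May have zero rows.
#' @param kind `"phenotype"` (continuants: cells and their parts) or
#'   `"mechanism"` (occurrents: interactions and events). If `NULL`, the
#'   kind is inferred from the term categories.
#' @return A `ceq_ontology` object: a list with elements `kind`, `terms`
#'   and `edges` (both tibbles).
#' @seealso [validate_ontology()], [positive_scope()], [read_obo()]
#' @examples
#' onto <- ceq_ontology(
#'   terms = tibble::tibble(
#'     id = c("CPH:1", "CPH:2"),
#'     label = c("Tight junction", "Occludin"),
#'     category = c("ultrastructure", "molecule")
#'   ),
#'   edges = tibble::tibble(
#'     subject = "CPH:1", relation = "has_part", object = "CPH:2"
#'   )
#' )
#' positive_scope(onto, "CPH:1")
#' @export
ceq_ontology <- function(terms, edges = NULL, kind = NULL) {
  terms <- as_tibble(terms)
  need <- c("id", "label", "category")
  if (!all(need %in% names(terms))) {
    abort(paste0("`terms` needs columns: ", paste(need, collapse = ", ")))
  }
  terms <- terms |>
    select(all_of(need)) |>
    mutate(across(all_of(need), as.character))
  if (is.null(edges) || nrow(as_tibble(edges)) == 0) {
    edges <- tibble(subject = character(), relation = character(),
                    object = character())
  }
  edges <- as_tibble(edges)
  eneed <- c("subject", "relation", "object")
  if (!all(eneed %in% names(edges))) {
    abort(paste0("`edges` needs columns: ", paste(eneed, collapse = ", ")))
  }
  edges <- edges |>
    select(all_of(eneed)) |>
    mutate(across(all_of(eneed), as.character))
  if (is.null(kind)) kind <- infer_kind(terms$category)
  kind <- match.arg(kind, c("phenotype", "mechanism"))
  structure(list(kind = kind, terms = terms, edges = edges),
            class = "ceq_ontology")
}

infer_kind <- function(categories) {
  if (any(categories %in% ceq_categories$mechanism)) "mechanism" else "phenotype"
}

#' @export
print.ceq_ontology <- function(x, ...) {
  cat(sprintf("<ceq_ontology> kind: %s | %d terms, %d edges (%d is_a, %d has_part)\n",
              x$kind, nrow(x$terms), nrow(x$edges),
              sum(x$edges$relation == "is_a"),
              sum(x$edges$relation == "has_part")))
  invisible(x)
}

violation <- function(rule, item, message) {
  tibble(rule = rule, item = item, message = message)
}

empty_report <- function() {
  tibble(rule = character(), item = character(), message = character())
}

#' Validate an ontology against its structural invariants
#'
#' Checks every invariant of the ontology model and returns the violations
#' as a tibble (one row per violation); an empty tibble means the ontology
#' is valid. Violations are data, not errors, so curation pipelines can
#' inspect all problems at once.
#'
#' Checked invariants: unique non-empty term ids; non-empty labels;
#' categories drawn from the vocabulary of the ontology's kind
#' (see [ceq_categories]); edge relations restricted to `is_a`/`has_part`;
#' no self-edges; edge endpoints resolving to terms; and acyclicity of each
#' relation's subgraph taken on its own.
#'
#' @param ontology A [ceq_ontology()].
#' @return A tibble with columns `rule`, `item`, `message`; zero rows iff
#'   the ontology is valid.
#' @export
validate_ontology <- function(ontology) {
  stopifnot(inherits(ontology, "ceq_ontology"))
  terms <- ontology$terms
  edges <- ontology$edges
  out <- list(empty_report())

  dup <- terms$id[duplicated(terms$id)]
  if (length(dup) > 0) {
    out <- c(out, list(violation("duplicate_id", unique(dup),
                                 "term id occurs more than once")))
  }
  bad_lab <- terms$id[is.na(terms$label) | terms$label == ""]
  if (length(bad_lab) > 0) {
    out <- c(out, list(violation("empty_label", bad_lab, "term label is empty")))
  }
  allowed <- ceq_categories[[ontology$kind]]
  bad_cat <- terms$id[!terms$category %in% allowed]
  if (length(bad_cat) > 0) {
    out <- c(out, list(violation(
      "category_kind_mismatch", bad_cat,
      sprintf("category not admissible in a %s ontology", ontology$kind))))
  }
  bad_rel <- which(!edges$relation %in% ceq_relations)
  if (length(bad_rel) > 0) {
    out <- c(out, list(violation(
      "unknown_relation", edge_id(edges[bad_rel, ]),
      "relation must be is_a or has_part")))
  }
  self_e <- which(edges$subject == edges$object)
  if (length(self_e) > 0) {
    out <- c(out, list(violation("self_edge", edge_id(edges[self_e, ]),
                                 "edge subject equals object")))
  }
  known <- terms$id
  dangling <- which(!(edges$subject %in% known) | !(edges$object %in% known))
  if (length(dangling) > 0) {
    out <- c(out, list(violation("dangling_endpoint", edge_id(edges[dangling, ]),
                                 "edge endpoint is not a term of this ontology")))
  }
  # Cycle checks per relation, only on well-formed edges between known terms.
  ok <- edges |>
    filter(.data$relation %in% ceq_relations,
           .data$subject %in% known, .data$object %in% known,
           .data$subject != .data$object)
  for (rel in ceq_relations) {
    sub <- ok |> filter(.data$relation == rel)
    cyc <- cycle_members(sub, known)
    if (length(cyc) > 0) {
      out <- c(out, list(violation(
        paste0("cycle_", rel), paste(sort(cyc), collapse = ","),
        sprintf("terms participate in a %s cycle", rel))))
    }
  }
  bind_rows(out)
}

edge_id <- function(edges) {
  paste(edges$subject, edges$relation, edges$object)
}

# Vertices lying on a directed cycle of the given edge set (empty if a DAG).
cycle_members <- function(edges, vertices) {
  if (nrow(edges) == 0) return(character())
  g <- igraph::graph_from_data_frame(
    edges[, c("subject", "object")], directed = TRUE,
    vertices = data.frame(name = unique(vertices)))
  if (igraph::is_dag(g)) return(character())
  # A vertex is on a cycle iff it reaches itself through >= 1 edge.
  comp <- igraph::components(g, mode = "strong")
  names(comp$membership)[comp$membership %in% which(comp$csize > 1)]
}

assert_valid_ontology <- function(ontology) {
  rep <- validate_ontology(ontology)
  if (nrow(rep) > 0) {
    abort(c("ontology is not valid",
            stats::setNames(paste(rep$rule, rep$item, sep = ": "),
                            rep("x", nrow(rep)))))
  }
  invisible(ontology)
}

assert_known_term <- function(ontology, term) {
  if (length(term) != 1 || is.na(term) || !term %in% ontology$terms$id) {
    abort(sprintf("unknown term id: %s", paste(term, collapse = ", ")))
  }
  invisible(term)
}

onto_graph <- function(ontology) {
  igraph::graph_from_data_frame(
    ontology$edges[, c("subject", "object")], directed = TRUE,
    vertices = data.frame(name = ontology$terms$id))
}

scope_one <- function(ontology, term, mode) {
  assert_known_term(ontology, term)
  g <- onto_graph(ontology)
  sort(names(igraph::subcomponent(g, term, mode = mode)))
}

#' Positive propagation scope of a term
#'
#' The set of terms that a positive annotation (e.g. `present`, `up`) of
#' `term` logically covers: the transitive closure following `is_a` from
#' subclass to superclass and `has_part` from whole to necessary part,
#' including `term` itself. Under all-some `has_part` semantics an
#' instance of a whole guarantees instances of all its necessary parts, so
#' positive information flows from wholes down to parts — the reverse of
#' the familiar anatomical `part_of` propagation.
#'
#' @param ontology A valid [ceq_ontology()].
#' @param term A single term id present in the ontology.
#' @return Sorted character vector of term ids (always contains `term`).
#' @seealso [negative_scope()] for the dual closure.
#' @export
positive_scope <- function(ontology, term) {
  scope_one(ontology, term, mode = "out")
}

#' Negative propagation scope of a term
#'
#' The set of terms that an `absent` annotation of `term` logically covers:
#' the transitive closure over the reversed edges (`is_a` followed
#' superclass to subclass, `has_part` followed part to whole), including
#' `term` itself. This is the contrapositive of the all-some reading: if a
#' necessary part is absent, every whole that requires it is absent too.
#'
#' The two scopes are dual: `t %in% negative_scope(o, s)` exactly when
#' `s %in% positive_scope(o, t)`.
#'
#' @inheritParams positive_scope
#' @return Sorted character vector of term ids (always contains `term`).
#' @export
negative_scope <- function(ontology, term) {
  scope_one(ontology, term, mode = "in")
}

# Closure sets for all terms at once, as a named list. mode "out" gives
# positive scopes, "in" negative scopes.
scope_table <- function(ontology, mode = c("out", "in")) {
  mode <- match.arg(mode)
  g <- onto_graph(ontology)
  res <- igraph::ego(g, order = igraph::vcount(g), mode = mode)
  stats::setNames(lapply(res, function(v) sort(names(v))),
                  ontology$terms$id)
}
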