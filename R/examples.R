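# Deterministic example ontologies and profiles (MET/EMT domain) plus
# seeded random generators.
#
# The example content encodes the epithelial/mesenchymal worked example:
# tight-junction anatomy on the continuant side, the corresponding
# mechanism networks and interactions on the occurrent side. Structural
# assertions (the TJ has_part Occludin/JAM/Claudin block, the epithelial
# network containing TJ-network, AJ formation and the Occludin-JAM
# interaction, mitosis having S-phase as a temporal part) are the domain
# backbone; the adherens-junction molecules, the mesenchymal branch and
# all numeric ids are invented glue needed to make the examples runnable.

#' Example ontology of cell parts
#'
#' A small continuant ontology around the epithelial/mesenchymal contrast:
#' three cell types, the cell membrane, the cell-junction ultrastructures
#' (tight and adherens junctions) and their necessary molecular parts.
#' All-some `has_part` edges run from wholes to necessary parts: every
#' tight junction has some Occludin, JAM and Claudin; every epithelial
#' cell has some tight junction and membrane.
#'
#' @return A valid [ceq_ontology()] of kind `"phenotype"` with ids in the
#'   reserved `CPH` test prefix.
#' @export
example_cell_ontology <- function() {
  terms <- tibble(
    id = sprintf("CPH:%04d", 1:13),
    label = c("Epithelial cell", "Mesenchymal cell", "Embryonic stem cell",
              "Cell membrane", "Cell junction", "Tight junction",
              "Adherens junction", "Occludin",
              "Junctional adhesion molecule", "Claudin",
              "E-cadherin", "N-cadherin", "beta-catenin"),
    category = c("cell", "cell", "cell", "structure",
                 "ultrastructure", "ultrastructure", "ultrastructure",
                 "molecule", "molecule", "molecule",
                 "molecule", "molecule", "molecule")
  )
  edge <- function(s, r, o) tibble(subject = s, relation = r, object = o)
  edges <- bind_rows(
    edge("CPH:0006", "is_a", "CPH:0005"),        # TJ is_a cell junction
    edge("CPH:0007", "is_a", "CPH:0005"),        # AJ is_a cell junction
    edge("CPH:0006", "has_part", "CPH:0008"),    # TJ has_part Occludin
    edge("CPH:0006", "has_part", "CPH:0009"),    # TJ has_part JAM
    edge("CPH:0006", "has_part", "CPH:0010"),    # TJ has_part Claudin
    edge("CPH:0001", "has_part", "CPH:0006"),    # epithelial has_part TJ
    edge("CPH:0001", "has_part", "CPH:0004"),    # epithelial has_part membrane
    # glue below: AJ composition and the mesenchymal branch
    edge("CPH:0001", "has_part", "CPH:0007"),
    edge("CPH:0007", "has_part", "CPH:0011"),
    edge("CPH:0007", "has_part", "CPH:0013"),
    edge("CPH:0002", "has_part", "CPH:0004"),
    edge("CPH:0002", "has_part", "CPH:0012")
  )
  ceq_ontology(terms, edges, kind = "phenotype")
}

#' Example ontology of cell mechanisms
#'
#' The occurrent counterpart of [example_cell_ontology()]: mechanism
#' networks for the epithelial cell, the mesenchymal cell and the tight
#' junction, ultrastructural events (junction formation, mitosis with
#' S-phase as a necessary temporal part) and molecular interactions.
#' The epithelial network has the TJ network and adherens-junction
#' formation among its parts; the TJ network has the Occludin-JAM
#' interaction as a part, so positive annotations of the whole network
#' propagate all the way down to that interaction.
#'
#' @return A valid [ceq_ontology()] of kind `"mechanism"` with ids in the
#'   reserved `CMM` test prefix.
#' @export
example_mechanism_ontology <- function() {
  terms <- tibble(
    id = sprintf("CMM:%04d", 1:12),
    label = c("Network of mechanisms relevant for epithelial cell",
              "Network of mechanisms relevant for mesenchymal cell",
              "Network of mechanisms relevant for tight junction",
              "Tight junction formation",
              "Adherens junction formation",
              "Interaction Occludin-JAM",
              "Mitosis",
              "S-phase",
              "Interaction Occludin-Claudin",
              "Interaction E-cadherin-beta-catenin",
              "Interaction N-cadherin-beta-catenin",
              "Stress fiber assembly"),
    category = c("mechanism-network", "mechanism-network", "mechanism-network",
                 "ultrastructural-event", "ultrastructural-event",
                 "molecular-interaction",
                 "ultrastructural-event", "ultrastructural-event",
                 "molecular-interaction", "molecular-interaction",
                 "molecular-interaction", "ultrastructural-event")
  )
  edge <- function(s, o) tibble(subject = s, relation = "has_part", object = o)
  edges <- bind_rows(
    edge("CMM:0001", "CMM:0003"),   # epithelial network has_part TJ network
    edge("CMM:0001", "CMM:0005"),   # epithelial network has_part AJ formation
    edge("CMM:0003", "CMM:0006"),   # TJ network has_part Occludin-JAM
    edge("CMM:0007", "CMM:0008"),   # mitosis has_part S-phase (temporal part)
    # glue below: further interactions and the mesenchymal branch
    edge("CMM:0003", "CMM:0009"),
    edge("CMM:0004", "CMM:0006"),
    edge("CMM:0005", "CMM:0010"),
    edge("CMM:0002", "CMM:0011"),
    edge("CMM:0002", "CMM:0012")
  )
  ceq_ontology(terms, edges, kind = "mechanism")
}

#' Example mechanism map
#'
#' The explicit cross-ontology link used by the transition examples:
#' marker rules tie the appearance of a cell type or junction to the
#' start-up of its mechanism network or formation event; participant
#' rules tie molecular interactions to their molecular participants.
#'
#' @return A valid [mechanism_map()] for the two example ontologies.
#' @export
example_mechanism_map <- function() {
  mechanism_map(
    rule_type = c("marker", "marker", "marker", "marker",
                  "participant", "participant", "participant"),
    mechanism_id = c("CMM:0001", "CMM:0002", "CMM:0003", "CMM:0005",
                     "CMM:0006", "CMM:0009", "CMM:0011"),
    phenotype_ids = list(
      "CPH:0001",                    # epithelial cell -> epithelial network
      "CPH:0002",                    # mesenchymal cell -> mesenchymal network
      "CPH:0006",                    # tight junction -> TJ network
      "CPH:0007",                    # adherens junction -> AJ formation
      c("CPH:0008", "CPH:0009"),     # Occludin + JAM -> their interaction
      c("CPH:0008", "CPH:0010"),     # Occludin + Claudin
      c("CPH:0012", "CPH:0013")      # N-cadherin + beta-catenin
    )
  )
}

#' Example epithelial phenotype profile
#'
#' The classic epithelial annotation profile: Occludin, JAM, Claudin and
#' tight junctions `present`, cell membranes `joined`.
#'
#' @param profile_id Profile id to use.
#' @return A corpus tibble with one phenotype profile.
#' @export
example_epithelial_profile <- function(profile_id = "epithelial") {
  bind_rows(
    annotation_profile(profile_id, "phenotype",
                       c("CPH:0008", "CPH:0009", "CPH:0010", "CPH:0006"),
                       "present"),
    annotation_profile(profile_id, "phenotype", "CPH:0004", "joined")
  )
}

#' Example mesenchymal-to-epithelial snapshot pair
#'
#' Two phenotype profiles encoding the MET endpoints at cell-type level:
#' the earlier snapshot is mesenchymal (epithelial cell absent), the later
#' epithelial (mesenchymal cell absent). Under the marker rules of
#' [example_mechanism_map()] their differential yields the canonical MET
#' coding: epithelial network up, mesenchymal network down.
#'
#' @return A corpus tibble with profiles `"mesenchymal"` and
#'   `"epithelial"`.
#' @export
example_met_pair <- function() {
  bind_rows(
    annotation_profile("mesenchymal", "phenotype",
                       c("CPH:0001", "CPH:0002"), c("absent", "present"),
                       timestamp_h = 0),
    annotation_profile("epithelial", "phenotype",
                       c("CPH:0001", "CPH:0002"), c("present", "absent"),
                       timestamp_h = 24)
  )
}

#' Example time-stamped phenotype series
#'
#' Three snapshots of one cell undergoing an MET-like transition: `A`
#' before the intervention (timestamp unset), `B` after 1 hour (adherens
#' junctions and their molecules have appeared) and `C` after 2 hours
#' (tight junctions and the epithelial phenotype established, the
#' mesenchymal markers gone). Consecutive snapshots each trigger at least
#' one marker and one participant rule of [example_mechanism_map()].
#'
#' @return A corpus tibble with phenotype profiles `A`, `B`, `C` at
#'   timestamps unset, 1 and 2 hours.
#' @export
example_timecourse <- function() {
  p <- function(id, ts, entities, qualities) {
    annotation_profile(id, "phenotype", entities, qualities, timestamp_h = ts)
  }
  bind_rows(
    p("A", NA, c("CPH:0002", "CPH:0012", "CPH:0013", "CPH:0004",
                 "CPH:0009", "CPH:0010",
                 "CPH:0008", "CPH:0007", "CPH:0011", "CPH:0006", "CPH:0001"),
      c(rep("present", 6), rep("absent", 5))),
    p("B", 1, c("CPH:0002", "CPH:0012", "CPH:0013", "CPH:0004",
                "CPH:0009", "CPH:0010", "CPH:0008", "CPH:0007", "CPH:0011",
                "CPH:0006", "CPH:0001"),
      c(rep("present", 9), rep("absent", 2))),
    p("C", 2, c("CPH:0001", "CPH:0006", "CPH:0008", "CPH:0009", "CPH:0010",
                "CPH:0007", "CPH:0011", "CPH:0013",
                "CPH:0002", "CPH:0012", "CPH:0004"),
      c(rep("present", 8), rep("absent", 2), "joined"))
  )
}

#' Example mechanism-change corpus at mixed granularities
#'
#' Three MET annotation profiles asserted at different levels of the
#' mechanism ontology — whole epithelial network, junction-formation
#' events, single molecular interaction — plus one unrelated control
#' profile (mesenchymal network down). Before propagation the three MET
#' profiles share almost nothing; after propagation all three carry the
#' Occludin-JAM interaction up, which is what makes cross-granularity
#' similarity search work.
#'
#' @return A corpus tibble with mechanism-change profiles `met_network`,
#'   `met_event`, `met_interaction` and `control_mesenchymal`.
#' @export
example_met_corpus <- function() {
  bind_rows(
    annotation_profile("met_network", "mechanism-change", "CMM:0001", "up"),
    annotation_profile("met_event", "mechanism-change",
                       c("CMM:0003", "CMM:0005"), "up"),
    annotation_profile("met_interaction", "mechanism-change", "CMM:0006", "up"),
    annotation_profile("control_mesenchymal", "mechanism-change",
                       "CMM:0002", "down")
  )
}

#' Prototype mechanism-change profiles with planted cluster structure
#'
#' Three well-separated prototypes over [example_mechanism_ontology()]
#' used as cluster centres by [simulate_corpus()]: an MET-like profile
#' (epithelial network and AJ formation up, mesenchymal network down), an
#' EMT-like profile (the reverse, with stress-fibre assembly up) and a
#' cell-cycle profile (mitosis and S-phase up).
#'
#' @return A corpus tibble with mechanism-change profiles `proto_met`,
#'   `proto_emt`, `proto_cycle`.
#' @export
example_met_prototypes <- function() {
  bind_rows(
    annotation_profile("proto_met", "mechanism-change",
                       c("CMM:0001", "CMM:0005", "CMM:0002"),
                       c("up", "up", "down")),
    annotation_profile("proto_emt", "mechanism-change",
                       c("CMM:0002", "CMM:0012", "CMM:0001"),
                       c("up", "up", "down")),
    annotation_profile("proto_cycle", "mechanism-change",
                       c("CMM:0007", "CMM:0008"), c("up", "up"))
  )
}

#' Random ontology generator
#'
#' Seeded random DAG ontologies for property testing: terms get categories
#' drawn from the kind's vocabulary; candidate edges respect a fixed
#' topological order, so each relation's subgraph is acyclic by
#' construction; relations are sampled between `is_a` and `has_part`.
#'
#' @param n_terms Number of terms.
#' @param seed Integer seed; the same seed reproduces the ontology.
#' @param kind `"phenotype"` or `"mechanism"`.
#' @param p_edge Probability of each forward candidate edge.
#' @return A valid [ceq_ontology()] with ids in a `RND` prefix.
#' @export
simulate_ontology <- function(n_terms, seed, kind = c("mechanism", "phenotype"),
                              p_edge = 0.08) {
  kind <- match.arg(kind)
  stopifnot(n_terms >= 1)
  with_seed(seed, {
    cats <- ceq_categories[[kind]]
    terms <- tibble(
      id = sprintf("RND:%04d", seq_len(n_terms)),
      label = sprintf("random term %d", seq_len(n_terms)),
      category = sample(cats, n_terms, replace = TRUE))
    pairs <- which(upper.tri(matrix(TRUE, n_terms, n_terms)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p_edge
    pairs <- pairs[keep, , drop = FALSE]
    edges <- tibble(
      subject = terms$id[pairs[, "row"]],
      relation = sample(ceq_relations, nrow(pairs), replace = TRUE),
      object = terms$id[pairs[, "col"]])
    ceq_ontology(terms, edges, kind = kind)
  })
}

#' Random annotation-profile generator
#'
#' Seeded random corpora for property testing and round-trip checks.
#' Entities are sampled without replacement within a profile, so no
#' polarity conflicts can arise; qualities are drawn from the core
#' vocabulary matching `kind` (restricted to positive ones when
#' `positive_only`).
#'
#' @param ontology A valid [ceq_ontology()].
#' @param n_profiles Number of profiles.
#' @param n_annotations Annotations per profile (capped at the term count).
#' @param kind Profile kind; default matches the ontology kind.
#' @param seed Integer seed.
#' @param positive_only Draw only positive-polarity qualities.
#' @param qualities Quality vocabulary.
#' @return A corpus tibble with profiles `r01`, `r02`, ...
#' @export
simulate_profiles <- function(ontology, n_profiles, n_annotations, seed,
                              kind = NULL, positive_only = FALSE,
                              qualities = default_qualities()) {
  if (is.null(kind)) {
    kind <- if (ontology$kind == "mechanism") "mechanism-change" else "phenotype"
  }
  wanted_class <- if (kind == "phenotype") "state" else "change"
  pool <- qualities |>
    filter(.data$class == wanted_class, .data$core,
           !positive_only | .data$polarity == "positive")
  n_annotations <- min(n_annotations, nrow(ontology$terms))
  with_seed(seed, {
    out <- lapply(seq_len(n_profiles), function(i) {
      ents <- sample(ontology$terms$id, n_annotations)
      annotation_profile(sprintf("r%02d", i), kind, ents,
                         sample(pool$quality, n_annotations, replace = TRUE))
    })
    bind_rows(out)
  })
}

#' Simulate a corpus with planted clusters
#'
#' Builds `profiles_per_cluster` noisy copies of each prototype profile:
#' each prototype annotation is dropped with probability `dropout`; each
#' surviving annotation is, with probability `granularity_shift`, moved to
#' a uniformly chosen member of its entity's [positive_scope()] (keeping
#' its quality) — emulating curation of the same biology at a coarser or
#' finer level; finally, with probability `dropout`, one spurious
#' annotation is added on a uniformly chosen not-yet-annotated term, with
#' a quality drawn from the prototype's own qualities so its polarity
#' profile is preserved. A shift whose target entity is already annotated
#' is skipped (the original annotation is kept), so shifts never change
#' the annotation count and no profile can become self-contradictory; the
#' expected number of asserted annotations per profile is therefore
#' exactly `m * (1 - dropout) + dropout` for a prototype of size `m`.
#' Fully reproducible from `seed`.
#'
#' @param prototypes Corpus tibble of prototype profiles (one per
#'   cluster), e.g. [example_met_prototypes()].
#' @param ontology A valid [ceq_ontology()].
#' @param profiles_per_cluster Copies per prototype.
#' @param dropout Per-annotation dropout rate in [0, 1).
#' @param granularity_shift Per-annotation shift rate in [0, 1).
#' @param seed Integer seed.
#' @param qualities Quality vocabulary.
#' @return A list with `profiles` (corpus tibble; ids
#'   `<prototype>_01` ...) and `labels` (tibble `profile_id`, `cluster`
#'   with the planted cluster index).
#' @export
simulate_corpus <- function(prototypes, ontology, profiles_per_cluster = 10,
                            dropout = 0.1, granularity_shift = 0.3, seed = 42,
                            qualities = default_qualities()) {
  stopifnot(dropout >= 0, dropout < 1,
            granularity_shift >= 0, granularity_shift < 1)
  prototypes <- check_profile_frame(prototypes)
  assert_valid_profiles(prototypes, ontology, qualities,
                        context = "prototype profiles")
  protos <- split_profiles(prototypes)
  scopes <- scope_table(ontology, "out")
  pol <- stats::setNames(qualities$polarity, qualities$quality)
  all_terms <- ontology$terms$id

  with_seed(seed, {
    rows <- list()
    labels <- list()
    for (ci in seq_along(protos)) {
      proto <- protos[[ci]]
      for (j in seq_len(profiles_per_cluster)) {
        pid <- sprintf("%s_%02d", names(protos)[[ci]], j)
        keep <- stats::runif(nrow(proto)) >= dropout
        ann <- proto[keep, c("entity_id", "quality")]
        if (nrow(ann) > 0) {
          for (r in seq_len(nrow(ann))) {
            if (stats::runif(1) < granularity_shift) {
              target <- sample(scopes[[ann$entity_id[[r]]]], 1)
              # count-preserving: a shift onto an already annotated entity
              # (either polarity) is skipped
              if (!target %in% ann$entity_id[-r]) {
                ann$entity_id[[r]] <- target
              }
            }
          }
        }
        if (stats::runif(1) < dropout) {
          free <- setdiff(all_terms, ann$entity_id)
          if (length(free) > 0) {
            ann <- bind_rows(ann,
                             tibble(entity_id = sample(free, 1),
                                    quality = sample(proto$quality, 1)))
          }
        }
        ann <- distinct(ann)
        if (nrow(ann) > 0) {
          rows[[length(rows) + 1]] <- annotation_profile(
            pid, proto$kind[[1]], ann$entity_id, ann$quality)
        } else {
          rows[[length(rows) + 1]] <- annotation_profile(
            pid, proto$kind[[1]], character(), character())
        }
        labels[[length(labels) + 1]] <- tibble(profile_id = pid, cluster = ci)
      }
    }
    list(profiles = bind_rows(rows), labels = bind_rows(labels))
  })
}
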