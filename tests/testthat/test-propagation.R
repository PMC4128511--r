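test_that("positive annotations propagate whole to part, absent part to whole", {
  om <- example_mechanism_ontology()
  up <- propagate_annotation("CMM:0001", "up", om)
  expect_true(all(c("CMM:0003", "CMM:0005", "CMM:0006") %in% up$entity_id))
  expect_true(all(up$quality == "up"))

  op <- example_cell_ontology()
  ab <- propagate_annotation("CPH:0008", "absent", op)
  expect_contains(ab$entity_id, c("CPH:0008", "CPH:0006", "CPH:0001"))
  expect_true(all(ab$quality == "absent"))

  # isolated term: propagation is the identity
  solo <- propagate_annotation("CPH:0003", "present", op)
  expect_identical(solo$entity_id, "CPH:0003")
})

test_that("'down' stays put in sound mode and flows whole to part heuristically", {
  om <- example_mechanism_ontology()
  sound <- propagate_annotation("CMM:0001", "down", om, mode = "sound")
  expect_identical(sound$entity_id, "CMM:0001")
  heur <- propagate_annotation("CMM:0001", "down", om, mode = "heuristic")
  expect_contains(heur$entity_id, c("CMM:0003", "CMM:0006"))
  expect_true(all(heur$quality == "down"))
})

test_that("profile propagation is a superset, idempotent, and preserves metadata", {
  om <- example_mechanism_ontology()
  p <- annotation_profile("met", "mechanism-change", "CMM:0001", "up",
                          timestamp_h = 3)
  prop <- propagate_profiles(p, om)
  expect_contains(prop$entity_id, c("CMM:0003", "CMM:0005", "CMM:0006"))
  expect_identical(unique(prop$timestamp_h), 3)
  expect_identical(unique(prop$kind), "mechanism-change")
  expect_true(all(prop$asserted[prop$entity_id == "CMM:0001"]))
  expect_false(any(prop$asserted[prop$entity_id != "CMM:0001"]))

  again <- propagate_profiles(prop, om)
  expect_equal(
    dplyr::arrange(again, entity_id),
    dplyr::arrange(prop, entity_id),
    ignore_attr = TRUE)

  for (seed in 1:5) {
    corpus <- simulate_profiles(om, 3, 4, seed = seed)
    p1 <- propagate_profiles(corpus, om)
    expect_equal(propagate_profiles(p1, om) |>
                   dplyr::arrange(profile_id, entity_id, quality),
                 p1 |> dplyr::arrange(profile_id, entity_id, quality),
                 ignore_attr = TRUE)
    # supersetness of the asserted annotations
    expect_identical(nrow(dplyr::anti_join(dplyr::distinct(corpus), p1,
                                           by = c("profile_id", "entity_id", "quality"))),
                     0L)
  }
})

test_that("sound propagation lands positives on positive scopes only", {
  onto <- simulate_ontology(30, seed = 7)
  corpus <- simulate_profiles(onto, 4, 5, seed = 11)
  prop <- propagate_profiles(corpus, onto)
  pos <- ceq:::scope_table(onto, "out")
  neg <- ceq:::scope_table(onto, "in")
  pol <- stats::setNames(default_qualities()$polarity,
                         default_qualities()$quality)
  asserted <- dplyr::filter(prop, asserted)
  inferred <- dplyr::filter(prop, !asserted)
  for (r in seq_len(nrow(inferred))) {
    row <- inferred[r, ]
    src <- dplyr::filter(asserted, profile_id == row$profile_id,
                         quality == row$quality)
    if (pol[[row$quality]] == "positive") {
      expect_true(any(purrr::map_lgl(src$entity_id,
                                     ~ row$entity_id %in% pos[[.x]])))
    } else {
      expect_true(any(purrr::map_lgl(src$entity_id,
                                     ~ row$entity_id %in% neg[[.x]])))
    }
  }
})

test_that("asserted annotations win propagation conflicts and are reported", {
  op <- example_cell_ontology()
  # TJ present (would infer Occludin present) but Occludin asserted absent:
  # the inferred positive on Occludin must yield to the asserted negative,
  # and the contrapositive absent on TJ must yield to the asserted present.
  p <- annotation_profile("odd", "phenotype", c("CPH:0006", "CPH:0008"),
                          c("present", "absent"))
  prop <- propagate_profiles(p, op)
  occ <- dplyr::filter(prop, entity_id == "CPH:0008")
  expect_identical(occ$quality, "absent")
  tj <- dplyr::filter(prop, entity_id == "CPH:0006")
  expect_identical(tj$quality, "present")
  confl <- propagation_conflicts(prop)
  expect_true(nrow(confl) > 0)
  expect_contains(confl$entity_id, "CPH:0008")
})

test_that("propagating a corpus preserves profile ids and count monotonicity", {
  om <- example_mechanism_ontology()
  corpus <- example_met_corpus()
  prop <- propagate_profiles(corpus, om)
  expect_setequal(unique(prop$profile_id), unique(corpus$profile_id))
  # every MET profile, regardless of curation granularity, ends up carrying
  # the Occludin-JAM interaction after propagation
  for (id in c("met_network", "met_event", "met_interaction")) {
    expect_true("CMM:0006" %in% prop$entity_id[prop$profile_id == id &
                                                 prop$quality == "up"])
  }
  # for each has_part(W, P): profiles annotated to P >= profiles annotated to W
  pos <- default_qualities()$quality[default_qualities()$polarity == "positive"]
  positive <- dplyr::filter(prop, quality %in% pos)
  n_annotated <- function(t) {
    dplyr::n_distinct(positive$profile_id[positive$entity_id == t])
  }
  hp <- dplyr::filter(om$edges, relation == "has_part")
  for (r in seq_len(nrow(hp))) {
    expect_gte(n_annotated(hp$object[[r]]), n_annotated(hp$subject[[r]]))
  }
  # empty corpus maps to empty corpus
  empty <- propagate_profiles(corpus[0, ], om)
  expect_identical(nrow(empty), 0L)
})
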