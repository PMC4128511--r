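op <- example_cell_ontology()
om <- example_mechanism_ontology()

test_that("the example mechanism map validates; broken maps are reported", {
  expect_identical(nrow(validate_mechanism_map(example_mechanism_map(),
                                               op, om)), 0L)
  # participant rule with a single molecule
  m1 <- mechanism_map("participant", "CMM:0006", list("CPH:0008"))
  expect_true("participant_arity" %in%
                validate_mechanism_map(m1, op, om)$rule)
  # marker rule targeting a molecular interaction
  m2 <- mechanism_map("marker", "CMM:0006", list("CPH:0006"))
  expect_true("marker_target_category" %in%
                validate_mechanism_map(m2, op, om)$rule)
  # dangling ids on both sides
  m3 <- mechanism_map("marker", "CMM:9999", list("CPH:9999"))
  rep3 <- validate_mechanism_map(m3, op, om)
  expect_setequal(rep3$rule,
                  c("dangling_mechanism_id", "dangling_phenotype_id"))
  expect_error(validate_mechanism_map(example_mechanism_map(), om, op),
               "phenotype ontology")
})

test_that("mechanism map TSV round trips", {
  map <- example_mechanism_map()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mechanism_map(map, path)
  back <- read_mechanism_map(path)
  expect_setequal(back$mechanism_id, map$mechanism_id)
  for (i in seq_len(nrow(map))) {
    j <- which(back$mechanism_id == map$mechanism_id[[i]] &
                 back$rule_type == map$rule_type[[i]])
    expect_setequal(back$phenotype_ids[[j]], map$phenotype_ids[[i]])
  }
})

test_that("the MET pair derives exactly epithelial-up, mesenchymal-down", {
  tr <- derive_transition(example_met_pair(), "mesenchymal", "epithelial",
                          example_mechanism_map(), op, om)
  expect_identical(sort(paste(tr$entity_id, tr$quality)),
                   c("CMM:0001 up", "CMM:0002 down"))
  expect_identical(unique(tr$kind), "mechanism-change")
  expect_equal(attr(tr, "start_h"), 0)
  expect_equal(attr(tr, "end_h"), 24)
})

test_that("identical snapshots derive an empty change profile", {
  pair <- dplyr::bind_rows(
    annotation_profile("a", "phenotype", "CPH:0006", "present", 0),
    annotation_profile("b", "phenotype", "CPH:0006", "present", 1))
  tr <- derive_transition(pair, "a", "b", example_mechanism_map(), op, om)
  expect_identical(nrow(tr), 0L)
})

test_that("participant rules fire on joint presence, verified over all cases", {
  # exhaustive 16-way check for the Occludin-JAM rule: every present/absent
  # assignment to the two molecules in the two snapshots, against a direct
  # re-statement of the rule
  map <- mechanism_map("participant", "CMM:0006",
                       list(c("CPH:0008", "CPH:0009")))
  states <- c("present", "absent")
  for (occ_a in states) for (jam_a in states)
    for (occ_b in states) for (jam_b in states) {
      pair <- dplyr::bind_rows(
        annotation_profile("a", "phenotype", c("CPH:0008", "CPH:0009"),
                           c(occ_a, jam_a), 0),
        annotation_profile("b", "phenotype", c("CPH:0008", "CPH:0009"),
                           c(occ_b, jam_b), 1))
      tr <- derive_transition(pair, "a", "b", map, op, om)
      expect_up <- occ_b == "present" && jam_b == "present" &&
        (occ_a == "absent" || jam_a == "absent")
      expect_down <- occ_a == "present" && jam_a == "present" &&
        (occ_b == "absent" || jam_b == "absent")
      want <- character()
      if (expect_up) want <- "CMM:0006 up"
      if (expect_down) want <- "CMM:0006 down"
      expect_identical(paste(tr$entity_id, tr$quality)[seq_along(want)], want)
      expect_identical(nrow(tr), length(want))
    }
})

test_that("unmentioned entities never fire rules (open world)", {
  pair <- dplyr::bind_rows(
    annotation_profile("a", "phenotype", "CPH:0009", "present", 0),
    annotation_profile("b", "phenotype", c("CPH:0008", "CPH:0009"),
                       "present", 1))
  # Occludin unknown in a (not absent): the participant rule must not fire
  map <- mechanism_map("participant", "CMM:0006",
                       list(c("CPH:0008", "CPH:0009")))
  tr <- derive_transition(pair, "a", "b", map, op, om)
  expect_identical(nrow(tr), 0L)
})

test_that("swapping the snapshots swaps up and down", {
  pair <- example_met_pair()
  fwd <- derive_transition(pair, "mesenchymal", "epithelial",
                           example_mechanism_map(), op, om)
  swapped <- pair
  swapped$timestamp_h <- ifelse(swapped$profile_id == "mesenchymal", 24, 0)
  rev <- derive_transition(swapped, "epithelial", "mesenchymal",
                           example_mechanism_map(), op, om)
  flip <- c(up = "down", down = "up")
  expect_identical(sort(paste(fwd$entity_id, unname(flip[fwd$quality]))),
                   sort(paste(rev$entity_id, rev$quality)))
})

test_that("timestamps must increase and kinds must be phenotype", {
  pair <- example_met_pair()
  expect_error(derive_transition(pair, "epithelial", "mesenchymal",
                                 example_mechanism_map(), op, om),
               "increase")
  mech <- annotation_profile("m", "mechanism-change", "CMM:0001", "up")
  both <- dplyr::bind_rows(pair, mech)
  expect_error(derive_transition(both, "mesenchymal", "m",
                                 example_mechanism_map(), op, om),
               "phenotype")
})

test_that("a time series yields n-1 transitions with inherited timestamps", {
  tr <- series_transitions(example_timecourse(), example_mechanism_map(),
                           op, om)
  ids <- unique(tr$profile_id)
  expect_identical(ids, c("A_to_B", "B_to_C"))
  ab <- dplyr::filter(tr, profile_id == "A_to_B")
  bc <- dplyr::filter(tr, profile_id == "B_to_C")
  expect_true(all(is.na(ab$start_h)))
  expect_identical(unique(ab$end_h), 1)
  expect_identical(unique(bc$start_h), 1)
  expect_identical(unique(bc$end_h), 2)
  # each leg triggers at least one marker and one participant rule
  expect_true("CMM:0005" %in% ab$entity_id)   # AJ formation marker
  expect_true("CMM:0006" %in% ab$entity_id)   # Occludin-JAM participants
  expect_true(all(c("CMM:0001", "CMM:0003") %in% bc$entity_id))
  expect_true("CMM:0011" %in% bc$entity_id)   # participant rule, down
  expect_identical(bc$quality[bc$entity_id == "CMM:0002"], "down")

  expect_error(series_transitions(example_met_pair()[1:2, ],
                                  example_mechanism_map(), op, om),
               "at least two")
})
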