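# The worked IC example used below: a four-profile mechanism corpus with
# two profiles asserting the epithelial network up, one the Occludin-JAM
# interaction up and one the mesenchymal network down. After sound
# propagation the interaction is carried by three of the four profiles
# (IC = -log2(3/4) ~ 0.415 bits) while the whole network is carried by two
# (IC = 1 bit): wholes are rarer, hence more informative, than their
# necessary parts.
ic_example_corpus <- function() {
  dplyr::bind_rows(
    annotation_profile("e1", "mechanism-change", "CMM:0001", "up"),
    annotation_profile("e2", "mechanism-change", "CMM:0001", "up"),
    annotation_profile("i1", "mechanism-change", "CMM:0006", "up"),
    annotation_profile("m1", "mechanism-change", "CMM:0002", "down"))
}

test_that("information content matches the hand-counted propagated corpus", {
  om <- example_mechanism_ontology()
  ic <- information_content(ic_example_corpus(), om)
  icv <- stats::setNames(ic$ic_bits, ic$term_id)
  cnt <- stats::setNames(ic$count, ic$term_id)
  expect_identical(cnt[["CMM:0001"]], 2L)
  expect_identical(cnt[["CMM:0006"]], 3L)
  expect_equal(icv[["CMM:0001"]], 1)
  expect_equal(icv[["CMM:0006"]], -log2(3 / 4))
  # never-annotated terms and negative-only ones get the finite maximum
  expect_equal(icv[["CMM:0002"]], 2)
  expect_equal(icv[["CMM:0007"]], -log2(1 / 4))
  expect_true(all(ic$ic_bits >= 0 & ic$ic_bits <= 2))
  expect_error(information_content(ic_example_corpus()[0, ], om), "empty")
})

test_that("a corpus annotating one isolated term everywhere gives it zero IC", {
  om <- example_mechanism_ontology()
  corpus <- dplyr::bind_rows(lapply(1:3, function(i) {
    annotation_profile(paste0("p", i), "mechanism-change", "CMM:0008", "up")
  }))
  ic <- information_content(corpus, om)
  expect_equal(ic$ic_bits[ic$term_id == "CMM:0008"], 0)
})

test_that("IC is anti-monotone along positive scopes (wholes beat parts)", {
  # fixture ontology with the worked corpus
  om <- example_mechanism_ontology()
  ic <- information_content(ic_example_corpus(), om)
  icv <- stats::setNames(ic$ic_bits, ic$term_id)
  hp <- dplyr::filter(om$edges, relation == "has_part")
  for (r in seq_len(nrow(hp))) {
    expect_gte(icv[[hp$subject[[r]]]], icv[[hp$object[[r]]]])
  }
  # random all-positive corpora over random DAGs, across the full scope order
  for (seed in 1:5) {
    onto <- simulate_ontology(25, seed = seed)
    corpus <- simulate_profiles(onto, 6, 4, seed = 100 + seed,
                                positive_only = TRUE)
    ic <- information_content(corpus, onto)
    icv <- stats::setNames(ic$ic_bits, ic$term_id)
    pos <- ceq:::scope_table(onto, "out")
    for (t in onto$terms$id) {
      expect_true(all(icv[pos[[t]]] <= icv[[t]] + 1e-12))
    }
  }
})

test_that("term similarity is the max IC over shared propagation targets", {
  om <- example_mechanism_ontology()
  ic <- information_content(ic_example_corpus(), om)
  # self-similarity equals own IC
  expect_equal(term_similarity("CMM:0003", "CMM:0003", ic, om),
               ic$ic_bits[ic$term_id == "CMM:0003"])
  # TJ network vs Occludin-JAM interaction: the interaction itself is the
  # most informative common target
  expect_equal(term_similarity("CMM:0003", "CMM:0006", ic, om), -log2(3 / 4))
  # disjoint components share nothing
  expect_equal(term_similarity("CMM:0007", "CMM:0001", ic, om), 0)
  # symmetric
  expect_equal(term_similarity("CMM:0006", "CMM:0003", ic, om),
               term_similarity("CMM:0003", "CMM:0006", ic, om))
})

test_that("quality compatibility is symmetric with the stipulated defaults", {
  tbl <- default_compatibility()
  expect_identical(quality_compatibility("up", "up", tbl), 1)
  expect_identical(quality_compatibility("up", "down", tbl), 0)
  expect_identical(quality_compatibility("up", "moderately_up", tbl), 0.5)
  expect_identical(quality_compatibility("moderately_up", "up", tbl), 0.5)
  expect_identical(quality_compatibility("present", "absent", tbl), 0)
  expect_identical(quality_compatibility("joined", "joined", tbl), 1)
  expect_error(quality_compatibility("up", "glowing", tbl), "not in")
})

test_that("BMA equals the naive double-loop oracle and is symmetric", {
  om <- example_mechanism_ontology()
  ic <- information_content(ic_example_corpus(), om)
  for (seed in 1:5) {
    corpus <- simulate_profiles(om, 2, 4, seed = 200 + seed)
    p1 <- dplyr::filter(corpus, profile_id == "r01")
    p2 <- dplyr::filter(corpus, profile_id == "r02")
    got <- profile_similarity(p1, p2, ic, om)
    expect_equal(got, oracle_bma(p1, p2, ic, om))
    expect_equal(got, profile_similarity(p2, p1, ic, om))
    expect_gte(got, 0)
  }
})

test_that("BMA self-similarity is the mean IC of the profile's entities", {
  om <- example_mechanism_ontology()
  ic <- information_content(ic_example_corpus(), om)
  icv <- stats::setNames(ic$ic_bits, ic$term_id)
  p <- annotation_profile("x", "mechanism-change",
                          c("CMM:0001", "CMM:0003", "CMM:0006"), "up")
  expect_equal(profile_similarity(p, p, ic, om),
               mean(icv[c("CMM:0001", "CMM:0003", "CMM:0006")]))
  # empty profiles score zero
  expect_identical(profile_similarity(p[0, ], p, ic, om), 0)
})

test_that("simGIC matches set arithmetic, with 1/0 at the extremes", {
  om <- example_mechanism_ontology()
  ic <- information_content(ic_example_corpus(), om)
  p1 <- annotation_profile("a", "mechanism-change",
                           c("CMM:0001", "CMM:0006"), "up")
  p2 <- annotation_profile("b", "mechanism-change",
                           c("CMM:0006", "CMM:0008"), "up")
  expect_equal(profile_similarity(p1, p1, ic, om, method = "simgic"), 1)
  p3 <- annotation_profile("c", "mechanism-change", "CMM:0007", "up")
  expect_equal(profile_similarity(p1, p3, ic, om, method = "simgic"), 0)
  for (seed in 1:5) {
    corpus <- simulate_profiles(om, 2, 4, seed = 300 + seed)
    q1 <- dplyr::filter(corpus, profile_id == "r01")
    q2 <- dplyr::filter(corpus, profile_id == "r02")
    got <- profile_similarity(q1, q2, ic, om, method = "simgic")
    expect_equal(got, oracle_simgic(q1, q2, ic))
    expect_lte(got, 1)
  }
})

test_that("profiles of different kinds refuse to be compared", {
  om <- example_mechanism_ontology()
  ic <- information_content(example_met_corpus(), om)
  p1 <- annotation_profile("a", "mechanism-change", "CMM:0001", "up")
  p2 <- annotation_profile("b", "phenotype", "CMM:0001", "present")
  expect_error(profile_similarity(p1, p2, ic, om), "kinds")
})

test_that("similarity search ranks self first, breaks ties by id, honours k", {
  om <- example_mechanism_ontology()
  corpus <- example_met_corpus()
  query <- dplyr::filter(corpus, profile_id == "met_network")
  res <- similarity_search(query, corpus, om, k = 10)
  expect_identical(res$profile_id[[1]], "met_network")
  expect_identical(nrow(res), 4L)
  expect_true(all(diff(res$score) <= 0))
  expect_identical(res$rank, 1:4)
  expect_identical(nrow(similarity_search(query, corpus, om, k = 0)), 0L)
  expect_identical(nrow(similarity_search(query, corpus, om, k = 2)), 2L)

  # deterministic tie-break by id: two identical members tie, lower id first
  twin <- dplyr::bind_rows(
    annotation_profile("zz_twin", "mechanism-change", "CMM:0006", "up"),
    annotation_profile("aa_twin", "mechanism-change", "CMM:0006", "up"))
  res2 <- similarity_search(
    annotation_profile("q", "mechanism-change", "CMM:0006", "up"),
    twin, om, k = 2)
  expect_identical(res2$profile_id, c("aa_twin", "zz_twin"))
  expect_equal(res2$score[[1]], res2$score[[2]])
})

test_that("cross-granularity MET profiles are retrieved above the control", {
  om <- example_mechanism_ontology()
  corpus <- example_met_corpus()
  query <- dplyr::filter(corpus, profile_id == "met_network")
  res <- similarity_search(query, corpus, om, k = 4)
  ranks <- stats::setNames(res$rank, res$profile_id)
  expect_lt(ranks[["met_event"]], ranks[["control_mesenchymal"]])
  expect_lt(ranks[["met_interaction"]], ranks[["control_mesenchymal"]])
})

test_that("propagation never decreases simGIC for nested-scope profiles", {
  om <- example_mechanism_ontology()
  corpus <- example_met_corpus()
  ic <- information_content(corpus, om)
  prop <- propagate_profiles(corpus, om)
  met <- c("met_network", "met_event", "met_interaction")
  for (i in 1:2) {
    for (j in (i + 1):3) {
      raw <- profile_similarity(
        dplyr::filter(corpus, profile_id == met[[i]]),
        dplyr::filter(corpus, profile_id == met[[j]]),
        ic, om, method = "simgic")
      after <- profile_similarity(
        dplyr::filter(prop, profile_id == met[[i]]),
        dplyr::filter(prop, profile_id == met[[j]]),
        ic, om, method = "simgic")
      expect_gte(after, raw)
    }
  }
})
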