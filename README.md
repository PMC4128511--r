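# ceq — entity–quality annotation profiles for cell phenotypes and cell transitions

Cell biology's knowledge about transitions between cell states —
reprogramming to pluripotency, the epithelial–mesenchymal transition
(EMT) and its reverse (MET), trans-differentiation — mostly sits in
prose, where it cannot be searched, compared or aggregated. `ceq` is an
R toolkit for curators and computational biologists who want that
knowledge in a computable form. It represents

* **cell phenotypes** as entity–quality (EQ) profiles over an ontology
  of cell parts (cells, structures, ultrastructures, molecules), with
  state qualities like `present`/`absent`, and
* **cell-mechanism changes** as EQ profiles over an ontology of cell
  mechanisms (networks, ultrastructural events, molecular
  interactions), with change qualities like `up`/`down`,

both ontologies built from `is_a` plus an all-some `has_part` relation
("every tight junction has some Occludin as part"). On top of the
representation it provides the algorithms that make it useful:

* **annotation propagation** — positive annotations flow from wholes to
  their necessary parts, `absent` flows contrapositively from parts to
  wholes; inferred annotations are made explicit and flagged;
* **information content** — `IC(t) = −log₂(count(t)/N)` over a
  propagated corpus; a whole process always scores at least as high as
  each of its necessary parts;
* **similarity and search** — Resnik-style term similarity over the
  propagation order, combined per profile by symmetric best-match
  averaging (BMA) or simGIC; `similarity_search()` is a BLAST-like
  ranked search in annotation space;
* **transition derivation** — qualitative differential analysis of two
  time-stamped phenotype snapshots under an explicit phenotype→mechanism
  map, turning continuant data into occurrent data, with inherited
  start/end timestamps;
* **clustering** — normalized similarity distances plus average-linkage
  agglomeration, the operational route from fine-grained phenotypes to
  coarse cell types and transition classes;
* **I/O and fixtures** — a deterministic OBO 1.4 subset and profile/map
  TSV formats, worked example ontologies for the MET/EMT domain, and a
  seeded synthetic-corpus generator with planted cluster structure.

Everything is tidyverse-native: corpora are plain tibbles (one
annotation per row), every function takes the data frame first, results
come back as tibbles, and clusterings support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

Mixed-granularity curation is the central headache this framework
solves: one source reports an MET as "the epithelial programme starts
up", another as "tight-junction and adherens-junction formation", a
third as "the Occludin–JAM interaction is upregulated". Those are the
three MET profiles of `example_met_corpus()`, plus an unrelated control
(mesenchymal network down):

```r
library(ceq)
library(dplyr)

om     <- example_mechanism_ontology()
corpus <- example_met_corpus()
om
#> <ceq_ontology> kind: mechanism | 12 terms, 9 edges (0 is_a, 9 has_part)

query <- filter(corpus, profile_id == "met_network")
similarity_search(query, corpus, om, k = 4)
#> # A tibble: 4 × 3
#>    rank profile_id          score
#>   <int> <chr>               <dbl>
#> 1     1 met_network         1.07
#> 2     2 met_event           0.893
#> 3     3 met_interaction     0.311
#> 4     4 control_mesenchymal 0
```

Scores are in bits (best-match-averaged Resnik similarity on propagated
profiles, IC computed from this corpus). The query retrieves itself
first, then both MET profiles curated at other granularities — because
propagation materializes their shared implied annotations, down to the
Occludin–JAM interaction — and the mesenchymal control scores zero:
`up` never matches `down`.

Transitions are derived, not asserted. Three time-stamped snapshots of
one cell (`A` before intervention, `B` at 1 h, `C` at 2 h) plus the
explicit mechanism map yield the two macroscale changes:

```r
op <- example_cell_ontology()
series_transitions(example_timecourse(), example_mechanism_map(), op, om)
#> # A tibble: 7 × 7
#>   profile_id kind             timestamp_h entity_id quality start_h end_h
#>   <chr>      <chr>                  <dbl> <chr>     <chr>     <dbl> <dbl>
#> 1 A_to_B     mechanism-change           1 CMM:0005  up           NA     1
#> 2 A_to_B     mechanism-change           1 CMM:0006  up           NA     1
#> 3 A_to_B     mechanism-change           1 CMM:0009  up           NA     1
#> 4 B_to_C     mechanism-change           2 CMM:0001  up            1     2
#> 5 B_to_C     mechanism-change           2 CMM:0002  down          1     2
#> 6 B_to_C     mechanism-change           2 CMM:0003  up            1     2
#> 7 B_to_C     mechanism-change           2 CMM:0011  down          1     2
```

Reading the first leg: between `A` and the 1-hour snapshot, adherens
junctions appeared (`CMM:0005` up, a marker rule) and Occludin became
present alongside JAM and Claudin, firing two participant rules
(`CMM:0006`, `CMM:0009` up). The second leg carries the canonical MET
coding — epithelial network up, mesenchymal network down — and inherits
its start (1 h) and end (2 h) from the snapshots' timestamps.

A command-line front end for shell pipelines lives at
`inst/cli/ceq.R` (`ceq.R onto validate`, `ceq.R search`,
`ceq.R transition`, ...), and the methods vignette
(`vignettes/cell-transition-profiles.Rmd`) documents the model,
propagation semantics, measures and design choices in detail.

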