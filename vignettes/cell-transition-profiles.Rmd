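---
title: "Representing cell phenotypes and cell transitions as EQ annotation profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing cell phenotypes and cell transitions as EQ annotation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceq)
library(dplyr)
```

## The model

A cell phenotype is, at its finest grain, the cell's repertoire of
molecules, ultrastructures and structural components at one point in
time; a cell transition (programming, reprogramming, EMT/MET) is the
change from one such repertoire to another. `ceq` makes both computable
with the entity–quality (EQ) annotation style: an annotation pairs an
**entity** term from an ontology with a **quality** modifier, and a
time-stamped set of annotations is an **annotation profile** describing
one cell state or one mechanism change.

Two ontologies carry the entity terms, and keeping them apart is a
deliberate ontological commitment:

* the **phenotype ontology** houses *continuants* — things wholly present
  whenever they exist: cells, structures (membranes), ultrastructures
  (junctions), molecules. Phenotype profiles use *state* qualities
  (`present`, `absent`, extensions such as `joined`).
* the **mechanism ontology** houses *occurrents* — temporally extended
  processes: networks of mechanisms, ultrastructural events, molecular
  interactions. Mechanism-change profiles use *change* qualities (`up`,
  `moderately_up`, `down`) describing macroscale changes of the
  microscale mechanisms.

Within each ontology only two relations are admitted: `is_a` and an
all-some `has_part` (every instance of the whole has some instance of
the part). `part_of` is deliberately excluded: a molecule like Occludin
is not confined to tight junctions, and an S-phase need not be followed
by the rest of a mitosis, so a universally quantified `part_of` would be
false of most cell parts and process parts. The converse direction is
safe: every tight junction requires its Occludin, every mitosis contains
an S-phase — the whole necessitates its parts. Readers of the OBO subset
therefore treat a `part_of` tag as a hard parse error rather than
silently inverting it.

## Propagation semantics

Annotation propagation makes the implied annotations explicit, and the
all-some reading fixes the direction:

| quality polarity | direction | justification |
|---|---|---|
| positive (`present`, `up`, …) | whole → part, subclass → superclass | an instance of the whole guarantees instances of all necessary parts |
| `absent` (negative state) | part → whole, superclass → subclass | contrapositive: a whole cannot be present while a necessary part is missing |
| `down` (negative change) | none (sound mode) | a whole's shutdown does not entail each part's shutdown — parts may serve other wholes |

`propagate_profiles()` defaults to the *sound* mode above; a *heuristic*
mode propagates `down` whole → part for users who want symmetric
treatment, clearly marked as not logically entailed. When inference
would contradict a directly asserted annotation on the same entity, the
asserted one wins and the conflict is reported
(`propagation_conflicts()`): curated data outranks reasoning.

Because positive annotations flow from wholes to parts, a part can only
accumulate annotation counts. With information content defined as
$IC(t) = -\log_2(\text{count}(t)/N)$ over a propagated corpus of $N$
profiles, a whole process therefore always has information content at
least as high as each of its necessary parts. Terms never annotated
receive the finite maximum $-\log_2(1/N)$ instead of infinity — scores
stay finite and no smoothing distorts the observed counts.

## Similarity

Term similarity is Resnik-style, with one twist forced by the direction
of propagation: the "most informative common ancestor" becomes the most
informative **common positive-propagation target** (a shared part or
superclass). A classic ancestor-based MICA would invert the IC ordering
above. Profile similarity combines term similarities two ways:

* **BMA** (default): symmetric best-match average, each annotation's best
  counterpart weighted by a quality-compatibility factor
  $\kappa(q_1, q_2)$. The default table is 1 on the diagonal, 0 across
  polarities, 0.5 between `up` and `moderately_up`, 0 elsewhere, and is
  overridable.
* **simGIC**: summed IC of the intersection over the union of the two
  (entity, polarity) sets, in $[0, 1]$.

The two measures play different roles, and the difference is worth
spelling out. Because the Resnik term kernel already scores a
network-level annotation against an interaction-level one through their
shared propagation target, BMA bridges curation granularity *without*
explicit propagation — and materializing the inferred annotations can
even dilute a best-match average by adding unmatched terms to the mean.
simGIC, a pure set-overlap measure, sees nothing across granularities
until propagation materializes the shared annotations; on profiles whose
asserted annotations lie in one another's scopes it never decreases
under propagation. We therefore use BMA for ranking and clustering (its
granularity-bridging is a feature there) and simGIC whenever we want to
*quantify the benefit of reasoning*, as in the mixed-granularity MET
example of `example_met_corpus()` and the planted-cluster study below.

`similarity_search()` is the BLAST-like operation in annotation space:
propagate query and corpus, score, rank descending with ties broken by
profile id. Phenotype and mechanism-change profiles are never compared
to each other; the bridge between the two spaces is the transition
module, not a similarity score.

## From snapshots to transitions

Differential analysis turns continuant information into occurrent
information. `derive_transition()` compares two time-stamped phenotype
profiles under an explicit **mechanism map** — curated input, never
inferred, because the links between cell parts and the mechanisms they
participate in must be explicitly established:

* a *marker* rule fires when its phenotype term flips `absent` →
  `present` (mechanism `up`) or `present` → `absent` (`down`);
* a *participant* rule fires `up` when all molecular participants are
  present in the later snapshot and at least one was explicitly absent
  before, and `down` in the mirror case.

Annotation is open-world: an entity missing from a profile is unknown,
not absent — curators rarely assert all negatives — and a quality change
within one polarity (`present` → `joined`) fires nothing. Only the
binary flip derives changes; deriving `moderately_up` from graded state
qualities would require a grading of `present` that the vocabulary does
not define. The derived profile inherits the two snapshots' timestamps
as its start and end; `series_transitions()` chains this over a series,
n snapshots yielding n − 1 transitions.

## Clustering

Fine-grained phenotype individuation (any molecular difference is a new
phenotype) is made usable by clustering: coarse cell types are clusters
of similar phenotype profiles and transition classes are clusters of
similar mechanism-change profiles. Raw similarity scores are
corpus-scale dependent, so `distance_matrix()` normalizes Lin-style,
$d(p,q) = 1 - s(p,q)/\sqrt{s(p,p)\,s(q,q)}$, clipped to $[0,1]$; a
profile with zero self-similarity sits at distance 1 from everything
else. `cluster_profiles()` applies average-linkage agglomeration
(complete/single configurable) and cuts at a user-chosen k — the
framework offers no principled cluster count, so none is guessed.
Determinism comes from sorted profile ids and `hclust`'s order-based tie
handling.

## The synthetic corpus generator

`simulate_corpus()` emulates what mixed-granularity literature curation
does to a set of underlying transition classes. Starting from prototype
profiles (one per planted cluster; `example_met_prototypes()` provides
an MET-like, an EMT-like and a cell-cycle prototype over the example
mechanism ontology), each copy

1. drops each annotation with probability ε (curators miss things),
2. shifts each survivor, with probability g, to a uniformly chosen
   member of its positive scope (the same biology reported coarser or
   finer),
3. with probability ε adds one spurious annotation on a not-yet-annotated
   term, its quality drawn from the prototype's own qualities.

Shifts that would collide with an existing annotation keep the original,
so the expected asserted count per profile is exactly
$m(1-\varepsilon) + \varepsilon$, and no profile can contradict itself.
Everything is reproducible from one seed.

The defaults — 3 clusters × 10 profiles, ε = 0.1, g = 0.3, seed 42 —
are the study conditions used across the documentation and tests: a 10%
curation error rate and a 30% granularity disagreement are on the
pessimistic side of what expert curation of a well-scoped domain
produces, and 10 profiles per class is a realistic corpus for a curated
niche. Under these conditions average-linkage clustering of the BMA
distance matrix recovers the planted partition (ARI ≥ 0.9 is the bar we
test), and the mean within-cluster simGIC similarity is strictly higher
with propagation than without — the "reasoning improves similarity
estimates" claim in a falsifiable form.

What the generator deliberately does *not* emulate: correlated curator
bias (errors here are independent), quality grading noise (`up` never
degrades to `moderately_up`), profiles drawn from overlapping ontology
regions, or annotations derived from real expression data. Passing the
recovery test therefore shows the pipeline is sound under honest
idealized noise, not that real curated corpora will cluster as cleanly.

## Numerical and design notes

* Log base 2 throughout; all IC and BMA values are bits.
* Closures are computed by graph reachability (igraph) and are
  value-identical to a fixpoint closure; the test suite checks this
  against an independent edge-relaxation oracle on ~100 random DAGs per
  run, and checks the duality
  `t ∈ negative_scope(s) ⇔ s ∈ positive_scope(t)` exhaustively.
* Cycles in either relation are rejected at validation — closures over a
  cyclic relation would be ill-defined — as are dangling edge endpoints
  and category/kind mismatches. Violations are returned as tibbles, not
  thrown, so curation pipelines can collect them.
* Serialization is deterministic (sorted terms and rows, fixed tag
  order, LF endings); write∘read and read∘write are identities on the
  dialect, which the suite checks byte-wise.
* Problem sizes in the test suite (random DAGs of 10–50 terms, corpora
  of ≤ 30 profiles) are chosen so every property is checked across
  hundreds of instances while the whole suite stays in the minutes
  range; all the algorithms are polynomial and small-scale by the
  standards of the intended curated corpora.
* Extension qualities (like `joined`) declare their polarity in the
  vocabulary and propagate accordingly; the default compatibility table
  scores them only against themselves, which keeps an extension from
  silently matching `present` — override the table to change that.

## Known limitations

* No OWL semantics: the closure rules above are the entire inference
  engine; qualified cardinalities, role chains and instance-level
  reasoning are out of scope.
* The mechanism map is curated input; the package will not guess links
  between the two ontologies from interaction databases.
* Search scores come without a significance calibration; ranks are
  comparable within one corpus and IC table only.
* Timestamps are plain hours after intervention; calendar normalization
  ("two days after intervention X") is the curator's job.
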