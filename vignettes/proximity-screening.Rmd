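---
title: "Network-proximity screening: model, null calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-proximity screening: model, null calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxscreen)
```

## The screening model

`proxscreen` ranks compounds by how close their protein targets sit to a
disease's associated proteins on a human protein–protein interactome. The
interactome is treated as an undirected, unweighted simple graph; `d(s, t)`
is the shortest-path hop count. For a disease-protein set `S` and a
compound's target set `T`, the *average closest distance* is

$$d_c(S, T) = \frac{1}{|T|} \sum_{t \in T} \min_{s \in S} d(s, t).$$

A target that is itself a disease protein contributes zero, so `d_c = 0`
exactly when the compound hits nothing but disease proteins. The inner
minimum is computed with a single multi-source breadth-first sweep from `S`
(a temporary super-source node adjacent to every member of `S`), which is
equivalent to, and tested against, the elementwise minimum of per-source
single-source searches.

Raw `d_c` values are incomparable across compounds: hubs are close to
everything, and larger target sets average differently. Each compound is
therefore standardized against a *degree- and size-matched null*: random
set pairs `(S*, T*)` matched to `S` and `T` in size and degree are drawn
repeatedly, `d_c(S*, T*)` is computed for each, and the observed distance
is expressed as

$$Z_{d_c} = \frac{d_c - \mu}{\sigma},$$

where `μ` and `σ` are the mean and standard deviation of that null
ensemble. More negative `Z` means more proximal than degree-matched chance.
Compounds are ranked by `Z` ascending, ties broken by `d_c` then compound
identifier; compounds whose null is degenerate (see below) sort last.

### Assumptions

* Interactions are undirected and unweighted; confidence scores, signs and
  directions on PPI edges are deliberately out of scope.
* The interactome is incomplete and study-biased; the degree-matched null
  corrects for hub bias but not for ascertainment bias of specific
  pathways.
* All distances are computed on the largest connected component (LCC).
  Disease proteins or targets outside it have no finite distance; they are
  dropped and counted (`n_targets_dropped`, manifest entries) rather than
  imputed. On the human interactome the LCC covers all but a small
  fraction of nodes, so this choice costs little and guarantees
  well-defined distances.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_bin_size` | 100 | Minimum occupancy of a degree bin in the null sampler (nodes). Smaller bins match degree more tightly but make samples less variable; 100 follows the convention of the proximity framework this package adopts. |
| `n_iterations` | 1000 | Null draws per compound. The Monte-Carlo standard error of `Z` scales as `1/√n`; 1000 keeps it near 0.03 standard units. |
| `qed_threshold` | 0.35 | Inclusive drug-likeness floor (QED units, `[0,1]`): a compound at exactly 0.35 passes. 0.35 is the mean QED of approved drugs. |
| `score_threshold` | 0.82 | Strict lower bound for predicted-interaction scores: a prediction at exactly 0.82 is excluded. 0.82 is the score at which the upstream target predictor reports a 1% false discovery rate. |
| `sigma_tolerance` | 1e-12 | Below this null SD the z-score is undefined (`NA`), not `±Inf`. |
| `seed` | 1 | Master seed. Every compound derives a child seed by hashing its identifier into the master seed, so results do not depend on row order and survive pipeline edits. |

## Degree binning and the null sampler

The binning rule sorts distinct degree values ascending and merges adjacent
values until each interval holds at least `min_bin_size` nodes; a trailing
undersized interval is absorbed by its predecessor. The result is a
complete partition of the vertex set. For each protein in a reference set
the sampler draws one node uniformly from the protein's bin, without
replacement across the whole sample; an exhausted bin is temporarily
widened to adjacent bins (with a message). `S*` and `T*` are drawn
independently in every iteration, both matched to their respective
reference sets.

`σ` uses the population (denominator-*n*) formula. The rationale: the
drawn ensemble *is* the null distribution being described, not a sample
from a larger one. The choice is recorded in every result row, and the
calibration test below verifies its consequence directly: z-scores of
fresh draws from the sampler itself have mean ≈ 0 and SD ≈ 1 (the package
requires mean within ±0.15 and SD within [0.8, 1.2] over 200 replicates on
a 500-node benchmark graph).

## Assembling the compound–target table

Validated and predicted interaction tables are merged to one row per
(compound, target) pair. A pair present in both is recorded as
`validated`; its action label is the validated one unless the validated
label is `other` and the prediction is directional
(`activatory`/`inhibitory`), in which case the predicted direction is
kept — the experiment confirms the interaction, the prediction refines its
direction. This conflict rule is a package design choice, declared rather
than inferred from any upstream source. Conflicting duplicates *within*
one source are an error: dirty inputs fail fast instead of being coerced.

## Recovery and enrichment statistics

Whether a predicted interaction set recovers a validated gold standard
more than chance is tested with the upper-tail hypergeometric probability
`P(X ≥ k)` (the conventional over-representation tail), and optionally
with a permutation twin that draws equally many pairs uniformly from the
predictable universe; the empirical p-value uses the add-one estimator so
it is never exactly zero. The two routes are cross-checked against each
other in the test suite, and the analytic tail is verified against
exhaustive enumeration of every universe up to 12 pairs.

Overrepresentation analysis uses the same tail (one-sided Fisher exact
test), fold enrichment `(k/n)/(K/N)`, and Benjamini–Hochberg correction
across all tested terms. Term membership is consumed from user-supplied
files (two-column or GMT), never fetched from an annotation service, so
results are insensitive to ontology-release drift. The universe is an
explicit argument because fold enrichment and p-values are meaningless
without it; report it alongside any result.

## Mechanism subnetworks

For a compound of interest, `extract_subnetwork()` returns its targets on
the interactome, the disease proteins directly adjacent to at least one
target, all interactome edges within that node set, and one
compound→target edge per target. Direct adjacency is the default because
mechanism figures of this kind show first-neighbour interactions; one-hop
intermediaries (a protein adjacent to both a target and a disease protein)
are admitted only with `include_bridges = TRUE`, since they multiply
rapidly on hub-rich graphs. When bridges are admitted, disease proteins
reachable only through a bridge are admitted too, so no bridge dangles
without the disease side it connects.

## The synthetic benchmark

`generate_scenario()` produces every pipeline input with known ground
truth. Its defaults define the package's reference conditions:

* **Interactome**: 500 nodes grown by preferential attachment with 3 edges
  per new node. The growth starts from 3 unlinked seed nodes and attaches
  each newcomer to existing nodes with probability proportional to
  degree + 1, giving exactly `3 × (500 − 3)` edges, guaranteed
  connectivity and a heavy-tailed degree distribution in one step (the
  reason preferential attachment was chosen over a configuration model).
* **Disease module**: 30 proteins grown by randomized breadth-first
  expansion from a random start node — connected by construction, like a
  disease module localized in one interactome neighbourhood. Process-group
  labels (lipid metabolism / inflammation / oxidative stress / other) are
  assigned uniformly at random.
* **Compound cohorts**: 20 *proximal* compounds draw 10–30 targets from
  nodes within 1 hop of the module; 20 *distal* compounds draw from nodes
  farther than 1 hop. Prediction scores are uniform on (0.82, 1.0) for
  proximal and (0.5, 0.95) for distal rows, so the two cohorts straddle
  the 0.82 call threshold and score filtering is exercised non-trivially
  on both sides. QED scores are uniform on (0.2, 0.9) for the same reason
  relative to the 0.35 threshold.
* **Annotations**: 20 random term sets; the first is over-sampled from a
  designated protein set so its expected overlap is 5× the chance level.

What the generator does **not** emulate: the real interactome's size
(hundreds of thousands of edges — reachable by configuration, not a test
default), its community and pathway structure, correlated target sets
across chemically similar compounds, and literature-driven annotation
bias. Passing the benchmark therefore shows the machinery is correct and
calibrated, not that any particular real compound ranking is right.

## Numerical choices and degenerate inputs

* Distances are integer hop counts; `d_c` is an exact rational mean, so
  oracle tests require exact equality, not tolerances.
* Degenerate nulls (`σ ≤ 1e-12`, e.g. on graphs that force a single
  possible distance) yield `NA` z-scores; such compounds sort after all
  scored compounds, ordered by `d_c`.
* Equal-size component ties in the LCC restriction are broken toward the
  component containing the lexicographically smallest node name, making
  the restriction deterministic.
* Empty inputs fail with named errors (empty set after restriction, empty
  universe, unknown compound) rather than returning empty results.
* Graphs of at most 3000 nodes get a precomputed all-pairs distance matrix
  inside `screen_compounds()`; larger graphs fall back to per-evaluation
  multi-source sweeps. Both paths are tested to agree exactly.

The test suite runs the full default benchmark (40 compounds × 1000 null
iterations on the 500-node scenario), a 200-replicate null-calibration
study, 200 random-graph oracle comparisons, exhaustive hypergeometric
enumeration to N = 12, and 100 seeded enrichment simulations; these sizes
were chosen so the whole suite completes in a couple of minutes on a
laptop while keeping Monte-Carlo error well below the asserted margins.

## Known limitations

* Only the *closest* proximity measure is implemented; shortest, centre,
  kernel and separation variants are out of scope.
* The degree-matched null treats `S` and `T` as exchangeable random sets;
  it does not model correlation between a compound's targets (e.g. one
  protein family), which can make real nulls slightly optimistic.
* Identifier harmonization is consumed, not performed: node names are
  opaque strings, and an optional two-column mapping file at load time is
  the only translation facility.
* `run_screen()` reports what was dropped (QED failures, score failures,
  off-component proteins, targetless compounds) but never imputes.

## A worked run

```{r example, eval = FALSE}
scenario <- generate_scenario(seed = 1)
dir <- tempfile("scenario")
paths <- write_scenario(scenario, dir)

cfg <- run_config(
  interactome = paths[["interactome"]],
  cti         = paths[["cti"]],
  disease     = paths[["disease"]],
  qed         = paths[["qed"]],
  n_iterations = 1000, seed = 1,
  output_dir  = file.path(dir, "out"))
run <- run_screen(cfg)
head(run$results)
```

The ranked table lands in `out/ranked_proximity.tsv` together with a
`manifest.yaml` recording the seed, thresholds, package version, input
checksums and every dropped-row count, so a rerun with the same
configuration reproduces the table byte-identically.
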