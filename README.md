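# proxscreen

Network-proximity screening of compound target sets against disease
modules on a protein–protein interactome.

## The problem

Natural products and other small molecules act on many protein targets at
once, and for most of them nobody has measured whether they could help a
given disease. Network medicine offers a screening principle: the closer a
compound's targets sit to the disease-associated proteins on the human
protein–protein interaction (PPI) network, the more likely the compound is
to modulate the disease phenotype. `proxscreen` implements that screen —
built for analyses such as prioritizing dietary flavonoids against
non-alcoholic fatty liver disease — as a tested, reusable R pipeline: no
web services, no hidden state, every random draw seeded.

## The statistic

For disease proteins $S$ and compound targets $T$ on an unweighted
interactome with hop distance $d(s,t)$:

$$d_c(S,T) = \frac{1}{|T|}\sum_{t \in T}\min_{s \in S} d(s,t)$$

$d_c$ is standardized against a null of random protein-set pairs matched
to $S$ and $T$ in **size and degree** (proteins resampled from degree
bins, 1000 iterations by default):

$$Z_{d_c} = \frac{d_c - \mu}{\sigma}$$

More negative $Z_{d_c}$ = more proximal than degree-matched chance.
Supporting stages: compound–target table assembly with drug-likeness
(QED ≥ 0.35, inclusive) and prediction-score (> 0.82, strict) filters;
upper-tail hypergeometric + permutation recovery tests of predicted
interactions against a validated gold standard; mechanism subnetwork
extraction; Fisher/Benjamini–Hochberg overrepresentation analysis; and a
seeded synthetic benchmark generator (scale-free interactome, planted
disease module, proximal/distal compound cohorts with known ground
truth).

## Worked example

```r
library(proxscreen)

scenario <- generate_scenario(seed = 1)            # 500-node benchmark
filtered <- filter_predictions_by_score(scenario$cti, 0.82)
res <- screen_compounds(filtered, scenario$disease,
                        scenario$interactome, seed = 2)
head(res[, c("compound_id", "n_targets_used", "d_c", "mu", "sigma",
             "z", "n_direct_interactions")])
```

```
  compound_id n_targets_used   d_c   mu sigma     z n_direct_interactions
1 proximal_17             28 0.821 1.56 0.128 -5.75                     5
2 proximal_15             25 0.800 1.50 0.131 -5.36                     5
3 proximal_18             23 0.826 1.53 0.139 -5.07                     4
4 proximal_05             26 0.846 1.48 0.133 -4.77                     4
5 proximal_09             14 0.643 1.44 0.170 -4.68                     5
6 proximal_19             19 0.842 1.55 0.154 -4.60                     3
```

Reading row 1: the compound's 28 usable targets average 0.82 hops to the
nearest disease protein, while degree-matched random sets average 1.56 ±
0.13 hops — 5.75 standard deviations farther. Five targets *are* disease
proteins (`n_direct_interactions`). The planted-proximal compounds fill
the top of the ranking, which is exactly the generator's ground truth.

Recovery statistics work the same way on any pair universe:

```r
u <- sprintf("pair%02d", 1:10)
hypergeometric_recovery_test(u, gold = u[1:5], predicted = u[1:5],
                             n_permutations = 10000, seed = 3)
```

```
Recovery test (upper-tail hypergeometric)
  universe: 10  gold: 5  predicted: 5  recovered: 5
  p (hypergeometric): 0.003968
  p (empirical, 10000 permutations): 0.0036
```

The analytic p is exactly `1/choose(10, 5)`; the permutation estimate
agrees within Monte-Carlo error.

For file-based runs, `run_screen()` takes a YAML config (paths +
thresholds + seed), applies the QED and score filters, screens every
compound and writes `ranked_proximity.tsv` plus a `manifest.yaml` with
seeds, parameters, input checksums and dropped-row counts; reruns are
byte-identical. See the vignette
(`vignettes/proximity-screening.Rmd`) for the model, null-calibration
evidence and all design decisions.

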