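---
title: "Ensemble QSAR screening: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble QSAR screening: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoscreen)
```

phytoscreen models phenotypic bioactivity — does a compound inhibit a given
cancer cell line? — from binary circular fingerprints, and uses those models
to screen large natural-product libraries and to rank the plant species that
contain the predicted actives. This vignette explains the science inside
each stage, the parameters that matter, and the design decisions taken where
more than one defensible choice existed.

## From activity records to labeled compounds

The unit of raw data is one reported IC50 measurement of a compound against
a cell line. Curation applies four rules:

* **Standardization.** Structures are reduced to an achiral canonical SMILES
  plus an InChIKey. Stereo descriptors are deliberately discarded: chirality
  is inconsistently reported across source databases (unknown configuration,
  racemates), and the binary fingerprints used downstream cannot encode it,
  so keeping enantiomers separate would only inflate apparent compound
  counts. Salt and mixture entries keep their largest covalent fragment
  before standardization. Structurally broken SMILES are rejected with a
  logged reason, never silently repaired.
* **Activity threshold.** Active means IC50 strictly below 10 µM. A value
  exactly at the threshold is inactive — the active class is defined by the
  strict inequality, and the complement absorbs equality.
* **Replicate consistency.** When a compound has several measurements
  against the same cell line, the pair is kept only if every report falls in
  the same class. Values are never averaged: class agreement, not numeric
  agreement, is the criterion, so a pair reported at 3 µM and 7 µM is kept
  (active) while 3 µM and 30 µM is excluded.
* **Training/screening partition.** Compounds with retained labels in three
  or more distinct cell lines are diverted to a reserved virtual-screening
  set and never enter any training pool. This keeps the multi-cell-line
  compounds — exactly the ones a cross-cell-line consensus model should be
  judged on — out of every model's training history.

Every input record is accounted for as kept, reserved, or excluded with a
reason; the counts sum to the input size by construction.

## Dataset construction

**Fingerprints.** Each standardized molecule is described by a 1,024-bit
circular fingerprint of radius 2 (ECFP4 family). The toolkit emits 4,096-bit
vectors; these are folded 4:1 by bitwise OR, the standard length reduction
for hashed fingerprints. Only this description is used — the pipeline takes
no other descriptors.

**Balancing.** Cell-line datasets are usually imbalanced. Rather than
discard majority compounds at random, the majority class is clustered with
k-means for every cluster count from 2 up to the minority size; the mean
silhouette width selects the cluster count (ties resolve toward fewer
clusters), and each cluster then contributes a proportional number of
randomly drawn compounds. Proportionality uses largest-remainder
apportionment, so the selection totals exactly the minority size — e.g.
clusters of 60 and 40 compounds contribute 30 and 20 toward a target of 50.
Balancing precedes splitting, preserving the pipeline's canonical order.
Degenerate input (all rows identical) falls back to plain random sampling
with a log flag.

**Splitting.** A seeded, label-agnostic random split at 60/20/20 into
train, test and external partitions, each within one compound of its exact
target. The split is not stratified by label; the preceding balancing step
keeps all three partitions usable. Fewer than 10 compounds is rejected —
the partitions would be empty.

**Variance filter.** Columns whose population variance on the *training*
partition falls below 0.05 are removed; for a binary column with set-bit
frequency $p$ this is $p(1-p) < 0.05$, i.e. bits set in fewer than ~5.3% or
more than ~94.7% of training compounds. The surviving column list is applied
unchanged to every other partition and to screening compounds — no
re-fitting.

**Applicability domain.** A model should only be trusted near its training
data. PCA is fitted on the variance-filtered training bits (mean-centered,
unscaled covariance — the bits share a scale, so rescaling would only
amplify noise in rare bits), keeping the smallest number of leading
components whose cumulative explained variance exceeds 90%. The domain is
the ball in that component space centred on the training centroid with
radius equal to the maximum training distance: all training compounds are
in-domain by construction, and any query farther from the centroid than the
farthest training compound is out. Euclidean distance in component space is
used because the components are continuous, orthogonal coordinates and the
computation is fast at screening scale. A relative tolerance of 1e-8 on the
radius absorbs floating-point noise when training compounds re-enter their
own domain.

## Classifiers and the BCR fitness

Three families are supported, each on a small variable subset (4–25
fingerprint columns): random forest (Gini splits, 100 trees), a single
decision tree (Gini splits, grown until every leaf holds fewer than 2
samples), and k-nearest neighbors (k = 5, Euclidean distance, which on
binary bits is the square root of the Hamming distance). The R tree
implementations differ slightly from other toolkits: `randomForest` has no
explicit depth cap (at these data sizes — hundreds of compounds, at most 25
variables — a cap of 100 would never bind, so fully grown trees are
equivalent), and `rpart` enforces a hard depth limit of 30, far beyond what
4–25 binary variables can produce. Probabilities are the fraction of trees
voting active (RF), the leaf class frequency (DTREE), or the neighbor vote
fraction (KNN); classification thresholds all sit at probability > 0.5.

Model quality is summarized by the balanced classification rate

$$\mathrm{BCR} = \frac{Se + Sp}{2}\,\bigl(1 - |Se - Sp|\bigr),$$

the mean of sensitivity and specificity discounted by their gap. Unlike
plain balanced accuracy it punishes lopsided models: a classifier with
$Se = 1, Sp = 0.5$ scores 0.375, not 0.75, and maximal imbalance
annihilates the score entirely. BCR is symmetric in $Se$ and $Sp$ and never
exceeds their mean.

## Genetic-algorithm variable selection

Variable subsets are evolved directly: a chromosome is a set of 4–25 column
indices, and its fitness is the BCR of the trained model on the **test**
partition. The external partition is never consulted during evolution — it
exists to measure, after the fact, whether the selected models generalize,
and the suite verifies behaviorally that scrambling external labels changes
nothing about an optimization run. No cross-validation is used anywhere:
train fits, test drives selection, external reports.

The operator suite (not fully dictated by the method's description, so fixed
here and recorded in every run's configuration): tournament selection of
size 3, uniform set crossover at rate 0.9 (shared genes kept,
symmetric-difference genes inherited with probability 1/2), per-gene swap
mutation at rate 1/|chromosome|, repair into the 4–25 window, and elitism
of 1. Elitism makes the best-fitness trace non-decreasing, which the tests
assert. Fitness values are cached by chromosome, and each chromosome trains
under a seed derived deterministically from its content, so a whole run is
reproducible from its configuration and seed. Fitness evaluations save and
restore the global RNG state, keeping model-training seeds from perturbing
the engine's own stream.

The reference budgets are a population of 1,000 evolved for 5,000
generations; those are configuration defaults for full-scale runs. The
package's own test suite and acceptance script use a scaled budget of 50 ×
50 on 400-compound synthetic datasets, which recovers planted informative
bits reliably and keeps a full run around one minute; any reported result
states which budget produced it.

Choosing "the best model" from a final population is a supervised act — the
population is returned ranked by test BCR with external metrics and
population means attached, and the final pick is left to the analyst.

## Ensembles

A pool of qualified base models is generated by rejection sampling: draw a
random family among RF/DTREE/KNN and a random 4–25 variable subset, train,
and admit only when test BCR exceeds 0.65, until the pool (default 200
members) is full. Random generation plus qualification is the minimal
faithful reading of "generated models meeting criteria"; a flag allows
seeding the pool from a GA-selected population instead, and seeded models
still face the same qualification. If the attempt budget is exhausted the
pool fails loudly, naming the shortfall — the signal of an unlearnable
dataset or a floor set too high.

Ensembles are subsets of 2–20 pool members; their prediction is the
arithmetic mean of member probabilities (no weighting, no stacking), which
makes the ensemble permutation-invariant in its members and idempotent when
members agree. Member sets are evolved with the same GA engine, fitness
again the test-partition BCR of the aggregated prediction. Because each
member's test probabilities are computed once up front, ensemble fitness
evaluation is a column average — the ensemble GA is orders of magnitude
cheaper than the variable-selection GA. Duplicate member sets are allowed
during evolution and deduplicated in the final ranking.

## Early-recognition metrics and the consensus screen

Virtual screening is a ranking problem: the question is not overall accuracy
but whether actives surface *early*. With $n$ actives among $N$ compounds
($R_a = n/N$) and active ranks $r_i$, the robust initial enhancement is

$$\mathrm{RIE} = \frac{\sum_i e^{-\alpha r_i / N}}
{\frac{n}{N}\,\frac{1 - e^{-\alpha}}{e^{\alpha/N} - 1}},$$

the exponentially weighted recovery of actives over its expectation under a
uniform random ranking. Its attainable extremes have closed forms,
$\mathrm{RIE}_{\max} = (1 - e^{-\alpha R_a})/(R_a(1 - e^{-\alpha}))$ and
$\mathrm{RIE}_{\min} = (1 - e^{\alpha R_a})/(R_a(1 - e^{\alpha}))$, and

$$\mathrm{BEDROC} = \frac{\mathrm{RIE} - \mathrm{RIE}_{\min}}
{\mathrm{RIE}_{\max} - \mathrm{RIE}_{\min}} \in [0, 1]$$

reaches exactly 1 when all actives occupy the top ranks and 0 at the bottom.
The package's implementation is pinned to brute-force exponential-sum
oracles at 1e-9 in the tests; the extremes' sign conventions are the only
ones consistent with BEDROC's range, which the property suite enforces.

The exponent $\alpha$ sets the early-recognition emphasis through the weight
mass $1 - e^{-\alpha\chi}$ contained in the top fraction $\chi$: requiring
80% of the mass in the top 1% gives $\alpha = -\ln(0.2)/0.01 = 160.9$, the
anchor value used throughout. The enrichment factor at a top fraction,
$\mathrm{EF} = \#\{r_i \le \chi N\}/(\chi n)$ with a window of
$\lfloor \chi N \rfloor$ compounds (minimum 1, ranks 1-based), is about 1
for a random ranking and at most $1/\chi$. Score ties are broken by a
seeded random permutation before ranking; reported metrics can average over
several tie-break draws (default 1). Both metrics are invariant to strictly
monotone transformations of the scores.

**Cross-cell-line consensus.** With one chosen family per cell line (RF,
DTREE, KNN or the optimized ensemble E), a compound's consensus score is the
mean of its per-cell-line probabilities. All family assignments are
enumerated — $4^4 = 256$ combinations for four cell lines — and ranked by
BEDROC at the anchor $\alpha$ with EF profiles alongside. A compound must be
in-domain for **every** cell line's applicability domain to be scored at
all; otherwise it is excluded from the ranking, mirroring how screening
libraries shrink slightly after domain filtering. Two top combinations can
then be intersected: compounds exceeding a probability threshold in *both*
consensus models form the hit set, at thresholds 0.5 / 0.55 / 0.6 (strict).

## Plant prioritization

Compound–plant association tables are merged across source databases,
species names resolved against an NCBI-style `fullnamelineage.dmp` dump
restricted to lineages containing Viridiplantae. Matching is exact after
case/whitespace normalization — no fuzzy matching, so processed-food
entries ("popcorn") and unresolvable names drop out with a logged reason.
Structures pass through the same standardization as everywhere else, which
collapses enantiomers reported under one species into a single association.

A compound's hit status is global (it comes from the consensus screen, not
from any species context). Species are ranked two ways, mirroring the
absolute and relative views: by the count of associated hit compounds, and
by the fraction of their reported compounds that are hits — a species with
three compounds, two of them hits, can matter as much as a
hundred-compound species with five. Tallies report how many species reach
at least 1, 2 and 5 hits. Genus summaries (genus = first token of the
binomial unless an explicit grouping is supplied) count *unique* hit
compounds across congeners, so a compound shared by two Taxus species
counts once. Chemical-class composition is reported only when an external
class annotation column is supplied; no class assignment is computed
internally.

## The synthetic-data generators

All tests run on generated inputs, so what the generators emulate bounds
what the tests can show.

* `simulate_fingerprint_dataset()` draws independent Bernoulli bits at a
  background set-bit probability of 0.1 — chosen so uninformative columns
  survive the 0.05 variance cut and variable selection faces a real search
  problem. Informative bits separate the classes by `effect`: actives carry
  them at $p_0 + e(1-p_0)$, inactives at $p_0(1-e)$, so effect 0 plants no
  signal and effect 1 is deterministic. The default effect of 0.8 gives a
  single informative bit a sensitivity near 0.82 at specificity near 0.98 —
  strong but not trivial signal, the regime where GA recovery is
  attainable at scaled budgets. Majority-class cluster structure for
  balancing tests lives on a dedicated 200-column block with
  Bernoulli(0.5) centers; a global flip noise of 0.02 is applied last.
* `simulate_screen()` is a location-shift normal model (unit spread) for
  active versus decoy scores. The early-recognition metrics are rank-based
  and distribution-free, so the distribution family is a documentation
  choice, not a modeling commitment.
* `simulate_plant_tables()` plants hot species with exact disjoint hit
  counts, enantiomer duplicates under single species, cross-source
  duplicated records, and non-plant source names, and emits the matching
  lineage dump. Every planted quantity is recoverable from the returned
  truth record.

What the generators do **not** emulate: real chemistry (synthetic SMILES
are simple homolog series), correlated fingerprint bits, activity cliffs,
assay noise structure, or the actual composition of natural-product
databases. Passing tests therefore demonstrate that the machinery is
correct and recovers planted structure under controlled conditions — not
that any particular real-world dataset will reach the same metrics.

## Numerical choices and degenerate inputs

* Exact closed forms are used for the RIE normalizer and extremes; no
  series approximations, so no $\alpha R_a$ smallness condition is needed.
* Silhouette ties resolve toward fewer clusters (parsimony); k-means runs
  10 seeded restarts per candidate k, and the silhouette scan subsamples
  beyond a configurable cap (default 1,000 rows).
* Largest-remainder ties resolve toward larger clusters, then lower index.
* The applicability-domain radius carries a 1e-8 relative tolerance.
* Empty variable-filter results, empty partitions, empty ensembles, pool
  shortfalls and out-of-range metric arguments all fail with explicit
  errors rather than propagating NA.

## Problem sizes used in the shipped runs

The test suite and acceptance script run entirely on synthetic data at
desk scale, chosen as the package's own study conditions: 400-compound
datasets (200 per class, 5 informative bits), GA budgets of 50 × 50,
pools of 20 with ensembles up to 10 members, 4,535-compound screens
(86 actives), and 40-species association tables. Full-scale budgets
(population 1,000, 5,000 generations, pools of 200, ensembles to 20) are
the documented defaults of the corresponding functions.

## Known limitations

* Chirality is intentionally ignored end to end; stereospecific activity
  differences are invisible to the models.
* The applicability domain is a single global ball in PCA space — a crude
  envelope that can admit far-off compounds lying along dense directions
  and reject legitimate ones in sparse corners.
* KNN probabilities at k = 5 are coarse (six possible values), which
  limits its contribution to fine-grained rankings.
* The pool qualification threshold (BCR > 0.65) and the GA operator suite
  are fixed conventions; no hyperparameter search is performed beyond the
  stated values, and none is intended.
* Units are µM only; qualified/censored activity values must be resolved
  upstream.
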