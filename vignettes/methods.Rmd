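---
title: "Gene prioritization by tensor factorization: models, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene prioritization by tensor factorization: models, training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Drug programs fail mostly because the chosen gene was not actually a
driver of the disease. `kgprio` ranks candidate genes for a disease by
learning low-dimensional embeddings of a heterogeneous biomedical
knowledge graph: typed entities (GeneProtein, Disease, GOProcess,
Pathway, Compound) connected by directed, labeled relations such as
protein-protein interaction, biological association, or the
disease-gene *therapeutic relationship* that serves as the benchmark.
A fact is a triple $(s, r, o)$; facts absent from the graph are treated
as false (the closed-world assumption), which is how negative examples
are manufactured for both training and evaluation.

## The model

Each entity and each relation is a $d$-dimensional complex vector. The
ComplEx decoder scores a triple as

$$\phi(s, r, o) = \mathrm{Re}\Big(\sum_{j=1}^{d} l_{rj}\, e_{sj}\,
\bar e_{oj}\Big)
= \langle e_{sa}, l_{ra}, e_{oa}\rangle
+ \langle e_{sb}, l_{ra}, e_{ob}\rangle
+ \langle e_{sa}, l_{rb}, e_{ob}\rangle
- \langle e_{sb}, l_{rb}, e_{oa}\rangle,$$

where $a$/$b$ denote real/imaginary parts and
$\langle x, y, z\rangle = \sum_j x_j y_j z_j$. The imaginary relation
component makes $\phi(s,r,o) \neq \phi(o,r,s)$ in general, so one
embedding space can model directed relations. Three comparison decoders
are provided in the same trainer: DistMult (real embeddings, exactly
symmetric — the baseline), CP (separate subject and object entity
tables, asymmetric), and HolE (relation vector dotted with the circular
correlation $[x \star y]_k = \sum_i x_i y_{(i+k) \bmod d}$ of the
entity vectors). HolE is computed by the direct $O(d^2)$ sum, with a
spectral (FFT) path used as an independent cross-check in the tests.
$\phi$ is unbounded; reported prioritization scores pass through the
logistic function into $(0, 1)$.

## Training recipe

* **Initialization** — every required matrix is Xavier/Glorot Gaussian,
  $\sigma^2 = 2/(\text{rows} + d)$, seeded.
* **Negative sampling** — 5 corruptions per positive (default); each
  corruption replaces the subject or object (uniform choice) with a
  uniformly drawn *different* entity of the same type. Negatives are not
  checked against known positives: under the closed world they are
  presumed false. A collision with a true edge is rare and acts as label
  noise, which is standard practice.
* **Relation-balanced batches** — every batch carries
  `floor(batch_size / #relations)` examples of each relation; relations
  with fewer triples than an epoch needs are drawn with replacement.
  This oversamples rare relations — deliberately, since the benchmark
  relation is one of them. One epoch covers the most frequent relation
  once.
* **Dropout** — each coordinate of the subject and object entity
  embeddings entering the decoder is independently zeroed with
  probability $p$ (default 0.5) and survivors are scaled by $1/(1-p)$
  (inverted dropout), so evaluation needs no rescaling. Masks are drawn
  per example and per real matrix: the factored "six real embeddings"
  view of ComplEx treats the real and imaginary parts as separate
  embeddings, and relation embeddings are left intact.
* **Loss and optimizer** — mean binary cross-entropy with logits
  (positives labeled 1, sampled corruptions 0), computed in softplus
  form so it is finite for any finite score; Adam with the published
  defaults ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$)
  and learning rate 0.01 by default. A reduce-on-plateau schedule
  multiplies the step size by `lr_decay` (default 0.5) after each epoch
  without validation improvement, so iterates settle onto the optimum
  instead of oscillating around it as stopping approaches. All
  gradients are analytic and are tested against central finite
  differences to a relative error below $10^{-4}$.
* **Early stopping** — after each epoch the validation metric (filtered
  average recall at `eval_k` on the benchmark relation) is computed;
  training stops once it has not improved by more than `improvement_tol`
  (default $10^{-4}$) for `patience_epochs` (default 5) consecutive
  epochs, and the best-epoch model is restored. With an empty
  validation set the negative epoch loss takes the metric's place.

One seeded RNG stream drives initialization, batching, corruption and
dropout, so a fixed seed reproduces a run bit for bit.

### Parameters that matter

| parameter | default | role |
|---|---|---|
| `embedding_dim` | 200 (16 at desk scale) | capacity; must be at least the latent rank of the data |
| `negatives_per_positive` | 5 | contrast strength of the loss |
| `batch_size` | 3000 (512 at desk scale) | per-relation quota = batch/#relations |
| `dropout_p` | 0.5 | regularization; see the discussion below |
| `learning_rate` | 0.01 | Adam step size; 0.05 converges faster on desk-scale graphs |
| `lr_decay` | 0.5 | reduce-on-plateau factor (1 disables) |
| `patience_epochs` | 5 | early-stopping window |

## Evaluation

For each disease the full candidate pool (every entity of the
benchmark relation's object type) is scored and sorted, ties broken by
ascending entity id. Candidates already linked to the disease in the
training or validation sets are *filtered* from the list so known facts
do not crowd out test items. Two metrics summarize a benchmark:

$$AP = \frac{\sum_{k=1}^{N} P(k)\,rel(k)}{GTP}, \qquad
mAP = \frac{1}{D}\sum_{d=1}^{D} AP(d), \qquad
\text{avg. } Recall@k = \frac{1}{D}\sum_{d=1}^{D} Recall@k(d).$$

$GTP$ is the disease's total ground-truth positive count (not capped at
the cutoff $N$), so a truncated list is penalized. Recall — not AUROC
or AUPR — is the headline metric because knowledge-graph edges are
positive-unlabelled: an absent edge may simply be undiscovered, so
precision-style metrics would punish correct novel predictions.
Diseases whose test positives are entirely filtered out have undefined
recall and are excluded from averages, with a logged count. Score
distributions (e.g. clinical successes versus failures) are compared
with a two-sided Mann-Whitney-Wilcoxon test; the significance threshold
is Bonferroni-corrected, $\alpha / m$ over $m$ comparisons.

Benchmark construction follows two protocols. The *random* split
partitions benchmark edges 60/20/20 (train/valid/test) by edge count —
floor rounding for valid and test, remainder to train, so train is
never starved — with every non-benchmark triple in train. The
*time-sliced* split trains on edges first reported up to and including
a year threshold and tests on benchmark edges after it, optionally
bounded to a 5-year window (threshold 2010 tests on 2011–2015
inclusive); an edge mentioned in several years is dated by its earliest
mention. Diseases with fewer than 30 distinct benchmark genes can be
removed from the test set — such low-degree diseases are typically
subtypes whose near-duplicates sit in training, which would inflate
measured performance. The degree filter only restricts the test set;
training keeps every edge.

Clinical-phase labeling aggregates a gene-disease pair tested with
several compounds to the single highest phase reached; the pair is a
*failure* only when that highest phase is Phase II or III and every
program reaching it was discontinued (late discontinuations are
overwhelmingly efficacy failures), a *success* when it reached
pre-registration or beyond, and *unassigned* otherwise (a highest
phase of Discovery or Phase I says nothing about efficacy). When the
same top phase is reached by both an ongoing and a discontinued
program, the ongoing one wins and the pair stays unassigned — a
discontinuation is not evidence of failure while another compound is
still advancing.

## The synthetic test substrate

Real biomedical knowledge graphs of useful size are built from licensed
databases and literature mining, so the package ships a generator
instead. It draws *planted* complex embeddings at a small rank
(`true_dim`, default 8), multiplies each entity's embedding by a
lognormal strength factor (`entity_scale_sd`, default 0.8), scores
every type-compatible pair of each of the 11 canonical relations with
the ComplEx form, and emits the top-scoring fraction (`edge_density`)
per relation as edges; labels can then be flipped at `noise_rate`.

The heterogeneous entity strengths deserve a word. Real curated graphs
are hub-dominated: a minority of well-studied genes and diseases carry
a large share of the edges, and that degree structure is precisely what
embedding models exploit first. With homogeneous Gaussian embeddings
the planted score distribution is thin-tailed, so the density threshold
falls in a crowded region: most edges sit within a sliver of score of
most non-edges, and no estimator can place such marginal positives
reliably into a top-20 list from binary labels alone — a margin
problem, not an optimization problem. That regime is both unrealistic
and unrecoverable, which would defeat the
generator's purpose of providing a substrate on which correct training
code demonstrably recovers structure. Lognormal strengths restore the
heavy-tailed, hub-dominated score distribution of real graphs and make
the planted ranking statistically recoverable at desk scale. Because the planted structure lives in
the family the model fits, link recovery is a meaningful benchmark, and
the planted scores supply a Bayes-optimal reference ranking
(`oracle_ranking`), which attains recall and mAP of 1 on the noise-free
graph. A `structure = "random"` mode generates edge sets of identical
size with no latent structure, as a negative control: trained recall
there should approach the random-ranker baseline.

Defaults describe the desk-scale study conditions used throughout the
tests: 500 entities, planted rank 8, and roughly 20 benchmark positives
per disease. The entity mix (300 GeneProteins, 40 Diseases, 70
GOProcesses, 20 Pathways, 70 Compounds) puts most entities in the gene
candidate pool. In the full-scale graphs this package emulates,
compounds are the most numerous type; at 500 entities that mix would
leave a candidate pool of well under 100 genes, where recall@20 nearly
saturates for any ranker and ranking metrics lose their dynamic range.
Since the generator's purpose is to exercise *ranking*, pool size wins;
the mix is fully configurable for users who want schema-faithful
proportions. Self-loops of within-type relations (PPI, GO-GO) are
excluded — a self-edge carries no ranking information. Year tags are
drawn uniformly over `year_range`, or by descending planted score
(`score_ordered`) to emulate strong relationships surfacing first.

What the generator does *not* emulate: literature-mention confidence,
database provenance, the heavy-tailed degree distributions of real
curated graphs, ontology structure among diseases, and the correlation
between entity degree and study intensity. Passing recovery tests here
shows the machinery is correct and that planted low-rank structure is
learnable; it does not certify performance on real data.

## Numerical choices and degenerate inputs

* Scoring associates entity products first, `(e_s * e_o) * l_r`, which
  makes DistMult's subject/object symmetry bit-exact and reduces
  ComplEx with zero imaginary parts to DistMult bit for bit.
* Ranking ties are broken by ascending entity id — deterministic across
  runs and platforms.
* The loss uses the softplus form; dropout with $p \ge 1$ is rejected;
  a non-finite loss aborts training with a diagnostic rather than
  continuing on NaNs.
* `split_random` floors the valid and test sizes; a benchmark with no
  triples is an error, but empty valid or test partitions are allowed.
* Duplicate $(s, r, o)$ triples collapse to one, keeping the earliest
  year, consistent with the earliest-mention dating rule.
* A triple whose endpoint types both have only one entity cannot be
  corrupted and raises an error during negative sampling.

## Desk-scale problem sizes

The test suite and the acceptance script run everything on the
generator's 500-entity default (about 4,400 edges), with $d = 16$,
batches of 512 and 5 negatives per positive — a deliberate scale-down
of the full recipe ($n = 322{,}591$, $d = 200$, batches of 3000) that
preserves every structural choice while keeping any single training run
in the tens of seconds on one CPU. Multi-seed recovery experiments use
5 seeds.

## Known limitations

* Training is plain R matrix code: perfectly adequate at desk scale,
  not intended for million-edge graphs.
* Dropout at $p = 0.5$ on $d = 16$ embeddings is a far stronger
  regularizer than the same rate at $d = 200$: each scored pair
  retains only about a quarter of its product terms. On the small
  planted graphs this visibly caps achievable recall relative to
  training without dropout; the dropout ablation tests therefore check
  the *direction* of the effect in an overfit-prone regime rather than
  absolute performance under the full-scale rate.
* The MWW test falls back to the normal approximation in the presence
  of ties (the exact enumeration is used for small untied samples).
* `read_edge_list` holds the graph in memory; edge lists beyond a few
  million rows belong in a database, not this package.
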