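---
title: "Coupled network propagation for disease-gene prioritization: model, evaluation and design notes"
author: "prioNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled network propagation for disease-gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, message=FALSE}
library(prioNet)
```

## The model

prioNet scores every disease-gene pair by coupling two networks: a disease
phenotype-similarity network $S$ (text-mining similarities in $[0,1]$) and a
protein-protein interaction network $A$ (binary). The guiding observation is
the modular organisation of genetic disease: genes involved in the same or
similar diseases tend to lie close together in the interactome, and
phenotypic overlap tracks genotypic overlap. The score of a pair $(p, g)$ is
therefore defined through the scores of all pairs formed by the diseases
similar to $p$ and the network neighbours of $g$ — a bilinear, fully coupled
smoothing of the association matrix over both networks at once, rather than
a per-disease walk on the interactome alone.

Concretely, with $\tilde S$ and $\tilde A$ the degree-normalized similarity
and adjacency matrices and $F_0$ the prior association matrix, the scores
iterate

$$F^{(t)} = (1 - w)\, \tilde S\, F^{(t-1)} \tilde A + w\, F_0,
\qquad F^{(0)} = F_0,$$

until the mean square deviation (MSD) between successive iterates is at most
`tol`. Both "neighbourhoods" include the node itself: the similarity matrix
carries a unit diagonal (every disease is maximally similar to itself) and
the interactome is extended with self-interactions before propagation
(`extendSelfLoops()`), so known associations contribute directly to their
own refreshed scores.

Three ingredients define the inputs:

* **Filtered similarity.** Off-diagonal similarities below the threshold
  $\theta$ are zeroed. Weak text-mining similarities (below roughly 0.3)
  carry no functional signal and values above 0.6 track genuine functional
  relatedness, so a cutoff of $\theta = 0.5$ purifies the network; the same
  filter is applied to derived prior scores.
* **Prior matrix $F_0$.** A known pair scores exactly 1. An unknown pair
  $(p, g)$ scores the similarity between $p$ and the most similar disease
  known to involve $g$, zeroed when below $\theta$
  (`buildPriorMatrix()`).
* **Normalization.** Both matrices are normalized symmetrically,
  $D^{-1/2} M D^{-1/2}$ with $D$ the diagonal of row sums. The update's
  linear operator then has spectral radius at most $(1-w)$, so the
  iteration contracts to a unique fixed point for any prior weight
  $w > 0$ — convergence is a theorem, not an observation. A row-stochastic
  alternative is selectable
  (`PropagationConfig(normalization = "row_stochastic")`).

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `theta` | 0.5 | similarity/prior filter threshold (unitless, $[0,1]$) |
| `priorWeight` | 0.6 | weight $w$ of the prior term in each update |
| `tol` | 1e-5 | MSD stopping threshold |
| `maxIter` | 1000 | safety cap; exceeding it warns, never silently stops |
| `normalization` | symmetric | degree normalization of both matrices |

The calibration $\theta = 0.5$, $w = 0.6$, MSD $\le 10^{-5}$ is the
published operating point of the method. One reading ambiguity is resolved
here explicitly: the 0.6 is bound to the **prior** term, since the parameter
"controls the relative importance of the prior information". The
complementary convention (0.6 on the network term) is reachable by setting
`priorWeight = 0.4`.

```{r worked}
net <- extendSelfLoops(GeneNetwork(data.frame(a = "g1", b = "g2")))
sim <- DiseaseSimilarityNetwork(matrix(1, 1, 1, dimnames = list("d1", "d1")))
prior <- buildPriorMatrix(data.frame(disease = "d1", gene = "g1"), sim, net)
scores(propagate(prior, sim, net)$scores)
```

This two-gene instance has the closed-form fixed point $(0.8, 0.2)$ at
$w = 0.6$, which the iteration reproduces; `propagateExact()` solves the
vectorized linear system directly for small instances and is used as a
cross-check in the test suite, never as the production path.

## Evaluation protocol

`crossValidate()` reproduces the method's evaluation design: associations
are partitioned into $k = 10$ near-equal folds; for each fold the hidden
associations are removed, **the prior is rebuilt from the remaining
associations only**, scores are propagated, and each hidden gene is ranked
genome-wide for its disease. Rebuilding the prior per fold is a deliberate
design choice (the protocol description is silent on it): without the
rebuild, the hidden pair's prior entry of 1 would leak the answer. The
leakage guard is a tested invariant — every hidden pair's rebuilt prior
entry is strictly below 1.

Two further conventions, both documented because the protocol leaves them
open:

* The queried disease's still-known training genes are excluded from the
  candidate list, so they cannot displace the hidden gene; ranking is
  otherwise genome-wide ("measured by ranks in the whole genome").
* Ranks use competition ranking (ties share the minimal rank) with
  alphabetical order among ties for byte-stable output.

Precision and recall at a rank cutoff $k$ follow the standard retrieval
definitions: an item is retrieved when its rank is at most $k$; precision is
the relevant fraction of retrieved items, recall the retrieved fraction of
relevant items. When nothing is retrieved, precision is reported as 1 (and
noted) so fold-averaged curves contain no NaN. Irrelevant items come from
three control constructions:

* **random** — $n$ genes sampled from the "unassociated genes" (network
  genes with no known association; unknown, not truly irrelevant);
* **genome-wide** — every unassociated network gene; necessarily the
  hardest control, since its pool contains any random draw, and a tested
  invariant checks genome-wide precision never exceeds random-control
  precision pointwise on the same instance;
* **linkage interval** — up to 50 genes upstream and 50 downstream of the
  hidden gene on its chromosome, mimicking a mapped susceptibility locus.
  Genes absent from the interaction network are skipped *without* counting
  toward the per-side quota (the alternative reading — count first, filter
  later — would make interval sizes depend on annotation coverage rather
  than on the locus), and the hidden gene itself is excluded.

Robustness is probed by `perturbNetworks()`: zero-mean Gaussian noise on a
random fifth of the off-diagonal similarity entries and on the interactions
among a random subset of genes, mirrored across the diagonal, clipped to
$[0,1]$, diagonals untouched. The noise standard deviation defaults to 0.1
— large enough to move similarity entries across the $\theta$ boundary
occasionally, small enough to represent measurement noise rather than data
replacement; the perturbed similarities pass through the $\theta$ filter
again because the pipeline only ever consumes filtered similarities.

## Local subnetwork discovery

`approximatePageRank()` and `sweepCut()` implement PageRankNibble. The push
approximation uses the lazy-walk convention — each push retains half of the
non-teleported mass at the node and spreads half over its neighbours — so
the in-test power-iteration oracle for exact personalized PageRank is
defined on the same lazy walk and the two agree as `epsilon` shrinks. At
termination every residual satisfies $r(u) < \varepsilon\,d(u)$, which is
asserted directly in the tests. The sweep orders the support by
degree-normalized mass and returns the prefix with minimum conductance
$\mathrm{cut}(S) / \min(\mathrm{vol}(S), \mathrm{vol}(\bar S))$; the full
vertex set is never a candidate. On the 6-node barbell (two triangles joined
by one edge) the minimum-conductance side is the seed's triangle at
conductance $1/7$ — a hand-checkable case frozen in the tests.

The discovery parameters (teleport 0.15, `epsilon` 1e-4, sizes 5–50, rank
cutoff 200) are package defaults, all configurable; no published values
exist for them. `discoverDiseaseSubnetworks()` filters candidate modules by
size and by the fraction of members ranking under the cutoff, and exports
member gene lists suitable for external enrichment services; enrichment
itself is out of scope.

## The synthetic benchmark

`generateModularInstance()` builds instances with exactly the structure the
method assumes, so every pipeline stage is testable without any data
download:

* gene modules as Erdős–Rényi blocks (`pIn = 0.3` within, `pOut = 0.01`
  between — a sharp but not caricatural modularity, average within-module
  degree ≈ 9 at the default module size of 30);
* disease clusters with similarity `simIn = 0.8` within and
  `simOut = 0.1` between, plus uniform jitter of ±0.05 so rank ties are
  rare, clipped to $[0,1]$; after the $\theta = 0.5$ filter the similarity
  is block-diagonal;
* each cluster matched to one module, with `assocPerCluster = 20` known
  associations per cluster.

Associations use distinct causal genes (a cluster's associations never
reuse a (disease, gene) pair and causal genes are distinct within the
cluster), and each causal gene is linked to **at least two** diseases of its
cluster whenever the counts allow. This multiplicity is essential, not
cosmetic: when an association $(d, g)$ is hidden, the method can recover it
only through the prior entry rebuilt from a *similar disease known for the
same gene* — that is the propagation principle itself. A generator whose
genes each belong to a single disease would make hidden associations
information-theoretically unrecoverable and would test nothing. With the
default counts (10 diseases, 10 causal genes, 20 associations per cluster)
every disease carries two associations and every causal gene two diseases;
it also mirrors real disease-gene catalogues, where a gene is typically
implicated in several phenotypically related disorders. The default of 20
associations per cluster also leaves 100 of the 150 genes unassociated, a
realistic pool for the random and genome-wide controls.

Two study conditions are fixed by design and verified end to end:

* **Recovery.** On the default instance (5 modules × 30 genes, 10
  diseases/cluster) with 10-fold cross-validation, the hidden gene ranks in
  the genome-wide top 10 in at least 80% of cases.
* **No-signal null.** With `pIn = pOut` and `simIn = simOut` below
  $\theta$, similarity filters to the identity and module labels carry no
  topological meaning; the hidden gene is then exchangeable with every
  unranked candidate and its normalized rank (rank divided by candidate
  count) is uniform — mean 0.5 within ±0.05 over ≥ 200 hidden pairs.

The generator emulates modular structure only. It does not reproduce the
heavy-tailed degree distribution of real interactomes, literature bias
(well-studied hub genes), the incompleteness and false-positive rate of
interaction data, or similarity matrices estimated from noisy text mining.
Passing the planted-structure tests therefore demonstrates correctness of
the machinery and recoverability under the model's own assumptions — not
performance on any real disease catalogue.

## Numerical choices and degenerate inputs

* **Stopping.** MSD between successive score matrices, threshold 1e-5;
  `maxIter` converts a non-contracting configuration into a loud warning
  with `converged = FALSE`, never a silent partial result.
* **Scale of tests.** The test suite exercises convergence on one hundred
  200 × 300 random instances and cross-validation on 50-disease × 150-gene
  modular instances — sizes chosen so the full suite completes in well
  under a minute while remaining two orders of magnitude above the
  hand-checkable examples. The real-data scale the method targets
  (≈ 5 000 diseases × 9 000 genes) is a dense-matrix desk computation and
  needs no special infrastructure.
* **Score range.** Prior scores live in $[0,1]$ by construction. Propagated
  scores stay within the prior's maximum on near-regular networks (and in
  every test instance), but symmetric normalization does not hard-bound
  them by 1 on very irregular graphs; values within 1e-9 of 1 are snapped
  to 1 to absorb rounding.
* **Ties and determinism.** Competition ranks with alphabetical tie order;
  every stochastic step (fold assignment, control sampling, generators,
  perturbation) is seeded and restores the caller's RNG state, so identical
  seeds give byte-identical outputs including on-disk files.
* **Degenerate inputs.** Zero-degree nodes are rejected by the normalizers
  by name (impossible after self-loop extension); conflicting duplicate
  similarity entries are an error, not an average, because silent averaging
  hides data corruption; an isolated seed without a self-loop cannot start
  a push; an all-zero PageRank vector cannot be swept; a fold that strips a
  disease of all similarity signal is permitted and reported, with scores
  falling back to network smoothing alone.

## Known limitations

* The propagation weights similarity contributions through global degree
  normalization; no per-disease renormalization of similarity weights is
  attempted between iterations (the scores are consumed as-is after
  convergence).
* Isolated proteins carry no propagation signal; they are retained in the
  gene universe (real interactomes contain dozens of isolated,
  disease-annotated proteins) but can only ever score through the prior.
* Identifier mapping between gene namespaces, parsing of the original
  disease/interaction databases, and enrichment analysis of discovered
  subnetworks are out of scope.
* Linkage-interval controls need an external gene coordinate table; the
  synthetic generator ships sequential coordinates that exercise the code
  path but not real gene density.
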