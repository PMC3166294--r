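# prioNet

Prioritizing candidate disease-causing genes by propagation over two
coupled heterogeneous networks: a disease phenotype-similarity network and
a protein-protein interaction (PPI) network.

## The problem and the method

Identifying the gene behind a disease phenotype is a needle-in-a-haystack
problem: a mapped locus or a whole genome offers hundreds to thousands of
candidates. Genes causing the same or similar diseases tend to lie close to
one another in the interactome, and phenotypic overlap between diseases
tracks genotypic overlap. prioNet exploits both regularities at once: the
association score of a disease-gene pair is defined as the weighted sum of
the association scores between the diseases similar to it and the gene's
network neighbours, and all pairs are solved simultaneously by an iterative
bilinear update.

With `S̃` and `Ã` the symmetrically degree-normalized disease-similarity
and self-loop-extended PPI matrices, `F₀` the prior association matrix
(known pairs = 1, otherwise the θ-filtered similarity to the most similar
disease known for the gene), and `w` the prior weight:

    F⁽ᵗ⁾ = (1 − w) · S̃ F⁽ᵗ⁻¹⁾ Ã + w · F₀ ,   F⁽⁰⁾ = F₀

iterated until the mean square deviation between successive iterates is
≤ `tol`. Defaults are the method's published operating point: θ = 0.5,
w = 0.6, tol = 1e-5. Symmetric normalization makes the update a contraction
for any w > 0, so convergence is guaranteed.

The package also provides:

* the full evaluation protocol — 10-fold cross-validation with per-fold
  prior rebuilding, three irrelevant control sets (random, genome-wide,
  linkage-interval), precision/recall at rank cutoffs, and Gaussian-noise
  robustness perturbation;
* PageRankNibble local clustering (push-approximated personalized PageRank
  plus a minimum-conductance sweep cut) to discover candidate disease
  subnetworks around known disease genes;
* a generator of modular synthetic benchmark instances emulating the
  coupled cluster structure the method assumes, so everything is testable
  without any data download;
* a command-line interface (`inst/scripts/prionet.R`) with subcommands
  `prioritize`, `crossval`, `nibble`, `simulate`, `perturb`.

## Worked example

```r
library(prioNet)

# a modular synthetic instance: 5 gene modules x 30 genes, 5 disease
# clusters x 10 diseases, 20 known associations per matched cluster
inst <- generateModularInstance(seed = 1)
inst
#> SyntheticInstance: 150 genes in 5 modules, 50 diseases in 5 clusters, 100 associations

net   <- extendSelfLoops(inst@network)
prior <- buildPriorMatrix(inst@associations, inst@similarity, net)
res   <- propagate(prior, inst@similarity, net)
res$report
#> ConvergenceReport: 3 iterations, final MSD 1.01e-06, converged

head(rankGenes(res$scores, "d001"), 5)
#>   gene     score rank
#> 1 g010 0.7386693    1
#> 2 g025 0.7221725    2
#> 3 g028 0.6465809    3
#> 4 g008 0.6401384    4
#> 5 g029 0.6365142    5
```

The top-ranked genes for disease `d001` are causal genes of its matched
module: their scores mix the similarity-derived prior (up to 0.8 through a
cluster-mate disease at similarity ≈ 0.8) with network smoothing over the
module. Cross-validation hides each association, rebuilds the prior without
it, and asks where the hidden gene ranks genome-wide:

```r
cv <- crossValidate(inst@network, inst@similarity, inst@associations,
                    control = "random", nControl = 30, seed = 1)
cv
#> prioNet cross-validation: 100 hidden associations, 10 folds, control = random
#>   hidden gene in top 10: 89.0%; median genome-wide rank: 7
cv$curve
#>   threshold  precision recall nRetrieved
#> 1         1 1.00000000   0.11        1.1
#> 2         5 1.00000000   0.36        3.6
#> 3        10 0.65860639   0.89       13.8
#> 4        50 0.09291808   1.00      108.3
#> 5       100 0.04826858   1.00      207.9
#> 6       300 0.03364055   1.00      298.0
```

89% of hidden genes return in the genome-wide top 10 of 150 genes; recall
at rank 10 is 0.89 while precision degrades as the 30 random control genes
(and, at larger cutoffs, everything) enter the retrieved set — the shape
the protocol is designed to expose.

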