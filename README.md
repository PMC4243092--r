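# MRFGeneRank

Guilt-by-association prioritization of candidate disease genes across
several biological networks at once, for computational biologists who
have a short list of known disease genes, one or more gene–gene networks
(protein–protein interaction, pathway co-existence, co-expression) and
protein-complex annotations, and want a ranked list of new candidates.

## The model

Every gene carries a binary label x<sub>i</sub> (disease-associated or
not). The joint labelling over all N genes and all K networks is an
Ising-type Gibbs distribution P(x | θ) ∝ exp(−U(x | θ)) with energy

```
U(x | θ) = − Σᵢ αᵢ xᵢ − Σₖ ( βᵏ N₁₀ᵏ + γᵏ N₁₁ᵏ + N₀₀ᵏ )
```

where N₁₁ᵏ, N₁₀ᵏ, N₀₀ᵏ count network k's edges with both, one, or
neither endpoint labelled 1; the 0–0 weight is fixed at 1, and the
per-gene field αᵢ is the log-odds of a protein-complex-derived prior
πᵢ. The conditional probability that gene i is associated, given all
other labels, is sigmoid of the local field

```
T(i) = αᵢ + Σₖ [ (βᵏ − 1) M₀ᵏ + (γᵏ − βᵏ) M₁ᵏ ]
```

with M₀ᵏ/M₁ᵏ its 0-/1-labelled neighbor counts. Known disease genes are
clamped to 1; the posterior of the rest is estimated by Gibbs sampling
while θ is re-estimated every sweep by a pseudo-likelihood binary
logistic regression of the current labels on the neighbor counts
(`runIMRF1`). `runIMRF2` adds a frozen-parameter prediction period, and
`runDeng` is the classical baseline that estimates θ once from known
genes only. Rankings use rank-percentile decision scores, evaluated by
leave-one-out cross-validation against disease genes of other classes
(`leaveOneOut`, `rocAuc`). A synthetic benchmark generator
(`makeBenchmark`) and an exact small-graph enumeration oracle
(`exactMarginals`) make every stage testable without database
downloads. The methods vignette
(`vignettes/mrf-gene-prioritization.Rmd`) documents the model,
parameter estimation, the field-anchoring modes and their stability,
and the generator's assumptions.

## A worked example

Simulate a genome-scale instance — a planted disease module of 60 genes
among 4000 (half revealed as known), one background network of mean
degree 10, 40 protein complexes — and rank the candidates:

```r
library(MRFGeneRank)

scenario <- makeBenchmark(nGenes = 4000, K = 1, edgeProb = 0.0025,
                          knownFraction = 0.5, nComplexes = 40, complexSize = 8,
                          seed = 1, truth = "planted", plantedSize = 60,
                          plantedDensity = 0.04)
scenario
#> BenchmarkScenario (seed 1): 4000 genes, 60 true positives (30 revealed),
#>   300 negative controls, K = 1

priors <- scenarioPriorBuilder(scenario)(scenario@knownGenes)
fit <- runIMRF1(scenario@collection, scenario@knownGenes, priors,
                SamplerConfig(seed = 11))
fit
#> SamplerResult (mode imrf1, alpha mode prior)
#>   4000 genes (30 known); mean free-gene posterior 0.227
#>   theta (averaged): alpha=-0.015 beta1=1.038 gamma1=2.075
```

The averaged edge weights say 1–1 edges are worth e^2.1 ≈ 8 times a 0–0
edge (γ̂₁ = 2.08) while mixed edges are near-neutral (β̂₁ ≈ 1) — the
sampler has learned that associated genes cluster. The top-ranked
candidates (known genes excluded) are dominated by genes whose complexes
contain only known genes of this class (prior ≈ 1):

```r
head(subset(rankingTable(fit), known_flag == 0), 6)
#>       gene known_flag    prior posterior decision_score
#> 2793 g2793          0 0.999999         1      1.0000000
#> 3235 g3235          0 0.999999         1      0.9997481
#> 1971 g1971          0 0.999999         1      0.9994962
#> 3492 g3492          0 0.999999         1      0.9992443
#> 728  g0728          0 0.999999         1      0.9989924
#> 2682 g2682          0 0.999999         1      0.9987406
```

How well are the 30 *hidden* module genes recovered against the 3940
true negatives?

```r
hidden <- setdiff(which(scenario@truth == 1), scenario@knownGenes)
zeros  <- which(scenario@truth == 0)
free   <- which(!fit@known)
score  <- decisionScores(posterior(fit)[free])
names(score) <- free
tab <- data.frame(label = c(rep(1, length(hidden)), rep(0, length(zeros))),
                  score = score[as.character(c(hidden, zeros))])
rocAuc(tab)
#> RocResult: 3970 thresholds, AUC = 0.7603
```

An AUC of 0.76 means a hidden module gene outranks a random negative
three times out of four, from 30 known genes and network structure
alone.

A thin command-line front end over the same functions ships in
`inst/scripts/imrf.R` with subcommands `simulate`, `build-net`, `rank`
and `evaluate`; every output carries a JSON manifest (input checksums,
effective configuration, seed) from which it can be regenerated.

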