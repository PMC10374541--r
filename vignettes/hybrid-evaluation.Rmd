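---
title: "Evaluating hybrid performance over a half diallel with additive + dominance GBLUP"
author: "diallelGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating hybrid performance over a half diallel with additive + dominance GBLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelGS)
```

## The problem

Hybrid breeding exploits heterosis: crossing two inbred lines often yields
offspring that outperform both parents. For a panel of $N_0$ inbred parents a
half diallel mating design defines $N_1 = \binom{N_0}{2}$ candidate hybrids —
10,011 for 142 parents — far more than can be field-tested. Genomic selection
replaces most of that testing with prediction: a training set of phenotyped,
genotyped hybrids calibrates a model that then scores every candidate cross
from marker data alone, and candidates are ranked by predicted performance,
combining ability and heterosis.

`diallelGS` implements this workflow end to end: marker quality control on
the parental panel, in-silico synthesis of all F1 genotypes, an additive +
dominance GBLUP model fitted by a Bayesian Gibbs sampler, GEBV prediction for
the full diallel, and GEBV-based general/specific combining abilities and
mid-/better-parent heterosis.

## The model

Phenotypes of the $n$ training hybrids follow

$$ y = 1_n\mu + g_A + g_D + e, \qquad
   g_A \sim N(0, \sigma_A^2 K_A),\;
   g_D \sim N(0, \sigma_D^2 K_D),\;
   e \sim N(0, \sigma_e^2 I_n), $$

with genomic relationship matrices $K_A = X_A X_A^\top / p$ and
$K_D = X_D X_D^\top / p$ built from $p$ standardized marker scores. Raw
additive scores are $-1/0/+1$ for the minor homozygote, heterozygote and
major homozygote; raw dominance scores are $1$ for the heterozygote and $0$
otherwise. Given variance components, the intercept (a BLUE) and the two
BLUP vectors solve Henderson's equations

$$ \begin{bmatrix} n & 1^\top & 1^\top \\
   1 & I + K_A^{-1}\lambda_A & I \\
   1 & I & I + K_D^{-1}\lambda_D \end{bmatrix}
   \begin{bmatrix} \hat\mu \\ \hat g_A \\ \hat g_D \end{bmatrix} =
   \begin{bmatrix} 1^\top y \\ y \\ y \end{bmatrix}, \qquad
   \lambda_A = \sigma_e^2/\sigma_A^2,\;
   \lambda_D = \sigma_e^2/\sigma_D^2. $$

Genomic heritability is $h^2 = (\sigma_A^2 + \sigma_D^2) /
(\sigma_A^2 + \sigma_D^2 + \sigma_e^2)$. BLUPs carry to the $N_1$ candidate
hybrids through the cross-GRMs between breeding and training populations,
$\hat g_A^{(bp)} = K_A^{(bp)} K_A^{-1}\hat g_A$ (likewise for dominance), and
the GEBV of a candidate is $\hat\mu + \hat g_A^{(bp)} + \hat g_D^{(bp)}$.

Combining abilities derive from the decomposition
$\hat g_A^{(ij)} = GCA_i + GCA_j$ and $\hat g_D^{(ij)} = SCA_{ij}$. With
$\bar G_A^{(i)}$ the mean additive BLUP over the $N_0 - 1$ hybrids of parent
$i$ and $\bar G_A$ the overall mean,

$$ \widehat{GCA}_i = \frac{(N_0-1)\bar G_A^{(i)}}{N_0-2}
   - \frac{N_0 \bar G_A}{2(N_0-2)}, \qquad
   \widehat{MPH}_{ij} = \widehat{SCA}_{ij}, \qquad
   \widehat{BPH}_{ij} = \widehat{SCA}_{ij} -
   \lvert \widehat{GCA}_i - \widehat{GCA}_j \rvert. $$

One genuine ambiguity sits in the overall mean $\bar G_A$: a literal double
sum over ordered pairs $(i, j\neq i)$ divided by $N_1$ counts every unordered
hybrid twice and therefore doubles $\bar G_A$. `gcaFromAdditive()` takes the
mean over the $N_1$ unordered hybrids, each counted once, because only that
reading makes the estimator invert the decomposition exactly: feeding
$\hat g_A^{(ij)} = GCA_i + GCA_j$ back in recovers the GCA vector to machine
precision, and the estimator coincides with the least-squares projection of
the additive BLUPs onto parental main effects (both are property-tested).
Under the ordered-sum reading every GCA would shift by a constant — rankings
would survive, better-parent heterosis would not.

## The Gibbs sampler

Variance components and location effects are estimated jointly by a Gibbs
sampler over the blocks of Henderson's system:

1. initialize $\mu = \bar y$, $g_A = g_D = 0$, $\sigma_e^2 = 1$,
   $\sigma_A^2 = \sigma_D^2 = 0.5$;
2. draw each location block $g_i \sim N\!\big(C_{ii}^{-1}(\gamma_i -
   C_{i,-i} g_{-i}),\; \sigma_e^2 C_{ii}^{-1}\big)$, sequentially for the
   intercept, additive and dominance blocks;
3. form residuals $e = y - 1\mu - g_A - g_D$ and draw
   $\sigma_e^2 = (e^\top e + S^* v^*) / \chi^2_{n+v^*}$,
   $\sigma_A^2 = (g_A^\top K_A^{-1} g_A + S^* v^*) / \chi^2_{n+v^*}$,
   $\sigma_D^2 = (g_D^\top K_D^{-1} g_D + S^* v^*) / \chi^2_{n+v^*}$;
4. refresh $\lambda_A$, $\lambda_D$ and repeat for $K$ iterations; discard
   the first $0.9K$, average the rest; run $M$ independent chains and
   average the per-chain means.

Defaults are $K = 5000$, $M = 5$, $v^* = 5$ and $S^* = 0.5V$ with $V$ the
sample variance of the phenotypes. The 90% burn-in with a 10% averaging
window is unusually long by MCMC convention but is kept verbatim as the
algorithm's definition; `burninFraction` is configurable. Chain $m$ uses
seed `seed + m`, so a run is bitwise reproducible and chains are mutually
independent.

### Numerical implementation

The inverse GRMs are fixed across iterations — only the scalars
$\lambda_A, \lambda_D$ move. Writing $K^{-1} = U\,\mathrm{diag}(s)\,U^\top$
once per fit turns every conditional block draw into two $n \times n$
matrix–vector products,

$$ g = U\Big[ \frac{U^\top r}{1 + \lambda s} +
   \sqrt{\sigma_e^2}\, \frac{z}{\sqrt{1 + \lambda s}} \Big],
   \quad z \sim N(0, I), $$

and the quadratic form $g^\top K^{-1} g$ into a diagonal sum in the same
basis. This is an exact reformulation, not an approximation: the chain's
distribution is identical to refactorizing $C_{22}$, $C_{33}$ every
iteration, at $O(n^2)$ instead of $O(n^3)$ per iteration. The exported
`sampleLocationBlock()` keeps the direct Cholesky form and serves as the
independent check of the conditional distribution in the test suite.

Dominance GRMs of hybrid sets are frequently rank-deficient (the additive
scores of a half diallel span at most $N_0$ dimensions, and dominance
columns are sparse), so the paper-level $K^{-1}$ cannot be taken for
granted. `stabilizedInverse()` attempts a Cholesky inverse and, on failure,
adds a ridge of $10^{-6} \times \mathrm{mean\,diag}$, doubling it up to ten
times; the ridge actually used is recorded in the `KinshipSet` and shown by
`show()`. A bounded, reported ridge was preferred over pseudo-inversion
because it keeps the downstream equations exact for a well-defined
(slightly regularized) kernel and makes conditioning problems visible
instead of silent.

Other numerical choices: the full $(2n+1)$ Henderson system is solved by
one Cholesky factorization, never by explicit inversion; standardization
uses the $n-1$ sd divisor, which makes the mean GRM diagonal exactly
$(n-1)/n$; tiny negative quadratic forms from floating-point cancellation
are clamped at zero while genuinely negative ones raise an error; exact
ties in ranking are broken lexicographically by parent pair, and the
major-allele tie at frequency $0.5$ imputes dosage 0 with a warning, so
every code path is deterministic.

## Standardization reference and cross-population consistency

Carrying BLUPs through $K^{(bp)} K^{-1}$ requires the square and cross GRMs
to live on one scale. The package therefore determines major/minor
orientation and column statistics on a single reference row set — by default
the combined training + breeding hybrids in `evaluateHybrids()` — and reuses
those statistics for all rows. Inside cross-validation the reference is the
training rows of each fold only, which is the stricter, leakage-free choice:
orientation, the zero-dominance filter, constant-column removal and
standardization are all recomputed per fold, so a held-out hybrid never
influences its own predictor.

## The synthetic-data generator

`simulateParents()` draws fully homozygous biallelic panels: per marker a
minor-allele frequency $q \sim U(0.05, 0.5)$ by default, each parent
carrying the dosage-2 homozygote with probability $1 - q$, independently
across parents and markers; monomorphic columns are redrawn.
`synthesizeHybrids()` then gives exact F1 genotypes (homozygote ×
homozygote arithmetic), and `simulatePhenotypes()` draws from the model
above through a PSD-safe eigendecomposition square root (negative
eigenvalues clipped at zero).

What the generator emulates: an inbred parental panel with a realistic MAF
spectrum, the exact diallel covariance structure between relatives, and
phenotypes whose genetic architecture matches the fitted model. What it does
not emulate: linkage disequilibrium along chromosomes (markers are
independent), population structure and heterotic groups, genotyping error,
epistasis, and genotype-by-environment variation. Passing tests therefore
demonstrate that the estimators recover the data-generating process they
assume — a necessary internal-consistency property — not that real crops
meet those assumptions.

Default study conditions in the tests mirror the method's intended regime:
parameter recovery uses 21 parents (210 training hybrids), 500 markers and
generating components $(0.4, 0.2, 0.4)$, i.e. $h^2 = 0.6$ with a 2:1
additive:dominance ratio; the simulation harness runs the
pumpkin-parameterized scenario $(0.306, 0.159, 0.111)$ on 119 training
hybrids. Sampler lengths in tests and the acceptance script are desk-scale
($K = 2000$, $M = 2$–$3$; 20–100 replicates) — chosen so the whole suite
runs in minutes on one core — while the package defaults stay at the
algorithm's $K = 5000$, $M = 5$, and survey-scale replication (3000 sets)
remains one argument away.

## Known limitations

* The sampler's posterior means inherit the documented behaviour of this
  prior/burn-in combination: variance components, and hence $h^2$, drift
  somewhat upward on small training sets (the simulation harness makes the
  bias visible per component).
* Repeated phenotype records per hybrid are deliberately rejected rather
  than averaged silently; multi-year data must be pre-adjusted upstream.
* Heterozygous calls in a parental panel are an error by default because
  hybrid synthesis assumes fully inbred parents; the permissive flag
  converts them to missing for imputation, which is only sensible at low
  residual heterozygosity.
* LD-based marker pruning, phasing and SNP calling are out of scope;
  genotypes arrive as dosage matrices or biallelic VCF.

## A compact walk-through

```{r example, eval = FALSE}
parents <- simulateParents(12, 400, seed = 1)
frame <- halfDiallel(parents)                 # 66 candidate hybrids
hyb <- synthesizeHybrids(parents, frame)
coded <- standardizeScores(dropZeroDominance(codeMarkers(hyb)))
kin <- makeKinship(coded, trainingRows = seq_len(nHybrids(frame)))
y <- simulatePhenotypes(kin, c(A = .4, D = .2, e = .4), mu = 2, seed = 2)

res <- evaluateHybrids(parents, y, config = GibbsConfig(nIter = 2000,
                                                        nChains = 3))
varianceComponents(res$fit)
rankHybrids(res$evaluation, topK = 5)
rankParents(res$evaluation, topK = 3)
```
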