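---
title: "Simulating complex traits and benchmarking genomic prediction machines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating complex traits and benchmarking genomic prediction machines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`gpbench` studies a practical question in animal and plant breeding: when a
quantitative trait is controlled by additive gene action, by dominance, or by
two-locus epistasis, which prediction machines recover genetic merit best
from SNP genotypes? The package provides the full experimental loop —
synthetic genotype panels, marker quality control, trait simulation with a
controlled variance partition, six prediction methods behind one `predict`
contract, and replicated cross-validation with shared folds.

Real dairy-cattle panels of the kind this experiment emulates (tens of
thousands of bulls genotyped at ~60k SNPs, with fertility evaluations as the
phenotype) are access-restricted, so the package generates synthetic stand-in
panels and works at a desk scale of `n = 2,000` individuals and `m = 5,000`
SNPs by default; every dimension is configurable up to the full scale.

## Genotype generator

Each SNP is assigned an expected allele frequency drawn uniformly from
`mafRange` (default `(0.05, 0.5)`), with the coded "A" allele oriented at
random so that the 0/1/2 code does not automatically count the minor allele.
Haplotypes are generated by a Gaussian-copula first-order Markov chain within
LD blocks (default 50 SNPs, 10 chromosomes): a latent AR(1) series with
correlation `withinBlockCorr` (default 0.7) is thresholded at each SNP's
frequency. Genotypes are the sum of two independent haplotypes, so each SNP
is in Hardy–Weinberg proportions before a small missing-data rate (default
1%) is injected uniformly at random.

What this emulates: a realistic MAF spectrum, block-local LD decaying with
distance, HWE at the SNP level, and sporadic missingness. What it does not
emulate: long-range LD and pedigree/family structure, selection signatures,
allele-frequency spectra skewed toward rare variants, and genotyping error
that violates HWE. Consequently, passing benchmarks here speak to method
behaviour under controlled architectures, not to absolute accuracies on any
real panel — on real data, family structure typically inflates all methods'
accuracies, and their ranking can compress.

The one-parameter block-LD model is deliberately minimal: it is the simplest
structure under which "clustered QTN" (three adjacent causal SNPs per
cluster) are a meaningfully different condition from randomly placed QTN.

## Quality control

`applyQC()` mirrors standard panel QC: SNPs are dropped when the minor
allele frequency is below 0.05, the missing rate exceeds 0.05, the exact
Hardy–Weinberg test p-value falls below 1e-6, or the SNP maps to an excluded
chromosome (default `"X"`). The HWE test is the exact (Wigginton-style) test
rather than a chi-square, matching the tool chain used for panels of this
kind. Surviving missing genotypes are imputed to the SNP's rounded mean code
— downstream fitters need complete matrices, and at ≤5% missingness the
choice of single-value imputation is immaterial; the pre-imputation mask is
retained, and all QC statistics are computed on originally observed
genotypes, which makes QC idempotent.

## Trait simulation

Causal loci (QTN) are placed either uniformly at random or as clusters: one
third of the QTN are sampled as cluster cores and each core contributes its
two immediate map neighbours. When the QTN count is not divisible by three,
random singletons top up the set — the count is always exact.

Effect distributions: additive `a ~ N(0, 1)`; dominance
`d ~ N(0, sd = 0.5)` (the 0.5 is a standard deviation); allele-substitution
effects `alpha = a + d(q - p)`. Dominance draws are used as-is — no
magnitude constraint relative to `a` is imposed, so heterozygote advantage
arises from the draw itself. Every QTN interacts with the three QTN that
follow it in genome order, giving `3·nQTN − 6` pairs (294 at 100 QTN, 2994
at 1000); each pair carries four epistatic effects (A×A, A×D, D×A, D×D)
with gamma-distributed magnitudes (shape 0.1, scale 10 — a long-tailed
distribution in which a few pairs dominate) and random signs. Interaction
covariates are Hadamard products of the additive (0/1/2) and dominance
(0/1/0) codings, so A×A takes values {0,1,2,4}, A×D and D×A {0,1,2}, and
D×D {0,1}.

### Variance calibration

The effect distributions above fix the *shape* of the genetic signal but not
the variance partition. To guarantee both, each genetic component is rescaled
by a constant so its empirical variance equals the targeted fraction of a
unit phenotypic variance, and residuals are drawn with
`sigma2_e = 1 − (h2_a + h2_d + h2_I)`. Default targets: purely additive
traits 0.30/0/0; non-additive traits 0.10/0.10/0.50 at 100 QTN and
0.02/0.02/0.68 at 1000 QTN (broad sense 0.70 in both cases). The raw draws
remain available in the returned `EffectSet`.

Components are *not* orthogonalized: the realized partition reports raw
ratios `Var(component)/Var(phenotype)`, and the broad-sense entry is
`Var(total genetic)/Var(phenotype)`. Because components built from the same
loci covary within a finite sample (the additive–dominance covariance has a
small positive expectation; the additive–epistatic covariance is mean-zero
but heavy-tailed across seeds), single-seed partitions scatter around the
targets by a few hundredths; averages over ~10 seeds sit within ±0.03 of
the targets at `n = 2,000`.

Every stochastic stage (placement, each effect class, epistatic signs and
magnitudes, residuals, fold assignment) consumes its own sub-seeded RNG
stream derived from a master seed, so one component can be varied while the
others stay fixed — in particular, switching placement from clustered to
random leaves the effect draws untouched.

# Prediction machines

All six methods train on the observed phenotype and expose
`predict(model, codes)` returning one deterministic value per row.

**GBLUP.** `y = 1·mu + g_A + e`, `g_A ~ N(0, G sigma2_g)` with
`G = ZZ'/m` from centered, standardized codes. The desk-scale default is the
closed-form solve at a fixed ratio `lambda = (1−h2)/h2`, with `y` centered
at the plain training mean; this makes GBLUP algebraically identical to
ridge regression on markers with penalty `m·lambda`, which the test suite
exploits as an oracle. A Gibbs mode samples the mean, the orthogonal
regression coefficients (after an eigendecomposition of `G`) and both
variance components under scaled-inverse-chi-square priors; desk-scale
chains are (6,000 iterations, 1,000 burn-in, thin 5) against the full-scale
(100,000 / 10,000 / 10) protocol. Test-set predictions use the
conditional-expectation map `G_new,train (G + lambda I)^{-1}(y − mu)`,
carried in marker space.

**Bayes B.** Marker-effect regression with a two-component mixture prior:
each marker is null with probability `pi` (default 0.95) or carries a
normal effect whose variance has a scaled-inverse-chi-square prior
(`nu = 5`), i.e. a scaled-t prior marginally. The single-site Gibbs sampler
updates indicators from the marginal likelihood ratio with the effect
integrated out. The prior scale `s2` is solved so the prior genetic variance
of included markers equals half the phenotypic variance — a transparent
default for internals that reference implementations leave unstated; `pi`
sensitivity is exposed in the config.

**Random forest / gradient boosting.** Backed by `ranger` and `xgboost`
(single-threaded), at the tuned reference settings: 500 trees,
`mtry = min(2000, m)`, node size 5; learning rate 0.10, depth 3, 80%
subsampling. The "20% not bagged" early-stopping rule is operationalized as
a fixed 20% holdout with a 50-round patience — per-iteration out-of-bag
stopping is implementation-specific, while a fixed holdout is reproducible.

**MLP / CNN.** Hand-written feed-forward networks trained by mini-batch SGD
with momentum 0.5, learning rate 0.01 and L2 weight decay 1e-5, matching
the tuned reference architectures: MLP 64→32 hidden units (ReLU, then
softReLU = softplus `log(1+e^x)`), dropout 0.1/0.1, batch 32; CNN with 16
filters (window 5, stride 3, ReLU), max-pool (2/2), dropout 0.3, FC-32
softplus, dropout 0.3, FC-1 softplus, linear output, batch 64. The two CNN
dropout layers sit after the pooling layer and after the 32-unit layer.
Inputs are z-scored per column (gradient methods need scaled inputs; trees
see raw 0/1/2 codes, being scale-invariant), and the response is
standardized internally and back-transformed. Output-layer weights start at
zero so an untrained network predicts the response mean. Per-epoch
train/validation MSE curves are retained for overfitting inspection.
Training is single-threaded with fixed seeds; identical seeds give
bit-identical runs.

# Evaluation protocol

`makeCVFolds()` draws stratification-free partitions (fold sizes within one
of each other), independently per replicate; one plan is shared by every
method, so all methods see identical train/test splits. The default
simulation protocol is 5 replicates × 5 folds. On simulated traits,
predictions are scored against the **total** genetic value (additive +
dominance + epistatic) — the switch `truthTarget = "phenotype"` reproduces
real-data-style scoring instead. Scoring against the total rather than the
additive-only genetic value is a deliberate choice: under non-additive
architectures it measures how much of the full genetic signal each machine
captures. Predictor sets: `"causal"` (exactly the QTN columns — the
idealized setting where causal loci are known) or `"markers"` (QTN columns
excluded entirely, so prediction rides on LD). Constant prediction vectors
yield a flagged `NA` correlation record rather than aborting a run, and
per-record failures are surfaced, never silently dropped. Summaries report
means and 95% t-intervals over replicate means, not fold-level records,
respecting the dependence between folds of one replicate.

# Numerical choices and degenerate inputs

- `G` receives a 1e-8 diagonal jitter before inversion (positive
  semi-definite up to rounding).
- Eigenvalues below 1e-10 are dropped in the Gibbs reparameterisation.
- The exact HWE test uses a midpoint-anchored probability recurrence
  (numerically stable at large counts); monomorphic SNPs return p = 1 by
  convention; the plain (not mid-p) test is used.
- Zero-variance feature columns are rejected by the GRM/GBLUP (monomorphic
  post-QC columns cannot occur) and guarded in the network scalers.
- Max-pool ties route the gradient to the first element; the pooling
  implementation supports the reference window-2/stride-2 geometry.
- Gamma-magnitude epistatic draws make the epistatic component heavy-tailed
  by design; the calibration rescales realized components, so the partition
  holds regardless.

# Desk-scale protocol sizes

The packaged tests and the acceptance script exercise the pipeline at sizes
chosen for a single CPU: panels of 2,000 × 5,000 for trait-calibration
checks; benchmark runs in causal-predictor mode (so feature counts are the
QTN counts) with `deskConfigs()` — closed-form GBLUP, 3,000-iteration
Bayes B chains, 200-tree forests, 40/24 network epochs; and 5 × 5
cross-validation for the method-ranking scenarios (the 1000-QTN
forest-degradation comparison uses two replicates of the same plan, with
100-tree forests in both arms). The benchmark presets estimate the Bayes B
mixture weight from the data rather than fixing it, which matches how the
reference samplers for this model family treat the null probability and is
essential in causal-predictor mode, where a high fixed null probability
would contradict the known design. These
are the package's desk-scale choices; full-scale settings are reachable
through the config constructors.

# Known limitations

- The LD model is block-local; methods that exploit long-range LD structure
  are not differentiated.
- Only two-locus epistasis is simulated; higher-order interactions and
  G×E are out of scope.
- The Bayes B hyperpriors are declared package defaults, not estimates of
  any reference implementation's internals.
- The generator's missingness is completely at random; informative
  missingness would interact with the imputation rule.
- Closed-form GBLUP uses a fixed variance ratio rather than REML; use the
  Gibbs mode when the ratio must be learned.
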