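---
title: "Additive-dominance encodings and boosted genomic prediction: models and methods"
author: "twonp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive-dominance encodings and boosted genomic prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twonp)
```

# The problem

In hybrid breeding programs, inbred lines are crossed to a small panel of
testers and the resulting test-cross hybrids are evaluated in multi-year,
multi-location trials. Genomic prediction ranks untested hybrids from
genome-wide SNP dosages. Classical GBLUP does this with a linear mixed
model whose genetic covariance is a genomic relationship matrix; it is
well calibrated for additive effects but treats additive and dominance
components as independent kernels and ignores higher-order interactions.
Gradient-boosted tree ensembles can represent interactions freely but see
only raw dosages, with no structural hint of where additive and dominance
signal lives.

`twonp` implements a hybrid of the two cultures. The marker matrix
$M \in \{0,1,2\}^{n \times m}$ (reference-allele counts) is transformed
into two quantitative-genetics encodings:

* the **additive-centered matrix** $Z = M - 2p$, column-centered by twice
  the allele frequency $p_i$ at each locus;
* the **dominance-deviation matrix** $W$, the Vitezica coding that assigns
  $-2p_i^2$, $2p_iq_i$ and $-2q_i^2$ to dosages 0, 1 and 2
  ($q_i = 1 - p_i$).

Their concatenation $G_{2NP} = [Z \mid W]$ — the **2NP matrix**, with
twice as many columns as loci — is the feature input to a leaf-wise
gradient-boosted regression ensemble, $y = f(G_{2NP}) + e$. The trees can
split on additive and dominance coordinates of the same locus and on
combinations across loci, so additive, dominance and epistatic (AA, AD,
DD) structure is all reachable without materializing interaction columns.
The classical baselines are retained: single-kernel GBLUP on
$A = ZZ'/\sum_i 2p_iq_i$ (VanRaden scaling) and two-kernel GBLUP adding
$D = WW'/\sum_i 4p_i^2q_i^2$.

A note on the additive scaling: the denominator is implemented as
$\sum_i 2p_i(1-p_i)$, the VanRaden form. It is positive for every
polymorphic locus and is the unique scaling that makes the mean diagonal
of $A$ approach 1 under Hardy–Weinberg proportions (checked by
simulation in the test suite).

# Workflow and data contracts

Genotypes enter as biallelic VCF (GT field only; dosage counts the REF
allele) or as a delimited matrix with locus ids in the header and
individual ids in the first column. Hybrid genotypes are built from
parental dosages as the cross expectation $(g_1 + g_2)/2$ — exact for
fully inbred parents, flagged as fractional otherwise. Missing genotypes
are preserved at I/O time and imputed to the column mean $2\hat p_i$ only
when an encoding is built, so GBLUP and the tree learner see identical
inputs. Loci with minor allele frequency below the threshold (default 1%)
are removed; a locus exactly at the threshold is retained.

Allele frequencies for the encodings are computed once from **all**
genotyped individuals, training and candidates together, because
candidate genotypes are always available at prediction time in genomic
selection; a train-only mode (`trainOnlyFreq`) exists for strict
separation studies. The dominance coding of a fractional expected dosage
interpolates linearly between the flanking integer codes, which equals
the Mendelian expectation for half-integer dosages from one heterozygous
parent (the mixture of two adjacent genotype classes); for the
dosage-1 offspring of two heterozygous parents — a three-class mixture —
it returns the heterozygote code, a deliberate simplification at dosage
level. $W$ is not re-centered after coding: the Vitezica columns are
mean-zero only under exact Hardy–Weinberg proportions, and re-centering
would break the closed-form relation between $W$ and $D$; test-cross
populations deviate from HWE by design, and we treat that deviation as
part of the signal.

Phenotypes follow the two-step route standard for large trial series:
within each environment (year × location), a fixed model
`value ~ hybrid + replicate` screens records with |standardized residual|
above 3 (configurable; the threshold is the common reading of the usual
outlier-screening recommendation) and then yields stage-1 hybrid BLUEs;
stage 2 combines environments with hybrid fixed and field location
random, fitted by the package's own REML machinery. Stage 2 runs per year
by default, because the temporal validation schemes need year-resolved
responses; a pooled mode serves the k-fold scheme.

# Variance components and GBLUP

`remlFit()` maximizes the restricted likelihood of
$y = Xb + \sum_k u_k + e$, $u_k \sim N(0, \sigma_k^2 K_k)$.

* **One kernel** is solved by spectral profiling: after projecting out the
  fixed effects, the kernel is eigendecomposed once and the restricted
  likelihood becomes a one-dimensional function of the variance ratio
  $\lambda = \sigma_a^2/\sigma_e^2$, scanned on a coarse grid over
  $\log\lambda \in [-18, 18]$ and refined by Brent optimisation. The
  boundary $\lambda \to 0$ is an explicit candidate.
* **Two kernels** use EM-REML: convergence when the relative
  log-likelihood change falls below $10^{-8}$, at most 500 iterations,
  components floored at $10^{-10}\,\mathrm{var}(y)$. EM is monotone and
  boundary-stable, which matters here because dominance components are
  routinely near zero; the cost (one Cholesky per iteration) is modest at
  the population sizes this package targets. Non-convergence is an error
  carrying the trace, never a silent result.

Kernels with a slightly negative smallest eigenvalue (numerical
round-off, common after subsetting to records with repeated hybrids)
receive a diagonal jitter of $10^{-8}\times$ mean diagonal, reported via
a message. An identically zero kernel is dropped from estimation and its
component reported as exactly zero. Fixed effects in genomic prediction
runs are intercept-only, since the two-step BLUEs have already absorbed
the design effects.

Heritabilities are reported from the fitted components: $h^2 = V_a/V_p$,
$H^2 = (V_a + V_d)/V_p$, $d^2 = V_d/V_p$ and $PDV = V_d/(V_a+V_d)$, with
$V_p = V_a + V_d + V_e$. This decomposition is self-consistent by
construction ($H^2 = h^2 + d^2$ exactly); reported tables that mix
estimates from different model fits will not share that property, which
is why the package always reports all four from a single two-kernel fit
(an additive-only $h^2$ is available from the single-kernel fit when
wanted).

Prediction for unphenotyped individuals uses the kernel extension
$\hat u_{test} = \sigma_k^2 K_{test,train} V^{-1} (y - X\hat b)$. For a
single additive kernel this is algebraically identical to ridge
regression on $Z$ with penalty $\lambda = V_e \cdot c / V_a$ (where $c$
is the GRM denominator), an identity the test suite checks to $10^{-6}$.

# The boosted learner

The ensemble is a leaf-wise, histogram-based gradient-boosted regression
forest (squared-error objective), run single-threaded and seeded so that
results are bit-reproducible. Eight hyperparameters are tuned: number of
trees (100–2000, log), learning rate (0.005–0.3, log), maximum leaves
(8–256, log), minimum samples per leaf (5–100), feature and row
subsampling fractions (0.3–1 and 0.5–1), and L1/L2 penalties (0–10).
These defaults are standard ranges for populations of $10^2$–$10^3$
individuals and $10^3$–$10^4$ features, and every bound is overridable;
analyses at reduced problem sizes (the acceptance script, several tests)
narrow the tree count to 50–400 to match their smaller n and m.

Tuning is sequential model-based optimisation: a Latin-hypercube initial
design covering roughly a third of the budget, then a Gaussian-process
surrogate (squared-exponential kernel on the unit cube, lengthscale set
from the median pairwise distance of evaluated points, fixed observation
noise) with expected-improvement acquisition over a random candidate set.
The default budget is 20 iterations scored by 5-fold inner
cross-validated MSE; the inner folds are drawn once per tuning run from
the seed, which the cross-validation driver derives from the outer fold
index — repetitions are independent but reproducible. The optimizer is
deliberately small and fully deterministic given its seed; with budgets
of tens of evaluations a GP surrogate with fixed hyperparameters is
competitive with more elaborate schemes, and determinism is worth more
here than the last few percent of tuning efficiency.

**Leakage guard.** Fold plans carry test ids; `tuneHyperparameters()` and
`fitBoosted()` refuse any feature row whose id is flagged as test by the
active fold (`forbiddenIds`), and the benchmark driver always passes the
fold's test ids down. Supplying a test row is a hard error, not a
warning.

# Attribution

Feature attributions are exact path-dependent TreeSHAP, implemented in
compiled code in double precision over the parsed tree structure, with
the per-tree expected value (cover-weighted leaf mean) in the bias
column. Predictions are likewise reconstructed in double precision by
summing leaf values, so the local-accuracy identity — attributions plus
bias equal the prediction — holds to ~$10^{-12}$ for every row rather
than to the single-precision tolerance a float32 backend provides. The
backend's own attribution routine serves as an independent cross-check
in the test suite (agreement to $10^{-4}$, the float32 scale), and a
hand-derived two-leaf stump provides a closed-form oracle.

Importance is the mean absolute attribution over the evaluation rows —
by default the training set of the fold, since attribution on the test
set would mix model explanation with generalisation error; this is
configurable by passing any row set. Block aggregation sums importances
within the additive and dominance halves of the 2NP matrix and reports
each block's share of the total; shares sum to 1 whenever any
attribution is nonzero. The top-k ranking (default 20) breaks ties by
original column order. SHAP interaction values are deliberately out of
the default pipeline: they are expensive and, at trial-scale n, rarely
conclusive. Attributions describe the model, not causal locus effects.

# Validation schemes and metrics

Five fold plans share one contract (disjoint train/test, non-empty test):

* **LOYO** — one fold per year, test = that year.
* **Rolling window** — train on `window` (default 3) consecutive years,
  test the next; advance by one year.
* **k-fold** — random partition into k = 5 folds, 10 repetitions.
* **Tester CV0** — per repetition the test-year testers are partitioned
  into $\lceil 1/\mathrm{frac} \rceil$ disjoint groups (5 at the default
  20%); each fold tests the test-year hybrids of one group. Training is
  all earlier-year records, *including* the held-out testers' own earlier
  hybrids. Test-year hybrids of other testers are not added to training.
* **Tester CV00** — as CV0, but every record of a held-out tester is
  removed from training across all years.

Partitioning the testers (rather than resampling 20% independently per
fold) is a design choice: it makes the five folds of a repetition
disjoint and every tester tested exactly once per repetition, mirroring
the k-fold structure.

Accuracy is the Pearson correlation between observed and predicted
values. Ranking quality is **selection efficiency**: with $k$ selected,
overlap $I$ between observed and predicted top-$k$ sets and chance
overlap $C = k^2/n$,
$$\mathrm{SE} = \frac{I - C}{k - C},$$
the chance-corrected coincidence index — 1 for perfect selection, 0 in
expectation under random ranking. A variant that divides by $(n - C)$
instead is available (`literalN = TRUE`); its maximum at 20% intensity is
about 0.17, so the default is the form whose scale matches reported
selection-efficiency values in the field. Selection takes the top
fraction by default, with a per-trait direction switch for traits where
low values are desirable. Ties are broken by stable id order, which makes
a constant predictor behave like a fixed permutation (SE ≈ 0 in
expectation).

# The simulator

`simulatePopulation()` draws fully inbred parents (dosage 0/2, locus
frequencies Uniform(0.05, 0.95)), crosses every line to the testers in a
sliding year assignment (so testers turn over but consecutive years
overlap, as in real programs), and builds hybrid genotypes through the
same `makeHybridGenotypes()` used for real data. The `g2fLikeSpec()`
preset — 6 years, 50 lines × 5 of 8 testers per year, 2 locations, 2
replicates, 2000 loci, $h^2 = 0.7$, $d^2 = 0.1$ — mirrors the structure
of a public multi-year maize test-cross series: a few hundred distinct
hybrids per year, tester-driven population structure (the leading
principal components separate tester groups), and dominance fractions in
the 0.08–0.17 range reported for such trials.

`simulatePhenotypes()` generates additive values as $Z a$ over causal
loci, dominance through heterozygosity *indicators* rather than through
$W$ — the generator is deliberately model-independent of the estimator,
so tests cannot trivially favor the 2NP encoding. Each indicator is
decomposed per locus (ordinary regression on dosage) into its
additive-direction part, which joins the additive component, and the
orthogonal dominance deviation: without this split, a share of the
"dominance" effect proportional to $(p - q)^2$ would silently be
additive variance, biasing every recovery check. Epistasis multiplies
centered causal codes (AA, AD, DD, cycled). Every genetic component is
rescaled so its realized variance over hybrids equals its target exactly
— exact-by-construction fractions keep recovery tolerances tight.

Heritability targets are defined on the **entry-mean basis**: the plot
residual variance is $(1 - h^2 - d^2 - \mathrm{epi}) \times \bar r$ with
$\bar r$ the mean number of plots per hybrid, so the targets are the
variance shares in per-hybrid phenotype means — the basis on which
multi-environment heritabilities are conventionally reported, and the
level at which GRM-based REML operates. Year and location main effects
(sd 0.5 and 0.3 on the unit-variance scale) are additive shifts that
cancel within balanced cohorts.

What the simulator does **not** emulate: linkage and LD structure (loci
are independent), genotype × environment interaction, selection over
cycles, missing-data patterns, and genotyping error. Passing tests
therefore demonstrate correctness of the machinery and calibrated
behavior under the stated architecture — not performance on any real
population, where LD, G×E and structure can change model rankings.

# Problem sizes and numerical choices

The test suite and acceptance script run at deliberately chosen
desk-scale sizes: oracle identities at $n = 50$–100; heritability
recovery at 500 hybrids × 1000 loci over 10 seeds; the model comparison
at 1000 hybrids (800 train / 200 test) × 200 loci over 5 seeds with a
10-iteration tuning budget; HWE calibration of $A$ at 2000 × 5000. These
sizes keep the full suite in the minutes range while leaving the
statistical assertions well-powered. Other fixed numerical choices:
GRM symmetry is enforced by averaging with the transpose after the
cross-product; PSD validity tolerates eigenvalues down to
$-10^{-8} \cdot \mathrm{tr}(K)/n$; EM starting values split
$\mathrm{var}(y)$ equally among components; the spectral grid spans
$\lambda \in e^{\pm 18}$; tree splits compare features at float32
precision (the backend's convention) while all accumulation is double.

# Known limitations

* Two genomic kernels at most (additive + dominance); no epistatic
  Hadamard kernels, multi-trait or G×E mixed models.
* EM-REML is robust but first-order; ill-conditioned kernel pairs can
  need many iterations (the iteration cap and trace make this visible).
* The dominance code for fractional expected dosages is an expectation at
  dosage level; with phased parental haplotypes a finer construction
  would be possible.
* Tree-ensemble randomness is reproducible only under single-threaded
  training, which is how the package always runs the backend.
* SHAP values explain the fitted model; they are not estimates of locus
  effects and inherit any confounding the model exploits (population
  structure above all).
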