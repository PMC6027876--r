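---
title: "Methods: genomic prediction for single-cross hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic prediction for single-cross hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milletgp)
```

`milletgp` implements the analysis chain of a three-line (CMS) hybrid
breeding program: genotype calls from reduced-representation sequencing
depths, marker quality control, projection of F1 genotypes from inbred
parents, an all-random multi-environment mixed model for the phenotypes,
and RR-BLUP genomic prediction under four training schemes. This vignette
explains the models, the assumptions behind each stage, the parameters
that matter, and what the bundled synthetic-data generator does and does
not emulate.

## Genotype calling and marker QC

Calls are made per (sample, site) from allele read counts. With total
depth $n$ and within-sample allele frequencies $f$:

* homozygous for the top allele when $n \ge 5$ and $f_{(1)} > 0.9$;
* heterozygous for the two top alleles when $n \ge 5$, the two jointly
  carry at least 90% of reads, each has at least 2 reads, and each has
  $f > 0.2$;
* missing otherwise. Missing is a value, not an error: low-depth GBS data
  are expected to leave most cells uncalled.

Boundary semantics are deliberate and unit-tested: depth "5 reads" is
$\ge 5$, the frequency thresholds 0.9 and 0.2 are strict, "at least 90%"
and "at least two reads" are inclusive. `min_depth` is exposed because
deeper platforms warrant a higher floor.

Marker filtering retains sites that are biallelic in their calls,
polymorphic (two or more genotype classes), at most 10% heterozygous among
called samples (inbred panels should be nearly homozygous, so high
heterozygosity flags paralog collapse), with the minor allele *carried by*
at least 5 samples (carriers, not allele copies — a single heterozygote
does not establish a polymorphism), and a call rate of at least 20%.
Boundary markers (exactly 10% het, exactly 5 carriers, exactly 20% called)
are retained; the MAF filter (`maf_filter`, default 0.05) is strict.
Per-marker statistics follow counting definitions: missing rate over all
samples; heterozygosity and MAF over called samples only.

`impute_naive` is a deliberately simple single-marker stand-in (draw from
the marker's observed genotype-class frequencies, or the modal class). It
uses no linkage information, so it preserves allele frequencies but not
haplotype structure; results that depend on LD-aware imputation should use
an external imputation tool and import the result.

## Projecting hybrid genotypes

On the 0–2 dosage scale, an F1 from parents with dosages $p_1, p_2$
receives $(p_1 + p_2)/2$: the same call when both parents are homozygous
identical, a heterozygous call when they are homozygous opposite, and the
parental mean when either parent is heterozygous. The three rules are
jointly the midpoint rule, which the tests verify over all nine integer
pairs. A missing parent call yields a missing hybrid call: after
imputation (the intended order of operations) this case does not arise,
and guessing one gamete would bias downstream allele frequencies.
Fractional dosages (e.g. 0.5) are kept as reals; the ridge model consumes
them directly. Recombination, residual parental heterozygosity and
cytoplasm effects are out of scope.

## The phenotype model

For one trait, plot values are modelled with only an intercept fixed:

$$y = \mu + G + L + G{:}L + R + B + \varepsilon,$$

genotype, location, genotype-by-location, replicate and block all random.
REML fitting is delegated to `lme4`; the package pins the optimizer to
`bobyqa` with a tight stopping rule (`rhoend = 1e-13`) so that on balanced
designs the estimates agree with closed-form ANOVA estimators to ~1e-6,
which is how the test suite validates the fit. Variance components are
constrained non-negative by `lme4`'s parameterisation; terms aliased with
a coarser factor (one block per replicate, one replicate per location) are
dropped rather than fit as singular.

Replicates are coded within location and blocks within replicate
(`nesting = "nested"`, the physical layout of a multi-location alpha
lattice); `"flat"` coding is available because field books sometimes
carry globally-labelled factors.

Broad-sense heritability is computed on an entry-mean basis,

$$H^2 = \frac{V_G}{V_G + V_{G \times L}/N_L + V_\varepsilon/(N_R N_L)},$$

with $N_L$ locations and $N_R$ replicates. Location, replicate and block
variances do not appear: they cancel from entry means in a balanced
trial.

Mid-parent heterosis per hybrid is
$(Y_{hybrid} - MP)/MP$ with $MP = (Y_{female}+Y_{male})/2$. By default
the $Y$ are mean-restored predictions (intercept + BLUP): a ratio of
zero-centred BLUPs is ill-defined (tiny or negative denominators), while
the restored scale reproduces the familiar percentage reading of
heterosis. `scale = "blup"` is provided for the alternative reading, and
hybrids whose mid-parent value is not strictly positive are flagged and
excluded from medians rather than silently producing nonsense ratios.

## RR-BLUP and the four training schemes

The marker model is $y = \mu + \sum_i x_i g_i + e$ with a common
normal prior on marker effects. Markers are column-centred on training
means and $\mu$ is the training mean. The ridge parameter
$\lambda = \sigma^2_e/\sigma^2_g$ is estimated by REML on the equivalent
kernel model: the restricted likelihood is profiled on the spectrum of
the centred kernel $K = X_c X_c'$, so a fit costs one $n \times n$
eigendecomposition however many markers are used, and effects are
recovered through
$g = X_c'(K+\lambda I)^{-1}(y-\bar y) =
(X_c'X_c+\lambda I)^{-1}X_c'(y-\bar y)$ — the marker-space/entry-space
identity that the tests check numerically (at fixed, well-posed $\lambda$:
at a REML boundary solution the marker-space system is singular and the
comparison is meaningless). $\log\lambda$ is optimised on $[-25, 25]$;
a constant response short-circuits to zero effects with a warning.

The training schemes:

* **M1** — inbreds only: split inbreds into $k$ folds, train on $k-1$,
  predict *all* hybrids; the scheme's accuracy per sub-prediction is the
  correlation over all hybrids, and the $k$ sub-predictions are averaged.
* **M2** — conventional fivefold CV on hybrids.
* **M3A** — M2 with all inbreds appended to every training fold on the
  joint (uncentred) value scale.
* **M3B** — as M3A after centring inbred and hybrid values on their own
  population means (`center_by_population`). Centring the test population
  is an affine map, so fold correlations are unaffected by it — the tests
  assert this invariance directly.

Accuracy of one repetition is the mean over folds of the Pearson
correlation between predicted and observed values (`method = "spearman"`
available); folds with undefined correlation are skipped with a message.
Fold remainders are spread one per fold. Within a repetition, the fold
split and each marker subset are shared across schemes so that scheme
contrasts are paired; `compare_schemes` accordingly uses paired two-sided
t-tests over repetitions. Marker subsets are uniform draws without
replacement, redrawn each repetition.

Why M3A can hurt and M3B repair: with directional dominance, hybrid
values sit far above inbred values. In a pooled training set, any marker
whose genotype distribution differs between the populations (B- and
R-pool allele frequencies diverge, and hybrids are enriched for
heterozygotes) absorbs part of that population-mean gap into its effect,
biasing predictions within the hybrid population. Per-population centring
removes the gap while keeping the inbreds' additive information.

`holdout_parent_cv` measures the harder problem of predicting hybrids of
untested parents: all hybrids sharing either held-out parent are removed
from the training pool, and each sub-prediction predicts exactly that
excluded set. `predict_all_hybrids` scores every cross in a plan, and
`pareto_frontier` returns the non-dominated set for a maximise/minimise
trait pair (exact ties kept on both axes), the production-possibility
frontier between, say, yield and season length.

## The synthetic-data generator

The generator exists so every downstream stage is testable without
external data. It emulates:

* two fully inbred founder pools whose per-marker allele frequencies are
  drawn independently per pool (uniform on `[maf_low, maf_high]`,
  defaults 0.05–0.5) — independent draws create the pool divergence that
  drives the M3A bias;
* traits with additive + dominance architecture,
  $\sum_j a_j(x_j-1) + d_j\,[x_j{=}1]$: inbreds receive no dominance, so
  `dominance_mean > 0` directly tunes mid-parent heterosis;
* field trials laid out as locations × replicates × incomplete blocks
  with repeated checks in every block and each experimental entry once
  per replicate, with independent normal location, G×L, replicate, block
  and plot effects. Setting `target_h2` derives the residual SD from the
  realised genetic variance so the trial's expected entry-mean
  heritability hits the target.

It does **not** emulate linkage maps or LD decay (markers are
independent), read-level sequencing error, spatial field trends,
multi-year effects, or non-normal error distributions. Passing tests
therefore demonstrate the correctness and internal consistency of the
statistical machinery under its stated assumptions — not robustness to
the various ways real field and sequencing data violate them.

Alpha-lattice blocking is emulated as random assignment of entries to
blocks within replicate: the downstream model consumes only the factor
labels, not the generating design, so an optimal alpha design would change
nothing in what the tests exercise. An option
(`segregate_populations`) places hybrids in the leading blocks and
inbreds in the trailing blocks of each replicate, mimicking trials that
separate the populations; it is off by default. Trait scales are
abstract — analyses are scale-free except the heterosis ratio, so worked
examples add a positive baseline rather than imitating kg/ha magnitudes.

## Default architectures and problem sizes

Where the package needs concrete study conditions (tests, the pipeline
defaults, `scripts/acceptance.R`) it uses: trials of 4 locations × 2
replicates × 15-plot blocks with 2 repeated checks; a high-heritability,
low-dominance "flowering-like" trait (target $H^2 = 0.88$) and a
moderately heritable "yield-like" trait with complete dominance
($|d/a| \approx 1$, `additive_sd = 1`, `dominance_mean = 1`, target
$H^2 = 0.60$). Complete dominance is the canonical single-locus model for
heterosis: it produces a large hybrid–inbred gap while leaving inbred
records genuinely informative about additive effects, which is the regime
in which naive pooling (M3A) hurts and centred pooling (M3B) helps. Under
strong overdominance the inbred data carry almost no transferable signal
and M3B becomes merely neutral. Cross-validation defaults to 20
repetitions of five folds; the bias-mechanism simulation in the
acceptance tests uses 50 paired repetitions at 300 hybrids from 40 + 40
parents and 600 markers, and the permutation-null check redraws the
permutation each repetition so that the averaged accuracy estimates the
null expectation rather than the chance association frozen into any
single relabelling. The acceptance script runs the trial-scale study (192
× 192 genotyped parents, 327 tested hybrids from 39 phenotyped parents,
1,000 markers) in a few minutes on one core.

## Numerical choices and edge cases

* Tie-breaks in calling: ref/alt at a site are the two deepest alleles
  (alphabetical on ties); when the 2nd and 3rd alleles tie in depth the
  heterozygote conditions are unsatisfiable anyway, so the choice cannot
  change a call. At MAF exactly 0.5 the minor allele is the one with
  fewer carriers.
* `filter_markers` tallies every rule a marker fails, so the exclusion
  counts sum to more than the number of excluded markers when rules
  overlap.
* REML convergence: kernel-spectrum profile likelihood optimised with
  `stats::optimize` at tolerance 1e-8; `lme4` fits use `bobyqa` with
  `rhoend = 1e-13`.
* Degenerate inputs error early with diagnostics: single-location books
  (G×L unidentifiable), unreplicated entries, all-missing markers at
  imputation, empty hold-out training pools, unknown parent ids (named in
  the message).
* Reproducibility: every stochastic function takes a `seed`; the pipeline
  writes the seed and a config hash into its manifest, and rerunning a
  config reproduces all numerics exactly.

## Known limitations

Prediction uses a purely additive marker model, as is conventional for
GCA-style ranking; dominance or epistatic prediction models (and GCA/SCA
decomposition) are not implemented. The mixed model fits one trait at a
time. Accuracies measured by within-sample cross-validation on hybrids of
a small parent set are optimistic for unrelated material — the
hold-out-parent analysis quantifies part of that optimism and is the
better guide to performance on new crosses.
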