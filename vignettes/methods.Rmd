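---
title: "Models and methods behind paleostrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleostrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

paleostrat analyzes low-coverage ancient-DNA genotype data from admixed
populations: it estimates where ancestry came from (f-statistics and a
qpAdm-style mixture model), whether it arrived through men or women
(X-vs-autosome comparison), when it arrived (ancestry-covariance decay
dating), and how the people carrying it were socially organized (kinship
classification and a binomial test for burial-group structure). This
vignette describes the models, their assumptions, the tunable parameters,
and the choices made where the design was genuinely open. The motivating
setting is a medieval Nubian community buried in two cemeteries with
suspected socioeconomic stratification, whose gene pool mixes a
Nilotic-related and a West-Eurasian-related component.

## Genotype model

All analyses run on a single container (`gen_dataset()`): an
individuals-by-SNPs matrix of alternate-allele counts with SNP and
individual metadata. Ancient samples are *pseudo-haploid*: at each site a
single sequencing read's allele stands in for the diploid genotype, so
calls take values 0 or 2 and each called genotype contributes exactly one
allele "slot" to frequency estimates. Diploid data uses the same matrix
with two slots per call; a dataset-level ploidy flag selects the counting
rule, so one code path serves both. Missing data is `NA` (serialized as
`9` in EIGENSTRAT files). Genetic positions are Morgans throughout; the
`.snp` dialect is fixed, not auto-detected. Y and mtDNA SNPs are dropped
on construction with a warning — uniparental analyses consume haplogroup
tables, not SNP matrices.

## f-statistics and the block jackknife

`f4(A,B;C,D)` averages `(pA-pB)(pC-pD)` over SNPs as a ratio of sums
across blocks; `f3_admixture_test()` computes `(pT-p1)(pT-p2)` minus the
target's frequency-sampling variance `p(1-p)/(n-1)` (computed on haploid
slots, the appropriate finite-sample correction for pseudo-haploid data —
the analogue of the "inbreed" correction in the classical toolchain).
Hudson FST uses the ratio-of-averages estimator with the same
finite-sample correction in the numerator. SNP inclusion is
complete-cases per statistic: a SNP where any involved population has
zero called slots is dropped for that statistic.

Standard errors come from a weighted delete-one block jackknife over
contiguous 5 cM blocks (Busing's weighted form, reducing to the classical
jackknife at equal weights; blocks weighted by usable SNP count). 5 cM is
the conventional width — comfortably longer than typical LD — and is
exposed as a parameter. On sparse maps, blocks are automatically widened
so each holds at least 40 SNPs: null-calibration experiments show that
block sums over fewer SNPs (under missingness) are non-normal enough to
make the jackknife-whitened chi-square tests anticonservative in the tail
(rejection ~8% at a nominal 5% with ~17 SNPs/block, well calibrated at
40–50). At real capture-panel densities the minimum never binds.
`make_blocks(x, "chromosome")` falls back to per-chromosome blocks.

Two statistics are biased *by construction* in finite samples and corrected
by design rather than formula: the f4 basis used by the admixture model
shares its first reference across statistics, which adds a common variance
term to every entry; because the model constrains mixture weights to sum
to one, that common term cancels identically in the residual, so no
explicit correction is applied.

Sign conventions, asserted by tests: negative admixture-f3 = evidence of
admixture; in `f4_outlier_scan()` positive Z = the individual carries
*more* West-Eurasian-related ancestry than the remaining pool.

## qpAdm-style mixture model

For target T, sources S1..Sk and references R1..Rm, the statistic vector
is `f4(pop, R1; Rj, R1)` for `pop` in {T, S1..Sk} and `j = 2..m`. Under
admixture the target vector is the weighted combination of source
vectors. `fit_qpadm()` minimizes the covariance-weighted residual
quadratic form subject to the weights summing to one, with the full
jackknife covariance of the stacked vector estimated from per-block
leave-one-out replicates. Because the covariance of the residual depends
on the weights, the solve iterates (generalized least squares with the
sum-to-one constraint, covariance refreshed each pass; convergence
tolerance 1e-10, at most 20 passes). The residual chi-square uses
`dof = (m-1) - (k-1)`, the standard convention for this model class;
`p > 0.05` is read as a fitting model. Because the whitening covariance
is itself estimated from a finite number of jackknife blocks, the
quadratic form is Hotelling-T2 rather than chi-square distributed;
p-values use the corresponding F transform, which calibrates the tail
with few blocks and converges to the chi-square p-value at real-data
block counts. Weight standard errors come from
refitting on each leave-one-block-out replicate. A singular covariance is
ridge-regularized with a logged warning rather than failing.

`qpwave_clade_test()` is the `k = 1` special case with the weight pinned
at 1: it tests whether two groups have identical f4 relationships to the
references (chi-square, `m - 1` dof). `model_competition()` refits each
candidate two-source model with the competing candidate moved into the
reference set; a model that stops fitting reveals shared drift between
the moved candidate and the target that the kept source does not capture.

Estimates and standard errors are expected to agree with the classical
implementations at the level of simulation recovery, not bit-exactness:
the original software's f4 basis bookkeeping differs in details that do
not affect the estimand.

## Sex-biased admixture

Females carry 2/3 of X chromosomes but 1/2 of autosomes, so a component
of ancestry contributed preferentially by women is enriched on X. With
`pA` and `pX` the West-Eurasian-related proportions on autosomes and X,
the female- and male-derived components are `F = 3 pX - 2 pA` and
`M = 4 pA - 3 pX` (identically `F + M = 2 pA`), and the female fraction
is `P = F / (2 pA)`. The X-autosome Z-score is
`(pX - pA) / sqrt(sA^2 + sX^2)`; we orient it so *positive = more
West-Eurasian-related ancestry on X*, i.e. female-biased gene flow. (The
source literature states the formula once with the opposite numerator
order while tabulating positive values for X-enrichment; we follow the
tabulated orientation and note the discrepancy here rather than silently
resolving it.) The confidence interval on `P` uses the delta method:
`Var(P) = (3/(2 pA))^2 sX^2 + (3 pX/(2 pA^2))^2 sA^2`. A poorly fitting
X-compartment model flags the result rather than raising an error,
since the X fit's p-value is part of the evidence a user should see.

## Kinship and the cross-cemetery test

`pairwise_mismatch()` computes `p0`, the fraction of discordant calls
among SNPs called in both members of a pair. For pseudo-haploid draws,
relatives are discordant at `baseline * (1 - k)` with kinship `k` = 1/4,
1/8, 1/16 for degrees 1–3, so the normalized coefficient
`phi = p0 / baseline` classifies pairs with bands at the halving
midpoints: `< 0.625` identical, `[0.625, 0.8125)` degree 1,
`[0.8125, 0.90625)` degree 2, `[0.90625, 0.953125)` degree 3, else
unrelated. The degree-3 band extends the classical median-normalized
scheme one halving further; the published analysis cites an external
method without formulas, and the halving geometry is the natural
continuation. The baseline is the median `p0` over scorable pairs (most
pairs are unrelated); it can be supplied explicitly for small cohorts.
Pairs overlapping at fewer than `min_overlap` SNPs (default 15,000) are
"unknown" — the source analysis marks such pairs unknown without stating
a number, so the threshold is configuration, not doctrine.

`cross_cemetery_test()` asks whether relatives are buried together more
often than random burial predicts. For each degree set, with `nR` and
`nS` the *distinct* individuals involved in such pairs per cemetery, the
chance that two randomly chosen involved individuals span the cemeteries
is `p = nR*nS / C(nR+nS, 2)` (unordered sampling without replacement —
this convention reproduces all five published expected probabilities
exactly); with `T` pairs the expected cross-cemetery count is `T*p` and
the one-sided p-value is `P(X <= observed)` under `Binomial(T, p)`.
Individuals appearing in several degree classes are counted once per
degree-set row; that this is how the published individual counts behave
across pooled rows is inferred from reproducing their arithmetic.

## Dating admixture from ancestry covariance

Recombination breaks ancestry blocks at a rate of one crossover per
Morgan per generation, so the covariance of ancestry-informative signal
between SNP pairs decays as `exp(-lambda d)` with `lambda` equal to the
number of generations since admixture. Per SNP the weight is the
reference frequency difference `w = p_ref1 - p_ref2` and the per-subject
signal is `x = g/2 - (p_ref1 + p_ref2)/2`; bin covariance is
`sum(x_i w_i x_j w_j) / sum(w_i^2 w_j^2)` over same-chromosome pairs.
Defaults follow the classical parameterization: 0.001 Morgan bins up to
`maxdis` 1.0 Morgans (interpreted in Morgans — 0.1 cM bins to 100 cM).
The fit `C(d) = A exp(-lambda d) + c` starts at 0.0045 Morgans to skip
unmodeled short-range background LD, and includes the affine offset `c`
to absorb baseline covariance; both choices are exposed because the
source analysis is silent on them. The fit itself profiles `lambda` on a
log grid with `(A, c)` solved linearly at each candidate, then polishes
with Levenberg–Marquardt — robust for flat or noisy curves where a naive
nonlinear start diverges.

Standard errors come from a leave-one-chromosome-out jackknife
(chromosomes weighted by pair mass). Estimates with `g/SE < 2.8` are
flagged invalid (99.5% confidence convention). Conversion uses 28
years/generation by default; calendar intervals subtract the years-range
from the sampling midpoint and round half-up to whole years, which can
differ by one year from truncation-based reporting. Pairwise date
differences use `Z = (g_i - g_j)/sqrt(SE_i^2 + SE_j^2)` against a
two-sided Bonferroni threshold (3.65 for 190 tests); any exceedance
yields the multiple-waves verdict.

## Uniparental summaries

`maternal_ancestry_range()` inverts an exact central (equal-tail)
binomial CI on an integer-percent grid: a maternal-ancestry proportion
is accepted iff neither exact tail at the observed haplogroup count is
at or below `(1-level)/2`. The equal-tail convention with strict
exclusion reproduces the published 43–68% range for 35 of 63
West-Eurasian mtDNA haplogroups; the convention is a parameter because
the source does not name one. `yates_chi2()` is the standard
continuity-corrected 2×2 chi-square with the correction clamped at zero
for `|O-E| < 0.5`. Haplogroup origin classes are user-declared
annotations — the package does not decide what counts as a
"West-Eurasian-distributed" haplogroup.

## Projection PCA

Axes are computed from designated (typically modern) reference
individuals: frequencies centered and scaled by `sqrt(p(1-p))`,
monomorphic SNPs dropped, residual missingness mean-imputed, components
from the SVD. Other (typically ancient, sparse) individuals are placed
by least squares on their called SNPs only, which is exact for
complete-data individuals in the reference span. Coordinates for
individuals sharing fewer than `min_snps` (default 30,000) SNPs with the
loadings are flagged unreliable. No shrinkage correction is applied to
co-visualize projected and non-projected samples; projected-vs-fit
comparisons are therefore qualitative.

## The synthetic-data generator

`simulate_study()` generates the statistical structure the analyses
assume, with a truth sidecar for closed-loop parameter recovery:

* **Sources and outgroups.** Balding–Nichols drift on a fixed small tree:
  an ancestral frequency (uniform 0.05–0.95) drifts into a Nilotic-like
  and a West-Eurasian-like branch, each carrying one source and one
  outgroup, plus two root outgroups. Branch drift is calibrated so the
  nominal Hudson FST between the sources equals `fst_source_divergence`
  (default 0.15, a realistic Nilotic-vs-Levantine-scale divergence). The
  branch-sharing outgroups give the reference set the differential
  relatedness qpAdm-style fitting requires.
* **Admixed cohort.** 60 individuals by default; per-individual
  West-Eurasian proportion from a truncated normal with mean 0.575 and
  s.d. 0.045 (reproducing the ~46–64% individual range of the motivating
  cohort). Chromosomes are two-state Markov ancestry mosaics with switch
  rate `g` per Morgan (default 22 generations) and stationary
  distribution equal to the individual's proportion, so the mean
  West-Eurasian tract is `1/(g(1-theta))` Morgans and the ancestry
  covariance decays at exactly the rate the dating module estimates.
* **Sex bias.** Female/male-derived components `F = 2*theta*P` and
  `M = 2*theta*(1-P)` with `P = female_fraction_WE` (default 0.68); X
  chromosomes are mosaics at `(2F+M)/3` — the identity the estimator
  inverts, so recovery is a closed loop. Males carry one X haplotype,
  females two; pseudo-haploid sampling collapses both to one call.
* **Relatives.** Planted pairs by gene-dropping: one recombining meiosis
  (Poisson crossovers, one per Morgan) per degree, chained through
  simulated mates, so degree-d pairs share the expected `2^-d` genome
  fraction with realistic variance. Relatives share autosomes only; their
  X chromosomes are independent mosaics.
* **Pseudo-haploid sampling and missingness.** One random allele slot per
  call, then Bernoulli missingness (default 0.2 — a single rate; real
  per-individual coverage variation is not modeled unless supplied).
* **Cemeteries.** Labels "R"/"S" split 27/33 by default, assigned
  independently of genotype (the null the cross-cemetery test assumes),
  except where a relative plan pins them.

Everything is driven by one mandatory seed; per-stage seeds are derived
deterministically, and identical configurations produce byte-identical
output files.

What the generator does *not* emulate: coalescent linkage disequilibrium
within sources (sites are independent given frequencies), sequencing
error and damage, contamination, per-individual coverage structure, and
reference-population admixture. Passing recovery tests therefore shows
the estimators are correct under their own model assumptions — it does
not certify behavior under real aDNA artifacts.

## Problem sizes and numerical choices

The test-suite simulations use 400–5,000 SNPs per chromosome over 10–22
chromosomes of 1.5 Morgans and cohorts of 15–60 individuals — two to
three orders of magnitude below the ~1.2M-SNP capture panel of real
studies, chosen so the full suite runs on a laptop in minutes while
keeping every estimator's signal-to-noise high enough for 2-SE recovery
checks. Degenerate inputs are handled explicitly: single jackknife blocks
raise, all-missing SNPs are flagged rather than propagated, identical
clade-test groups short-circuit to `p = 1`, unscorable individuals in the
outlier scan are reported rather than flagged, and a flat decay curve
returns its grid optimum rather than a convergence failure.

## Known limitations

* qpAdm-style fits assume the reference set is differentially related to
  the sources; with exchangeable references the system is degenerate and
  the ridge fallback will warn.
* The FST finite-sample correction assumes independent samples: feeding
  the *same* individuals as both populations yields a small negative
  offset (about `-1/(n-1)`), not zero.
* Dating interprets a single-pulse model; under continuous admixture the
  estimate is an average, and the per-individual mode inherits the
  pooled estimator's bias at low SNP counts.
* The kinship bands assume a homogeneous unrelated baseline; strong
  population structure within the cohort inflates the baseline spread
  and can blur degree-3 calls, which is why only degrees 1–2 carry
  recovery guarantees.

One further small-sample note: when `estimate_sex_bias()` computes the
interval on the female fraction P, it uses a Student-t quantile with
degrees of freedom one less than the smaller compartment's jackknife
block count, since the X compartment of a sparse simulated map may rest
on only a dozen blocks; with many blocks (any real capture panel) this
is indistinguishable from the normal quantile used by
`sex_bias_decompose()` on published proportions.
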