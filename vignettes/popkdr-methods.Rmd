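---
title: "Methods and design of popkdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of popkdr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popkdr)
```

popkdr packages the analysis chain of a mosquito resistance survey: *kdr*
genotype decomposition, microsatellite summary statistics, equilibrium
screening, differentiation and isolation by distance, admixture
clustering and DAPC. This vignette is the package's own account of the
underlying models, the defaults and why they were chosen, and what the
synthetic-data generator does and does not emulate.

## The kdr haplotype algebra

The three pyrethroid-resistance SNPs of the voltage-gated sodium channel
— V410L, V1016I, F1534C — are genotyped per site, so an individual's
record is a triple of diploid genotypes such as LL + VI + FC. The
haplotypes (alleles) circulating in Brazilian *Aedes aegypti* form a
closed six-letter alphabet over the site states:

| allele | 410 | 1016 | 1534 | role |
|---|---|---|---|---|
| S  | V | V | F | wild type |
| R1 | V | V | C | F1534C only |
| R2 | L | I | C | triple mutant, strongest resistance |
| X1 | L | V | C | rare arrangement |
| X2 | L | V | F | rare arrangement |
| X3 | L | I | F | rare arrangement |

`kdr_decompose()` returns every unordered pair of alphabet haplotypes
whose site-wise union equals the observed triple. Correctness is not
assumed: the test suite brute-forces all 21 unordered pairs for each of
the 27 possible calls and checks both soundness (each returned pair
recombines into the call) and completeness (no pair is missed).

Three outcomes deserve comment:

* **Y.** LL + VI + FC is consistent with exactly two pairs, R2/X2 and
  X1/X3. It is reported as its own genotype class "Y", never silently
  resolved.
* **Other ambiguities.** Once the X alleles are admitted, a few more
  calls become ambiguous — e.g. VL + VI + FC is S/R2 or R1/X3, and
  VL + VV + FC is S/X1 or R1/X2. Field reports that only use the
  {S, R1, R2} alphabet call these SR2 and (never observed) SX1; popkdr
  labels them `AMBIGUOUS` and lists all consistent pairs, because that
  is what the data support. This is a deliberate deviation from the
  informal practice of naming a double heterozygote after its most
  common composition.
* **UNRESOLVED.** Calls requiring a haplotype outside the alphabet
  (e.g. VV + VI + CC needs VIC) are flagged rather than forced;
  `kdr_alphabet(open = TRUE)` enumerates all eight possible triples for
  novel-genotype screening.

**Frequencies.** Genotype-class frequencies are plain counts over fully
genotyped individuals; any missing site excludes the individual from
all denominators (no partial imputation — sample sizes then mean "fully
genotyped mosquitoes"). For allele frequencies, ambiguous individuals
are apportioned either

* `equal_split` (default): weight 1/m to each of the m consistent
  pairs. A lone Y individual yields R2 = X2 = X1 = X3 = 0.25. This is
  the conservative choice when no external information favours a pair,
  and it is the default because the published tables we mirror kept Y
  as its own unresolved class; or
* `em`: iterate expected pair weights proportional to the
  Hardy–Weinberg probability of each pair under the current allele
  frequencies until the largest change drops below 1e-10 (capped at
  10,000 iterations). The observed-data log-likelihood is
  non-decreasing across iterations (tested). In a cohort rich in
  unambiguous R2 carriers the EM pushes Y towards R2/X2, which is the
  behaviour a maximum-likelihood reading of the data implies.

Gene duplication (a suspected cause of the rare arrangements) is not
modelled; all individuals are treated as diploid single-copy.

## Microsatellite diversity

Per population and locus, with missing calls excluded from every
denominator: Na (observed alleles), Ne = 1/Σp², Ho (fraction of
heterozygous typed individuals), He = 1 − Σp², uHe = 2n/(2n−1)·He, and
Fis = (He − Ho)/He (NA at monomorphic loci). He is the
frequency-based (GenAlEx-style) quantity; uHe is reported alongside
because published tables rarely say which convention they used.
Population summaries are unweighted means across loci — hence
fractional private-allele counts (2 private alleles across 12 loci
appear as 0.167) and fractional mean sample sizes.

Rarefied allelic richness uses the closed form
R(g) = Σᵢ [1 − C(N−Nᵢ, g)/C(N, g)] with binomial coefficients in log
space; g defaults, per locus, to the minimum number of typed gene
copies across populations so values are comparable. The closed form is
tested against exhaustive subset enumeration for all N ≤ 12.
Hierarchical (multi-level) rarefaction of private allelic richness is
out of scope; Np is a plain private-allele count.

## Equilibrium screening

**Hardy–Weinberg.** The null distribution is Levene's conditional
distribution of genotype arrays given allele counts,

P(array) = n! · 2^h · Π aⱼ! / (Π n_gg! · (2n)!),

with h the heterozygote count. The p-value sums P over arrays with
P ≤ P(observed). With ≤ 4 distinct alleles (configurable cap) the
feasible arrays are enumerated completely; above the cap the null is
sampled by independently re-pairing the allele vector. For
exchangeable arrays this draws from exactly the same conditional
distribution as the classic Markov-chain approach, with no
dememorization or batch tuning, at the price of somewhat more work per
draw — a good trade at survey scale. The Monte-Carlo p-value uses the
standard (1 + hits)/(iterations + 1) correction so p > 0, and the
enumeration path is verified to sum probabilities to 1 and to
reproduce hand-computed cases (two individuals {11, 22} give p = 1/3).

**Linkage disequilibrium.** Phase is unknown, so the test is the
genotypic G-test: the contingency table of unphased genotype categories
at two loci, G = 2ΣO·ln(O/E), with significance from permuting one
locus's genotype column within the population. The full grid is all
C(L,2) locus pairs × populations — 396 tests for 12 loci and 6
populations. Degenerate tables give G = 0, p = 1.

**Multiple testing.** `bonferroni()` divides alpha by the family size;
the family is all tests of one analysis type by default, or
per-population families via `by = "pop"` (published practice varies and
is often ambiguous, so both are available).

**Null alleles.** Brookfield's estimator 1, r = (He − Ho)/(1 + He),
truncated at zero. It is a heterozygote-deficit screen, not a proof:
inbreeding and Wahlund effects inflate it equally. The fuller
Micro-Checker diagnostics (stutter, large-allele dropout) are out of
scope.

## Differentiation and isolation by distance

**Fst.** Weir & Cockerham's (1984) θ: per locus and allele the a
(among-population), b (among-individual) and c (within-individual)
components are accumulated and θ = Σa / Σ(a+b+c). The implementation is
property-tested to 1e-10 against an independent plain-loop
transcription of the component formulas, and hits its limits (θ ≈ 0
for identical populations, θ = 1 for fixed differences). The ENA
correction for null alleles is not implemented; θ is the uncorrected
estimator, and the output says so.

**Nm.** The island-model transform Nm = (1 − Fst)/(4·Fst), flagged
infinite at Fst ≤ 0. Published Nm tables produced by spreadsheet tools
do not always satisfy this identity (the table shipped in
`inst/extdata` pairs Fst = 0.004 with Nm = 53.0 where the transform
gives 62.25); popkdr exposes the textbook formula rather than
reverse-engineering any particular tool's variant.

**AMOVA.** Two-level locus-by-locus decomposition on allele-identity
distances (squared inter-genotype distance = number of non-shared
allele copies): among populations / among individuals within
populations / within individuals. Sums of squares and degrees of
freedom are summed across loci; the unequal-sample-size coefficient
n_c is averaged across loci weighted by its degrees of freedom.
Negative variance components are reported as-is with a warning —
truncation would silently bias the F-statistics. Permutation schemes:
whole individuals among populations (Fst), alleles among individuals
within populations (Fis).

**Geography.** Haversine distances on a 6371-km sphere, from
coordinates parsed out of degree-minute-second strings (including the
typographic quirks of published tables — doubled apostrophes, curly
primes, a 60-second field). Road distances are not computable from
coordinates; where a survey's authors correlated genetics against road
kilometres, a Mantel r computed from great-circle distances will
differ. For the shipped six-city table the great-circle Mantel r is
0.680 — the package reports what it computes and the discrepancy is
documented rather than tuned away.

**Mantel.** Pearson correlation over the lower triangle with
simultaneous row+column permutation of one matrix, one-tailed for
positive association, (1 + exceedances)/(permutations + 1). The
statistic is cross-checked against vegan's implementation in the test
suite; permutation counts default to 9,999 + the observed arrangement.

## Admixture clustering

The admixture model: individual i has ancestry proportions
q_i over K clusters; each allele copy picks an origin cluster
z ~ Cat(q_i) and then an allele from that cluster's frequency vector.
The Gibbs sampler (Rcpp) alternates:

1. z for every allele copy, with P(z = k) ∝ q_ik · p_k(allele);
2. cluster allele frequencies ~ Dirichlet(λ + counts);
3. q_i ~ Dirichlet(α + origin counts).

Q is the posterior mean after burn-in. Design choices, all documented
divergences from the reference desktop implementation:

* **Independent allele frequencies, fixed α.** λ = 1 and α = 1 by
  default, both configurable; the Metropolis update of α and the
  correlated-frequencies prior are omitted for tractability. The
  consequence is some shrinkage of extreme ancestry proportions toward
  1/K when the signal per individual is weak; the two-cluster
  transect structure this package targets is recoverable regardless
  (tested: mean absolute error of Q below 0.1 at F = 0.2 with 20
  ten-allele loci and 50 individuals per population).
* **Model evidence.** ln P(X|K) ≈ mean(L) − var(L)/2 over the
  post-burn-in trace of the observed-data log-likelihood — the usual
  harmonic-style approximation. It is rough, but ΔK uses only second
  differences of it across K, which is exactly the regime where the
  approximation's constant offsets cancel.
* **ΔK.** ΔK = |L̄(K−1) − 2L̄(K) + L̄(K+1)| / sd(L(K)) over replicate
  runs, defined for interior K with positive sd; the selected K is the
  argmax. Note ΔK can never select the boundary values of the scanned
  range; scan at least K = 1..(K_expected + 2).
* **Label alignment.** Cluster labels are exchangeable, so replicate
  runs are aligned by exhaustive search over the K! column permutations
  (K ≤ 8) maximizing G-similarity 1 − ‖A−B‖_F/√(2N) against the first
  run, with a greedy assignment fallback above K = 8. The consensus Q
  is the mean of aligned runs.
* **Desk-scale defaults.** 2,000 sweeps with 20% burn-in per run as the
  function default; the survey-scale scan in `scripts/acceptance.R`
  uses 10 replicates × 20,000 sweeps for K = 1..5, which completes in a
  few minutes of C++ time. Longer chains are supported but change
  nothing detectable on datasets of this size (trace drift is tested to
  be absent after burn-in).

## DAPC

Genotypes are encoded as an individuals × alleles dosage matrix (0,
0.5, 1 per allele; missing calls imputed with the group mean, matching
the behaviour of the standard R implementation), column-centred,
reduced by PCA (SVD), and the retained scores passed to linear
discriminant analysis (`MASS::lda`) on the group labels. Group
membership probabilities are the LDA posteriors (Gaussian densities
with pooled covariance in discriminant space). Defaults: groups are
the sampling populations (the survey figures label points by
population; discovering groups by k-means/BIC is out of scope); n_pca
is the smallest number of components explaining ≥ 90% variance unless
given, with a hard error when n_pca would reach the number of
individuals (overfitting guard); the discriminant count is
min(n_pca, groups − 1). No cross-validation of n_pca is performed.

## The synthetic-data generator

`simulate_msat()` implements the Balding–Nichols F-model: per locus an
ancestral frequency vector p ~ Dirichlet(1, …, 1); cluster k draws
p_k ~ Dirichlet(p·(1−F)/F), so E[Fst] between cluster-pure populations
is approximately F; each allele copy samples a cluster from the
population's admixture vector Q_true, then an allele from that
cluster. This is exactly the model family the clustering stage assumes,
which is the point: parameter recovery becomes quantitative (estimated
θ between pure populations recovers F; posterior Q recovers Q_true).
Missing data are masked per call; a null allele, when enabled,
segregates at the given frequency and turns heterozygous carriers into
apparent homozygotes and null homozygotes into missing calls — the
signature Micro-Checker-type estimators detect.

`preset_amapa()` fixes the study conditions emulated throughout the
package: six populations in south-to-north transect order (MAC, PGR,
FGO, TTZ, CAL, OIA), 45 individuals each, 12 loci carrying 60 alleles
in total (2 to 17 per locus, matching the published locus panel), two
ancestral clusters at F = 0.07 with Q_true interpolating linearly along
the transect between cluster-pure endpoints (the published two-cluster
South–North gradient), a 3% missing-call rate, and no null alleles.
The kdr frequency vectors follow the published per-population figures
where stated (MAC: S 0.128, R1 0.779, R2 0.093; OIA: R1 0.152, R2
0.522; CAL: R2 0.359 with X1 segregating; S absent in PGR) and fill
the unstated remainder so that the rare-genotype reports (R2X1 in CAL
and OIA, Y only in OIA) are plausible under Hardy–Weinberg draws.
Under this preset the mean pairwise θ falls inside the published
0.004–0.084 band (checked over 20 replicate seeds) and ΔK selects
K = 2.

What the generator does **not** emulate: mutation models (SMM/IAM) and
hence allele-size structure, linkage between loci, selection at the kdr
locus, demographic history (the preset is calibrated to printed summary
ranges, not to effective sizes or migration rates), genuine
heterozygote-deficit processes other than null alleles, and
allele-frequency clines that are not two-cluster admixture. Passing
tests on this preset therefore demonstrate that the estimators recover
the truth of this model family at survey-like sample sizes — not that
any particular field dataset satisfies the model.

**Reproducibility.** Every stochastic operation takes a seed and the
generator is bit-reproducible given one: the same seed yields the same
GENEPOP file byte-for-byte. The microsatellite and kdr stages use
fixed, distinct offsets of the configured seed so that changing one
stage's draws cannot silently change the other's.

## Input formats and interface

GENEPOP text (2- or 3-digit allele codes, auto-detected; mixed widths
are a fatal error, never a guess), kdr call CSV (`id, pop, g410, g1016,
g1534`), sites CSV with decimal or DMS coordinates (west longitudes
negative), and lower-triangular Fst CSV. GENEPOP files carry no
population names, so blocks are labelled by their last individual ID
unless explicit labels are supplied — the common ID-prefix convention.
The parser never silently drops individuals; structural problems abort
with the offending line number.

The package's interface is its functions: every stage takes a tibble
(or returns one via `tidy()`/`glance()`), so a full analysis is a
short pipe-friendly script, and the vignette and README serve as the
entry points a separate command-line wrapper would otherwise provide.

## Known limitations

* The HWE enumeration path can be slow for 4-allele loci with large n;
  lower `cap` to force Monte-Carlo there.
* ln P(X|K) shares the reference tool's known tendency to plateau
  rather than peak; rely on ΔK, and on DAPC as an assumption-free
  cross-check.
* Permutation p-values are seed-dependent at the third decimal for
  default permutation counts; raise the counts for publication tables.
* The AMOVA is two-level (no regional stratum), matching the analysis
  it reproduces.
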