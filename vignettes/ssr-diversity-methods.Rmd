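---
title: "Methods: SSR diversity, AMOVA, admixture clustering and DAPC in ssrpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR diversity, AMOVA, admixture clustering and DAPC in ssrpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrpop)
```

`ssrpop` analyses codominant microsatellite (SSR) panels from germplasm
collections. This vignette is the package's own account of the models and
numerical choices behind each stage, of the synthetic data generator used to
validate them, and of what the validation does and does not demonstrate.

## Data model: multisets of fragment sizes, then allele presence

An SSR genotype in a polyploid is scored as a set of fragment-peak sizes:
between 1 and `ploidy` distinct integers per locus, with allele dosage
unresolvable from peak intensities in routine scoring. `genotype_tbl()`
therefore stores one allele-call multiset per sample × locus, a genotype
being missing exactly when no call was recorded (serialised as all-zero
slots in the GenAlEx dialect).

All multivariate stages operate on the **binary allele-presence encoding**
(`allele_presence()`): one 0/1 column per observed (locus, allele) pair, a 1
meaning the sample carries at least one copy. This discards dosage
deliberately. Two consequences drive later choices:

- squared Euclidean distance between rows equals the allele mismatch count,
  the standard inter-individual distance for binary marker data;
- the AMOVA-based differentiation statistic on such data is PhiPT, whose
  companion gene-flow transform is the haploid/binary one (below).

Cells belonging to a missing genotype are masked, never treated as observed
zeros. Where a complete matrix is required (distances, PCA) masked cells are
imputed by their column mean; a pairwise-deletion alternative was considered
and rejected because it breaks the Euclidean embedding that the AMOVA
decomposition relies on, while mean imputation at the ~2% missingness
typical of SSR panels perturbs distances negligibly.

## Diversity indices

Per locus, with missing genotypes excluded from all proportions:

- `Na`: distinct alleles; `Ng`: distinct genotype classes, a class being the
  *multiset* of calls ({173, 175} ≡ {175, 173});
- Shannon–Wiener `H = -sum(p_i log p_i)` over genotype-class proportions.
  `H` is computed in **nats**. The evenness index used alongside it is
  `E5 = (1/lambda - 1)/(exp(H) - 1)` (Stoddart–Taylor 1/λ = inverse
  Simpson), and `E5`'s exp() pairing is only internally consistent with a
  natural-log `H`; a `base` argument exposes other conventions.
- Nei's gene diversity `h = n/(n-1) * (1 - sum(p_i^2))` over allele
  frequencies, averaged over loci into `GD`. The correction's `n` is the
  number of observed **gene copies** at the locus — the standard
  small-sample correction. Field descriptions of this formula sometimes read
  "number of observed alleles", which could also mean distinct alleles; that
  reading is available as `n_convention = "distinct_alleles"` but is not the
  default, because the correction's purpose is to unbias against sampling
  depth, not allelic richness.
- `E5` is defined as 1 for a single genotype class (no unevenness is
  expressible), and report tables round to 2 decimals while full precision
  is kept internally.

## Distance AMOVA, PhiPT and gene flow

For groups g of sizes n_g (N samples, k groups) and squared distances d²:

```
SS_total  = sum_{i<j} d2_ij / N
SS_within = sum_g [ sum_{i<j in g} d2_ij / n_g ]
SS_among  = SS_total - SS_within
MS        = SS / df,  df_among = k - 1,  df_within = N - k
n0        = (N - sum(n_g^2)/N) / (k - 1)
Va        = max(0, (MS_among - MS_within) / n0),   Vw = MS_within
PhiPT     = Va / (Va + Vw)
```

On one-dimensional data this reduces exactly to classical one-way ANOVA
(verified against `stats::aov` in the tests). A negative among-group
component is truncated to zero so PhiPT stays in [0, 1].

Gene flow uses the island-model transform for haploid/binary data,
`Nm = (1 - Phi)/(2 Phi)`. The diploid codominant transform (divisor 4)
exists behind `data_type = "codominant"`, but binary allele-presence input
calls for the divisor-2 form — it is also the only transform consistent with
published PhiPT→Nm pairs for this data type (e.g. Φ = 0.290 → Nm = 1.224).

Significance is a permutation test: whole-sample label shuffles with group
sizes fixed, `p = (#{Phi_perm >= Phi_obs} + 1)/(n_perm + 1)`, one seeded RNG
stream. Degenerate inputs (all-zero distances) return p = 1. The test's
type-I error at the 999-permutation default is checked at nominal level by
simulation in the acceptance suite.

`amova_components()` exposes the n₀ → Va → PhiPT → Nm chain directly from
mean squares and group sizes, so published AMOVA tables can be audited
without the raw data.

## Admixture-model Gibbs sampler

`structure_admixture()` is a deliberately lean, desk-scale admixture model
on the binary matrix: cell (i, j) draws its cluster of origin
`z_ij ~ Categorical(q_i)` and its value `x_ij ~ Bernoulli(f_k j)`, with
priors `q_i ~ Dirichlet(alpha)` and `f ~ Beta(beta, beta)`; `alpha = beta =
1` by default. It is *not* a reimplementation of the STRUCTURE program: one
binary observation per allele column, no diploid phase, no
correlated-frequencies model, no alpha updating. Matching such programs'
numeric output is neither possible nor attempted; what is validated instead
is statistical recovery on synthetic panels (below).

Numerical choices:

- label switching is resolved by greedily matching each recorded draw's `f`
  rows to the first recorded draw (L2 cost) before averaging;
- `f` is clamped inside (0, 1) so the likelihood never degenerates;
- the evidence estimate is `lnPD = mean(lnL) - var(lnL)/2` with the n−1
  variance denominator;
- run seeds in `structure_scan()` derive as `seed + run_index`, making a
  whole scan reproducible from one integer.

Model selection follows Evanno's ΔK: with runs paired by index,
`ΔK = mean_runs |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))`, defined for interior
K only, with a zero run-to-run sd yielding an undefined sentinel rather than
an infinite score. Membership uses the q > 0.8 rule: every sample is
labelled by its argmax cluster (ties to the lowest index), and samples at
q_max ≤ 0.8 — the boundary inclusive — are flagged genetically admixed.

Defaults are desk-scale (burn-in 1,000; 10,000 sweeps; thin 10), chosen so a
full K-scan of a few-hundred-sample panel runs in minutes in plain R
sessions; the reference field protocol for production analyses (burn-in
50,000; 500,000 iterations; 3 runs per K, K = 1..11) is documented in
`?structure_admixture` and is what the defaults stand in for.

## DAPC

`pca_fit()` (centred, unscaled by default — the columns are 0/1),
`find_clusters()` (k-means over retained PC scores, best of 10 seeded
restarts per K, `BIC(K) = N log(W_K/N) + K log(N)`, argmin over K), and
`dapc_fit()` (Fisher discriminant axes via within-group whitening, so the
axes are orthonormal in the within-group metric; at most K−1 informative
axes; ridge regularisation at 1e-8 of the mean within-variance when the
within-scatter is near-singular).

One practical property of the BIC criterion deserves emphasis: its penalty
`K log N` only dominates when the retained space has enough dimensions that
splitting true clusters yields a small *relative* reduction in W. In very
low-dimensional score spaces k-means can keep cutting W fast enough that BIC
decreases for ever; cluster detection should therefore retain a generous
number of PCs (the package's subset pipeline defaults to the axes covering
90% of variance). This is a property of the criterion, not an
implementation artefact, and the tests exercise it with high-dimensional
constructions.

`dapc_xval()` validates the retained-PC count by repeated stratified
holdout (default 10% per group, 30 repetitions): the recommended `n_pcs`
maximises mean held-out assignment success, ties resolved toward fewer PCs
(parsimony). Prediction assigns new samples to the nearest group centroid in
discriminant space with Gaussian posterior weights. `dapc_subset()` re-runs
the whole pipeline on a sample subset, re-deriving the allele-presence
columns so private alleles of excluded groups drop out.

## The synthetic panel generator

No suitable public SSR panel with known structure exists at the scale this
package targets, so validation rests on `simulate_panel()`, a nested
Balding–Nichols generator:

1. per locus, an allele count is drawn uniformly from `allele_range`
   (default 4–20) and ancestral frequencies from a flat Dirichlet;
2. each of `k_subpop` latent subpopulations draws its frequencies
   `Dirichlet(p_anc (1-F)/F)` at divergence `F = f_subpop`;
3. each origin group (country of provenance) perturbs its subpopulation's
   frequencies the same way at its own smaller `f`;
4. genotypes are `ploidy` independent allele draws (the recorded genotype is
   the set of distinct drawn sizes, as fragment analysis would score it);
   a fraction `admix_frac` of samples instead receives a Dirichlet
   admixture vector over subpopulations and draws each allele copy from the
   subpopulation it selects; genotypes go missing MCAR at `missing_rate`.

The default configuration emulates a genebank potato collection: 482
accessions × 24 loci, ploidy 4, seven origins of sizes (29, 42, 48, 122,
60, 41, 140), the 41-accession origin (wild-relative-like) carrying the
second latent subpopulation, 7% admixed, 2% missing. The divergence
defaults — `f_subpop = 0.025`, origin `f = 0.006` (0.02 for the diverged
origin) — were fixed once by a small calibration sweep so that a one-way
AMOVA by origin attributes about 3% of molecular variance to among-origin
differences (a 20-seed check gives 2.9–3.7%), the level reported for real
germplasm collections of this composition; they were not adjusted
afterwards.

What the generator does *not* emulate: stepwise mutation (allele sizes are
exchangeable labels), linkage between loci, genotyping artefacts other than
MCAR missingness (no null alleles, stutter or size homoplasy), pedigree
relatedness within origins, and dosage information. Passing recovery tests
on these panels therefore demonstrates correctness of the statistical
machinery under a clean frequency-divergence model — not robustness to every
failure mode of real fragment data.

## Validation strategy and problem sizes

The test suite pairs every estimator with an independent oracle: hand-
evaluable closed forms for the indices, brute-force pairwise loops for
distances, `stats::aov` for the AMOVA decomposition on 1-D data, a
unit-circle scan and `MASS::lda` for the Fisher axis, and generator truth
for recovery. Published AMOVA tables enter only through their printed mean
squares and group sizes, from which the package re-derives the variance
components, PhiPT and Nm.

Simulation-based checks run at deliberately modest sizes chosen as the
smallest that make the property sharp: 500 null panels (N = 60, 10 loci,
99 permutations) for type-I error calibration of the permutation test;
10 replicates of N = 120, ~100-column, F = 0.3 two-population panels for
admixture recovery (posterior-mean q within 0.1 of truth; Evanno ΔK
selecting K = 2 in at least 8 of 10); and 90-sample blob constructions for
cluster detection.

## Known limitations

- The admixture sampler ignores dosage and treats allele-presence columns
  as independent given ancestry; with few loci its q estimates are
  prior-shrunk toward 1/K (visible in the separable-data tests).
- Evanno's ΔK cannot select K = 1; inspect mean ln P(D|K) directly when a
  panmictic panel is plausible.
- The GenAlEx reader targets one canonical codominant dialect; it is not a
  general GenAlEx-workbook parser.
- Pairwise PhiPT p-values are not multiplicity-adjusted (matching standard
  practice in germplasm reports); adjust downstream if needed.
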