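# ssrpop

Genetic diversity and population structure analysis of codominant SSR
(microsatellite) germplasm panels, in R.

Genebank curators and breeders routinely genotype germplasm collections —
often polyploid, like potato — at a few dozen SSR loci and then ask the same
chain of questions: how diverse is each locus and each origin group, how much
molecular variance lies among versus within groups, how many latent
populations does the collection contain, and which parents dominate the
pedigrees. `ssrpop` implements that entire chain as composable, tibble-first
R functions:

- **Data model and I/O** — a `genotype_tbl` of multi-allelic SSR calls
  (fragment sizes, up to `ploidy` per genotype), read and written in a
  GenAlEx-style codominant CSV dialect, exportable to STRUCTURE's multi-row
  format, and converted to the binary **allele-presence** matrix (one 0/1
  column per locus/allele, dosage discarded) on which all multivariate
  statistics operate.
- **Diversity indices** — per locus and per group: allele count Na, genotype
  count Ng, Shannon–Wiener index *H* = −Σ pᵢ ln pᵢ over genotype classes,
  Nei's corrected gene diversity *h* = n/(n−1)·(1 − Σ pᵢ²) averaged over
  loci (GD), and evenness *E5* = (1/λ − 1)/(e^H − 1).
- **Distance AMOVA** — one-way partition of squared Euclidean distances on
  allele-presence rows; variance components via the weighted group size
  n₀ = (N − Σ nᵍ²/N)/(k−1); **PhiPT** = Vₐ/(Vₐ+V_w); permutation test
  (label shuffles); gene flow **Nm** = (1 − Φ)/(2Φ); pairwise PhiPT/Nm
  matrices; and `amova_components()` to audit published AMOVA tables from
  their printed mean squares and group sizes.
- **Admixture-model clustering** — a simplified Gibbs sampler (Rcpp) for the
  binary admixture model, the ln P(D|K) evidence estimate
  (mean − variance/2), **Evanno ΔK** model selection, and the q > 0.8
  membership rule with admixed flagging.
- **DAPC** — PCA reduction, BIC-guided k-means cluster detection
  (`find_clusters`), Fisher discriminant axes, stratified cross-validation of
  the retained-PC count, and subset re-analysis.
- **Pedigree analysis** — cross-string parsing ("Superior x Dejima"),
  parent-usage frequencies and co-usage network edges.
- **Synthetic panels** — a Balding–Nichols generator of structured SSR
  panels with known truth (`simulate_panel`), used throughout the test suite
  in place of collection data that is not publicly deposited.

Fitted objects have broom-style `tidy()`/`glance()` methods and ggplot2
`autoplot()` support.

## Worked example

Simulate a genebank-like panel — 482 accessions × 24 SSR loci, seven origin
groups, two latent subpopulations, weak among-origin differentiation — and
run the AMOVA stage:

```r
library(ssrpop)

sim <- simulate_panel(sim_config(seed = 42))
bm  <- allele_presence(sim$table)
amova(bm, n_perm = 999, seed = 42)
#> One-way distance-based AMOVA
#>         source  df        SS      MS est_var pct
#>   Among groups   6   610.344 101.724   1.049   3
#>  Within groups 475 15973.623  33.629  33.629  97
#>          Total 481 16583.966      NA  34.678 100
#> PhiPT = 0.030 **  Nm = 16.022  (p = 0.001, 999 permutations)
```

Only 3% of the molecular variance lies among origins (PhiPT = 0.030,
p = 0.001 from 999 label permutations), and the implied gene flow
Nm ≈ 16 migrants per generation says the origin groups are nearly panmictic
— the classic signature of a breeding-exchange germplasm collection. The
locus diversity table and the pairwise origin matrix come from the same
objects:

```r
locus_table(sim$table)         # Na, Ng, H, GD, E5 per locus + mean row
group_table(sim$table)         # the same indices per origin
pairwise_phipt(bm, n_perm = 99, seed = 7)  # PhiPT above / Nm below diagonal
```

Population structure, two ways:

```r
scan <- structure_scan(bm, k_range = 1:5, n_runs = 3,
                       burn_in = 1000, n_iter = 10000, seed = 7)
ev <- evanno(scan)
best_k(ev)                          # ΔK peak
assign_membership(scan$runs[["2"]][[1]])   # q > 0.8 rule, admixed flags

pca <- pca_fit(bm)
cl  <- find_clusters(pca, k_range = 1:10, n_pcs = 60, seed = 11)
fit <- dapc_fit(pca, cl$labels, n_pcs = 60)
autoplot(fit)                       # samples on the discriminant axes
```

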