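# grassmannfuse

Patient subgrouping from multiple omics views by subspace fusion on the
Grassmann manifold.

Cohort studies increasingly measure several omics modalities — miRNA
expression, mRNA expression, DNA methylation — on the same patients, and a
clustering supported by all modalities jointly is usually more biologically
and clinically meaningful than one derived from any single view (subgroups
with distinct survival profiles, candidate disease subtypes).
`grassmannfuse` is an intermediate-integration pipeline for exactly this:
it learns a per-view representation, converts each view into a patient
similarity graph, summarizes each graph by a spectral subspace, and merges
the subspaces into one consensus representation before clustering.

## Method

For each view $m$ with patient-by-feature matrix $X^{(m)}$:

1. **z-score** each feature: $Z^{(m)}_{pf} = (X^{(m)}_{pf} - \bar X_f)/\sigma_f$;
2. **PCA**, retaining the minimal set of leading components explaining
   ≥ 95% of the variance → patient scores $H^{(m)}$;
3. **patient graph**: Gaussian-kernel similarity
   $W^{(m)}_{ij} = \exp(-\lVert H_i - H_j \rVert^2 / 2t^2)$, sparsified to
   each patient's $k$ nearest neighbours (union-symmetrized);
4. **spectral embedding**: the basis $U^{(m)}$ of the $k$ smallest
   eigenvectors of the normalized Laplacian
   $L^{(m)} = D^{-1/2}(D - \tilde W^{(m)})D^{-1/2}$.

Each $U^{(m)}$ is treated as a point on the Grassmann manifold $G(k, N)$,
with squared projection distance
$d^2_{proj}(Y, \tilde Y) = \sum_i \sin^2 \Theta_i = k - \mathrm{tr}(YY^\top\tilde Y\tilde Y^\top)$
($\Theta_i$ = principal angles). The fused representation minimizes
$\sum_m d^2_{proj}(U, U^{(m)})$; its closed form is the top-$k$ eigenvector
basis of the modified Laplacian $L_{mod} = \sum_m U^{(m)} U^{(m)\top}$.
k-means on the rows of the fused basis gives the subgroups; the subgroup
count can be chosen by a silhouette scan, and subgroups can be evaluated
against reference labels (NMI, accuracy via optimal assignment, pairwise
F-score/precision/recall, purity) or survival follow-up (K-sample log-rank
test with per-group Kaplan–Meier summaries).

A synthetic multi-view generator with a shared latent cluster structure
(`simulate_multiomics()`) makes the whole pipeline testable end to end
without any data download.

## Worked example

```r
library(grassmannfuse)

sim <- simulate_multiomics(n_samples = 120, n_clusters = 3,
                           view_feature_counts = c(100, 400, 200),
                           latent_dim = 8, separation = 4, seed = 42)
fit <- fuse_pipeline(sim$views, n_clusters = 3, seed = 42)
glance(fit)
#> # A tibble: 1 × 8
#>   n_patients n_views n_clusters embed_dim inertia silhouette fusion_objective
#>        <int>   <int>      <int>     <int>   <dbl>      <dbl>            <dbl>
#> 1        120       3          3         3  0.0972      0.844             8.95

clustering_metrics(fit$result, sim$true_labels$cluster)
#> # A tibble: 1 × 6
#>     nmi   acc f_score precision recall purity
#>   <dbl> <dbl>   <dbl>     <dbl>  <dbl>  <dbl>
#> 1     1     1       1         1      1      1

tidy(fit$fusion)
#> # A tibble: 3 × 2
#>   view        projection_distance2
#>   <chr>                      <dbl>
#> 1 mirna                     0.0202
#> 2 mrna                      0.0155
#> 3 methylation               0.0152
```

The three simulated views (100/400/200 features) share one 3-cluster
latent structure; the pipeline recovers it exactly (all agreement metrics
1.0). `glance()` summarizes the fit: the fusion objective 8.95 is
$\sum_m \mathrm{tr}(UU^\top U^{(m)}U^{(m)\top})$, close to its ceiling
$kM = 9$ — the three views' subspaces nearly coincide — and `tidy()` on the
fusion shows each view sitting at squared projection distance ≈ 0.02 from
the consensus (0 = identical span, upper bound $k = 3$).

`tidy(fit)` returns per-patient subgroup assignments with fused
coordinates; `autoplot()` methods draw the silhouette scan, the fused
embedding and Kaplan–Meier curves; `logrank_test(fit$result, surv)`
compares subgroup survival given a `patient_id`/`time_days`/`event` table.

On-disk workflows use TSV matrices (patients in rows, features in
columns, IDs in the first column): `read_views()` aligns patients across
files, `write_subgroups()`/`read_subgroups()` round-trip assignments, and
`inst/cli/grassmannfuse.R` exposes `fuse`, `simulate`, `evaluate` and
`select-k` subcommands for shell use.

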