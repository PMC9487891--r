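# mstnet

Resting-state EEG functional network analysis: phase-lag-index (PLI)
connectivity, minimum-spanning-tree (MST) network backbones, and the
group-level statistics used to compare them across cohorts and recording
conditions.

## Who this is for and what it does

EEG groups studying functional network differences — for example between
children with early versus late cochlear implantation and normally
hearing controls — need a pipeline that goes from raw multichannel
recordings to defensible group statistics without a density threshold
confounding the graph comparisons. `mstnet` implements that chain:

1. **Preprocess** — zero-phase Butterworth band-pass (0.5–30 Hz),
   resampling (500 Hz), removal of the eight periocular channels
   (128 → 120), segmentation into non-overlapping 2-s epochs with a
   fixed count per subject (72), common-average re-reference, and
   decomposition into delta (0.5–4), theta (4–8), alpha (8–13) and
   beta (13–30 Hz) bands; plus Welch-style absolute and relative band
   power.
2. **Connectivity** — instantaneous phases from the analytic (Hilbert)
   signal, and per-epoch connectivity between every channel pair

   `PLI = | < sign[ sin(Δφ(t_k)) ] > |`,

   the asymmetry of the phase-difference distribution around zero. PLI
   is 0 for no coupling *or* coupling at zero lag (which is what
   volume conduction produces) and 1 for perfect locking at any
   nonzero lag. Region-of-interest connectivity averages PLI over all
   electrode pairs spanning two scalp regions (temporal, occipital,
   parietal, left/right).
3. **Tree backbone** — per epoch, Kruskal's algorithm on link weights
   1/PLI yields the minimum spanning tree (120 nodes, 119 links): the
   strongest-coupling backbone, density-free by construction. A
   ten-metric panel summarises each tree: maximum degree, leaf number
   L, diameter, eccentricity, radius, strength, betweenness and
   closeness centralities, degree broadness κ = ⟨k²⟩/⟨k⟩, and tree
   hierarchy Th = L / (2·M·BCmax).
4. **Statistics** — log transform, Shapiro–Wilk gate choosing between a
   parametric and an aligned-rank-transform 2 (condition) × 3 (group)
   mixed ANOVA with age/IQ covariates, Bonferroni post-hocs, and
   permutation-tested Pearson correlations (5,000 permutations)
   between tree metrics and speech-perception accuracy.
5. **Synthetic ground truth** — a generator of band-limited
   multichannel signals whose cross-channel phase differences follow a
   controllable coupling graph, and of whole cohorts (group sizes
   31/24/29) with a known group-by-condition coupling effect and a
   known topology→behaviour slope, used to validate every stage.

Everything tabular flows as tibbles, chains with the pipe, and has
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Simulate a small cohort with a theta-band hub-coupling difference in the
eyes-closed condition and a behavioural slope on hub breadth, then run
the full pipeline:

```r
library(mstnet)

cohort <- generate_cohort(
  cohort_spec(n_per_group = c(eCI = 12, lCI = 12, NH = 12)),
  seed = 42
)
cfg <- pipeline_config(
  bands = band_definitions("theta"),
  target_rate = NULL,          # recordings are already at 128 Hz
  n_epochs = 4,
  eye_channels = character(0), # 14-channel synthetic montage
  rois = NULL,
  n_perm = 1000, seed = 1
)
res <- run_pipeline(cohort, cfg, metrics = c("kappa", "leaf"),
                    cor_metrics = "kappa")

dplyr::filter(res$anova, metric == "kappa")
#> # A tibble: 3 × 9
#>   band  metric effect            df1   df2     F         p   eta2 route     
#>   <chr> <chr>  <chr>           <dbl> <dbl> <dbl>     <dbl>  <dbl> <chr>     
#> 1 theta kappa  group               2    33  4.82 0.0145    0.226  parametric
#> 2 theta kappa  condition           1    33  1.55 0.223     0.0447 parametric
#> 3 theta kappa  group:condition     2    33 13.2  0.0000618 0.444  parametric
```

The group-by-condition interaction on theta-band kappa (F(2, 33) = 13.2,
p = 6.2e-5, partial η² = 0.44) recovers the injected effect: the lCI
group's hub coupling was narrowed only in the eyes-closed condition, so
its trees are less star-like there and the group differences vanish in
the eyes-open condition. Behaviour tracks topology among the implanted
children:

```r
ci <- dplyr::filter(res$metrics, condition == "EC", group != "NH")
perm_correlation(ci$kappa, ci$acc, n_perm = 5000, seed = 7) |> generics::tidy()
#> # A tibble: 1 × 4
#>   estimate  p.value     n n_perm
#>      <dbl>    <dbl> <int>  <dbl>
#> 1    0.671 0.000400    24   5000
```

A Pearson r of 0.67 with permutation p = 4e-4 (the minimum attainable at
5,000 permutations is 1/5001): subjects with broader ground-truth hubs
have both higher kappa and higher accuracy. `plot_metric_by_group(res$metrics, "kappa")`
and `plot_behavior_correlation(ci, "kappa")` draw the corresponding
panels.

At full montage scale the tree size is fixed by construction:

```r
set.seed(1)
m <- matrix(runif(120^2), 120); m <- (m + t(m)) / 2; diag(m) <- 0
build_mst(m)
#> <spanning_tree> 120 nodes, 119 links, total 1/PLI distance 128.3
```

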