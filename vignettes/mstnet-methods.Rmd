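---
title: "Methods: phase-lag-index connectivity and minimum-spanning-tree topology of resting-state EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLI connectivity and MST topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstnet)
```

## The analysis in one paragraph

Resting-state EEG functional networks are compared across groups of
children (early cochlear implantation, eCI; late implantation, lCI;
normal hearing, NH) and eye conditions (closed, EC; open, EO). Continuous
recordings are band-pass conditioned, epoched, average-referenced and
decomposed into delta/theta/alpha/beta bands; functional connectivity
between every channel pair is the phase lag index (PLI), computed per 2-s
epoch; each epoch's weighted connectivity matrix is reduced to its
minimum spanning tree (MST) with link weight 1/PLI; a ten-metric topology
panel summarises each tree; subject-level (epoch-averaged) metrics enter
a normality-gated mixed ANOVA with covariates and permutation-tested
correlations with speech-perception accuracy. A synthetic generator with
a known phase-coupling graph supplies ground truth for every stage.

## Signal model and preprocessing

A recording is a channels-by-samples matrix at a known sampling rate
(`recording()`). Conditioning (`condition_signal()`) applies a zero-phase
Butterworth band-pass (default 0.5–30 Hz) and resamples (default 500 Hz).
Zero net phase shift matters because the connectivity measure lives
entirely in the phase domain; forward–backward (filtfilt) application of
a 4th-order Butterworth achieves it. Two numerical details:

* **Filter topology.** A true band-pass of order 4 is used whenever the
  lower band edge is at least 0.002 of the Nyquist frequency; its
  passband is flat, so in-band tones are preserved to within about 1%.
  Below that edge ratio the band-pass recursion is numerically unstable
  (poles virtually on the unit circle), and a cascade of 4th-order
  high-pass and low-pass substitutes; it is unconditionally stable at
  the cost of slight passband droop. With the default 500 Hz rate every
  analysis band, including delta (0.5–4 Hz), uses the flat band-pass.
* **Resampling.** When the rate ratio is an integer the signal is
  decimated by plain subsampling — the preceding band-pass has already
  removed all content above the target Nyquist, so this is alias-free
  and exactly amplitude-preserving. Non-integer ratios fall back to
  polyphase resampling.

Epoching (`epoch_and_select()`) tiles the recording into non-overlapping
consecutive 2-s windows. Visual/ICA artifact screening is out of scope
here; its deterministic surrogate is a peak-amplitude threshold, after
which the *first* `n_keep` surviving epochs (default 72) are retained in
time order. Fixing the epoch count per subject keeps the variance of
network metrics comparable across subjects. Head selection (rather than
random selection) was chosen because it is reproducible without extra
state; with clean synthetic data the two coincide.

Average re-referencing (`rereference_average()`) subtracts the
instantaneous mean over the retained channels, and is applied after the
eight periocular channels are removed (`drop_channels()`; the default
list E8, E14, E21, E25, E125–E128 covers the standard periocular
positions of a 128-channel geodesic net and is configurable, since
montages differ). Re-referencing is idempotent; a second application is
flagged.

Band decomposition uses the same zero-phase filters. Inside
`run_pipeline()` bands are filtered on the *continuous* conditioned
signal and then sliced at the selected epoch windows: filtering a 2-s
segment directly loses a noticeable fraction of variance to edge
transients, while continuous filtering has a single transient at each
end of the recording. The epoch-level operator (`band_decompose()`)
remains available and is what the tests use to characterise the filter
responses.

Band power (`band_power()`) averages per-epoch periodograms (the epochs
act as Welch segments) and integrates them over each band; relative
power divides by total 0.5–30 Hz power, so the four bands sum to one up
to band-edge coverage.

## Phase lag index

The instantaneous phase of each band-limited channel is the angle of its
analytic signal (frequency-domain Hilbert construction,
`instantaneous_phase()`). For two phase series the PLI is

$$\mathrm{PLI} = \left| \left\langle \operatorname{sign}\,
\sin\!\big(\Delta\phi(t_k)\big) \right\rangle \right|,$$

the absolute mean sign of the sine of the phase difference: the
asymmetry of the phase-difference distribution around zero. Differences
of exactly 0 or $\pi$ contribute zero, which is the point of the index —
instantaneous (volume-conduction-like) mixing produces zero-lag
coupling, and the PLI is blind to it. PLI is 0 for no coupling or
zero-centred coupling and 1 for perfect locking at any nonzero lag.

Two implementation choices:

* A configurable fraction (default 5%) of samples at each epoch end is
  excluded from the PLI sums, because the analytic signal is distorted
  near segment boundaries.
* Samples where $\sin\Delta\phi$ is exactly zero contribute 0 to the
  mean (they lower the index rather than inflate it), consistent with
  the index's insensitivity to 0/$\pi$ differences.

Connectivity between scalp regions (`roi_mean_pli()`) is the unweighted
mean PLI over all cross-region electrode pairs; the default six regions
(left/right temporal, occipital, parietal; 7–9 electrodes each) target
the auditory, visual and somatosensory cortices of the 128-channel
montage.

## Minimum spanning tree and the metric panel

Thresholded graph metrics depend on connection density, which confounds
group comparisons; the MST avoids the choice of threshold by always
keeping exactly $N-1$ links. With link weight $1/\mathrm{PLI}$,
Kruskal's algorithm (`build_mst()`) retains the strongest couplings that
join all channels without cycles — 119 links for the 120-channel
montage. Ties in PLI are broken by ascending channel-index order so the
tree is deterministic (with continuous weights, exact ties have measure
zero); zero-PLI entries receive distance $1/\varepsilon$
($\varepsilon = 10^{-12}$), which guarantees a spanning tree exists
while such links are chosen only when no positive-PLI alternative is
left.

`tree_metrics()` reports, per tree: maximum degree; leaf number $L$
(degree-1 nodes); hop-based diameter, per-node eccentricity (reported as
its mean over nodes) and radius; node strength (sum of incident PLI
weights; maximum and mean); betweenness centrality as the *raw count* of
node pairs whose unique tree path crosses the node (maximum and median);
hop-based closeness centrality (maximum and median); the degree
broadness $\kappa = \langle k^2\rangle/\langle k\rangle$; and tree
hierarchy

$$T_h = \frac{L}{2\,M\,\mathrm{BC}_{\max}}, \qquad M = N - 1 .$$

Several conventions in published metric panels for this analysis are
ambiguous; the package resolves them as follows, each choice checked for
magnitude consistency against tabulated group means on 120-node trees:

* **Strength** uses PLI (not $1/\mathrm{PLI}$) weights: tabulated mean
  strengths (≈1.65 delta, ≈0.83 beta) lie below the forced mean degree
  $2\cdot119/120 \approx 1.98$, which is impossible for weights
  $1/\mathrm{PLI} \ge 1$.
* **Betweenness** is reported as raw pair counts, not normalised:
  tabulated maxima near 4,700 (for $N = 120$, where the star maximum is
  $\binom{119}{2} = 7{,}021$) and the tabulated $T_h \approx 6\times
  10^{-5}$ are only mutually consistent with raw counts.
* **Closeness, eccentricity, radius** use hop distances; tabulated radii
  (~10.4) and closeness maxima (~0.002) match hop metrics on a 120-node
  tree, not $1/\mathrm{PLI}$-weighted distances.
* **Eccentricity** is summarised as the mean over nodes, the only scalar
  reading lying strictly between the radius and the diameter bound.
* **Diameter.** The true hop diameter is reported as `diameter`. The
  tabulated "diameter" columns in the source panels instead satisfy
  leaf + diameter ≈ $N + 1$ almost exactly and violate
  diameter ≤ 2·radius, so they cannot be the graph-theoretic diameter;
  the package therefore also emits `reported_diameter` $= N + 1 - L$ as
  a compatibility value. (Two tabulated theta-band cells sum to 121.04
  and 121.13 rather than 121.00 — presumably rounding or typos — so the
  compatibility formula cannot be confirmed exactly for those cells.)
* **Kappa.** No explicit formula accompanies "broadness of the degree
  distribution"; $\kappa = \langle k^2\rangle/\langle k\rangle$ is the
  standard choice in the MST-EEG literature and reproduces the tabulated
  magnitude (≈3.2–3.7).

Per-epoch panels are averaged per subject, condition and band
(`aggregate_epochs()`); aggregation across 72 epochs shrinks the
sampling noise of each metric roughly as $1/\sqrt{72}$.

## Statistics

Metrics are natural-log transformed (all are strictly positive by
construction; a nonpositive value is treated as a data error rather than
silently offset). A Shapiro–Wilk test runs per group × condition cell;
if any cell rejects at $\alpha = 0.05$ the analysis routes to the
aligned-rank procedure, otherwise to the parametric mixed ANOVA
(`transform_and_gate()`). Cells that are too small or constant are
flagged degenerate and do not influence the route.

The factorial model is 2 (condition, within-subject) × 3 (group,
between-subject). Age and nonverbal IQ enter as covariates by **pooled
within-group residualisation**: their slopes are estimated in a linear
model that includes the design factors (so group differences are not
absorbed into the slopes) and then removed from the response before the
factorial fit. This choice is a documented substitute — the aligned-rank
procedure has no canonical covariate formulation, and applying one
common adjustment to both routes keeps them comparable. Partial
$\eta^2$ accompanies each $F$.

The aligned rank transform (`art_anova()`) aligns the response for each
effect by subtracting the cell-mean estimates of all *other* effects,
ranks the aligned values across the whole dataset, and applies the same
mixed ANOVA to the ranks, reading off only that effect. Post-hoc
pairwise group contrasts run within each condition with Bonferroni
correction (raw $p$ × family size, capped at 1). Variance homogeneity
(Brown–Forsythe) is reported as a diagnostic and is non-blocking.

Behaviour correlations (`perm_correlation()`) are Pearson coefficients
with permutation $p$-values,
$p = (1 + \#\{|r_{\text{perm}}| \ge |r_{\text{obs}}|\})/(1 + n_{\text{perm}})$,
5,000 permutations by default, two-sided, Bonferroni-corrected across
the metric family; subjects are relabelled within the group being
tested. The "+1" convention keeps the test exact (never anti-conservative).

## The synthetic generator: what it emulates and what it does not

`generate_recording()` synthesises band-limited multichannel signals
with a controllable coupling graph. Each free channel carries a latent
phase: a ramp at a base frequency drawn uniformly within the band, a
uniform starting phase, and a Gaussian random-walk drift (default 0.05
rad/sample). Drawing distinct base frequencies is what makes independent
channels genuinely incoherent at 2-s epoch scale — identical pure
sinusoids would have frozen phase differences and degenerate PLI, which
is also why the degenerate no-drift configuration (an exact cosine) is
reserved for closed-form tests. A driven channel's phase is its driver's
phase minus the lag $\delta$ plus wrapped-normal noise with standard
deviation $1/\sqrt{\kappa}$ (a von Mises-style concentration
parameterisation: $\kappa \to \infty$ is perfect locking, $\kappa = 0$
uniform). The estimated PLI of a coupled pair rises monotonically with
$\kappa$, and a pair with $\delta = 0$ is indistinguishable from an
independent pair — the volume-conduction control.

`generate_cohort()` builds the three-group, two-condition design: group
sizes default to the study design (31/24/29); ages and IQs follow the
published group demographics. Coupling ground truth is a theta-band hub:
channel 1 drives $h$ neighbours at lag $\pi/2$, concentration 6, where
the hub breadth $h$ is drawn per subject and condition from a
group-dependent range. Eyes-closed ranges are 5–9 for eCI and NH but
2–5 for lCI; eyes-open ranges are 3–7 for everyone — so the injected
group difference exists only in the EC condition, mirroring the
reported interaction pattern. A broader hub produces a more star-like
tree (higher leaf, degree, kappa), so the injection is visible in
exactly the metrics the analysis panel tracks. Speech-perception
accuracy follows `acc = 45 + 4·h_EC + N(0, 9)`, clipped to [0, 100]:
with the default ranges this yields group means near 73/61/73% and a
metric–behaviour correlation of about 0.5–0.6 within a CI group —
matching the published standardized effect sizes (interaction
$\eta^2 \approx 0.1$–0.2, $r \approx 0.5$–0.6), which is the scale at
which "recovery" is a meaningful claim. One master seed spawns
independent per-subject substreams, so cohorts are bit-reproducible
while subjects stay independent.

Deliberately *not* emulated: biophysical volume conduction and head
geometry (only its zero-lag signature), cochlear-implant electrical
artifacts, eye movements, 1/f background spectra, and any spatial
correlation structure beyond the coupling graph. Passing tests on this
generator therefore demonstrate that the estimators and the inference
chain recover known coupling and behaviour structure — not that they
would survive every real-data artifact; the artifact-handling steps that
deal with those (ICA, visual inspection, interpolation) are outside this
package's scope.

## Problem sizes used by the test suite

The validation suite runs the full chain at reduced geometry chosen as
the package's desk-scale default: cohorts of 31/24/29 subjects with
14-channel, 8-s, 128-Hz recordings and four 2-s epochs per condition,
theta band. These sizes keep a 50-replicate end-to-end recovery study
(interaction detection plus kappa–accuracy correlation) in the
several-minute range while leaving the statistical design at full
strength; the single-recording path is exercised at the full
120-channel scale where the claim concerns tree size. Estimator
calibration uses 1,000 null simulations per route at 30 subjects;
permutation tests in simulations use 199–499 permutations (the exact
"+1" convention makes the attainable $p$ resolution explicit), while
the analysis default stays at 5,000.

## Known limitations

* The epoch-selection surrogate (amplitude threshold + head selection)
  is not a substitute for ICA-based artifact removal on real data.
* The cascade fallback for extreme normalized band edges has passband
  droop (about 12% amplitude at the delta centre when filtering at
  1,000 Hz); conditioning to 500 Hz first, as the default pipeline
  does, avoids it entirely.
* The ~2× spread between delta- and beta-band closeness magnitudes in
  the published panels is not explainable under any single distance
  convention tried; the hop-distance convention adopted here matches
  the majority of the panel and is flagged rather than resolved.
* The aligned rank transform is anticonservative on strongly *skewed*
  responses (its alignment relies on cell means); in this pipeline it is
  only ever applied after the log transform, and its type-I calibration
  is verified on that scale with symmetric heavy-tailed noise.
* ART with continuous covariates has no canonical definition; the
  residualisation used here is a documented substitute, and parametric
  and ART routes agree in accept/reject terms on normal data in the
  suite's concordance check.
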