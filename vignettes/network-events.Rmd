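---
title: "Detecting and characterizing dentate network events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing dentate network events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgnet)
```

# Background

Dentate granule cells are among the most sparsely active neurons in the
hippocampus: in head-fixed mice on a treadmill, a typical cell emits on the
order of one calcium event per minute. Against this sparse background,
immobile animals intermittently produce brief synchronous activations of a
few percent of the population — *network events* (NEs). dgnet implements the
per-session statistics needed to detect these events from binarized
two-photon calcium imaging and to characterize their structure: how
orthogonal the events are to one another, whether specific sub-ensembles
recur across events, how place- and speed-coding cells participate, how the
events relate to bulk input-pathway (medial perforant path, MPP) activity
and to pupil-linked arousal, and whether the population patterns expressed
during immobility resemble those expressed during locomotion.

All analyses operate on a per-session bundle: a binary event-onset raster
(cells × frames, 15 Hz), continuous ΔF/F traces, running speed and belt
position on a circular track, and optional bulk MPP and pupil traces.
Frames are indexed 1-based throughout, the R convention; behavioral epochs
are inclusive integer intervals `[start, end]`.

# Network-event detection

An NE is operationalized as a moment when many distinct cells emit onsets
within a short moving window. `window_counts()` counts, for every frame,
the distinct cells with at least one onset in a centered window of 3 frames
(200 ms at 15 Hz); multiple onsets of one cell in a window count once.

Because sparse independent activity also produces coincidences, the minimal
NE size is calibrated per session against shuffled rasters
(`size_threshold()`). Three surrogate constructions are available, each
conserving every cell's onset count exactly:

* **redistribute** — onset times are redrawn uniformly, destroying all
  temporal structure (the default for thresholding);
* **trace_shift** — each cell's onset train is circularly shifted,
  preserving within-cell interval structure while destroying between-cell
  alignment;
* **state_constrained** — onsets are redrawn only within their behavioral
  state, so state-dependent rate differences survive the shuffle.

For each candidate size $s$, the fraction of events explainable by chance is
estimated as the pooled number of size-$\ge s$ events across shuffles
divided by $n_\text{shuffles}$ times the real count; the threshold is the
smallest $s$ at which this fraction falls below $\alpha$ (default 0.001).
When the real raster has no events of size $\ge s$, the fraction is 0 if the
shuffles also produce none and effectively infinite otherwise; on fully
structureless rasters the threshold therefore settles just above the largest
coincidence the shuffles can produce, and fresh structureless rasters
yield essentially no detections. An alternative rule (`"per_shuffle"`: the
fraction of shuffles containing any size-$\ge s$ event) is switchable, since
the pooled-count reading is one of two defensible operationalizations. For
$\alpha \ge 1$ the criterion is vacuous and the threshold degenerates to 2.

`detect_network_events()` merges maximal supra-threshold runs of frames into
single events (the merging rule is ours; the peak is the count argmax,
earliest on ties) and collects as members every cell with an onset within
the run extended by the half-window. `ne_state_stats()` reports run/rest
counts and frequencies; duration-equalized frequencies truncate the longer
state's timeline by a seeded random contiguous subsample, since the two
states never have equal duration in practice.

# Orthogonality and sub-ensembles

Each NE is summarized by a binary participation vector over cells
(`participation_matrix()`). Cosine similarity between two events is the
normalized dot product of their vectors — 1 for identical member sets, 0 for
disjoint ones. `orthogonal_fraction_test()` compares the observed fraction
of exactly-orthogonal pairs against a null in which every event's members
are redrawn uniformly, preserving each event's participant count; the
p-value is one-sided for greater-than-chance orthogonality.

Recurring sub-ensembles are found by agglomerative clustering of the cells'
participation rows (`hierarchical_clusters()`), using a standardized
Euclidean distance (coordinates scaled by their standard deviation across
cells) and weighted average (WPGMA) linkage. Significance is calibrated by
`cluster_threshold_null()`: each cell's participations are reassigned to
uniformly chosen events 1000 times, all pairwise Pearson correlations are
pooled, and the 95th percentile is the cluster threshold.

Two choices here deserve comment.

* **Cluster definition.** We report the *maximal dendrogram nodes* whose
  mean internal pairwise correlation exceeds the threshold: agglomeration
  inside such a node effectively continues until adding further cells would
  drop its internal mean below significance. A sequential variant that
  applies merges in tree order while the pooled within-cluster mean stays
  above threshold is available (`merge_stop_rule = "global_mean"`), but it
  is fragile on sparse data: cells with few participations have the
  *smallest* standardized Euclidean distances (their rows are mostly equal
  zeros), merge first, and pull the pooled mean down before genuinely
  correlated ensembles get merged, fragmenting them.
* **Minimum participation.** Cells with fewer than 2 event participations
  are excluded before clustering. A correlation estimated from a single
  participation is degenerate — any two single-event cells sharing that
  event correlate at exactly 1 — and such pairs otherwise flood the output
  with spurious two-cell clusters.

# Place and speed coding

`spatial_tuning_vector()` maps the belt to the unit circle and averages unit
vectors pointing at the animal's position at each run-epoch onset, each
weighted by the reciprocal of the occupancy time of its 3 cm spatial bin;
weights are normalized to sum to 1, so the resultant length lies in [0, 1]
and reaches 1 for a perfectly concentrated cell regardless of occupancy.
Cells with fewer than 4 run-epoch onsets are not tested.
`place_cell_test()` redraws the onset frames uniformly over run frames 1000
times; the p-value is the fraction of shuffled vector lengths exceeding the
observed one. Note that the resultant length of $n$ uniform unit vectors
scales as $1/\sqrt{n}$, which is why the shuffle must condition on the
observed onset count.

`speed_tuning()` bins speed into 20 equal-width bins between 0 and the
session maximum and correlates bin centers with mean ΔF/F per bin. By
default all frames enter the binning, so the lowest bin contains immobility
frames (`running_only` switches this). A candidate speed cell needs
$r \ge 0.9$; significance additionally requires that circular time-shifts of
the trace against fixed behavior fall below the observed $r$ in at least 95%
of shuffles (`speed_cell_test()`). Because the within-bin mean speed is
never exactly the bin center in a finite sample, $r$ for a perfectly linear
cell is slightly below 1 — the 0.9 candidacy criterion is far from this
limit.

# Bulk MPP input and pupil

The bulk MPP trace is converted to ΔF/F against a slow baseline — the
zero-phase low-pass filtered raw trace at 0.01 Hz (`bulk_dff()`). Transients
are recovered by inverting the single-exponential calcium forward model:
with $g = e^{-1/(f_s \tau)}$, the activity proxy is
$s_t = y_t - g\,y_{t-1}$, clipped at zero (`deconvolve_bulk()`, τ default
1.5 s, GCaMP6s-like). Events are local maxima of the proxy above a
noise-scaled floor (3 × a robust noise estimate); amplitudes are reported
raw and normalized to the proxy's per-session standard deviation. "Large"
events exceed the mean amplitude by 2 standard deviations
(`bulk_event_state_stats()`).

`mpp_gc_crosscorr()` correlates the MPP ΔF/F with summed granule-cell
activity at integer lags over immobility frames (Pearson correlation on the
lag overlap, so a shifted copy of a signal correlates at exactly 1 at its
lag). `granger_test()` runs the nested-autoregression F-test with the lag
order chosen by BIC; the F-test itself is delegated to
`lmtest::grangertest()`. `ne_mpp_delay()` reports the signed delay from
each NE to its nearest deconvolved MPP event, positive when the input leads.

Pupil traces are preprocessed by linear interpolation across blink-masked
frames (interpolation rather than deletion keeps a uniform time base for
filtering and alignment), zero-phase 4th-order low-pass filtering at 4 Hz,
resampling to the imaging rate, and normalization to unit mean
(`preprocess_pupil()`). `pupil_state_stats()` averages diameter and its
first-difference rate of change over locomotion epochs, immobility epochs,
and the single frame of peak summed granule-cell activity within each NE
window.

# Locomotion–immobility population similarity

The ΔF/F matrix is z-scored per cell and decomposed by PCA
(`pca_basis()`; X = VW via SVD/eigendecomposition, eigenvector signs fixed
by making the largest-magnitude loading positive). The component count $k$
is the smallest explaining ≥ 50% of variance. Three similarity measures
compare the locomotion basis $V_{run}$ (from all run-epoch frames) with the
NE basis $V_{net}$ (from 2 s windows centered on NE peaks, ±1 s):

* the **projected variance ratio**
  $\mathrm{tr}(V_{net}^\top C_{run} V_{net}) /
   \mathrm{tr}(V_{run}^\top C_{run} V_{run})$,
  where $C_{run}$ is the run-epoch covariance;
* $S_{PCA} = \mathrm{tr}(V_{net}^\top V_{run} V_{run}^\top V_{net})
  = \sum_i \cos^2\theta_i$ over principal angles (Krzanowski);
* $\mathrm{EROS} = \sum_i w_i\,|\cos\theta_i|$ over *paired* principal
  directions, with $w_i$ the renormalized average of the two eigenvalue
  fractions (the published EROS aggregates eigenvalues over a corpus; a
  two-matrix reduction is needed here and averaging is the natural one).

When the two bases have different $k$, $S_{PCA}$ and EROS truncate to the
smaller count. `geometry_shuffle_test()` builds nulls with three shuffles
that never touch the run side: circular time-shifts of each cell's
immobility series (≥ 5 s, re-reading the original NE windows from the
shifted traces); permutation of cell identities within each NE window; and
permutation of each cell's window segments across NEs. For the two
within-NE shuffles, observed and null measures are computed on the same
concatenated matrix of full equal-length NE windows (edge-clipped events
dropped), so the comparison is like for like.

One numerical caveat: $k$ is re-selected for every shuffled basis, as the
50%-variance rule implies. If the observed spectrum is much sharper than the
shuffled one — as in low-rank toy constructions — the shuffled $k$ exceeds
the observed $k$ and the projected-variance-ratio null shifts upward, making
the per-cell-reassignment variant conservative there. At session scale, with
broad spectra, the effect is negligible.

`weight_lap_autocorr()` quantifies the lap-periodicity of population
activity: the leading run-epoch component weights are resampled onto a
uniform position grid per lap (150 bins; bin means with linear interpolation
across gaps; laps covering < 75% of bins are dropped), concatenated, and
autocorrelated; the value at a lag of exactly one lap, averaged over the
first five components, is the periodicity score. The autocorrelation at a
lag is a Pearson correlation over the overlap, so perfectly periodic weights
score exactly 1.

# The synthetic-session generator

`generate_session()` produces sessions with planted ground truth so that
every stage can be validated end to end. The generator's defaults encode the
study conditions the analyses are designed for:

* 20-minute sessions at 15 Hz on a 150 cm belt; alternating immobility and
  running bouts (gamma-distributed, means 20 s and 8 s) with plateau speeds
  of 8–14 cm/s, giving session distances of roughly 30–40 m; immobility is
  *completely* immobile (speed exactly 0), so the "events during complete
  immobility" statistic is representable;
* background onsets at 1 event/min/cell (Poisson);
* 30 planted NEs at immobility frames (≥ 3 s apart), sizes ~N(11, 1.5²)
  cells — about 5–7% of the 200-cell population — with onset jitter of ±1
  frame;
* four sub-ensembles of 7 cells; each NE recruits one ensemble (members
  join with probability 0.9) plus random filler cells;
* 5% place cells with von Mises fields (κ = 4 — concentrated enough to be
  detectable but far from trivial — and 3 extra events/min in-field during
  running) and 2% speed cells. Speed cells couple ΔF/F linearly to speed
  (0.03 ΔF/F per cm/s) with a mild rate scaling: the detector operates on
  binned ΔF/F, so the ground-truth parameter is a ΔF/F slope;
* a *replay* coupling (`replay_strength`): each sub-ensemble shares a von
  Mises place field whose field-modulated bulk drive is added to every
  member's ΔF/F during running. This aligns run-epoch covariance with
  NE covariance — the structure the subspace-similarity tests are designed
  to detect — without adding raster onsets that would confound NE
  detection. Setting `replay_strength = 0` yields replay-negative control
  sessions;
* bulk MPP: positive baseline with slow drift, frequent small transients
  during running, sparse ones during immobility, and a large transient
  leading each NE by 2 frames; ΔF/F kernels are single-exponential with
  τ = 1.5 s (the binarization upstream of the real data means no kernel is
  ever stated for it; GCaMP6s-like decay is the natural choice);
* pupil: first-order dilation dynamics toward a higher set-point during
  running, Gaussian constriction transients (amplitude 0.15) at NE frames,
  and ~0.3% blink-dropout frames.

Generation is deterministic given `(params, seed)`; per-stage seeds are
derived from the master seed, so stages can be regenerated in isolation.

**What the generator does not emulate.** Calcium dynamics are linear
single-exponential kernels without saturation, rise time, or
indicator-specific nonlinearity; onsets are conditionally Poisson without
refractoriness or burstiness; behavior has no acceleration structure,
grooming, or reward events; the replay coupling is a stationary
field-locked drive rather than sequential reactivation. Passing the
recovery tests therefore demonstrates that the *statistics are implemented
correctly and calibrated*, not that they would behave identically on real
recordings, where these complications are present.

# Numerical choices

* Zero-phase filtering uses 4th-order Butterworth coefficients applied
  forward and backward with odd-reflection padding of three filter time
  constants, which suppresses the edge transients a recursive filter
  otherwise produces at very low cutoffs (0.01 Hz baselines).
* The deconvolution proxy zeroes values below `1e-8 × max` before noise
  estimation, so exact exponential decays do not leave floating-point
  residue that would masquerade as noise; near-noiseless traces (fewer than
  1% positive proxy values) fall back to an epsilon floor.
* Cosine similarities divide by `sqrt(‖u‖²·‖v‖²)` rather than
  `sqrt(‖u‖²)·sqrt(‖v‖²)`, so identical member sets score exactly 1.
* Pearson correlations between binary participation rows exclude
  zero-variance rows; identical non-constant rows correlate at 1.
* Detection ties (equal window counts across a supra-threshold run) resolve
  to the earliest frame; eigenvector signs are fixed by the
  largest-magnitude-loading convention so paired principal angles are
  deterministic.
* Supra-threshold locomotion bouts shorter than 2.5 s belong to neither
  run nor rest: they fail the run duration criterion but are not
  "running speed < 4 cm/s" either. A switch
  (`rest_includes_short_bouts`) folds them into rest for sensitivity
  analyses.

# Validation scale

The test suite validates the chain at sizes chosen to finish in minutes on
one core: oracle equivalence of the detector on 200 random rasters up to
20 cells × 300 frames; null calibration of the size threshold on
200-cell × 18000-frame Poisson rasters (200 shuffles, 100 fresh rasters);
place/speed/Granger false-positive calibration on 100–500 null cells or
series; and ground-truth recovery (detection, sub-ensembles, place cells,
subspace similarity under all three shuffles, lap-periodicity contrast) on
batches of ten 200-cell default sessions with 200 shuffles per test.
`scripts/acceptance.R` re-runs the full pipeline on one default session and
writes the headline quantities as JSON.

# Limitations

The package consumes binarized rasters and ΔF/F; motion correction, source
extraction, and single-cell event detection are upstream and out of scope.
Group-level inference across animals (repeated-measures designs) is not
reimplemented; `compare_conditions()` provides only two-condition,
session-level contrasts. The clustering and orthogonality analyses read NE
membership as binary participation; a frame-resolved variant within NE
windows would be a natural extension.
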