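---
title: "Methods: calcium-event segmentation, motility statistics, and signature filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium-event segmentation, motility statistics, and signature filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the model behind
each statistic, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the underlying analysis left the design open.

## The measurement model

A two-photon time-lapse run yields, per tracked cell and per frame (every
`frame_interval_s` = 10 s by default), a 3D position in μm and two
fluorescence intensities: the calcium-bound and calcium-unbound channels of
a ratiometric indicator. Two derived series carry all downstream analysis:

* the **calcium ratio** `r_t = bound_t / unbound_t` (dimensionless;
  independent of dye load, hence comparable across cells), and
* the **instantaneous speed** `v_t` = Euclidean displacement from frame
  `t−1` to `t`, divided by the frame interval, in μm/min.

Speed at a track's first frame is undefined and omitted: the analysis uses
a trailing backward difference, and the smoothed speed is a *trailing*
rolling mean over `speed_smoothing_window` = 2 timepoints (20 s). Whether
the original analysis used backward, forward, or centered displacement is
not documented by trackers uniformly; the trailing convention is this
package's documented choice, and a window of 1 recovers `v_t` exactly.
Tracks are split at frame gaps longer than one interval — a gap means the
spot detector lost the cell, and bridging it would manufacture a spurious
large displacement. Fragments are treated as independent tracks
(`id.1`, `id.2`, …).

## Event segmentation

Let `B` be the background ratio: the mean of `r_t` over all timepoints of
all tracks imaged under **nonselecting** conditions (tissue lacking the
restricting MHC, where TCR-driven flux is absent; ≈ 0.675 for the reference
genotypes). `estimate_background()` pools across runs by default; a
`per_run` scope exists because run-wise background subtraction is a
plausible alternative, but the pooled mean is the default since a single
reference value is the published convention.

Segmentation is hysteresis thresholding with persistence:

* **trigger**: an event starts at the *first* of ≥ `min_consecutive` (2)
  consecutive timepoints with `r ≥ B + δ_high` (δ_high = 0.2; values
  exactly at threshold count as high);
* **release**: the event ends at the *first* of 2 consecutive timepoints
  with `r < B + δ_low` (δ_low = 0.1); the span is half-open
  `[start, end)`, so `duration = (t_end − t_start)`;
* a track that ends while signaling yields an **incomplete** event: no end,
  no duration; scanning resumes after each release pair.

The two-level rule is what makes the segmentation robust: with amplitude
0.3 and noise SD 0.03, an in-event dip must fall > 6σ to break an event,
and baseline noise must rise > 3σ twice in a row to start one. The
inequality directions (≥ for trigger, < for release) follow the stated
rules verbatim; a `smooth_window` option applies a trailing rolling mean to
`r_t` before thresholding (default off — raw ratios are the plainest
reading; the smoothing option mirrors the 2-point speed averaging for users
who want the "average ratio" reading).

Three statistics sit on top:

* **Durations** use only each track's *first* event, and only if complete —
  truncated events would bias durations down, and later events are
  conditionally sampled (they require the track to have survived the first).
* **Percent elevated timepoints** classifies each timepoint independently
  (`r ≥ B + δ_high`, no persistence): it is a per-condition occupancy
  measure, not an event count, and is the plainest per-timepoint reading.
* **Frequency** counts events merged across nonsignaling gaps shorter than
  `quiescence_gap_s` = 240 s — rapid re-triggering is one biological
  signaling episode — divided by the cumulative track time (sum of per-track
  last-minus-first times over *all* compiled tracks, signaling or not).
  Track boundaries count as bounding quiescence by default
  (`boundary_quiescence = TRUE`), so boundary-truncated events still count
  toward frequency (never toward duration); with 15–20 min tracks and 4 min
  events, requiring recorded flanking quiescence would systematically
  undercount. The strict mode is provided and tested.

## Aligned kinetics and the pause index

`align_events()` shifts each signaling track so its **first** event onset
(the trigger timepoint, i.e. the initial calcium rise) sits at time 0, then
averages ratio and speed across tracks on the grid
`[−window_pre_s, +window_post_s]` (defaults 60 s and 600 s; the published
plots include pre-onset context but do not state their extent). Averaging
is ragged — each track contributes wherever it has data — so the
per-timepoint `n_cells` is reported and `n_cells[0]` equals the number of
aligned events. First-event alignment matches the duration statistic; an
all-events mode exists. Curves use the smoothed speed by default, while the
pause index uses the instantaneous speed — mirroring how the two speed
definitions are used in the source analysis. SDs (not SEMs) are reported,
with n exposed so either can be derived.

The **pause index** of a track is
`mean(v_t | nonsignaling) − mean(v_t | signaling)`, with signaling defined
by the hysteresis event spans (not the per-timepoint elevated rule — "the
signaling portion of a track" refers to the segmented events). It is
translation-invariant by construction, may be negative, and is undefined
(excluded, with a warning) for tracks entirely inside or entirely outside
events. A conservation identity — the track's overall mean speed equals
the n-weighted mean of the two portion means — is enforced in the tests.

## The synthetic world

`simulate_tracks()` generates what the detector assumes plus the minimum of
biology needed to test recovery:

* **Events**: onsets arrive as a homogeneous Poisson process on the track
  window (default rate 1/75 per min, the published order of magnitude for
  the high-self-reactivity genotype), thinned so that an onset closer than
  `refractory_s` = 240 s to the previous event's end is dropped. Durations
  are Normal(240 s, 60 s) rounded to frames and floored at 2 frames —
  a unimodal, moderately dispersed duration law a scientist would call
  realistic for multi-minute transients; the SD is not a published value
  and is fixed once here. The Poisson-then-thin construction (rather than
  a sequential renewal process) keeps the measured event frequency an
  unbiased estimate of the injected rate at low rates.
* **Ratio**: `B0 + amplitude · shape(t) + N(0, σ)` with `B0` = 0.675,
  amplitude 0.3, σ = 0.03. The default shape is a **pure square pulse**:
  the generator's first job is unambiguous ground truth for oracle tests,
  and a half-amplitude edge frame would shift detected onsets by one frame.
  A `rise_decay` shape (one-frame rise, exponential decay with τ = half
  the duration) is available for realism-sensitivity checks. Channels are
  emitted as `unbound = 1500 a.u.`, `bound = r_t × unbound`, so the derived
  ratio is exact.
* **Motility**: a persistent random walk; each step direction is the
  normalized blend `p·previous + (1−p)·random` with persistence `p` = 0.6,
  and each step speed is Normal(6, 1.5) μm/min floored at 0, minus a
  3 μm/min drop on in-event steps (thymocytes pause while signaling).
  The base speed and drop match the magnitudes seen in cortical thymocyte
  imaging; the floor at 0 shifts the realized signaling mean up by
  ≈ 0.01 μm/min (2σ truncation), negligible against the ±0.4 acceptance
  tolerance.

What the generator does **not** emulate: tissue geometry and confinement,
chemokine-directed motion, cell–cell contacts, photobleaching or drift,
tracker identity switches, and non-square transient shapes (beyond the
optional decay). A green recovery test therefore establishes that the
pipeline is an unbiased estimator *under the stated noise model* — not that
it is robust to tracker pathology.

`simulate_expression()` plants a signature in a three-population
(DN4 / DP69neg / DP69pos × 3 replicates) matrix: log-normal baselines
(meanlog log 500, sdlog 1), planted genes at `signature_base` = 1200 a.u.
in the comparators and `base · 2^lfc` in DP69neg, and multiplicative
log-normal noise (sdlog 0.2 by default) with `E[noise] = 1`, so planted
fold changes hold in expectation.

## Signature filtering

`derive_preselection_signature()` computes per-gene population
replicate-means, then
`L1 = log2((DP69neg + ε)/(DN4 + ε))`,
`L2 = log2((DP69neg + ε)/(DP69pos + ε))`, and keeps genes with
`L1 > 1 ∧ L2 > 1 ∧ (combined > 2000 ∨ (L1 > 2 ∧ L2 > 2))`, minus
`Rag1`/`Rag2`. Diagnostics record the admitting branch per gene. Three
open interpretation points, each with a selectable alternative:

* **"Combined expression"** defaults to the *sum of the three population
  means* — the plainest reading of "combined" — with `dp69neg` and `max`
  modes available.
* **Pseudocount** ε = 1 a.u.: RMA microarray intensities are bounded away
  from zero, so ε is inert on real data, but it protects synthetic zeros.
* **Scale**: linear intensities by default; a `log_scale` mode treats the
  matrix as already log2 (fold changes become differences).

`filter_ion_channels()` consumes differential-expression output rather than
computing it (DE belongs to established tools): candidates must exceed 20
reads in ≥ 1 sample and reach padj < 0.05 in ≥ 1 developmental stage, with
`Tmie` always included. Candidates missing from the DE table are dropped
with a warning (they survive only via `always_include`).

`scale_and_cluster()` reproduces heatmap preprocessing: replicate-average
per (genotype, stage), z-score each row (constant rows → zeros, with a
warning), agglomerative clustering on Euclidean distance with complete
linkage — the defaults of the plotting tool named in the source methods —
cut into k = 4 groups. Raw `cutree` labels depend on row order, so labels
are renumbered deterministically by each cluster's developmental
expression order: ascending column index of the peak of the cluster-mean
scaled profile, ties broken by the profile's center of mass, then by first
gene name.

## Numerical and degenerate-case conventions

* Frames are 0-based; event spans are half-open `[start, end)`; durations
  are differences of recorded times (identical to frame arithmetic on
  contiguous tracks).
* Thresholds compare with `≥` (trigger/elevated) and `<` (release) exactly
  as specified; a nonsignaling gap of exactly 240 s does *not* merge.
* Empty inputs return empty, correctly-typed tables; single-point tracks
  give empty speed traces with a warning; `ca_unbound ≤ 0`, duplicate
  (track, frame) pairs, unknown condition labels, and non-finite ratios
  are validation errors naming the offending row or constraint.
* All simulators take a single integer seed that fixes every stream; the
  CLI writes a manifest (parameters, seed, input/output digests) and equal
  config + seed gives byte-identical outputs.

## Known limitations

* The published imaging statistics came from undeposited movies, so
  numerical agreement with them cannot be tested at desk scale; the
  acceptance surface is oracle equivalence, hand-worked cases, parameter
  recovery on seeded simulations, invariance checks, and planted-signature
  recovery. The one external benchmark (the 11-gene preselection signature
  on the public ImmGen Phase 1 microarray series) requires a network
  download; the reader, population mapping, and filter are implemented and
  exercised on a packaged synthetic series-matrix fixture instead.
* The curated 207-gene ion-channel candidate list is not printed in any
  source available to this package, so the 56-gene published result is only
  approximately checkable even with the RNA-seq DE tables in hand.
* Background estimation assumes the nonselecting condition is truly
  signaling-free; contamination inflates `B` and deflates event counts
  symmetrically in both conditions.
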