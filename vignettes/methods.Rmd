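---
title: "Quantifying stress-induced transcription from live-cell stem-loop movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stress-induced transcription from live-cell stem-loop movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsburst)
```

## The measurement problem

Phage coat-protein reporters (PP7, MS2) make nascent mRNA visible in live
cells: an array of RNA stem-loops transcribed from a promoter of interest is
bound by fluorescently tagged coat proteins, so active transcription shows up
as a bright nuclear focus — the transcription site (TS) — whose intensity is
proportional to the instantaneous number of nascent transcripts, and hence to
the PolII load. In budding yeast under hyper-osmotic stress, the MAPK Hog1
enters the nucleus for a limited time and gates the activation of
stress-response promoters; the interesting biology (activation timing and
probability, shutoff, bursting) lives in per-cell time series of TS
intensity.

`tsburst` implements the full quantification chain for such experiments:

1. **Segmentation** of a nuclear-marker channel and a cell-body channel into
   Cell, Nucleus, and expanded-nucleus (ExpNucl) label masks, plus tracking
   and quality filters.
2. **TS quantification** on maximum-intensity projections of the GFP
   Z-stacks: the statistics *HiPix* and *ConnectedHiPix* (below).
3. **Trace features**: Start/End Time, transcription period, responder
   class, trace maximum and integral; MAPK relocation features with
   censoring.
4. **Burst detection** with a four-rule peak filter.
5. **Population statistics**: start-time CDFs, end-time survival curves,
   responder fractions, quartile analyses, adaptation/end-time correlation.

Because raw microscopy of this kind is rarely redistributable, the package
ships a **simulator** that generates the same movies the analysis consumes —
stimulus profiles, MAPK activity traces, stochastic promoter activation,
PolII convoys, optics, camera noise and bleaching — with per-cell ground
truth, so every stage is testable end to end as a parameter-recovery
problem.

## The TS statistics

For each cell and frame, on the Z-projected GFP image:

* **HiPix** — the mean of the $k = 20$ brightest pixels inside the ExpNucl
  region minus the median pixel value of the whole cell. Subtracting the
  cell median removes the diffuse coat-protein background, so the statistic
  is near zero without a TS and rises by up to a few hundred counts with
  one. It is invariant to adding a constant to the frame.
* **ConnectedHiPix** — from the same top-$k$ pixel set, a binary
  morphological opening removes isolated pixels; the value is the mean raw
  intensity of the largest surviving 8-connected component, and it is
  *missing* when nothing survives. This is the detection criterion: random
  noise pixels are scattered and die in the opening, a real spot's pixels
  cluster and survive.

The ExpNucl region is the nucleus mask dilated by 5 px (Euclidean disk) and
clipped to the cell, so sites at the nuclear periphery are not missed.

Two choices the statistic's verbal definition leaves open are fixed as
follows and exposed in the configuration: the structuring element of the
opening is the 3×3 cross (4-neighbourhood), which removes isolated pixels
and diagonal-only chains while preserving compact clusters; component ties
are broken towards the component containing the brightest pixel. Both the
statistics are verified exactly (to machine precision) against brute-force
implementations on random frames in the test suite.

## From traces to features

ConnectedHiPix detections present for a single isolated frame are removed;
the first and last surviving detections define the **Start Time** and **End
Time** (minutes relative to time zero, the first post-stimulus frame —
frame 4 of the 15 s grid). Cells with any detection strictly before time
zero are **basal**, cells whose first detection is at/after time zero are
**responders**, undetected cells are **non-responders**.

The HiPix trace is normalized by subtracting its value at the first
post-stimulus frame and smoothed with a centred 3-frame (45 s) moving
average. The **trace maximum** and the trapezoidal **integral** are computed
from the normalized trace restricted to `[start, end]`, which makes them
invariant to anything outside the transcription period (up to the
normalization reference frame itself).

**Burst detection** runs on the smoothed normalized trace inside
`[start, end]`: all local maxima above a 7-count threshold are candidates;
neighbouring candidates are kept apart only if the drop to the trough
exceeds a quarter of the left peak and the rise from the trough exceeds a
third of the trough value, otherwise the pair merges into its higher peak
(left-to-right, recomputed after every merge); finally peaks below a fifth
of the trace maximum are discarded. Peak durations split the transcription
period at the troughs, so a single-peak trace has duration equal to the
period. Cells are classified 1P / 2P / ≥3P by surviving peak count.
Where the verbal rules leave order ambiguous we fix: threshold → trough
merging → fifth-of-max pruning, strict inequalities for "larger"/"more
than", non-strict for "at least"; the suite checks the filter against an
independent exhaustive implementation on 1000 random traces.

**MAPK features** from a nuclear-enrichment trace: entry (first
post-stimulus crossing of baseline + 20% of amplitude), maximum, decay time
(first time after the maximum below 80% of the maximum), and adaptation time (first return below baseline + 20% of
amplitude). The adaptation fraction is an interpretation (the source
analysis defines only the decay operationally); it is exposed as a
parameter. Cells that have not adapted by the end of the movie are censored
at 35 min and counted.

## The simulator

The generator reproduces the acquisition geometry of the reference
experiments: 100 frames at 15 s for 25 min, stimulus added before frame 4
(= time zero), six Z-planes 0.4 µm apart spanning about ±1.2 µm for the GFP
channel, exponential photobleaching totalling 32% (GFP) and 26% (RFP)
across the movie.

**Stimulus.** Deterministic concentration profiles: a 0.2 M step; a pulse
returning to 0 M at 7 min; a ramp from 0.2 M to 0.6 M over 20 min.

**MAPK activity.** A piecewise-smooth trace per cell: linear rise to the
peak over 1 min, a plateau, then an exponential return timed so the cell
has adapted at its adaptation time. The nominal adaptation parameter
(20 min to ~95% return at 0.2 M) puts the *measured* adaptation feature
near 14 min and the decay feature near 7 min at 0.2 M, the reference values
for this pathway; adaptation scales linearly with stress amplitude, so
0.1 M adapts faster and 0.3 M slower. The decay schedule is clocked from
the last increase of the stimulus: a rising ramp defers adaptation beyond
the movie (those cells are censored), and a pulse truncates the trace with
a fast nuclear-exit exponential (τ ≈ 0.3 min). Per-cell lognormal
variability (CV 0.15) multiplies peak, adaptation, and exit time. This is a
phenomenological shape, not a mechanistic ODE — it reproduces the features
the analysis extracts, not the signalling biochemistry.

**Promoter activation.** One irreversible ON switch per stress episode with
hazard `rate × max(activity(t − delay) − threshold, 0)`: a chromatin
threshold (0.3) and remodeling delay (1.5 min) gate activation to the
early high-activity window, reproducing the observation that activation
concentrates before the MAPK decay time while a substantial fraction of
cells never activates. The default hazard scale (0.19 /min) was set so the
integrated hazard over the 0.2 M activity window gives ~60% responders,
the reference responder fraction for a repressed stress promoter; the
`permissive` preset (higher rate, lower threshold, basal firing at
0.02 /min) emulates a constitutively accessible promoter.

**Transcripts.** Once ON, convoys of PolII (mean 8 polymerases loading
within 15 s) initiate every 1.5 min (gamma-distributed gaps) until the
gating activity falls below threshold plus a 1 min shutoff lag. Each
transcript's fluorescence ramps linearly while the 1.5 kb stem-loop
cassette is transcribed (75 s at 20 bp/s) and stays constant until
termination at `transcript_length / speed` — 400 s for the 8 kb reporter
transcript (1.5 kb cassette + 6.5 kb downstream ORF), the expected
lifetime of a transcript at the TS (6.7 min). Bursts arise from convoy
gaps, not from OFF/ON cycling: with the default near-continuous loading
almost all traces are single-peaked, while long convoy intervals (the
"sparse" regime) produce separable peaks whose durations cluster near the
single-transcript lifetime.

**Rendering.** Cells are non-overlapping disks on a jittered grid (≤25 per
field); the nucleus is a smaller disk; the TS is a Gaussian spot (σ 1.3 px)
at a fixed position inside the nucleus with 0.3 px frame jitter, attenuated
and broadened across Z around its own axial position. The spot's integrated
intensity is calibrated so that a noise-free HiPix measurement returns the
truth amplitude (`counts_per_mRNA` = 12 HiPix counts per resident
transcript, placing typical convoy-loaded sites 50–300 counts above
background so that the 7-count burst threshold is a meaningful scale).
Noise is Poisson shot noise at the photon level (10 photons per camera
count) plus Gaussian read noise (σ 1.5 counts); absolute fluorescence count
scales are instrument-specific, so this calibration treats the 7-count
threshold as an absolute on background-subtracted traces and is documented
here as such.

**Ground truth** records, per cell, the continuous event times (ON switch,
convoy and initiation times, last termination) and the frame-grid
`true_start_time` / `true_end_time` — the first and last frames carrying
nascent signal. The frame-grid convention matches what a sampled
measurement can recover; comparing a frame-quantized detection against
continuous event times would charge the detector with the sampling offset.

Two fidelity levels exist: full rendering (the image pipeline end to end)
and a trace-level observation model (`observe_traces()`: scaled truth plus
Gaussian noise, detection when ≥1.5 transcript equivalents are resident)
for fast statistical tests.

**What the simulator does not emulate**: cell growth, division and crowding;
uneven illumination and drift; bright-field segmentation artifacts; camera
fixed-pattern noise; diffusing cytoplasmic mRNA speckles; multi-spot nuclei
(except through the eccentricity filter fixture). Passing recovery tests
therefore demonstrates correctness of the computation, not robustness to
every real-microscopy pathology.

## Segmentation design

Yeast time-lapse pipelines typically segment cell bodies from bright-field
images with dedicated platforms; that step is upstream of this package's
concern. The simulator instead emits a fluorescent cell-body proxy channel,
and the
segmentation is: Otsu threshold + hole filling + minimum area on the
nuclear channel; seeded Voronoi-style growth (EBImage `propagate`)
constrained to above-background proxy signal for the cells; Euclidean
dilation clipped to the own cell for ExpNucl, with collisions resolved by
nearest nucleus. A bypass mode accepts ground-truth masks directly, so
downstream stages are testable independent of segmentation quality. The
mask hierarchy nucleus ⊆ ExpNucl ⊆ cell is asserted on every frame.
Tracking is greedy nearest-centroid with a one-cell-radius gate (cells are
immobilized on Concanavalin A in such experiments, so the gate is
conservative); gaps are explicit, never interpolated. Per-frame nuclei with
second-moment eccentricity above 0.95 are invalidated (mitosis duplicates
the locus and the signal); whole tracks failing area or intensity bounds
are removed. Shape and intensity bounds are dataset-specific; they are
configuration with wide defaults.

## Numerical choices and degenerate inputs

* Percentiles and quartile summaries use linear interpolation
  (`quantile` type 7) throughout.
* Top-$k$ ties are broken by pixel linear index (ascending); with
  continuous-valued images ties have measure zero.
* If ExpNucl holds fewer than $k$ pixels, all are used and the value is
  flagged; an empty region yields a missing value with an error flag.
* Start-time quartiles require ≥8 responders, the adaptation/end-time
  correlation ≥3 complete pairs and non-degenerate variances; both flag
  rather than extrapolate.
* Blank frames segment to zero labels (not an error); a proxy channel with
  no signal triggers a flagged nucleus-dilation fallback for the cells.
* All simulation randomness derives from one master seed through fixed
  per-cell streams, so any cell can be regenerated in isolation and the
  whole pipeline is bit-reproducible.

## Problem sizes used in validation

The shipped validation runs use: a 300-cell rendered movie (12 fields,
100 frames, 6 Z-planes) for parameter recovery — Start-time recovery within
±1 frame for ≥90% of responders, End times within ±2 frames for ≥80%,
responder/basal classification ≥95%; 200-cell trace-level simulations for
peak-count recovery in the sparse regime and the single-peak fraction under
continuous loading; 1000 activation draws for the closed-form
exponential-hazard check (KS distance < 0.05); 100 ramp cells for the
35-min censoring convention. These sizes are chosen to keep the full
validation suite comfortably inside a desktop run while leaving the
statistical assertions well-powered.

## Known limitations

* The adaptation/end-time association in simulated data is tighter than in
  real cells under a step (both quantities inherit the same per-cell
  adaptation multiplier, and independent intrinsic noise in shutoff is
  limited); within the pulse and ramp regimes the variance of the
  adaptation time collapses (everything is slaved to the stimulus), so the
  correlation is small or undefined there by construction.
* The intensity model ignores PP7 binding kinetics and assumes
  instantaneous, permanent coat-protein occupancy of completed stem-loops.
* Absolute mRNA counting, sub-pixel localization, and multi-spot
  deconvolution are out of scope; the statistics quantify one dominant site
  per nucleus.
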