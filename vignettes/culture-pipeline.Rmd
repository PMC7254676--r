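---
title: "From calcium movies to effective networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From calcium movies to effective networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`calnet` implements the analysis chain used to characterise spontaneous and
pharmacologically perturbed activity in dissociated neuronal cultures
(wild-type versus Huntington's-disease striatal and cortical cultures)
recorded with a calcium indicator at 20 frames/s for 10 minutes: ROI
detection, trace normalization, trace classification, spike reconstruction,
network-burst statistics, Generalized Transfer Entropy (GTE) effective
connectivity, graph topology, and group-level statistics. Because such
recordings are rarely shareable, the package also contains a synthetic
culture generator whose presets are calibrated to the published group
statistics, so that every stage of the chain can be validated against
planted ground truth. This vignette documents the models, the parameters
that matter, the numerical choices, and the known limits of what the
synthetic validation shows.

## The imaging front-end

ROIs are detected on the time-averaged movie. The average image is
normalized by an affine rescale that maps its 20th intensity percentile to 0
and its 30th to 1 (linear-interpolation quantiles). We read "normalizing the
image between its percentiles" as this affine map rather than a clipped
map: clipping to [0, 1] saturates every pixel above the 30th percentile and
destroys the soma/background contrast that the subsequent steps rely on,
whereas the affine map expresses the image in units of the background band.
A Gaussian blur of width 7 pixels (read as the Gaussian sigma, applied with
replicate padding so nothing wraps across image edges) is subtracted as a
background estimate, the difference is binarized at 0.08, holes are filled,
a morphological opening with a 4 x 4 square structuring element removes thin
debris, and connected components (8-connectivity) below 10 pixels are
dropped. Labels are ordered by centroid (row, column), making the output
deterministic. Note that any region surviving a 4 x 4 opening necessarily
contains at least 16 pixels, so the 10-pixel floor only becomes active when
a smaller structuring element is configured.

Traces are the spatial mean over each ROI's pixels. Baseline correction
follows the block scheme: traces are smoothed with a 5-frame centred boxcar,
each 50 s block contributes one reference point (the sample closest to the
block's 10th lower percentile; a trailing partial block contributes its own
point when at least 10 s long, otherwise it merges into the previous block),
and a smoothing spline through the reference points gives `F0`. The spline
stiffness is expressed as equivalent degrees of freedom, ~1.35 per 100 s;
with 50-s reference spacing this tracks bleaching-scale drift while ignoring
calcium transients. The spline is evaluated on a 25-frame grid and linearly
interpolated, which is exact to well below the noise floor for baselines
this slow. Traces whose fitted baseline is not strictly positive are flagged
invalid and excluded downstream. The normalized trace is
`r = 100 * (F - F0) / F0` (% dF/F0).

## Trace classification

Each ROI trace is classified as neuron, glia, or silent from an 8-feature
vector (mean, variance, skewness, excess kurtosis, upward crossings of twice
the robust noise SD, fraction of time above that threshold, sub-0.1 Hz
spectral power fraction, maximum). The classifier is adaptive boosting
(multi-class SAMME) over depth-1 `rpart` stumps, 50 rounds by default; the
feature space is small enough that stumps suffice. A default ensemble is
trained lazily on generator-rendered traces that pass through the same
normalization as pipeline traces (this matters: the feature distributions
of raw and baseline-corrected traces differ substantially), covering a range
of firing rates, wave amplitudes, drift and noise levels. Manually curated
labels always override: retraining on an amended label set is one function
call, which replaces the interactive refinement loop of the original
workflow. Only neuron-labelled ROIs proceed to spike inference; the
percentage of active neurons uses all cell (neuron- or silent-labelled) ROIs
as its denominator, with "active" pinned at >= 2 reconstructed spikes per
recording.

## Spike reconstruction by peeling

Spikes are reconstructed by iterative kernel peeling with a single
non-saturating exponential transient (amplitude 1% dF/F0, decay 3 s):
find the earliest frame where the residual crosses the event criterion,
record a spike, subtract the kernel from the residual, repeat; no sub-frame
timing is attempted, and a residual still crossing after subtraction can
only schedule a spike from the next frame on (binary raster contract). The
event criterion is `residual >= max(0.5 A, 2 sigma)` plus an onset-shaped
rise of at least `0.3 A` over the preceding two frames, with `sigma` a
robust noise scale (1.4826 x MAD of frame differences / sqrt(2)). The rise
requirement is what separates transient onsets (which jump by ~0.6 A within
a frame even after boxcar smoothing, several noise SDs above the rise
floor) from residual baseline drift and chance noise excursions. The first
two frames of a recording are never assigned events: their baseline is
unconstrained by any reference point and the rise test undefined, and the
generator's recording-edge guard mirrors the same convention.

Detection runs on the smoothed normalized trace, where the noise floor is
low, but the crossing frame can jitter by one or two frames because
smoothing smears the onset. Each detected event is therefore re-anchored to
the frame with the largest onset-sized (>= 0.4 A) single-frame rise of the
*unsmoothed* residual within two frames of the crossing. Without this step,
one-frame timing
errors systematically destroyed the isolation of genuinely independent
spikes in validation runs, biasing the independent-spike statistic by tens
of percentage points. Peeling is capped at a sustained 10 spikes/s; traces
that hit the cap are flagged rather than silently truncated.

## Network bursts and activity statistics

The population-activity signal counts unique neurons spiking in the trailing
1 s window. A Schmitt trigger with thresholds at 10% and 5% of the active
set segments putative bursts; segments closer than 0.5 s are merged; bursts
with fewer than 10 participants are discarded. Because both thresholds act
on a trailing window, the raw trigger times lag spiking by up to a window;
onset and offset are therefore snapped to the burst core - the first and
last frame within the lag-corrected span carrying at least 3 coincident
spikes (with a fallback to the first/last spike when no frame reaches 3).
Without the correction, a burst's measured span includes up to a second of
pure background and the participation and duration statistics are
systematically inflated. Participants are the neurons spiking within
[onset, offset]; participation is reported as the per-burst mean over the
active count. The inter-burst interval is onset-to-onset (the offset-based
alternative differs by the mean burst duration, which is an order of
magnitude smaller than the IBIs here); a culture is bursty when its mean
IBI is below 45 s. A spike is independent when no other spike anywhere in
the recording falls within one frame (50 ms) of it. Single-cell statistics
(rate, inter-spike interval, single-cell burst rate/interval, with a
single-cell burst pinned as >= 3 spikes at gaps < 0.5 s) are carried for
completeness.

## Effective connectivity and topology

GTE is computed directly on the binary spike trains with Markov order 2 and
instant feedback (the source's same-frame state joins the conditioning set,
following the original convention). Probabilities are plug-in counts over
all frames; zero-count states contribute zero. The estimator is exact - it
agrees to machine precision with an exhaustive joint-histogram oracle - and
non-negative. No burst-conditioning of the estimate is applied (an optional
exclusion of burst frames is deliberately not a default, following the
modified method's description). A connection i -> j is significant when its
score strictly exceeds the mean + 2 SD of the joint distribution of all
scores into j and out of i; a degenerate null yields no edges. Inference is
refused, with an explicit status, when 25 or fewer active neurons are
available.

Topology summaries: directed global efficiency (mean inverse shortest-path
length, 1/Inf = 0); Louvain communities on the largest weakly-connected
component (resolution 1, 10 seed-controlled restarts, best modularity kept),
treating the graph as undirected for community detection while keeping
efficiency directed; connector hubs by the network-cartography convention
(participation coefficient > 0.3 and within-module degree z >= 1.5, degrees
on the union of in- and out-edges; the z cutoff is relaxed from the
classical 2.5 because culture graphs are sparse). The community statistic is
reported twice: Newman-Girvan modularity `Q` (what Louvain maximizes, the
headline number) and the literal ratio of intra- to inter-modular edge
counts (`Q_ratio`), because the verbal definition of the statistic in the
source literature matches the ratio while the computational pipeline matches
modularity; both are emitted so either reading can be compared.

## Group statistics

Outliers are excluded by the Tukey reading of the "quartile criterion":
values outside [Q1 - 1.5 IQR, Q3 + 1.5 IQR], linear-interpolation quartiles,
computed per group; groups under four values are left untouched with a
warning. Basal genotype comparisons use the unpaired pooled-variance
Student's t test. Treatment designs use the classical two-way mixed-design
(split-plot) ANOVA - `aov(dv ~ genotype * phase + Error(culture / phase))` -
rather than a random-slope mixed model, matching the `F(df1, df2)` reporting
style; cultures missing a phase are excluded listwise with a warning, and a
fully degenerate stratum (zero effect and residual sums of squares) is
reported as F = 0, p = 1 by convention. Two Bonferroni families are computed
and labelled - phase within genotype (paired t) and genotype within phase
(unpaired t) - since the exact post hoc family membership is ambiguous in
the source reporting.

## The synthetic-culture generator

The generator is phenomenological: no conductance-based model, no receptor
pharmacodynamics. A culture consists of ROIs split into active neurons,
silent cells and glia (default 10% glia; the active fraction is the preset's
headline number). A planted directed network with `n_modules` near-equal
modules (stochastic block model, `p_intra`/`p_inter`) organises the active
neurons. Network bursts follow a renewal process with gamma-distributed
inter-onset intervals (shape 4, giving the unimodal regularity seen in real
burst rasters); each burst recruits a fixed fraction of active neurons drawn
without replacement with weight `participation_weight` for the burst's seed
module and with gamma-distributed per-neuron propensity
(`recruitment_shape`), so that co-bursting carries both the planted
community structure and realistic recruitment heterogeneity. Participants
emit `spikes_per_burst_neuron` spikes uniformly jittered within the
`burst_duration` window.

Background ("independent") spikes are drawn with the preset rate and placed
by uniform sampling of minimum-gap frame sets within the burst-free
segments, so that every background spike sits at least three frames from
every other spike. This is a deliberate deviation from a homogeneous Poisson background:
the independent-spike statistic counts spikes isolated by more than one
frame, and a homogeneous background at the published rates can never reach
the published independent fractions (at 6.3 spikes/s, at most ~53% of
Poisson spikes are isolated within +-50 ms). Planting isolation makes the
independent-spike count a ground-truth quantity; the extra frame of slack
keeps single-frame reconstruction jitter from breaking it. When a requested
rate exceeds what strict isolation can accommodate (the cortical presets
operate at this packing limit), the excess is placed without the isolation
guarantee and counted separately.

Traces are rendered as `F_base * (1 + (signal + drift + noise) / 100)` with
linear kernel superposition, per-frame Gaussian noise (0.15% dF/F0 default),
and drift summing a small 120 s sinusoid (10% of the drift amplitude), a
300 s sinusoid (45%) and a slow reflected random walk (45%): a large fast
component is untrackable in principle from 50-s baseline blocks, and real
drift is dominated by slow bleaching-like trends. Glia get smooth 5-20%
waves of ~30 s period; silent ROIs carry noise only. Movies paint disk
footprints on a smooth wide illumination vignette with per-frame pixel
noise; the vignette's correlation length is kept much larger than the
detector's blur radius so background curvature stays below the binarization
threshold, and there is deliberately no per-pixel fixed-pattern noise (the
time-average of a shot-noise-limited camera is smooth).

### Preset calibration

The published per-figure means come from different analysis populations:
the active-fraction, rate and independent-fraction means cover all cultures
of a group, while the IBI and participation means cover only the cultures
with a defined bursty IBI, and the topology means cover cultures passing the
25-active-neuron inference floor. A single homogeneous culture cannot
satisfy all of them at once (e.g. wild-type striatal: 6.3 spikes/s total,
76% independent, 17 s IBI and >= 10 participants per burst are mutually
inconsistent for one culture). The presets therefore model a two-state
population: a `bursty_fraction` of cultures (the observed bursty shares,
22/38 wild-type and 16/37 HD striatal) bursts at the published IBI with a
higher background rate, the remainder is non-bursty with a lower background
rate; the per-state rates are solved so the population means match all the
published numbers jointly. `simulate_batch()` allocates the bursty state by
stratified rounding rather than i.i.d. coin flips, which removes needless
small-batch variance from the group means without changing the per-culture
model. Group summaries in this package mirror the per-figure populations
(IBI/participation over bursty cultures; topology over cultures whose
largest component exceeds 25 neurons).

The community-weighted, heterogeneous recruitment is what gives the
GTE-inferred networks their published topology range: the intra:inter
recruitment weight (8) and the propensity shapes (2.5 wild-type striatal,
4 HD striatal, 2 elsewhere) were calibrated once on planted rasters and
frozen; with them, the full chain lands at wild-type global efficiency
~0.24 and HD modularity ~0.55 on ten-culture batches. The cortical presets
match the published active fraction, IBI and participation exactly, but
their published rate/independent-fraction pair lies beyond the 50 ms
isolation packing limit, so their background rate is the nearest feasible
point; the striatal presets are unaffected.

### What passing the synthetic round trips does and does not show

The generator emulates: recurring coordinated bursts with genotype-dependent
IBI, isolated background spikes, modular co-activation, glia waves, slow
drift, trace noise, and a movie front-end with realistic illumination.
It does not emulate: overlapping or moving ROIs, neuropil contamination,
indicator saturation or amplitude adaptation, avalanche statistics,
sub-burst coordination in non-bursty cultures (their effective networks are
near-empty here, unlike in real recordings - the reason the topology
averages follow the component-size floor), or any receptor-level
pharmacology ("BIC-like"/"NMDA-like" are parameter presets only). Passing
the round trips therefore shows that the chain measures what was planted at
realistic noise levels, not that it is robust to every artefact of real
recordings.

## Problem sizes and determinism

Validation runs use ten cultures per group at the preset scale (1000 ROIs,
600 s at 20 fps; ~130 active wild-type neurons per culture, GTE over all
active pairs); the movie-chain benchmark runs at 100 ROIs in a 120 x 120 px
field over 300 s, which preserves every fraction-valued observable while
keeping movie rendering light. All stochastic stages are seed-controlled;
identical seeds give bitwise-identical cultures, reconstructions and
networks, and long movies are rendered in deterministic chunks so the
averaging and extraction passes see identical data.
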