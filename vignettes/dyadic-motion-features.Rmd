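---
title: "Extracting dyadic motion features from mother-infant motion capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting dyadic motion features from mother-infant motion capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadmotion)
```

## The problem

Observational rating systems such as the Coding Interactive Behavior (CIB)
summarise the quality of an adult-infant interaction on 1-5 Likert scales
that trained coders average into composites (maternal sensitivity, infant
negativity, dyadic reciprocity, ...). Manually annotating the *movements*
that carry much of this interaction is prohibitively slow, but optical
motion capture makes it automatic: reflective markers on the head, wrists,
elbows and shoulders of both partners are tracked at 240 Hz, the
translational kinetic energy of each body part is computed, and a threshold
on that energy segments each recording into movement and pause episodes.
From two such segment lists per dyad this package derives eight
coordination features and correlates them with the CIB composites.

## Pipeline and model

For each actor the marker trajectories are:

1. **Trimmed** to the rated window (the supported study design rates 3
   consecutive minutes starting at 2 minutes for 4-month-olds, 5 minutes for
   13-month-olds).
2. **Gap-filled** by per-coordinate linear interpolation across missing runs,
   holding the nearest valid frame at the edges. If any single marker is
   missing 5% or more of the window the recording is rejected rather than
   repaired (`max_missing_fraction`, applied per marker — the strictest
   reading of a per-recording rule, and configurable).
3. **Low-pass filtered** with a 4th-order Butterworth at 10 Hz, applied
   forward-backward. Zero-phase filtering is a deliberate choice: a causal
   pass would delay every movement onset by tens of milliseconds, biasing
   the response-window features below. The effective amplitude response is
   the squared single-pass magnitude $1/(1+(f/f_c)^{2n})$, which is what the
   tests assert.
4. Converted to **segment centre-of-mass speeds** by central finite
   differences. Centres of mass are the head-marker centroid, the midpoint
   of wrist and elbow (forearm + hand), the midpoint of elbow and shoulder
   (upper arm), and the shoulder marker itself; the midpoint fraction is
   configurable (`com_fraction`) for adopting published segment CoM
   locations. No extra smoothing is applied before differentiation — the
   10 Hz low-pass already bounds the differentiation noise.
5. Converted to **kinetic energy** per body part with anthropometric mass
   fractions $m_i$ of total body mass $M$:
   $$K_h = \tfrac12 m_h v_h^2,\qquad
     K_a = \sum_{\text{sides}} \tfrac12 m_{fa} v_{fa}^2
           \;(+ \tfrac12 m_{ua} v_{ua}^2),$$
   $$K_{ub} = K_h + \sum_{\text{sides}} \tfrac12 m_{fa} v_{fa}^2
           \;(+ \tfrac12 m_{ua} v_{ua}^2 + \tfrac12 m_s v_s^2),$$
   the parenthesised terms entering only when those segments are modelled.
   Infants seated in a supportive chair have limited, poorly tracked
   shoulders, so the infant model at 4 months carries only head and forearm
   terms. The default adult fractions come from the standard anthropometric
   tables (head 0.081, forearm+hand 0.022/side, upper arm 0.028/side);
   those tables define no shoulder segment, so the shipped 0.05/side is an
   explicit approximation, and all fractions are configuration, not
   constants. No standard infant rescaling exists, so infant fractions
   default to the adult table behind the same configuration hook.
6. **Segmented**: frames whose energy strictly exceeds 20% of the series'
   spike-robust mean energy are moving. The robust mean excludes samples
   above the 99th percentile — sparse single-sample spikes from impulsive
   movements would otherwise inflate the mean, while the spikes themselves,
   being far above threshold, cannot affect the segment boundaries. Then
   pauses shorter than 350 ms are merged away and movements shorter than
   350 ms discarded, in that order (two 200 ms bursts 100 ms apart therefore
   survive as one 500 ms movement); 350 ms is the mean human reaction time
   to visual stimuli, so shorter events are not perceptible structure.
   Exactly-350 ms gaps and movements are kept ("shorter than" is strict).
   Thresholds are per actor and body part; a grand-mean threshold can be
   injected via `mean_energy`.

From the cleaned segment lists of the two actors over a common window:

* **activity ratios** — the fraction of the window each actor moves;
* **overlap ratio** — both moving simultaneously; **silence ratio** —
  neither moving. These satisfy
  $\text{infant} + \text{mother} - \text{overlap} + \text{silence} = 1$;
* **coactive onset ratio** — the fraction of an actor's movement onsets
  falling *inside* a partner movement at most 1.5 s after that movement's
  own onset (simultaneous-activity coordination);
* **alternating onset ratio** — onsets falling in a partner *pause* at most
  1.5 s after the most recent partner offset (turn-taking-like
  coordination).

The 1.5 s response window is inclusive at its bound; an onset exactly
simultaneous with the partner's counts as coactive by default
(`include_simultaneous_onset = FALSE` flips the convention, which the
definitions leave open). The denominator is the actor's total movement
count in the window; when an actor never moves, the ratio is reported as a
missing value with a logged reason — 0/0 is undefined and a silent zero
would bias toward "no coordination". Missing values are excluded pairwise
from correlations, maximising and reporting the per-cell n.

Rating-side statistics: composites are means of orientation-adjusted scales
(reversal is $r \mapsto 6-r$ on the 1-5 scale) driven entirely by a
composite map (the built-in CIB maps differ by age group, e.g. labile
affect joins infant negativity only at 13 months); internal consistency is
Cronbach's $\alpha$; inter-rater reliability is ICC(2,1) — two-way random
effects, absolute agreement, single measures — computed from the ANOVA mean
squares with the standard F-based interval; feature-composite association
is Spearman's $\rho$ (Pearson on average ranks) with a two-tailed
$t$-approximation p-value on $n-2$ degrees of freedom, appropriate at the
cohort sizes this design targets (an exact permutation null is available
for $n \le 9$). No multiplicity correction is applied by default, matching
per-cell reporting; Benjamini-Hochberg is available behind
`bh_correction = TRUE` for responsible reuse.

## The synthetic-dyad generator

Real recordings of this kind are not publicly deposited, so the package
ships a generator that plants known structure and lets every downstream
stage be tested against ground truth.

Each actor alternates pauses and movement episodes from a renewal process
(defaults: mother movements uniform on 1-2.5 s, pauses on 2.5-4 s, infant
movements on 0.5-1.2 s, 0.15 m displacement per episode — magnitudes of
ordinary seated reaching/gesturing at the study's 240 Hz rate). During an
episode the whole marker set translates at constant speed along a fixed
direction with alternating sign; episode bounds are snapped to the frame
grid. This profile was chosen over a smooth bump deliberately: the energy
of a smooth bump leaves zero gradually, so any fractional-mean threshold
crosses it well inside the true boundary, whereas the boxcar speed is above
threshold from the first frame, making ground truth recoverable to within
one sample (onset exact, offset one frame late — the half-open frame
convention). All planted durations and gaps are at least 0.5 s so the
350 ms cleaning passes ground truth through unchanged.

Infant coupling is constructive, not inferred: per mother episode the
infant either starts inside it after a drawn latency (coactive, probability
`p_co`), starts in the following pause within 1.5 s of her offset
(alternating, `p_alt`), or starts deep in the pause outside the response
window (independent) — so the planted label *is* the definition-based label,
which the tests verify exhaustively. Sensor noise is additive Gaussian
(default 0.5 mm, typical optical-capture jitter); spikes are single-sample
position jumps planted inside movement episodes, because impulsive
movements are their physical source — a spike planted in a pause adjacent
to a segment would legitimately be merged in by the 350 ms rule and move a
boundary; missing data are contiguous runs, matching occlusion, which makes
interpolation meaningful.

`generate_cohort()` plants a feature-composite Spearman correlation: a
generative parameter varies monotonically across dyads (pause duration for
the time-share features, coupling probability for the onset features) to
spread the target feature, and the composite is drawn through a Gaussian
copula on the extracted feature's ranks with normal-score correlation
$r = 2\sin(\pi\rho/6)$, which makes the population Spearman correlation
exactly $\rho$. Calibrating against the extracted feature rather than the
raw parameter is deliberate: extraction jitter across dyads exceeds the
spacing of adjacent parameter values, so only this construction can realise
$\rho = 1$ exactly in the noise-free case.

What the generator does *not* emulate: articulated limb kinematics (markers
translate rigidly), rotational energy, camera-geometry-driven occlusion,
drift or marker swaps, and any dependence of movement style on interaction
quality. Passing tests therefore demonstrate that the pipeline measures
what it defines — not that those definitions capture real mother-infant
behaviour.

## Numerical choices and degenerate inputs

* Half-open time convention throughout: frame $i$ covers
  $[t_0 + (i-1)/f_s,\; t_0 + i/f_s)$; segments are $[on, off)$.
* Strict threshold inequality (`energy > threshold`); exactly-threshold
  frames are silence.
* Cleaning comparisons use a $10^{-9}$ s tolerance so representable
  350 ms boundaries behave as exact.
* An all-zero energy series is flagged all-silent (empty segment list), not
  an error; a constant rating vector yields a missing correlation; a
  degenerate ICC table with zero between-target variance reports its
  (possibly non-positive) coefficient rather than clamping.
* Edge missing-runs are filled by nearest-valid hold because linear
  interpolation needs two anchors and extrapolation would manufacture
  spikes.
* Zero-noise recovery checks run the unfiltered stage chain: with nothing
  to filter, the low-pass would only smear the (deliberately sharp) energy
  edges by a few samples; the filtered path is exercised by the end-to-end
  coupling and correlation checks, whose margins absorb that smear.

## Problem sizes

The shipped checks use 60 s dyads at 240 Hz; cohorts of 100 dyads for
segmentation recovery, 200 for coupling-rate recovery (about 2 300
movements), and 200 for planted-correlation recovery (plus 30 noise-free
dyads for the exact case); 1 000 randomised segment-list pairs for the
conservation and cleaning properties. These sizes give sampling error well
inside the asserted bounds (binomial and Fisher-z) while keeping a full run
in minutes on one core.

## Worked example

```{r example, eval = FALSE}
library(dyadmotion)

co <- generate_cohort(n_dyads = 40, feature_target = "silence_ratio",
                      planted_rho = 0.6, seed = 1, duration_s = 60)
res <- run_extract(co$dyads, co$config, co$models)
head(res$features)
tab <- run_correlate(res$features, co$ratings)
subset(tab, feature == "silence_ratio" & body_part == "arms")
```

## Known limitations

* No rotational kinetic energy, full-body models, or leg features.
* No C3D binary ingestion (the TSV dialect only), no gap-filling beyond
  linear/hold, no relabelling of swapped markers.
* No windowed or time-varying synchrony measures (cross-correlation,
  wavelet coherence) and no lead-lag estimation beyond the onset rules.
* No multivariate or mixed-effects modelling of the feature-composite
  relations; the statistics mirror per-cell rank correlations.
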