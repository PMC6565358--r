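---
title: "Methods: task model, surprise, permutation statistics and microstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task model, surprise, permutation statistics and microstates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surpriseERP)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, and the design decisions taken where the
methodology left genuine freedom. It states no empirical result beyond what
the test suite and `scripts/acceptance.R` themselves compute.

## The task model

A session is a stream of coloured digits at a fixed stimulus-onset
asynchrony (`trialDuration`, default 500 ms). Two colours are cues: the
short cue announces an ascending digit sequence of regular length 5, the
long cue of length 7 (digits increase by one, circularly after 9).
Terminated sequences are `deltaItems = 2` items shorter, extended ones two
items longer. Blocks are either low- or high-uncertainty; the default
compositions over (terminated, regular, extended) are (.05, .90, .05) and
(.15, .70, .15). These two triples were chosen so that (a) block-wise
outcome entropy clearly differs between levels and (b) the session-wide
fraction of regular sequences — the cue validity — is exactly .80 with
four blocks of each level. Each is overridable in `taskConfig()`.

Composition is realized by **exact counts shuffled within block**, never by
i.i.d. sampling, so the validity of .80 is a property of every session, not
an expectation. Cue validity is read as P(regular | cue); an alternative
reading (probability that a cue is followed by any sequence) exists but is
not implemented as the default, since under it the three compliance levels
would not define the outcome space the observer model counts.

Structural choices the task text leaves open, fixed here: random gaps
between sequences are uniform on 4–9 trials (`randomGapRange`); sequence
start digits, filler colours and random-trial digits come from reshuffled
round-robin pools so presentation frequencies are balanced up to rounding;
and a random trial never continues its predecessor by +1, so only genuine
sequences ascend and the first trial after a terminated or regular sequence
demonstrably breaks the rule. Sequence positions are 1-based from the cue;
stream indices are 0-based; all times are ms from stream start.

Event labels follow from the sequence geometry: with regular length L and
delta 2, position L − 1 carries the termination check (`PE_termination` on
a random digit for terminated sequences, else `CP_term_check`), position
L + 1 the extension check (`PE_extension` on an unexpected sequential
digit, else `CP_ext_check` on the expected regular end), and position 4 of
every long extended sequence is a deterministic `STD`. Note the extension
check falls on a *random* trial when the sequence ended regularly: the
expected, model-compliant outcome at that position is precisely a
non-sequential digit.

## The ideal observer

Surprise of outcome j is `I = −ln p`, `p = (n_j + 1)/(Σ_k n_k + 1)`, with
counts taken before the current observation. Two properties deserve
emphasis. First, the weights over the three outcomes do **not** form a
normalized distribution (an empty history yields p = 1 for every outcome);
the formula is implemented exactly in this form, and a normalized variant
(denominator `Σ_k n_k + K`) is available via `normalized = TRUE` for
sensitivity analyses only. Second, the counting scope is not dictated by
the formula: counts could accumulate over the whole session, per block, or
per block and cue. The default is **per block**, because uncertainty is
manipulated block-wise and the within-block fluctuation of surprise is what
the subgroup analyses exploit; both alternatives are selectable in
`scoreSession()`.

## Behavioural scoring

Onset latency is the press time minus the onset of the *second* sequence
trial (the earliest moment a sequential pattern is detectable); offset
latency is the release time minus the onset of the first random trial after
the sequence. Offset latencies outside [−500, 2000] ms are flagged
excluded; onsets inherit only the press-side rule (presses earlier than
500 ms before the cue are not attributable). A sequence is a hit if a press
falls between cue onset − 500 ms and sequence end + 2000 ms; unattributable
presses are false alarms. Because the discrimination index PR needs a
false-alarm opportunity count and none is defined by the two-high-threshold
model for continuous streams, the number of inter-sequence runs of random
trials is used as the denominator.

The 2×3 repeated-measures ANOVA is the classical within-subject
decomposition on per-participant cell means (each effect tested against its
participant × effect stratum), delegated to `stats::aov` with an error
model `participant/(uncertainty × compliance)`; the test suite checks it
against textbook sums-of-squares arithmetic. FDR correction is
Benjamini–Hochberg step-up via `stats::p.adjust`. Note that the BH
*adjusted values* are monotone and bounded but are not a fixed point of the
adjustment map for general inputs; only the hand-checkable tied-output
cases are.

The cue-learning median split assigns participants strictly above the
median gain score (mean onset latency to new minus learned cues in the post
session) to the gain group; ties at the median are resolved in stable
participant-id order so group sizes differ by at most one. Surprise–latency
correlations pool extended-sequence trials across participants within each
group — with ~15 participants and a handful of extended sequences each,
participant-level correlations would be too unstable, and pooling matches
the degrees of freedom such analyses report. The two groups' coefficients
are compared with Fisher's z, one-tailed where a direction is hypothesized.

## The synthetic cohort

`simulateResponses()` draws, per hit sequence, a press at the second-trial
onset plus Gaussian onset latency and a release at the sequence end plus
Gaussian offset latency for the compliance level. Defaults (versioned in
`inst/extdata/model-defaults.yaml`) are trial-level means/SDs in ms:
terminated 619.48/96.55, regular 532.81/99.74, extended 346.68/219.35;
onsets 788.02/168.00 (learned) and 844.59/172.31 (new). Interpreting these
as trial-level parameters is a modelling choice: it makes recovered
trial-level means and SDs directly comparable to the configured values, at
the cost of understating between-participant spread.

Surprise enters through a group-specific slope (default −150 ms/nat for the
gain group, 0 for no-gain) applied to the **condition-centred** surprise,
with the Gaussian component shrunk so the total trial-level variance stays
at the configured SD. This keeps the configured condition means and SDs
exact calibration targets while still inducing the within-condition
surprise–latency coupling the subgroup analyses look for. Premature
releases place the release at the would-be end of an extended sequence
(offset latency uniform in [−1000, −500] ms) with probability .12 (gain)
/ .02 (no-gain). The per-participant cue-learning gain is drawn from
N(178.54, 106.62) (gain) or N(−45.40, 82.24) (no-gain) and shifts new-cue
presses. Misses (5 %) and false alarms (5 % per gap) complete the model.

`simulateEpochs()` is a forward model on a 62-channel 10-10 layout:
components are average-referenced, unit-norm Gaussian topographies times
Gaussian temporal kernels, weighted per condition — a parieto-central P3b
(peak 388 ms for PE, 420 ms for CP, absent for STD, 5 µV), a central
negativity for PE only (418 ms, −3 µV), a right-parietal late positivity
(500/554 ms, 2.5 µV) and an early frontal map strongest for standards
(~300 ms). Sensor noise is spatially smoothed Gaussian noise (default
3 µV); there is no 1/f spectrum, no ocular artifacts and no latency jitter
— ocular correction is out of scope, so the generator does not produce what
that step would remove. Relative component amplitudes are a calibration
(chosen so the noiseless PE−STD difference peaks at the P3b), not an
inference about cortical sources. Consequently, passing tests show the
*pipeline* behaves correctly on data with the assumed structure; they say
nothing about components the generator does not emulate (drifts, muscle
artifacts, between-participant topography variability).

`simulateMicrostateErps()` builds group ERPs per condition as piecewise
sequences of maps from a shared orthonormal pool, scaled by a smooth GFP
envelope, plus white sensor noise (default 5 % of the mean clean GFP).
Every map is guaranteed at least one appearance: coverage fix-up overwrites
only runs of maps that occur more than once, or splits the longest run when
every map has a single run.

## ERP preprocessing

The stage order is filter → epoch → reject → interpolate → re-reference →
average; every stage is pure. Filtering is a zero-phase (forward–backward)
Butterworth band-pass, default 0.1–30 Hz at order 3 — chosen so a 50 Hz
tone is attenuated by more than 90 % while 10 Hz passes within 5 %. Epochs
are [−100, 600) ms — half-open on the 2 ms grid, the only convention
consistent with both of the printed comparison counts 18600 (62 channels ×
[0, 600)) and 1350 (9 channels × [300, 600)) — with the [−100, 0) ms mean
subtracted per channel (baseline correction is assumed, and configurable,
since the preprocessing description does not state it). Epochs are rejected
at |v| > 200 µV or steps > 50 µV per sample; the "semiautomatic" element is
implemented as the automatic rule plus an exported rejection log for manual
override lists. Channels whose excess kurtosis (population SD z-score
across channels) exceeds z = 6 are replaced by the unweighted mean of their
neighbours — "linear interpolation of neighbour electrodes" read as
neighbour-mean; spline interpolation would be the obvious alternative but
is not the default. Note the z > 6 criterion is only attainable on dense
arrays: with C channels the population z-score is bounded by about
(C−1)/√C.

## Cluster-mass permutation testing

Paired t-tests at every channel-time point; points with uncorrected
p ≤ .05 and equal sign join a cluster when temporally adjacent on the same
channel or simultaneous on adjacent channels; a cluster's mass is its
summed t. The null takes, per within-participant sign flip of the
difference maps, the most extreme cluster mass (max |mass| two-sided, max
signed mass one-sided), with the observed set counted as one permutation —
p-values are ranks in that null and can never be 0. When 2^n does not
exceed the requested permutation count the test switches to exhaustive
enumeration and is exact. Zero-variance points yield ±∞ t-scores; they
participate in clusters with magnitude capped at the largest finite |t| in
the map, keeping masses finite while preserving their extremeness.

Channel neighbourhooods come from a distance rule — two channels are
neighbours within 1.5 × the median nearest-neighbour distance of the 2-D
layout — with a JSON override for curated adjacency lists. A Delaunay
triangulation with edge pruning would be the other standard construction;
the distance rule was preferred because it needs no triangulation machinery
and produces the expected lattice neighbourhoods on regular layouts. The
inclusive-endpoint grid convention is selectable in
`buildComparisonGrid()` because one printed count (6262 over 62 channels ×
300–500 ms) implies 101 samples, which contradicts the half-open reading
that the other counts require; neither convention is asserted as intended.

## Microstates

GFP is the spatial standard deviation of the average-referenced map. AAHC
starts from every sample as its own cluster and repeatedly atomizes the
cluster contributing least to the global explained variance, reassigning
each freed map to the centroid with the highest squared spatial
correlation; centroids are polarity-aligned, unit-norm member means. While
many clusters remain, "least contribution" is measured by the cluster's own
explained sum of squares; below a refinement bound (4 × the largest
requested K, at least 64) the exact criterion — the explained-variance loss
if the cluster were atomized — is used. The refinement protects coherent
low-GFP maps from being absorbed while duplicate clusters of the same map
still exist, which is exactly the regime where the cheap criterion errs.

The map count is selected by minimizing
`CV(K) = σ̂²_K ((C−1)/(C−1−K))²` over the sweep (K ≥ C−1 excluded), with a
Krzanowski–Lai criterion as alternative and a meta mode taking the rounded
median of the criteria's choices (an approximation to composite
"meta-criteria" in microstate toolboxes, documented as such). Back-fitting
assigns each sample the template with maximal signed correlation by default
(`polarity = "respect"`, the ERP convention; samples with no positively
correlated template stay unassigned) or maximal squared correlation
(`polarity = "ignore"`). No temporal smoothing or minimum-duration
constraint is applied by default; an optional `minDuration` exists. By
default the conditions are concatenated before clustering ("pooled" mode):
a per-condition mode is provided, but selecting a single K on a merged pool
of per-condition clusterings has no well-defined CV criterion, so the
pooled description is the one the selection is performed on. Segment
statistics report every visit of a template (onset, duration, mean GFP),
and group comparisons use Welch's t with Satterthwaite degrees of freedom,
one-sided where a direction is hypothesized.

## Problem sizes and numerical choices

The test suite and acceptance script use: 1000 white-noise cohorts of 12
participants × 8 channels × 100 samples at 500 permutations for the
familywise-error calibration; 100 replicates of 62-channel, 4-condition,
350-sample synthetic ERPs for the map-count recovery; and 30 synthetic
participants × 8 blocks for the behavioural recovery — sizes chosen to
make Monte-Carlo error small relative to the tolerances being checked.
Seeds flow from a single master seed through `sample.int`, so every result
is bit-reproducible. Ties in back-fitting resolve to the first maximal
template; the median split resolves ties by participant id; permutation
p-values use a 1e−12 comparison cushion against floating-point equality.

## Known limitations

The response model is Gaussian (matching mean/SD calibration targets);
reaction-time skew is not modelled. The ERP generator has fixed
topographies across participants, so between-participant spatial
variability — a major driver of cluster-test power in real data — is
absent, and power estimates on synthetic data will be optimistic. The AAHC
refinement bound makes the atomization criterion exact only below it;
pathological inputs with more than ~4 × K_max coherent low-power states
could still lose one early. Vendor EEG formats are not read; epochs are
exchanged as plain TSV.
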