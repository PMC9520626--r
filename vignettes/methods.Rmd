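---
title: "Models and methods behind thetagamma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thetagamma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data tests do and do not establish
about real recordings. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` compute.

## The measurement problem

Gamma-band transcranial stimulation studies in amyloid-model mice ask
whether treatment restores three linked phenotypes: hippocampal gamma
oscillations and their coupling to theta phase, short-term spatial memory in
a Y-maze, and microglial/amyloid pathology in stained sections. Each
phenotype has a standard quantification — band power and the Tort
modulation index for LFP, windowed accuracy and trials-to-criterion for
behavior, skeleton morphometry for microglia — and the package implements
that chain end to end with group statistics on top.

## Phase-amplitude coupling

**Filtering.** Zero-phase (forward–backward) Butterworth band-pass, one-way
order 4 (effective order 8). Defaults follow the two conventions common in
this literature and are both configurable: theta 8–13 Hz and gamma 30–42 Hz
for the coupling analysis, theta 8–12 Hz and gamma 30–45 Hz for spectral
summaries. Zero-phase filtering matters because MI compares phase and
amplitude *at the same instant*; a causal filter would shear the two series
against each other.

**Phase and amplitude.** The analytic signal is built by the FFT
construction (double positive frequencies, zero negative ones). Phase is
the complex argument in [−π, π); by this convention the phase of
`sin(ωt)` is `ωt − π/2`, so on the package's synthetic signals the gamma
envelope minimum sits at extracted phase ±π, not −π/2. One second is
trimmed from each end before binning (configurable) to drop filter and FFT
edge transients.

**Binning and MI.** 24 half-open bins of 15°, edge values to the upper bin,
phase = π wrapped to −π. The mean gamma amplitude per bin, normalized to a
distribution `p`, gives `MI = [ln N − H(p)]/ln N`. Numerically the
equivalent Kullback–Leibler form `Σ p ln(pN)/ln N` is used so the uniform
case is exactly 0 and the one-hot case exactly 1. Empty phase bins get mean
amplitude 0, raise a flag on the result, and flagged subjects are excluded
from group statistics rather than aborting a long run. MI is scale-free in
the amplitude, which the tests assert to 1e-12.

Typical MI magnitudes are small: even 100 % sinusoidal modulation depth
yields MI ≈ 0.006 on a clean 10/40 Hz signal, because the binned
distribution of a sinusoidal modulator stays close to uniform. Group
contrasts, not absolute magnitudes, carry the signal.

**Comodulogram.** MI on a grid of band pairs (phase 2–15 Hz in 1 Hz steps,
amplitude 20–100 Hz in 2 Hz steps by default). Phase bands are 2 Hz wide.
Amplitude bands must span the modulation sidebands at `f_a ± f_p`, so their
half-width is `f_p` plus a 2 Hz pad (about one filter transition width);
with the sidebands exactly on the band edges they are half-attenuated and
off-centre "beat" cells — a sideband plus the carrier shoulder — can show
deeper relative envelope modulation than the true cell. Two validity rules
mark cells `NA` rather than computing them: the amplitude band may not reach
down to the phase frequency, and — because the phase of a band-pass filter
applied off any rhythm is just attenuated leakage, not a rhythm of that
frequency — the phase band must contain a local maximum of the recording's
Welch spectrum (`require_phase_peak`, on by default, togglable). Without
that gate a noiseless coupled tone lights up the entire phase axis through
perfectly coherent leakage phase. A known limitation remains: at moderate
coupling depths on noiseless signals the amplitude-axis argmax can still
drift a few Hz toward beat cells; realistic in-band noise suppresses them.

## Spectra and band power

Welch averaged periodograms: Hann-tapered, mean-subtracted windows (default
1 s, i.e. 1 Hz resolution) sliding in 0.1 s steps, one-sided density
normalization such that the integral of the PSD equals the signal variance
(verified against Parseval within 5 % on white noise and against the A²/2
closed form for tones). A 0.1 s *window* would give 10 Hz resolution —
far too coarse to resolve 30–45 Hz structure — so 0.1 s is interpreted as
the step, with the window length a separate parameter. Band power is the
trapezoidal integral over the band with edge interpolation; the mean
density (µV²/Hz) is reported alongside for comparison with per-Hz
summaries.

## Behavior

Windowed accuracy over a 90-trial session: window 10, step 5, trailing
partial windows discarded, giving the 17 windows starting 1, 6, …, 81;
`step = window_len` gives the non-overlapping variant. The 80 % criterion is
evaluated on windowed (not cumulative) accuracy; the first window at or
above threshold is reported by its last trial index, with no persistence
requirement. Curves are refused for tables mixing subjects, since a
concatenation's curve is not the mixture of the subjects' curves.

## Morphometry

Binarization is Otsu's between-class-variance threshold (fixed-threshold
mode available); a constant image yields an empty, flagged mask.
Skeletonization is parallel Zhang–Suen thinning with 8-connected graph
extraction following AnalyzeSkeleton conventions: endpoints have one
neighbour, junction pixels three or more, 8-adjacent junction pixels merge
into one junction node (otherwise a single bifurcation would count two or
three junctions). Branches are components of the skeleton minus junction
pixels; length sums 1 per axial and √2 per diagonal adjacency times the
pixel size, so a 50-pixel line spans 49 µm, and the step onto a junction
pixel is not attributed to any branch.

Soma diameter uses the Euclidean distance transform: pixels whose distance
to background reaches the radius of the minimum acceptable inscribed disk
(default 12 µm²) form soma cores; each core is one cell and its diameter is
`2·max(distance) − 0.5` pixels, the half-pixel correcting the transform's
raster bias (measured on rendered disks of 7–30 µm, recovery is within one
pixel). Counting cells by soma cores rather than connected components keeps
touching processes from merging cells, and thin processes never reach the
core radius. Per-cell means divide field totals by the cell count; branch
attribution to individual somas is not attempted. For amyloid-like
channels the stained-area fraction of the thresholded image is reported;
per-plaque area statistics are deliberately out of scope because
threshold and normalization conventions vary between labs.

## Group statistics

One-way ANOVA by direct sums of squares, with mean, SD and SEM all reported
per group. Variance homogeneity uses the Brown–Forsythe (median-centred
Levene) statistic, chosen for robustness; at α = 0.05 it routes the
post-hoc method: LSD (pairwise t on the pooled within-group mean square,
unadjusted) under homogeneity, Tamhane T2 (pairwise Welch t with a
Šidák-style adjustment `1 − (1 − p)^m`) otherwise. Degenerate inputs —
all groups constant but unequal — report p = 0 with a flag instead of
failing. Pearson correlation reports r, a two-sided t-based p, and the
least-squares line. The unit of analysis is one value per subject
throughout; within-subject epochs are never treated as replicates.

## The synthetic-data generators

The generators define the study conditions under which everything is
tested; their defaults were chosen once, as plausible values for this kind
of experiment, and the tests run against them.

**LFP.** `x(t) = A_s sin(2πf_p t) + A_f·[(1−χ) + χ(1+sin(2πf_p t))/2]·
sin(2πf_a t) + ε(t)`, the standard PAC benchmark: a 10 Hz theta carrier
(50 µV), a 40 Hz gamma carrier (10 µV) whose amplitude is sinusoidally
modulated by theta phase with depth χ ∈ [0, 1], and 1/f^β background
(β = 1, 5 µV) made by spectral shaping of white noise. 500 Hz sampling,
60 s default. χ = 0 gives a constant envelope; χ = 1 zeroes the envelope at
the theta trough. Note the modulator's mean-square falls as χ rises, so
coupling and gamma power are independent dials: the seven-group design
raises `gamma_amp_uv` with treatment (6→18 µV, about a 4.8× band-power span)
to emulate treated animals' stronger spontaneous gamma.

**Behavior.** Success probability `p_t = p_final − (p_final − p_start)
e^{−t/τ}` with independent Bernoulli outcomes — matches the concave shape
of rodent discrimination learning without claiming any particular
acquisition model (none is identifiable from accuracy curves alone).
Defaults: p_start 0.5 (chance), τ = 20 trials, 90 trials.

**Microglia images.** Somas are disks; processes are 1-pixel polylines
along the 8-connected lattice directions, evenly spread around the soma,
bifurcating at their midpoint with the configured probability into ±45°
children. Because such trees are invariant under Zhang–Suen thinning and
cells are placed with clearance radii covering their sampled process
lengths, the skeletal render (`render_soma = FALSE`) reproduces its
ground-truth endpoint and junction counts *exactly* — the tests assert
identity, not tolerance. With filled somas the thinned soma blob can add
hub pixels, so full renders are held to a ±10 % endpoint tolerance (in
practice they usually also match exactly). The seven-group study draws
per-subject cell counts from a Poisson around the group mean so that count
comparisons have within-group variance.

**What passing these tests does not show.** The generators produce
stationary, single-channel, artifact-free signals with sinusoidal coupling
at a single band pair; real LFP is non-stationary, broadband, and
contaminated by movement and volume conduction, and real microglia overlap,
vary in intensity, and live in 3-D. Results here validate the *computations*
against known truths, not the biological claims of any particular study.

## Determinism and problem sizes

Every stochastic step takes an explicit seed; the study generator derives
one stream per subject and data type from the master seed, so any subject
can be regenerated in isolation, and seed-matched pipeline reruns reproduce
every report byte for byte (numbers are formatted with fixed precision on
write). The shipped simulation sizes — 60 s traces for single-study
checks, 20 s traces across the 100 replicate studies of the
rejection-rate estimate, 1000 replicates for the ANOVA type-I rate — were
chosen as the smallest sizes at which the quantities under test are stable;
shorter traces only lower detection power, so the replicate-study bound is
conservative.
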