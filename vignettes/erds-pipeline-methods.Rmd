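---
title: "Methods: simulation, preprocessing and statistics of the ERD/S pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, preprocessing and statistics of the ERD/S pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
**erdspipe**: what the synthetic-data generator emulates (and what it does
not), how each preprocessing stage is parameterized, how ERD/S values and
time–frequency maps are defined, and how the mixed repeated-measures ANOVA
is computed. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## The measurement model

An epoch is a −2 to 7 s window around the onset of a visual cue instructing
a left-hand, right-hand or bimanual (repeated) ball squeeze — executed (ME)
or imagined (MI). Event-related desynchronization/synchronization is the
relative band-power change

$$\mathrm{ERD/S} = 100\,\frac{A - R}{R}\ [\%],$$

with $R$ the mean of the squared band-filtered signal over the reference
window $[-1.5, 0)$ s and $A$ over the activation window $[2, 6)$ s. Bands
are alpha/mu $8\!-\!13$ Hz and beta $16\!-\!24$ Hz. All windows are
half-open on sample times (`t >= start & t < end`), which makes sample
counts unambiguous: at 500 Hz an epoch holds exactly 4500 samples.

Channel values are averaged over six electrode groups (FL, FR, CL, CR, PL,
PR — frontal/central/parietal by hemisphere) with equal weight, then over
trials within condition, then over participants for grand averages.

## What the simulator emulates

`simulation_config()` defaults encode the study conditions: 500 Hz sampling,
32 scalp + 2 EOG channels on an idealized spherical 10–20 montage, 6 runs
alternating ME/MI (roughly half the cohort starting with MI — exposed as
`alternate_start` because the original design fixes only "approximately
half"), 10 trials per condition per run in randomized order, trials of 2 s
fixation + 7 s cue + a break drawn uniformly from 3–5 s (the design states
only the range; we use the maximum-entropy choice).

Each configured rhythm is a narrowband oscillation with a near-constant
envelope: a frequency-modulated cosine whose instantaneous frequency wanders
smoothly inside the band (Ornstein–Uhlenbeck drive with ≈200 ms coherence
time, soft-clipped to the band's inner 70 %), at a baseline RMS amplitude of
9 µV (mu, central channels), 8 µV (posterior alpha) and 5 µV (beta,
central). During the activation window of a matching trial the amplitude is
scaled by $\sqrt{g}$, with 250 ms cosine ramps placed immediately *outside*
$[2, 6)$ s, so the expected activation/reference power ratio is exactly $g$
and the injected ground truth is $\mathrm{ERD/S} = (g-1)\cdot 100\,\%$.

A constant-modulus rhythm was chosen deliberately over band-limited Gaussian
noise. The per-epoch ratio estimator is biased upward by the squared
coefficient of variation of the windowed reference power,
$E[A/R] \approx g\,(1 + \mathrm{CV}^2(R))$; a Gaussian-envelope rhythm has
$\mathrm{CV}^2(R) \approx 1/(B\,T) \approx 0.13$ for a 5 Hz band and 1.5 s
reference window, which would shift every recovered value by over 10 % of
its magnitude — an artifact of the generator, not of the analysis. The
constant-modulus process keeps the spectrum band-limited while making
windowed power essentially deterministic, so parameter recovery is a clean
test of the analysis chain.

The default ground-truth profile (`default_erd_profile()`) injects
contralateral mu suppression ($g = 0.6$) for unimanual trials, bilateral mu
suppression ($g = 0.65$) for bimanual trials, and broad bilateral beta
suppression ($g = 0.75$), identically for both handedness groups, tasks and
sexes — a deliberately neutral cohort in which ROI and ROI × condition
effects are real but group differences are null.

Background activity is $1/f$ noise (FFT-shaped, clipped below 1 Hz,
6 µV RMS per channel, independent across channels). Blinks are 300 ms
biphasic templates at Poisson times (8/min), projected onto channels with
weights decaying exponentially with spherical distance from a point between
the eyes; EOG channels sit closest and receive the strongest projection,
which is what makes the artifact recoverable by the EOG-correlation rule.

What the simulator does **not** emulate: volume-conducted correlation
between neighbouring channels (rhythms and noise are channel-independent),
line noise, EMG, electrode drift and impedance changes, and inter-subject
variability of rhythm frequency or amplitude. Passing tests therefore
demonstrate correctness of the computations under a known generative model,
not robustness to every pathology of real recordings.

## Preprocessing choices

The stage order is fixed: spherical-spline repair of flat channels →
average reference → ocular component removal → 1–40 Hz zero-phase FIR →
epoching → peak-to-peak rejection.

* **Flat channels** are those with sample SD below 0.1 µV (a disconnected
  electrode digitizes as a constant).
* **Spherical splines** use the field-standard parameterization: order
  $m = 4$, Legendre series truncated at 50 terms, diagonal regularization
  $\lambda = 10^{-5}$. The interpolation weights depend only on montage
  geometry; a dense independently-coded series evaluation agrees to
  $10^{-6}$ and constants are reproduced exactly (tested).
* **Ocular removal** replaces manual component selection with a
  deterministic rule: FastICA (symmetric fixed-point, tanh contrast,
  seed-controlled initialization, estimated on a ≤50 k-sample strided
  subset of a 1 Hz high-passed copy) followed by zeroing of every component
  whose absolute Pearson correlation with an EOG channel reaches 0.7. The
  unmixing is applied to the unfiltered signal; the report lists every
  component's correlation, so the decision is reproducible and auditable.
  No R FastICA implementation was available as a dependency, so the
  (standard) algorithm is implemented here. The original analysts also
  removed occasional single-channel-noise components by eye; we do not
  attempt to replicate subjective choices.
* **FIR design**: Hamming windowed-sinc, transition bandwidth
  $\min(\max(0.25\,f_{edge}, 2\,\mathrm{Hz}), f_{edge})$ per edge, length
  $3.3/\Delta f$, applied by centred FFT convolution (exactly zero group
  delay; verified by cross-correlation).
* **Rejection**: an epoch is dropped when any EEG channel's max−min within
  the epoch exceeds the threshold (default 120 µV, the modal
  per-participant value in this paradigm; EOG channels are excluded from
  the criterion). Raising the threshold can only keep more epochs.

## Time–frequency maps

Per kept epoch and ROI channel, a spectrogram with consecutive Fourier
transforms: Tukey window with taper fraction 0.25 (the common default; the
taper is not otherwise specified), segment length 250 samples, overlap 225,
per-segment mean removal, one-sided power-spectrum scaling
($|X|^2/(\sum w)^2$, doubled off DC/Nyquist) — verified bin-for-bin against
an independent reference implementation. At 500 Hz this gives 2 Hz × 50 ms
bins; rows are restricted to 1–35 Hz and the time range to $[-1.5, 7)$ s.

Power is averaged over epochs and ROI channels *before* normalization
(dividing per epoch would inject ratio noise), then each frequency row is
converted to percent change against its mean over the baseline bins — the
bins whose centres fall in $[-1.5, 0)$ s. The map normalization is the same
percent-change convention as the window-based ERD/S; this is our documented
assumption, as the map normalization is not otherwise pinned down.
Rejected epochs are excluded from maps via the same kept mask as everywhere
else.

## The mixed repeated-measures ANOVA

`mixed_rm_anova()` fits the balanced split-plot design (within: ROI ×
condition; between: handedness × sex; participants nested in the between
cells) by the classical sums-of-squares partition into four error strata
(participant, participant:ROI, participant:condition,
participant:ROI:condition). The partition is delegated to `stats::aov()`
with an `Error()` term; an independent brute-force projection oracle in the
test suite reproduces every SS to $10^{-8}$ relative.

Sphericity is corrected with the Greenhouse–Geisser (Box) sample estimator
only — no Huynh–Feldt fallback, matching the reported analysis. For a
$k$-level factor, $\varepsilon = \mathrm{tr}(M)^2 / ((k-1)\,
\mathrm{tr}(M^2))$ with $M$ the pooled within-cell covariance of subject
scores projected onto an orthonormal contrast basis, clipped to
$[1/(k-1), 1]$; interaction $\varepsilon$ uses the Kronecker product of the
factors' contrast bases. All within effects (and their interactions with
between factors) are reported with $\varepsilon$-scaled degrees of freedom.
One caveat: the common claim that the corrected p-value can only be larger
holds for $F \ge 1$; for $F < 1$ shrinking both df proportionally can
lower p slightly. We report the standard corrected value unconditionally,
as the common tools do.

Marginal means are raw cell means averaged with equal weight over non-focal
factors (exact for a balanced design). Their standard errors derive from
subject-level scores at the focal level, with variance pooled within
between-subject cells (df = participants − cells). Post-hoc p-values come
from the studentized range distribution, $p = P(q_{k,\mathrm{df}} \ge
|t|\sqrt2)$, evaluated by `stats::ptukey` (numerical integration of the
range distribution, no table lookup); for $k = 2$ this reduces to the
ordinary two-sided comparison. Main-effect comparisons use the effect's own
error stratum. The reported relevance filter for interaction comparisons
(same ROI across handedness, mirrored ROIs within handedness) is a
reporting choice, not a correction choice, and is left to the analyst.

The four standard analyses (ME/MI × alpha/beta) run from one tidy ROI-level
table via `run_erds_anovas()` — one parameterized code path.

## Problem sizes, determinism and degenerate inputs

All randomness flows through explicit integer seeds (`with_seed`
internally); identical configurations reproduce identical arrays, tables
and exported EDF bytes. Derived seeds stay below $2^{31}$.

The validation experiments use these sizes, chosen as the smallest that
make the checks sharp: parameter recovery and map-flatness use one
participant with 2 × 102-trial runs (≥200 epochs); the type-I simulation
uses 28 simulated participants per replicate at the design level (1000
replicates in the test suite, 500 in the acceptance script); the full-chain
power study uses 8 participants × 1 MI run × 6 trials per replicate with
ocular artifacts disabled and ICA skipped (100 replicates in the test
suite, 50 in the acceptance script) — the minimal balanced cohort, which
makes a ≥90 % detection rate for the injected contralateral ERD a
conservative bar.

Degenerate inputs are reported, not silently handled: reference power that
is numerically zero (< 10⁻¹⁰ µV²) yields `NA` cells listed in an attribute
plus a warning; conditions with no kept trials, unbalanced designs, missing
ROI channels and too few good channels for interpolation all raise errors
naming the offending cell/channel; epochs too close to a recording edge are
dropped with a warning.

## Known limitations

* The simulator's channel independence means spatial filters (average
  reference, splines, ICA) face an easier problem than on real,
  volume-conducted EEG.
* The EOG-correlation rule removes blink/saccade components but not the
  muscle or single-channel-noise components a human rater might flag.
* Marginal-mean standard errors use a per-level pooled-variance convention;
  other software may pool differently and report slightly different SEs
  (the means themselves are exact for balanced designs).
* The EDF writer targets the simulator's own round-trip (16-bit, 1 s
  records); it is not a general-purpose EDF+ implementation.
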