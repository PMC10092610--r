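---
title: "Analysing late beta/gamma oscillations in corticothalamic recordings"
author: "ctcgamma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing late beta/gamma oscillations in corticothalamic recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In the sedated rat, a brief whisker stimulus elicits two kinds of fast
(beta 17–29 Hz, gamma 30–80 Hz) oscillatory activity in the
somatosensory cortico-thalamo-cortical loop: an *evoked* response,
phase-locked to the stimulus and over within ~150 ms, and *induced*
oscillations — stimulus-related but with a random phase on every trial —
that dominate the 200–700 ms post-stimulus window. NMDA-receptor
antagonism (a psychotomimetic low dose of ketamine, with each animal its
own saline control) reorganises this activity in a characteristic
four-way pattern: ongoing (pre-stimulus) beta/gamma power rises
everywhere, induced beta/gamma power falls, gamma-band signal complexity
(multiscale entropy) rises specifically in layer 6 and the VPm, and
gamma-band coherence between layer 6 and the VPm collapses while pairs
involving the higher-order PoM nucleus are unaffected.

`ctcgamma` implements the complete analysis chain for this design —
epoching, band power, the evoked/induced decomposition, band-limited
multiscale entropy, magnitude-squared coherence and the statistical
battery — together with a synthetic session generator that reproduces
the design's statistical structure, so every stage is testable without
recorded data.

## Analysis model

**Windows and spectra.** The baseline is the 500 ms before each
stimulus; the late window is 200–700 ms after it. Both last 500 ms, so a
single Hamming-tapered segment (no averaging, no overlap) gives a
periodogram on an exact 2 Hz grid at any sampling rate. Power is
normalised so the one-sided spectrum sums to the windowed signal's
energy (Parseval), and per-epoch mean subtraction (default on) prevents
DC leakage through the Hamming window. Band power sums bins with
`low <= f <= high`; on the 2 Hz grid the canonical odd-Hz band edges
never produce a bin shared between adjacent bands.

**Normalised power.** For trial $i$, with baseline power $P_{b i}$ and
late-window power $P_{e i}$, the average normalised power is the mean of
per-trial ratios

$$P_v = \frac{1}{N}\sum_{i=1}^{N} \frac{P_{ei}}{P_{bi}},$$

*not* the ratio of means; the same formula applied to the ketamine
session gives $P_{kv}$. The baseline contrast is
$\mathrm{mean}_i(P_{kbi}/P_{bi})$.

**Evoked/induced decomposition.** Per trial,
$\text{Induced}_i = \text{Total}_i - \text{Evoked} - \text{Baseline}_i$,
where Evoked is the band power of the time-domain average of the same
trials' late epochs (phase-locked activity survives averaging; induced
activity cancels as $1/N$). A `definition = "figure3"` variant omits the
evoked term, because both definitions circulate for this quantity; the
subtractive three-term form is the default. Induced power is also
reported as a percent change, $100\,\text{Induced}_i/\text{Baseline}_i$.

**Multiscale entropy.** Sample entropy is
$-\ln(A/B)$, where $B$ counts pairs of $m$-point templates within
Chebyshev distance $r$ (self-matches excluded) and $A$ the same for
$m+1$ points. Coarse-graining at scale $\tau$ replaces the series by
non-overlapping block means (length $\lfloor N/\tau \rfloor$; $\tau = 1$
is the identity). Parameters follow the conventions of the literature
this analysis descends from: $m = 2$, $r = 0.2\,\mathrm{SD}$, scales
1–20, all configurable. $r$ is fixed from the scale-1 (band-filtered,
uncoarsened) series and held constant across scales; recomputing per
scale is available behind a flag. The epoch is band-filtered (beta or
gamma) *before* entropy, one curve per trial, and curves are averaged
across the 40 trials — never computed on concatenated trials. Scales
with zero template matches are flagged undefined and excluded with a
logged count rather than imputed.

**Coherence.** Magnitude-squared coherence
$C(f) = |S_{xy}|^2/(S_{xx}S_{yy})$ with Welch cross/auto spectra over
Hamming segments; defaults mirror the common engineering convention of 8
segments with 50% overlap, applied within each 500 ms late-window epoch.
At that epoch length the estimator's own grid is ~9 Hz; band averaging
uses that grid without interpolation, since resampling coherence onto a
finer grid would fabricate resolution. Coherence is computed per trial
and the 40 values per pair enter the condition contrast; a pooled
estimator (spectra averaged over trials first) is available behind a
flag. Note the estimator's small-sample bias: independent signals show a
nonzero coherence floor (~0.2 at these settings) that *depends on the
signals' in-band spectral shape* — narrowband-dominated pairs sit on a
higher floor than white-dominated ones. This matters when comparing
conditions whose spectra differ (see Limitations).

**Statistics.** Paired t (two-sided, zero-variance differences flagged
degenerate), Wilcoxon matched-pairs signed-rank (zeros dropped with a
logged count; exact p for ≤ 25 nonzero pairs, tie-corrected normal
approximation above), classical one-way ANOVA with Holm–Šidák-adjusted
pairwise post hocs on the pooled error, and balanced two-way ANOVA whose
time × condition interaction is the test of interest for induced power.
Holm–Šidák: sort ascending, $\tilde p_{(i)} = 1-(1-p_{(i)})^{m-i+1}$,
enforce monotonicity, restore order. Power enters the paired t
(baseline contrast) and the two-way ANOVA on the log10 scale: spectral
power has SD proportional to its mean, and the log transform restores
the homoscedasticity both tests assume; ratios are still reported on the
natural scale. Trials are treated as independent units (the pooled
"40 values" design); a rat-level mixed model would be the statistically
stricter choice and is deliberately out of scope — a documented
limitation of the design being replicated, not of the implementation.
Multiple-comparison families are defined per figure panel (the four
channels of a band's power panel; the three pairs of a band's coherence
panel), and the four-way signature check consults the family-adjusted
p-values throughout.

## The synthetic session generator

Each channel (EEG, L6, VPm, PoM) sums phenomenological components:
1/f background, a 2 Hz delta sinusoid, intermittent sigma spindles
(10–16 Hz noise under Hanning-bump envelopes), ongoing theta noise,
ongoing beta and gamma oscillations, white noise, a phase-locked evoked
kernel (40 Hz carrier under a Gaussian envelope, support 0–150 ms —
over well before the late window opens), and random-phase band-limited
beta/gamma bursts confined to the 200–700 ms window with a
near-rectangular envelope (10 ms edge ramps). All band-limited noise is
produced by frequency-domain shaping of white noise, scaled to unit
variance *in expectation* so short bursts keep the natural
trial-to-trial power fluctuation a pinned-variance draw would suppress.

Two design choices deserve emphasis:

* **Finite oscillation linewidth.** The beta and gamma *sources* use
  narrowband carriers (20–26 and 38–48 Hz) inside the wider analysis
  bands. If the generated "gamma" filled the full 30–80 Hz band it would
  be spectrally indistinguishable from band-filtered white noise, and no
  noise manipulation could move band-limited entropy — a narrowband
  oscillation riding on broadband noise is also what real recordings
  look like.
* **Shared-source coherence.** The L6 and VPm gamma carriers (ongoing
  and induced) are a linear mix of one common source and private
  sources; `shared_gamma_mix` is the single knob behind L6–VPm
  coherence, and mixing gives a closed-form expected coherence usable as
  a test oracle. EEG and PoM gamma are private.

The canonical ketamine configuration applies the condition contrast as
power multipliers: ongoing beta/gamma power ×2, induced burst power
×0.5, `shared_gamma_mix` 0.8 → 0.4, plus an injection of fast 55–85 Hz
("high-gamma") band-limited noise at L6 and VPm only (amplitude 0.75).
The injection is what raises gamma-band entropy specifically in the
L6–VPm loop; confining it above the beta band leaves beta-band entropy
unchanged, matching the corresponding negative finding, and leaving PoM
untouched keeps its entropy flat. "Rat" exists only as trial grouping
(4 × 10 trials), matching the pooled 40-value analyses.

Default amplitudes (delta 4, theta 1, sigma 1.5, beta 1, gamma 1, pink
1, white 1, evoked 8, burst SD 1.5/1.8 for beta/gamma) were chosen once
so that a slow-wave-sleep-like background dominates the raw trace while
the stimulus-locked quantities are detectable at the 40-trial design
size — which is precisely the regime the original design documents.

**What the generator does not emulate:** volume conduction, non-Gaussian
spike contamination, electrode drift, rat-level random effects
(available only as trial grouping), pharmacokinetic time courses within
a session, and any biophysical network mechanism (no thalamic reticular
bursting, no membrane dynamics). Passing tests therefore show the
*analysis chain* is correct and sensitive at the design size under a
realistic statistical structure — not that the biological effect sizes
are predicted.

## Numerical choices

* Band-pass filtering is zero-phase frequency-domain filtering with
  raised-cosine transitions (2 Hz default) and reflection padding. A
  causal IIR filter would shift energy across the hard 200 ms window
  boundary, and high-order IIR bandpasses at 30–80 Hz become numerically
  fragile at the acquisition rate of 20 kHz; the FFT filter is exact,
  stable at any rate, and length-preserving.
* Time-to-sample convention: samples are 0-based, onset time $t$ maps to
  sample $\mathrm{round}(t \cdot f_s)$, windows are half-open — a 500 ms
  window is exactly $f_s/2$ samples, so baseline and late spectra share
  one bin grid.
* Epoching refuses out-of-range onsets for the whole run; trials are
  never dropped silently.
* The sample-entropy kernel (C++) uses an early-abort template scan; a
  literal full-distance-matrix oracle in R is exported and the exact
  equality of their match counts is a tested invariant.
* Undefined entropy (zero matches, or an all-constant epoch) is flagged,
  excluded from averages with a logged count, and never imputed.
* Default working rate is 1 kHz: the highest analysed frequency is
  80 Hz, so 1 kHz is lossless for every statistic while 20× faster than
  the acquisition rate, which remains fully supported.
* Test and acceptance runs use a 2.5 s inter-stimulus interval (the
  canonical default is 15 s): the analysis touches only −0.5 to +0.7 s
  around each onset, so inter-stimulus padding carries no information,
  and 40-trial sessions stay ~100 s long.

## Limitations

* The coherence floor of independent channel pairs depends on in-band
  spectral flatness. Because the ketamine configuration adds fast noise
  at L6/VPm, the L6–PoM and VPm–PoM floors sit ~0.01 lower under
  ketamine, and a 40-pair Wilcoxon occasionally (order 10% of seeds)
  flags that as a spurious "change". This is a property of the
  per-trial Welch estimator on 500 ms epochs, shared with any analysis
  using it at these sizes; the end-to-end signature check accordingly
  tolerates a minority of seeds failing.
* Mean percent-change values inherit heavy tails from per-trial ratio
  denominators; directional claims in the signature therefore use the
  log-scale interaction contrast that the ANOVA actually tests.
* Treating 40 pooled trials as independent units understates rat-level
  correlation; a hierarchical reanalysis is a possible extension, not
  part of the replicated procedure.
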