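---
title: "Methods: mu desynchronization, multiscale entropy and phase-coherence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mu desynchronization, multiscale entropy and phase-coherence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mures` implements an EEG analysis of motor resonance — the engagement of
an observer's sensorimotor system while watching another person act — as a
fully testable pipeline. The chain is: band power and mu (8–13 Hz)
desynchronization scoring; multiscale entropy (MSE) of raw and
band-limited signals; phase-locking-value connectivity networks with a
weighted clustering coefficient and global efficiency; and the group-level
statistics connecting baseline complexity to desynchronization. Because no
human recordings ship with the package, a synthetic EEG generator with
known ground truth stands in for data acquisition, and every downstream
stage is validated against what the generator injected.

# The measurement model, stage by stage

## Mu desynchronization

Band power is estimated by Welch averaging: Hamming windows of 1 s with
25% overlap, periodograms normalized as one-sided spectral densities and
integrated over all bins whose frequency lies inside the band, both edges
inclusive. With this normalization the integrated power of a sinusoid of
amplitude $A$ is $A^2/2$ — the calibration constant is 1, and "power"
means the band's contribution to signal variance in µV². The
desynchronization score at an electrode is

$$D = \frac{\ln P_{task} - \ln P_{rest}}{\ln P_{rest}} \times 100,$$

computed from the trial-averaged task power (per-epoch powers averaged
over the seven 2-s observation epochs) against the resting baseline.
Negative values mean suppression. Note the unusual normalization by
$\ln P_{rest}$ rather than $P_{rest}$: it makes the score scale-dependent
and undefined (or sign-flipped) when the resting power is at or below
1 µV². The package makes this latent assumption explicit: `desync_score()`
refuses `rest_power <= 1` with a hard error rather than returning a
sign-flipped value. The window length is configurable; 1 s is the shortest
Hamming window that still resolves the 8–13 Hz band with useful margin
inside a 2 s epoch (a 0.2 s window, i.e. 5 Hz resolution, cannot separate
the alpha band from its neighbors).

Whether task power should be integrated per epoch and then averaged, or
integrated once across the concatenated task record, is not uniquely
determined; `trial_average_desync()` averages per-epoch powers, which
keeps epochs exchangeable and makes dropped epochs (artifact screening)
well defined.

## Multiscale entropy

Sample entropy of a series $x$ with template length $m$ and tolerance $r$
is $-\ln(A/B)$, where $B$ counts pairs of $m$-point templates within
Chebyshev distance strictly less than $r$ and $A$ the subset whose
$(m+1)$-th points also match; self-matches are excluded. MSE computes this
on coarse-grained versions of the series: scale factor $s$ averages $s$
consecutive samples, yielding $\lfloor N/s\rfloor$ points (so 14,000
points at scale 20 give 700, enough for stable estimates; the code warns
below 100). Defaults are $m = 2$, $r = 0.15\,SD$, scales 1–20 and
$N = 14{,}000$, and the complexity score is the mean entropy over scales.

Two conventions are deliberately fixed and exposed as flags rather than
silently chosen:

* the absolute tolerance is $r$ times the SD of the *original* (scale-1)
  series, reused at all scales — the standard MSE convention; per-scale
  renormalization is available via `per_scale_r = TRUE`;
* for band-limited MSE the SD is taken *after* filtering, otherwise the
  tolerance would be dominated by out-of-band variance and band-specific
  entropy differences would be crushed.

Undefined entropies (no template matches, e.g. constant coarse-grained
series) propagate as `NA` flags, never as sentinel values, and are
excluded from the scale average with a message. Band-limited profiles use
a zero-phase Hamming-window FIR band-pass (>= 50 dB stopband; order from
the 3.3/transition-width rule with the transition set to a quarter of the
band width, floored at 1 Hz, and capped to a third of short segments).
Whether the reference analysis filtered per band or used some other
decomposition is not stated in the source; filtering is this package's
reading, and `band = NULL` gives the raw-signal profile. Task-side MSE
uses the first $N$ clean task samples (concatenation), rather than
per-epoch profiles averaged afterwards; the alternative is one flag away
in user code since `mse_curve()` operates on any series.

Profile classification against the resting reference follows the
three-shape scheme — increased complexity (up at all scales), toward
regularity (down at all scales), toward randomness (up at fine scales,
down beyond a crossover) — plus an explicit `"mixed"` outcome so the
function is total; without it, profiles fitting none of the three shapes
would need an arbitrary forced assignment.

## Phase-coherence networks

Connectivity in a band is the phase-locking value: each channel is
band-passed (zero-phase FIR), the instantaneous phase is taken from the
analytic signal, one filter length is trimmed from each end (analytic
transients bias locking estimates upward), and the weight between two
electrodes is the modulus of the circular mean of their phase difference —
1 for constant lag, near 0 for independent phases. Among the several
synchronization indices in the phase-locking framework this is the
dominant reading; an entropy-of-phase-difference index is available via
`method = "entropy"`. Weights are used as computed, fully connected, with
no thresholding.

The clustering coefficient is implemented exactly as the source analysis
prints it:

$$CC_j = \frac{\sum_{i,m} (w_{ij} w_{im} w_{jm})^{1/3}}{k_j (k_j - 1)},
\qquad k_j = \sum_i w_{ij},$$

with $k_j$ the *weighted* degree. The standard formulation normalizes by
the count of neighbors; with the weighted degree the value can exceed 1,
and — importantly for interpreting condition contrasts — uniformly
*weakening* all weights can *raise* $CC_j$, because the denominator
shrinks quadratically while the numerator shrinks linearly in the weights.
The strict standard variant is available via `degree = "count"`. Nodes
with $k_j(k_j-1) \le 0$ are flagged undefined and excluded from the
network average.

Global efficiency uses shortest weighted paths with the inverse map
$f(w) = 1/w$ (the map is pluggable): $GE = \frac{1}{N(N-1)} \sum_{i \ne j}
1/d_{ij}$ with $1/\infty = 0$, so isolated nodes are tolerated; a fully
disconnected graph has $GE = 0$ and a complete unit-weight graph 1.
Shortest paths are delegated to Dijkstra's algorithm (`igraph`); the test
suite checks it against an independent exhaustive path enumeration.

## Group statistics

One-sample and paired t-tests (two-sided; sidedness is not stated in the
source and two-sided is the conservative default) carry Cohen's
$d = |\bar x - \mu_0| / SD$; paired tests operate on task-minus-rest
differences so positive statistics mean task increases. Bonferroni control
for the 12 electrode comparisons reports both $\alpha/k$ at full precision
and the 3-decimal rounding (0.05/12 = 0.004). The three regression models
for C3 desynchronization (baseline entropy, task entropy, baseline mu
power — single-predictor models, as printed) are ordinary least squares
with $R^2$, residual standard error (RMSE) and residual df; the
entropy-change/efficiency-change association is a Pearson correlation with
$t = r\sqrt{n-2}/\sqrt{1-r^2}$. Repeated-measures ANOVAs and normality
checks are routine fits available from standard R (`aov`, `car`,
`ks.test`) and are not re-derived here. One edge case: constant data
exactly at the null mean returns $t = 0$, $d = 0$; constant data away from
it is a hard error (zero variance).

# The synthetic generator: what it emulates, and what not

Each channel is a sum of band oscillations plus $1/f^\beta$ background
(spectrally shaped white Gaussian noise, $\beta = 1$ by default).
Oscillations are *narrowband processes*, not pure tones: the instantaneous
frequency drifts slowly inside the band around a randomized center, and a
slow phase random walk decoheres channels that share no coupling — pure
tones would make any two same-band channels trivially phase-locked.
Pairwise coupling sets a target channel's band phase to its source's phase
plus von Mises jitter of concentration $\kappa$; for raw phase pairs
(`gen_coupled_phases()`) the jitter is i.i.d. and the expected
phase-locking value is exactly $I_1(\kappa)/I_0(\kappa)$. Inside
*recordings* the jitter is held piecewise-constant for 0.2 s: i.i.d.
per-sample jitter is broadband and would be filtered away by the
band-pass in the measurement chain, silently erasing the injected
coupling contrast; holding preserves the von Mises marginal while keeping
the jitter inside the filter's passband (the measured PLV then sits at or
somewhat above the Bessel ratio, and the $\kappa$ ordering — which is what
the condition contrast needs — survives measurement).

Injected desynchronization is translated into task amplitudes with a
noise-floor correction: the target ratio applies to the *total* in-band
power (oscillation plus the analytically known in-band share of the $1/f$
background on the discrete Fourier grid), because that total is what band
power measures. Without the correction, injected scores would be
systematically under-recovered at strong suppression.

Cohort defaults — the study conditions for the end-to-end checks — are 45
subjects, 32 channels (10–20 montage), 500 Hz, 30 s per condition; alpha
amplitudes 10 µV at C3/Cz/C4, 12 µV occipitally, 6 µV elsewhere; delta 8,
theta 6, beta 4, gamma 2 µV everywhere; background SD 7 µV (in-band alpha
SNR of roughly 20 at sensorimotor sites). The effect cohort draws each
subject's C3 desynchronization from $N(-15, 20)$ (C4: $N(-9, 20)$) —
matching a strong single-electrode effect of roughly $d = 0.75$ — and
weakens an alpha coupling star (Cz to the central/frontal/parietal sites)
from $\kappa = 4$ at rest to $\kappa = 1$ in the task. The null preset
injects nothing: identical amplitudes and coupling in both conditions, so
the two conditions are exchangeable and any detected "effect" is a false
positive by construction. MSE uses $N = 14{,}000$ samples (the source
analysis reports both "at least 20,000" resting points and
$N = 14{,}000$; the pipeline takes $N$ as configuration and does not
resolve that discrepancy), networks use the first 2 s of each condition,
and desynchronization uses seven 2-s task epochs — sizes chosen to mirror
the reference design while keeping a full 45-subject cohort tractable on
one core.

What the generator does *not* emulate: volume conduction and a forward
head model (so re-referencing uses the common average as a stand-in for
reference standardization techniques that need a lead field), ocular/EMG
artifacts beyond optional amplitude spikes, non-stationary amplitude
dynamics, and any genuine coupling between a subject's baseline complexity
and their desynchronization (the regression models therefore recover ~0
slope on synthetic cohorts, and their parameter recovery is tested at the
records level instead). Passing end-to-end tests consequently show that
the *measurement chain* recovers known effects of realistic size through
realistic backgrounds — not that real EEG behaves like the generator.

One observed interaction worth noting: the common-average reference
subtracts the coherent part of the coupled alpha star from every channel,
which partially absorbs injected desynchronization (a few percentage
points at C3) and is condition-dependent when coupling changes. This is a
real property of reference choice, not an artifact of the implementation;
the effect-cohort significance checks pass with it in place, and the
parameter-recovery check (±2 points) is defined on as-recorded data.

# Numerical choices

* Sample indexing is 0-based with half-open intervals, uniformly.
* Band-power bin inclusion is `low <= f <= high`, both edges inclusive,
  fixed for bit-reproducibility.
* Sample entropy matching is strict (`< r`), self-matches excluded;
  the Rcpp kernel is checked for *exact* equality against an exhaustive
  R oracle.
* The von Mises sampler is Best–Fisher rejection sampling, deterministic
  under `set.seed`.
* All cohort randomness derives from one root seed via fixed per-subject
  offsets; identical configs give byte-identical outputs.
* Artifact screening defaults: 100 µV amplitude limit, 0.1 s flatline
  limit; per-channel rejection fractions are reported rather than
  excluding subjects.
* EDF I/O quantizes to 16 bits over a per-channel physical range slightly
  widened so the ASCII-rounded header bounds still bracket the data;
  round trips are exact to the quantization step.

# Known limitations

* The printed clustering coefficient (weighted-degree denominator) is not
  bounded by 1 and responds non-monotonically to uniform weight changes;
  use `degree = "count"` for the standard behavior.
* The desynchronization score's $\ln$ normalization ties results to the
  working units (µV²); powers must exceed 1 in those units.
* PLV on short (2 s) segments has a nonzero floor for independent signals
  (~0.05 at 300+ effective samples); condition contrasts, not absolute
  weights, are the meaningful quantity.
* Filter orders are capped on short segments, widening transition bands;
  delta-band phase estimates on 2 s segments are accordingly coarse.
* `files` mode expects recordings already free of gross artifacts beyond
  what the amplitude/flatline screen catches; there is no ICA or
  regression-based ocular correction.
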