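# mures

EEG analysis of **motor resonance**: when people watch someone else act,
the mu rhythm (8–13 Hz) over their sensorimotor cortex desynchronizes.
`mures` implements the full analysis chain used to study how *nonlinear*
brain dynamics change during this state — and, because studies of this
kind rarely deposit raw recordings, it ships a synthetic EEG generator
with known ground truth so that every stage of the chain can be validated
end to end.

The pipeline, for each subject:

1. **Mu desynchronization** — Welch band power (Hamming windows, 25%
   overlap; integrated band power of a sinusoid of amplitude *A* is
   *A*²/2) and the score
   *D* = (ln *P*<sub>task</sub> − ln *P*<sub>rest</sub>) / ln *P*<sub>rest</sub> × 100,
   trial-averaged over 2-s observation epochs. Negative *D* = suppression.
2. **Multiscale entropy (MSE)** — sample entropy SE = −ln(*A*/*B*)
   (*m* = 2, *r* = 0.15 SD, Chebyshev matching, self-matches excluded) on
   coarse-grained series at scales 1–20 of *N* = 14,000 points, raw or
   band-limited (zero-phase FIR); the complexity score is the mean over
   scales, and task-vs-rest profiles are classified as increased
   complexity / toward regularity / toward randomness / mixed.
3. **Phase-coherence networks** — per band, instantaneous phases from the
   analytic signal give phase-locking weights w<sub>ij</sub> ∈ [0,1] for
   all electrode pairs (undirected, weighted, fully connected); node-level
   clustering coefficient
   CC<sub>j</sub> = Σ<sub>i,m</sub>(w<sub>ij</sub>w<sub>im</sub>w<sub>jm</sub>)<sup>1/3</sup> / [k<sub>j</sub>(k<sub>j</sub>−1)]
   with weighted degree k<sub>j</sub> = Σ<sub>i</sub>w<sub>ij</sub>, and
   global efficiency GE = 1/(N(N−1)) Σ<sub>i≠j</sub> 1/d<sub>ij</sub>
   over shortest weighted paths with length map 1/w (1/∞ = 0).
4. **Group statistics** — one-sample and paired t-tests with Cohen's *d*,
   Bonferroni control (0.05/12 = 0.004 for the electrode family), the
   single-predictor regression models of desynchronization on baseline
   complexity, and the entropy-change vs efficiency-change correlation.

Who it is for: EEG researchers who want a scriptable, tested
implementation of these measures, and methodologists who want to probe how
reliably the chain recovers known effects (amplitude suppression, phase
coupling) injected into realistic 1/f backgrounds.

## Worked example

Inject a −20% mu desynchronization at C3 into a synthetic recording pair
and recover it:

```r
library(mures)

spec <- recovery_spec(-20, seed = 1)        # 3 channels, known ground truth
recs <- gen_recording(spec)
ep   <- extract_epochs(recs$task, (0:6) * 1000, 1000)   # seven 2-s epochs
trial_average_desync(ep, recs$rest, "C3", "alpha", rest_samples = 14000)
#> <desync> C3: -19.98% (task 22.26 / rest 48.31 uV^2, 7 epochs)

band_limited_mse(recs$rest, "C3", "alpha", n_samples = 14000, condition = "rest")
#> <mse_profile> C3/alpha/rest avg entropy 0.6478 over 20 scales (m=2, r=0.15)
band_limited_mse(recs$task, "C3", "alpha", n_samples = 7000, condition = "task")
#> <mse_profile> C3/alpha/task avg entropy 0.6947 over 20 scales (m=2, r=0.15)
```

The injected suppression is recovered to 0.02 percentage points, and the
alpha-band complexity at the suppressed electrode rises (entropy +7.2%
here): less rhythmic mass in the band leaves relatively more irregular
background, which is the mechanism the group-level analyses look for.

The full study-shaped analysis lives in `analysis/` as numbered drivers
over the package functions:

```sh
Rscript analysis/01_simulate.R          # example subject, EDF/TSV + spec YAML
Rscript analysis/02_desync_recovery.R   # D in {-40,-20,-10,0} recovered within 2 pp
Rscript analysis/03_cohorts.R           # 45-subject effect + null cohorts (minutes)
Rscript analysis/04_group_stats.R       # the motor-resonance sign pattern
Rscript analysis/05_figures.R           # MSE profiles and network heatmaps
```

Stage 3/4 outputs land in `results/`: per-subject records
(`subjects.tsv`), the test table, regression models and the
change-correlation. In the effect cohort (central alpha suppression, mean
−15% at C3; task-weakened alpha coupling) the pipeline reproduces the
motor-resonance pattern — significant negative C3 desynchronization,
significantly *increased* C3 alpha entropy, significantly *decreased*
alpha-band global efficiency — while the matched null cohort (nothing
injected) reproduces none of it.

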