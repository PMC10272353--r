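---
title: "Analysing stimulation-evoked multi-unit activity with evokedmua"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing stimulation-evoked multi-unit activity with evokedmua}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

`evokedmua` analyses how cortical multi-unit spiking responds to two kinds of
stimulation delivered under anesthesia: a mechanical tap to the forepaw
("Solenoid") and a single weak intracortical microstimulation pulse in
premotor cortex ("ICMS"), alone or combined at a fixed latency
("ICMS+Solenoid"). Recordings come from two 32-channel microelectrode arrays
(4 shanks x 8 sites), one in the rostral forelimb area (RFA, the rat premotor
homologue) and one in forelimb primary somatosensory cortex (S1), sampled at
30 kHz. Trials of the three types are cycled serially, one per second, in
blocks of 100 per type.

The scientific questions are about the *structure* of the evoked response:
an early S1-specific peak (~25 ms after solenoid contact), a later peak
(~50 ms after contact) shared by S1 and RFA, an immediate post-pulse response
in RFA, and whether covariates — cortical area, the volume of an ischemic
lesion in primary motor cortex, and trial type — predict the weights of these
response components.

Because no public recording accompanies the design, the package ships a
ground-truthed synthetic cohort generator with exactly this structure, so
every stage of the pipeline is testable end to end.

## Pipeline overview

1. **Conditioning and spike detection** (`bandpass_filter`,
   `common_average_reference`, `sneo`, `detect_spikes`,
   `reject_artifacts`): a 4th-order elliptic IIR bandpass (300–5000 Hz,
   0.1 dB ripple, 40 dB attenuation) applied zero-phase
   (forward–backward), per-array common average referencing, and a smoothed
   nonlinear energy operator for multi-unit event detection.
2. **Rates** (`bin_spikes`, `sqrt_rate`, `smooth_sg_kaiser`,
   `baseline_stats`, `evoked_flags`, `confidence_band`): 5-ms peri-event
   bins, a square-root variance-stabilising transform of the trial-mean
   rate, Kaiser-weighted local-cubic smoothing, baseline statistics with a
   3-SD evoked threshold and a 2.4 sqrt(spikes/s) channel-inclusion cutoff.
3. **Decomposition** (`pca_topk`, `combined_basis`, `rica_fit`,
   `project_weights`, `reconstruct_profile`): per-trial-type PCA of the
   250 ms of response following solenoid onset, then a PCA-seeded
   reconstruction-ICA model `x = mu + A s` with `q = 3` components, fitted
   per trial type and for the combined Solenoid / ICMS+Solenoid grouping.
4. **Models** (`fit_weight_model`, `summarize_weights`,
   `cavalieri_volume`): mixed-effects models of component weights on
   area x lesion volume x trial type (all interactions, effects coding)
   with a random intercept per animal.
5. **Orchestration** (`run_pipeline`, `summarize_run`): staged execution
   with CSV/JSON outputs, a manifest, seed control and `--resume`-style
   incremental re-runs.

```{r}
library(evokedmua)
cfg <- pipeline_config(sim = sim_config(n_animals = 4, n_trials_per_type = 30,
                                        rng_seed = 1))
res <- run_pipeline(cfg, "run1")
summarize_run("run1")
```

## Spike detection

The nonlinear energy operator `psi[n] = x[n]^2 - x[n-k] x[n+k]` (delay
`k = 1`) responds jointly to amplitude and frequency transients; it is
smoothed with a unit-area triangular window of five samples. Candidates are
samples whose smoothed energy exceeds an adaptive threshold — 10 times a
median-based noise scale of the energy trace — and whose waveform reaches at
least 15 µV (absolute) within ±0.5 ms. The 15 µV floor is applied to the
*waveform*, not the energy statistic: the energy threshold has no natural
microvolt scale, while the amplitude floor directly encodes the minimum
physiological event size. Events closer than a 1-ms dead time are merged,
keeping the larger energy peak.

Artifact handling has two independent rules: any sample exceeding 450 µV
(absolute) defines an artifact, and events within ±4 ms of an artifact
sample are discarded; independently, events within ±4 ms of a known ICMS
pulse time are discarded (the imposed blanking period). The halo is a closed
interval with half-a-sample slack so boundary events quantized to sample
times are not lost to floating-point rounding. Referencing is performed
*before* artifact handling because stimulation artifacts are largely
common-mode and partially cancelled by the array reference.

Zero-phase filtering was chosen so detected event times are not lag-shifted
with respect to the stimulus clock; the elliptic design parameters not fixed
by the analysis (ripple, attenuation) use conventional values of 0.1 dB and
40 dB.

## Rates and smoothing

Spike counts are accumulated in half-open 5-ms bins anchored at trial zero
and converted to `sqrt(mean count / bin width)` — the square root is the
canonical variance-stabilising transform for Poisson-like counts, making the
across-trial variance of the rate estimate approximately independent of the
underlying rate (the test suite verifies a < 2x variance ratio across rates
of 5–50 spikes/s, against a proportional-to-rate raw variance).

Smoothing is a Kaiser-weighted Savitzky–Golay filter: each interior bin is
replaced by the centre value of a cubic fitted by weighted least squares over
a 21-sample neighbourhood with Kaiser(21, beta = 38) weights. With beta as
large as 38 the weights are sharply concentrated at the window centre, so
the equivalent kernel is short; polynomial *extrapolation* to the window
ends is therefore severely ill-conditioned, and edge bins are instead passed
through unsmoothed and flagged edge-unreliable. This mirrors the analysis
convention of disregarding 50 ms (10 bins) of smoothed values at each end of
a segment. For the same reason the default peri-event window is
[-250, +350) ms around trial zero: 250 ms of recorded pre-trial baseline,
and enough post-stimulus margin that the 250-ms analysis window
[+50, +300) ms (solenoid onset is at +50 ms) consists entirely of interior
bins.

Baseline statistics use the 30 bins in [-200, -50) ms — the 250-ms recorded
baseline with 50 ms trimmed at each end. The evoked threshold is the
baseline mean plus three baseline standard deviations; a channel-condition
is *significant* when any non-edge post-onset bin exceeds it, and *included*
when its baseline mean reaches 2.4 sqrt(spikes/s) (equivalently a mean count
of 0.0288 per 5-ms bin); quieter channels cannot power the downstream
statistics. The 95% confidence band is a percentile bootstrap over trials
(1000 resamples by default) of the smoothed sqrt rate; a trial-level
bootstrap was chosen for channel-level histograms because trials are the
exchangeable unit there, while grand averages aggregate over channels.

## Component analysis

For each trial type, the included channels' smoothed sqrt rates over the 50
bins of the analysis window form the observation matrix (rows = time
samples, columns = channels). The top-3 principal components (SVD of the
column-centred matrix) seed a reconstruction-ICA fit of

\[ x = \mu + A s, \]

where the columns of `s` are zero-mean, unit-variance and as statistically
independent as possible. The objective is a reconstruction penalty plus a
smooth independence contrast,

\[ \frac{\lambda}{n}\lVert A A^\top X_c - X_c \rVert_F^2 +
   \frac{1}{n}\sum \log\cosh(A^\top X_c), \]

minimised by L-BFGS from the PCA seed (`lambda = 1`, iteration cap 1000,
relative-objective tolerance 1e-6). After optimisation, sources are the
least-squares projections of the centred observations onto `A`,
standardised across observations with the scaling folded back into `A` and
`mu`, so projection and reconstruction are exact inverses on the model
span. ICA leaves order and sign undetermined; components are reordered to
match the seed (or any reference, e.g. ground-truth shapes, via
`align_components`) and oriented so each column's largest-magnitude
coefficient is positive. Reconstructions are invariant under alignment.

ICMS-only trials lack the solenoid-evoked response, so a basis shared with
solenoid trials would reconstruct them poorly; following that rationale the
*combined* decomposition (the one used for statistical comparison) pools
only the Solenoid and ICMS+Solenoid observations, while all three trial
types also receive their own per-type decomposition. ICMS-only responses
are still expressed on the same 250-ms grid, aligned to where solenoid onset
would have fallen, so all matrices are commensurate.

In both the synthetic cohort and the recorded data that motivated the
design, the first component is essentially flat — a trial-invariant offset
tracking each channel's overall excitability — so the models below analyse
components 2 and 3.

## Mixed models of component weights

Two models are fitted, one per component, of weight on
`area * lesion_volume * trial_type` (all interactions) with a random
intercept per animal — the only natural grouping level above channel, since
channels are repeated measures within an animal. Factors are effects-coded
(sum-to-zero), so a two-level factor's level effects are sign-symmetric
deviations from the grand mean; lesion volume is standardised internally
for conditioning and reported per SD. The default family is Gaussian with
identity link, fitted by REML with Satterthwaite degrees of freedom
(`lmerTest`). A quasi-binomial/logit variant is available
(`family = "quasibinomial"`), fitted by penalized quasi-likelihood
(`MASS::glmmPQL`); because continuous weights have no natural (0, 1) range,
they are affinely rescaled into (0.025, 0.975) before the logit fit. The
Gaussian variant is the validation default — its calibration is verified by
simulation — and the two variants agree in coefficient sign on
well-separated effects.

`cavalieri_volume` implements the stereological lesion-volume estimate:
section sampling interval (0.6 mm) times the summed marked lesion areas.

## The synthetic cohort

The generator emulates the study conditions: three serially cycled trial
types (default 100 trials each at 1 Hz; acceptance runs use 30), per-channel
baseline multi-unit rates around 10 spikes/s with lognormal channel
heterogeneity (sd 0.25 on the log scale), an early Gaussian rate bump
restricted to S1 (peak +40 spikes/s at 75 ms from trial zero, i.e. 25 ms
after solenoid onset; sd 6 ms), a late bump shared by both areas (+30
spikes/s at 100 ms; sd 10 ms), and an RFA-only post-pulse bump (+50
spikes/s, 5 ms after the pulse; sd 3 ms). Amplitudes chosen where the
design gives none are typical of anesthetized sensory-evoked multi-unit
rates. Per-channel lognormal gains (sd 0.4) applied independently per
component create the channel-level response heterogeneity the component
analysis relies on; the ICMS+Solenoid condition multiplies the late-bump
amplitude by 1.5 (the injected facilitation), and lesion volume can modulate
the early and late amplitudes log-linearly (off by default).

Spike trains are inhomogeneous Poisson, sampled by thinning against the
known intensity bound. Traces are white Gaussian noise (5 µV sd) plus a
stereotyped negative-leading biphasic template (~1.2 ms, 80 µV peak)
superposed linearly at each spike time — multi-unit activity, not sorted
units, so a single template suffices — plus a critically damped biexponential
ICMS artifact (2 kV-scale is not needed; 2000 µV peak, 0.6 ms time constant,
comfortably beyond the 450 µV criterion) with a per-channel coupling factor
in [0.75, 1.25] so the artifact is mostly, but not exactly, common-mode.
Lesion volumes are lognormal, moment-matched to mean 5.4 and sd 3.7 mm³ —
lognormal rather than clipped normal so volumes are positive while the first
two moments are exact. The ICMS-to-solenoid latency, which the design leaves
free, defaults to 10 ms. An optional low-frequency "whisking" artifact
injector exists but is off by default, matching the pharmacological
suppression of whisking during recording.

What the generator does *not* emulate: anesthesia-depth dynamics, cortical
layer-specific waveforms or connectivity, receptive-field structure,
electrode drift, and correlated (non-Poisson) spiking. Passing tests on this
cohort therefore demonstrate that the pipeline recovers the statistical
structure it assumes, not that the assumptions hold in any particular
recording.

Every random quantity derives from one configured seed; per-animal and
per-channel sub-seeds make cohorts reproducible channel-by-channel, which
also allows recordings to be synthesized and processed one channel at a
time in bounded memory (the common average reference of the filtered array
equals the filtered array-mean trace, by linearity).

## Numerical choices and degenerate inputs

- Zero-phase filtering uses reflected-edge padding of three filter orders;
  signals shorter than the padding are rejected.
- The energy operator zero-pads its `k`-sample boundaries and flags them;
  boundary samples never seed detections.
- Half-open bins carry a one-picosecond guard so sample-aligned spike times
  land in their nominal bin.
- Degenerate decompositions (rank < 3) return fewer components with a
  warning rather than fabricating directions.
- Singular model designs fail with the aliased term named.
- Problem sizes in the test suite (e.g. 30-trial, 4-animal cohorts; 60-s
  detection fixtures) are the package's validation defaults, chosen to
  exercise every stage at full sampling rate while keeping a complete run
  in the minutes range.

## Known limitations

- The energy-threshold multiplier (10) is adaptive but fixed; extremely
  bursty channels could warrant per-channel tuning.
- The quasi-binomial variant's rescaling to (0, 1) makes its coefficient
  *scale* depend on the observed weight range; only signs and p-values are
  comparable across datasets.
- Degrees of freedom for the quasi-binomial variant come from the
  penalized-quasi-likelihood working model and are approximate.
- The bootstrap band is pointwise, not simultaneous.
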