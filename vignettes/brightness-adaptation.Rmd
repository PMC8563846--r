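---
title: "Modelling adaptive auditory brightness perception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adaptive auditory brightness perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brightadapt)
library(dplyr)
```

## The phenomenon and the model

Auditory brightness is the timbral attribute tied to the balance of low-
versus high-frequency energy. Like many perceptual attributes it is judged
*relative to context*: after a run of bright-sounding stimuli the same
excerpt sounds duller, and vice versa. `brightadapt` provides a fully
synthetic test bed for this contrastive adaptation: stimulus generation,
coloration, feature extraction, experiment designs, a decision-criterion
model of the listener, and the analysis stack that evaluates that model.

The listener model is deliberately minimal. The only percept is the
spectral centroid (SC) of the stimulus,

$$SC = \frac{\sum_j f_j E_j}{\sum_j E_j},$$

where $E_j$ is the linear FFT magnitude pooled into the $j$-th of 128 bands
spaced uniformly on the ERB-number scale and $f_j$ its center frequency.
Magnitude bins below $-90$ dB full scale are zeroed first. On trial $n$ the
virtual listener answers *bright* iff

$$SC[n] > \alpha \,\mathrm{med}\{SC[n-1-k], \ldots, SC[n-1]\}
        + (1-\alpha)\,\mathrm{med}\{SC[1], \ldots, SC[N]\},$$

where the first median runs over the trials of the last $L$ seconds of
*stimulation* (silences excluded, whole trials only, always at least trial
$n-1$), and the second is a long-term reference. $\alpha = 1$ gives the pure
short-term (ST) model, $\alpha = 0$ the fixed long-term (LT) model,
$\alpha = 0.5$ their mixture. A lapse rate (default 5%) flips the indicated
response on a random subset of trials. The median, rather than a leaky
integrator, is used because the SC distribution of naturalistic excerpts is
skewed.

Two long-term references exist in the literature on this design: the median
SC over all (filtered) stimuli of the session, and the median SC of the
*unprocessed* corpus for the stimulus domain. Both are implemented
(`lt_mode = "session_median"` / `"unprocessed_domain_median"`). The session
median is the default inside the mixed criterion; the pure LT model in
`evaluate_model()` uses the unprocessed-domain median. On the first trial
the ST history is empty; the default policy emits no response there
(`first_trial_policy = "skip"`), a chance response is available behind the
flag. Ties at the criterion count as *dull* (the comparison is strict).

## Synthetic stimuli

No licensed audio ships with the package; only the *spectral statistics*
of the stimuli matter downstream, and these are enforced by construction.

* **Music-like excerpts** (`generate_music_corpus()`): an octave-band-shaped
  noise bed plus 4--8 harmonic tones (random F0s between 100 and 400 Hz,
  2--8 Hz amplitude modulation) following the same spectral envelope.
  Per-excerpt octave-band offsets are drawn around a fixed corpus profile
  so that the mean absolute band deviation from the corpus grand mean
  matches the `heterogeneity_db` parameter (default 1.8 dB, the homogeneity
  level a real-corpus selection procedure would enforce). Durations are
  exactly 1, 2, 4 or 8 s; every excerpt carries 50-ms raised-cosine ramps
  and is peak-normalized to $-3$ dBFS (free-field calibration has no
  digital-domain equivalent).
* **Speech-like excerpts** (`generate_speech_corpus()`): harmonic complexes
  (F0 $\approx$ 120 Hz male / 210 Hz female) with three formant-like
  spectral peaks, a $-6$ dB/oct source tilt, a shaped noise floor and a
  syllabic envelope. Durations are drawn from a truncated normal (mean
  2.0 s, SD 0.26 s, clipped to 1.4--2.8 s) and snapped to FFT-friendly
  sample counts (grid < 10 ms). Male voices receive an extra downward tilt,
  reproducing the gender separation of real sentence material.
* **Transfer functions** (`generate_transfer_function_pair()`): two smooth
  minimum-phase responses; the "device" amplifies lows (below 1 kHz) and
  attenuates highs (above 4 kHz) relative to the "open ear", each side by
  at least `contrast_db / 2` dB on average.

What the generators do *not* emulate: rhythmic/melodic structure,
intelligible phonetics, room acoustics, or any perceptual quality beyond
long-term spectra. Tests passing on this material therefore validate the
processing chain and the model's logic on spectrally realistic inputs; they
do not certify behaviour on real recordings.

## Colorations

Spectral-slope coloration decomposes the waveform with a 5th-order
Butterworth octave filterbank (centers 125 Hz--16 kHz) and scales band $b$
by $s \cdot \log_2(f_b / 1\,\mathrm{kHz})$ dB for centers between 125 Hz and
8 kHz, holding boundary gains outside. The 16-kHz band therefore receives
the 8-kHz gain by default; a variant that slopes it too is available
(`extend_to_16k`), since figure captions and method descriptions of such
protocols disagree on the upper limit. The filterbank is implemented by
spectral multiplication with the analytic Butterworth magnitude response:
the default zero-phase mode applies $|H|^2$ (one forward--backward pass,
delay-free, doubled roll-off), a causal mode applies the complex $H$. Band
edges are geometric ($f_c/\sqrt2$ to $f_c\sqrt2$, top edge capped at
$0.999$ Nyquist). Reconstruction is a plain band sum; because squared
Butterworth crossovers sum flat, the slope-0 chain is flat within
$\pm 1$ dB over 0.125--8 kHz (measured: $+0.33$ dB worst case), which is the
contract the tests enforce.

Transfer-function morphing interpolates (and extrapolates) linearly in the
log-magnitude and unwrapped-phase domains on a common FFT grid (next power
of two at least twice the longer impulse response, by default), then
returns to an impulse response. $m = 0$ reproduces the device exactly,
$m = 1$ the open ear; $m \in [-0.5, 1.5]$ exaggerates either. Stimuli are
convolved and truncated to the input length, re-normalizing only if the
peak would clip.

## Experiment designs

All designs randomize coloration order uniformly, never repeat an excerpt
within a session, and (for speech) never present the same speaker twice in
a row.

* Baseline: 350 trials, 50 at each slope in $\{-2, -1, -0.5, 0, 0.5, 1, 2\}$
  dB/oct, 2-s targets.
* Hidden adaptors: 300 trials alternating adaptor/target; targets 2 s at
  slopes $\{-1, 0, 1\}$ (50 each), adaptors at $\pm 1$ dB/oct with durations
  1/2/4/8 s. The protocol describes random draws; the default here
  counterbalances exactly (75 per adaptor slope, 38/37/38/37 per duration)
  because exact balance sharpens desk-scale statistics; a pure-random mode
  is behind `balancing = "random"`.
* Global shift: the baseline slope set shifted $\pm 1$ dB/oct in two
  sessions, sharing $\{-1, 0, 1\}$.
* Morph: 300 trials over six morph levels per session. The protocol states
  the range $[-0.5, 1.5]$ and 50 trials per level but not the level values;
  the grids $\{-0.5, \ldots, 0.75\}$ and $\{0.25, \ldots, 1.5\}$ (step
  0.25) mirror the slope experiment's overlap structure and share three
  interior levels.

## Simulation, analysis, evaluation

`simulate_participants()` gives every virtual participant an independent
design randomization and lapse stream; there is no per-participant
criterion noise. Adaptor trials are answered and enter the short-term
history; they are excluded from analysis. `aggregate_conditions()` forms
the condition cells (level x previous-trial class x context), averaging
participant proportions, with 2000-resample percentile bootstrap intervals
over participants. Previous-trial classes follow each experiment's
convention: sign of the previous slope (baseline; a relative previous-vs-
current variant is a flag), preceding adaptor slope (hidden adaptors), or
previous level above/below the session mean (shifted and morph designs).

The inclusion criterion retains a participant who gains at least 40
percentage points between the extreme levels of every session (20 points
for the $\pm1$ dB/oct span of the adaptor experiment); equality retains,
since the rule excludes *smaller* gains. The same 40-point rule is applied
to the morph experiment's extreme levels as a package decision (no separate
morph criterion is documented). Comparisons use a $10^{-9}$ guard so that
floating-point noise cannot flip a boundary case.

`evaluate_model()` simulates the suite at every integration length of a
grid (default $\{4, 8, \ldots, 256\}$ s, powers of two spanning the
protocol's printed extremes), pools the squared cell errors against the
reference *unweighted across all cells of all experiments* (a
per-experiment weighting is a flag), and reports the RMS profile, its
argmin and the Pearson correlation at the argmin. The same per-participant
seeds are reused at every grid point (common random numbers), so the
profile varies with the integration length alone; this also makes
degenerate checks exact (an $\alpha = 0$ model's profile is exactly flat).

A fixed-effects binomial regression (`fit_logistic_context_model()`, logit
link, effects-coded binary predictors, Wald intervals) stands in for the
random-effects models used on human data; it is intended for sign and
direction checks on simulated cohorts only, and flags separation instead
of failing.

## Numerical choices and problem sizes

FFTs are taken over whole excerpts without windowing; the ERB grid spans
25 Hz--20 kHz (the filterbank family's range and spacing are a package
decision); bin magnitudes are pooled into the nearest ERB center
(triangular weighting is a flag); dBFS uses $20\log_{10}(2|X_k|/N)$ with
the factor 2 dropped at DC and Nyquist. Batch SC tables exploit the
linearity of the filterbank (one FFT per excerpt serves all slopes) and are
numerically identical to the per-excerpt path, which the tests assert.

The test and example simulations use 350-excerpt music corpora (the
minimum the 350-trial designs admit), cohorts of 50 virtual participants
for model evaluation and 20 for directional checks, and the
$\{4 \ldots 256\}$ s grid; these sizes give clearly resolved effects (the
RMS trough at the generating $L$ is a factor of two below its neighbours)
while keeping a full run in minutes.

## Known limitations

* Human effect sizes are not reproduced, only directions and orderings:
  the synthetic listener has no sensory noise apart from the lapse rate,
  so context effects are sharper than empirical ones.
* The exact excerpt selection of any real corpus cannot be replicated from
  its published summary statistics; the deviation statistic ("mean RMS
  deviation over bands") is read as mean absolute deviation, with an RMS
  reading behind a flag.
* The morph-level grids and the adaptor slope-duration allocation are
  inferred from printed ranges and counts, not stated values.
* Random-effects (mixed-model) estimation is out of scope; the logistic
  summarizer is fixed-effects only.
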