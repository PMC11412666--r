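---
title: "Encoding models for audiovisual EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding models for audiovisual EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avTRF)
```

## The model

avTRF fits forward (encoding) models — multivariate temporal response
functions, mTRFs — that predict each EEG channel from time-lagged stimulus
features:

$$\hat y(t, n) \;=\; \sum_f \sum_\tau w(f, \tau, n)\, s(f, t - \tau),$$

where $s(f, t)$ is a feature stream sampled at 128 Hz, $\tau$ ranges over
integer lags 0–76 samples (0 to ~594 ms; the conventional "0–600 ms" window
at this rate), and $n$ indexes channels. Weights are the closed-form ridge
solution

$$\hat w = (S^\top S + \lambda I)^{-1} S^\top Y,$$

computed by Cholesky factorization of the normal equations — solved, never
inverted. The regularization $\lambda$ is selected per channel by
cross-validation: 15 log-spaced candidates between $10^2$ and $10^8$, scored
on 20 random *contiguous* 80/20 splits of the training time axis
(contiguity preserves the autocorrelation structure that makes sample-wise
splits optimistic); ties resolve toward the smaller $\lambda$. Evaluation is
the Pearson correlation $r$ between predicted and held-out EEG, with
held-out data always coming from trailers never seen in training.

Two feature families are modeled separately, as in the analyses this
package supports: an auditory family (14 binary phonological-onset streams,
the acoustic envelope, pitch) and a visual family (10 motion-energy
principal components, scene-cut impulses).

### Standardization

Feature columns and responses are z-scored before fitting (a single
$\lambda$ across heterogeneous feature scales — binary onsets, an envelope
in arbitrary units, pitch in Hz — is meaningless otherwise). The z-scoring
acts on the *delay-embedded design columns*, not the raw streams: scaling
embedded columns is an affine reparameterization of exactly the linear map
being fit, so a model generated in the lag domain is recovered exactly in
the noise-free limit, whereas scaling before embedding perturbs the map at
window boundaries and those perturbations load onto the design's weakest
eigendirections. Training statistics are stored on the model and reused
verbatim for test data. `nativeWeights()` maps fitted weights back to
native units (multiply by $sd(y_n)$, divide by the embedded column's sd),
which is the scale on which fitted kernels are compared with generative
ground truth. A `standardize = FALSE` switch disables all of this.

### Shuffle significance

Model significance uses a chunk-shuffle null: the training time axis is cut
into 2-s chunks (a trailing partial chunk is kept) and the pairing between
the delay-embedded stimulus and the response chunks is permuted, the model
is refit at the same $\lambda$, and the held-out $r$ is recomputed; 100
permutations by default. Permuting the pairing is statistically identical
to permuting stimulus chunks — the exchange is the stimulus–response
alignment — and leaves the design Gram matrix unchanged, so all refits
share one eigendecomposition. p-values use the add-one estimator
$p = (1 + \#\{r_{null} \ge r_{obs}\})/(1 + n_{shuffles})$, which cannot
return 0. Within a chunk the lag structure is intact, so the null preserves
the autocorrelation that makes naive sample-permutation nulls anticonservative.

### Cross-condition generalization

`crossPredict()` applies a model trained on audiovisual (AV) data — using
one unimodal feature family — to unimodal test data (audio-only A for the
auditory family, visual-only V for the visual family).
`withinVsCrossTable()` pairs these with the matched within-condition
evaluations and reports the least-squares regression of $r_{cross}$ on
$r_{within}$; `weightCorrelationMap()` correlates two models' flattened
(feature × lag) weight matrices per channel, on the native scale;
`eegConditionCorrelation()` correlates the band-passed EEG itself between
conditions. For topography display the latter's channel vector is min–max
scaled to [0, 1]; the raw correlations are always retained, since the
scaling is display-only and not invertible.

Group-level ROI comparisons use descriptive aggregation plus a paired
within-subject sign-flip permutation test (10,000 flips, seeded) on
subject-mean differences. A sign-flip test with $n$ subjects cannot produce
$p < 2^{-n}$ — with few subjects its resolution is coarse, which is the
price of making no distributional assumptions.

### Whole-study fitting

`trainTRF()`, `shuffleTest()` and friends are the single-model building
blocks. For a whole study — several conditions recorded against the *same*
stimuli — `runConditionAnalysis()` fits one feature family across all
conditions at once: the delay-embedded design, its Gram matrix and
eigendecomposition are built once and reused for the lambda search, the
final solves, the test evaluation and the shuffle null. Column
standardization is folded into the normal equations (with \(D\) the diagonal
of column SDs and \(m\) the column means, the standardized Gram is
\(D^{-1}(S^\top S - n\,m m^\top)D^{-1}\), and the resulting constant offsets
cancel in every correlation), so the design matrix itself is never copied or
modified — for an hour of 128 Hz data with 16 features and 77 lags that is
the difference between one ~1 GB matrix and several. The two paths are
numerically identical (a test asserts weights agree to ~1e-14).

## Preprocessing

The chain mirrors standard continuous-EEG practice: mastoid (TP9/TP10)
re-referencing; resampling to 128 Hz; a 58–62 Hz FIR notch; a 1–15 Hz
band-pass. Both filters are Hamming-window linear-phase FIR kernels applied
in one pass with group-delay compensation, giving exactly zero phase; kernel
length follows the Hamming design rule (≈3.3/transition-width, 1 Hz
default transition). The channel mean is removed first so DC rejection is
exact rather than limited by the −53 dB stopband. Resampling is
Fourier-domain (spectrum truncation): zero-phase, inherently anti-aliasing,
and free of the impractically long polyphase filters a 44100→128 conversion
would need. Stimulus–EEG alignment is matched filtering: normalized
cross-correlation of the stimulus against the recorded audio channel, on
rectified low-passed envelopes by default (robust to playback coloration),
with a raw-waveform mode and a correlation floor (default 0.2) below which
alignment fails loudly rather than silently.

## Feature extraction

**Phonological onsets.** A (time × 14) binary matrix with a single 1 at the
sample nearest each phoneme onset, in every articulatory-class column the
phoneme carries (onset coding; interval coding is available behind
`durationCoding`). The 14-feature inventory (sonorant, obstruent, voiced,
nasal, syllabic, fricative, plosive, labial, coronal, dorsal, front, back,
high, low) keyed to ARPAbet is a conventional place/manner/voicing set and
is user-overridable; any standard inventory of the same size works
identically.

**Envelope.** Magnitude of the analytic (Hilbert) signal, 3rd-order
Butterworth low-pass at 25 Hz applied forward–backward, resampled to
128 Hz, with sub-zero ripple clipped.

**Pitch.** Frame-wise normalized autocorrelation on a 1/128 s hop grid,
peak search restricted to 50–300 Hz, voiced/unvoiced decided by a
normalized-autocorrelation floor of 0.3, parabolic peak refinement. The
analysis window is 40 ms — the minimum that contains two periods of the
50 Hz lower bound; a hop-sized (7.8 ms) window cannot estimate F0 in this
range. A pure tone above the range (e.g. 400 Hz) is reported at its
in-range subharmonic, since a sinusoid's autocorrelation peaks at every
multiple of its period; broadband voiced speech does not have this
ambiguity to the same degree.

**Motion energy.** Frames are zero-padded to square, downsampled to 96×96,
and reduced to L\* luminance. The Gabor bank tiles five log-spaced spatial
frequencies (1.5–24 cycles/image) over a centered lattice whose spacing is
4 spatial-envelope SDs; the envelope SD is 0.6 wavelengths, capped at 0.3
image widths; temporal frequencies are 0, 1.33 and 2.667 Hz with eight
directions (four orientations at 0 Hz), a 10-frame temporal window with a
2.5-frame Gaussian envelope, plus one zero-spatial-frequency filter. Under
these defaults the bank has 2,781 quadrature pairs
(`countPhases = TRUE` enumerates phases separately). Spatial kernels are
exactly DC-free, so energies are invariant to global luminance offsets; the
quadrature pair combines to the phase-invariant energy
$\sqrt{r_0^2 + r_{90}^2}$, log-transformed as $\log(1+E)$ ($\log(1+x)$
because exact zeros occur, e.g. a blank movie). Energies are computed at
24 Hz and upsampled to 128 Hz by linear interpolation (nearest-frame mode
behind a flag). PCA (fit on training data only, projection reused for test
data) reduces the bank to 10 components.

## The synthetic test bed

`makeDataset()` generates what the real experiment would record, with known
ground truth: per trailer, one 27-feature stream shared verbatim across
conditions, and 64-channel EEG per condition (AV/A/V) built as
kernel-convolved feature sums plus noise.

* **Phoneme stream**: a renewal process (exponential waits plus a 60 ms
  refractory period) at 6 events/s — a deliberate compromise between
  running speech (~10–12 phonemes/s) and trailers' frequent speech pauses —
  with each event drawing an ARPAbet phoneme (vowels twice as likely as any
  consonant) and lighting its feature bundle, which induces the
  within-modality co-occurrence structure of real phonological matrices.
* **Envelope**: the phoneme train convolved with a causal 50 ms alpha
  kernel, *plus* independent slow and fast background-energy components
  (music and effects dominate real trailer soundtracks). The independent
  components also matter statistically: were the envelope an exact linear
  functional of the phoneme train, envelope and phonological kernels would
  be jointly unidentifiable at any SNR.
* **Pitch**: a band-limited random walk mapped into 50–300 Hz, gated by
  voiced-phoneme spans of random (60–220 ms) duration.
* **Visual PCs**: independent Gaussian processes with ~200 ms
  autocorrelation width and variance falling as $1/j$, plus a weak faster
  component that keeps their delayed copies linearly independent — without
  it, a 600 ms lag span of a process this smooth is numerically rank
  deficient and kernel recovery is impossible in principle, not just hard.
* **Scene cuts**: Poisson impulses at 0.4/s (a typical trailer cut rate).
* **Kernels**: damped Gabor-shaped temporal responses, latency 50–350 ms,
  envelope SD 40–90 ms, carrier 1.5–5 Hz — the early-deflection morphology
  of sensory evoked responses. Each kernel's amplitude is divided by its
  feature's nominal scale so every feature drives comparable response
  variance; without this, pitch (sd ~86 Hz) would be the entire signal and
  binary onsets (sd ~0.1) would contribute nothing recoverable.
* **Topography**: auditory gains peak over fronto-temporal channels,
  visual gains over occipital/parietal channels, with 10% jitter;
  `drivenChannels()` returns the channels at ≥70% of the maximum gain.
* **Noise**: 1/f-spectrum Gaussian noise band-limited to 1–15 Hz (matching
  the analysis band), scaled per channel so the *audiovisual* response
  attains the requested SNR ($10\log_{10}(\mathrm{var_{signal}} /
  \mathrm{var_{noise}})$); condition gain zeroing happens after scaling, so
  A and V conditions carry the same noise level as AV. With noise disabled
  the AV response equals A + V sample-wise.

What the simulator does *not* emulate: volume conduction and channel
covariance (noise is independent across channels), eye/muscle artifacts,
nonlinear or adaptive neural responses, audiovisual interaction (a
condition-gain hook exists, default off), and real phonotactics. Passing
recovery tests therefore demonstrates the estimator and pipeline are
correct, not that real EEG meets the model's assumptions.

## Problem sizes and numerical choices

The validation suite runs the full pipeline at 8 trailers × 150 s × 3
conditions × 64 channels at 0 dB SNR (6 trailers training / 2 test), the
scale at which kernel recovery, shuffle significance, cross-condition
equivalence and ROI ranking are all checked in a few minutes of CPU time.
Shuffle-null calibration uses 400 independent null channels with 59
shuffles — 59 makes the add-one threshold exact at
$3/60 = \alpha = 0.05$. Degenerate inputs are handled by convention:
zero-variance channels score $r = 0$ with a warning; $\lambda = 0$ on a
rank-deficient design is an error advising $\lambda > 0$; signals shorter
than 3 filter kernels, epochs out of bounds, unknown trailer ids and
mismatched feature families are errors, not silent coercions.

## Known limitations

Per-channel $\lambda$ selection (a `--global-lambda`-style average is a
one-liner on the CV curves attached to `cvLambda()`'s result) slightly
overfits channels with weak signal; the regression of cross- on
within-condition $r$ is computed on noisy per-channel estimates and is
mildly attenuated at short test durations; the bank's filter count depends
on the position-lattice convention, which published grids rarely pin down
exactly — the construction here is fully documented above so the count is
reproducible from its parameters; EDF and BrainVision readers cover the
continuous, single-rate recordings this workflow uses, not those formats'
full generality.
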