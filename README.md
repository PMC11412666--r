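# avTRF

Forward encoding models (multivariate temporal response functions, mTRFs)
for continuous EEG recorded during audiovisual stimulation — movie-style
stimuli seen and heard together (AV), heard only (A), or seen only (V).

The scientific question this package serves: when the brain's response to a
rich multimodal stimulus is modeled from one modality's features alone, is
the derived feature tuning the same as under unimodal stimulation? The
package provides the full workflow: stimulus feature extraction, EEG
preprocessing, regularized model fitting, permutation significance, and the
within- versus cross-condition comparisons that answer the question —
plus a synthetic-data generator with known ground truth so every stage is
testable end to end without any recordings.

## The model

Each EEG channel \(n\) is predicted from time-lagged stimulus features:

    y(t, n) = sum_f sum_tau  w(f, tau, n) * s(f, t - tau) + e(t, n)

with lags tau spanning 0–600 ms at 128 Hz and weights fit by ridge
regression, `w = (S'S + lambda I)^-1 S'Y`, with per-channel lambda chosen
by cross-validation over 15 log-spaced values (1e2–1e8, 20 contiguous
80/20 splits). Performance is the Pearson correlation between predicted
and held-out EEG; significance comes from refitting after shuffling the
stimulus–response pairing in 2-s chunks.

Feature families:

* **auditory** — 14 binary phonological-onset streams (place/manner/voicing
  classes of ARPAbet phonemes), the Hilbert acoustic envelope (25 Hz
  low-passed), and autocorrelation pitch (50–300 Hz);
* **visual** — a spatiotemporal Gabor motion-energy filter bank
  (5 spatial frequencies, 3 temporal frequencies, 8 directions, quadrature
  pairs, 2,781 filters under the default lattice) reduced to 10 principal
  components, plus scene-cut impulses.

## Worked example

Simulate a small three-condition dataset with known kernels, fit the
auditory-family model on audio-only data from two trailers, and evaluate on
two held-out trailers:

```r
library(avTRF)

ds    <- makeDataset(nTrailers = 4, duration = 60, snrDb = 0, seed = 1)
split <- splitByTrailer(ds, ds@testTrailers)

stimTrain <- concatenateStreams(lapply(ds@features[split$train],
                                       featureFamily, "auditory"))
stimTest  <- concatenateStreams(lapply(ds@features[split$test],
                                       featureFamily, "auditory"))
yTrain <- concatenateEpochs(lapply(ds@eeg[split$train], `[[`, "A"))
yTest  <- concatenateEpochs(lapply(ds@eeg[split$test],  `[[`, "A"))

model <- trainTRF(stimTrain, yTrain, nIter = 10, seed = 1,
                  condition = "A", trainTrailers = split$train)
model
#> TRFModel [A]: 16 features x 77 lags x 64 channels
#>   lags 0-593.8 ms; lambda in [720, 1e+08]; trained on: tr01, tr02

evaluateTRF(model, stimTest, yTest, modelTag = "auditory_within")
#> EvalResult 'auditory_within': 64 channels, r in [-0.003, 0.690]
```

Prediction is best on the channels the simulator drives with auditory
gain (fronto-temporal sites): mean held-out r over
`drivenChannels(ds@truth, "auditory")` is 0.66 here, and the fitted
kernels (`nativeWeights(model)`) correlate 0.83 on average with the
generating kernels — rising above 0.9 at the full validation scale of
8 trailers × 150 s (see the vignette). Cross-condition analysis replaces
the A-trained model with an AV-trained one via `crossPredict()`, and
`withinVsCrossTable()`, `weightCorrelationMap()`, `roiSummary()` and
`eegConditionCorrelation()` summarize how tuning generalizes across
conditions and scalp regions.

Real data enter through `readAudio()`, `readTextGrid()`, `readEEG()`
(BrainVision, EDF, or the package's bit-exact container), then
`rereferenceMastoids()`, `resampleTo128()`, `filterChain()`,
`alignStimulus()` and `epochRecording()`.

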