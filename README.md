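# popdecode

Linear population decoding of two-photon calcium-imaging recordings from
mouse visual cortex, as a tested, reusable R package.

Two-photon imaging yields fluorescence traces for hundreds of simultaneously
recorded neurons while a mouse watches drifting gratings, static gratings,
sparse noise, natural images, natural movies, or a gray screen. `popdecode`
turns such recordings (plus their stimulus tables) into quantitative answers
to four questions:

1. **How well can the stimulus be decoded from joint population activity?**
   Traces become $\Delta F/F = (F - F_0)/F_0$ (sliding 1-s baseline $F_0$);
   stimulus-class epochs are cut into 10-s intervals and grating trials into
   their 2-s presentation windows; the per-neuron mean $\Delta F/F$ per window
   is z-scored into population feature vectors. A linear SVM or multinomial
   logistic regression with $\ell_2$ penalty $\lVert\theta\rVert^2/2C$ is
   trained with nested cross-validation
   ($C \in \{10^{-2},\ldots,10^3,\infty\}$), balanced training subsamples and
   unbalanced test sets.
2. **How does accuracy scale with population size?** Random neuron subsamples
   of sizes $1, 2, 4, \ldots$ are decoded (10 resamples per size) and the mean
   accuracies fitted with the constrained generalized logistic
   $\mathrm{accuracy}(n) = (1-c)/(1+e^{-an})^b + c$
   ($a \ge 0$, $b \in [0,1]$, $c \ge 0$), used to extrapolate to 128 neurons.
3. **Do noise correlations carry information?** A correlation-blind decoder is
   trained on within-class trial-shuffled data and tested on intact data; the
   joint-minus-blind accuracy difference (paired t test) quantifies synergy.
4. **How direction-selective are single neurons?** Per-neuron orientation and
   direction selectivity indices
   $OSI = (R_{pref}-R_{orth})/(R_{pref}+R_{orth})$,
   $DSI = (R_{pref}-R_{null})/(R_{pref}+R_{null})$, with the standard
   $[0, 2]$ exclusion rule and group averages, plus Tukey HSD / Holm-adjusted
   one-sided t comparisons between groups of populations.

Because the original recordings cannot be redistributed, the package includes
a first-class synthetic-data generator (`simulateRecording()`) producing
multi-session recordings with parameterized direction tuning, sparse calcium
events, and a controllable shared-gain noise-correlation structure, so every
stage is testable end to end. See the vignette
(`vignettes/population-decoding.Rmd`) for the model details and design
rationale.

## Worked example

Simulate a grating session for a tuned 16-neuron population, decode motion
direction, fit the population-size scaling curve, and compute selectivity:

```r
library(popdecode)

model <- tunedPopulationModel(16, seed = 1, tuningAmplitude = 2, noiseSd = 0.2)
sim   <- simulateRecording(model, defaultSessionSpecs()$A, seed = 1)
sim$recording
#> FluorescenceRecording, session A: 16 neurons x 90000 frames (3000.0 s)

dff <- computeDFF(sim$recording)
ds  <- zscoreFeatures(segmentGratingTrials(dff, timestamps(sim$recording),
                                           sim$trials, sessionId = "A"))
ds
#> FeatureDataset: 16 neurons x 600 samples (z-scored)
#>   labels: 0=75, 135=75, 180=75, 225=75, 270=75, 315=75, 45=75, 90=75

decode(ds, decoderSpec("svm", scheme = "holdout"), seed = 1)
#> DecodingResult (svm): accuracy 0.742 over 8 classes, C = 1

curve <- fitAccuracyCurve(subsampleCurve(ds,
           decoderSpec("svm", scheme = "holdout"), nResamples = 3, seed = 2))
curve
#> AccuracyCurve (holdout): sizes 1, 2, 4, 8, 16
#>   mean accuracy: 0.222, 0.244, 0.403, 0.636, 0.675
#>   fit: a = 0.03167, b = 1, c = 0 (SSE 0.18)
round(extrapolateAccuracy(curve, 128), 3)
#> [1] 0.983
```

So 16 neurons decode the 8 directions at 74% (chance 12.5%); accuracy climbs
from 22% for single neurons toward saturation, and the fitted curve predicts
98% at 128 neurons. Per-neuron selectivity from the same trials:

```r
st <- selectivityTable(segmentGratingTrials(dff, timestamps(sim$recording),
                                            sim$trials))
head(st[, c("neuron_id", "pref_dir", "pref_tf", "OSI", "DSI")], 3)
#>   neuron_id pref_dir pref_tf   OSI   DSI
#> 1  neuron_1      315      15 0.793 0.390
#> 2  neuron_2      180      15 1.163 0.292
#> 3  neuron_3       90      15 1.424 0.439
```

`runPipeline()` (or `inst/scripts/popdecode.R` from a shell) drives the whole
analysis from a YAML configuration and writes features, results, and a
reproducibility manifest as CSV/JSON.

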