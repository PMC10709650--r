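# megaccum

Time-resolved zero-shot decoding of event-related MEG responses, built
to answer one question: when the brain recognises a concept, is encoded
information **maintained** or does it keep **accumulating**?

`megaccum` is for cognitive neuroscientists working with averaged,
binned sensor- or source-level response tensors (concepts × channels ×
time bins) and concept feature vectors — semantic word embeddings or
visual-network layer outputs. It provides the full analysis chain:

* **Zero-shot ridge decoding** — leave-one-concept-out multivariate
  ridge regression from a response window to the concept's feature
  vector, scored by Euclidean prediction–target distance. For a window
  with training responses $Z$ (standardized per predictor on the
  training concepts only) and features $Y$, the held-out prediction is
  $\hat y = \bar y + (Zz)^\top (ZZ^\top + \lambda I)^{-1}(Y-\bar y)$.
* **Three window schemes** — sliding fixed-length, cumulative
  (anchored at stimulus onset, growing per step), and cross-temporal
  (train at one bin, test at another; the temporal generalization
  matrix).
* **Plateau / trough detection** — the earliest window within 5% of a
  distance curve's total reduction.
* **Permutation statistics** — label-shuffle nulls for chance-level
  tests, sign-flip nulls for the paired sliding-vs-cumulative
  comparison, add-one p-values, Benjamini–Hochberg FDR, and the
  generalization-window onset from consecutive cross-temporal cells.
* **Searchlight RSA** — cosine model DSMs, Pearson brain DSMs, Spearman
  scoring over spatial patches, and a one-sample cluster permutation
  test across participants (cluster threshold p = 0.01, sum-of-t
  statistics, max-statistic sign-flip null).
* **Group modelling** — linear mixed models of plateau times
  (`plateauMs ~ model + (1 | concept)`, Satterthwaite df, estimated
  marginal means, Tukey contrasts), between-participant SD time
  courses, and plateau correlations between feature models.
* **A synthetic-data generator** with known encoding dynamics
  (accumulation / maintenance / transient / null scenarios) and
  ground-truth plateau times, so the entire chain is testable without
  access to recordings.

## Worked example

Simulate an accumulation scenario at the default study dimensions
(60 concepts in 7 categories, 204 channels, 50 × 20 ms bins), decode it
cumulatively, and compare the detected plateau with the generator's
ground truth and with the onset of cross-temporal generalization:

```r
library(megaccum)

cfg <- generatorConfig(nParticipants = 1, seed = 1)
ds  <- makeScenario("accumulation", cfg)
rt  <- ds@responses[[1]]
fm  <- ds@features$semantic

cu <- cumulativeDecode(rt, fm)          # 50 cumulative windows
pt <- detectStabilizationPoint(conceptMeans(cu), 0.05, windowEndMs(cu))
pt$index
#> [1] 24
pt$timeMs
#> [1] 480
ds@truth$plateauBin[1]                  # ground truth
#> [1] 23

ctp <- crossTemporalPvalues(rt, fm, nPerm = 200, seed = 501,
                            cells = "consecutive")
generalizationOnset(ctp)
#> [1] 7
```

The cumulative curve plateaus at bin 24 (480 ms), one bin after the
generator's ground truth of 23, while significant generalization
between consecutive bins starts at bin 7 (140 ms): information keeps
accumulating for ~340 ms after generalization begins — the accumulation
signature. On a `"maintenance"` scenario the two time points coincide
to within a bin or two.

The same chain runs end to end, writing tidy CSV tables, a manifest and
a plain-text report:

```r
runPipeline(list(scenario = "accumulation", nParticipants = 5,
                 nLayers = 4, nPerm = 200), "results/run1")
```

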