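# dectdnc

Physics-informed synthesis of non-contrast head CT images from dual-energy
CT (DECT).

## What it does

Contrast-enhanced DECT acquires a low-kVp and a high-kVp image of the same
anatomy. Physics-based three-material decomposition can remove the iodine
to give a *virtual non-contrast* (VNC) image, but the result is noisier
than, and systematically offset from, a *true non-contrast* (TNC)
acquisition. `dectdnc` implements a two-stage framework that combines the
decomposition physics with supervised learning:

1. **Lookup VNC (L-VNC).** A 2-D lookup image over 1-HU (low, high) bins
   is estimated from training pairs and their VNC values
   (`buildLookup`), unobserved cells are imputed by a DCT-based
   penalized-least-squares inpainter run for 100 iterations with
   zero-fill of anything still undefined (`inpaintLookup`), and the table
   is applied and 5x5-median-filtered (`applyLookup`,
   `medianFilterImage`).
2. **Deep non-contrast (DNC).** A residual CNN — three groups of three
   residual blocks with dilations 1, 2 and 4 — takes the (low, high,
   L-VNC) channels and predicts the difference TNC − L-VNC inside the
   brain mask (`buildNetwork`, `trainModel`, `predictDifference`);
   `composeDNC` adds the prediction back to the L-VNC.

Performance is measured as brain-masked RMSE and Spearman rank
correlation over batches of pooled voxels (`batchedMetrics`), comparing
DNC, L-VNC and the decomposition VNC against TNC.

Because clinical DECT cohorts are not redistributable, the package ships
a synthetic brain-phantom DECT simulator (`makeScene`, `renderTNC`,
`simulateDECT`, `makeDataset`) with HU-realistic tissue classes, iodine
enhancement with a low/high ratio of 2.12, energy-dependent noise and
patient-level train/validation/test partitioning, plus a linear
three-material decomposition (`decomposeDECT`) standing in for vendor VNC
software. Everything is runnable end to end (`runPipeline`) without any
external data.

## Worked example

```r
library(dectdnc)

cfg <- pipelineConfig(nScenes = 40L, seed = 5L, maxEpochs = 6L,
                      patience = 3L, evalBatchSize = 2L)
rep <- runPipeline(cfg)
rep$summary
#>                comparison n_batches rmse_mean rmse_ci95 spearman_mean
#> DNC-vs-TNC     DNC-vs-TNC         2  5.750669 0.8664081     0.8083837
#> L-VNC-vs-TNC L-VNC-vs-TNC         2  9.468050 1.1365302     0.7996268
#> S-VNC-vs-TNC S-VNC-vs-TNC         2  9.476839 0.5605857     0.7770132
rep$history
#> TrainingHistory: 6 epochs (max_epochs), best val 6.673 HU at epoch 6
```

Reading the output: on the held-out synthetic patients the raw physics
products disagree with the true non-contrast image by ~9.5 HU RMSE — the
decomposition VNC (`S-VNC-vs-TNC`) because of noise amplification and a
systematic per-tissue offset, the lookup VNC (`L-VNC-vs-TNC`) because it
reproduces the same physics (with less noise after median filtering).
After six epochs of training, adding the network's predicted difference
(`DNC-vs-TNC`) cuts the error to ~5.8 HU and raises the rank correlation
above both physics baselines — the learning stage recovers the
anatomy-dependent discrepancy that pure physics cannot see. Longer
training (the study below) widens the margin.

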