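# deepRCB

Deep radiomics from segmentation-network bottlenecks for modeling residual
cancer burden (RCB) on breast DCE-MRI.

After neoadjuvant chemotherapy (NAC), the pathologist scores how much
invasive disease remains with the residual cancer burden index

    RCB = 1.4 (f_inv * d_prim)^0.17 + [4 (1 - 0.75^LN) d_met]^0.17

(invasive cellularity `f_inv`, tumor-bed diameter `d_prim` in mm, `LN`
positive nodes, largest nodal metastasis `d_met` in mm), with classes
RCB-0 (= pCR, score 0), RCB-I (0, 1.36], RCB-II (1.36, 3.28] and RCB-III
(> 3.28). `deepRCB` is for imaging researchers who want to test whether
the *bottleneck activations* of tumor-segmentation networks — "deep
features" extracted at the coarse voxels overlapping the tumor mask on
pre- and post-NAC dynamic contrast-enhanced MRI — predict this score, and
whether they add anything over clinical-radiological baselines (tumor
volume; volume + receptor subtype).

The package implements the full chain:

* **Preprocessing** — anterior-posterior landmark crop (10 mm anterior of
  the nipple to 50 mm posterior of the intermammary cleft), registration
  of post-contrast series to the pre-contrast volume (pluggable backend:
  FFT phase correlation by default, rigid mutual-information optimization
  optional), resampling to the cohort-median voxel spacing, and
  carry-forward of the last series to five post-contrast volumes.
* **Segmentation** — seeded constrained region growing for ground truth,
  and three desk-scale networks implemented natively (Rcpp kernels,
  hand-written backpropagation): a 3D U-Net, a 2D attention-gated U-Net
  and a 2D vector-quantized encoder-decoder, all exposing their bottleneck
  through one contract.
* **Deep features** — per-channel summary statistics (or codebook-usage
  histograms for the vector-quantized model) over mask-overlapping coarse
  voxels; pre-NAC, post-NAC and delta (pre − post) feature sets; a
  documented fallback for complete responders with empty masks.
* **Models** — variance filter (drop < 0.0005) → per-set PCA → random
  forest with 5-fold cross-validated hyperparameter search; volume and
  volume+subtype baselines; a nonnegative least-squares stacking ensemble
  with zero intercept whose weights report each model's contribution.
* **Statistics** — Spearman correlation, Mann-Whitney AUC for pCR and
  RCB-0/I endpoints, DeLong confidence intervals and paired tests,
  influence-function confidence intervals for cross-validated AUC,
  Kruskal-Wallis / chi-square / t / Mann-Whitney association and cohort
  comparisons.
* **Synthetic cohorts** — a generator of paired pre/post-NAC examinations
  with enhancing ellipsoidal tumors, per-subtype shrinkage, heterogeneous
  contrast uptake driven by a latent texture amplitude, and RCB outcomes
  produced through the pathology index, so the whole pipeline is testable
  end to end with no external data.

## Worked example

A complete six-model comparison on a 60-patient synthetic cohort:

```r
library(deepRCB)
cfg <- run_config(out_dir = file.path(tempdir(), "demo"), seed = 7,
                  synth = synthetic_config(n_patients = 60),
                  n_seg_train = 10, seg_epochs = 2)
res <- run_pipeline(cfg)
res$report[, c("model", "auc_pcr", "auc_rcb", "spearman_rcb")]
```

```
[simulate] 60 patients generated
[preprocess] 60 patients preprocessed, target spacing 2x2x2
[segment] unet3d trained on 10 exams, final loss 1.1
[segment] attn-unet2d trained on 10 exams, final loss 1.66
[segment] vqed2d trained on 10 exams, final loss 1.44
[extract] unet3d: 40 features/set, 15 components, 2 post-NAC fallbacks
[extract] attn-unet2d: 40 features/set, 19 components, 0 post-NAC fallbacks
[extract] vqed2d: 16 features/set, 3 components, 58 post-NAC fallbacks
[train] 5 base models fitted
[ensemble] weights: unet3d=0.000, attn-unet2d=0.245, vqed2d=0.000, volume-subtype=0.829
[evaluate] 18 held-out patients, 6 models

           model auc_pcr auc_rcb spearman_rcb
1         unet3d   0.556   0.679       0.4561
2    attn-unet2d   0.489   0.536       0.0817
3         vqed2d   0.356   0.402      -0.1894
4         volume   1.000   1.000       0.5784
5 volume-subtype   1.000   1.000       0.5580
6       ensemble   1.000   1.000       0.5574
```

On this default cohort the outcome is driven largely by residual volume,
so the volume baselines dominate and the nonnegative ensemble assigns most
of its weight to the clinical model — the AUC columns are the areas under
the ROC for predicting pCR and responder status (RCB-0/I) from the
predicted score (lower prediction = responder), and `spearman_rcb` is the
rank correlation between predicted and true RCB on the 18 held-out
patients. When the generator's latent texture amplitude drives the outcome
instead, the deep-feature models win; see the methods vignette
(`vignettes/deep-radiomics-rcb.Rmd`) for that positive control and every
modeling convention.

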