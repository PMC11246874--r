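# sarcoseg

Segmentation of soft-tissue sarcoma in multi-modal thigh MRI, end to end:
preprocessing of co-registered T1WI / T2WI / STIR volumes, a multi-encoder
U-Net with attention-weighted modality fusion, masking-based
self-supervised pretraining of the per-modality encoders, supervised
training with Adam and early stopping, and a segmentation evaluation suite
(accuracy, Dice, sensitivity, specificity, 95th-percentile Hausdorff
distance).  Because clinical sarcoma cohorts are small and rarely
shareable, the package includes a seeded synthetic phantom cohort
generator with exact ground truth, so the whole framework runs and is
tested fully offline.

The package is aimed at medical-image-analysis researchers who want a
self-contained, dependency-light reference implementation of this model
family in R: every network layer (im2col convolution, pooling, transposed
convolution, per-channel normalization, the attention gates, Adam) is
implemented in the package on BLAS matrix operations with hand-derived
backward passes — there is no deep-learning framework underneath.  The hot
kernels are compiled via Rcpp/RcppArmadillo.

## The model

Each modality slice (256 x 256, cropped around the clinical marker box
after 1 mm resampling and per-slice trimmed min–max normalization) is
encoded by its own 4-layer convolutional path (channels 64 → 512).  At
every resolution level the M = 3 per-modality feature maps are
channel-concatenated into F and fused by

    F_f = F_c + F_s

where the channel gate rescales channel k by
`sigmoid(W2 · relu(W1 · Z))_k`, with `Z_k` the global average of channel k
(squeeze-and-excitation style, reduction ratio 2), and the spatial gate
rescales position (i, j) by `sigmoid(p_ij + q_ij)` with `q = Ws * F` a
learned 1×1 projection and `p` the parameter-free channel-wise max.  The
fused maps feed a skip-connected decoder with a per-pixel softmax over
{background, tumor}.  Two baselines of the same backbone are included: a
single-encoder U-Net (`sunet`, modalities stacked as input channels) and a
concatenation-fusion multi-encoder U-Net (`munet`).

Before supervised training, each encoder can be pretrained on its own
modality with a masking pretext task: a 30×30 patch at the tumor boundary
is hidden, and the loss `(1 − cos(F, G)) + DiceLoss(prediction, truth)`
aligns the features of the clean (`F`) and corrupted (`G`) inputs through
one weight-shared encoder while the clean branch also learns to segment.

## Worked example

A miniature but complete run on a synthetic cohort (small native volumes;
the resampled layout is the standard 1 mm / 512-plane / 256-crop /
64-slice one):

```r
library(sarcoseg)

## 1. a seeded 3-subject phantom cohort on disk
pp  <- phantom_params(n_subjects = 3, volume_shape = c(10, 80, 80),
                      spacing = c(8, 3, 3), seed = 1)
coh <- generate_cohort(pp, "cohort")

## 2. preprocessing pipeline -> aligned manifest
man <- build_dataset(load_cohort(coh), "dataset")
nrow(man)                                  # 192 slice records (3 x 64)

## 3. patient-level 80/20 split
sp <- patient_split(man, 0.8, seed = 1)

## 4. train the attention-fusion model on a subset of training slices
sl  <- sarcoseg:::load_manifest_slices(sp$train[seq(1, 128, by = 16), ])
mod <- build_model(model_config("ours", base_channels = 16), seed = 1)
run <- train_on_slices(mod, sl$stacks, sl$masks, steps = 150,
                       learning_rate = 1e-3, batch_size = 1,
                       stop_dice = 0.95, seed = 1)

## 5. evaluate on the held-out patient
report <- evaluate_models(list(Ours = run$model),
                          sp$test[seq(1, 64, by = 8), ])
print(report)
```

Output of the final step from this exact script:

```
Segmentation results
 Model    Acc   Dice Sensitivity Specificity Hausdorff95
  Ours 0.9958 0.9216      0.9212      0.9982      2.2906
Aggregation: mean over test slices (undefined excluded); Hausdorff95 in mm
```

Reading: on the held-out phantom patient the model reaches 92% Dice
overlap with the rectangle ground truth, recovers 92% of tumor pixels
(sensitivity) and stays within about 2.3 mm at the 95th percentile of
boundary distance.  Phantom numbers characterize the pipeline and the
optimizer, not clinical accuracy.

`fit_segmenter()` runs the full epoch-based protocol (Adam at 1e-5, ≤100
epochs, patience-10 early stopping on a patient-level validation
carve-out) and returns a fitted-model object with `print`, `summary`,
`predict` and `plot` methods.  A thin command-line front end over the same
functions is installed at `inst/cli/sarcoseg`
(`sarcoseg synth | preprocess | split | pretrain | train | evaluate |
predict`).

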