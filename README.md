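# hicflow

Optical-flow forecasting of spatiotemporal Hi-C contact maps.

Developmental time courses of Hi-C (chromosome conformation capture) produce
one symmetric contact matrix per chromosome per timepoint, with entry
*(i, j)* counting contacts between 40-kb genomic bins *i* and *j*. `hicflow`
treats these matrices as frames of a video and forecasts the next three
frames from the last two observed ones. It is aimed at researchers studying
chromatin reorganization — embryogenesis, reprogramming, infection time
courses — who have a short Hi-C series and want a principled extrapolation
plus the evaluation machinery to judge it.

## The model

A prediction for frame *I*<sub>t+1</sub> is synthesized by **backward
warping**: two displacement fields *f*<sub>t+1→t−1</sub>, *f*<sub>t+1→t</sub>
resample the input frames, and a pixelwise mask *m* ∈ [0, 1] fuses them:

> Ĩ<sub>t+1</sub> = m ⊙ W(I<sub>t−1</sub>, f<sub>t+1→t−1</sub>) + (1 − m) ⊙ W(I<sub>t</sub>, f<sub>t+1→t</sub>)

Flow, mask and prediction are refined through a chain of nine **multi-scale
voxel flow blocks** (coarse-to-fine scale schedule 4,4,4,2,2,2,1,1,1), each
with a downscaled six-convolution PReLU motion path, a full-resolution
spatial path and a transposed-convolution head emitting residual flows. A
**routing module** converts the input pair into inclusion probabilities
w̃<sub>i</sub> = min{(n/2)·σ(ṽ<sub>i</sub>)/Σσ(ṽ<sub>j</sub>), 1} and gates
blocks by straight-through Bernoulli sampling, so the gate is discrete
forward and differentiable backward. Training minimizes the block-weighted
reconstruction loss

> L = Σ<sub>i</sub> 0.8<sup>n−i</sup> · d(Ĩ<sup>i</sup><sub>t+1</sub>, I<sub>t+1</sub>) (+ optional perceptual term)

with *d* the l1, MSE, or Laplacian-pyramid-l1 distance, under Adam with a
cosine-annealed learning rate (10⁻⁴ → 10⁻⁵, batch 8, 100 epochs by
default), and checkpoint selection weights validation concordance toward
later forecast horizons. Matrices are clipped at a cutoff, scaled to
[0, 1], forecast as 64×64 diagonal patches (stride 60) and evaluated on the
central 60×60 crops, which tile the diagonal gaplessly. The evaluation
suite implements random-walk graph concordance (t = 3), Pearson
correlation, PSNR, SSIM, interaction recovery rate, and cross-timestep
similarity matrices — all averaged over non-empty diagonal patches.

The network itself (convolutions, transposed convolutions, bilinear
warping/resizing, reverse-mode autodiff, Adam) is implemented in the
package with RcppArmadillo kernels; no deep-learning framework is required.

## Worked example

A synthetic cohort with known dynamics (TAD boundaries drifting one bin per
step, Poisson counts) stands in for a real time course:

```r
library(hicflow)
cohort <- simulate_cohort(n_chrom = 3, n_bins = 128, drift = 1,
                          noise = "poisson", seed = 42)
series <- lapply(cohort, `[[`, "series")
series$chr1
#> HiCTimeSeries chr1: 6 timepoints (t1, t2, t3, t4, t5, t6), 128 bins @ 40000 bp

cfg <- voxelflow_config(ch_spatial = 4, ch_motion = 8, cutoff = 100)
fit <- hicflow(series, val_chroms = "chr2", test_chroms = "chr3",
               model = cfg, loss = loss_config("l1"),
               epochs = 10, lr_init = 2e-2, lr_final = 2e-3, seed = 1)
fit
#> Hi-C voxel-flow forecaster
#>   9 MVFB blocks (scales 4,4,4,2,2,2,1,1,1), 64x64 patches, cutoff 100
#>   trained on 6 windows, 10 optimizer steps; final loss 0.18841
#>   selected checkpoint: epoch 8 (validation score 0.9234)

preds <- predict(fit, series$chr3$frames[2:3], horizon = 3)
preds[["t+1"]]
#> ContactMatrix chr3: 128 x 128 bins @ 40000 bp, start bin 0
#>   total contacts 2.454e+05, max 100, nonzero 52.9%

truth <- clip_normalize(series$chr3$frames[[4]], 100)
evaluate_matrices(clip_normalize(preds[["t+1"]], 100), truth)
#> MetricReport: 3 patches used, 0 skipped (window 60)
#> genomedisco         pcc        psnr        ssim
#>      0.9539      0.9874     25.2361      0.9873
evaluate_matrices(clip_normalize(series$chr3$frames[[3]], 100), truth)
#> MetricReport: 3 patches used, 0 skipped (window 60)
#> genomedisco         pcc        psnr        ssim
#>      0.9229      0.9506     19.1627      0.9498
```

Even this ten-step fit on a held-out chromosome-like unit clearly beats the
copy-last-frame (persistence) baseline shown last: the model has learned
the one-bin diagonal drift, which persistence by definition cannot follow.
Concordance, PCC and SSIM lie in [−1, 1] (1 = structurally identical);
PSNR is in decibels on the normalized scale (higher is better).

A command-line wrapper with `simulate` / `train` / `predict` / `evaluate`
subcommands is installed at `inst/cli/hicflow`:

```sh
Rscript inst/cli/hicflow simulate --out bench --n-bins 256 --seed 1
```

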