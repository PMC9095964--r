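# cinerecon

Joint groupwise registration and unrolled reconstruction of undersampled
dynamic (cine) MRI, for researchers studying motion-compensated
reconstruction at high acceleration factors.

Accelerated dynamic MRI undersamples each temporal frame's k-space far below
the Nyquist rate; the frames are redundant up to inter-frame (cardiac)
motion. `cinerecon` implements an end-to-end trainable unrolled cascade in
which every iteration couples

- a **groupwise diffeomorphic registration network** `F_θ`: the stack of
  frame magnitudes is mapped to stationary velocity fields `v_1…v_N`
  (centered so they sum to zero), integrated by scaling-and-squaring to
  invertible transforms `T_n`, `T_n⁻¹`, with the implicit template
  `X̄ = (1/N) Σ_n T_n ∘ X_n`;
- a **motion-augmented residual dealiasing network** `H_Φ`: each frame
  receives the template warped back to its anatomy with data consistency
  re-injecting the acquired lines, `G_n = DC(T_n⁻¹ ∘ X̄)`, and the 3D
  network predicts a residual correction
  `Z^k = H_Φ(G^{k-1}, G^0, X^{k-1}) + X^{k-1}`, followed by `X^k = DC(Z^k)`.

Training minimises `Σ_k e^{k-K} (L_rec^k + λ L_reg^k)` over both networks
jointly, with the registration loss

```
L_reg = (1/N) Σ ||X̄ − T_n∘X_n||² + (1/N) Σ ||X_n − T_n⁻¹∘X̄||² + α (1/N) Σ ||∇v_n||²
```

evaluated against the fully sampled ground truth (α = 0.05, λ = 1,
K = 4, Adam at 1e-4 halved every 20 epochs, on-the-fly Gaussian-density
Cartesian masks with 5 central lines at 8×/12×/16× — all defaults). The
pairwise-reference ablation (`reg_config(mode = "pairwise")`) and the
motion-free cascade (`recon_config(motion_mode = "none")`, the classic
dealiasing+DC network) are first-class configurations.

Because no deep-learning runtime exists for R in the target environment,
the package includes its own reverse-mode autodiff tape with compiled
RcppArmadillo kernels (conv2d/conv3d, pooling, transposed convolution,
differentiable bilinear warping, FFT/data-consistency layers); all backward
passes are verified against finite differences in the test suite. Training
runs on a single CPU at desk scale.

A synthetic dynamic phantom generator (`generate_sequence`) provides
complex-valued sequences with *known* ground-truth motion — a contracting
annulus on a textured background with smooth phase — standing in for the
(private) cardiac cine data; `build_dataset` writes reproducible
train/val/test splits.

## Worked example

```r
library(cinerecon)

# 10 training + 5 test phantoms (64x64, 8 frames, contracting annulus)
build_dataset(10, 0, 5, "phantoms", seed = 1)
train <- load_sequences("phantoms/train.rds")
test  <- load_sequences("phantoms/test.rds")

# small joint model: K = 2 unrolled iterations, 8x undersampling
model <- grd_model(8,
                   reg   = reg_config(channels = c(8, 16, 32, 16, 8)),
                   recon = recon_config(channels = c(8, 16, 32, 16, 8),
                                        iterations = 2),
                   seed = 1)
res <- train_model(train, train_config(accelerations = 8, epochs = 3,
                                       seed = 1), model = model)

# reconstruct one held-out sequence
s    <- test[[1]]$sequence
mask <- generate_mask(s$width, s$height, s$frame_count, 8, rng_seed = 99)
und  <- undersample(sequence_to_kspace(s), mask)
st   <- unrolled_forward(res$final_model, und, mask)

psnr(abs(s$frames), abs(attr(st, "x0")))        # zero-filled baseline
psnr(abs(s$frames), abs(st[[2]]$x))             # final iterate
r <- evaluate_registration(s, st[[2]]$velocities, mode = "groupwise")
r$psnr                                          # regenerated-sequence PSNR
```

`scripts/acceptance.R` runs this same pipeline end to end; for `--seed 1`
it prints

```
 sequence psnr_zero_filled psnr_recon ssim_recon psnr_registration
        1         19.82900   20.20480  0.6656420          17.49982
        2         19.35106   19.84180  0.6574506          18.23258
        3         19.58240   20.00552  0.6878647          17.59069
        4         20.39890   21.11438  0.7386279          18.82080
        5         20.10989   21.22206  0.6980698          19.25481
mean held-out PSNR: zero-filled 19.85 dB, reconstruction 20.48 dB
```

i.e. after a three-epoch demo training the cascade already recovers
~0.6 dB over zero-filling and reports the registration-protocol PSNR per
sequence. At the scale the test suite trains (50 phantoms, 6 epochs,
`tests/testthat/test-acceptance.R`), the same model reaches +4.3 dB over
zero-filling (24.3 vs 20.0 dB held-out mean) and beats its motion-free
ablation, and the trained registration scores 23.2 dB against 18.8 dB for
the zero-motion frame-average baseline.

PSNR here is `10·log10(peak²/MSE)` with the reference-sequence peak and the
MSE pooled over frames; higher is better, `Inf` means identical. SSIM is the
standard Gaussian-window structural similarity in [−1, 1].

## Command line

```sh
inst/cli/cinerecon simulate --out data --n-train 10 --n-test 5 --seed 1
inst/cli/cinerecon train --data data --out run --channels 8,16,32,16,8 \
    --iterations 2 --epochs 3 --accel 8 --seed 1
inst/cli/cinerecon reconstruct --input data/test.rds \
    --checkpoint run/checkpoint.rds --accel 8 --out rec --seed 1
inst/cli/cinerecon evaluate --pred rec/reconstructions.rds \
    --gt data/test.rds --out metrics.csv
```

Every run writes a `run_config.txt` snapshot (flags, seeds, timestamp) into
its output directory.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch — simulates a phantom
dataset, trains the scaled-down joint model at 8×, reconstructs held-out
sequences, and prints per-sequence zero-filled/reconstruction/registration
PSNR and SSIM — then writes the JSON report to `--out`.
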