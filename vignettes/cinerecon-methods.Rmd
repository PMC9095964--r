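---
title: "Joint groupwise registration and unrolled reconstruction of dynamic MRI: methods"
author: "cinerecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint groupwise registration and unrolled reconstruction of dynamic MRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dynamic (cine) MRI acquires a short movie — here a cardiac cycle of
\(N\) frames — but k-space sampling is slow, so clinically useful temporal
resolution requires undersampling each frame far below the Nyquist rate
(8–16 fold here). The resulting zero-filled reconstructions are heavily
aliased. The frames are, however, highly redundant: they show the same
anatomy deformed by (mostly cardiac) motion. If the inter-frame motion were
known, every frame's measurements could be pooled into every other frame;
estimating motion from aliased frames is in turn easier when the
reconstruction is better. `cinerecon` implements an unrolled architecture
that interleaves these two problems and trains them jointly, end to end.

## The model

### Groupwise diffeomorphic registration

All \(N\) frames are registered *at once* to an implicit template rather
than pairwise to a designated frame. A registration network \(F_\theta\)
maps the stack of frame magnitudes to \(N\) stationary velocity fields
\(v_n\). Each field is integrated over unit time by scaling and squaring
(7 halvings, then repeated self-composition) to a displacement \(T_n\), and
the negated field to its inverse \(T_n^{-1}\); this parameterisation keeps
the transforms diffeomorphic (smooth and invertible) by construction. The
implicit template is the mean of the forward-warped frames,

\[ \bar X = \frac1N \sum_n T_n \circ X_n , \]

and the velocities are centered (the mean field subtracted, so the fields
sum to zero pixelwise), which pins the template to the geometric center of
the group instead of biasing it toward any frame. The registration loss is

\[ L_{reg} = \frac1N \sum_n \lVert \bar X - T_n \circ X_n \rVert^2
   + \frac1N \sum_n \lVert X_n - T_n^{-1} \circ \bar X \rVert^2
   + \alpha \frac1N \sum_n \lVert \nabla v_n \rVert^2 . \]

In the pairwise ablation (`reg_config(mode = "pairwise")`), the reference is
the first (end-diastolic) frame, whose own velocity field is forced to zero,
and no centering is applied.

### Motion-augmented unrolled reconstruction

Iteration \(k\) of the cascade starts from the previous reconstruction
\(X^{k-1}\) (iteration 1 from the zero-filled \(X^0\)):

1. \(F_\theta\) predicts velocities from \(|X^{k-1}|\); transforms and the
   template follow as above.
2. The template is warped back to each frame and data consistency re-injects
   that frame's measurements: \(G_n = \mathrm{DC}(T_n^{-1} \circ \bar X)\).
   Each \(G_n\) thus fuses *all* frames' acquired data into frame \(n\)'s
   anatomy.
3. A residual 3D dealiasing network takes \(G^{k-1}\), the corresponding
   zero-filled-based \(G^0\), and \(X^{k-1}\) (real/imaginary parts as
   channels, frames as the third axis) and outputs
   \(Z^k = H_\Phi(\cdot) + X^{k-1}\).
4. \(X^k = \mathrm{DC}(Z^k)\), so every iterate agrees exactly with the
   acquired k-space on the sampled support.

Both networks share parameters across the \(K\) iterations. Training
minimises

\[ \sum_{k=1}^{K} e^{k-K}\left( L_{rec}^k + \lambda L_{reg}^k \right), \]

with \(L_{rec}^k\) the complex MSE of \(X^k\) against the fully sampled
ground truth and \(L_{reg}^k\) evaluated on the ground-truth magnitudes with
iteration \(k\)'s transforms — so the registration learns real motion even
though its inputs are aliased. The motion-free ablation
(`recon_config(motion_mode = "none")` with \(\lambda = 0\)) reduces to the
classic dealiasing + data-consistency cascade.

### Acquisition model

Cartesian undersampling: every phase-encode line is fully read along
frequency-encode; lines are drawn without replacement with probability
proportional to a zero-mean Gaussian over the offset from the central line
(\(\sigma = n_{pe}/6\) by default, configurable), the 5 central lines are
always sampled, and exactly `round(n_pe / R)` lines are kept per frame.
Masks are drawn independently per frame (`shared = TRUE` gives a common
mask). All Fourier operators are centered and orthonormal so the
data-consistency layer mixes spectra at a consistent scale.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `channels` | `c(32, 64, 128, 256, 128, 64, 32)` | convolution widths of both UNets; the list names the conv layers (encoder, bottleneck, decoder) |
| `iterations` (K) | 4 | unrolled iterations |
| `alpha` | 0.05 | velocity smoothness weight (per-pixel-mean norms make it resolution independent) |
| `lambda` | 1 | registration-loss weight in the composite loss |
| `integration_steps` | 7 | scaling-and-squaring halvings |
| `learning_rate` | 1e-4, halved every 20 epochs | Adam schedule |
| acceleration R | 8 / 12 / 16 | `round(n_pe/R)` sampled lines per frame |

## The synthetic phantom

No real cine data ships with the package (the reference dataset is
private), so `generate_sequence()` renders an analytic scene: a bright
annulus ("myocardium") around a mid-intensity disk ("blood pool") on a
piecewise-smooth textured background, deformed by *prescribed* stationary
velocity fields — a radial contraction localised on the annulus and a bulk
translation, both modulated sinusoidally over the cycle (hence cyclic, and
summing to zero across frames, i.e. centered by construction). Frame
\(n\) is the template resampled through the integrated negated field, so the
returned fields are exactly the frame-to-template velocities the
registration is asked to recover; warping frame \(n\) forward recovers the
template at better than 35 dB, which is what makes motion-recovery tests
meaningful. A smooth static low-order phase map makes the frames complex;
optional complex Gaussian noise is added last (default 0 — the reference
protocol's "fully sampled" references are themselves reconstructions, and a
noise-free stated world keeps the acceptance properties sharp; set
`noise_sd` for robustness experiments).

Defaults are desk-scale (64×64, 8 frames, 3 px contraction, 1 px
translation); 176×144 with 25 frames mirrors the reference acquisition
protocol. Scene edges use a 2.5 px smoothstep transition (`edge_width`):
partial-volume-like smoothing that keeps the scene band-limited enough for
bilinear resampling to close the warp loop at better than 35 dB — with
much sharper edges the loop-closure invariant itself becomes
interpolation-limited. What the phantom does **not** emulate: anatomical heterogeneity,
through-plane motion, coil sensitivities, off-resonance. A green test
therefore establishes correctness of the algorithmic machinery and the
direction of the method's benefits, not clinical performance.

## Numerical choices

- **Norms in the losses** are per-pixel means (the source formulation is
  ambiguous); this makes `alpha` and `lambda` independent of matrix size.
- **Warping** is backward-mapping bilinear interpolation with border
  replication (no zero leakage at edges); complex frames interpolate real
  and imaginary parts independently. The warp is exactly linear in the
  image.
- **Velocity-gradient penalty** uses forward differences, each direction
  normalised over its own valid positions, summed over the two components
  (a single linear ramp of slope *s* scores *s²*).
- **UNet layout**: one convolution per named width, max-pool ×2 between
  encoder stages, transposed convolution (kernel 2, stride 2) + skip
  concatenation in the decoder, leaky-ReLU (slope 0.01) everywhere except
  the final prediction layer, which is zero-initialised so the cascade
  starts as the identity map (identity motion, identity residual).
- **3D pooling is spatial-only**: the frame axis keeps full resolution
  (pooling it would forbid odd frame counts such as 25); temporal mixing
  happens through the (3,3,3) kernels.
- **Template phase**: the template is real (built from magnitudes); it is
  lifted to a zero-phase complex frame before data consistency, letting DC
  re-inject the measured phase on sampled lines
  (`template_phase = "previous"` borrows \(X^{k-1}\)'s phase instead,
  treated as fixed).
- **Autodiff**: no deep-learning runtime exists for R in this environment,
  so the package carries a small reverse-mode tape over R arrays with
  compiled (RcppArmadillo) kernels; every operator's backward pass is tested
  against central finite differences, and the composed cascade gradient is
  checked end to end. The 3D convolutions — the dominant cost — run their
  im2col/GEMM in float32 by default;
  `options(cinerecon.conv_precision = "double")` selects the exact
  reference path.
- **Determinism**: single-threaded tape + seeded mask/shuffle streams make
  training runs bit-reproducible for a fixed seed.

## Known limitations

Single-coil acquisition only (no sensitivity maps or parallel-imaging
extension); 2D+time (no 3D volumes); the frame count is a build-time
constant of the registration network (it sets channel counts); training at
the reference scale (K = 4, 32–256 channels, 25 frames, 60 epochs) is far
outside a 1-CPU budget — the package trains faithfully scaled-down models
and exposes every protocol parameter, but absolute reference-scale metrics
are not reproducible here (and the reference dataset is private regardless).
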