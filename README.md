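# endofog

Single-image defogging of endoscopic video frames by luminance blending,
with a physically based smoke simulator and reference-based quality
metrics.

## The problem

Electrosurgical smoke scatters the light source into the camera and
attenuates light from the tissue, washing out contrast exactly like
atmospheric fog. The observed frame follows the standard degradation
model

    I(x) = F(x) T(x) + A∞ (1 − T(x))

where `F` is the smoke-free radiance, `T ∈ (0,1]` the transmission and
`A∞` the airlight. `endofog` restores `F` from a single frame by fusing
two branches in BT.601 luminance space:

1. **Contrast enhancement** — re-expand the frame about its mean luma,
   `L = β (I − λ)`, which recovers visibility in dense smoke.
2. **Visibility restoration** — estimate the atmospheric veil
   `X = A∞(1 − T)` from windowed medians of the per-pixel minimum
   channel, invert the model `F = A∞ (I − X)/(A∞ − X)`, and denoise with
   a joint bilateral filter.

The branches are converted to studio-range YCbCr and blended per plane
with edge-aware illumination weights, then the fused luminance is
stretched onto `[15, 236]`. Quality is scored with SSIM `S`, a
statistical-naturalness score `N`, and the hybrid
`ψ = 0.6 S + 0.4 N`.

## Worked example

Simulate a heavy-smoke frame with known ground truth, defog it, and
score the result:

```r
library(endofog)

fx  <- simulate_smoke_frame(320, 240, preset = "heavy", seed = 7)
out <- defog_frame(fx$hazy)

ssim(fx$hazy,  fx$clean)   # 0.6480
ssim(out$frame, fx$clean)  # 0.8154

naturalness(fx$hazy)       # 0.0004
naturalness(out$frame)     # 0.2284

hybrid_quality(ssim(fx$hazy,  fx$clean), naturalness(fx$hazy))   # 0.3889
hybrid_quality(ssim(out$frame, fx$clean), naturalness(out$frame)) # 0.5806
```

Defogging lifts the hybrid score from 0.3889 to 0.5806 on this frame:
structure recovers from 0.648 to 0.815 and naturalness from near zero to
0.23. For batches, `defog_sequence()` defogs a list of frames with a
majority-voted smoke level and returns a quality report;
`evaluate_sequence()` scores any test/reference pair.

A command-line interface with `simulate`, `defog` and `evaluate`
subcommands is installed at
`system.file("cli", "endofog.R", package = "endofog")`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","endofog.R",package="endofog"))')" \
  defog --input hazy_frames/ --output defogged/
```

Known limitation: on *thin* smoke the hazy frame is already close to the
truth and veil subtraction can shift tissue colour, so defogging may not
improve fidelity there; see the methods vignette
(`vignettes/methods.Rmd`) for the full analysis and parameter rationale.

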