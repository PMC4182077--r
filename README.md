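# greysharp

Adaptive sharpening of 8-bit grayscale images — medical scans, SAR/aerial
imagery, fingerprints, natural photographs — for users who want edges made
conspicuous without saturating intensities or amplifying salt-and-pepper
noise, and who want the strength of the sharpening chosen from the image
itself rather than hand-tuned.

## The method

Three passes:

1. **Global budget.** A GM(1,1) Grey prediction model is fitted to the
   image's four global intensity statistics (Min, Mid, Max, Avg) through
   the difference relation *x⁽⁰⁾(k) + a z⁽¹⁾(k) = b* (closed-form least
   squares on the accumulated sequence), and the one-step white-response
   forecast *x⁽⁰⁾(5)* gives the maximal additive magnitude

   **Δ = |x⁽⁰⁾(5) − Avg|.**

   No pixel ever moves by more than *s·Δ*, which prevents over-sharpening.
2. **Edge selection.** The horizontal–vertical differencer flags pixel *x*
   when |x − x_W| ≥ θ_eth or |x − x_N| ≥ θ_eth (θ_eth typically 8–18); a
   low-pass count filter then keeps a flag only if at least θ_Lpf of the
   pixel's 8 neighbours are also flagged (default 3), discarding isolated
   salt-and-pepper detections.
3. **Adaptive adjustment.** Each surviving edge pixel moves away from the
   mean of its 3×3 neighbourhood by
   δ_x = s·Δ·x/LocalMean (if x < LocalMean) or s·Δ·LocalMean/x (otherwise),
   rounded and clamped to [0, 255]. Fainter local discontinuities get the
   larger boost. Non-edge pixels are copied through bit-exactly.

PSNR against the original, 10·log₁₀(255²/MSE), quantifies how much content
the sharpening preserved.

## Worked example

```r
library(greysharp)
img <- make_fixture("checkerboard", shape = c(64, 64),
                    levels = c(60, 180), block = 8)
res <- sharpen_image(img, sharpen_params(theta_eth = 14, s = 1))
summary(res)
#> Three-pass adaptive sharpening
#> sharpen_params: detector = hvd, theta_eth = 14, lpf = on (theta_lpf = 3), s = 1
#>   mid_mode = range-middle, gm_order = text
#> intensity stats: Min = 60, Mid = 120 (range-middle), Max = 180, Avg = 120
#>   Delta = 20.0000
#>   edge pixels: 245 of 4096 (5.98%), changed: 245
#>   PSNR vs input: 37.937 dB
```

Reading the numbers: the Grey forecast of the statistics sequence
(60, 120, 180, 120) lands 20 intensity levels from the mean, so no pixel
may move by more than 20; 245 pixels around the block boundaries were
flagged and adjusted; the 37.9 dB PSNR says the sharpened image stays
close to the original everywhere else (non-edge pixels are bit-identical).

`plot(res)` shows input, edge map and output side by side. The same
pipeline runs from the shell:

```sh
greysharp fixture --kind vstep --shape 64x64 --levels 50,150 --out step.pgm
greysharp sharpen step.pgm sharp.pgm --eth 18 --no-lpf --report \
          --save-edges edges.pgm --psnr-against step.pgm
```

Lower-level pieces are exported too: `gm11()` fits the Grey model on any
short sequence (with `coef`/`predict`/`fitted`/`residuals` methods),
`hvd_detect()` / `lowpass_filter()` / `detect_edges()` give the edge maps,
`psnr()` and `table1_report()` the quality grid, and `read_gray()` /
`write_gray()` handle PGM (P2/P5) and PNG.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the synthetic fixture set from the seed, runs the full
three-pass pipeline over a grid of detector configurations and scaling
factors s ∈ {0.5, 0.8, 1.0}, and prints the PSNR/Δ grid before writing the
JSON report to `--out`.
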