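---
title: "Adaptive image sharpening with Grey-prediction magnitude selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive image sharpening with Grey-prediction magnitude selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greysharp)
```

## The method

Sharpening highlights intensity discontinuities by pushing pixels near an
edge away from their local surroundings. Two decisions dominate the result:
*how much* to push (too much saturates intensities and destroys content)
and *which pixels* to push (naive differencing also fires on isolated noise
pixels). `greysharp` makes both decisions adaptively, in three passes.

### Pass 1 — the global budget Δ from a GM(1,1) Grey forecast

A GM(1,1) model is the first-order, single-variable Grey prediction model:
given a short sequence $x^{(0)}(1..n)$, its cumulative sums
$x^{(1)}(k)=\sum_{i\le k}x^{(0)}(i)$ form a smoother "generated" sequence,
and the model assumes the difference relation

$$x^{(0)}(k) + a\,z^{(1)}(k) = b, \qquad
  z^{(1)}(k) = \tfrac12\bigl(x^{(1)}(k-1)+x^{(1)}(k)\bigr),$$

whose two parameters — the developing coefficient $a$ and the Grey input
$b$ — are estimated by closed-form least squares over $k = 2..n$. Forecasts
come from the white response of the associated differential equation
$\mathrm{d}x^{(1)}/\mathrm{d}t + a x^{(1)} = b$,

$$x^{(1)}(k+1) = \Bigl(x^{(0)}(1)-\tfrac{b}{a}\Bigr)e^{-ak}+\tfrac{b}{a},$$

differenced back to the original scale. The appeal here is that GM(1,1)
extracts a trend from as few as four samples.

The four samples used are the image's global intensity statistics
(Min, Mid, Max, Avg). The one-step forecast $x^{(0)}(5)$ extrapolates the
trend of the intensity distribution, and the sharpening budget is

$$\Delta = \lvert x^{(0)}(5) - \mathrm{Avg}\rvert .$$

No pixel ever moves by more than $s\Delta$ ($s$ below), which is what
prevents over-sharpening: an image whose statistics are tightly clustered
gets a small budget, a wide-spread image a larger one.

```{r}
fit <- gm11(c(1, 2, 4, 8))
coef(fit)                       # a = -2/3, b = 2/3 (exact for this sequence)
predict(fit, n.ahead = 1)       # 2*exp(8/3) - 2*exp(2)
img <- make_fixture("vstep", shape = c(32, 32), levels = c(50, 150))
compute_delta(img)
```

### Pass 2 — edge selection with noise suppression

The horizontal–vertical differencer (HVD) flags pixel $x$ when
$\lvert x-x_W\rvert \ge \theta_{\mathrm{eth}}$ or
$\lvert x-x_N\rvert \ge \theta_{\mathrm{eth}}$, comparing only against the
west and north neighbours. It is cheap (at most two subtractions per
pixel) but also fires on isolated outliers, so a low-pass count filter
follows: a flagged pixel survives only if at least $\theta_{\mathrm{Lpf}}$
of its 8-connected neighbours are also flagged in the *pre-filter* map
(single pass, no cascading). Genuine edges form connected flag chains and
survive; salt-and-pepper detections form tiny clusters and do not.

```{r}
sp <- make_fixture("salt-pepper", shape = c(64, 64), density = 0.01, seed = 7)
sum(hvd_detect(sp, 18))                                    # detector fires
sum(detect_edges(sp, sharpen_params(theta_eth = 18)))      # filter cleans
```

### Pass 3 — local-mean-adaptive adjustment

For each surviving edge pixel, `LocalMean` is the mean of the pixel and
its existing 8-neighbours in the *original* image. The additive magnitude

$$\delta_x = \begin{cases}
 s\,\Delta\,(x/\mathrm{LocalMean}) & x < \mathrm{LocalMean}\\
 s\,\Delta\,(\mathrm{LocalMean}/x) & \text{otherwise}
\end{cases}$$

is subtracted when the pixel is darker than its local mean and added
otherwise, then the result is rounded and clamped to $[0,255]$. The ratio
term is the adaptation: the *smaller* the local discontinuity, the closer
the ratio is to 1 and the larger the boost, so faint edges are helped most
while strong edges are not blown out. Non-edge pixels are copied through
bit-exactly.

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `theta_eth` | edge threshold (intensity units) | 14 | useful range 8–18; per-image values in that range suit different content |
| `theta_lpf` | neighbour-count threshold (1–8) | 3 (HVD), 2 (Canny) | 3 matches the two-pixel-wide HVD response on ramped edges; one-pixel-wide detectors need 2 |
| `s` | scaling factor | 1.0 | in $[0,1]$; 0 is the identity |
| `mid_mode` | "middle intensity" policy | `range-middle` | see below |
| `gm_order` | sequence order policy | `text` | see below |
| `delta_override` | fixed Δ | off | bypasses pass 1, for controlled experiments |

## Design choices where the method statement is open

* **"Middle intensity"** is not a uniquely defined quantity. The default is
  the midrange $(\mathrm{Min}+\mathrm{Max})/2$; `mid_mode = "median"`
  selects the sample median instead (even counts: mean of the two central
  order statistics). Both are first-class and testable rather than one
  being silently chosen.
* **Sequence order.** The statistics are fed to the Grey model as
  (Min, Mid, Max, Avg) by default (`gm_order = "text"`, the order in which
  the method lists them); `"sorted"` gives (Min, Mid, Avg, Max), the
  monotone reading. Δ generally differs between the two.
* **$a \to 0$ degeneracy.** The white response divides by $a$; when
  $\lvert a\rvert < 10^{-12}$ the analytic limit
  $x^{(1)}(k+1)=x^{(0)}(1)+bk$ is used, so constant images yield exactly
  $\Delta = 0$ (no warning — the fit itself is fine). Only a truly
  degenerate fit (normal-equation denominator $(n-1)F-C^2$ below
  $10^{-12}\max(1,F)$, e.g. an all-zero image) raises a condition that
  `compute_delta()` converts to $\Delta=0$ with a warning.
* **Borders.** A missing west/north neighbour cannot trigger a detection;
  the neighbour count and the local mean use existing cells only and the
  thresholds are not rescaled, which slightly biases against border edges.
* **$x = \mathrm{LocalMean}$** falls on the "otherwise" branch, so the full
  $s\Delta$ is *added*. This is the literal reading of the two-branch rule
  and consistent with its stated direction of adaptation (largest boost at
  zero local contrast), but it is surprising on near-flat flagged pixels —
  documented rather than patched.
* **Rounding.** All arithmetic is real-valued; a single
  half-away-from-zero rounding is applied at output, then clamping. Δ is
  never rounded on its way through the pipeline, avoiding double-rounding
  bias.
* **Double buffering.** $x$ and LocalMean are always read from the input
  image, making the result independent of traversal order and bit-wise
  deterministic.
* **Canny.** The comparison detector is a stock external operator, so it
  is a plugin hook (`canny_fun`), not a reimplementation; requesting it
  without a plugin is a feature-unavailable error, and its `theta_lpf`
  default is 2.

## What the synthetic fixtures emulate — and what they do not

`make_fixture()` generates the structures the method targets: ideal step
discontinuities (`vstep`/`hstep`), smooth gradients (`ramp`,
`smooth-field`), flat fields (`constant`), block patterns
(`checkerboard`), and sparse isolated outliers (`salt-pepper`). Outlier
placement enforces a Chebyshev separation of at least 3 between outliers:
each outlier's HVD response is a small cluster (itself plus its east and
south neighbours), and separation 3 guarantees clusters from distinct
outliers never touch, so every flagged pixel has at most two flagged
neighbours and the $\theta_{\mathrm{Lpf}}=3$ filter removes all of them.
Mere non-adjacency would *not* guarantee this (two outliers two columns
apart produce a flagged pixel with four flagged neighbours).

Two behaviours of ideal fixtures are worth knowing. On a perfect step the
HVD response is exactly one pixel wide (only the high side of the jump is
flagged), so the $\theta_{\mathrm{Lpf}}=3$ filter removes the whole line —
the two-pixel-wide response that motivates the default occurs on the
ramped edges of real images, not on ideal steps. Step-fixture experiments
that need surviving edges therefore disable the filter or use
$\theta_{\mathrm{Lpf}}=2$. Similarly, on a checkerboard only boundary
pixels near line intersections have three or more flagged neighbours, so
the filtered map keeps crosses at the corners, not full boundary lines.

Real photographs differ from these fixtures in having textured regions,
ramped (multi-pixel) edges and correlated noise; a green test on fixtures
establishes the algebra of the passes exactly, but says nothing about
perceptual quality on natural images, which is why PSNR reporting against
the original is part of the package.

## Quality evaluation

`psnr()` uses the standard 8-bit definition
$10\log_{10}(255^2/\mathrm{MSE})$ (the only definition consistent with the
published dB magnitudes for this method), with $+\infty$ for identical
images. `table1_report()` sweeps images × configurations ×
$s \in \{0.5, 0.8, 1.0\}$ and reports PSNR, MSE and Δ per cell; on a fixed
edge map PSNR decreases as $s$ grows.

```{r}
step <- make_fixture("vstep", shape = c(32, 32), levels = c(50, 150))
cfg <- sharpen_params(theta_eth = 18, lpf_enabled = FALSE)
tab <- table1_report(list(step = step), list(cfg))
tab[, c("image", "s", "psnr_db", "delta", "edge_pixels")]
```

## Known limitations

* Only 8-bit grayscale is supported (no 16-bit, color, TIFF or DICOM).
* Δ reproduces published per-image values only when the exact image file,
  the Mid policy and the sequence order match the original experiments;
  both policies are exposed for that reason.
* The low-pass filter's literal one-pass reading removes one-pixel-wide
  edges entirely (see above); users sharpening synthetic or rasterised
  line art should lower `theta_lpf` or disable the filter.
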