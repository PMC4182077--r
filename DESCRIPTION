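Package: greysharp
Title: Adaptive Image Sharpening with Grey-Prediction Magnitude Selection
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Three-step adaptive sharpening of 8-bit grayscale images. A
    GM(1,1) Grey prediction model fitted to the image's global intensity
    statistics (Min, Mid, Max, Avg) selects a maximal additive magnitude;
    a horizontal-vertical differencing edge detector combined with an
    isolated-pixel low-pass filter selects the pixels around edges; and a
    local-mean-adaptive rule sharpens only those pixels, leaving the rest
    of the image bit-exact. Includes PGM (P2/P5) and optional PNG readers
    and writers, a deterministic synthetic-fixture generator, and PSNR
    reporting for quantifying how much image content the sharpening
    preserves.
License: MIT
Encoding: UTF-8
Imports: stats, grDevices, graphics, utils
Suggests: testthat (>= 3.0.0), png, jsonlite, withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
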