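#' Peak signal-to-noise ratio between two 8-bit images
#'
#' The standard 8-bit definition 10 * log10(255^2 / MSE) with MSE the mean
#' squared pixel difference over the whole image. Identical images give
#' +Inf. Symmetric in its arguments; used here to quantify how much of the
#' original content a sharpened image preserves (higher = closer).
#'
#' @param reference,test numeric matrices of identical shape.
#' @return PSNR in decibels (scalar; `Inf` when the images are identical).
#' @examples
#' a <- matrix(100, 4, 4); b <- matrix(105, 4, 4)
#' psnr(a, b)  # 10*log10(255^2/25) ~ 34.15 dB
#' @export
psnr <- function(reference, test) {
  assert_image(reference, "reference")
  assert_image(test, "test")
  if (!identical(dim(reference), dim(test))) {
    stop_greysharp("images must have identical shapes",
                   "greysharp_invalid_input")
  }
  mse <- mean((as.numeric(reference) - as.numeric(test))^2)
  if (mse == 0) Inf else 10 * log10(255^2 / mse)
}

#' PSNR grid report over images and configurations
#'
#' Runs [sharpen_image()] for every combination of image, parameter
#' configuration and scaling factor, and returns the PSNR of each sharpened
#' result against its original — the layout of the method's published
#' comparison table (detector / low-pass combinations across s in
#' {0.5, 0.8, 1.0}, plus the per-image Delta). A cell whose pipeline fails
#' is reported as NA with a warning and the run continues.
#'
#' @param images named list of image matrices (names label the rows).
#' @param configs list of [sharpen_params()] objects; the `s` in each is
#'   replaced by the values of `s`.
#' @param s scaling factors to sweep (default the published 0.5, 0.8, 1.0).
#' @return data frame with one row per (image, config, s): columns `image`,
#'   `detector`, `lpf`, `theta_eth`, `theta_lpf`, `s`, `psnr_db`, `mse`,
#'   `delta`, `edge_pixels`.
#' @export
table1_report <- function(images, configs, s = c(0.5, 0.8, 1.0)) {
  if (!is.list(images) || length(images) == 0L) {
    stop_greysharp("'images' must be a non-empty list of matrices",
                   "greysharp_invalid_input")
  }
  if (!is.list(configs) || length(configs) == 0L) {
    stop_greysharp("'configs' must be a non-empty list of sharpen_params",
                   "greysharp_invalid_input")
  }
  if (is.null(names(images))) names(images) <- paste0("image", seq_along(images))
  rows <- list()
  for (nm in names(images)) {
    for (cfg in configs) {
      stopifnot(inherits(cfg, "sharpen_params"))
      for (si in s) {
        cfg_s <- cfg; cfg_s$s <- si
        cell <- tryCatch({
          res <- sharpen_image(images[[nm]], cfg_s)
          p <- psnr(images[[nm]], res$image)
          list(psnr = p,
               mse = mean((as.numeric(images[[nm]]) - as.numeric(res$image))^2),
               delta = res$delta, edges = res$edge_pixel_count)
        }, error = function(e) {
          warning(sprintf("cell (%s, %s, s=%g) failed: %s",
                          nm, cfg$detector, si, conditionMessage(e)),
                  call. = FALSE)
          list(psnr = NA_real_, mse = NA_real_, delta = NA_real_,
               edges = NA_integer_)
        })
        rows[[length(rows) + 1L]] <- data.frame(
          image = nm, detector = cfg$detector, lpf = cfg$lpf_enabled,
          theta_eth = cfg$theta_eth, theta_lpf = cfg$theta_lpf, s = si,
          psnr_db = cell$psnr, mse = cell$mse, delta = cell$delta,
          edge_pixels = cell$edges, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
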