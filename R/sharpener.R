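#' Parameters of the sharpening pipeline
#'
#' Collects and validates every tunable of the three-pass algorithm.
#'
#' @param theta_eth HVD intensity threshold; 8-18 is the useful range for
#'   8-bit images, default 14.
#' @param theta_lpf low-pass count threshold in 1..8; defaults to 3 for the
#'   HVD detector (two-pixel-wide edges) and 2 for Canny (one-pixel-wide).
#' @param s scaling factor in [0, 1] multiplying the additive magnitude;
#'   s = 0 leaves the image untouched, s = 1 applies the full Delta budget.
#' @param detector `"hvd"` or `"canny"`.
#' @param lpf_enabled apply the isolated-pixel filter (default TRUE).
#' @param mid_mode,gm_order policies resolving the "middle intensity" and
#'   sequence-order ambiguities; see [intensity_stats()] and
#'   [delta_from_stats()].
#' @param delta_override optional fixed Delta (>= 0) bypassing the Grey
#'   model, mainly for testing and controlled experiments.
#' @param canny_fun optional plugin function `(img, params) -> 0/1 matrix`
#'   implementing Canny detection; required when `detector = "canny"`.
#' @return an object of class `"sharpen_params"`.
#' @export
sharpen_params <- function(theta_eth = 14,
                           theta_lpf = NULL,
                           s = 1,
                           detector = c("hvd", "canny"),
                           lpf_enabled = TRUE,
                           mid_mode = c("range-middle", "median"),
                           gm_order = c("text", "sorted"),
                           delta_override = NULL,
                           canny_fun = NULL) {
  detector <- match.arg(detector)
  mid_mode <- match.arg(mid_mode)
  gm_order <- match.arg(gm_order)
  if (is.null(theta_lpf)) theta_lpf <- if (detector == "canny") 2L else 3L
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s > 1) {
    stop_greysharp("'s' must be a scalar in [0, 1]",
                   "greysharp_invalid_parameter")
  }
  if (!is.numeric(theta_eth) || length(theta_eth) != 1L || theta_eth <= 0) {
    stop_greysharp("'theta_eth' must be positive",
                   "greysharp_invalid_parameter")
  }
  if (!is.numeric(theta_lpf) || length(theta_lpf) != 1L ||
      theta_lpf < 1 || theta_lpf > 8) {
    stop_greysharp("'theta_lpf' must be in [1, 8]",
                   "greysharp_invalid_parameter")
  }
  if (!is.null(delta_override) &&
      (!is.numeric(delta_override) || delta_override < 0)) {
    stop_greysharp("'delta_override' must be >= 0",
                   "greysharp_invalid_parameter")
  }
  if (!is.null(canny_fun) && !is.function(canny_fun)) {
    stop_greysharp("'canny_fun' must be a function",
                   "greysharp_invalid_parameter")
  }
  structure(list(theta_eth = theta_eth, theta_lpf = as.integer(theta_lpf),
                 s = s, detector = detector, lpf_enabled = isTRUE(lpf_enabled),
                 mid_mode = mid_mode, gm_order = gm_order,
                 delta_override = delta_override, canny_fun = canny_fun),
            class = "sharpen_params")
}

#' @export
print.sharpen_params <- function(x, ...) {
  cat(sprintf(
    "sharpen_params: detector = %s, theta_eth = %g, lpf = %s (theta_lpf = %d), s = %g\n",
    x$detector, x$theta_eth, if (x$lpf_enabled) "on" else "off",
    x$theta_lpf, x$s))
  cat(sprintf("  mid_mode = %s, gm_order = %s%s\n", x$mid_mode, x$gm_order,
              if (!is.null(x$delta_override))
                sprintf(", delta_override = %g", x$delta_override) else ""))
  invisible(x)
}

# local mean of every pixel at once: 3x3 window sum over existing cells,
# centre included, divided by the number of existing cells
local_mean_matrix <- function(img) {
  window_sum3(img) / window_count3(nrow(img), ncol(img))
}

#' Local mean around a pixel
#'
#' Arithmetic mean of a pixel and its existing 8-connected neighbours
#' (9 terms in the interior, 6 along borders, 4 at corners), always read
#' from the original image. Determines the sharpening direction and the
#' adaptive magnitude.
#'
#' @param img numeric matrix.
#' @param r,c 1-based row and column of the pixel.
#' @return the local mean (scalar).
#' @export
local_mean <- function(img, r, c) {
  assert_image(img)
  if (r < 1 || r > nrow(img) || c < 1 || c > ncol(img)) {
    stop_greysharp("pixel coordinates out of bounds",
                   "greysharp_invalid_input")
  }
  rows <- max(1L, r - 1L):min(nrow(img), r + 1L)
  cols <- max(1L, c - 1L):min(ncol(img), c + 1L)
  mean(img[rows, cols])
}

#' Adaptive additive magnitude for one pixel
#'
#' The fraction of the global budget Delta applied to a pixel:
#' `s * delta * x / local_mean` when the pixel is darker than its local
#' mean, `s * delta * local_mean / x` otherwise. The ratio is always in
#' [0, 1], so the result lies in [0, s * delta]; the closer the pixel is to
#' its local mean (the fainter the discontinuity) the larger the boost.
#' The degenerate 0/0 case (x = local_mean = 0) yields 0. Vectorised.
#'
#' @param x pixel intensity (or vector of intensities).
#' @param local_mean local mean(s) from [local_mean()].
#' @param s scaling factor in [0, 1].
#' @param delta global maximal additive magnitude (>= 0).
#' @return additive magnitude(s), same length as `x`.
#' @export
additive_magnitude <- function(x, local_mean, s, delta) {
  ratio <- ifelse(x < local_mean, x / local_mean, local_mean / x)
  ratio[x == 0 & local_mean == 0] <- 0
  s * delta * ratio
}

#' Sharpen a single intensity value
#'
#' Moves the pixel away from its local mean by `delta_x` (subtracted when
#' darker than the local mean, added otherwise), rounds half away from
#' zero, and clamps to [0, 255]. Vectorised.
#'
#' @param x pixel intensity (or vector).
#' @param local_mean local mean(s).
#' @param delta_x additive magnitude(s) from [additive_magnitude()].
#' @return sharpened integer intensity in [0, 255].
#' @export
sharpen_pixel <- function(x, local_mean, delta_x) {
  xhat <- ifelse(x < local_mean, x - delta_x, x + delta_x)
  as.integer(clamp255(round_half_away(xhat)))
}

#' Sharpen an 8-bit grayscale image
#'
#' Runs the full three-pass pipeline. Pass 1 derives the maximal additive
#' magnitude Delta from the GM(1,1) Grey forecast of the image's global
#' intensity statistics (unless `delta_override` fixes it). Pass 2 computes
#' the final edge map with [detect_edges()]. Pass 3 adjusts every edge
#' pixel away from its 3x3 local mean by [additive_magnitude()], reading
#' both the pixel and its local mean from the unmodified input
#' (double-buffered, so the result is independent of traversal order);
#' every non-edge pixel is copied through bit-exactly.
#'
#' A pixel exactly at its local mean falls on the "otherwise" branch: the
#' full `s * Delta` is added. This is the literal reading of the adaptive
#' rule — the additive magnitude grows as the local discontinuity shrinks —
#' and is worth knowing about when sharpening near-flat regions.
#'
#' @param img numeric matrix with intensities in [0, 255].
#' @param params a [sharpen_params()] object.
#' @return an object of class `"sharpen_result"`: list with `image`
#'   (sharpened integer matrix), `edge_map`, `delta`, `stats`
#'   (the [intensity_stats()]), `changed_pixel_count`, `edge_pixel_count`,
#'   `params`, and `input`.
#' @examples
#' img <- make_fixture("vstep", shape = c(16, 16), levels = c(50, 150))
#' res <- sharpen_image(img, sharpen_params(theta_eth = 18, s = 1))
#' res
#' @export
sharpen_image <- function(img, params = sharpen_params()) {
  assert_image(img)
  stopifnot(inherits(params, "sharpen_params"))
  if (min(img) < 0 || max(img) > 255) {
    stop_greysharp("image intensities must lie in [0, 255]",
                   "greysharp_invalid_input")
  }
  stats <- intensity_stats(img, params$mid_mode)
  delta <- if (!is.null(params$delta_override)) params$delta_override
           else delta_from_stats(stats, params$gm_order)
  edges <- detect_edges(img, params)

  out <- matrix(as.integer(round_half_away(img)), nrow(img), ncol(img))
  idx <- which(edges == 1L)
  if (length(idx) > 0L && params$s > 0 && delta > 0) {
    lm <- local_mean_matrix(img)
    dx <- additive_magnitude(img[idx], lm[idx], params$s, delta)
    out[idx] <- sharpen_pixel(img[idx], lm[idx], dx)
  } else if (length(idx) > 0L) {
    # s = 0 or Delta = 0: edge pixels still pass through the (identity)
    # adjustment, i.e. they are rounded like everything else
    out[idx] <- as.integer(clamp255(round_half_away(img[idx])))
  }
  structure(list(image = out,
                 edge_map = edges,
                 delta = delta,
                 stats = stats,
                 edge_pixel_count = length(idx),
                 changed_pixel_count = sum(out != img),
                 params = params,
                 input = img),
            class = "sharpen_result")
}

#' @export
print.sharpen_result <- function(x, ...) {
  cat(sprintf("sharpened %d x %d image (%s detector)\n",
              nrow(x$image), ncol(x$image), x$params$detector))
  cat(sprintf("  Delta = %.4f, s = %g, edge pixels = %d, changed pixels = %d\n",
              x$delta, x$params$s, x$edge_pixel_count, x$changed_pixel_count))
  invisible(x)
}

#' @export
summary.sharpen_result <- function(object, ...) {
  p <- psnr(object$input, object$image)
  cat("Three-pass adaptive sharpening\n")
  print(object$params)
  print(object$stats)
  cat(sprintf("  Delta = %.4f\n", object$delta))
  cat(sprintf("  edge pixels: %d of %d (%.2f%%), changed: %d\n",
              object$edge_pixel_count, length(object$input),
              100 * object$edge_pixel_count / length(object$input),
              object$changed_pixel_count))
  cat(sprintf("  PSNR vs input: %s dB\n",
              if (is.infinite(p)) "Inf" else sprintf("%.3f", p)))
  invisible(object)
}

#' Display input, edge map and sharpened output side by side
#'
#' @param x a `"sharpen_result"`.
#' @param ... unused.
#' @export
plot.sharpen_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  draw <- function(m, main, maxv = 255) {
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = ncol(m) / nrow(m))
    graphics::rasterImage(grDevices::as.raster(m / maxv), 0, 0, 1, 1)
    graphics::title(main)
  }
  draw(x$input, "input")
  draw(x$edge_map, "edge map", maxv = 1)
  draw(x$image, "sharpened")
  invisible(x)
}
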