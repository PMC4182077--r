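#' Horizontal-vertical differencing (HVD) edge detection
#'
#' Flags a pixel as "around an edge" when the absolute intensity difference
#' to its west neighbour (same row, previous column) or to its north
#' neighbour (previous row, same column) meets or exceeds `theta_eth`.
#' Pixels in the first row have no north neighbour and pixels in the first
#' column no west neighbour; a missing neighbour cannot trigger a
#' detection. Values of `theta_eth` between 8 and 18 suit typical 8-bit
#' images: lower values flag fainter discontinuities.
#'
#' @param img numeric matrix of intensities.
#' @param theta_eth positive intensity threshold.
#' @return integer 0/1 matrix of the same shape (1 = edge pixel).
#' @seealso [lowpass_filter()] to remove isolated detections,
#'   [detect_edges()] for the combined step.
#' @export
hvd_detect <- function(img, theta_eth) {
  assert_image(img)
  if (!is.numeric(theta_eth) || length(theta_eth) != 1L || theta_eth <= 0) {
    stop_greysharp("'theta_eth' must be a positive number",
                   "greysharp_invalid_parameter")
  }
  H <- nrow(img); W <- ncol(img)
  g <- matrix(0L, H, W)
  if (W > 1L) {
    west <- abs(img[, -1L, drop = FALSE] - img[, -W, drop = FALSE]) >= theta_eth
    g[, -1L] <- g[, -1L] | west
  }
  if (H > 1L) {
    north <- abs(img[-1L, , drop = FALSE] - img[-H, , drop = FALSE]) >= theta_eth
    g[-1L, ] <- g[-1L, ] | north
  }
  mode(g) <- "integer"
  g
}

# sum over the 3x3 window (existing cells only, centre included) at every
# pixel, via a zero-padded shift-and-add; shared by the low-pass filter and
# the local mean.
window_sum3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- m
  s <- matrix(0, H, W)
  for (dr in 0:2) for (dc in 0:2) {
    s <- s + p[dr + seq_len(H), dc + seq_len(W), drop = FALSE]
  }
  s
}

# number of existing cells in each pixel's 3x3 window (centre included):
# 9 interior, 6 on borders, 4 at corners
window_count3 <- function(H, W) {
  rc <- ifelse(seq_len(H) %in% c(1L, H) & H > 1L, 2L, 3L)
  cc <- ifelse(seq_len(W) %in% c(1L, W) & W > 1L, 2L, 3L)
  if (H == 1L) rc[] <- 1L
  if (W == 1L) cc[] <- 1L
  outer(rc, cc)
}

#' Isolated-pixel low-pass filter on an edge map
#'
#' A pixel keeps its edge flag only if at least `theta_lpf` of its
#' 8-connected neighbours are also flagged in the input map; otherwise it
#' is regarded as an isolated point (salt-and-pepper noise) and discarded.
#' Non-edge pixels stay 0, so the output is always a subset of the input.
#' The filter is a single pass over the input map: removals do not cascade.
#' At borders only existing neighbours are counted and the threshold is not
#' rescaled, which slightly biases against border edges.
#'
#' The default `theta_lpf = 3` matches the two-pixel-wide responses of the
#' HVD detector; with a one-pixel-wide detector such as Canny a value of 2
#' is appropriate.
#'
#' @param edges integer 0/1 matrix from an edge detector.
#' @param theta_lpf integer count threshold in 1..8.
#' @return integer 0/1 matrix, subset of `edges`.
#' @export
lowpass_filter <- function(edges, theta_lpf = 3L) {
  assert_image(edges, "edges")
  if (!all(edges %in% c(0L, 1L))) {
    stop_greysharp("'edges' must be a bi-level 0/1 matrix",
                   "greysharp_invalid_input")
  }
  if (!is.numeric(theta_lpf) || length(theta_lpf) != 1L ||
      theta_lpf < 1 || theta_lpf > 8) {
    stop_greysharp("'theta_lpf' must be in [1, 8]",
                   "greysharp_invalid_parameter")
  }
  n8 <- window_sum3(edges) - edges   # neighbour count excludes the centre
  out <- edges
  out[n8 < theta_lpf] <- 0L
  mode(out) <- "integer"
  out
}

#' Detect edge pixels for the sharpening pass
#'
#' Dispatches to the HVD detector or a user-supplied Canny plugin, then
#' applies the isolated-pixel low-pass filter when enabled in `params`.
#' This is pass 2 of the pipeline; the returned bi-level map decides which
#' pixels [sharpen_image()] adjusts.
#'
#' No Canny implementation is bundled (it is a stock external operator);
#' to use one, supply a function of `(img, params)` returning a 0/1 matrix
#' as `canny_fun` in [sharpen_params()]. Requesting Canny without a plugin
#' raises a feature-unavailable error.
#'
#' @param img numeric matrix of intensities.
#' @param params a [sharpen_params()] object.
#' @return integer 0/1 matrix, the final edge map.
#' @examples
#' img <- make_fixture("vstep", shape = c(8, 8), levels = c(50, 150))
#' detect_edges(img, sharpen_params(theta_eth = 18))
#' @export
detect_edges <- function(img, params = sharpen_params()) {
  assert_image(img)
  stopifnot(inherits(params, "sharpen_params"))
  g <- switch(params$detector,
    hvd   = hvd_detect(img, params$theta_eth),
    canny = {
      if (is.null(params$canny_fun)) {
        stop_greysharp(
          "Canny detection requires a plugin: supply 'canny_fun' in sharpen_params()",
          "greysharp_feature_unavailable")
      }
      g <- params$canny_fun(img, params)
      assert_image(g, "canny edge map")
      if (!identical(dim(g), dim(img)) || !all(g %in% c(0, 1))) {
        stop_greysharp("Canny plugin must return a 0/1 matrix of the image shape",
                       "greysharp_invalid_input")
      }
      mode(g) <- "integer"
      g
    })
  if (isTRUE(params$lpf_enabled)) g <- lowpass_filter(g, params$theta_lpf)
  g
}
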