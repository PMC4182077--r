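#' Accumulated generating operation (AGO)
#'
#' The AGO turns an irregular short sequence into a monotone "Grey generated"
#' sequence by cumulative summation; it is the first step of GM(1,1)
#' modelling. Element k of the result is the sum of the first k input
#' samples.
#'
#' @param x numeric vector, the original sequence x0 (length >= 1).
#' @return numeric vector of the same length, the accumulated sequence x1.
#' @seealso [iago()] for the inverse, [gm11()] for the model fit.
#' @examples
#' ago(c(1, 2, 4, 8))   # 1 3 7 15
#' @export
ago <- function(x) {
  check_sequence(x, min_n = 1L)
  cumsum(x)
}

#' Inverse accumulated generating operation (IAGO)
#'
#' First difference with the first element preserved; exact inverse of
#' [ago()]. Used to map forecasts of the accumulated sequence back to the
#' original scale.
#'
#' @param x numeric vector, an accumulated sequence (length >= 1).
#' @return numeric vector of the same length.
#' @examples
#' iago(c(1, 3, 7, 15))  # 1 2 4 8
#' @export
iago <- function(x) {
  check_sequence(x, min_n = 1L)
  c(x[1L], diff(x))
}

#' Adjacent-mean sequence of an accumulated sequence
#'
#' Pairwise means z1(k) = (x1(k) + x1(k+1)) / 2 of consecutive accumulated
#' values; the background values against which GM(1,1) regresses the
#' original samples.
#'
#' @param x1 numeric vector, an accumulated sequence (length >= 2).
#' @return numeric vector of length `length(x1) - 1`.
#' @export
mean_sequence <- function(x1) {
  check_sequence(x1, min_n = 2L)
  (x1[-length(x1)] + x1[-1L]) / 2
}

check_sequence <- function(x, min_n) {
  if (!is.numeric(x) || length(x) < min_n || anyNA(x) || any(!is.finite(x))) {
    stop_greysharp(
      sprintf("sequence must be finite numeric of length >= %d", min_n),
      "greysharp_invalid_input")
  }
  invisible(x)
}

#' Fit a GM(1,1) Grey prediction model
#'
#' Fits the first-order single-variable Grey model to a short sequence.
#' The original samples x0(k) are regressed on the adjacent means z1(k) of
#' the accumulated sequence through the Grey difference equation
#' x0(k) + a * z1(k) = b for k = 2..n, solved in closed form by least
#' squares. `a` is the developing coefficient (the exponential trend rate),
#' `b` the Grey input. Forecasts come from the white response
#' x1(k+1) = (x0(1) - b/a) * exp(-a k) + b/a, differenced back to the
#' original scale.
#'
#' A sequence on which the difference equation has no unique solution
#' (the normal-equation denominator (n-1) F - C^2 vanishes, e.g. a constant
#' accumulated spacing of zero) raises a degenerate-model error with
#' condition class `greysharp_degenerate_model`.
#'
#' @param x numeric vector of at least 3 finite samples; 4 in the image
#'   application (Min, Mid, Max, Avg).
#' @return an object of class `"gm11"`: a list with elements `a`, `b`,
#'   `x0_1` (first sample), `n`, and the data `x0`.
#' @examples
#' fit <- gm11(c(1, 2, 4, 8))
#' coef(fit)                 # a = -2/3, b = 2/3
#' predict(fit, n.ahead = 1) # one-step forecast of the original sequence
#' @export
gm11 <- function(x) {
  check_sequence(x, min_n = 3L)
  n  <- length(x)
  x1 <- cumsum(x)
  z1 <- mean_sequence(x1)        # z1(k) for k = 2..n
  xk <- x[-1L]                   # x0(k) for k = 2..n
  C <- sum(z1)
  D <- sum(xk)
  E <- sum(z1 * xk)
  F <- sum(z1^2)
  den <- (n - 1) * F - C^2
  if (abs(den) < 1e-12 * max(1, F)) {
    stop_greysharp("GM(1,1) normal equations are degenerate for this sequence",
                   "greysharp_degenerate_model")
  }
  a <- (C * D - (n - 1) * E) / den
  b <- (D * F - C * E) / den
  structure(list(a = a, b = b, x0_1 = x[1L], n = n, x0 = x),
            class = "gm11")
}

#' @export
print.gm11 <- function(x, digits = max(4L, getOption("digits") - 3L), ...) {
  cat("GM(1,1) Grey prediction model\n")
  cat(sprintf("  n = %d samples, first sample x0(1) = %s\n",
              x$n, format(x$x0_1, digits = digits)))
  cat(sprintf("  developing coefficient a = %s\n  Grey input           b = %s\n",
              format(x$a, digits = digits), format(x$b, digits = digits)))
  invisible(x)
}

#' @export
coef.gm11 <- function(object, ...) c(a = object$a, b = object$b)

#' White-response value of the accumulated sequence
#'
#' Evaluates the closed-form solution of the Grey differential equation at
#' position k + 1 of the accumulated sequence. For |a| below `eps` the
#' analytic a -> 0 limit x1(k+1) = x0(1) + b * k is used, so constant
#' sequences are handled exactly.
#'
#' @param model a fitted [gm11()] object.
#' @param k non-negative integer index; k = 0 returns x0(1) exactly.
#' @param eps threshold below which `a` is treated as zero.
#' @return the predicted accumulated value x1(k + 1).
#' @export
gm11_predict_x1 <- function(model, k, eps = 1e-12) {
  stopifnot(inherits(model, "gm11"))
  if (any(k < 0)) {
    stop_greysharp("prediction index k must be >= 0", "greysharp_invalid_input")
  }
  if (abs(model$a) < eps) {
    model$x0_1 + model$b * k
  } else {
    (model$x0_1 - model$b / model$a) * exp(-model$a * k) + model$b / model$a
  }
}

#' Predict future samples from a GM(1,1) model
#'
#' Forecasts of the original (differenced) sequence obtained by evaluating
#' the white response on the accumulated scale and applying the inverse
#' accumulated generating operation.
#'
#' @param object a fitted [gm11()] object.
#' @param n.ahead number of steps past the fitted sample to forecast.
#' @param ... unused.
#' @return numeric vector of length `n.ahead`: x0(n+1), ..., x0(n+n.ahead).
#' @export
predict.gm11 <- function(object, n.ahead = 1L, ...) {
  stopifnot(n.ahead >= 1L)
  k  <- (object$n - 1L):(object$n + n.ahead - 1L)
  x1 <- gm11_predict_x1(object, k)
  diff(x1)
}

#' @export
fitted.gm11 <- function(object, ...) {
  # values implied by the Grey difference equation x0(k) = b - a z1(k),
  # k = 2..n; position 1 is reproduced exactly by construction
  z1 <- mean_sequence(cumsum(object$x0))
  c(object$x0_1, object$b - object$a * z1)
}

#' @export
residuals.gm11 <- function(object, ...) object$x0 - fitted(object)

#' One-step Grey forecast of a sequence
#'
#' Convenience wrapper: fits [gm11()] and returns the single next sample
#' x0(n + 1) of the original sequence.
#'
#' @inheritParams gm11
#' @return the forecast value (scalar).
#' @examples
#' gm11_forecast_next(c(1, 2, 4, 8))  # 2*exp(8/3) - 2*exp(2) ~ 14.0057
#' @export
gm11_forecast_next <- function(x) {
  as.numeric(predict(gm11(x), n.ahead = 1L))
}

#' Global intensity statistics of an image
#'
#' The four summary values that form the GM(1,1) input sequence: smallest
#' intensity (Min), middle intensity (Mid), largest intensity (Max) and
#' average intensity (Avg). "Middle" is not uniquely defined in the
#' literature; two readings are supported: the midrange (Min + Max) / 2
#' (default) and the sample median (even pixel counts take the mean of the
#' two central order statistics).
#'
#' @param img numeric matrix of intensities.
#' @param mid_mode `"range-middle"` (midrange, default) or `"median"`.
#' @return an object of class `"intensity_stats"`: list with `min`, `mid`,
#'   `max`, `avg` (avg is the exact real-valued mean).
#' @export
intensity_stats <- function(img, mid_mode = c("range-middle", "median")) {
  assert_image(img)
  mid_mode <- match.arg(mid_mode)
  lo <- min(img); hi <- max(img)
  mid <- if (mid_mode == "range-middle") (lo + hi) / 2 else stats::median(img)
  structure(list(min = lo, mid = mid, max = hi, avg = mean(img),
                 mid_mode = mid_mode),
            class = "intensity_stats")
}

#' @export
print.intensity_stats <- function(x, ...) {
  cat(sprintf("intensity stats: Min = %g, Mid = %g (%s), Max = %g, Avg = %g\n",
              x$min, x$mid, x$mid_mode, x$max, x$avg))
  invisible(x)
}

#' Maximal additive magnitude from intensity statistics
#'
#' Forms the four-sample Grey sequence from precomputed statistics, fits
#' GM(1,1), forecasts the fifth sample x0(5), and returns
#' Delta = |x0(5) - Avg|, the global cap on the per-pixel intensity change.
#' Delta is kept real-valued; rounding happens only at final pixel output.
#'
#' If the Grey fit is degenerate (e.g. all four statistics are equal, as in
#' a constant image) Delta is 0 with a warning.
#'
#' @param stats an [intensity_stats()] object.
#' @param order sample ordering of the sequence: `"text"` = (Min, Mid, Max,
#'   Avg) as listed in the method's description, or `"sorted"` =
#'   (Min, Mid, Avg, Max).
#' @return Delta >= 0 (scalar).
#' @export
delta_from_stats <- function(stats, order = c("text", "sorted")) {
  stopifnot(inherits(stats, "intensity_stats"))
  order <- match.arg(order)
  seq4 <- switch(order,
                 text   = c(stats$min, stats$mid, stats$max, stats$avg),
                 sorted = c(stats$min, stats$mid, stats$avg, stats$max))
  x5 <- tryCatch(gm11_forecast_next(seq4),
                 greysharp_degenerate_model = function(e) {
                   warning("degenerate GM(1,1) fit; Delta set to 0",
                           call. = FALSE)
                   stats$avg
                 })
  abs(x5 - stats$avg)
}

#' Maximal additive magnitude of an image
#'
#' Pass 1 of the sharpening pipeline: [intensity_stats()] followed by
#' [delta_from_stats()]. Depends only on the multiset of intensities, not
#' on pixel positions.
#'
#' @inheritParams intensity_stats
#' @inheritParams delta_from_stats
#' @return Delta >= 0 (scalar).
#' @examples
#' img <- make_fixture("vstep", shape = c(16, 16), levels = c(50, 150))
#' compute_delta(img)
#' @export
compute_delta <- function(img, mid_mode = c("range-middle", "median"),
                          order = c("text", "sorted")) {
  delta_from_stats(intensity_stats(img, mid_mode), order)
}
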