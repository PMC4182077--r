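# Independent brute-force reimplementations used as oracles: straight-line
# per-pixel loops, no vectorisation, no shared helpers with the package.

naive_hvd <- function(img, theta) {
  H <- nrow(img); W <- ncol(img)
  g <- matrix(0L, H, W)
  for (r in 1:H) for (c in 1:W) {
    hit <- FALSE
    if (c > 1 && abs(img[r, c] - img[r, c - 1]) >= theta) hit <- TRUE
    if (r > 1 && abs(img[r, c] - img[r - 1, c]) >= theta) hit <- TRUE
    if (hit) g[r, c] <- 1L
  }
  g
}

naive_lpf <- function(g, theta) {
  H <- nrow(g); W <- ncol(g)
  out <- g
  for (r in 1:H) for (c in 1:W) {
    if (g[r, c] == 1L) {
      cnt <- 0L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && g[rr, cc] == 1L)
          cnt <- cnt + 1L
      }
      if (cnt < theta) out[r, c] <- 0L
    }
  }
  out
}

naive_local_mean <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  s <- 0; n <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
      s <- s + img[rr, cc]; n <- n + 1L
    }
  }
  s / n
}

# GM(1,1) coefficients by an independent route: ordinary least squares of
# x0(k) on z1(k) via stats::lm (x0 = b - a * z, so a = -slope, b = intercept)
naive_gm11 <- function(x) {
  x1 <- Reduce(`+`, x, accumulate = TRUE)
  z <- (head(x1, -1) + tail(x1, -1)) / 2
  fit <- stats::lm(x[-1] ~ z)
  list(a = -unname(coef(fit)[2]), b = unname(coef(fit)[1]))
}

naive_delta <- function(img, mid_mode = "range-middle") {
  lo <- min(img); hi <- max(img); avg <- mean(img)
  mid <- if (mid_mode == "range-middle") (lo + hi) / 2 else median(img)
  x <- c(lo, mid, hi, avg)
  cf <- naive_gm11(x)
  a <- cf$a; b <- cf$b
  x1_pred <- function(k) {
    if (abs(a) < 1e-12) x[1] + b * k
    else (x[1] - b / a) * exp(-a * k) + b / a
  }
  abs((x1_pred(4) - x1_pred(3)) - avg)
}

# full three-pass pipeline as literal per-pixel loops
naive_sharpen <- function(img, theta_eth, theta_lpf, s, delta,
                          lpf_enabled = TRUE) {
  g <- naive_hvd(img, theta_eth)
  if (lpf_enabled) g <- naive_lpf(g, theta_lpf)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0L, H, W)
  for (r in 1:H) for (c in 1:W) {
    x <- img[r, c]
    if (g[r, c] == 1L) {
      lm_ <- naive_local_mean(img, r, c)
      if (x < lm_) {
        dx <- s * delta * (x / lm_)
        xh <- x - dx
      } else {
        dx <- if (x == 0 && lm_ == 0) 0 else s * delta * (lm_ / x)
        xh <- x + dx
      }
      xh <- sign(xh) * floor(abs(xh) + 0.5)
      out[r, c] <- as.integer(min(255, max(0, xh)))
    } else {
      out[r, c] <- as.integer(x)
    }
  }
  out
}

random_image <- function(H, W) {
  matrix(sample.int(256L, H * W, replace = TRUE) - 1L, H, W)
}
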