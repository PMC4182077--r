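#' Read an 8-bit grayscale image
#'
#' Reads PGM (P2 ASCII or P5 binary, maxval <= 255; `#` comments accepted
#' in the header) or, when the `png` package is installed, 8-bit PNG.
#' Grayscale PNG is used as is; RGB(A) is converted by Rec. 601 luma
#' 0.299 R + 0.587 G + 0.114 B, rounded half away from zero, with a notice.
#' PGM maxval other than 255 is accepted as-is (never rescaled — the Grey
#' statistics depend on the raw intensities) as long as it is <= 255.
#'
#' @param path file path; format is detected from the content (PGM magic)
#'   or the `.png` extension.
#' @return integer matrix (rows x columns) with intensities in [0, 255].
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) {
    stop_greysharp(sprintf("file not found: %s", path), "greysharp_format_error")
  }
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) >= 8L &&
      identical(as.integer(raw[1:4]), c(137L, 80L, 78L, 71L))) {
    return(read_png_gray(path))
  }
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P5")) {
    stop_greysharp(sprintf("%s: not a P2/P5 PGM or PNG file", path),
                   "greysharp_format_error")
  }
  read_pgm(raw, magic, path)
}

# PGM header tokenizer: skips whitespace and '#' comments
pgm_tokens <- function(raw, pos, n_tokens) {
  ws <- as.raw(c(9L, 10L, 13L, 32L))
  out <- character(n_tokens)
  for (i in seq_len(n_tokens)) {
    while (pos <= length(raw) && (raw[pos] %in% ws || raw[pos] == as.raw(35L))) {
      if (raw[pos] == as.raw(35L)) {          # comment to end of line
        while (pos <= length(raw) && raw[pos] != as.raw(10L)) pos <- pos + 1L
      } else pos <- pos + 1L
    }
    start <- pos
    while (pos <= length(raw) && !(raw[pos] %in% ws)) pos <- pos + 1L
    if (start > length(raw)) return(NULL)
    out[i] <- rawToChar(raw[start:(pos - 1L)])
  }
  list(tokens = out, pos = pos)
}

read_pgm <- function(raw, magic, path) {
  if (magic == "P2") {
    # whole file is text: tokenize in one vectorized pass
    toks <- tryCatch(
      scan(text = rawToChar(raw), what = character(), comment.char = "#",
           quiet = TRUE),
      error = function(e) NULL)
    if (is.null(toks) || length(toks) < 4L) {
      stop_greysharp(sprintf("%s: truncated PGM file", path),
                     "greysharp_format_error")
    }
    hd <- list(tokens = toks[2:4])
  } else {
    hd <- pgm_tokens(raw, 3L, 3L)   # width, height, maxval after the magic
    if (is.null(hd)) {
      stop_greysharp(sprintf("%s: truncated PGM header", path),
                     "greysharp_format_error")
    }
  }
  dims <- suppressWarnings(as.integer(hd$tokens))
  if (anyNA(dims) || any(dims[1:2] < 1L)) {
    stop_greysharp(sprintf("%s: malformed PGM header", path),
                   "greysharp_format_error")
  }
  W <- dims[1L]; H <- dims[2L]; maxval <- dims[3L]
  if (maxval > 255L || maxval < 1L) {
    stop_greysharp(sprintf("%s: PGM maxval %d unsupported (need <= 255)",
                           path, maxval), "greysharp_format_error")
  }
  n <- H * W
  if (magic == "P2") {
    if (length(toks) < 4L + n) {
      stop_greysharp(sprintf("%s: truncated P2 pixel data", path),
                     "greysharp_format_error")
    }
    px <- suppressWarnings(as.integer(toks[5:(4L + n)]))
  } else {
    pos <- hd$pos + 1L            # single whitespace byte after maxval
    if (pos + n - 1L > length(raw)) {
      stop_greysharp(sprintf("%s: truncated P5 pixel data", path),
                     "greysharp_format_error")
    }
    px <- as.integer(raw[pos:(pos + n - 1L)])
  }
  if (anyNA(px) || any(px < 0L | px > maxval)) {
    stop_greysharp(sprintf("%s: pixel values outside [0, maxval]", path),
                   "greysharp_format_error")
  }
  matrix(px, nrow = H, ncol = W, byrow = TRUE)
}

read_png_gray <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_greysharp("PNG support requires the 'png' package",
                   "greysharp_feature_unavailable")
  }
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) {
    m <- round_half_away(a * 255)
  } else {
    ch <- dim(a)[3L]
    if (ch >= 3L) {
      message("read_gray: RGB PNG converted to grayscale by Rec. 601 luma")
      m <- round_half_away((0.299 * a[, , 1L] + 0.587 * a[, , 2L] +
                              0.114 * a[, , 3L]) * 255)
    } else {
      m <- round_half_away(a[, , 1L] * 255)   # gray + alpha
    }
    dim(m) <- dim(a)[1:2]                     # 1-pixel slices drop dims
  }
  storage.mode(m) <- "integer"
  m
}

#' Write an 8-bit grayscale image
#'
#' Writes PGM ASCII (P2), PGM binary (P5) or PNG. Round trips through
#' [read_gray()] are bit-exact for all three formats.
#'
#' @param img integer matrix with intensities in [0, 255].
#' @param path output file path.
#' @param format `"pgm-ascii"`, `"pgm-binary"` or `"png"`; by default
#'   inferred from the extension (`.png` -> png, otherwise binary PGM).
#' @return the path, invisibly.
#' @export
write_gray <- function(img, path,
                       format = c("auto", "pgm-ascii", "pgm-binary", "png")) {
  assert_image(img)
  format <- match.arg(format)
  if (min(img) < 0 || max(img) > 255 || any(img != floor(img))) {
    stop_greysharp("image must contain integers in [0, 255]",
                   "greysharp_invalid_input")
  }
  if (format == "auto") {
    format <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png"
              else "pgm-binary"
  }
  H <- nrow(img); W <- ncol(img)
  switch(format,
    "pgm-ascii" = {
      con <- file(path, "wb"); on.exit(close(con))
      writeLines(c("P2", paste(W, H), "255",
                   apply(img, 1L, paste, collapse = " ")), con)
    },
    "pgm-binary" = {
      con <- file(path, "wb"); on.exit(close(con))
      writeChar(sprintf("P5\n%d %d\n255\n", W, H), con, eos = NULL)
      writeBin(as.raw(as.integer(t(img))), con)
    },
    "png" = {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop_greysharp("PNG support requires the 'png' package",
                       "greysharp_feature_unavailable")
      }
      png::writePNG(img / 255, path)
    })
  invisible(path)
}

#' Export a bi-level edge map
#'
#' Writes an [detect_edges()] map for visual inspection: P2 with maxval 1,
#' or P5 with edge pixels at 255.
#'
#' @param edges integer 0/1 matrix.
#' @param path output file path.
#' @param format `"pgm-ascii"` (maxval 1) or `"pgm-binary"` (0/255).
#' @return the path, invisibly.
#' @export
write_edge_map <- function(edges, path, format = c("pgm-ascii", "pgm-binary")) {
  assert_image(edges, "edges")
  format <- match.arg(format)
  if (!all(edges %in% c(0L, 1L))) {
    stop_greysharp("'edges' must be bi-level 0/1", "greysharp_invalid_input")
  }
  if (format == "pgm-ascii") {
    con <- file(path, "wb"); on.exit(close(con))
    writeLines(c("P2", paste(ncol(edges), nrow(edges)), "1",
                 apply(edges, 1L, paste, collapse = " ")), con)
  } else {
    write_gray(edges * 255L, path, "pgm-binary")
  }
  invisible(path)
}

#' Generate a deterministic synthetic test image
#'
#' Produces the structures the sharpening method targets — step
#' discontinuities, smooth gradients, flat fields, block patterns and
#' sparse isolated (salt-and-pepper) outliers — as small integer matrices.
#' Identical arguments (including `seed` for the stochastic kinds) give
#' bit-identical images; the pipeline itself contains no randomness.
#'
#' Kinds:
#' \describe{
#'   \item{constant}{flat field at `levels[1]`.}
#'   \item{vstep}{`split` leading columns at `levels[1]`, the rest at
#'     `levels[2]` (one vertical discontinuity).}
#'   \item{hstep}{same with leading rows (one horizontal discontinuity).}
#'   \item{ramp}{linear column-wise gradient from `levels[1]` to
#'     `levels[2]`.}
#'   \item{checkerboard}{`block`-sized squares alternating between the two
#'     levels.}
#'   \item{salt-pepper}{flat field at `levels[1]` with
#'     `floor(density * H * W)` isolated outliers alternating between
#'     `levels[2]` and `levels[3]`. Outliers are placed by rejection so
#'     that no two lie within Chebyshev distance 2 of each other; the
#'     3-pixel separation guarantees the detection clusters of distinct
#'     outliers never touch, so the low-pass filter at `theta_lpf = 3`
#'     removes every one of them.}
#'   \item{smooth-field}{seeded sum of low-frequency sinusoids around
#'     `levels[1]` with amplitude `levels[2]`: smooth enough that adjacent
#'     pixel differences stay far below the edge threshold.}
#' }
#'
#' @param kind fixture kind, see above.
#' @param shape integer c(height, width).
#' @param levels intensity parameters per kind (see above). Defaults:
#'   constant 100; steps/ramp/checkerboard c(50, 150); salt-pepper
#'   c(100, 0, 255); smooth-field c(128, 40).
#' @param density outlier fraction for salt-pepper, must be < 0.2.
#' @param block block size for checkerboard (>= 1).
#' @param split leading columns (vstep) or rows (hstep) at `levels[1]`;
#'   default half the extent.
#' @param seed integer seed for the stochastic kinds (salt-pepper,
#'   smooth-field); the caller's RNG state is left untouched.
#' @return integer matrix with values in [0, 255].
#' @examples
#' make_fixture("vstep", shape = c(4, 4), levels = c(50, 150))
#' @export
make_fixture <- function(kind = c("constant", "vstep", "hstep", "ramp",
                                  "checkerboard", "salt-pepper", "smooth-field"),
                         shape = c(64L, 64L), levels = NULL,
                         density = 0.01, block = 8L, split = NULL,
                         seed = 1L) {
  kind <- match.arg(kind)
  H <- as.integer(shape[1L]); W <- as.integer(shape[2L])
  if (is.na(H) || is.na(W) || H < 1L || W < 1L) {
    stop_greysharp("'shape' must be two positive integers",
                   "greysharp_invalid_parameter")
  }
  img <- switch(kind,
    constant = {
      lv <- if (is.null(levels)) 100L else levels[1L]
      matrix(as.integer(lv), H, W)
    },
    vstep = {
      lv <- if (is.null(levels)) c(50L, 150L) else levels
      sp <- if (is.null(split)) W %/% 2L else as.integer(split)
      m <- matrix(as.integer(lv[2L]), H, W)
      if (sp > 0L) m[, seq_len(min(sp, W))] <- as.integer(lv[1L])
      m
    },
    hstep = {
      lv <- if (is.null(levels)) c(50L, 150L) else levels
      sp <- if (is.null(split)) H %/% 2L else as.integer(split)
      m <- matrix(as.integer(lv[2L]), H, W)
      if (sp > 0L) m[seq_len(min(sp, H)), ] <- as.integer(lv[1L])
      m
    },
    ramp = {
      lv <- if (is.null(levels)) c(50L, 150L) else levels
      g <- if (W == 1L) lv[1L]
           else lv[1L] + (lv[2L] - lv[1L]) * (seq_len(W) - 1) / (W - 1)
      matrix(as.integer(round_half_away(g)), H, W, byrow = TRUE)
    },
    checkerboard = {
      lv <- if (is.null(levels)) c(50L, 150L) else levels
      block <- as.integer(block)
      if (is.na(block) || block < 1L) {
        stop_greysharp("'block' must be a positive integer",
                       "greysharp_invalid_parameter")
      }
      parity <- outer((seq_len(H) - 1L) %/% block,
                      (seq_len(W) - 1L) %/% block, "+") %% 2L
      matrix(as.integer(ifelse(parity == 0L, lv[1L], lv[2L])), H, W)
    },
    "salt-pepper" = make_salt_pepper(H, W, levels, density, seed),
    "smooth-field" = make_smooth_field(H, W, levels, seed))
  storage.mode(img) <- "integer"
  img
}

make_salt_pepper <- function(H, W, levels, density, seed) {
  lv <- if (is.null(levels)) c(100L, 0L, 255L) else levels
  if (!is.numeric(density) || density < 0 || density >= 0.2) {
    stop_greysharp("'density' must be in [0, 0.2)",
                   "greysharp_invalid_parameter")
  }
  n_out <- floor(density * H * W)
  img <- matrix(as.integer(lv[1L]), H, W)
  if (n_out == 0L) return(img)
  with_fixture_seed(seed, {
    order <- sample.int(H * W)
    blocked <- matrix(FALSE, H, W)
    placed <- 0L
    for (cell in order) {
      r <- ((cell - 1L) %% H) + 1L
      c <- ((cell - 1L) %/% H) + 1L
      if (blocked[r, c]) next
      placed <- placed + 1L
      img[r, c] <- as.integer(lv[2L + (placed %% 2L)])
      # block a 5x5 neighbourhood: Chebyshev separation >= 3 keeps the
      # HVD detection clusters of distinct outliers disjoint
      blocked[max(1L, r - 2L):min(H, r + 2L),
              max(1L, c - 2L):min(W, c + 2L)] <- TRUE
      if (placed == n_out) break
    }
    if (placed < n_out) {
      stop_greysharp("salt-pepper density too high for isolated placement",
                     "greysharp_invalid_parameter")
    }
    img
  })
}

make_smooth_field <- function(H, W, levels, seed) {
  lv <- if (is.null(levels)) c(128, 40) else levels
  with_fixture_seed(seed, {
    ph <- stats::runif(4L, 0, 2 * pi)
    r <- (seq_len(H) - 1) / max(1L, H - 1L)
    c <- (seq_len(W) - 1) / max(1L, W - 1L)
    f <- outer(sin(2 * pi * r + ph[1L]), cos(2 * pi * c + ph[2L])) +
         0.5 * outer(cos(pi * r + ph[3L]), sin(pi * c + ph[4L]))
    matrix(as.integer(clamp255(round_half_away(lv[1L] + lv[2L] * f / 1.5))),
           H, W)
  })
}

# run expr under a fixture-local seed, restoring the caller's RNG state
with_fixture_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
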