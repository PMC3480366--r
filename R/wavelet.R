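# Periodized orthogonal discrete wavelet transform.
#
# The multiresolution front end of the texture method: an L-level separable
# 2-D DWT with periodic boundary extension. Periodization keeps the transform
# orthonormal on the torus, so coefficient counts halve exactly per level and
# Parseval's identity holds, which the tests exploit.

#' Orthonormal scaling filters
#'
#' Available wavelets: `"haar"`, `"d4"` (Daubechies, 4 taps / 2 vanishing
#' moments, the default throughout the package) and `"d8"` (8 taps).
#'
#' @param wavelet filter name.
#' @return Numeric vector of scaling (low-pass) coefficients, summing to
#'   `sqrt(2)`.
#' @export
wavelet_filter <- function(wavelet = "d4") {
  s3 <- sqrt(3)
  switch(match.arg(wavelet, c("d4", "haar", "d8")),
    haar = c(1, 1) / sqrt(2),
    d4   = c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2)),
    d8   = c(0.23037781330885523, 0.71484657055254153,
             0.63088076792959036, -0.02798376941698385,
             -0.18703481171888114, 0.03084138183598697,
             0.03288301166698295, -0.01059740178499728))
}

qmf <- function(h) {
  n <- seq_along(h) - 1L
  rev(h) * (-1)^n
}

# One analysis step along dim 1 (columns filtered downwards), periodic.
# Returns N/2-row low-pass and high-pass parts.
dwt_step_dim1 <- function(x, h) {
  g <- qmf(h)
  n <- nrow(x)
  if (n %% 2L != 0L) stop("dimension must be even for a DWT step")
  half <- n %/% 2L
  lo <- matrix(0, half, ncol(x))
  hi <- matrix(0, half, ncol(x))
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(h)) {
    rows <- (base + (k - 1L)) %% n + 1L
    lo <- lo + h[k] * x[rows, , drop = FALSE]
    hi <- hi + g[k] * x[rows, , drop = FALSE]
  }
  list(lo = lo, hi = hi)
}

# One synthesis step along dim 1 (transpose of the orthonormal analysis).
idwt_step_dim1 <- function(lo, hi, h) {
  g <- qmf(h)
  half <- nrow(lo)
  n <- 2L * half
  x <- matrix(0, n, ncol(lo))
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(h)) {
    rows <- (base + (k - 1L)) %% n + 1L
    x[rows, ] <- x[rows, , drop = FALSE] + h[k] * lo + g[k] * hi
  }
  x
}

# Single-level separable 2-D step: filter along rows (dim 1), then columns.
dwt2_step <- function(x, h) {
  v <- dwt_step_dim1(x, h)                 # vertical filtering
  ll_lh <- dwt_step_dim1(t(v$lo), h)       # then horizontal
  hl_hh <- dwt_step_dim1(t(v$hi), h)
  list(ll = t(ll_lh$lo),
       v  = t(ll_lh$hi),   # low vertical / high horizontal: vertical edges
       h  = t(hl_hh$lo),   # high vertical / low horizontal: horizontal edges
       d  = t(hl_hh$hi))   # high / high: diagonal detail
}

idwt2_step <- function(ll, h_band, v_band, d_band, h) {
  lo <- t(idwt_step_dim1(t(ll), t(v_band), h))
  hi <- t(idwt_step_dim1(t(h_band), t(d_band), h))
  idwt_step_dim1(lo, hi, h)
}

#' Full L-level 2-D wavelet analysis
#'
#' @param x numeric matrix with both dimensions divisible by `2^levels`.
#' @param wavelet filter name, see [wavelet_filter()].
#' @param levels number of decomposition levels.
#' @return List with `approx` (coarsest low-pass matrix) and `details`, a list
#'   of length `levels`; `details[[l]]` holds matrices `h`, `v`, `d` for the
#'   horizontal, vertical and diagonal detail subbands at level `l` (finest
#'   level first).
#' @export
dwt2 <- function(x, wavelet = "d4", levels = 1L) {
  h <- wavelet_filter(wavelet)
  if (any(dim(x) %% 2L^levels != 0L))
    stop(errorCondition(
      sprintf("matrix %dx%d not divisible by 2^%d", nrow(x), ncol(x), levels),
      class = c("texdiv_size_error", "texdiv_error", "error", "condition")))
  details <- vector("list", levels)
  approx <- x
  for (l in seq_len(levels)) {
    s <- dwt2_step(approx, h)
    details[[l]] <- list(h = s$h, v = s$v, d = s$d)
    approx <- s$ll
  }
  list(approx = approx, details = details, wavelet = wavelet, levels = levels)
}

#' Inverse of [dwt2()]
#'
#' @param w decomposition list as returned by [dwt2()].
#' @return Reconstructed matrix.
#' @export
idwt2 <- function(w) {
  h <- wavelet_filter(w$wavelet)
  approx <- w$approx
  for (l in rev(seq_len(w$levels))) {
    d <- w$details[[l]]
    approx <- idwt2_step(approx, d$h, d$v, d$d, h)
  }
  approx
}

#' Detail subbands of an analysis window
#'
#' Applies the L-level decomposition and collects the `3 * levels` detail
#' subbands, discarding the approximation band. If `window` carries a validity
#' mask, invalid pixels are first replaced by the median of the valid ones
#' (the transform needs a complete grid); dimensions are cropped down to
#' multiples of `2^levels`.
#'
#' @param window an [analysis_window()] or a plain numeric matrix.
#' @param wavelet filter name.
#' @param levels decomposition depth; each cropped window side must be at
#'   least `16 * 2^levels` so the coarsest subband keeps >= 16x16
#'   coefficients.
#' @return List of `3 * levels` subbands ordered by level (fine to coarse)
#'   and, within a level, horizontal, vertical, diagonal. Each element has
#'   fields `level`, `orientation`, `coef`.
#' @export
decompose <- function(window, wavelet = "d4", levels = 3L) {
  px <- window_pixels(window)
  f <- 2L^levels
  if (any(dim(px) < 16L * f))
    stop(errorCondition(
      sprintf("window %dx%d too small for %d levels (need >= %d per side)",
              nrow(px), ncol(px), levels, 16L * f),
      class = c("texdiv_size_error", "texdiv_error", "error", "condition")))
  px <- px[seq_len(f * (nrow(px) %/% f)), seq_len(f * (ncol(px) %/% f)), drop = FALSE]
  w <- dwt2(px, wavelet, levels)
  out <- vector("list", 3L * levels)
  i <- 0L
  for (l in seq_len(levels)) {
    for (o in c("h", "v", "d")) {
      i <- i + 1L
      out[[i]] <- list(
        level = l,
        orientation = c(h = "horizontal", v = "vertical", d = "diagonal")[[o]],
        coef = w$details[[l]][[o]])
    }
  }
  out
}

# Extract a complete pixel matrix from a window object or matrix, filling
# masked pixels with the median of the valid ones.
window_pixels <- function(window) {
  if (is.matrix(window)) return(window * 1.0)
  if (inherits(window, "analysis_window")) {
    px <- window$pixels * 1.0
    if (!is.null(window$valid_mask) && !all(window$valid_mask)) {
      if (!any(window$valid_mask))
        stop_degenerate("window has no valid pixels")
      px[!window$valid_mask] <- stats::median(px[window$valid_mask])
    }
    return(px)
  }
  stop(errorCondition("expected a matrix or analysis_window",
                      class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
}
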