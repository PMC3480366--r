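# Raster band handling: TIFF I/O with a JSON sidecar for georeferencing,
# cloud-constrained window selection, pixel-intensity Shannon entropy, and
# the dry/wet season calendar.

#' Band raster container
#'
#' A single-band raster of digital numbers (DN) with an optional validity
#' mask. Band semantics follow the visible Landsat bands: 1 = blue (water),
#' 2 = green (healthy vegetation), 3 = red (soil). `nodata_mask` is TRUE
#' where a pixel is invalid (cloud, SLC-off stripe, nodata).
#'
#' @param pixels integer matrix of DN values.
#' @param band band index in 1..3.
#' @param geotransform GDAL-style affine vector `c(x0, dx, rx, y0, ry, dy)`
#'   mapping pixel (col, row) corners to geographic coordinates.
#' @param resolution meters per pixel (default 30, Landsat-like).
#' @param nodata_mask logical matrix, same shape as `pixels`; TRUE = invalid.
#' @return An object of class `"band_raster"`.
#' @export
band_raster <- function(pixels, band = 2L,
                        geotransform = c(0, 30, 0, 0, 0, -30),
                        resolution = 30, nodata_mask = NULL) {
  pixels <- as.matrix(pixels)
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, nrow(pixels), ncol(pixels))
  if (!identical(dim(pixels), dim(nodata_mask)))
    stop(errorCondition("pixels and nodata_mask must have identical shape",
                        class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
  structure(list(pixels = pixels, band = as.integer(band),
                 geotransform = as.numeric(geotransform),
                 resolution = as.numeric(resolution),
                 nodata_mask = nodata_mask),
            class = "band_raster")
}

#' @export
print.band_raster <- function(x, ...) {
  cat(sprintf("Band raster: %dx%d px, band %d, %.0f m/px, %.1f%% masked\n",
              nrow(x$pixels), ncol(x$pixels), x$band, x$resolution,
              100 * mean(x$nodata_mask)))
  invisible(x)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a raster to TIFF (8-bit) with a JSON georeferencing sidecar
#'
#' Multi-band input is written as a multi-channel TIFF. The sidecar (same
#' path with `.json` extension) stores the geotransform, resolution and
#' nodata value so [read_band()] can rebuild the `band_raster`.
#'
#' @param pixels integer matrix (one band) or H x W x B array, DN in 0..255.
#' @param path output `.tif` path.
#' @param geotransform,resolution see [band_raster()].
#' @param nodata optional DN value marking invalid pixels.
#' @return `path`, invisibly.
#' @export
write_raster <- function(pixels, path, geotransform = c(0, 30, 0, 0, 0, -30),
                         resolution = 30, nodata = NULL) {
  arr <- if (length(dim(pixels)) == 2L) array(pixels, c(dim(pixels), 1L)) else pixels
  tiff::writeTIFF(arr / 255, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(geotransform = geotransform, resolution = resolution, nodata = nodata),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read one band of a TIFF raster
#'
#' Pixels tagged with the sidecar's nodata value, plus any pixels set in
#' `mask`, are marked invalid in the returned raster's `nodata_mask` (this is
#' how SLC-off stripes and hand-drawn cloud masks are folded in).
#'
#' @param path `.tif` file written by [write_raster()] or any baseline TIFF.
#' @param band band (channel) index to extract.
#' @param mask optional logical matrix or path to a 0/1 mask raster; TRUE/1
#'   marks invalid pixels.
#' @return A [band_raster()].
#' @export
read_band <- function(path, band = 2L, mask = NULL) {
  if (!file.exists(path))
    stop(errorCondition(paste("no such raster:", path),
                        class = c("texdiv_io_error", "texdiv_error", "error", "condition")))
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (!is.integer(img)) {
    # multi-channel TIFFs come back rescaled to [0, 1]; undo to DN
    bps <- attr(img, "bits.per.sample") %||% 8L
    img <- round(img * (2^bps - 1))
  }
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (band < 1L || band > dim(img)[3L])
    stop(errorCondition(sprintf("band %d not present (file has %d)", band, dim(img)[3L]),
                        class = c("texdiv_io_error", "texdiv_error", "error", "condition")))
  px <- img[, , band]
  gt <- c(0, 30, 0, 0, 0, -30); res <- 30; nodata <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp)
    gt <- as.numeric(unlist(side$geotransform))
    res <- as.numeric(side$resolution)
    nodata <- side$nodata
  }
  nd <- matrix(FALSE, nrow(px), ncol(px))
  if (!is.null(nodata)) nd <- nd | (px == as.numeric(nodata))
  if (!is.null(mask)) {
    if (is.character(mask)) {
      mimg <- tiff::readTIFF(mask, as.is = TRUE)
      if (length(dim(mimg)) == 3L) mimg <- mimg[, , 1L]
      mask <- mimg > 0
    }
    nd <- nd | mask
  }
  band_raster(px, band = band, geotransform = gt, resolution = res, nodata_mask = nd)
}

#' Analysis window
#'
#' A rectangular single-band pixel patch cut out of a raster, together with
#' its validity mask, achieved cloud/nodata fraction, half-open 0-based
#' bounds `(row0, col0, height, width)` in the source raster, and period
#' labels.
#'
#' @param pixels integer matrix.
#' @param valid_mask logical matrix (TRUE = usable pixel).
#' @param cloud_fraction fraction of invalid pixels in the window.
#' @param bounds integer vector `(row0, col0, height, width)`, 0-based.
#' @param season `"dry"` or `"wet"` (optional).
#' @param year integer (optional).
#' @export
analysis_window <- function(pixels, valid_mask = NULL, cloud_fraction = NULL,
                            bounds = NULL, season = NULL, year = NULL) {
  pixels <- as.matrix(pixels)
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  if (is.null(cloud_fraction)) cloud_fraction <- mean(!valid_mask)
  if (is.null(bounds)) bounds <- c(0L, 0L, nrow(pixels), ncol(pixels))
  structure(list(pixels = pixels, valid_mask = valid_mask,
                 cloud_fraction = cloud_fraction,
                 bounds = as.integer(bounds), season = season, year = year),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("Analysis window: %dx%d px at (%d,%d), %.1f%% clouded%s\n",
              x$bounds[3L], x$bounds[4L], x$bounds[1L], x$bounds[2L],
              100 * x$cloud_fraction,
              if (!is.null(x$year)) sprintf(" [%s %s]", x$year, x$season) else ""))
  invisible(x)
}

#' Select the largest representative cloud-free window
#'
#' Scans axis-aligned rectangles (positions and side lengths stepped by
#' `stride`; the full extent is always among the candidates) and returns the
#' largest-area window whose masked fraction is *strictly* below
#' `max_cloud_frac`. Ties on area are broken by the smallest `(row0, col0)`,
#' then by height and width. This mirrors the moving-window selection used to
#' maximize the extension of the analyzed patch under a <20% cloud-cover
#' constraint.
#'
#' @param r a [band_raster()].
#' @param max_cloud_frac strict upper bound on the masked fraction
#'   (default 0.20).
#' @param min_side smallest acceptable window side, in pixels; must satisfy
#'   the decomposition minimum of the planned [decompose()] call.
#' @param stride scan step in pixels (default 16; use 1 for exhaustive).
#' @param season,year period labels copied onto the result.
#' @return An [analysis_window()], or an error of class
#'   `"texdiv_nowindow_error"` when no candidate satisfies the threshold.
#' @export
select_window <- function(r, max_cloud_frac = 0.20, min_side = 128L,
                          stride = 16L, season = NULL, year = NULL) {
  stopifnot(inherits(r, "band_raster"))
  H <- nrow(r$pixels); W <- ncol(r$pixels)
  if (min_side > H || min_side > W)
    stop(errorCondition("min_side exceeds raster extent",
                        class = c("texdiv_nowindow_error", "texdiv_error", "error", "condition")))
  # integral image of the mask: O(1) masked count per candidate rectangle
  S <- matrix(0, H + 1L, W + 1L)
  S[-1L, -1L] <- apply(apply(r$nodata_mask * 1L, 2L, cumsum), 1L, cumsum) |> t()
  strided <- function(lo, hi) unique(c(seq(lo, hi, by = stride), hi))
  hs <- strided(min_side, H); ws <- strided(min_side, W)
  best <- NULL
  for (h in hs) {
    r0s <- strided(1L, H - h + 1L)
    for (w in ws) {
      c0s <- strided(1L, W - w + 1L)
      cnt <- S[r0s + h, c0s + w, drop = FALSE] - S[r0s, c0s + w, drop = FALSE] -
        S[r0s + h, c0s, drop = FALSE] + S[r0s, c0s, drop = FALSE]
      ok <- which(cnt / (h * w) < max_cloud_frac, arr.ind = TRUE)
      if (nrow(ok) == 0L) next
      # smallest (row0, col0) lexicographically among qualifying positions
      cand_r <- r0s[ok[, 1L]]; cand_c <- c0s[ok[, 2L]]
      o <- order(cand_r, cand_c)[1L]
      cand <- list(area = h * w, r0 = cand_r[o], c0 = cand_c[o], h = h, w = w,
                   frac = cnt[ok[o, 1L], ok[o, 2L]] / (h * w))
      if (is.null(best) ||
          cand$area > best$area ||
          (cand$area == best$area &&
           (cand$r0 < best$r0 ||
            (cand$r0 == best$r0 && (cand$c0 < best$c0 ||
             (cand$c0 == best$c0 && (cand$h < best$h ||
              (cand$h == best$h && cand$w < best$w)))))))) {
        best <- cand
      }
    }
  }
  if (is.null(best))
    stop(errorCondition(
      sprintf("no window of side >= %d has masked fraction < %.2f", min_side, max_cloud_frac),
      class = c("texdiv_nowindow_error", "texdiv_error", "error", "condition")))
  rows <- best$r0:(best$r0 + best$h - 1L)
  cols <- best$c0:(best$c0 + best$w - 1L)
  analysis_window(r$pixels[rows, cols, drop = FALSE],
                  valid_mask = !r$nodata_mask[rows, cols, drop = FALSE],
                  cloud_fraction = best$frac,
                  bounds = c(best$r0 - 1L, best$c0 - 1L, best$h, best$w),
                  season = season, year = year)
}

#' Pixel-intensity Shannon entropy of a window
#'
#' Maximum-likelihood (plug-in) Shannon index over intensity bins,
#' `H = -sum(p_i * log(p_i, log_base))` with `p_i` the observed sample
#' fraction of valid pixels in bin `i`; empty bins contribute nothing.
#' For 8-bit DN with the default 256 bins each intensity level is its own
#' bin, so `0 <= H <= 8` bits. This is the image-side analogue of the
#' Shannon diversity index, the proxy of local species richness.
#'
#' @param w an [analysis_window()] or numeric matrix.
#' @param n_bins number of intensity bins (default 256).
#' @param log_base logarithm base (default 2, bits).
#' @return Non-negative scalar entropy.
#' @export
intensity_entropy <- function(w, n_bins = 256L, log_base = 2) {
  if (inherits(w, "analysis_window")) {
    v <- w$pixels[w$valid_mask]
  } else {
    v <- as.numeric(w)
  }
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop_degenerate("no valid pixels to histogram")
  if (all(v == round(v)) && min(v) >= 0 && max(v) < n_bins) {
    counts <- tabulate(as.integer(v) + 1L, nbins = n_bins)
  } else {
    rng <- range(v)
    if (rng[1L] == rng[2L]) return(0)
    idx <- pmin(floor((v - rng[1L]) / diff(rng) * n_bins) + 1L, n_bins)
    counts <- tabulate(idx, nbins = n_bins)
  }
  p <- counts[counts > 0L] / length(v)
  -sum(p * log(p, base = log_base))
}

#' Season of a calendar date
#'
#' December through April is the dry season, May through November the wet
#' season (South Florida calendar; January and August are the representative
#' acquisition months).
#'
#' @param date a `Date`, or anything `as.Date()` accepts.
#' @return `"dry"` or `"wet"`.
#' @examples
#' season_of("2001-01-15")  # dry
#' season_of("2001-08-01")  # wet
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  ifelse(m == 12L | m <= 4L, "dry", "wet")
}
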