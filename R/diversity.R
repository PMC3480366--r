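# Occurrence-data diversity machinery: nearest-neighbor gridding of species
# occurrences, alpha / beta / gamma diversity, Jaccard turnover in time,
# regridding, calibration of image statistics against measured diversity,
# and covariate cross-correlation.

# Nearest-pixel-center assignment along one axis. Centers sit at
# origin + (k + 0.5) * res, k = 0 .. n-1. A point equidistant to two centers
# (i.e. exactly on a cell boundary) goes to the smaller index; points outside
# [origin, origin + n * res] return NA.
axis_cell <- function(coord, origin, res, n) {
  d <- coord - origin
  k <- ceiling(d / res) - 1
  k[d == 0] <- 0
  k[d < 0 | d > n * res] <- NA_integer_
  as.integer(k)
}

#' Grid species occurrences onto pixels
#'
#' Assigns each occurrence record to the pixel whose center is nearest
#' (boundary ties go to the smaller `(row, col)`), collapsing duplicate
#' (species, pixel) pairs: per-pixel richness counts *unique* species.
#' Records outside the domain box are dropped with a warning count.
#'
#' @param records data frame with columns `species`, `x`, `y` (and optionally
#'   `date`); coordinates share the raster CRS.
#' @param resolution cell size in meters (default 30).
#' @param origin `c(x0, y0)` of the grid's lower-left corner.
#' @param dim `c(nrow, ncol)` cells; rows index `y`, columns index `x`.
#' @param period label of the time slice (e.g. `"2001-dry"`).
#' @return An `"occurrence_grid"`: list with `resolution`, `origin`, `dim`,
#'   `period`, `cells` (named list, key `"row,col"` 0-based, value character
#'   vector of species ids) and `n_dropped`.
#' @export
grid_occurrences <- function(records, resolution = 30, origin = c(0, 0),
                             dim = c(1L, 1L), period = NULL) {
  stopifnot(is.data.frame(records), all(c("species", "x", "y") %in% names(records)))
  dim <- as.integer(dim)
  col <- axis_cell(records$x, origin[1L], resolution, dim[2L])
  row <- axis_cell(records$y, origin[2L], resolution, dim[1L])
  inside <- !is.na(col) & !is.na(row)
  n_dropped <- sum(!inside)
  if (n_dropped > 0L)
    warning(sprintf("%d occurrence(s) outside the domain box were excluded", n_dropped))
  cells <- list()
  if (any(inside)) {
    key <- sprintf("%d,%d", row[inside], col[inside])
    sp <- as.character(records$species[inside])
    cells <- lapply(split(sp, key), unique)
  }
  structure(list(resolution = resolution, origin = as.numeric(origin),
                 dim = dim, period = period, cells = cells,
                 n_dropped = n_dropped),
            class = "occurrence_grid")
}

#' @export
print.occurrence_grid <- function(x, ...) {
  cat(sprintf("Occurrence grid: %dx%d cells at %.0f m, %d occupied, gamma = %d%s\n",
              x$dim[1L], x$dim[2L], x$resolution, length(x$cells),
              gamma_diversity(x),
              if (!is.null(x$period)) paste0(" [", x$period, "]") else ""))
  invisible(x)
}

#' Local species richness (alpha diversity)
#'
#' Per-cell richness is the number of unique species in the cell; the summary
#' value is the mean over occupied cells.
#'
#' @param g an [grid_occurrences()] result.
#' @return List with `per_cell` (named integer vector) and `mean`; an empty
#'   grid gives `mean = 0` with attribute `zero_cells = TRUE`.
#' @export
alpha_diversity <- function(g) {
  stopifnot(inherits(g, "occurrence_grid"))
  per_cell <- vapply(g$cells, length, integer(1))
  if (length(per_cell) == 0L) {
    m <- 0
    attr(m, "zero_cells") <- TRUE
    return(list(per_cell = integer(0), mean = m))
  }
  list(per_cell = per_cell, mean = mean(per_cell))
}

#' Domain-wide species richness (gamma diversity)
#'
#' Number of distinct species over all cells; always at least the maximum
#' per-cell alpha.
#'
#' @inheritParams alpha_diversity
#' @return Non-negative integer.
#' @export
gamma_diversity <- function(g) {
  stopifnot(inherits(g, "occurrence_grid"))
  length(unique(unlist(g$cells, use.names = FALSE)))
}

#' Species turnover between two periods (beta diversity)
#'
#' Per cell, the complement of the Jaccard Similarity Index evaluated in
#' time: `beta = 1 - |S1 n S2| / |S1 u S2|`, in `[0, 1]`. Cells empty in both
#' periods are excluded (0/0 Jaccard is undefined); the summary is the mean
#' over compared cells.
#'
#' @param g1,g2 grids with identical resolution, origin and dims.
#' @return List with `per_cell` (named numeric vector) and `mean`.
#' @export
beta_turnover <- function(g1, g2) {
  stopifnot(inherits(g1, "occurrence_grid"), inherits(g2, "occurrence_grid"))
  if (!isTRUE(all.equal(g1$resolution, g2$resolution)) ||
      !isTRUE(all.equal(g1$origin, g2$origin)) || !identical(g1$dim, g2$dim))
    stop(errorCondition("grids have different resolution, origin or extent",
                        class = c("texdiv_incompatible_error", "texdiv_error",
                                  "error", "condition")))
  keys <- union(names(g1$cells), names(g2$cells))
  if (length(keys) == 0L) return(list(per_cell = numeric(0), mean = 0))
  per_cell <- vapply(keys, function(k) {
    s1 <- g1$cells[[k]] %||% character(0)
    s2 <- g2$cells[[k]] %||% character(0)
    1 - length(intersect(s1, s2)) / length(union(s1, s2))
  }, numeric(1))
  list(per_cell = per_cell, mean = mean(per_cell))
}

#' Regrid an occurrence grid to a new resolution
#'
#' Coarsening (larger cells) unions the species sets of the source cells
#' falling into each target cell; refining (smaller cells) replicates each
#' parent cell's set into the child cells it covers — a deterministic
#' coarse-graining that preserves gamma diversity in both directions.
#'
#' @param g source grid.
#' @param new_resolution target cell size in meters.
#' @return A new `"occurrence_grid"` over the same domain box.
#' @export
regrid <- function(g, new_resolution) {
  stopifnot(inherits(g, "occurrence_grid"), new_resolution > 0)
  extent <- g$dim * g$resolution            # (y, x) meters
  new_dim <- as.integer(ceiling(extent / new_resolution - 1e-9))
  cells <- list()
  add <- function(key, sp) cells[[key]] <<- unique(c(cells[[key]], sp))
  old_idx <- do.call(rbind, lapply(strsplit(names(g$cells), ","), as.integer))
  if (new_resolution >= g$resolution) {
    # old cell centers -> containing new cell
    for (i in seq_along(g$cells)) {
      cy <- g$origin[2L] + (old_idx[i, 1L] + 0.5) * g$resolution
      cx <- g$origin[1L] + (old_idx[i, 2L] + 0.5) * g$resolution
      r <- axis_cell(cy, g$origin[2L], new_resolution, new_dim[1L])
      c <- axis_cell(cx, g$origin[1L], new_resolution, new_dim[2L])
      add(sprintf("%d,%d", r, c), g$cells[[i]])
    }
  } else {
    # new cell centers inside the old cell's square inherit its set
    child_range <- function(k, old_res) {
      lo <- k * old_res; hi <- (k + 1) * old_res
      ks <- seq.int(floor(lo / new_resolution), ceiling(hi / new_resolution))
      ctr <- (ks + 0.5) * new_resolution
      ks[ctr >= lo & ctr < hi]
    }
    for (i in seq_along(g$cells)) {
      rs <- child_range(old_idx[i, 1L], g$resolution)
      cs <- child_range(old_idx[i, 2L], g$resolution)
      for (r in rs) for (c in cs) add(sprintf("%d,%d", r, c), g$cells[[i]])
    }
  }
  structure(list(resolution = new_resolution, origin = g$origin, dim = new_dim,
                 period = g$period, cells = cells, n_dropped = 0L),
            class = "occurrence_grid")
}

#' Effective number of species from an entropy value
#'
#' The Hill order-1 diversity `log_base^H`: the number of equally common
#' species whose community entropy equals `H`. This is the standard
#' rescaling from entropy (uncertainty) to true diversity.
#'
#' @param H non-negative entropy value.
#' @param log_base base in which `H` was computed (2 for bits, `exp(1)` for
#'   nats).
#' @return Positive scalar (>= 1).
#' @export
diversity_number <- function(H, log_base = 2) {
  if (any(!is.finite(H)) || any(H < 0))
    stop(errorCondition("entropy must be finite and non-negative",
                        class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
  log_base^H
}

#' Linear calibration of an image statistic against measured diversity
#'
#' Ordinary least squares of `y` on `x` with a 95% confidence interval on the
#' slope, either from `n_boot` bootstrap resamples of the points (percentile
#' interval; `method = "linear"`) or from leave-one-out jackknife standard
#' errors (`method = "jackknife"`).
#'
#' @param x,y numeric series of equal length >= 3.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed optional integer for reproducible resampling.
#' @param method `"linear"` (bootstrap CI) or `"jackknife"`.
#' @param normalize if TRUE, min-max normalize `x` before the regression.
#' @return A `"calibration_fit"`: slope, intercept, r_squared, ci_low,
#'   ci_high, method, n_boot, seed.
#' @export
calibrate_linear <- function(x, y, n_boot = 1000L, seed = NULL,
                             method = c("linear", "jackknife"),
                             normalize = FALSE) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0)
    stop(errorCondition("x has zero variance: slope is undefined",
                        class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
  if (normalize) x <- (x - min(x)) / (max(x) - min(x))
  n <- length(x)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- if (stats::var(y) == 0) 0 else unname(stats::cor(x, y)^2)
  ols_slope <- function(xs, ys) {
    # column-wise OLS slope for matrices of resampled points
    mx <- colMeans(xs); my <- colMeans(ys)
    (colMeans(xs * ys) - mx * my) / (colMeans(xs * xs) - mx * mx)
  }
  if (method == "linear") {
    ci <- with_seed(seed, {
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
      slopes <- ols_slope(matrix(x[idx], n), matrix(y[idx], n))
      stats::quantile(slopes[is.finite(slopes)], c(0.025, 0.975), names = FALSE)
    })
  } else {
    loo <- vapply(seq_len(n), function(i) {
      xi <- x[-i]; yi <- y[-i]
      stats::cov(xi, yi) / stats::var(xi)
    }, numeric(1))
    se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
    ci <- slope + c(-1, 1) * stats::qnorm(0.975) * se
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 ci_low = ci[1L], ci_high = ci[2L], method = method,
                 n_boot = if (method == "linear") as.integer(n_boot) else NA_integer_,
                 seed = seed, n = n),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration (%s): slope %.4g [%.4g, %.4g], intercept %.4g, R^2 = %.3f (n = %d)\n",
              x$method, x$slope, x$ci_low, x$ci_high, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Cross-correlation between two series at a range of lags
#'
#' Pearson correlation of lag-aligned overlapping segments: at lag `k >= 0`,
#' `cor(a[t], b[t + k])`, so a series `b` that lags `a` by `k` steps attains
#' its maximum at lag `k` (e.g. rainfall leading the green-band entropy).
#'
#' @param a,b numeric series of equal length `> max_lag + 2`.
#' @param max_lag maximum lag (in series steps) in either direction.
#' @return Data frame with columns `lag` and `correlation`.
#' @export
cross_correlation <- function(a, b, max_lag) {
  n <- length(a)
  stopifnot(length(b) == n, n > max_lag + 2)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop(errorCondition("correlation undefined for a constant series",
                        class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(a[seq_len(n - k)], b[seq_len(n - k) + k])
    else stats::cor(a[seq_len(n + k) - k], b[seq_len(n + k)])
  }, numeric(1))
  data.frame(lag = lags, correlation = r)
}

# ---- occurrence and grid I/O ----------------------------------------------

#' Read / write species-occurrence tables
#'
#' CSV with required header `species,x,y,date`.
#'
#' @param path CSV path.
#' @return A data frame of occurrence records.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "x", "y", "date")
  if (!all(need %in% names(df)))
    stop(errorCondition(
      paste("occurrence CSV must have columns:", paste(need, collapse = ",")),
      class = c("texdiv_io_error", "texdiv_error", "error", "condition")))
  df
}

#' @rdname read_occurrences
#' @param records data frame with columns `species,x,y,date`.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records[, c("species", "x", "y", "date")], path, row.names = FALSE)
  invisible(path)
}

#' Read / write occurrence grids as JSON
#'
#' @param g an `"occurrence_grid"`.
#' @param path JSON path.
#' @export
write_grid <- function(g, path) {
  jsonlite::write_json(
    list(resolution = g$resolution, origin = g$origin, dim = g$dim,
         period = g$period, cells = g$cells),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  obj <- jsonlite::read_json(path)
  cells <- lapply(obj$cells, function(sp) as.character(unlist(sp)))
  structure(list(resolution = as.numeric(obj$resolution),
                 origin = as.numeric(unlist(obj$origin)),
                 dim = as.integer(unlist(obj$dim)),
                 period = obj$period, cells = cells, n_dropped = 0L),
            class = "occurrence_grid")
}
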