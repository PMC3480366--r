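# Analysis orchestration: entropy time series, per-band divergence matrices
# with chronological labels and anomaly flagging, and validation of the image
# statistics against occurrence-derived diversity. These functions, together
# with the thin command-line wrapper shipped in inst/scripts/texdiv.R, are
# the package's pipeline surface.

season_rank <- function(season) match(season, c("dry", "wet"))

period_label <- function(year, season) paste0(year, "-", season)

check_manifest <- function(manifest) {
  need <- c("path", "band", "year", "season")
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop(errorCondition("manifest must be a non-empty data frame",
                        class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
  if (!all(need %in% names(manifest)))
    stop(errorCondition(paste("manifest needs columns:", paste(need, collapse = ",")),
                        class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
  manifest[order(manifest$year, season_rank(manifest$season), manifest$band), ,
           drop = FALSE]
}

write_run_log <- function(out_dir, config, warnings = character(0)) {
  if (is.null(out_dir)) return(invisible(NULL))
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(
    list(package = "texdiv",
         version = as.character(utils::packageVersion("texdiv")),
         config = config,
         config_md5 = unname(tools::md5sum(cfg_file)),
         warnings = warnings),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' Entropy time series over an image manifest
#'
#' For each manifest row: read the band, select the largest window under the
#' cloud threshold, and compute its pixel-intensity Shannon entropy.
#' Rows whose raster is unreadable or admits no window are recorded with a
#' status message rather than aborting the series.
#'
#' @param manifest data frame with columns `path`, `band`, `year`, `season`
#'   (ordered chronologically on output: dry before wet within a year).
#' @param max_cloud_frac,min_side,stride window selection controls, see
#'   [select_window()].
#' @param n_bins,log_base entropy controls, see [intensity_entropy()].
#' @param out_dir optional directory; if given, writes `entropy_series.csv`
#'   and a machine-readable `run_log.json` there.
#' @return Data frame with columns `year, season, band, entropy, row0, col0,
#'   height, width, cloud_fraction, status` (`"ok"` or the failure reason).
#' @export
run_entropy_series <- function(manifest, max_cloud_frac = 0.20, min_side = 128L,
                               stride = 16L, n_bins = 256L, log_base = 2,
                               out_dir = NULL) {
  manifest <- check_manifest(manifest)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    mi <- manifest[i, ]
    out <- data.frame(year = mi$year, season = mi$season, band = mi$band,
                      entropy = NA_real_, row0 = NA_integer_, col0 = NA_integer_,
                      height = NA_integer_, width = NA_integer_,
                      cloud_fraction = NA_real_, status = "ok",
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      r <- read_band(mi$path, band = mi$band)
      w <- select_window(r, max_cloud_frac = max_cloud_frac,
                         min_side = min_side, stride = stride,
                         season = mi$season, year = mi$year)
      list(w = w, H = intensity_entropy(w, n_bins = n_bins, log_base = log_base))
    }, texdiv_error = function(cnd) cnd)
    if (inherits(res, "condition")) {
      out$status <- conditionMessage(res)
    } else {
      out$entropy <- res$H
      out$row0 <- res$w$bounds[1L]; out$col0 <- res$w$bounds[2L]
      out$height <- res$w$bounds[3L]; out$width <- res$w$bounds[4L]
      out$cloud_fraction <- res$w$cloud_fraction
    }
    out
  })
  df <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(df, file.path(out_dir, "entropy_series.csv"), row.names = FALSE)
    write_run_log(out_dir, list(task = "entropy", max_cloud_frac = max_cloud_frac,
                                min_side = min_side, stride = stride,
                                n_bins = n_bins, log_base = log_base),
                  warnings = df$status[df$status != "ok"])
  }
  df
}

#' Per-band divergence matrices over an image manifest
#'
#' Fits a texture signature per image (window selection then per-subband GGD
#' fits), builds the symmetric pairwise divergence matrix per band with
#' chronologically ordered labels, flags anomalous rows (see
#' [flag_anomalies()]), and — when more than one band shares the same period
#' labels — an elementwise-max matrix across bands, representing the overall
#' maximum ecosystem change per period pair. Bands with fewer than two
#' usable signatures are skipped with a warning.
#'
#' @inheritParams run_entropy_series
#' @param wavelet,levels,method signature controls, see [fit_signature()].
#' @param weights per-subband divergence weights, see [kl_signature()].
#' @return List with `per_band` (named list of [divergence_matrix()]),
#'   `anomalies` (named list of [flag_anomalies()] tables), and `max_matrix`
#'   (or NULL). With `out_dir`, each matrix is written as labelled CSV and
#'   PNG heatmap.
#' @export
run_divergence_matrix <- function(manifest, wavelet = "d4", levels = 3L,
                                  method = "mle", weights = NULL,
                                  max_cloud_frac = 0.20, min_side = 128L,
                                  stride = 16L, out_dir = NULL) {
  manifest <- check_manifest(manifest)
  warns <- character(0)
  per_band <- list(); anomalies <- list()
  for (b in sort(unique(manifest$band))) {
    mb <- manifest[manifest$band == b, , drop = FALSE]
    sigs <- list(); labels <- character(0)
    for (i in seq_len(nrow(mb))) {
      mi <- mb[i, ]
      sig <- tryCatch({
        r <- read_band(mi$path, band = mi$band)
        w <- select_window(r, max_cloud_frac = max_cloud_frac,
                           min_side = min_side, stride = stride,
                           season = mi$season, year = mi$year)
        fit_signature(w, wavelet = wavelet, levels = levels, method = method,
                      meta = list(band = mi$band))
      }, texdiv_error = function(cnd) cnd)
      if (inherits(sig, "condition")) {
        warns <- c(warns, sprintf("band %s, %s: %s", b,
                                  period_label(mi$year, mi$season),
                                  conditionMessage(sig)))
      } else {
        sigs <- c(sigs, list(sig))
        labels <- c(labels, period_label(mi$year, mi$season))
      }
    }
    if (length(sigs) < 2L) {
      warns <- c(warns, sprintf("band %s skipped: fewer than 2 usable signatures", b))
      warning(sprintf("band %s skipped: fewer than 2 usable signatures", b))
      next
    }
    m <- divergence_matrix(sigs, weights = weights, labels = labels)
    per_band[[as.character(b)]] <- m
    anomalies[[as.character(b)]] <- flag_anomalies(m)
  }
  max_matrix <- NULL
  if (length(per_band) >= 2L) {
    lab <- lapply(per_band, rownames)
    if (all(vapply(lab, identical, logical(1), lab[[1L]]))) {
      max_matrix <- Reduce(pmax, lapply(per_band, unclass))
      class(max_matrix) <- c("divergence_matrix", class(max_matrix))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (b in names(per_band)) {
      write_divergence_csv(per_band[[b]],
                           file.path(out_dir, sprintf("divergence_band%s.csv", b)))
      plot_divergence(per_band[[b]],
                      file.path(out_dir, sprintf("divergence_band%s.png", b)),
                      main = sprintf("Band %s symmetrized KL divergence", b))
    }
    if (!is.null(max_matrix)) {
      write_divergence_csv(max_matrix, file.path(out_dir, "divergence_max.csv"))
      plot_divergence(max_matrix, file.path(out_dir, "divergence_max.png"),
                      main = "Elementwise-max divergence across bands")
    }
    write_run_log(out_dir, list(task = "matrix", wavelet = wavelet,
                                levels = levels, method = method,
                                max_cloud_frac = max_cloud_frac,
                                min_side = min_side, stride = stride),
                  warnings = warns)
  }
  list(per_band = per_band, anomalies = anomalies, max_matrix = max_matrix)
}

#' Validate image statistics against occurrence-derived diversity
#'
#' Three regressions tie the imagery side to the occurrence side:
#' (i) per-period window entropy against measured mean local richness
#' (alpha); (ii) consecutive-period measured turnover (mean 1 - Jaccard,
#' beta) against the absolute entropy difference `|dH|`; and (iii) the same
#' turnover against the symmetrized signature divergence. The report states
#' which turnover predictor attains the higher R^2.
#'
#' @param entropy named numeric vector of per-period window entropies; names
#'   are period labels like `"2001-dry"`, in chronological order.
#' @param signatures named list of per-period `"texture_signature"` objects
#'   with the same labels.
#' @param grids named list of per-period [grid_occurrences()] results with
#'   the same labels.
#' @param n_boot,seed calibration controls, see [calibrate_linear()].
#' @param out_dir optional output directory for `validation.json`.
#' @return A `"validation_report"`: list with `alpha_fit`, `beta_vs_dH`,
#'   `beta_vs_kl`, `best_beta_predictor` (`"kl"` or `"dH"`), and the
#'   underlying per-period/per-pair tables.
#' @export
run_validation <- function(entropy, signatures, grids, n_boot = 1000L,
                           seed = NULL, out_dir = NULL) {
  labels <- names(entropy)
  if (is.null(labels) || !identical(labels, names(grids)) ||
      !identical(labels, names(signatures))) {
    miss <- unique(c(setdiff(labels, names(grids)), setdiff(names(grids), labels),
                     setdiff(labels, names(signatures))))
    stop(errorCondition(
      paste("period labels of images and occurrences do not match:",
            paste(miss, collapse = ", ")),
      class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
  }
  n <- length(labels)
  mean_alpha <- vapply(grids, function(g) alpha_diversity(g)$mean, numeric(1))
  alpha_fit <- calibrate_linear(unname(entropy), unname(mean_alpha),
                                n_boot = n_boot, seed = seed)
  pairs <- data.frame(from = labels[-n], to = labels[-1L],
                      beta = NA_real_, dH = NA_real_, kl = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n - 1L)) {
    pairs$beta[i] <- beta_turnover(grids[[i]], grids[[i + 1L]])$mean
    pairs$dH[i] <- abs(entropy[[i + 1L]] - entropy[[i]])
    pairs$kl[i] <- kl_signature(signatures[[i]], signatures[[i + 1L]])
  }
  beta_vs_dH <- calibrate_linear(pairs$dH, pairs$beta, n_boot = n_boot, seed = seed)
  beta_vs_kl <- calibrate_linear(pairs$kl, pairs$beta, n_boot = n_boot, seed = seed)
  report <- structure(
    list(alpha_fit = alpha_fit, beta_vs_dH = beta_vs_dH, beta_vs_kl = beta_vs_kl,
         best_beta_predictor = if (beta_vs_kl$r_squared >= beta_vs_dH$r_squared)
           "kl" else "dH",
         per_period = data.frame(label = labels, entropy = unname(entropy),
                                 mean_alpha = unname(mean_alpha)),
         pairs = pairs),
    class = "validation_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(alpha_fit = unclass(alpha_fit), beta_vs_dH = unclass(beta_vs_dH),
           beta_vs_kl = unclass(beta_vs_kl),
           best_beta_predictor = report$best_beta_predictor,
           per_period = report$per_period, pairs = pairs),
      file.path(out_dir, "validation.json"),
      auto_unbox = TRUE, digits = NA, null = "null", dataframe = "rows")
    write_run_log(out_dir, list(task = "validate", n_boot = n_boot, seed = seed))
  }
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation of image statistics against occurrence-derived diversity\n")
  cat(sprintf("  entropy vs mean alpha:  R^2 = %.3f (slope %.3g)\n",
              x$alpha_fit$r_squared, x$alpha_fit$slope))
  cat(sprintf("  |dH| vs measured beta:  R^2 = %.3f\n", x$beta_vs_dH$r_squared))
  cat(sprintf("  KL   vs measured beta:  R^2 = %.3f\n", x$beta_vs_kl$r_squared))
  cat(sprintf("  better turnover predictor: %s\n",
              if (x$best_beta_predictor == "kl") "symmetrized KL divergence"
              else "entropy difference"))
  invisible(x)
}
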