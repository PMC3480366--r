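#' Fit a multiresolution texture signature
#'
#' Decomposes a window into its `3 * levels` detail subbands and fits a
#' generalized Gaussian to each, assuming independence across subbands. The
#' resulting ordered set of `(alpha, beta)` pairs is the texture's signature;
#' the joint density it represents is the product of the per-subband GGDs.
#'
#' Subbands whose coefficients are all equal (e.g. a constant window) cannot
#' identify a shape parameter; such entries are kept in the signature but
#' flagged `degenerate`, and [kl_signature()] refuses signatures containing
#' them. An MLE fit that falls back to moment matching is flagged in the
#' entry's `fallback` field but used normally.
#'
#' @param window an [analysis_window()] or numeric matrix.
#' @param wavelet filter name, see [wavelet_filter()].
#' @param levels decomposition depth (default 3, i.e. 9 subbands).
#' @param method `"mle"` (default) or `"moment"` per-subband estimator.
#' @param meta optional named list of provenance (band, season, year, bounds);
#'   season/year are filled in automatically from an analysis window.
#' @return An object of class `"texture_signature"`: list with `wavelet`,
#'   `levels`, `entries` (one per subband: level, orientation, alpha, beta,
#'   n, method, fallback, degenerate) and `meta`.
#' @export
fit_signature <- function(window, wavelet = "d4", levels = 3L,
                          method = c("mle", "moment"), meta = list()) {
  method <- match.arg(method)
  if (inherits(window, "analysis_window")) {
    meta$season <- meta$season %||% window$season
    meta$year <- meta$year %||% window$year
    meta$bounds <- meta$bounds %||% window$bounds
    meta$cloud_fraction <- meta$cloud_fraction %||% window$cloud_fraction
  }
  subbands <- decompose(window, wavelet, levels)
  entries <- lapply(subbands, function(sb) {
    x <- as.numeric(sb$coef)
    e <- list(level = sb$level, orientation = sb$orientation, n = length(x),
              alpha = NA_real_, beta = NA_real_, method = method,
              fallback = FALSE, degenerate = FALSE)
    fit <- tryCatch(
      if (method == "mle") ggd_fit_mle(x) else ggd_fit_moment(x),
      texdiv_degenerate_error = function(cnd) NULL,
      texdiv_fit_error = function(cnd) NULL)
    if (is.null(fit)) {
      e$degenerate <- TRUE
    } else {
      e$alpha <- fit$alpha
      e$beta <- fit$beta
      e$method <- attr(fit, "method")
      e$fallback <- isTRUE(attr(fit, "fallback"))
    }
    e
  })
  structure(list(wavelet = wavelet, levels = as.integer(levels),
                 entries = entries, meta = meta),
            class = "texture_signature")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.texture_signature <- function(x, ...) {
  cat(sprintf("Texture signature: %s wavelet, %d levels, %d subbands\n",
              x$wavelet, x$levels, length(x$entries)))
  df <- signature_table(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tabulate a signature's per-subband parameters
#'
#' @param sig a `"texture_signature"`.
#' @return A data frame with one row per subband.
#' @export
signature_table <- function(sig) {
  do.call(rbind, lapply(sig$entries, function(e)
    data.frame(level = e$level, orientation = e$orientation, n = e$n,
               alpha = e$alpha, beta = e$beta, method = e$method,
               fallback = e$fallback, degenerate = e$degenerate)))
}

check_compatible <- function(a, b, what = "signatures") {
  ok <- identical(a$wavelet, b$wavelet) && identical(a$levels, b$levels) &&
    length(a$entries) == length(b$entries) &&
    all(vapply(seq_along(a$entries), function(i)
      a$entries[[i]]$level == b$entries[[i]]$level &&
        identical(a$entries[[i]]$orientation, b$entries[[i]]$orientation),
      logical(1)))
  if (!ok)
    stop(errorCondition(paste(what, "have incompatible decomposition structure"),
                        class = c("texdiv_incompatible_error", "texdiv_error",
                                  "error", "condition")))
  invisible(TRUE)
}

#' Symmetrized KL divergence between two texture signatures
#'
#' For each subband `b` with weight `w_b`, adds
#' `w_b * (KL(p_b^a || p_b^b) + KL(p_b^b || p_b^a))` — Kullback's J
#' (discriminant information) summed over subbands. Symmetric, non-negative,
#' and zero exactly when all per-subband parameters agree. Halve the result
#' for the averaged symmetrization.
#'
#' @param a,b compatible `"texture_signature"` objects (same wavelet, levels,
#'   subband order).
#' @param weights optional non-negative per-subband weights, default all 1.
#' @return Non-negative scalar (nats).
#' @export
kl_signature <- function(a, b, weights = NULL) {
  check_compatible(a, b)
  nb <- length(a$entries)
  if (is.null(weights)) weights <- rep(1, nb)
  if (length(weights) != nb || any(weights < 0) || all(weights == 0))
    stop(errorCondition("weights must be one non-negative value per subband, not all zero",
                        class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
  total <- 0
  for (i in seq_len(nb)) {
    if (weights[i] == 0) next
    ea <- a$entries[[i]]; eb <- b$entries[[i]]
    if (ea$degenerate || eb$degenerate)
      stop(errorCondition(
        sprintf("degenerate subband (level %d, %s) cannot enter the divergence",
                ea$level, ea$orientation),
        class = c("texdiv_degenerate_error", "texdiv_error", "error", "condition")))
    pa <- ggd_params(ea$alpha, ea$beta)
    pb <- ggd_params(eb$alpha, eb$beta)
    total <- total + weights[i] * (kl_ggd(pa, pb) + kl_ggd(pb, pa))
  }
  total
}

#' Pairwise divergence matrix over a series of signatures
#'
#' @param signatures list of >= 2 mutually compatible signatures.
#' @param weights per-subband weights passed to [kl_signature()].
#' @param labels optional period labels (default taken from each signature's
#'   `meta$year`/`meta$season`, else positional).
#' @return A `"divergence_matrix"`: symmetric numeric matrix with zero
#'   diagonal, dimnames set to the labels.
#' @export
divergence_matrix <- function(signatures, weights = NULL, labels = NULL) {
  n <- length(signatures)
  if (n < 2L)
    stop(errorCondition("need at least two signatures",
                        class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
  for (i in seq_len(n)[-1L]) {
    tryCatch(check_compatible(signatures[[1L]], signatures[[i]]),
             texdiv_incompatible_error = function(cnd)
               stop(errorCondition(
                 sprintf("signature %d is incompatible with signature 1", i),
                 class = c("texdiv_incompatible_error", "texdiv_error",
                           "error", "condition"))))
  }
  if (is.null(labels)) {
    labels <- vapply(seq_len(n), function(i) {
      m <- signatures[[i]]$meta
      if (!is.null(m$year) && !is.null(m$season)) paste0(m$year, "-", m$season)
      else sprintf("sig%02d", i)
    }, character(1))
  }
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- kl_signature(signatures[[i]], signatures[[j]], weights)
  }
  class(m) <- c("divergence_matrix", class(m))
  m
}

#' Flag anomalous periods in a divergence matrix
#'
#' A row whose mean off-diagonal divergence exceeds `median + 3 * MAD` of the
#' row means is flagged as suspect — the pattern a heavily clouded acquisition
#' leaves behind (a bright row/column crossing the whole matrix), usable as an
#' a-posteriori indicator of images to exclude.
#'
#' @param m a [divergence_matrix()].
#' @return Data frame with `label`, `mean_divergence`, `suspect`.
#' @export
flag_anomalies <- function(m) {
  n <- nrow(m)
  means <- vapply(seq_len(n), function(i) mean(m[i, -i]), numeric(1))
  thr <- stats::median(means) + 3 * stats::mad(means)
  data.frame(label = rownames(m), mean_divergence = means,
             suspect = means > thr, row.names = NULL)
}

# ---- serialization ---------------------------------------------------------

#' Read and write texture signatures as JSON
#'
#' @param sig a `"texture_signature"`.
#' @param path file path.
#' @return `write_signature` returns `path` invisibly; `read_signature`
#'   returns the signature.
#' @export
write_signature <- function(sig, path) {
  obj <- list(wavelet = sig$wavelet, levels = sig$levels,
              entries = lapply(sig$entries, function(e) e[c(
                "level", "orientation", "n", "alpha", "beta",
                "method", "fallback", "degenerate")]),
              meta = sig$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path)
  entries <- lapply(obj$entries, function(e) list(
    level = as.integer(e$level), orientation = e$orientation,
    n = as.integer(e$n),
    alpha = if (is.null(e$alpha)) NA_real_ else as.numeric(e$alpha),
    beta = if (is.null(e$beta)) NA_real_ else as.numeric(e$beta),
    method = e$method, fallback = isTRUE(e$fallback),
    degenerate = isTRUE(e$degenerate)))
  structure(list(wavelet = obj$wavelet, levels = as.integer(obj$levels),
                 entries = entries, meta = obj$meta),
            class = "texture_signature")
}

#' Read and write divergence matrices as labelled CSV
#'
#' The CSV carries the period labels as both header row and first column.
#'
#' @param m a [divergence_matrix()].
#' @param path file path.
#' @export
write_divergence_csv <- function(m, path) {
  df <- data.frame(label = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_divergence_csv
#' @export
read_divergence_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  class(m) <- c("divergence_matrix", class(m))
  m
}

#' Heatmap of a divergence matrix
#'
#' Renders the lower triangle plus diagonal (the upper triangle is left
#' blank, the matrix being symmetric) with a blue-to-red colormap: the bluer
#' the cell the lower, the redder the higher the divergence.
#'
#' @param m a [divergence_matrix()].
#' @param path output PNG path.
#' @param main plot title.
#' @export
plot_divergence <- function(m, path = NULL, main = "Pairwise symmetrized KL divergence") {
  v <- unclass(m)
  v[upper.tri(v)] <- NA
  n <- nrow(v)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(64)
  if (!is.null(path)) {
    grDevices::png(path, width = 720, height = 720)
    on.exit(grDevices::dev.off())
  }
  graphics::par(mar = c(6, 6, 3, 1))
  graphics::image(seq_len(n), seq_len(n), t(v[n:1, , drop = FALSE]),
                  col = pal, axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::axis(1, at = seq_len(n), labels = colnames(v), las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(v)), las = 2, cex.axis = 0.7)
  invisible(path)
}
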