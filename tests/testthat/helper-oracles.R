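# Independent numerical oracles used across the suite. These deliberately
# avoid the closed forms under test: divergences and entropies are obtained
# by adaptive quadrature, window search by naive scanning, and turnover by a
# direct set-process simulation.

# adaptive quadrature of the directed KL integral between two GGDs
numeric_kl <- function(p1, p2) {
  f <- function(x) ggd_pdf(x, p1) * (ggd_logpdf(x, p1) - ggd_logpdf(x, p2))
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-12, abs.tol = 1e-13,
                   subdivisions = 2000L)$value
}

# adaptive quadrature of the differential entropy of a GGD
numeric_entropy <- function(p) {
  f <- function(x) ggd_pdf(x, p) * ggd_logpdf(x, p)
  -stats::integrate(f, -Inf, Inf, rel.tol = 1e-12, abs.tol = 1e-13,
                    subdivisions = 2000L)$value
}

# the standard (alpha, beta) evaluation grid: 20 parameter points
ggd_grid <- function() {
  expand.grid(alpha = c(0.5, 1, 2, 4), beta = c(0.7, 1, 1.5, 2, 3))
}

# 2-D composite-Simpson integral of the directed KL between two independent
# 2-subband product densities p = p1(x) p2(y), q = q1(x) q2(y)
numeric_kl_2d <- function(p1, p2, q1, q2, half_width = 60, n = 3000L) {
  stopifnot(n %% 2L == 0L)
  xs <- seq(-half_width, half_width, length.out = n + 1L)
  hw <- diff(xs[1:2])
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1) * hw / 3
  lp1 <- ggd_logpdf(xs, p1); lp2 <- ggd_logpdf(xs, p2)
  lq1 <- ggd_logpdf(xs, q1); lq2 <- ggd_logpdf(xs, q2)
  lp <- outer(lp1, lp2, "+")
  lq <- outer(lq1, lq2, "+")
  sum(outer(w, w) * exp(lp) * (lp - lq))
}

# exhaustive rectangle search by 1-D moving sums (independent of the
# integral-image route used by select_window); returns 1-based
# (area, r0, c0, h, w) or NULL
brute_window <- function(mask, thr, min_side) {
  H <- nrow(mask); W <- ncol(mask)
  best <- NULL
  better <- function(cand, best) {
    is.null(best) || cand[1] > best[1] ||
      (cand[1] == best[1] && (cand[2] < best[2] ||
        (cand[2] == best[2] && (cand[3] < best[3] ||
          (cand[3] == best[3] && (cand[4] < best[4] ||
            (cand[4] == best[4] && cand[5] < best[5])))))))
  }
  m <- mask * 1
  for (h in min_side:H) {
    # vertical moving sums over h rows
    cs <- apply(m, 2, function(col) {
      s <- stats::filter(col, rep(1, h), sides = 1)
      s[h:H]
    })
    cs <- matrix(cs, nrow = H - h + 1L)
    for (w in min_side:W) {
      rs <- t(apply(cs, 1, function(rw) {
        s <- stats::filter(rw, rep(1, w), sides = 1)
        s[w:W]
      }))
      rs <- matrix(rs, nrow = H - h + 1L)
      hit <- which(rs / (h * w) < thr, arr.ind = TRUE)
      if (nrow(hit) == 0L) next
      o <- order(hit[, 1L], hit[, 2L])[1L]
      cand <- c(h * w, hit[o, 1L], hit[o, 2L], h, w)
      if (better(cand, best)) best <- cand
    }
  }
  best
}

# naive quadruple-loop window search (tiny fixtures only)
brute_window_naive <- function(mask, thr, min_side) {
  best <- NULL
  for (h in min_side:nrow(mask)) for (w in min_side:ncol(mask))
    for (r0 in 1:(nrow(mask) - h + 1L)) for (c0 in 1:(ncol(mask) - w + 1L)) {
      if (mean(mask[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]) < thr) {
        cand <- c(h * w, r0, c0, h, w)
        if (is.null(best) || cand[1] > best[1] ||
            (cand[1] == best[1] && (cand[2] < best[2] ||
              (cand[2] == best[2] && (cand[3] < best[3] ||
                (cand[3] == best[3] && (cand[4] < best[4] ||
                  (cand[4] == best[4] && cand[5] < best[5]))))))))
          best <- cand
      }
    }
  best
}

# direct simulation of the species-replacement process: mean Jaccard
# distance between consecutive communities, bypassing records and grids
brute_turnover <- function(tau, richness, pool_size, n_rep, seed) {
  set.seed(seed)
  pool <- seq_len(pool_size)
  mean(vapply(seq_len(n_rep), function(i) {
    c1 <- sample(pool, richness)
    gone <- stats::runif(richness) < tau
    c2 <- c(c1[!gone], sample(setdiff(pool, c1), sum(gone)))
    1 - length(intersect(c1, c2)) / length(union(c1, c2))
  }, numeric(1)))
}

# build a texture signature object directly from known parameters
make_signature <- function(params, levels = 1L, wavelet = "d4",
                           orientations = NULL) {
  n <- length(params)
  if (is.null(orientations))
    orientations <- rep(c("horizontal", "vertical", "diagonal"), length.out = n)
  entries <- lapply(seq_len(n), function(i) {
    p <- params[[i]]
    list(level = ((i - 1L) %/% 3L) + 1L, orientation = orientations[i],
         n = 0L, alpha = p$alpha, beta = p$beta, method = "manual",
         fallback = FALSE, degenerate = FALSE)
  })
  structure(list(wavelet = wavelet, levels = as.integer(levels),
                 entries = entries, meta = list()),
            class = "texture_signature")
}

# nine-subband parameter set with a common shape, alphas decaying by level
subband_params_for <- function(beta, base_alpha = 8) {
  lapply(rep(c(1, 1, 0.75), times = 3) * base_alpha *
           rep(c(1, 1.6, 2.5), each = 3),
         function(a) ggd_params(a, beta))
}

# 2-level texture series whose consecutive-window divergence (after
# standardizing each window to unit variance) is exactly amp * beta:
# level-1 subband scales drift up and level-2 down by a common log-step,
# solved per pair by root finding against the closed-form model divergence
drifted_texture_series <- function(betas, amp = 3) {
  base <- subband_params_for(2)[1:6]
  frac <- c(rep(1 / 4, 3), rep(1 / 16, 3))   # coefficient share per subband
  sig_tot <- function(u) {
    sqrt(sum(frac * vapply(seq_len(6), function(k)
      (ggd_sigma(base[[k]]) * (if (k <= 3) exp(u) else exp(-u)))^2,
      numeric(1))))
  }
  jdiv <- function(u1, u2) {
    s1 <- sig_tot(u1); s2 <- sig_tot(u2)
    tot <- 0
    for (k in seq_len(6)) {
      m1 <- if (k <= 3) exp(u1) else exp(-u1)
      m2 <- if (k <= 3) exp(u2) else exp(-u2)
      p1 <- ggd_params(base[[k]]$alpha * m1 / s1, 2)
      p2 <- ggd_params(base[[k]]$alpha * m2 / s2, 2)
      tot <- tot + kl_ggd(p1, p2) + kl_ggd(p2, p1)
    }
    tot
  }
  u <- 0
  for (b in betas) {
    u0 <- u[length(u)]
    u <- c(u, if (b == 0) u0 else
      stats::uniroot(function(x) jdiv(u0, x) - amp * b, c(u0, u0 + 2))$root)
  }
  params <- lapply(u, function(ui) {
    mult <- c(rep(exp(ui), 3), rep(exp(-ui), 3))
    lapply(seq_len(6), function(k)
      ggd_params(base[[k]]$alpha * mult[k], base[[k]]$beta))
  })
  list(u = u, params = params)
}
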