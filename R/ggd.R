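#' Generalized Gaussian density parameters
#'
#' Constructs and validates the two-parameter zero-mean generalized Gaussian
#' density (GGD) used to model wavelet detail coefficients,
#' \deqn{f(x) = \frac{\beta}{2\alpha\Gamma(1/\beta)}
#'       \exp\{-(|x|/\alpha)^\beta\},}
#' where `alpha` is the distribution width factor and `beta` the dimensionless
#' shape parameter. `beta = 2` gives a Gaussian, `beta = 1` a Laplacian, and
#' `beta -> Inf` a uniform density on `(-alpha, alpha)`. The location (mean) is
#' fixed at zero: detail coefficients are outputs of high-pass filters.
#'
#' @param alpha positive real; width factor, same units as the coefficients.
#' @param beta positive real; shape parameter.
#' @return An object of class `"ggd"` with fields `alpha` and `beta`.
#' @examples
#' p <- ggd_params(sqrt(2), 2)   # standard Gaussian
#' ggd_sigma(p)                  # 1
#' @export
ggd_params <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 ||
      !is.numeric(beta)  || length(beta)  != 1L || !is.finite(beta)  || beta  <= 0) {
    stop(errorCondition("GGD parameters must be finite positive scalars (alpha > 0, beta > 0)",
                        class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)), class = "ggd")
}

#' @export
print.ggd <- function(x, ...) {
  cat(sprintf("Generalized Gaussian: alpha = %.6g, beta = %.6g (sigma = %.6g)\n",
              x$alpha, x$beta, ggd_sigma(x)))
  invisible(x)
}

as_ggd <- function(p) {
  if (inherits(p, "ggd")) return(p)
  if (is.list(p) && all(c("alpha", "beta") %in% names(p))) return(ggd_params(p$alpha, p$beta))
  if (is.numeric(p) && length(p) == 2L) return(ggd_params(p[[1L]], p[[2L]]))
  stop(errorCondition("not interpretable as GGD parameters",
                      class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
}

#' GGD probability density
#'
#' @param x numeric vector of evaluation points (finite).
#' @param p GGD parameters from [ggd_params()].
#' @return Density values, same length as `x`.
#' @export
ggd_pdf <- function(x, p) {
  p <- as_ggd(p)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(errorCondition("x must be finite numeric",
                        class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
  # log-space normalization: Gamma(1/beta) overflows for small beta
  exp(ggd_logpdf(x, p))
}

#' @rdname ggd_pdf
#' @export
ggd_logpdf <- function(x, p) {
  p <- as_ggd(p)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(errorCondition("x must be finite numeric",
                        class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
  # log-space normalization: Gamma(1/beta) overflows for small beta
  log(p$beta) - log(2 * p$alpha) - lgamma(1 / p$beta) - (abs(x) / p$alpha)^p$beta
}

#' GGD standard deviation
#'
#' \eqn{\sigma = \alpha \sqrt{\Gamma(3/\beta)/\Gamma(1/\beta)}}.
#'
#' @inheritParams ggd_pdf
#' @return Positive scalar.
#' @export
ggd_sigma <- function(p) {
  p <- as_ggd(p)
  p$alpha * exp(0.5 * (lgamma(3 / p$beta) - lgamma(1 / p$beta)))
}

#' GGD differential entropy (nats)
#'
#' Closed form \eqn{H = 1/\beta - \ln\{\beta/(2\alpha\Gamma(1/\beta))\}}.
#' Doubling `alpha` adds `log(2)` for any shape.
#'
#' @inheritParams ggd_pdf
#' @return Entropy in nats.
#' @export
ggd_entropy <- function(p) {
  p <- as_ggd(p)
  1 / p$beta - (log(p$beta) - log(2 * p$alpha) - lgamma(1 / p$beta))
}

#' Draw i.i.d. samples from a GGD
#'
#' Exact sampler: `x = sign * alpha * G^(1/beta)` with `G ~ Gamma(shape =
#' 1/beta, scale = 1)` and an independent random sign; no rejection step.
#'
#' @inheritParams ggd_pdf
#' @param n number of draws.
#' @param seed optional integer; if given, draws are reproducible and the
#'   caller's RNG state is left untouched.
#' @return Numeric vector of length `n`.
#' @export
ggd_sample <- function(p, n, seed = NULL) {
  p <- as_ggd(p)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop(errorCondition("n must be a positive integer",
                        class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
  n <- as.integer(n)
  with_seed(seed, {
    g <- stats::rgamma(n, shape = 1 / p$beta, scale = 1)
    s <- sample(c(-1, 1), n, replace = TRUE)
    s * p$alpha * g^(1 / p$beta)
  })
}

# Run expr with a private, seeded RNG stream; restore caller state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Closed-form Kullback-Leibler divergence between two GGDs
#'
#' Directed divergence \eqn{D(p_1 \| p_2) = \int p_1 \ln(p_1/p_2)} in nats:
#' \deqn{\ln\frac{\beta_1 \alpha_2 \Gamma(1/\beta_2)}
#'               {\beta_2 \alpha_1 \Gamma(1/\beta_1)}
#'   + \left(\frac{\alpha_1}{\alpha_2}\right)^{\beta_2}
#'     \frac{\Gamma((\beta_2+1)/\beta_1)}{\Gamma(1/\beta_1)}
#'   - \frac{1}{\beta_1}.}
#' Not symmetric in its arguments; see [kl_signature()] for the symmetrized
#' multi-subband form. All Gamma ratios are computed in log space.
#'
#' @param p1,p2 GGD parameters from [ggd_params()].
#' @return Non-negative scalar (nats); zero iff `p1` equals `p2`.
#' @examples
#' kl_ggd(ggd_params(sqrt(2), 2), ggd_params(2 * sqrt(2), 2))  # log(2) + 1/8 - 1/2
#' @export
kl_ggd <- function(p1, p2) {
  p1 <- as_ggd(p1); p2 <- as_ggd(p2)
  a1 <- p1$alpha; b1 <- p1$beta
  a2 <- p2$alpha; b2 <- p2$beta
  if (a1 == a2 && b1 == b2) return(0)
  log(b1 / b2) + log(a2 / a1) + lgamma(1 / b2) - lgamma(1 / b1) +
    exp(b2 * log(a1 / a2) + lgamma((b2 + 1) / b1) - lgamma(1 / b1)) -
    1 / b1
}

# log-likelihood of a GGD at samples x (used to compare fits)
ggd_loglik <- function(x, p) {
  p <- as_ggd(p)
  n <- length(x)
  n * (log(p$beta) - log(2 * p$alpha) - lgamma(1 / p$beta)) -
    sum((abs(x) / p$alpha)^p$beta)
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("texdiv_degenerate_error", "texdiv_error",
                                     "error", "condition")))
}

check_fit_input <- function(x, min_n = 64L) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(errorCondition("samples must be finite numeric",
                        class = c("texdiv_domain_error", "texdiv_error", "error", "condition")))
  if (length(x) < min_n)
    stop_degenerate(sprintf("need at least %d samples for a stable GGD fit", min_n))
  if (stats::sd(x) == 0)
    stop_degenerate("constant samples: GGD shape is unidentifiable")
  invisible(x)
}

# r(beta) = Gamma(2/b)^2 / (Gamma(1/b) Gamma(3/b)); strictly increasing,
# r -> 0 as b -> 0 and r -> 3/4 (uniform limit) as b -> Inf.
ggd_moment_ratio <- function(beta) {
  exp(2 * lgamma(2 / beta) - lgamma(1 / beta) - lgamma(3 / beta))
}

# Solve f(beta) = 0 on the standard bracket [0.15, 10], expanding both ends
# geometrically (factor 2, up to 4 times) if the root lies outside.
solve_beta <- function(f, lower = 0.15, upper = 10) {
  fl <- f(lower); fu <- f(upper)
  k <- 0L
  while (fl * fu > 0 && k < 4L) {
    lower <- lower / 2; upper <- upper * 2
    fl <- f(lower); fu <- f(upper)
    k <- k + 1L
  }
  if (!is.finite(fl) || !is.finite(fu) || fl * fu > 0) return(NULL)
  stats::uniroot(f, c(lower, upper), tol = 1e-10)$root
}

#' Moment-matching GGD fit
#'
#' Matches the ratio \eqn{r(\beta) = \Gamma(2/\beta)^2 /
#' \{\Gamma(1/\beta)\Gamma(3/\beta)\} = (E|x|)^2 / E(x^2)} by 1-D root finding,
#' then sets `alpha = sd(x) * sqrt(Gamma(1/beta)/Gamma(3/beta))`.
#'
#' @param x numeric sample of detail coefficients (length >= 64, not constant).
#' @return A `"ggd"` object with attribute `method = "moment"`.
#' @export
ggd_fit_moment <- function(x) {
  check_fit_input(x)
  r <- mean(abs(x))^2 / mean(x^2)
  if (r <= 0 || r >= 1)
    stop(errorCondition(sprintf("moment ratio %.4f outside attainable range (0, 1)", r),
                        class = c("texdiv_fit_error", "texdiv_error", "error", "condition")))
  beta <- solve_beta(function(b) ggd_moment_ratio(b) - r)
  if (is.null(beta))
    stop(errorCondition("moment-ratio equation has no root in the expanded shape bracket",
                        class = c("texdiv_fit_error", "texdiv_error", "error", "condition")))
  alpha <- stats::sd(x) * exp(0.5 * (lgamma(1 / beta) - lgamma(3 / beta)))
  out <- ggd_params(alpha, beta)
  attr(out, "method") <- "moment"
  out
}

#' Maximum-likelihood GGD fit
#'
#' Profiles the width out of the likelihood, `alpha(beta) = ((beta/n) *
#' sum(|x|^beta))^(1/beta)`, and solves the resulting 1-D score equation in
#' `beta` by bracketed root finding, initialized from [ggd_fit_moment()]. If
#' the score has no bracketed root after geometric bracket expansion the
#' moment estimate is returned with attribute `fallback = TRUE` so downstream
#' signatures can record it.
#'
#' @inheritParams ggd_fit_moment
#' @param init optional `"ggd"` starting value (defaults to the moment fit).
#' @return A `"ggd"` object with attributes `method` ("mle" or "moment") and
#'   `fallback` (logical).
#' @export
ggd_fit_mle <- function(x, init = NULL) {
  check_fit_input(x)
  n <- length(x)
  ax <- abs(x)
  pos <- ax > 0
  lax <- numeric(n)
  lax[pos] <- log(ax[pos])
  score <- function(b) {
    w <- ax^b                       # zero samples contribute 0 to both sums
    s1 <- sum(w)
    s2 <- sum(w * lax)
    1 + digamma(1 / b) / b - s2 / s1 + log((b / n) * s1) / b
  }
  moment <- tryCatch(if (is.null(init)) ggd_fit_moment(x) else as_ggd(init),
                     texdiv_fit_error = function(e) NULL)
  # bracket around the initial shape first, then fall back to the full bracket
  beta <- NULL
  if (!is.null(moment)) {
    b0 <- moment$beta
    beta <- solve_beta(score, lower = max(b0 / 4, 0.05), upper = min(b0 * 4, 40))
  }
  if (is.null(beta)) beta <- solve_beta(score)
  if (is.null(beta)) {
    if (is.null(moment))
      stop(errorCondition("GGD likelihood maximization failed and no moment fallback exists",
                          class = c("texdiv_fit_error", "texdiv_error", "error", "condition")))
    out <- moment
    attr(out, "method") <- "moment"
    attr(out, "fallback") <- TRUE
    return(out)
  }
  alpha <- ((beta / n) * sum(ax^beta))^(1 / beta)
  out <- ggd_params(alpha, beta)
  attr(out, "method") <- "mle"
  attr(out, "fallback") <- FALSE
  out
}
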