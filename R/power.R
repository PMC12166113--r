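#' Specify the distribution of the segmented covariate
#'
#' Power and sample-size computations need covariate values at every
#' candidate sample size, so the covariate is described by a distribution
#' whose quantile function generates the values: `"equispaced"` gives
#' `z_i = i/n`; the distribution kinds evaluate the named quantile function
#' at the mid-probabilities `p_i = (i - 0.5)/n` (which avoids the infinite
#' extreme quantiles of unbounded families); `"explicit"` passes a fixed
#' numeric vector through.
#'
#' @param kind one of `"equispaced"`, `"normal"`, `"uniform"`,
#'   `"exponential"`, `"beta"`, `"explicit"`.
#' @param ... distribution parameters: `mean`, `sd` (normal); `min`, `max`
#'   (uniform); `rate` (exponential); `shape1`, `shape2` (beta);
#'   `values` (explicit).
#' @return An object of class `"covariate_spec"`.
#' @export
covariate_spec <- function(kind = c("equispaced", "normal", "uniform",
                                    "exponential", "beta", "explicit"),
                           ...) {
  kind <- match.arg(kind)
  params <- list(...)
  defaults <- switch(kind,
    equispaced  = list(),
    normal      = list(mean = 0, sd = 1),
    uniform     = list(min = 0, max = 1),
    exponential = list(rate = 1),
    beta        = list(shape1 = 1, shape2 = 1),
    explicit    = list(values = NULL))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for kind '", kind, "': ",
         paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, params)
  if (kind == "normal" && params$sd <= 0) stop("'sd' must be positive")
  if (kind == "uniform" && params$max <= params$min)
    stop("'max' must exceed 'min'")
  if (kind == "exponential" && params$rate <= 0) stop("'rate' must be positive")
  if (kind == "beta" && (params$shape1 <= 0 || params$shape2 <= 0))
    stop("beta shapes must be positive")
  if (kind == "explicit") {
    if (is.null(params$values) || anyNA(params$values) ||
        any(!is.finite(params$values)))
      stop("explicit covariate values must be a finite numeric vector")
    params$values <- as.numeric(params$values)
  }
  structure(list(kind = kind, params = params), class = "covariate_spec")
}

#' Realize a covariate vector from its specification
#'
#' @param spec a [covariate_spec()].
#' @param n sample size (`>= 4`).
#' @return Sorted numeric vector of length `n`.
#' @export
covariate_from_spec <- function(spec, n) {
  stopifnot(inherits(spec, "covariate_spec"))
  n <- as.integer(n)
  if (n < 4L) stop("'n' must be at least 4")
  p <- (seq_len(n) - 0.5) / n
  pr <- spec$params
  z <- switch(spec$kind,
    equispaced  = seq_len(n) / n,
    normal      = stats::qnorm(p, pr$mean, pr$sd),
    uniform     = stats::qunif(p, pr$min, pr$max),
    exponential = stats::qexp(p, pr$rate),
    beta        = stats::qbeta(p, pr$shape1, pr$shape2),
    explicit    = {
      if (length(pr$values) != n)
        stop("explicit covariate has length ", length(pr$values),
             " but n = ", n)
      pr$values
    })
  sort(z)
}

#' Power-analysis specification for the segmented changepoint test
#'
#' Collects the quantities that determine the sampling distribution of the
#' pseudo-score statistic under a broken-line alternative: the changepoint
#' `psi` (in covariate units), the slope difference `delta`, the response
#' standard deviation `sigma`, the sample size `n` (omit it when solving
#' for the sample size), the level and alternative, the covariate
#' specification and the candidate-grid size `K`.
#'
#' @param psi changepoint, strictly inside the covariate range.
#' @param delta slope difference under the alternative.
#' @param sigma response standard deviation (> 0).
#' @param n sample size (`NULL` when solving for it).
#' @param alpha level (default 0.01).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param covariate a [covariate_spec()]; default equispaced on (0, 1].
#' @param K candidate-grid size for the averaged basis (default 10).
#' @return An object of class `"power_spec"`.
#' @export
power_spec <- function(psi, delta, sigma, n = NULL, alpha = 0.01,
                       alternative = c("two.sided", "greater", "less"),
                       covariate = covariate_spec("equispaced"), K = 10L) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(covariate, "covariate_spec"))
  if (sigma <= 0) stop("'sigma' must be positive")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (!is.null(n) && n < 4) stop("'n' must be at least 4")
  structure(list(psi = psi, delta = delta, sigma = sigma,
                 n = if (is.null(n)) NULL else as.integer(n),
                 alpha = alpha, alternative = alternative,
                 covariate = covariate, K = as.integer(K)),
            class = "power_spec")
}

#' Mean of the pseudo-score statistic under the segmented alternative
#'
#' Under the broken-line alternative `y = X beta + delta (z - psi)_+ + e`
#' the statistic keeps unit variance and normal shape but acquires mean
#' \deqn{E_1[s_0] = \delta\,\bar\varphi^T(I - A)(z - \psi)_+ \; / \;
#'       \{\sigma^2 \bar\varphi^T(I - A)\bar\varphi\}^{1/2},}
#' where the null design is the straight-line fit `X = [1, z]` (the linear
#' component of the broken line belongs to the null) and \eqn{\bar\varphi}
#' is the ramp basis averaged over the default candidate grid.
#'
#' @param spec a [power_spec()] with `n` present.
#' @param n optional override of `spec$n`.
#' @return The alternative mean `E1`; its sign equals `sign(delta)`.
#' @export
expected_s0_h1 <- function(spec, n = spec$n) {
  stopifnot(inherits(spec, "power_spec"))
  if (is.null(n)) stop("sample size 'n' is required")
  z <- covariate_from_spec(spec$covariate, n)
  if (spec$psi <= min(z) || spec$psi >= max(z))
    stop("the changepoint 'psi' must lie strictly inside the covariate range [",
         signif(min(z), 4), ", ", signif(max(z), 4), "]")
  X <- cbind(1, z)
  phibar <- build_phibar(z, phi_spec("segmented", default_psi_grid(z, spec$K)))
  rphi <- qr.resid(qr(X), phibar)
  quad <- sum(rphi^2)
  if (quad <= 1e-12 * max(sum(phibar^2), 1))
    stop("degenerate averaged basis: the candidate grid spans no curvature ",
         "(psi too close to the boundary, or K too small)")
  spec$delta * sum(rphi * pmax(z - spec$psi, 0)) /
    (spec$sigma * sqrt(quad))
}

#' Analytic power of the pseudo-score changepoint test
#'
#' With the alternative mean `E1` from [expected_s0_h1()] and the standard
#' normal reference, the power is
#' `pnorm(-z_{1-a/2} - E1) + 1 - pnorm(z_{1-a/2} - E1)` (two-sided) or the
#' corresponding single tail.  At `delta = 0` the power equals the level
#' exactly.
#'
#' @param spec a [power_spec()] with `n` present.
#' @param n optional override of `spec$n`.
#' @return Power in `(0, 1)`.
#' @examples
#' sp <- power_spec(psi = 0.6, delta = 0.5, sigma = 0.1, n = 100)
#' seg_power(sp)   # 0.749
#' @export
seg_power <- function(spec, n = spec$n) {
  stopifnot(inherits(spec, "power_spec"))
  e1 <- expected_s0_h1(spec, n)
  a <- spec$alpha
  switch(spec$alternative,
    two.sided = stats::pnorm(-stats::qnorm(1 - a / 2) - e1) +
                stats::pnorm(stats::qnorm(1 - a / 2) - e1,
                             lower.tail = FALSE),
    greater   = stats::pnorm(stats::qnorm(1 - a) - e1, lower.tail = FALSE),
    less      = stats::pnorm(-stats::qnorm(1 - a) - e1))
}

#' Sample size for a target power
#'
#' Smallest integer `n` whose analytic power reaches the target, found by
#' a doubling bracket followed by bisection on the integer grid; the
#' covariate is regenerated from its specification at every candidate `n`.
#'
#' @param spec a [power_spec()]; any `n` it carries is ignored.
#' @param target_power desired power, in `(alpha, 1)`.
#' @param n_max search ceiling (default 1e6).
#' @return The minimal sample size (integer).
#' @export
seg_sample_size <- function(spec, target_power, n_max = 1e6L) {
  stopifnot(inherits(spec, "power_spec"))
  if (target_power <= spec$alpha || target_power >= 1)
    stop("'target_power' must lie in (alpha, 1)")
  if (spec$covariate$kind == "explicit")
    stop("cannot solve for the sample size with an explicit covariate ",
         "vector; describe the covariate by a distribution")
  pw <- function(n) tryCatch(seg_power(spec, n), error = function(e) 0)
  lo <- 4L; hi <- 8L
  while (pw(hi) < target_power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > n_max)
      stop("target power not reachable below n = ", n_max)
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

#' Fit the broken-line (segmented) regression by profiling the changepoint
#'
#' For each candidate changepoint on the profile grid (midpoints between
#' consecutive distinct covariate values within the 10--90 percentile
#' band), ordinary least squares of `y` on `[1, z, (z - psi)_+]` is
#' computed; the changepoint estimate minimizes the residual sum of
#' squares (smallest candidate on ties).  The covariance of
#' `(delta_hat, psi_hat)` comes from the working linear model at the
#' optimum augmented with the changepoint-derivative column
#' `-delta_hat * I(z > psi_hat)`.
#'
#' A near-flat profile (no evidence of curvature, e.g. `delta = 0` truth)
#' triggers a warning and a widest-uncertainty covariance: the variance of
#' `psi_hat` is replaced by the squared half-range of the covariate.
#'
#' @param series a gaussian [cp_series()] with `n >= 8`.
#' @return An object of class `"segmented_fit"`: `delta_hat`, `psi_hat`,
#'   `cov` (2x2, rows/cols `delta`, `psi`), `sigma_hat`, `n`, `z`,
#'   `coefficients` of the working fit, `flat_profile` flag.
#' @export
fit_segmented <- function(series) {
  stopifnot(inherits(series, "cp_series"))
  if (series$family != "gaussian")
    stop("segmented profile fitting is implemented for the gaussian family")
  n <- series$n
  if (n < 8L) stop("need at least 8 observations to profile a breakpoint")
  y <- series$y; z <- series$z
  # straight-line null design: intercept + z (+ any extra columns)
  X <- series$X
  if (max(abs(qr.resid(qr(X), z))) > 1e-8 * max(abs(z), 1)) X <- cbind(X, z = z)
  grid <- segmented_profile_grid(z)
  rss <- vapply(grid, function(pk) {
    sum(qr.resid(qr(cbind(X, pmax(z - pk, 0))), y)^2)
  }, numeric(1))
  rss0 <- sum(qr.resid(qr(X), y)^2)
  k <- which.min(rss)
  psi_hat <- grid[k]
  D <- cbind(X, U = pmax(z - psi_hat, 0))
  fit <- stats::lm.fit(D, y)
  delta_hat <- unname(fit$coefficients["U"])
  p <- ncol(D)
  sigma2_hat <- sum(fit$residuals^2) / max(n - p - 1L, 1L)
  flat <- (rss0 - min(rss)) <= 1e-8 * max(rss0, 1e-12)

  V <- -delta_hat * as.numeric(z > psi_hat)
  Dv <- cbind(D, V = V)
  qrv <- qr(Dv)
  cov <- matrix(NA_real_, 2, 2, dimnames = list(c("delta", "psi"),
                                                c("delta", "psi")))
  if (!flat && qrv$rank == ncol(Dv)) {
    XtXinv <- chol2inv(qr.R(qrv))
    vc <- sigma2_hat * XtXinv
    iU <- ncol(Dv) - 1L; iV <- ncol(Dv)
    cov[] <- vc[c(iU, iV), c(iU, iV)]
  } else {
    if (!flat) flat <- TRUE
    warning("flat (or degenerate) residual profile: changepoint location is ",
            "weakly identified; reporting widest-uncertainty covariance")
    vc_d <- tryCatch({
      sigma2_hat * chol2inv(qr.R(qr(D)))[p, p]
    }, error = function(e) stats::var(y))
    cov[] <- diag(c(vc_d, (diff(range(z)) / 2)^2))
  }
  structure(list(delta_hat = delta_hat, psi_hat = psi_hat, cov = cov,
                 sigma_hat = sqrt(sigma2_hat), n = n, z = z,
                 coefficients = fit$coefficients, flat_profile = flat),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("\n\tBroken-line fit (profiled changepoint)\n\n")
  cat(sprintf("delta_hat = %.4f (SE %.4f), psi_hat = %.4f (SE %.4f)\n",
              x$delta_hat, sqrt(x$cov["delta", "delta"]),
              x$psi_hat, sqrt(x$cov["psi", "psi"])))
  cat(sprintf("sigma_hat = %.4f, n = %d%s\n", x$sigma_hat, x$n,
              if (x$flat_profile) " [flat profile]" else ""))
  invisible(x)
}

#' Post-experimental power with a simulation-based confidence interval
#'
#' Plugs the fitted `(delta_hat, psi_hat, sigma_hat)` into the analytic
#' power formula using the observed covariate values.  Optionally, a 95%
#' interval for the power is built from `ci_reps` draws of
#' `(delta, psi)` from the bivariate normal centred at the estimates with
#' the fitted covariance; draws whose changepoint falls outside the open
#' covariate range are redrawn (at most 10 attempts, then clamped just
#' inside the range).
#'
#' @param fit a [fit_segmented()] result.
#' @param alpha level (default 0.01).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param ci logical: compute the interval?
#' @param ci_reps number of parameter draws (default 500).
#' @param ci_level interval level (default 0.95).
#' @param K candidate-grid size (default 10).
#' @param seed optional seed for the draws.
#' @return A list of class `"postexp_power"`: `power`, and when
#'   `ci = TRUE` also `ci` (length 2), `ci_level`, `ci_reps`.
#' @export
postexp_power <- function(fit, alpha = 0.01,
                          alternative = c("two.sided", "greater", "less"),
                          ci = FALSE, ci_reps = 500L, ci_level = 0.95,
                          K = 10L, seed = NULL) {
  stopifnot(inherits(fit, "segmented_fit"))
  alternative <- match.arg(alternative)
  ev <- eigen(fit$cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1)))
    stop("covariance of (delta_hat, psi_hat) is not positive semi-definite")
  zspec <- covariate_spec("explicit", values = fit$z)
  mk <- function(delta, psi)
    power_spec(psi = psi, delta = delta, sigma = fit$sigma_hat, n = fit$n,
               alpha = alpha, alternative = alternative, covariate = zspec,
               K = K)
  zr <- range(fit$z)
  eps <- 1e-6 * diff(zr)
  point <- seg_power(mk(fit$delta_hat,
                        min(max(fit$psi_hat, zr[1] + eps), zr[2] - eps)))
  out <- list(power = point, alpha = alpha, alternative = alternative)
  if (ci) {
    if (!is.null(seed)) set.seed(seed)
    covm <- (fit$cov + t(fit$cov)) / 2
    draws <- MASS::mvrnorm(ci_reps, mu = c(fit$delta_hat, fit$psi_hat),
                           Sigma = covm)
    pw <- apply(draws, 1, function(par) {
      psi <- par[2]
      att <- 0L
      while ((psi <= zr[1] || psi >= zr[2]) && att < 10L) {
        psi <- MASS::mvrnorm(1, mu = c(fit$delta_hat, fit$psi_hat),
                             Sigma = covm)[2]
        att <- att + 1L
      }
      psi <- min(max(psi, zr[1] + eps), zr[2] - eps)
      seg_power(mk(par[1], psi))
    })
    out$ci <- unname(stats::quantile(pw, c((1 - ci_level) / 2,
                                           1 - (1 - ci_level) / 2)))
    out$ci_level <- ci_level
    out$ci_reps <- ci_reps
  }
  class(out) <- "postexp_power"
  out
}

#' @export
print.postexp_power <- function(x, ...) {
  cat(sprintf("Post-experimental power: %.4f (alpha = %g, %s)\n",
              x$power, x$alpha, x$alternative))
  if (!is.null(x$ci))
    cat(sprintf("%.0f%% interval from %d parameter draws: (%.3f, %.3f)\n",
                100 * x$ci_level, x$ci_reps, x$ci[1], x$ci[2]))
  invisible(x)
}
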