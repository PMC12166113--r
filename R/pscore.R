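#' Hat (projection) operator of the null model
#'
#' For the gaussian family this is the ordinary least-squares hat matrix
#' `X (X'X)^-1 X'`; for the binomial family it is the IRLS-weighted
#' projection `X (X'WX)^-1 X'W` of the null logistic fit, with
#' `W = diag(mu(1-mu))` evaluated at the null fitted probabilities.  Both
#' satisfy `A X = X`; the gaussian operator is in addition symmetric and
#' idempotent.
#'
#' @param X full-column-rank design matrix.
#' @param family `"gaussian"` or `"binomial"`.
#' @param y response vector; required for the binomial family (the weights
#'   come from the null fit).
#' @return An `n x n` matrix.
#' @export
hat_projection_h0 <- function(X, family = c("gaussian", "binomial"),
                              y = NULL) {
  family <- match.arg(family)
  X <- as.matrix(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    nm <- colnames(X)
    if (is.null(nm)) nm <- paste0("x", seq_len(ncol(X)))
    bad <- nm[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  if (family == "gaussian") {
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    return(tcrossprod(Q))
  }
  if (is.null(y)) stop("binomial hat operator needs the response 'y'")
  fit <- stats::glm.fit(X, y, family = stats::binomial())
  w <- fit$fitted.values * (1 - fit$fitted.values)
  XtW <- t(X * w)
  X %*% solve(XtW %*% X, XtW)
}

#' Pseudo-score statistic for a changepoint
#'
#' Computes the score-type statistic
#' \deqn{s_0 = \bar\varphi^T (I - A) y \; / \;
#'       \{\sigma^2 \bar\varphi^T (I - A) \bar\varphi\}^{1/2}}
#' where \eqn{\bar\varphi} is the changepoint basis averaged over the
#' candidate grid and `A` the null-model hat operator.  Under the null
#' hypothesis of no changepoint, `s0` is (asymptotically, when the error
#' variance is estimated or the response is binomial) standard normal.
#'
#' For the binomial family the statistic is the standard GLM score test of
#' the added variable \eqn{\bar\varphi} in the null logistic model:
#' numerator \eqn{\bar\varphi^T(y - \hat\mu_0)}, denominator
#' \eqn{\{\bar\varphi^T(W - WX(X'WX)^{-1}X'W)\bar\varphi\}^{1/2}}.
#'
#' Degenerate inputs (constant response with an estimated variance, or
#' \eqn{\bar\varphi} lying in the column span of the design) yield
#' `s0 = 0`, `p = 1` and a `"degenerate"` warning flag rather than an
#' error, so that simulation loops stay alive.
#'
#' @param series a [cp_series()] object.
#' @param spec a [phi_spec()] object.
#' @param sigma2_source `"h0_estimate"` (residual variance of the null fit,
#'   divisor `n - p`), `"h1_estimate"` (residual variance of the null fit
#'   augmented with the averaged basis, divisor `n - p - 1`), or
#'   `"known"` (supply `sigma2`).  Ignored for the binomial family, where
#'   the variance function plays the role of `sigma2`.
#' @param sigma2 known error variance, when `sigma2_source = "known"`.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return An object of class `"cp_score_test"` with components
#'   `statistic` (`s0`), `p_value`, `alternative`, `sigma2`,
#'   `sigma2_source`, `psi_grid`, `phi_kind`, `psi_hat` (`NA` here; filled
#'   by [pscore_test()]), `n`, `family` and `warnings`.
#' @export
pscore_statistic <- function(series, spec,
                             sigma2_source = c("h0_estimate", "h1_estimate",
                                               "known"),
                             sigma2 = NULL,
                             alternative = c("two.sided", "greater", "less")) {
  stopifnot(inherits(series, "cp_series"), inherits(spec, "phi_spec"))
  sigma2_source <- match.arg(sigma2_source)
  alternative <- match.arg(alternative)
  y <- series$y; X <- series$X; n <- series$n
  phibar <- build_phibar(series$z, spec)
  warn <- character(0)

  if (series$family == "gaussian") {
    qx <- qr(X)
    rphi <- qr.resid(qx, phibar)
    ry <- qr.resid(qx, y)
    quad <- sum(rphi^2)                       # phibar' (I-A) phibar
    if (sigma2_source == "known") {
      if (is.null(sigma2) || sigma2 <= 0)
        stop("sigma2_source = 'known' requires a positive 'sigma2'")
      s2 <- sigma2
    } else if (sigma2_source == "h0_estimate") {
      s2 <- sum(ry^2) / (n - ncol(X))
    } else {
      ra <- qr.resid(qr(cbind(X, phibar)), y)
      s2 <- sum(ra^2) / (n - ncol(X) - 1L)
    }
    den2 <- s2 * quad
    scale <- max(sum(phibar^2), 1) * max(stats::var(y), 1e-16)
    if (!is.finite(den2) || den2 <= 1e-12 * scale) {
      warn <- c(warn, "degenerate")
      s0 <- 0
      s2 <- max(s2, 0)
    } else {
      s0 <- sum(rphi * y) / sqrt(den2)
    }
  } else {
    fit <- stats::glm.fit(X, y, family = stats::binomial())
    mu <- fit$fitted.values
    w <- mu * (1 - mu)
    sw <- sqrt(w)
    rphi_w <- qr.resid(qr(X * sw), phibar * sw)
    den2 <- sum(rphi_w^2)
    if (!is.finite(den2) || den2 <= 1e-12 * max(sum(phibar^2), 1)) {
      warn <- c(warn, "degenerate")
      s0 <- 0
    } else {
      s0 <- sum(phibar * (y - mu)) / sqrt(den2)
    }
    s2 <- 1          # variance function takes the place of sigma^2
  }

  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(s0)),
              greater   = stats::pnorm(s0, lower.tail = FALSE),
              less      = stats::pnorm(s0))
  if (length(warn)) p <- 1
  structure(list(statistic = s0, p_value = p, alternative = alternative,
                 sigma2 = s2, sigma2_source = sigma2_source,
                 psi_grid = spec$psi_grid, phi_kind = spec$kind,
                 psi_hat = NA_real_, n = n, family = series$family,
                 warnings = warn),
            class = "cp_score_test")
}

#' Pseudo-score test for the existence of a changepoint
#'
#' High-level interface: builds the default candidate grid
#' ([default_psi_grid()]), computes the pseudo-score statistic and its
#' normal-reference p-value, and profiles a changepoint-location estimate
#' over a fine candidate grid.
#'
#' @inheritParams pscore_statistic
#' @param K size of the candidate grid for the averaged basis.
#' @param kind changepoint basis, `"jump"` (default; matches the jump-point
#'   model for time-ordered sequences) or `"segmented"` (broken line).
#' @param psi_grid optional explicit candidate grid overriding the default.
#' @return A `"cp_score_test"` object (see [pscore_statistic()]) with
#'   `psi_hat` filled in.
#' @examples
#' set.seed(1)
#' s <- gen_normal_jump(50, delta = 1)
#' pscore_test(s)
#' @export
pscore_test <- function(series,
                        alternative = c("two.sided", "greater", "less"),
                        K = 10L,
                        sigma2_source = c("h0_estimate", "h1_estimate",
                                          "known"),
                        sigma2 = NULL,
                        kind = c("jump", "segmented"),
                        psi_grid = NULL) {
  stopifnot(inherits(series, "cp_series"))
  alternative <- match.arg(alternative)
  sigma2_source <- match.arg(sigma2_source)
  kind <- match.arg(kind)
  if (is.null(psi_grid)) psi_grid <- default_psi_grid(series$z, K)
  spec <- phi_spec(kind, psi_grid)
  res <- pscore_statistic(series, spec, sigma2_source, sigma2, alternative)
  res$psi_hat <- if (length(res$warnings)) NA_real_ else
    estimate_changepoint(series, kind = kind,
                         sigma2_source = sigma2_source, sigma2 = sigma2)
  res
}

#' Profile estimate of the changepoint location
#'
#' Scans a candidate grid and returns the candidate maximizing the squared
#' single-candidate pseudo-score statistic (the averaged basis collapsed to
#' one value).  Ties are broken by the smallest candidate; if every
#' candidate is degenerate (e.g., constant response) the estimate is `NA`
#' with a warning.
#'
#' @inheritParams pscore_statistic
#' @param candidates candidate changepoint values; defaults to the
#'   midpoints between consecutive distinct `z` values within the 10--90
#'   percentile range of `z`.
#' @param kind changepoint basis.
#' @return A single numeric value (or `NA`).
#' @export
estimate_changepoint <- function(series, candidates = NULL,
                                 kind = c("jump", "segmented"),
                                 sigma2_source = c("h0_estimate",
                                                   "h1_estimate", "known"),
                                 sigma2 = NULL) {
  stopifnot(inherits(series, "cp_series"))
  kind <- match.arg(kind)
  sigma2_source <- match.arg(sigma2_source)
  if (is.null(candidates)) candidates <- profile_grid(series$z)
  if (any(candidates <= min(series$z)) || any(candidates >= max(series$z)))
    stop("candidate changepoints must lie strictly inside range(z)")
  stat2 <- vapply(candidates, function(pk) {
    r <- pscore_statistic(series, phi_spec(kind, pk), sigma2_source, sigma2)
    if (length(r$warnings)) NA_real_ else r$statistic^2
  }, numeric(1))
  if (all(is.na(stat2))) {
    warning("all candidate statistics are degenerate; changepoint estimate is NA")
    return(NA_real_)
  }
  candidates[which.max(stat2)]   # which.max: first (smallest) on ties
}

# midpoints between consecutive distinct z values, trimmed to the middle
# 10-90 percentile band; canonical for the jump basis, whose statistic is
# constant between data points
profile_grid <- function(z) {
  zs <- sort(unique(z))
  mid <- (zs[-1] + zs[-length(zs)]) / 2
  q <- stats::quantile(z, c(0.10, 0.90), names = FALSE, type = 7)
  keep <- mid >= q[1] & mid <= q[2]
  if (!any(keep)) mid else mid[keep]
}

# midpoints plus the interior data values themselves: the ramp basis
# (z - psi)_+ varies continuously in psi and breakpoints frequently sit on
# observed covariate values
segmented_profile_grid <- function(z) {
  zs <- sort(unique(z))
  g <- sort(unique(c((zs[-1] + zs[-length(zs)]) / 2,
                     zs[-c(1L, length(zs))])))
  q <- stats::quantile(z, c(0.10, 0.90), names = FALSE, type = 7)
  keep <- g >= q[1] & g <= q[2]
  if (!any(keep)) g else g[keep]
}

#' @export
print.cp_score_test <- function(x, ...) {
  cat("\n\tPseudo-score test for a changepoint\n\n")
  cat(sprintf("family: %s, basis: %s, n = %d\n", x$family, x$phi_kind, x$n))
  cat(sprintf("s0 = %.4f, p-value = %.6g (%s)\n",
              x$statistic, x$p_value, x$alternative))
  if (!is.na(x$psi_hat))
    cat(sprintf("estimated changepoint: %.4g\n", x$psi_hat))
  cat(sprintf("candidate grid: K = %d in [%.4g, %.4g]; sigma2 = %.4g (%s)\n",
              length(x$psi_grid), min(x$psi_grid), max(x$psi_grid),
              x$sigma2, x$sigma2_source))
  if (length(x$warnings))
    cat("warnings:", paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}
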