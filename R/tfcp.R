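#' Two-sample t statistic at a fixed split point
#'
#' The pooled-variance two-sample t statistic comparing the first `j`
#' observations with the remaining `n - j`:
#' \deqn{t_{jn} = \sqrt{j(n-j)/n}\,(\bar Y_{jn} - \bar Y^*_{jn})/s_{jn}}
#' with the pooled variance on `n - 2` degrees of freedom.  If both
#' segments are constant (`s = 0`) the statistic is defined as 0 and a
#' warning is issued.
#'
#' @param y numeric vector, length `n >= 3`.
#' @param j split index, `1 <= j <= n - 1` (last observation of the first
#'   segment).
#' @return The t statistic (signed).
#' @export
two_sample_t_at <- function(y, j) {
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations")
  j <- as.integer(j)
  if (j < 1L || j > n - 1L) stop("'j' must be in 1..(n-1)")
  m1 <- mean(y[1:j]); m2 <- mean(y[(j + 1):n])
  s2 <- (sum((y[1:j] - m1)^2) + sum((y[(j + 1):n] - m2)^2)) / (n - 2)
  if (s2 <= 0) {
    if (m1 != m2) warning("zero pooled variance with unequal means")
    return(0)
  }
  sqrt(j * (n - j) / n) * (m1 - m2) / sqrt(s2)
}

# Critical values of the maximum |t| changepoint statistic, by sample size
# and level; linear interpolation in n between tabulated rows.
wmax_table <- data.frame(
  n     = seq(10L, 50L, by = 5L),
  a0.10 = c(3.14, 2.97, 2.90, 2.89, 2.86, 2.88, 2.88, 2.86, 2.87),
  a0.05 = c(3.66, 3.36, 3.28, 3.23, 3.19, 3.21, 3.17, 3.18, 3.16),
  a0.01 = c(4.93, 4.32, 4.13, 3.94, 3.86, 3.87, 3.77, 3.79, 3.79)
)

#' Critical value of the maximum-|t| changepoint test
#'
#' Tabulated for `n` in 10..50 and levels 0.10, 0.05, 0.01; values at
#' non-tabulated `n` are linearly interpolated.  Outside the tabulated
#' range no value is returned: either restrict `n` to 10..50 or calibrate
#' the critical value by Monte-Carlo simulation.
#'
#' @param n sample size in `[10, 50]`.
#' @param alpha one of 0.10, 0.05, 0.01.
#' @return The critical value.
#' @export
wmax_critical_value <- function(n, alpha = 0.05) {
  col <- c("0.1" = "a0.10", "0.05" = "a0.05", "0.01" = "a0.01")[
    as.character(alpha)]
  if (is.na(col))
    stop("critical values are tabulated for alpha in {0.10, 0.05, 0.01}")
  if (n < 10 || n > 50)
    stop("critical values are tabulated for n in [10, 50]; for other n ",
         "simulate the null distribution or restrict the sample")
  stats::approx(wmax_table$n, wmax_table[[col]], xout = n)$y
}

#' Maximum two-sample-t changepoint test for normal sequences
#'
#' Scans every split point `j = 1..n-1`, takes the maximum absolute pooled
#' two-sample t statistic, and rejects when it exceeds the tabulated
#' critical value.
#'
#' @param y numeric vector, `n >= 4` (critical values require
#'   `10 <= n <= 50`).
#' @param alpha level, one of 0.10, 0.05, 0.01.
#' @return An object of class `"cp_classic_test"` with components
#'   `statistic`, `changepoint_index` (last pre-change observation,
#'   smallest on ties), `critical_value`, `alpha`, `reject`, `method`,
#'   `n`.
#' @examples
#' set.seed(2)
#' wmax_test(c(rnorm(10), rnorm(10, 3)))
#' @export
wmax_test <- function(y, alpha = 0.05) {
  n <- length(y)
  if (n < 4L) stop("need at least 4 observations")
  tj <- vapply(seq_len(n - 1L), function(j) abs(two_sample_t_at(y, j)),
               numeric(1))
  jstar <- which.max(tj)
  crit <- wmax_critical_value(n, alpha)
  structure(list(statistic = tj[jstar], changepoint_index = jstar,
                 critical_value = crit, alpha = alpha,
                 reject = tj[jstar] > crit, method = "wmax", n = n),
            class = "cp_classic_test")
}

#' Rasch / 3PL item bank
#'
#' Holds the item parameters of the logistic item-response model
#' \deqn{P_i(\theta) = c_i + (1 - c_i)\,
#'       \frac{\exp\{a_i(\theta - b_i)\}}{1 + \exp\{a_i(\theta - b_i)\}}.}
#' The Rasch case has all `a = 1` and `c = 0`.
#'
#' @param b difficulty vector.
#' @param a discrimination (scalar or vector, default 1).
#' @param c guessing (scalar or vector, default 0).
#' @return An object of class `"rasch_bank"`.
#' @export
rasch_item_bank <- function(b, a = 1, c = 0) {
  b <- as.numeric(b)
  if (length(b) < 1L || anyNA(b) || any(!is.finite(b)))
    stop("'b' must be a finite difficulty vector")
  a <- rep_len(as.numeric(a), length(b))
  c <- rep_len(as.numeric(c), length(b))
  if (any(c < 0 | c >= 1)) stop("guessing parameters must lie in [0, 1)")
  structure(list(b = b, a = a, c = c, n = length(b)), class = "rasch_bank")
}

#' Item response probabilities
#'
#' @param bank a [rasch_item_bank()].
#' @param theta ability (scalar).
#' @param items item indices (default all).
#' @return Vector of probabilities of a correct response.
#' @export
rasch_prob <- function(bank, theta, items = seq_len(bank$n)) {
  b <- bank$b[items]; a <- bank$a[items]; c <- bank$c[items]
  c + (1 - c) * stats::plogis(a * (theta - b))
}

#' Bernoulli log-likelihood of a response pattern
#'
#' @param scores 0/1 response vector aligned with the bank.
#' @param bank a [rasch_item_bank()].
#' @param theta ability.
#' @param items item indices over which to sum (default all).
#' @return The log-likelihood.
#' @export
rasch_loglik <- function(scores, bank, theta, items = seq_len(bank$n)) {
  if (!all(scores[items] %in% c(0, 1))) stop("scores must be 0/1")
  if (!is.finite(theta)) stop("'theta' must be finite")
  # Rasch (c = 0) path in log space for numerical stability
  if (all(bank$c[items] == 0)) {
    eta <- bank$a[items] * (theta - bank$b[items])
    return(sum(scores[items] * stats::plogis(eta, log.p = TRUE) +
               (1 - scores[items]) * stats::plogis(-eta, log.p = TRUE)))
  }
  p <- rasch_prob(bank, theta, items)
  sum(scores[items] * log(p) + (1 - scores[items]) * log1p(-p))
}

#' Maximum-likelihood ability estimate
#'
#' Maximizes the Bernoulli log-likelihood over `theta` in `[-6, 6]`
#' (tolerance 1e-8).  All-correct / all-incorrect patterns push the
#' estimate to the bound; such estimates carry the attribute
#' `"boundary" = TRUE`.
#'
#' @inheritParams rasch_loglik
#' @return The ability estimate, with attribute `"loglik"` (the maximized
#'   log-likelihood) and `"boundary"`.
#' @export
mle_theta <- function(scores, bank, items = seq_len(bank$n)) {
  if (length(items) < 1L) stop("need at least one item")
  bound <- 6
  if (all(scores[items] == 1)) {
    th <- bound
  } else if (all(scores[items] == 0)) {
    th <- -bound
  } else {
    th <- stats::optimize(function(t) rasch_loglik(scores, bank, t, items),
                          c(-bound, bound), maximum = TRUE,
                          tol = 1e-8)$maximum
  }
  structure(th, loglik = rasch_loglik(scores, bank, th, items),
            boundary = abs(th) >= bound - 1e-6)
}

#' Trimmed likelihood-ratio changepoint test for binary Rasch sequences
#'
#' For each candidate split `j` in the trimmed range
#' `[n1, n - n1]` (with `n1` the nearest integer to `0.15 n`, ties rounded
#' away from zero), compares segment-wise ability MLEs against the pooled
#' MLE:
#' \deqn{L_{jn} = 2\{\ell(\hat\theta_1; 1..j) + \ell(\hat\theta_2; j+1..n)
#'       - \ell(\hat\theta_0; 1..n)\} \ge 0.}
#' The statistic is the maximum over `j`; the null is rejected above the
#' tabulated critical value 8.85 (trimming fraction 0.15, level 0.05 — the
#' only tabulated level).  Item difficulties are treated as known
#' (calibrated), the usual computerized-adaptive-testing setting.
#'
#' @param scores 0/1 response vector, `n >= 10`.
#' @param bank a [rasch_item_bank()] with Rasch parameters (`a = 1`,
#'   `c = 0`).
#' @param alpha must be 0.05.
#' @return A `"cp_classic_test"` object (`method = "lmax"`) with the extra
#'   components `n1` and `search_range`.
#' @export
lmax_test <- function(scores, bank, alpha = 0.05) {
  stopifnot(inherits(bank, "rasch_bank"))
  if (alpha != 0.05)
    stop("the critical value of the trimmed LRT is tabulated only for alpha = 0.05")
  n <- length(scores)
  if (n < 10L) stop("need at least 10 items")
  if (n != bank$n) stop("scores and item bank differ in length")
  if (!all(bank$a == 1) || !all(bank$c == 0))
    stop("the trimmed LRT likelihood is the Rasch model (a = 1, c = 0)")
  n1 <- round_half_away(0.15 * n)
  js <- n1:(n - n1)
  l0 <- attr(mle_theta(scores, bank), "loglik")
  L <- vapply(js, function(j) {
    l1 <- attr(mle_theta(scores, bank, 1:j), "loglik")
    l2 <- attr(mle_theta(scores, bank, (j + 1):n), "loglik")
    2 * (l1 + l2 - l0)
  }, numeric(1))
  k <- which.max(L)
  structure(list(statistic = L[k], changepoint_index = js[k],
                 critical_value = 8.85, alpha = alpha,
                 reject = L[k] > 8.85, method = "lmax", n = n,
                 n1 = n1, search_range = range(js)),
            class = "cp_classic_test")
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.cp_classic_test <- function(x, ...) {
  lab <- c(wmax = "Maximum two-sample-t changepoint test",
           lmax = "Trimmed Rasch likelihood-ratio changepoint test")[x$method]
  cat("\n\t", lab, "\n\n", sep = "")
  cat(sprintf("statistic = %.4f, critical value = %.2f (alpha = %.2f), %s\n",
              x$statistic, x$critical_value, x$alpha,
              if (x$reject) "reject H0" else "do not reject H0"))
  cat(sprintf("changepoint index (last pre-change observation): %d of %d\n",
              x$changepoint_index, x$n))
  if (!is.null(x$n1))
    cat(sprintf("trimmed search range: [%d, %d]\n",
                x$search_range[1], x$search_range[2]))
  invisible(x)
}
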