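#' Construct a changepoint series
#'
#' Bundles a univariate response together with the ordered covariate that is
#' suspected of carrying a changepoint, an optional design matrix of
#' additional non-segmented covariates, and the response family.
#'
#' The covariate `z` defaults to the scaled observation index `i/n`, the
#' natural choice when the observations form a time-ordered sequence.  The
#' design matrix `X` always contains an intercept column; further columns
#' (for instance the covariate itself, when the null model is a straight
#' line rather than a constant) may be supplied via `X`.
#'
#' @param y numeric response vector of length `n >= 4`; for
#'   `family = "binomial"` the values must be 0/1.
#' @param z numeric covariate vector of the same length; defaults to
#'   `seq_along(y) / length(y)`.
#' @param X optional numeric matrix of additional non-segmented covariates
#'   (`n` rows).  An intercept column is prepended unless one is already
#'   present in its column span.
#' @param family `"gaussian"` or `"binomial"`.
#' @return An object of class `"cp_series"`: a list with components `y`,
#'   `z`, `X`, `family` and `n`.
#' @examples
#' s <- cp_series(rnorm(20))
#' s
#' @export
cp_series <- function(y, z = NULL, X = NULL,
                      family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 4L) stop("need at least 4 observations, got ", n)
  if (anyNA(y)) stop("missing values in 'y' are not supported")
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial responses must be coded 0/1")
  if (is.null(z)) z <- seq_len(n) / n
  z <- as.numeric(z)
  if (length(z) != n) stop("'y' and 'z' must have the same length")
  if (anyNA(z)) stop("missing values in 'z' are not supported")
  if (diff(range(z)) <= 0)
    stop("'z' must not be constant")
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("'X' must have ", n, " rows")
    if (anyNA(X)) stop("missing values in 'X' are not supported")
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    # prepend intercept unless the constant vector already lies in span(X)
    fit <- stats::lm.fit(X, rep(1, n))
    if (max(abs(fit$residuals)) > 1e-8)
      X <- cbind("(Intercept)" = 1, X)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(y = y, z = z, X = X, family = family, n = n),
            class = "cp_series")
}

#' @export
print.cp_series <- function(x, ...) {
  cat(sprintf("Changepoint series: n = %d, family = %s\n", x$n, x$family))
  cat(sprintf("  z range: [%.4g, %.4g]; design columns: %s\n",
              min(x$z), max(x$z), paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

#' Read a changepoint series from a delimited text file
#'
#' Expects a header with a `y` column and, optionally, a `z` column; absent
#' `z` the scaled row index `i/n` is used.  The delimiter is a tab for
#' `.tsv` files and a comma otherwise.  Missing values are rejected.
#'
#' @param path file path.
#' @param family response family, passed to [cp_series()].
#' @return A `"cp_series"` object.
#' @export
read_series <- function(path, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  dat <- read_delim_auto(path)
  if (!"y" %in% names(dat)) stop("input file must contain a 'y' column")
  z <- if ("z" %in% names(dat)) dat$z else NULL
  if (anyNA(dat)) stop("missing values in ", path, " are not supported")
  cp_series(dat$y, z = z, family = family)
}

#' Read a Rasch item bank from a delimited text file
#'
#' Expects a header with a `b` (difficulty) column.
#'
#' @param path file path.
#' @return A `"rasch_bank"` object, see [rasch_item_bank()].
#' @export
read_item_bank <- function(path) {
  dat <- read_delim_auto(path)
  if (!"b" %in% names(dat)) stop("item-bank file must contain a 'b' column")
  rasch_item_bank(dat$b)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = TRUE)
}
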