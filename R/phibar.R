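#' Specify the changepoint basis function and its candidate grid
#'
#' The segmented term of the model is `phi(z, psi)`, either the jump
#' indicator `I(z > psi)` (`kind = "jump"`) or the broken-line ramp
#' `(z - psi)_+` (`kind = "segmented"`).  Because the changepoint `psi` is
#' unknown, the test works with the basis averaged over a grid of `K`
#' candidate values.
#'
#' @param kind `"jump"` or `"segmented"`.
#' @param psi_grid strictly increasing numeric vector of candidate
#'   changepoints; each must lie strictly inside the covariate range when
#'   the basis is evaluated.
#' @return An object of class `"phi_spec"`.
#' @export
phi_spec <- function(kind = c("jump", "segmented"), psi_grid) {
  kind <- match.arg(kind)
  psi_grid <- as.numeric(psi_grid)
  if (length(psi_grid) < 1L) stop("'psi_grid' must contain at least one value")
  if (anyNA(psi_grid)) stop("'psi_grid' must be finite")
  if (is.unsorted(psi_grid, strictly = TRUE))
    stop("'psi_grid' must be strictly increasing")
  structure(list(kind = kind, psi_grid = psi_grid), class = "phi_spec")
}

#' Default candidate-changepoint grid
#'
#' `K` values placed at equally spaced quantiles of `z` between its 10th
#' and 90th percentiles.  Trimming keeps candidates away from the covariate
#' boundaries, where a changepoint is indistinguishable from an intercept
#' shift; duplicated quantiles (possible for heavily tied `z`) are dropped.
#'
#' @param z covariate vector.
#' @param K number of candidate values (default 10).
#' @return Strictly increasing numeric vector of candidates.
#' @export
default_psi_grid <- function(z, K = 10L) {
  if (K < 1L) stop("'K' must be at least 1")
  g <- as.numeric(stats::quantile(z, seq(0.10, 0.90, length.out = K),
                                  names = FALSE, type = 7))
  g <- unique(g)
  g <- g[g > min(z) & g < max(z)]
  if (length(g) == 0L)
    stop("no admissible candidate changepoints strictly inside range(z)")
  g
}

#' Average the changepoint basis over the candidate grid
#'
#' Returns the vector with elements `mean_k phi(z_i, psi_k)`.  For the jump
#' basis each element lies in `[0, 1]` and the vector is non-decreasing in
#' `z`.
#'
#' @param z covariate vector.
#' @param spec a [phi_spec()] object.
#' @return Numeric vector of the same length as `z`.
#' @export
build_phibar <- function(z, spec) {
  stopifnot(inherits(spec, "phi_spec"))
  grid <- spec$psi_grid
  if (any(grid <= min(z)) || any(grid >= max(z)))
    stop("candidate changepoints must lie strictly inside (min(z), max(z))")
  basis <- vapply(grid, function(pk) {
    if (spec$kind == "jump") as.numeric(z > pk) else pmax(z - pk, 0)
  }, numeric(length(z)))
  rowMeans(matrix(basis, nrow = length(z)))
}
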