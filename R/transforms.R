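## Monotone scale transformations: Box-Cox power family and RINT.

#' Box-Cox power transformation
#'
#' \eqn{(y^\lambda - 1)/\lambda} for \eqn{\lambda \neq 0} and \eqn{\log y}
#' at \eqn{\lambda = 0}. Strictly increasing in \code{y} for every lambda,
#' so ranks are preserved; \eqn{\lambda = 1} is an affine map (no real
#' transformation). Defined only for strictly positive \code{y} — no
#' automatic shifting is applied, because a silent shift would change the
#' scale being tested.
#'
#' @param y strictly positive numeric vector.
#' @param lam transformation parameter lambda; |lam| < 1e-12 is treated as 0
#'   to avoid catastrophic cancellation.
#' @return transformed vector.
#' @examples
#' boxCox(c(1, 4), 1)   # c(0, 3)
#' boxCox(exp(1), 0)    # 1
#' @export
boxCox <- function(y, lam) {
  if (!is.numeric(y)) stop("y must be numeric")
  if (anyNA(y)) stop("y must not contain missing values")
  if (any(y <= 0))
    stop(sprintf(
      "Box-Cox requires a strictly positive phenotype (defined for Y' > 0); smallest value is %g",
      min(y)))
  if (abs(lam) < 1e-12) log(y) else (y^lam - 1) / lam
}

#' Evenly spaced lambda grid for Box-Cox profiling
#'
#' Defaults to 25 points between -1 and 2 (spacing 0.125), which contains
#' both the log scale (lambda = 0) and the untransformed scale (lambda = 1)
#' exactly.
#'
#' @param lo,hi grid endpoints, \code{lo < hi}.
#' @param nPoints number of grid points (>= 2), both endpoints included.
#' @return numeric vector of lambdas.
#' @export
lambdaGrid <- function(lo = -1, hi = 2, nPoints = 25) {
  if (!(lo < hi)) stop("lo must be < hi")
  if (nPoints < 2) stop("nPoints must be >= 2")
  seq(lo, hi, length.out = nPoints)
}

#' Rank inverse normal transformation (RINT)
#'
#' Maps phenotype ranks to Gaussian quantiles using the Blom offset:
#' \eqn{\Phi^{-1}((r_i - 3/8)/(n + 1/4))}, with ties given their mean rank.
#' The output is a monotone recoding of \code{y}, so it is identical for any
#' strictly increasing transformation of the input.
#'
#' @param y finite numeric vector of length >= 2; ties permitted.
#' @return transformed vector with approximately standard-normal quantiles.
#' @export
rint <- function(y) {
  if (!is.numeric(y)) stop("y must be numeric")
  if (anyNA(y) || any(!is.finite(y))) stop("y must be finite")
  n <- length(y)
  if (n < 2) stop("RINT needs at least 2 observations")
  r <- rank(y, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Apply a named transformation
#'
#' Dispatch helper for the transformation family used in profiling:
#' \code{"box_cox"} (requires \code{lam}), \code{"rint"} or
#' \code{"identity"}.
#'
#' @param y numeric vector (strictly positive for \code{"box_cox"}).
#' @param kind one of \code{"box_cox"}, \code{"rint"}, \code{"identity"}.
#' @param lam Box-Cox parameter, required (and finite) when
#'   \code{kind = "box_cox"}.
#' @return transformed vector.
#' @export
applyTransform <- function(y, kind = c("box_cox", "rint", "identity"), lam = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    box_cox = {
      if (is.null(lam) || !is.finite(lam)) stop("box_cox requires a finite lambda")
      boxCox(y, lam)
    },
    rint = rint(y),
    identity = y
  )
}
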