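#' Normalized first-order Legendre basis
#'
#' Evaluates the orthonormal Legendre polynomials of order 0 and 1 on the
#' standardized environmental gradient: \eqn{\phi_0 = \sqrt{1/2}} and
#' \eqn{\phi_1(x) = \sqrt{3/2}\,x}. The basis is orthonormal on
#' \eqn{[-1, 1]}, i.e. \eqn{\int \phi_i \phi_j = \delta_{ij}}. The
#' normalized (not raw \eqn{(1, x)}) basis is used throughout the package,
#' for both the fixed regression and the random intercept/slope terms; the
#' across-environment genetic correlations derived from a fitted model
#' depend on this choice.
#'
#' @param x Numeric vector of standardized covariate values in \eqn{[-1, 1]}.
#' @return A numeric matrix with columns `phi0` and `phi1`, one row per
#'   element of `x`.
#' @examples
#' legendre_basis(c(-1, 0, 1))
#' @export
legendre_basis <- function(x) {
  if (!is.numeric(x)) hn_abort("`x` must be numeric.", "heatnorm_domain_error")
  if (any(!is.finite(x)) || any(abs(x) > 1 + 1e-8)) {
    hn_abort("standardized covariate values must lie in [-1, 1].",
             "heatnorm_domain_error")
  }
  cbind(phi0 = rep(sqrt(0.5), length(x)), phi1 = sqrt(1.5) * x)
}
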