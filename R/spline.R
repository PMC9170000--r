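#' Cubic B-spline basis for the within-shift trend
#'
#' Evaluates a clamped B-spline basis on the within-shift time axis. The
#' basis is the standard Cox-de Boor construction (evaluated via
#' [splines::splineDesign()]): all values are non-negative and, at any
#' point of the domain, the basis functions sum to one. With `n_knots`
#' interior knots and degree `degree` the basis has
#' `n_knots + degree + 1` columns.
#'
#' @param t evaluation times in minutes from shift start.
#' @param domain numeric length-2 domain `(0, shift length)`.
#' @param n_knots number of equally spaced interior knots (default 8).
#' @param degree polynomial degree (default 3, cubic).
#' @return matrix `length(t)` x `n_knots + degree + 1`.
#' @export
#' @examples
#' B <- spline_basis(c(0, 90, 180), domain = c(0, 360))
#' rowSums(B)  # partition of unity
spline_basis <- function(t, domain = c(0, 360), n_knots = 8L, degree = 3L) {
  stopifnot(length(domain) == 2L, domain[2] > domain[1], n_knots >= 1L)
  tol <- 1e-8 * (domain[2] - domain[1])
  if (any(t < domain[1] - tol) || any(t > domain[2] + tol)) {
    abort(sprintf("evaluation times outside the basis domain [%g, %g].",
                  domain[1], domain[2]),
          class = "subwaypm_extrapolation_error")
  }
  t <- pmin(pmax(t, domain[1]), domain[2])
  interior <- seq(domain[1], domain[2], length.out = n_knots + 2L)[-c(1L, n_knots + 2L)]
  knots <- c(rep(domain[1], degree + 1L), interior, rep(domain[2], degree + 1L))
  B <- splines::splineDesign(knots, x = t, ord = degree + 1L, outer.ok = FALSE)
  colnames(B) <- sprintf("b%02d", seq_len(ncol(B)))
  B
}
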