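# Quadrature over the exponential signal law.  Integrals of the form
# int_0^inf f(h) lambda e^{-lambda h} dh are computed by Gauss-Laguerre
# quadrature under the substitution x = lambda h, which absorbs the
# exponential weight exactly; the remaining integrands (activation
# probabilities, entropies of mixtures) are smooth and bounded.

#' Quadrature rule for the exponential signal law
#'
#' Nodes and weights such that \code{sum(w * f(h))} approximates the
#' expectation of \code{f} under an exponential law with rate \code{lambda}.
#'
#' @param lambda rate of the exponential signal law (1/mean signal), > 0.
#' @param n number of Gauss-Laguerre nodes.
#' @return list with numeric vectors \code{h} (nodes) and \code{w}
#'   (weights, summing to 1 up to quadrature truncation).
#' @export
signal_quadrature <- function(lambda, n = 512) {
  stopifnot(lambda > 0, n >= 2)
  key <- as.character(n)
  rule <- .quad_cache[[key]]
  if (is.null(rule)) {
    rule <- pracma::gaussLaguerre(n)
    .quad_cache[[key]] <- rule
  }
  list(h = rule$x / lambda, w = rule$w)
}

.quad_cache <- new.env(parent = emptyenv())

# Convergence check: doubling the node count must leave the value of the
# functional unchanged within tol.  `fun(quad)` evaluates the functional.
.quad_converged <- function(fun, lambda, n, tol = 1e-6) {
  v1 <- fun(signal_quadrature(lambda, n))
  v2 <- fun(signal_quadrature(lambda, 2 * n))
  if (!all(abs(v1 - v2) <= tol * pmax(1, abs(v1))))
    stop("numerical-accuracy error: signal quadrature did not converge ",
         "(node doubling changed the result by more than ", tol, ")")
  v2
}
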