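#' Gauss-Hermite quadrature for standard-normal integrals
#'
#' Nodes and weights for approximating \eqn{\int f(\theta)\phi(\theta)d\theta}
#' where \eqn{\phi} is the standard normal density. Physicists' Gauss-Hermite
#' rules (from \code{pracma::gaussHermite}) are rescaled to the probabilist
#' convention; weights are renormalised to sum to exactly 1 so that discrete
#' posterior weights behave as probabilities.
#'
#' @param n number of nodes (default 21).
#' @return list with \code{nodes} (length-n numeric, symmetric about 0) and
#'   \code{weights} (positive, summing to 1).
#' @examples
#' q <- gh_quadrature(21)
#' sum(q$weights * q$nodes^2)  # ~ Var of N(0,1) = 1
#' @export
gh_quadrature <- function(n = 21) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  gh <- pracma::gaussHermite(as.integer(n))
  nodes <- gh$x * sqrt(2)
  weights <- gh$w / sqrt(pi)
  # symmetrise against round-off so identical seeds give bit-identical grids
  ord <- order(nodes)
  nodes <- nodes[ord]
  weights <- weights[ord]
  weights <- weights / sum(weights)
  list(nodes = nodes, weights = weights)
}

# Tensor-product grid over d dimensions of a 1-D rule; returns matrix of node
# coordinates (prod(n)^d rows) and the product weights (normalised).
gh_grid <- function(n1d, d) {
  q <- gh_quadrature(n1d)
  grids <- rep(list(q$nodes), d)
  Z <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  dimnames(Z) <- NULL
  W <- rep(list(q$weights), d)
  w <- Reduce(function(a, b) as.vector(outer(a, b)), W)
  w <- w / sum(w)
  list(nodes = Z, weights = w)
}
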