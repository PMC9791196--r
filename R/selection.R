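#' Model-selection indices
#'
#' The four information criteria used for comparing calibrated models:
#' \deqn{AIC = -2\ell + 2p, \quad BIC = -2\ell + p\log N,}
#' \deqn{SABIC = -2\ell + p\log((N + 2)/24), \quad
#'       HQ = -2\ell + 2p\log\log N,}
#' where \eqn{\ell} is the converged marginal log-likelihood, \eqn{p} the
#' number of free parameters, and \eqn{N} the number of persons. Smaller is
#' better for all four; they differ only in how strongly extra parameters are
#' penalised.
#'
#' @param object an \code{\link{irt_fit}} object, or a numeric
#'   log-likelihood.
#' @param ... further arguments for methods.
#' @return named numeric vector \code{c(AIC, SABIC, HQ, BIC)}.
#' @examples
#' fit_indices(-100, p = 10, n = 100)
#' @export
fit_indices <- function(object, ...) UseMethod("fit_indices")

#' @rdname fit_indices
#' @param p number of free parameters (p >= 1).
#' @param n number of persons (n >= 2; n >= 3 for HQ, which needs
#'   log log n > 0).
#' @export
fit_indices.default <- function(object, p, n, ...) {
  loglik <- as.numeric(object)
  stopifnot(is.finite(loglik), p >= 1, n >= 2)
  if (n < 3)
    stop("HQ is undefined for n < 3 (log log n <= 0)")
  dev <- -2 * loglik
  c(AIC = dev + 2 * p,
    SABIC = dev + p * log((n + 2) / 24),
    HQ = dev + 2 * p * log(log(n)),
    BIC = dev + p * log(n))
}

#' @rdname fit_indices
#' @export
fit_indices.irt_fit <- function(object, ...) {
  fit_indices(object$loglik, p = object$n_params, n = object$N)
}

#' Compare competing fitted models
#'
#' Tabulates AIC, SABIC, HQ and BIC for several fits of the same data and
#' flags the best (smallest) model under each index. Ties are broken toward
#' the model with fewer parameters.
#'
#' @param ... \code{\link{irt_fit}} objects (optionally named), or a single
#'   list of them.
#' @return object of class \code{irt_fit_comparison}: the index table
#'   (\code{indices}), \code{best_by_index}, and the per-model parameter
#'   counts.
#' @export
compare_fits <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "irt_fit")) fits <- fits[[1]]
  if (!all(vapply(fits, inherits, logical(1), "irt_fit")))
    stop("all arguments must be irt_fit objects")
  nm <- names(fits)
  if (is.null(nm) || any(nm == ""))
    nm <- vapply(fits, function(f) f$model, character(1))
  names(fits) <- nm
  Ns <- vapply(fits, function(f) f$N, numeric(1))
  nobs <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(Ns)) != 1L || length(unique(nobs)) != 1L)
    stop("fits were not computed on the same data ",
         "(person or observed-cell counts differ)")
  tab <- t(vapply(fits, fit_indices, numeric(4)))
  p <- vapply(fits, function(f) f$n_params, numeric(1))
  best <- apply(tab, 2, function(col) {
    cand <- which(col <= min(col) + 1e-9)
    cand[which.min(p[cand])]
  })
  structure(list(indices = tab, best_by_index = structure(nm[best],
                 names = colnames(tab)), n_params = p, N = Ns[1]),
            class = "irt_fit_comparison")
}

#' @export
print.irt_fit_comparison <- function(x, ...) {
  tab <- cbind(p = x$n_params, round(x$indices, 1))
  cat("Model comparison (N =", x$N, "persons):\n")
  print(tab)
  cat("best by index:",
      paste(names(x$best_by_index), x$best_by_index, sep = "=",
            collapse = "  "), "\n")
  invisible(x)
}
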