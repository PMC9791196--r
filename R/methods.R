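#' @export
print.irt_fit <- function(x, ...) {
  cat(x$model, "model fitted by MML-EM (", x$N, "persons,", x$M, "items )\n")
  cat(sprintf("  log-likelihood %.2f  (%d parameters, %s in %d cycles)\n",
              x$loglik, x$n_params,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  if (x$model == "MIRT")
    cat("  latent correlations: ",
        paste(sprintf("%.2f", x$Sigma[upper.tri(x$Sigma)]), collapse = " "),
        "\n")
  invisible(x)
}

#' @export
summary.irt_fit <- function(object, ...) {
  it <- object$items
  out <- list(model = object$model, N = object$N, M = object$M,
              loglik = object$loglik, n_params = object$n_params,
              converged = object$converged, n_iter = object$n_iter,
              indices = fit_indices(object),
              slopes = rbind(
                general = summary(it$a0[it$a0 != 0 | object$model != "MIRT"]),
                specific = summary(it$av[it$av != 0 |
                                         object$model != "UIRT"])),
              Sigma = object$Sigma, warnings = object$warnings)
  class(out) <- "summary.irt_fit"
  out
}

#' @export
print.summary.irt_fit <- function(x, ...) {
  cat(x$model, "calibration:", x$N, "persons,", x$M, "items\n")
  cat(sprintf("  log-likelihood %.2f | parameters %d | %s (%d EM cycles)\n",
              x$loglik, x$n_params,
              if (x$converged) "converged" else "not converged", x$n_iter))
  cat("  fit indices:\n")
  print(round(x$indices, 2))
  cat("  slope distributions:\n")
  print(round(x$slopes, 3))
  if (!is.null(x$Sigma)) {
    cat("  latent correlation matrix:\n")
    print(round(x$Sigma, 3))
  }
  if (length(x$warnings)) cat("  warnings:", x$warnings, sep = "\n   ")
  invisible(x)
}

#' @export
coef.irt_fit <- function(object, ...) object$items

#' @export
logLik.irt_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$N,
            class = "logLik")
}

#' EAP ability estimates for an irt_fit
#'
#' @param object an \code{\link{irt_fit}}.
#' @param newdata optional response matrix to score instead of the
#'   calibration data.
#' @param type "eap" returns the posterior-mean matrix, "psd" the posterior
#'   standard deviations.
#' @param ... unused.
#' @return persons x factors numeric matrix.
#' @export
predict.irt_fit <- function(object, newdata = NULL,
                            type = c("eap", "psd"), ...) {
  type <- match.arg(type)
  eap_matrix(object, newdata)[[type]]
}

#' Simulate response data from a fitted model
#'
#' Draws new abilities from the latent distribution (standard normal factors;
#' the estimated correlation matrix for MIRT) and new responses from the
#' estimated item parameters, preserving the observed missing-by-design
#' pattern of the calibration data.
#'
#' @param object an \code{\link{irt_fit}}.
#' @param nsim number of replicate data sets.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of integer response matrices.
#' @export
simulate.irt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  N <- object$N
  D <- object$n_domains
  inc <- !is.na(object$responses)
  items <- object$items
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    theta <- switch(object$model,
      FIBF = matrix(rnorm(N * (D + 1)), N, D + 1),
      UIRT = matrix(rnorm(N), N, 1),
      MIRT = matrix(rnorm(N * D), N, D) %*% chol(object$Sigma))
    X <- matrix(NA_integer_, N, object$M,
                dimnames = dimnames(object$responses))
    for (j in seq_len(object$M)) {
      obs <- which(inc[, j])
      it <- items[j, ]
      eta <- switch(object$model,
        FIBF = it$a0 * theta[obs, 1] + it$av * theta[obs, 1 + it$domain],
        UIRT = it$a0 * theta[obs, 1],
        MIRT = it$av * theta[obs, it$domain])
      u <- runif(length(obs))
      x <- integer(length(obs))
      for (k in seq_len(it$K - 1L))
        x <- x + (u < plogis(eta + it[[paste0("b", k)]]))
      X[obs, j] <- x
    }
    out[[s]] <- X
  }
  out
}

#' Score residuals of a fitted model
#'
#' Observed category code minus its model-expected value at the person's EAP
#' ability, for every observed cell (NA elsewhere). Useful as a rough
#' item-fit diagnostic.
#'
#' @param object an \code{\link{irt_fit}}.
#' @param ... unused.
#' @return persons x items numeric matrix.
#' @export
residuals.irt_fit <- function(object, ...) {
  eap <- eap_matrix(object)$eap
  items <- object$items
  res <- matrix(NA_real_, object$N, object$M,
                dimnames = dimnames(object$responses))
  for (j in seq_len(object$M)) {
    obs <- which(!is.na(object$responses[, j]))
    if (!length(obs)) next
    it <- items[j, ]
    eta <- switch(object$model,
      FIBF = it$a0 * eap[obs, 1] + it$av * eap[obs, 1 + it$domain],
      UIRT = it$a0 * eap[obs, 1],
      MIRT = it$av * eap[obs, it$domain])
    expected <- 0
    for (k in seq_len(it$K - 1L))
      expected <- expected + plogis(eta + it[[paste0("b", k)]])
    res[obs, j] <- object$responses[obs, j] - expected
  }
  res
}

#' Plot method for irt_fit objects
#'
#' \code{type = "trace"} shows the EM log-likelihood trace;
#' \code{type = "icc"} draws the category characteristic curves of one item
#' against the factor it loads on (other factors at 0).
#'
#' @param x an \code{\link{irt_fit}}.
#' @param type "trace" or "icc".
#' @param item item index or id for \code{type = "icc"}.
#' @param ... passed to the underlying plotting functions.
#' @export
plot.irt_fit <- function(x, type = c("trace", "icc"), item = 1L, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    graphics::plot(seq_along(x$trace), x$trace, type = "b", pch = 16,
                   cex = 0.6, xlab = "EM cycle",
                   ylab = "marginal log-likelihood", ...)
    return(invisible(x))
  }
  if (is.character(item)) item <- match(item, x$items$item_id)
  it <- x$items[item, ]
  th <- seq(-4, 4, length.out = 161)
  slope <- if (x$model == "MIRT") it$av else it$a0
  cum <- vapply(seq_len(it$K - 1L),
                function(k) plogis(slope * th + it[[paste0("b", k)]]),
                numeric(length(th)))
  P <- cbind(1 - cum[, 1], cum)
  if (it$K > 2L)
    for (k in 2L:(it$K - 1L)) P[, k] <- cum[, k - 1L] - cum[, k]
  graphics::matplot(th, P, type = "l", lty = 1, lwd = 2,
                    xlab = expression(theta), ylab = "category probability",
                    main = it$item_id, ...)
  invisible(x)
}
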