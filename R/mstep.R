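# M-step: weighted maximum likelihood for one item's logistic / graded
# logistic model given expected category counts on the quadrature grid.
#
# r  : G x K expected counts (E-step sufficient statistics)
# Z  : G x p_s latent covariate design (theta coordinates at the grid points)
# par: c(slopes, b_1..b_{K-1}) with b strictly decreasing for K > 2
#
# Fisher scoring with step-halving; slopes box-constrained to `bounds`.
# An intercept ordering violation makes some category probability negative,
# which sends the objective to -Inf and is rejected by the halving line
# search, so the canonical decreasing order is preserved.

glogit_probs <- function(par, Z, K) {
  p_s <- ncol(Z)
  eta <- as.vector(Z %*% par[seq_len(p_s)])
  b <- par[p_s + seq_len(K - 1L)]
  s <- plogis(outer(eta, b, "+"))          # G x (K-1) cumulative P(X >= k)
  P <- cbind(1 - s[, 1L], s, deparse.level = 0)
  if (K > 2L)
    for (k in 2L:(K - 1L)) P[, k] <- s[, k - 1L] - s[, k]
  P
}

glogit_Q <- function(par, Z, K, r) {
  P <- glogit_probs(par, Z, K)
  if (any(P[r > 0] <= 0)) return(-Inf)
  sum(r[r > 0] * log(P[r > 0]))
}

fit_item_glogit <- function(r, Z, par, K, bounds = c(-10, 10),
                            max_iter = 25L, gtol = 1e-8) {
  p_s <- ncol(Z)
  np <- p_s + K - 1L
  cum_probs <- function(par) plogis(outer(as.vector(Z %*% par[seq_len(p_s)]),
                                          par[p_s + seq_len(K - 1L)], "+"))
  cat_probs <- function(s) {
    P <- cbind(1 - s[, 1L], s, deparse.level = 0)
    if (K > 2L)
      for (k in 2L:(K - 1L)) P[, k] <- s[, k - 1L] - s[, k]
    P
  }
  Qfun <- function(P) {
    if (any(P[r > 0] <= 0)) return(-Inf)
    sum(r[r > 0] * log(P[r > 0]))
  }
  s <- cum_probs(par)
  P <- cat_probs(s)
  Q_old <- Qfun(P)
  n_g <- rowSums(r)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d <- s * (1 - s)                        # G x (K-1)
    U <- r / pmax(P, 1e-300)                # G x K, zero where r = 0
    U[r == 0] <- 0

    # gradient: d log L / d s_m = u_{m+1} - u_m, chain through d_m
    Gm <- d * (U[, 2:K, drop = FALSE] - U[, 1:(K - 1L), drop = FALSE])
    grad <- c(colSums(Z * rowSums(Gm)), colSums(Gm))
    if (max(abs(grad)) < gtol) { converged <- TRUE; break }

    # expected (Fisher) information of the complete-data likelihood
    info <- matrix(0, np, np)
    for (cc in seq_len(K)) {
      V <- matrix(0, nrow(Z), np)
      if (cc > 1L) {
        V[, seq_len(p_s)] <- V[, seq_len(p_s)] + Z * d[, cc - 1L]
        V[, p_s + cc - 1L] <- d[, cc - 1L]
      }
      if (cc < K) {
        V[, seq_len(p_s)] <- V[, seq_len(p_s)] - Z * d[, cc]
        V[, p_s + cc] <- -d[, cc]
      }
      wgt <- n_g / pmax(P[, cc], 1e-12)
      info <- info + crossprod(V, V * wgt)
    }
    step <- tryCatch(solve(info + diag(1e-8, np), grad),
                     error = function(e) grad / max(1, max(abs(diag(info)))))
    lambda <- 1
    improved <- FALSE
    for (h in seq_len(20L)) {
      cand <- pmin(pmax(par + lambda * step, bounds[1]), bounds[2])
      if (K > 2L && any(diff(cand[p_s + seq_len(K - 1L)]) >= 0))
        cand[p_s + seq_len(K - 1L)] <- cand[p_s + seq_len(K - 1L)] -
          (seq_len(K - 1L) - 1L) * 1e-6  # break clipping-induced ties
      s_new <- cum_probs(cand)
      P_new <- cat_probs(s_new)
      Q_new <- Qfun(P_new)
      if (is.finite(Q_new) && Q_new >= Q_old - 1e-12) {
        par <- cand
        Q_old <- Q_new
        s <- s_new                          # reuse for the next gradient
        P <- P_new
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break                    # cannot improve further
  }
  bounded <- any(par <= bounds[1] + 1e-9) || any(par >= bounds[2] - 1e-9)
  list(par = par, Q = Q_old, converged = converged, bounded = bounded)
}
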