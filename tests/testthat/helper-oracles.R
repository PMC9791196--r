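# Independent oracles and small fixtures, coded without reusing the package
# internals they are meant to check.

# category probabilities straight from the model equations
oracle_item_prob <- function(theta0, thetav, a0, av, b) {
  eta <- a0 * theta0 + av * thetav
  cum <- c(1, exp(eta + b) / (1 + exp(eta + b)), 0)
  -diff(cum)
}

# brute-force marginal log-likelihood over a full (1 + D)-dimensional
# tensor quadrature grid (no bifactor reduction)
oracle_loglik_full_grid <- function(X, items, n_nodes, n_domains = 5) {
  q <- bifactorirt::gh_quadrature(n_nodes)
  dims <- rep(list(q$nodes), 1 + n_domains)
  grid <- as.matrix(expand.grid(dims))
  wg <- Reduce(function(a, b) as.vector(outer(a, b)),
               rep(list(q$weights), 1 + n_domains))
  ll <- 0
  for (i in seq_len(nrow(X))) {
    if (all(is.na(X[i, ]))) next
    Lg <- rep(1, nrow(grid))
    for (j in seq_len(ncol(X))) {
      x <- X[i, j]
      if (is.na(x)) next
      it <- items[j, ]
      eta <- it$a0 * grid[, 1] + it$av * grid[, 1 + it$domain]
      bks <- as.numeric(it[paste0("b", seq_len(it$K - 1))])
      cum <- cbind(1, plogis(outer(eta, bks, "+")), 0)
      p <- cum[, x + 1] - cum[, x + 2]
      Lg <- Lg * p
    }
    ll <- ll + log(sum(wg * Lg))
  }
  ll
}

# naive double-loop recovery metrics
oracle_armse <- function(est, truth) {
  G <- nrow(est); M <- ncol(est)
  tm <- if (is.matrix(truth)) truth else
    matrix(truth, G, M, byrow = TRUE)
  total <- 0
  for (j in seq_len(M)) {
    s <- 0
    for (g in seq_len(G)) s <- s + (est[g, j] - tm[g, j])^2
    total <- total + sqrt(s / G)
  }
  total / M
}

oracle_acor <- function(est, truth) {
  G <- nrow(est)
  tm <- if (is.matrix(truth)) truth else
    matrix(truth, G, ncol(est), byrow = TRUE)
  s <- 0
  for (g in seq_len(G)) s <- s + cor(est[g, ], tm[g, ])
  s / G
}

# small mixed-format item table (2 dichotomous + 2 graded, two domains)
tiny_items <- function() {
  out <- data.frame(
    item_id = c("d1", "d2", "g1", "g2"),
    item_type = c("dichotomous", "dichotomous", "graded", "graded"),
    K = c(2L, 2L, 3L, 3L),
    domain = c(1L, 2L, 1L, 2L),
    a0 = c(1.2, 0.9, 1.6, 1.1),
    av = c(0.8, 0.5, 0.4, 1.0),
    b1 = c(0.3, -0.5, 0.2, -0.1),
    b2 = c(NA, NA, -0.9, -1.4))
  attr(out, "model") <- "FIBF"
  out
}

# small complete-data response fixture aligned with tiny_items()
tiny_responses <- function() {
  X <- matrix(c(1L, 0L, 2L, 1L,
                0L, 1L, 0L, 2L,
                1L, NA, 1L, 0L,
                0L, 0L, NA, NA,
                NA, NA, NA, NA), 5, 4, byrow = TRUE)
  colnames(X) <- c("d1", "d2", "g1", "g2")
  X
}
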