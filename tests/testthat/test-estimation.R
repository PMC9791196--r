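# shared small bifactor data set used by several estimation tests
sim_small <- local({
  d <- build_design(n_persons = 800)
  sim <- sim_study("FIBF", d, seed = 2718)
  list(d = d, sim = sim)
})
# one shared calibration of the small data set, reused across blocks
fit_fibf_shared <- irt_fit(sim_small$sim$responses, "FIBF",
                           domains = sim_small$d$items$domain,
                           K = sim_small$d$items$K, tol = 1e-3,
                           max_iter = 200)

test_that("dimension-reduced likelihood equals brute-force tensor quadrature", {
  set.seed(314)
  d <- build_design(n_persons = 6)
  items <- sim_item_params("FIBF", d)[c(1, 2, 7, 20), ]  # spans 2 domains
  X <- matrix(c(1L, 0L, 2L, 1L,
                0L, 1L, 0L, 0L,
                1L, NA, 1L, NA,
                NA, NA, NA, NA,
                0L, 0L, 2L, 1L,
                1L, 1L, NA, 0L), 6, 4, byrow = TRUE)
  colnames(X) <- items$item_id
  for (nq in c(7, 11)) {
    ll_brute <- oracle_loglik_full_grid(X, items, nq)
    ll_red <- marginal_loglik(X, items, "FIBF", quad_nodes = nq,
                              n_domains = 5)
    expect_equal(ll_red, ll_brute, tolerance = 1e-8)
  }
})

test_that("constrained bifactor likelihoods collapse to UIRT, and empty data to 0", {
  items <- tiny_items()
  X <- tiny_responses()
  u <- transform(items, av = 0)
  attr(u, "model") <- "FIBF"
  ll_f <- marginal_loglik(X, u, "FIBF", quad_nodes = 15, n_domains = 5)
  uu <- u; attr(uu, "model") <- "UIRT"
  ll_u <- marginal_loglik(X, uu, "UIRT", quad_nodes = 15)
  expect_equal(ll_f, ll_u, tolerance = 1e-10)

  empty <- matrix(NA_integer_, 3, 4,
                  dimnames = list(NULL, items$item_id))
  expect_identical(marginal_loglik(empty, items, "FIBF", n_domains = 5), 0)
})

test_that("EM is monotone, reaches a fixed point, and beats the truth", {
  d <- sim_small$d; sim <- sim_small$sim
  fit <- fit_fibf_shared
  expect_true(all(diff(fit$trace) > -1e-6))
  expect_true(fit$converged)
  # loglik at the fit exceeds loglik at the generating parameters
  ll_truth <- marginal_loglik(sim$responses, sim$items, "FIBF",
                              n_domains = 5)
  expect_gte(fit$loglik, ll_truth)
  # refitting from the solution moves the loglik less than tol
  refit <- suppressWarnings(
    irt_fit(sim$responses, "FIBF", domains = d$items$domain,
            K = d$items$K, tol = 1e-3, max_iter = 5, init = fit$items))
  expect_lt(abs(refit$trace[1] - fit$loglik), 1e-3)
})

test_that("a tiny three-item calibration still dominates the truth", {
  set.seed(99)
  d <- build_design(n_persons = 30)
  items <- sim_item_params("FIBF", d)[c(1, 2, 7), ]
  th <- sim_abilities("FIBF", 30, 5)$theta
  X <- cbind(
    rbinom(30, 1, plogis(items$a0[1] * th[, 1] + items$av[1] * th[, 1 + items$domain[1]] + items$b1[1])),
    rbinom(30, 1, plogis(items$a0[2] * th[, 1] + items$av[2] * th[, 1 + items$domain[2]] + items$b1[2])),
    rbinom(30, 1, plogis(items$a0[3] * th[, 1] + items$av[3] * th[, 1 + items$domain[3]] + items$b1[3])))
  storage.mode(X) <- "integer"
  colnames(X) <- items$item_id
  fit <- suppressWarnings(
    irt_fit(X, "FIBF", domains = items$domain, K = items$K, tol = 1e-5,
            max_iter = 300, n_domains = 5))
  it_true <- items
  it_true$K <- 2L  # all responses dichotomous here
  it_true$item_type <- "dichotomous"
  it_true$b2 <- NULL
  ll_truth <- marginal_loglik(X, it_true, "FIBF", n_domains = 5)
  expect_gte(fit$loglik, ll_truth - 1e-6)
})

test_that("nested models are ordered in converged log-likelihood", {
  d <- sim_small$d; sim <- sim_small$sim
  fitF <- fit_fibf_shared
  fitU <- suppressWarnings(irt_fit(sim$responses, "UIRT", K = d$items$K,
                                   tol = 1e-3, max_iter = 200))
  fitM <- suppressWarnings(irt_fit(sim$responses, "MIRT",
                                   domains = d$items$domain, K = d$items$K,
                                   tol = 1e-3, max_iter = 200))
  eps <- 10 * 1e-3
  expect_gte(fitF$loglik, fitU$loglik - eps)
  expect_gte(fitF$loglik, fitM$loglik - eps)
  expect_true(all(diff(fitU$trace) > -1e-6))
  expect_true(all(diff(fitM$trace) > -1e-6))
})

test_that("EAP scores: prior for empty patterns, monotone in evidence, accurate", {
  d <- sim_small$d; sim <- sim_small$sim
  fit <- fit_fibf_shared
  X <- sim$responses
  X[1, ] <- NA  # person with no data
  sc <- predict(fit, newdata = X)
  psd <- predict(fit, newdata = X, type = "psd")
  expect_equal(unname(sc[1, ]), rep(0, 6))
  expect_equal(unname(psd[1, ]), rep(1, 6))

  # a single answered dichotomous item with positive slope pulls the
  # general score above the prior mean
  one <- matrix(NA_integer_, 1, fit$M,
                dimnames = list("p1", fit$items$item_id))
  j <- which(fit$items$item_type == "dichotomous" & fit$items$a0 > 0.5)[1]
  one[1, j] <- 1L
  expect_gt(predict(fit, newdata = one)[1, "general"], 0)

  # general score tracks the generating ability
  sc_all <- predict(fit)
  expect_gt(cor(sc_all[, "general"], sim$theta[, 1]), 0.8)
})

test_that("bifactor EAP score vectors are near-orthogonal under identity truth", {
  fit <- fit_fibf_shared
  sc <- predict(fit)
  cc <- cor(sc)
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.15))
})

test_that("degenerate inputs are handled as specified", {
  X <- tiny_responses()
  X[, 2] <- NA
  expect_error(irt_fit(X, "UIRT"), "without any observed response")
  X2 <- tiny_responses()
  X2[1, 1] <- 5L
  expect_error(irt_fit(X2, "UIRT", K = c(2L, 2L, 3L, 3L)), "exceed")
  # item answered identically by everyone: slope is bounded, fit flagged
  set.seed(10)
  X3 <- cbind(const = rep(1L, 120),
              v = rbinom(120, 1, 0.5), w = rbinom(120, 1, 0.4))
  expect_warning(f <- irt_fit(X3, "UIRT", tol = 1e-4, max_iter = 50),
                 "bound")
  expect_true(length(f$warnings) >= 1)
})
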