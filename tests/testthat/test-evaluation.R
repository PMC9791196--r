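test_that("ARMSE matches its definition and the naive oracle", {
  expect_equal(armse(matrix(c(1.3, 2.4), 1), c(1, 2)), 0.35)
  truth <- c(0.5, 1, 1.5)
  est <- matrix(truth, 4, 3, byrow = TRUE)
  expect_equal(armse(est, truth), 0)
  # constant bias c reduces ARMSE to |c|
  expect_equal(armse(est - 0.7, truth), 0.7)
  expect_equal(armse(est + 0.2, truth), 0.2)
  set.seed(42)
  for (i in 1:10) {
    G <- sample(1:6, 1); M <- sample(3:8, 1)
    e <- matrix(rnorm(G * M), G, M)
    t1 <- rnorm(M)
    expect_equal(armse(e, t1), oracle_armse(e, t1), tolerance = 1e-12)
    tm <- matrix(rnorm(G * M), G, M)
    expect_equal(armse(e, tm), oracle_armse(e, tm), tolerance = 1e-12)
  }
  expect_error(armse(matrix(0, 2, 3), c(1, 2)), "length")
})

test_that("ACor averages per-replication Pearson correlations", {
  truth <- c(0.2, 0.9, 1.4, 2.0)
  est <- matrix(truth, 5, 4, byrow = TRUE)
  expect_equal(acor(est, truth), 1)
  expect_equal(acor(-est, truth), -1)
  set.seed(7)
  noisy <- est * 2 + matrix(rnorm(20, sd = 1e-8), 5, 4)
  expect_equal(acor(noisy, truth), 1, tolerance = 1e-6)
  for (i in 1:10) {
    G <- sample(2:5, 1); M <- sample(3:9, 1)
    e <- matrix(rnorm(G * M), G, M)
    t1 <- rnorm(M)
    expect_equal(acor(e, t1), oracle_acor(e, t1), tolerance = 1e-12)
  }
  degenerate <- est
  degenerate[2, ] <- 3
  expect_error(acor(degenerate, truth), "replication 2")
  expect_error(acor(est, rep(1, 4)), "constant")
  expect_error(acor(matrix(0, 2, 2), c(1, 2)), "at least 3")
})

test_that("score correlations align persons by id and bound null correlations", {
  set.seed(8)
  n <- 2000
  ids <- sprintf("p%04d", 1:n)
  a <- setNames(rnorm(n), ids)
  b <- setNames(rnorm(n), ids)
  cc <- score_correlations(list(a = a, b = b, self = a))
  expect_equal(diag(cc), c(a = 1, b = 1, self = 1))
  expect_equal(cc, t(cc))
  expect_equal(cc["a", "self"], 1)
  expect_lt(abs(cc["a", "b"]), 0.07)  # ~3/sqrt(N) null bound
  # alignment by name, not position
  perm <- sample(n)
  expect_equal(score_correlations(list(a = a, b2 = a[perm]))["a", "b2"], 1)
  expect_error(score_correlations(list(x = a[1:2], y = b[1:2])), "3 common")
})

test_that("the replication study pipeline runs end to end at smoke scale", {
  d <- build_design(n_booklets = 4, items_per_booklet = 6, n_dich = 4,
                    n_poly = 2, n_persons = 200, n_domains = 2)
  st <- run_replication_study("UIRT", G = 1, design = d,
                              fit_models = c("UIRT", "MIRT"), seed = 5,
                              tol = 1e-2, max_iter = 60)
  expect_s3_class(st, "replication_study")
  expect_equal(nrow(st$indices), 2)
  expect_true(all(c("AIC", "SABIC", "HQ", "BIC") %in% names(st$indices)))
  expect_false(is.null(st$recovery))
  expect_setequal(st$recovery$table$class, c("a0", "b"))
  expect_true(all(is.finite(st$recovery$table$ARMSE)))
  # identical seed reproduces the study exactly
  st2 <- run_replication_study("UIRT", G = 1, design = d,
                               fit_models = c("UIRT", "MIRT"), seed = 5,
                               tol = 1e-2, max_iter = 60)
  expect_identical(st$indices, st2$indices)
  expect_identical(st$recovery$table, st2$recovery$table)
})

test_that("recovery improves with sample size", {
  # UIRT-only comparison at reduced scale: a 4x sample should not recover
  # worse in any parameter class
  d_small <- build_design(n_persons = 500)
  d_big <- build_design(n_persons = 4000)
  s_small <- run_replication_study("UIRT", G = 3, design = d_small,
                                   fit_models = "UIRT", seed = 17,
                                   tol = 1e-3, max_iter = 200)
  s_big <- run_replication_study("UIRT", G = 3, design = d_big,
                                 fit_models = "UIRT", seed = 17,
                                 tol = 1e-3, max_iter = 200)
  small_tab <- s_small$recovery$table
  big_tab <- s_big$recovery$table
  for (cl in small_tab$class) {
    expect_lt(big_tab$ARMSE[big_tab$class == cl],
              small_tab$ARMSE[small_tab$class == cl])
  }
})

test_that("general-factor scores agree across bifactor and unidimensional fits", {
  d <- build_design(n_persons = 1000)
  sim <- sim_study("FIBF", d, seed = 606)
  fF <- suppressWarnings(irt_fit(sim$responses, "FIBF",
                                 domains = d$items$domain, K = d$items$K,
                                 tol = 1e-3, max_iter = 200))
  fU <- suppressWarnings(irt_fit(sim$responses, "UIRT", K = d$items$K,
                                 tol = 1e-3, max_iter = 200))
  g_f <- predict(fF)[, "general"]
  g_u <- predict(fU)[, "general"]
  r <- score_correlations(list(bifactor_general = g_f, unidimensional = g_u))
  expect_gt(r["bifactor_general", "unidimensional"], 0.9)
})
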